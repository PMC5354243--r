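#' Load and canonicalize a participant metabolite table
#'
#' Reads a delimited text file (CSV, header row) with one participant per row,
#' maps its columns onto the canonical 24-variable panel plus a cohort label
#' column and optional id / Vineland Adaptive Behavior Composite columns, and
#' returns a validated \code{focm_dataset}.
#'
#' Cohort labels are normalized to \code{ASD}, \code{SIB}, \code{NEU}
#' (case-insensitively; a \code{cohort_map} may translate other labels such as
#' "control"). All 24 panel variables must be present and numeric.
#'
#' @param path path to the CSV file.
#' @param schema optional named character vector mapping raw column headers to
#'   canonical names (panel names, "cohort", "id", "vineland").
#' @param cohort_map optional named character vector mapping raw cohort labels
#'   to "ASD"/"SIB"/"NEU".
#' @param on_missing what to do with a row containing a missing metabolite
#'   value: \code{"error"} (default) or \code{"drop"} the sample. Values are
#'   never imputed.
#' @return A \code{focm_dataset}: list with \code{panel} (character),
#'   \code{data} (data.frame of metabolite values, row order preserved),
#'   \code{id}, \code{cohort} (factor ASD/SIB/NEU), \code{vineland} (numeric,
#'   \code{NA} where unrecorded) and \code{provenance}.
#' @export
load_dataset <- function(path, schema = NULL, cohort_map = NULL,
                         on_missing = c("error", "drop")) {
  on_missing <- match.arg(on_missing)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("no samples: '", path, "' contains no data rows")

  resolved <- resolve_panel_names(names(raw), aliases = schema)
  panel <- metabolite_panel()
  missing_cols <- setdiff(panel, resolved)
  if (length(missing_cols))
    stop("missing panel column(s): ", paste(missing_cols, collapse = ", "))
  if (!"cohort" %in% resolved) stop("missing cohort column")

  pick <- function(canonical) raw[[which(resolved == canonical)[1L]]]

  vals <- lapply(panel, function(v) {
    col <- pick(v)
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & col != "" & is.na(num))
    if (length(bad))
      stop("non-numeric value in column '", v, "', row ", bad[1L],
           ": '", col[bad[1L]], "'")
    num
  })
  names(vals) <- panel
  data <- as.data.frame(vals, check.names = FALSE, optional = TRUE)

  cohort_raw <- trimws(as.character(pick("cohort")))
  if (!is.null(cohort_map)) {
    hit <- match(cohort_raw, names(cohort_map))
    cohort_raw[!is.na(hit)] <- cohort_map[hit[!is.na(hit)]]
  }
  cohort <- toupper(cohort_raw)
  unknown <- setdiff(unique(cohort), c("ASD", "SIB", "NEU"))
  if (length(unknown))
    stop("unknown cohort label(s): ", paste(unknown, collapse = ", "))

  id <- if ("id" %in% resolved) as.character(pick("id")) else
    sprintf("S%03d", seq_len(nrow(raw)))
  vineland <- if ("vineland" %in% resolved)
    suppressWarnings(as.numeric(pick("vineland"))) else rep(NA_real_, nrow(raw))

  incomplete <- !stats::complete.cases(data)
  if (any(incomplete)) {
    if (on_missing == "error")
      stop("missing metabolite value(s) in row(s) ",
           paste(utils::head(which(incomplete), 5L), collapse = ", "),
           " (use on_missing = \"drop\" to discard these samples)")
    keep <- !incomplete
    data <- data[keep, , drop = FALSE]
    id <- id[keep]; cohort <- cohort[keep]; vineland <- vineland[keep]
  }

  new_focm_dataset(data, cohort, id = id, vineland = vineland,
                  provenance = list(source = "real", path = path))
}

#' Construct a focm_dataset from in-memory pieces
#'
#' @param data data.frame of metabolite values, columns named by the panel.
#' @param cohort character/factor of labels in ASD/SIB/NEU, one per row.
#' @param id sample identifiers (default generated).
#' @param vineland numeric vector of Vineland composite scores (NA = absent).
#' @param panel panel names (default: \code{colnames(data)}).
#' @param provenance free-form list tag (source = "real"/"synthetic", ...).
#' @return A \code{focm_dataset}.
#' @export
new_focm_dataset <- function(data, cohort, id = NULL, vineland = NULL,
                             panel = colnames(data),
                             provenance = list(source = "unknown")) {
  stopifnot(is.data.frame(data), length(cohort) == nrow(data))
  if (anyDuplicated(panel)) stop("panel names must be unique")
  if (is.null(id)) id <- sprintf("S%03d", seq_len(nrow(data)))
  if (is.null(vineland)) vineland <- rep(NA_real_, nrow(data))
  cohort <- factor(as.character(cohort), levels = c("ASD", "SIB", "NEU"))
  if (anyNA(cohort)) stop("cohort labels must be ASD, SIB or NEU")
  structure(list(panel = panel, data = data, id = as.character(id),
                 cohort = cohort, vineland = as.numeric(vineland),
                 provenance = provenance),
            class = "focm_dataset")
}

#' @export
print.focm_dataset <- function(x, ...) {
  cts <- table(x$cohort)
  cat("focm_dataset:", nrow(x$data), "samples x", length(x$panel),
      "variables\n  cohorts:",
      paste(sprintf("%s=%d", names(cts), cts), collapse = ", "),
      "\n  with Vineland score:", sum(!is.na(x$vineland)),
      "\n  source:", x$provenance$source, "\n")
  invisible(x)
}

#' Cohort sample counts
#' @param ds a \code{focm_dataset}.
#' @return Named integer vector with ASD/SIB/NEU counts.
#' @export
cohort_counts <- function(ds) {
  out <- table(ds$cohort)
  stats::setNames(as.integer(out), names(out))
}

#' Extract the measurement matrix for a cohort/variable subset
#' @param ds a \code{focm_dataset}.
#' @param variables variables to keep (default all).
#' @param cohorts cohorts to keep (default all).
#' @return Numeric matrix with rownames = sample ids.
#' @export
dataset_matrix <- function(ds, variables = ds$panel, cohorts = levels(ds$cohort)) {
  miss <- setdiff(variables, ds$panel)
  if (length(miss)) stop("variable(s) not in panel: ", paste(miss, collapse = ", "))
  keep <- ds$cohort %in% cohorts
  m <- as.matrix(ds$data[keep, variables, drop = FALSE])
  rownames(m) <- ds$id[keep]
  m
}

#' Write a focm_dataset back to CSV
#'
#' Inverse of \code{\link{load_dataset}} up to declared precision; numeric
#' values are written with 15 significant digits so a load/write/load round
#' trip is value-preserving.
#'
#' @param ds a \code{focm_dataset}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_dataset <- function(ds, path) {
  out <- cbind(data.frame(id = ds$id, cohort = as.character(ds$cohort),
                          stringsAsFactors = FALSE),
               ds$data,
               data.frame(vineland = ds$vineland))
  op <- options(digits = 15); on.exit(options(op))
  utils::write.csv(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Validate internal consistency of a loaded panel
#'
#' Report-only check: recomputes each derived ratio variable (SAM/SAH,
#' fGSH/GSSG, tGSH/GSSG, fCystine/fCysteine) from its components and flags rows
#' whose stored ratio deviates by more than \code{rel_tol} relative error, and
#' flags nonpositive values in strictly-positive analytes (all base
#' concentrations; percentage variables may validly be small but not
#' negative).
#'
#' @param ds a \code{focm_dataset}.
#' @param rel_tol relative tolerance for ratio recomputation (default 0.01).
#' @return data.frame of flags (row, id, variable, kind, stored, expected);
#'   zero rows when the panel is consistent. Also serializable via
#'   \code{\link{write_validation_report}}.
#' @export
validate_panel <- function(ds, rel_tol = 0.01) {
  flags <- list()
  for (ratio in names(panel_ratios())) {
    comp <- panel_ratios()[[ratio]]
    if (!all(c(ratio, comp) %in% ds$panel)) next
    stored <- ds$data[[ratio]]
    expect <- ds$data[[comp[1L]]] / ds$data[[comp[2L]]]
    bad <- which(is.finite(stored) & is.finite(expect) &
                   abs(stored - expect) > rel_tol * abs(expect))
    if (length(bad))
      flags[[length(flags) + 1L]] <- data.frame(
        row = bad, id = ds$id[bad], variable = ratio,
        kind = "ratio_mismatch", stored = stored[bad], expected = expect[bad],
        stringsAsFactors = FALSE)
  }
  for (v in ds$panel) {
    bad <- which(is.finite(ds$data[[v]]) & ds$data[[v]] <= 0)
    if (length(bad))
      flags[[length(flags) + 1L]] <- data.frame(
        row = bad, id = ds$id[bad], variable = v,
        kind = "nonpositive", stored = ds$data[[v]][bad],
        expected = NA_real_, stringsAsFactors = FALSE)
  }
  if (!length(flags))
    return(data.frame(row = integer(), id = character(), variable = character(),
                      kind = character(), stored = numeric(),
                      expected = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, flags)
}

#' Serialize a validation report to JSON (and optionally plain text)
#' @param report output of \code{\link{validate_panel}}.
#' @param json_path output JSON path.
#' @param text_path optional plain-text path.
#' @return \code{json_path}, invisibly.
#' @export
write_validation_report <- function(report, json_path, text_path = NULL) {
  jsonlite::write_json(report, json_path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(text_path)) {
    lines <- if (nrow(report) == 0L) "panel consistent: no flags" else
      sprintf("row %d (%s): %s %s stored=%g expected=%g",
              report$row, report$id, report$variable, report$kind,
              report$stored, report$expected)
    writeLines(lines, text_path)
  }
  invisible(json_path)
}
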