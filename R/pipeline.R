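# Orchestration of the full analysis: load/generate -> validate -> full-panel
# classification -> sibling projection -> subset search (exhaustive + greedy
# sibling augmentation) -> final classifier -> regression search. Every stage
# writes its table under the output directory with a stable filename, and a
# rerun with the same config reproduces identical numerics (all stages are
# deterministic given the config seed).

#' Build a run configuration for the analysis pipeline
#'
#' @param input path to a participant CSV, or \code{NULL} to generate
#'   synthetic data from \code{synthetic_cfg}.
#' @param synthetic_cfg a \code{synthetic_config} used when \code{input} is
#'   NULL.
#' @param output_dir directory for stage artifacts (created).
#' @param stages character subset of
#'   \code{c("load","classify","sib","search","final","regress")}.
#' @param classes primary cohort pair.
#' @param search_k_max exhaustive-search size cap (default 3; the full study
#'   sweep uses 6 but costs ~190k combinations on the 24-panel).
#' @param search_pool candidate variables for the searches (default: full
#'   panel).
#' @param sib_extra variables to add greedily for sibling separability
#'   (default 2).
#' @param regress_k_max regression-search size cap (default 3).
#' @param schema,cohort_map passed to \code{\link{load_dataset}}.
#' @param seed recorded seed (the pipeline itself is deterministic; the seed
#'   feeds the synthetic generator).
#' @return A validated \code{run_config} list.
#' @export
run_config <- function(input = NULL, synthetic_cfg = synthetic_config(),
                       output_dir = tempfile("focm_run_"),
                       stages = c("load", "classify", "sib", "search",
                                  "final", "regress"),
                       classes = c("ASD", "NEU"),
                       search_k_max = 3L, search_pool = NULL,
                       sib_extra = 2L, regress_k_max = 3L,
                       schema = NULL, cohort_map = NULL, seed = 1L) {
  if (!length(stages)) stop("stage list is empty")
  stages <- match.arg(stages, several.ok = TRUE)
  if (!is.null(input) && !file.exists(input))
    stop("input file does not exist: ", input)
  if (is.null(input)) synthetic_cfg$seed <- as.integer(seed)
  structure(list(input = input, synthetic_cfg = synthetic_cfg,
                 output_dir = output_dir, stages = stages, classes = classes,
                 search_k_max = as.integer(search_k_max),
                 search_pool = search_pool, sib_extra = as.integer(sib_extra),
                 regress_k_max = as.integer(regress_k_max),
                 schema = schema, cohort_map = cohort_map,
                 seed = as.integer(seed)),
            class = "run_config")
}

.write_table <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# Full classification block for one variable set: LOO scores, per-cohort
# KDEs, frozen full-data threshold, confusion and error curves.
.classification_block <- function(ds, variables, classes) {
  cv <- loo_scores(ds, variables, classes)
  s_pos <- cv$score[cv$cohort == classes[1L]]
  s_neg <- cv$score[cv$cohort == classes[2L]]
  pdf_pos <- estimate_pdf(s_pos, select_bandwidth(s_pos)$sigma_star)
  pdf_neg <- estimate_pdf(s_neg, select_bandwidth(s_neg)$sigma_star)
  roc <- roc_c_statistic(pdf_pos, pdf_neg)
  thr <- decision_threshold(pdf_pos, pdf_neg)
  cm <- confusion_at(cv, positive = classes[1L], threshold = as.numeric(thr))
  list(cv = cv, pdf_pos = pdf_pos, pdf_neg = pdf_neg, roc = roc,
       threshold = thr, confusion = cm,
       errors = error_curves(cv, positive = classes[1L]))
}

#' Run the full analysis workflow
#'
#' Executes the configured stages in order on real or synthetic data and
#' writes each stage's artifact to \code{cfg$output_dir}:
#' \code{dataset.csv}, \code{validation.json}, \code{classify_scores.csv} and
#' \code{classify_confusion.json} (full-panel classification),
#' \code{sib_scores.csv} (sibling projection through the full-panel model),
#' \code{search_curve.csv} (best C-statistic per subset size),
#' \code{final_confusion.json} / \code{final_error_curves.csv} (greedy
#' sibling-augmented final panel), \code{regression_curve.csv} and
#' \code{regression_predictions.csv}.
#'
#' @param cfg a \code{run_config}.
#' @return A \code{focm_report} list holding every stage result and the paths
#'   of the written artifacts.
#' @export
run_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = cfg, artifacts = character(0))
  add_artifact <- function(p) report$artifacts <<- c(report$artifacts, p)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  # load
  gt <- NULL
  ds <- stage("load", {
    if (!is.null(cfg$input)) {
      load_dataset(cfg$input, schema = cfg$schema, cohort_map = cfg$cohort_map)
    } else {
      g <- synthetic_dataset(cfg$synthetic_cfg)
      gt <- g$ground_truth
      g$dataset
    }
  })
  report$dataset <- ds
  report$ground_truth <- gt
  add_artifact(write_dataset(ds, file.path(cfg$output_dir, "dataset.csv")))
  vrep <- validate_panel(ds)
  report$validation <- vrep
  add_artifact(write_validation_report(
    vrep, file.path(cfg$output_dir, "validation.json")))
  pool <- if (is.null(cfg$search_pool)) ds$panel else cfg$search_pool

  if ("classify" %in% cfg$stages) {
    blk <- stage("classify", .classification_block(ds, ds$panel, cfg$classes))
    report$classify <- blk
    add_artifact(.write_table(blk$cv, cfg$output_dir, "classify_scores.csv"))
    add_artifact(write_confusion_summary(
      blk$confusion, file.path(cfg$output_dir, "classify_confusion.json")))
  }

  if ("sib" %in% cfg$stages && any(ds$cohort == "SIB")) {
    sib <- stage("sib", {
      m <- fit_fda(ds, ds$panel, cfg$classes)
      project_external(m, ds, "SIB")
    })
    report$sib_scores <- sib
    add_artifact(.write_table(sib, cfg$output_dir, "sib_scores.csv"))
  }

  if ("search" %in% cfg$stages) {
    sr <- stage("search",
                exhaustive_search(ds, k_max = cfg$search_k_max,
                                  classes = cfg$classes, variables = pool))
    report$search <- sr
    add_artifact(.write_table(search_table(sr), cfg$output_dir,
                              "search_curve.csv"))
  }

  if ("final" %in% cfg$stages) {
    final <- stage("final", {
      base <- if (!is.null(report$search)) {
        sizes <- as.integer(names(report$search$best_by_size))
        report$search$best_by_size[[as.character(max(sizes))]]
      } else {
        combo_c_statistic(ds, pool[seq_len(min(5L, length(pool)))],
                          cfg$classes)
      }
      path <- if (any(ds$cohort == "SIB") && cfg$sib_extra > 0L)
        greedy_extend(ds, base, cfg$sib_extra,
                      criterion = "sib_separability",
                      classes = cfg$classes, pool = pool)
      else list(base)
      vars <- path[[length(path)]]$variables
      c(list(variables = vars, greedy_path = path),
        .classification_block(ds, vars, cfg$classes))
    })
    report$final <- final
    add_artifact(write_confusion_summary(
      final$confusion, file.path(cfg$output_dir, "final_confusion.json")))
    add_artifact(.write_table(final$errors, cfg$output_dir,
                              "final_error_curves.csv"))
  }

  if ("regress" %in% cfg$stages && any(!is.na(ds$vineland))) {
    reg <- stage("regress", {
      rs <- regression_search(ds, k_max = cfg$regress_k_max, variables = pool)
      sizes <- as.integer(names(rs))
      best <- rs[[which.max(vapply(rs, `[[`, numeric(1), "q2"))]]
      list(search = rs, best = best,
           q2 = loo_q2(ds, best$variables))
    })
    report$regress <- reg
    curve <- data.frame(
      size = as.integer(names(reg$search)),
      variables = vapply(reg$search, function(b)
        paste(b$variables, collapse = "; "), character(1)),
      q2 = vapply(reg$search, `[[`, numeric(1), "q2"))
    add_artifact(.write_table(curve, cfg$output_dir, "regression_curve.csv"))
    add_artifact(.write_table(reg$q2$predictions, cfg$output_dir,
                              "regression_predictions.csv"))
  }

  class(report) <- "focm_report"
  report
}

#' @export
print.focm_report <- function(x, ...) {
  cat("focm_report with artifacts:\n")
  for (p in x$artifacts) cat("  ", p, "\n", sep = "")
  if (!is.null(x$classify))
    cat("full-panel C-statistic:",
        format(x$classify$roc$c_statistic, digits = 4), "\n")
  if (!is.null(x$final))
    cat("final panel (", length(x$final$variables), " vars) C-statistic: ",
        format(x$final$roc$c_statistic, digits = 4), "\n", sep = "")
  if (!is.null(x$regress))
    cat("best regression Q2:", format(x$regress$best$q2, digits = 4), "\n")
  invisible(x)
}

#' Minimal command-line entry point
#'
#' Subcommands: \code{simulate} (write a synthetic dataset),
#' \code{run} (full pipeline). Flags: \code{--seed}, \code{--out},
#' \code{--input}, \code{--k-max}, \code{--regress-k-max}.
#'
#' @param args character vector (default: command-line arguments).
#' @return Invisibly, the subcommand's result.
#' @export
focm_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: focm-screen <simulate|run> [--seed N] ...")
  cmd <- args[1L]
  opt <- function(flag, default) {
    i <- which(args == flag)
    if (length(i) && i[1L] < length(args)) args[i[1L] + 1L] else default
  }
  seed <- as.integer(opt("--seed", "1"))
  out <- opt("--out", file.path(getwd(), "focm_out"))
  if (cmd == "simulate") {
    g <- synthetic_dataset(synthetic_config(seed = seed))
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_dataset(g$dataset, file.path(out, "synthetic.csv"))
    jsonlite::write_json(g$ground_truth,
                         file.path(out, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    message("wrote ", file.path(out, "synthetic.csv"))
    invisible(g)
  } else if (cmd == "run") {
    input <- opt("--input", NULL)
    cfg <- run_config(input = input, output_dir = out, seed = seed,
                      search_k_max = as.integer(opt("--k-max", "3")),
                      regress_k_max = as.integer(opt("--regress-k-max", "3")))
    rep <- run_analysis(cfg)
    print(rep)
    invisible(rep)
  } else stop("unknown subcommand: ", cmd)
}
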