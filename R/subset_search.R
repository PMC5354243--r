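# Metabolite subset selection by cross-validated C-statistic: exhaustive
# enumeration of all combinations up to a size cap, then greedy extension —
# either to keep improving ASD-vs-NEU separation or to add variables that
# improve ASD-vs-SIB separability (the step that grows the 5-variable panel
# to the final 7).

#' Cross-validated C-statistic of one variable combination
#'
#' The full per-combination pipeline: leave-one-out discriminant scores for
#' the two classes, an LSCV-bandwidth Gaussian KDE per cohort, and the
#' PDF-based ROC C-statistic.
#'
#' @param ds a \code{focm_dataset}.
#' @param variables panel subset to evaluate.
#' @param classes length-2 cohort pair (default \code{c("ASD","NEU")}).
#' @return A \code{combo_score} list: \code{variables} (in canonical panel
#'   order), \code{classes}, \code{c_statistic}.
#' @export
combo_c_statistic <- function(ds, variables, classes = c("ASD", "NEU")) {
  variables <- .canonical_order(ds, variables)
  cv <- tryCatch(loo_scores(ds, variables, classes),
                 error = function(e)
                   stop("combo {", paste(variables, collapse = ", "), "}: ",
                        conditionMessage(e), call. = FALSE))
  cs <- .scores_c_statistic(cv, classes)
  structure(list(variables = variables, classes = classes, c_statistic = cs),
            class = "combo_score")
}

# KDE + ROC stage shared by the search paths.
.scores_c_statistic <- function(cv, classes) {
  s_pos <- cv$score[cv$cohort == classes[1L]]
  s_neg <- cv$score[cv$cohort == classes[2L]]
  pdf_pos <- estimate_pdf(s_pos, select_bandwidth(s_pos)$sigma_star)
  pdf_neg <- estimate_pdf(s_neg, select_bandwidth(s_neg)$sigma_star)
  roc_c_statistic(pdf_pos, pdf_neg)$c_statistic
}

.canonical_order <- function(ds, variables) {
  variables[order(match(variables, ds$panel))]
}

#' Exhaustive search over all variable combinations up to a size cap
#'
#' Evaluates every subset of sizes 1..\code{k_max} by
#' \code{\link{combo_c_statistic}} and records the best combination per size
#' (the C-statistic-versus-panel-size curve). Ties are broken toward the
#' lexicographically first combination in canonical panel order, so the result
#' is independent of evaluation order.
#'
#' @param ds a \code{focm_dataset}.
#' @param k_max largest subset size (default 6).
#' @param classes cohort pair.
#' @param variables candidate pool (default the full panel).
#' @param keep_all if TRUE, also return every evaluated combination.
#' @param sizes subset sizes to evaluate (default \code{1:k_max}; a subset
#'   thereof restricts the sweep, e.g. to a single size).
#' @return A \code{search_result} list: \code{best_by_size} (list of
#'   \code{combo_score} keyed by size), \code{evaluated_count},
#'   \code{search_mode = "exhaustive"}, optionally \code{all}.
#' @export
exhaustive_search <- function(ds, k_max = 6L, classes = c("ASD", "NEU"),
                              variables = ds$panel, keep_all = FALSE,
                              sizes = seq_len(k_max)) {
  variables <- .canonical_order(ds, variables)
  p <- length(variables)
  stopifnot(k_max >= 1L, k_max <= p, all(sizes >= 1L), all(sizes <= p))
  best <- list()
  all_rows <- if (keep_all) list() else NULL
  count <- 0L
  for (k in sizes) {
    combos <- utils::combn(variables, k, simplify = FALSE)
    best_k <- NULL
    for (combo in combos) {
      cs <- combo_c_statistic(ds, combo, classes)
      count <- count + 1L
      if (keep_all) all_rows[[count]] <- cs
      if (is.null(best_k) || cs$c_statistic > best_k$c_statistic)
        best_k <- cs
    }
    best[[as.character(k)]] <- best_k
  }
  structure(list(best_by_size = best, evaluated_count = count,
                 search_mode = "exhaustive", all = all_rows),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("search_result (", x$search_mode, "), ", x$evaluated_count,
      " combinations evaluated\n", sep = "")
  for (k in names(x$best_by_size)) {
    b <- x$best_by_size[[k]]
    cat(sprintf("  k=%s C=%.4f {%s}\n", k, b$c_statistic,
                paste(b$variables, collapse = ", ")))
  }
  invisible(x)
}

#' Greedy extension of a variable combination
#'
#' Adds \code{k_extra} variables one at a time, each step choosing the
#' candidate that maximizes the criterion:
#' \describe{
#'   \item{\code{"classification"}}{the ASD-vs-NEU cross-validated
#'     C-statistic.}
#'   \item{\code{"sib_separability"}}{the ASD-vs-SIB C-statistic under the
#'     same LOO-FDA + KDE + ROC pipeline, subject to not decreasing the
#'     ASD-vs-NEU C-statistic by more than \code{guard} (default 0.002)
#'     relative to the current set. This is the step that augments the
#'     best classification panel to retain sibling separability.}
#' }
#' Ties are broken by canonical panel order.
#'
#' @param ds a \code{focm_dataset}.
#' @param base a \code{combo_score} (or character vector of variables) to
#'   extend.
#' @param k_extra number of variables to add.
#' @param criterion \code{"classification"} or \code{"sib_separability"}.
#' @param classes primary cohort pair (default \code{c("ASD","NEU")}).
#' @param pool candidate variables (default the full panel).
#' @param guard maximum allowed drop in primary C for sib_separability.
#' @return List of \code{combo_score}s: element 1 is the base, element i+1 the
#'   base plus i added variables; sib criterion scores carry
#'   \code{c_statistic_sib}.
#' @export
greedy_extend <- function(ds, base, k_extra,
                          criterion = c("classification", "sib_separability"),
                          classes = c("ASD", "NEU"), pool = ds$panel,
                          guard = 0.002) {
  criterion <- match.arg(criterion)
  if (is.character(base)) base <- combo_c_statistic(ds, base, classes)
  stopifnot(length(base$variables) >= 1L, k_extra >= 0L)
  remaining <- setdiff(.canonical_order(ds, pool), base$variables)
  if (k_extra > length(remaining))
    stop("k_extra (", k_extra, ") exceeds remaining variables (",
         length(remaining), ")")

  current <- base
  if (criterion == "sib_separability")
    current$c_statistic_sib <-
      combo_c_statistic(ds, current$variables, c(classes[1L], "SIB"))$c_statistic
  out <- list(current)
  for (step in seq_len(k_extra)) {
    cand_primary <- vapply(remaining, function(v)
      combo_c_statistic(ds, c(current$variables, v), classes)$c_statistic,
      numeric(1))
    if (criterion == "classification") {
      pickable <- seq_along(remaining)
      score <- cand_primary
    } else {
      score <- vapply(remaining, function(v)
        combo_c_statistic(ds, c(current$variables, v),
                          c(classes[1L], "SIB"))$c_statistic, numeric(1))
      pickable <- which(cand_primary >= current$c_statistic - guard)
      if (!length(pickable)) pickable <- seq_along(remaining)
    }
    # which.max returns the first maximum; `remaining` is in canonical order
    best_i <- pickable[which.max(score[pickable])]
    v <- remaining[best_i]
    current <- structure(list(
      variables = .canonical_order(ds, c(current$variables, v)),
      classes = classes, c_statistic = cand_primary[[best_i]]),
      class = "combo_score")
    if (criterion == "sib_separability")
      current$c_statistic_sib <- score[[best_i]]
    out[[step + 1L]] <- current
    remaining <- setdiff(remaining, v)
  }
  out
}

#' Tabulate a search result
#' @param sr a \code{search_result}.
#' @return data.frame with columns \code{size}, \code{variables} (collapsed),
#'   \code{c_statistic}.
#' @export
search_table <- function(sr) {
  rows <- lapply(sr$best_by_size, function(b)
    data.frame(size = length(b$variables),
               variables = paste(b$variables, collapse = "; "),
               c_statistic = b$c_statistic, stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
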