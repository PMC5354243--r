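# ROC curve and C-statistic computed from the two fitted score densities
# (not from empirical ranks): tail probabilities P(score > t | cohort) are
# trapezoidal integrals of each KDE above each threshold on a merged grid,
# and the C-statistic is the trapezoidal area under tpr(fpr).

# Survival function P(X > grid[i]) of a density tabulated on grid, by reverse
# cumulative trapezoid.
.tail_prob <- function(grid, dens) {
  seg <- diff(grid) * (utils::head(dens, -1L) + utils::tail(dens, -1L)) / 2
  rev(cumsum(rev(c(seg, 0))))
}

#' ROC curve and C-statistic from two score densities
#'
#' Both densities are re-evaluated exactly on a common grid spanning the union
#' of their supports. For each threshold t the false- and true-positive rates
#' are the tail masses of the negative and positive densities above t; the
#' C-statistic is the area under the ROC curve. If the curve comes out below
#' chance the orientation is flipped (C := 1 - C) and \code{flipped} is set.
#'
#' @param pdf_pos \code{score_distribution} of the positive cohort (ASD).
#' @param pdf_neg \code{score_distribution} of the negative cohort (NEU).
#' @param n_grid merged-grid resolution (default 2048).
#' @return A \code{roc_result} list: \code{thresholds}, \code{fpr}, \code{tpr},
#'   \code{c_statistic}, \code{flipped}.
#' @export
roc_c_statistic <- function(pdf_pos, pdf_neg, n_grid = 2048L) {
  stopifnot(inherits(pdf_pos, "score_distribution"),
            inherits(pdf_neg, "score_distribution"))
  lo <- min(pdf_pos$grid, pdf_neg$grid)
  hi <- max(pdf_pos$grid, pdf_neg$grid)
  grid <- seq(lo, hi, length.out = n_grid)
  dp <- reevaluate_pdf(pdf_pos, grid)$density
  dn <- reevaluate_pdf(pdf_neg, grid)$density
  if (.trapz(grid, dp) < 0.5 || .trapz(grid, dn) < 0.5)
    stop("degenerate (zero-mass) PDF on merged grid")

  tpr <- pmin(1, .tail_prob(grid, dp))
  fpr <- pmin(1, .tail_prob(grid, dn))

  # area under tpr(fpr); fpr decreases with t so integrate in fpr order
  o <- order(fpr)
  auc <- .trapz(fpr[o], tpr[o])
  flipped <- FALSE
  if (auc < 0.5) { auc <- 1 - auc; flipped <- TRUE }
  structure(list(thresholds = grid, fpr = fpr, tpr = tpr,
                 c_statistic = auc, flipped = flipped),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("roc_result: C-statistic =", format(x$c_statistic, digits = 4),
      if (x$flipped) "(orientation flipped)" else "", "\n")
  invisible(x)
}

#' Choose a linear decision threshold from the two densities
#'
#' Equal-density rule: the score where the positive and negative fitted
#' densities cross, searched between the two cohort score means; with several
#' crossings the one nearest the midpoint of the means is used. If no crossing
#' exists in the inter-mean interval the midpoint of the means is returned and
#' the result carries \code{attr(, "fallback") = TRUE} with a warning.
#'
#' @inheritParams roc_c_statistic
#' @return Numeric threshold; attribute \code{fallback} (logical).
#' @export
decision_threshold <- function(pdf_pos, pdf_neg, n_grid = 4096L) {
  m_pos <- mean(pdf_pos$reference_scores)
  m_neg <- mean(pdf_neg$reference_scores)
  lo <- min(m_pos, m_neg); hi <- max(m_pos, m_neg)
  mid <- (m_pos + m_neg) / 2
  if (lo == hi) {
    warning("cohort score means coincide; using their common value")
    return(structure(mid, fallback = TRUE))
  }
  grid <- seq(lo, hi, length.out = n_grid)
  diffd <- reevaluate_pdf(pdf_pos, grid)$density -
    reevaluate_pdf(pdf_neg, grid)$density
  sgn <- sign(diffd)
  cross <- which(sgn[-1L] * sgn[-length(sgn)] < 0)
  zero <- which(diffd == 0)
  cand <- numeric(0)
  if (length(cross)) {
    # linear interpolation of the sign change within each bracketing segment
    x1 <- grid[cross]; x2 <- grid[cross + 1L]
    y1 <- diffd[cross]; y2 <- diffd[cross + 1L]
    cand <- x1 - y1 * (x2 - x1) / (y2 - y1)
  }
  cand <- c(cand, grid[zero])
  if (!length(cand)) {
    warning("no density crossing between cohort means; midpoint fallback")
    return(structure(mid, fallback = TRUE))
  }
  structure(cand[which.min(abs(cand - mid))], fallback = FALSE)
}

#' Confusion matrix and derived rates at a threshold
#'
#' Classification rule: score strictly greater than the threshold is called
#' positive (ties classify negative). Rates with zero denominators are
#' reported as \code{NA} and listed in the \code{undefined} field rather than
#' coerced to 0.
#'
#' @param scores a \code{cv_scores} data.frame (columns cohort, score).
#' @param positive cohort label counted as positive (default \code{"ASD"}).
#' @param threshold decision threshold.
#' @return A \code{confusion_summary} list: \code{threshold}, counts
#'   \code{TP FP TN FN}, rates \code{TPR FPR PPV NPV}, \code{undefined}.
#' @export
confusion_at <- function(scores, positive = "ASD", threshold) {
  stopifnot(nrow(scores) > 0L, is.finite(threshold))
  is_pos <- scores$cohort == positive
  called <- scores$score > threshold
  TP <- sum(is_pos & called);  FN <- sum(is_pos & !called)
  FP <- sum(!is_pos & called); TN <- sum(!is_pos & !called)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  rates <- c(TPR = rate(TP, TP + FN), FPR = rate(FP, FP + TN),
             PPV = rate(TP, TP + FP), NPV = rate(TN, TN + FN))
  structure(list(threshold = threshold, TP = TP, FP = FP, TN = TN, FN = FN,
                 TPR = rates[["TPR"]], FPR = rates[["FPR"]],
                 PPV = rates[["PPV"]], NPV = rates[["NPV"]],
                 undefined = names(rates)[is.na(rates)]),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("confusion at t = %.4g: TP=%d FP=%d TN=%d FN=%d\n",
              x$threshold, x$TP, x$FP, x$TN, x$FN))
  cat(sprintf("  TPR=%.3f FPR=%.3f PPV=%.3f NPV=%.3f\n",
              x$TPR, x$FPR, x$PPV, x$NPV))
  if (length(x$undefined))
    cat("  undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Type I / Type II error curves over a threshold grid
#'
#' Empirical per-threshold error rates from the cross-validated scores:
#' Type I = false positive rate (negative cohort called positive),
#' Type II = false negative rate (positive cohort called negative).
#'
#' @param scores a \code{cv_scores} data.frame.
#' @param thresholds numeric grid (default: 512 points spanning the scores).
#' @param positive positive cohort label (default \code{"ASD"}).
#' @return data.frame with columns \code{threshold}, \code{type1},
#'   \code{type2}.
#' @export
error_curves <- function(scores, thresholds = NULL, positive = "ASD") {
  if (is.null(thresholds)) {
    r <- range(scores$score)
    pad <- diff(r) * 0.05 + 1e-9
    thresholds <- seq(r[1L] - pad, r[2L] + pad, length.out = 512L)
  }
  pos <- scores$score[scores$cohort == positive]
  neg <- scores$score[scores$cohort != positive]
  data.frame(
    threshold = thresholds,
    type1 = vapply(thresholds, function(t) mean(neg > t), numeric(1)),
    type2 = vapply(thresholds, function(t) mean(pos <= t), numeric(1)))
}

#' Serialize a confusion summary to JSON
#' @param cm a \code{confusion_summary}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_confusion_summary <- function(cm, path) {
  jsonlite::write_json(unclass(cm), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
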