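# Fisher discriminant analysis on standardized metabolite panels.
#
# Scatter definitions (k classes, n_i samples in class i, class means xbar_i,
# grand mean xbar):
#   S_B = sum_i n_i (xbar_i - xbar)(xbar_i - xbar)'
#   S_W = sum_i sum_{j in i} (x_j - xbar_i)(x_j - xbar_i)'
# and the criterion J(w) = (w' S_B w) / (w' S_W w). For two classes the
# maximizer is colinear with S_W^{-1}(xbar_1 - xbar_2); the generalized
# eigen-decomposition of S_W^{-1} S_B is also exposed (rank(S_B) <= k-1).

# Moore-Penrose pseudo-inverse, relative singular-value cutoff.
.pinv <- function(A, rcond = 1e-10) {
  s <- svd(A)
  keep <- s$d > rcond * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

# Per-variable center/scale from a training matrix. Zero-variance columns get
# scale 1: they standardize to exactly 0 and cannot influence the projection.
.standardizer <- function(X) {
  n <- nrow(X)
  center <- colMeans(X)
  ss <- colSums(X^2) - n * center^2
  ss[ss < 0] <- 0
  scale <- sqrt(ss / (n - 1))
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

# Discriminant direction pinv(SW) %*% dm: plain solve when SW is nonsingular
# (equals the pseudo-inverse there), SVD pseudo-inverse with relative cutoff
# 1e-10 when LAPACK reports computational singularity.
.fda_direction <- function(SW, dm) {
  w <- tryCatch(solve(SW, dm), error = function(e) NULL)
  if (is.null(w) || !all(is.finite(w))) w <- drop(.pinv(SW) %*% dm)
  drop(w)
}

.apply_standardizer <- function(X, std) {
  sweep(sweep(X, 2L, std$center, "-"), 2L, std$scale, "/")
}

# Scatter matrices of a standardized matrix Z given a class factor.
.scatter <- function(Z, cls) {
  xbar <- colMeans(Z)
  p <- ncol(Z)
  SB <- matrix(0, p, p); SW <- matrix(0, p, p)
  means <- list()
  for (g in levels(cls)) {
    Zg <- Z[cls == g, , drop = FALSE]
    ng <- nrow(Zg)
    mg <- colMeans(Zg)
    means[[g]] <- mg
    d <- mg - xbar
    SB <- SB + ng * tcrossprod(d)
    Cg <- sweep(Zg, 2L, mg, "-")
    SW <- SW + crossprod(Cg)
  }
  list(SB = SB, SW = SW, means = means)
}

#' Fit a two-class Fisher discriminant model
#'
#' Standardizes the training samples of the two named cohorts (z-score per
#' variable from the training data only), forms the between- and within-class
#' scatter matrices and returns the unit-norm projection vector maximizing
#' J(w) = (w'S_B w)/(w'S_W w). For two classes the solution is the direction
#' of \code{pinv(S_W) \%*\% (xbar_1 - xbar_2)}; a Moore-Penrose pseudo-inverse
#' (relative cutoff 1e-10) handles the near-collinear ratio variables. The
#' sign of \code{w} is fixed so the mean projected score of \code{classes[1]}
#' exceeds that of \code{classes[2]} (by convention ASD scores plot high).
#'
#' @param ds a \code{focm_dataset}.
#' @param variables panel subset to use (default: full panel).
#' @param classes length-2 character, the positive and negative cohorts
#'   (default \code{c("ASD","NEU")}).
#' @return A \code{discriminant_model}: list with \code{variables},
#'   \code{classes}, \code{standardizer}, unit-norm \code{w},
#'   \code{class_score_means}, and \code{fit} holding \code{SB}, \code{SW},
#'   criterion value \code{J} and the generalized eigenvalues of
#'   \code{pinv(S_W) S_B}.
#' @export
fit_fda <- function(ds, variables = ds$panel, classes = c("ASD", "NEU")) {
  stopifnot(length(classes) == 2L, length(variables) >= 1L)
  X <- dataset_matrix(ds, variables, cohorts = classes)
  cls <- factor(as.character(ds$cohort[ds$cohort %in% classes]),
                levels = classes)
  n_per <- table(cls)
  if (any(n_per == 0L))
    stop("empty class: ", paste(classes[n_per == 0L], collapse = ", "))
  if (any(n_per < 2L))
    stop("each class needs >= 2 samples")

  std <- .standardizer(X)
  Z <- .apply_standardizer(X, std)
  sc <- .scatter(Z, cls)
  if (max(abs(sc$SW)) == 0 && max(abs(sc$SB)) == 0)
    stop("degenerate scatter: all samples identical")

  w <- .fda_direction(sc$SW, sc$means[[classes[1L]]] - sc$means[[classes[2L]]])
  nw <- sqrt(sum(w^2))
  if (nw == 0) stop("degenerate scatter: class means coincide after projection")
  w <- w / nw

  m_pos <- sum(w * sc$means[[classes[1L]]])
  m_neg <- sum(w * sc$means[[classes[2L]]])
  if (m_pos < m_neg) { w <- -w; tmp <- m_pos; m_pos <- m_neg; m_neg <- tmp }

  J <- drop(crossprod(w, sc$SB %*% w) / crossprod(w, sc$SW %*% w))
  eigvals <- Re(eigen(.pinv(sc$SW) %*% sc$SB, only.values = TRUE)$values)

  structure(list(
    variables = variables, classes = classes, standardizer = std, w = w,
    class_score_means = stats::setNames(c(m_pos, m_neg), classes),
    fit = list(SB = sc$SB, SW = sc$SW, J = J, eigvals = eigvals)
  ), class = "discriminant_model")
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat("discriminant_model:", x$classes[1L], "vs", x$classes[2L], "on",
      length(x$variables), "variables; J =", format(x$fit$J, digits = 4), "\n")
  invisible(x)
}

#' Project samples onto a fitted discriminant
#'
#' Score = w' z where z is the sample standardized by the model's training
#' standardizer. Higher scores are more like \code{classes[1]} (ASD-like under
#' the default orientation).
#'
#' @param m a \code{discriminant_model}.
#' @param X numeric matrix/data.frame with the model's variables as columns,
#'   or a \code{focm_dataset}.
#' @return Numeric score vector, one per row.
#' @export
project_scores <- function(m, X) {
  if (inherits(X, "focm_dataset")) X <- dataset_matrix(X, m$variables)
  X <- as.matrix(as.data.frame(X, check.names = FALSE)[, m$variables, drop = FALSE])
  drop(.apply_standardizer(X, m$standardizer) %*% m$w)
}

#' Leave-one-out cross-validated discriminant scores
#'
#' For each sample of the two classes, refits the discriminant (including the
#' standardizer) on all remaining samples and projects the held-out sample.
#' Deterministic and invariant to input row order.
#'
#' @inheritParams fit_fda
#' @return A \code{cv_scores} data.frame with columns \code{id}, \code{cohort},
#'   \code{score}; attribute \code{fold_count} = number of samples.
#' @export
loo_scores <- function(ds, variables = ds$panel, classes = c("ASD", "NEU")) {
  keep <- ds$cohort %in% classes
  X <- dataset_matrix(ds, variables, cohorts = classes)
  cls <- factor(as.character(ds$cohort[keep]), levels = classes)
  ids <- ds$id[keep]
  n <- nrow(X)
  if (any(table(cls) < 3L)) stop("each class needs >= 3 samples for LOO")

  # Exact rank-one downdates of the per-class sufficient statistics: each
  # fold's standardizer, scatter and discriminant equal a from-scratch refit
  # (same math as fit_fda, in raw coordinates with the scale folded back in:
  # w_std  proportional to  D %*% solve(SW_raw, dm_raw), D = diag(scale)).
  g1 <- cls == classes[1L]
  s_all <- colSums(X); ss_all <- colSums(X^2)
  s_cls <- list(colSums(X[g1, , drop = FALSE]),
                colSums(X[!g1, , drop = FALSE]))
  G_cls <- list(crossprod(X[g1, , drop = FALSE]),
                crossprod(X[!g1, , drop = FALSE]))
  n_cls <- c(sum(g1), sum(!g1))

  score <- numeric(n)
  for (j in seq_len(n)) {
    xj <- X[j, ]
    gj <- if (g1[j]) 1L else 2L
    nj <- n_cls; nj[gj] <- nj[gj] - 1L
    sj <- s_cls; sj[[gj]] <- sj[[gj]] - xj
    m1 <- sj[[1L]] / nj[1L]; m2 <- sj[[2L]] / nj[2L]
    # within-class scatter of the remaining samples, raw coordinates
    G1 <- G_cls[[1L]]; G2 <- G_cls[[2L]]
    if (gj == 1L) G1 <- G1 - tcrossprod(xj) else G2 <- G2 - tcrossprod(xj)
    SW <- (G1 - nj[1L] * tcrossprod(m1)) + (G2 - nj[2L] * tcrossprod(m2))
    # training standardizer
    ctr <- (s_all - xj) / (n - 1L)
    ssv <- (ss_all - xj^2) - (n - 1L) * ctr^2
    ssv[ssv < 0] <- 0
    scl <- sqrt(ssv / (n - 2L))
    scl[!is.finite(scl) | scl == 0] <- 1
    if (max(abs(SW)) == 0 && all(m1 == m2))
      stop("LOO fold ", j, " (id ", ids[j],
           "): degenerate scatter: all samples identical")
    w <- scl * .fda_direction(SW, m1 - m2)
    nw <- sqrt(sum(w^2))
    if (nw == 0)
      stop("LOO fold ", j, " (id ", ids[j], "): degenerate scatter")
    w <- w / nw
    zm1 <- sum(w * (m1 - ctr) / scl); zm2 <- sum(w * (m2 - ctr) / scl)
    if (zm1 < zm2) w <- -w
    score[j] <- sum(w * (xj - ctr) / scl)
  }
  out <- data.frame(id = ids, cohort = as.character(cls), score = score,
                    stringsAsFactors = FALSE)
  attr(out, "fold_count") <- n
  class(out) <- c("cv_scores", class(out))
  out
}

#' Project an external cohort through a trained discriminant
#'
#' Scores every sample of a cohort that was not used for training (the SIB
#' projection), reusing the trained model's standardizer without refitting.
#'
#' @param m a \code{discriminant_model}.
#' @param ds a \code{focm_dataset}.
#' @param cohort cohort label to project (default \code{"SIB"}).
#' @return data.frame with columns \code{id}, \code{score}.
#' @export
project_external <- function(m, ds, cohort = "SIB") {
  if (!any(ds$cohort == cohort)) stop("cohort absent: ", cohort)
  X <- dataset_matrix(ds, m$variables, cohorts = cohort)
  data.frame(id = rownames(X), score = project_scores(m, X),
             stringsAsFactors = FALSE)
}

#' Serialize a discriminant model to JSON
#' @param m a \code{discriminant_model}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_discriminant_model <- function(m, path) {
  jsonlite::write_json(list(
    variables = m$variables, classes = m$classes,
    standardizer = m$standardizer, w = m$w,
    class_score_means = as.list(m$class_score_means),
    J = m$fit$J, eigvals = m$fit$eigvals
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
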