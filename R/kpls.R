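# Gaussian-kernel partial least squares regression in dual (kernel) form.
#
# The predictor rows are mapped into feature space by a Gaussian kernel
# k(a, b) = exp(-||a - b||^2 / (2 sigma_k^2)) and the response is regressed
# onto that feature space by dual NIPALS: latent score vectors are extracted
# from the (double-centered) kernel matrix with deflation, and predictions
# take the dual form yhat = Kc_test %*% dual_coef + y_center.

#' Gaussian kernel matrix between two sets of rows
#'
#' Entry (i, j) = exp(-||A[i,] - B[j,]||^2 / (2 sigma_k^2)).
#'
#' @param A,B numeric matrices with the same number of columns (standardized
#'   predictor rows).
#' @param sigma_k kernel width, > 0.
#' @return \code{nrow(A)} x \code{nrow(B)} kernel matrix; symmetric PSD when
#'   \code{A} and \code{B} are identical.
#' @export
kernel_matrix <- function(A, B, sigma_k) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) stop("dimension mismatch between A and B")
  if (!is.numeric(sigma_k) || length(sigma_k) != 1L || sigma_k <= 0)
    stop("sigma_k must be a positive scalar")
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma_k^2))
}

#' Double-center a training kernel matrix (feature-space mean removal)
#' @param K symmetric training kernel.
#' @return Centered kernel \code{H K H} with \code{H = I - 11'/n}.
#' @export
center_kernel <- function(K) {
  n <- nrow(K)
  cm <- colMeans(K)
  K - matrix(rowMeans(K), n, n) -
    matrix(cm, n, n, byrow = TRUE) + mean(K)
}

# Center a test-vs-train kernel consistently with the training centering.
.center_test_kernel <- function(Kt, K_train) {
  n <- ncol(Kt)
  Kt - matrix(rowMeans(Kt), nrow(Kt), n) -
    matrix(colMeans(K_train), nrow(Kt), n, byrow = TRUE) + mean(K_train)
}

#' Fit kernel PLS from a centered kernel (dual NIPALS)
#'
#' Extracts \code{n_components} latent score vectors from the centered kernel
#' by dual NIPALS with deflation of both the kernel and the response, then
#' forms the dual regression coefficients
#' \code{dual_coef = U (T' K U)^{-1} T' y} so that predictions are
#' \code{Kc_new \%*\% dual_coef + y_center}.
#'
#' This low-level fitter is kernel-agnostic: any valid centered kernel (e.g. a
#' linear one, which reproduces ordinary linear PLS) may be supplied.
#'
#' @param K_centered double-centered training kernel (see
#'   \code{\link{center_kernel}}).
#' @param y numeric response vector.
#' @param n_components number of latent variables, in \code{[1, n-1]}.
#' @return A \code{kpls_fit} list: \code{dual_coef}, \code{y_center},
#'   \code{n_components}, \code{T} (latent scores), \code{fitted}.
#' @export
fit_kpls <- function(K_centered, y, n_components) {
  n <- length(y)
  stopifnot(nrow(K_centered) == n, ncol(K_centered) == n)
  if (stats::sd(y) == 0) stop("zero-variance response")
  if (n_components < 1L || n_components > n - 1L)
    stop("n_components must be in [1, n-1]")
  y_center <- mean(y)
  yc <- y - y_center

  Kres <- K_centered
  yres <- yc
  Tm <- matrix(0, n, n_components)
  Um <- matrix(0, n, n_components)
  for (a in seq_len(n_components)) {
    u <- yres
    t <- drop(Kres %*% u)
    nt <- sqrt(sum(t^2))
    if (nt < 1e-12) { # kernel exhausted: trim the component count
      Tm <- Tm[, seq_len(a - 1L), drop = FALSE]
      Um <- Um[, seq_len(a - 1L), drop = FALSE]
      break
    }
    t <- t / nt
    Tm[, a] <- t
    Um[, a] <- u
    # deflate: remove the extracted direction from kernel and response
    Kres <- Kres - t %*% crossprod(t, Kres)
    Kres <- Kres - (Kres %*% t) %*% t(t)
    yres <- yres - t * sum(t * yres)
  }
  M <- crossprod(Tm, K_centered %*% Um)
  dual_coef <- drop(Um %*% solve(M, crossprod(Tm, yc)))
  fitted <- drop(K_centered %*% dual_coef) + y_center
  structure(list(dual_coef = dual_coef, y_center = y_center,
                 n_components = ncol(Tm), T = Tm, fitted = fitted),
            class = "kpls_fit")
}

#' Median pairwise distance of standardized rows (kernel-width heuristic)
#' @param Z numeric matrix of standardized rows.
#' @return Median Euclidean inter-row distance.
#' @export
median_heuristic <- function(Z) {
  d <- stats::dist(Z)
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m <= 0) stop("degenerate predictor rows")
  m
}

#' Fit a Gaussian-kernel PLS regression on raw predictors
#'
#' Standardizes the predictors (z-score), builds the Gaussian kernel with
#' width \code{sigma_k} (default: median pairwise distance of the
#' standardized rows), double-centers it and fits dual-NIPALS KPLS.
#'
#' @param X numeric predictor matrix (rows = samples).
#' @param y numeric response vector.
#' @param sigma_k kernel width; \code{NULL} for the median heuristic.
#' @param n_components latent variables (default 4, capped at n-1).
#' @return A \code{kpls_model}: the \code{kpls_fit} plus \code{train_inputs}
#'   (standardized rows), \code{standardizer}, \code{sigma_k},
#'   \code{K_train}.
#' @export
kpls <- function(X, y, sigma_k = NULL, n_components = 4L) {
  X <- as.matrix(X)
  std <- .standardizer(X)
  Z <- .apply_standardizer(X, std)
  if (is.null(sigma_k)) sigma_k <- median_heuristic(Z)
  K <- kernel_matrix(Z, Z, sigma_k)
  n_components <- min(n_components, nrow(Z) - 1L)
  fit <- fit_kpls(center_kernel(K), y, n_components)
  structure(c(fit, list(train_inputs = Z, standardizer = std,
                        sigma_k = sigma_k, K_train = K)),
            class = c("kpls_model", "kpls_fit"))
}

#' Predict from a fitted Gaussian-kernel PLS model
#'
#' Standardizes new rows with the training standardizer, forms the test
#' kernel against the training rows, centers it consistently with the
#' training centering and applies the dual coefficients.
#'
#' @param m a \code{kpls_model} from \code{\link{kpls}}.
#' @param X_new numeric matrix of new predictor rows (raw scale).
#' @return Numeric predictions.
#' @export
predict_kpls <- function(m, X_new) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != ncol(m$train_inputs)) stop("dimension mismatch")
  Z <- .apply_standardizer(X_new, m$standardizer)
  Kt <- kernel_matrix(Z, m$train_inputs, m$sigma_k)
  drop(.center_test_kernel(Kt, m$K_train) %*% m$dual_coef) + m$y_center
}

#' Leave-one-out cross-validated Q2 of a KPLS regression
#'
#' For every sample carrying a response, fits the model on all other
#' responding samples (standardizer, kernel width and component count all
#' recomputed inside the fold) and predicts the held-out response. Returns
#' the cross-validated R-squared
#' \deqn{Q^2 = 1 - \sum_i (y_i - \hat y_{-i})^2 / \sum_i (y_i - \bar y)^2}
#' with the full-sample mean in the denominator.
#'
#' Hyperparameter policies: \code{"fixed"} uses the in-fold median-heuristic
#' kernel width times \code{sigma_mult} and \code{n_components} latent
#' variables; \code{"nested"} selects both by an inner leave-one-out grid
#' (\code{sigma_mult} in \{0.25, 0.5, 1, 2, 4\}, components 1..min(10, n-2))
#' inside every outer fold.
#'
#' @param ds a \code{focm_dataset}.
#' @param variables predictor subset of the panel.
#' @param hyper_policy \code{"fixed"} (default) or \code{"nested"}.
#' @param n_components fixed-policy component count (default 4).
#' @param sigma_mult fixed-policy multiplier of the median-heuristic width.
#' @param cohorts cohorts whose responding samples enter (default
#'   \code{"ASD"}, the study design).
#' @return A \code{q2_result} list: \code{q2}, \code{predictions} (data.frame
#'   id, y, y_hat), \code{hyperparams}.
#' @export
loo_q2 <- function(ds, variables, hyper_policy = c("fixed", "nested"),
                   n_components = 4L, sigma_mult = 1, cohorts = "ASD") {
  hyper_policy <- match.arg(hyper_policy)
  keep <- ds$cohort %in% cohorts & !is.na(ds$vineland)
  if (sum(keep) < 10L) stop("need >= 10 samples with responses")
  X <- as.matrix(ds$data[keep, variables, drop = FALSE])
  y <- ds$vineland[keep]
  ids <- ds$id[keep]
  n <- length(y)

  y_hat <- numeric(n)
  hp <- list(policy = hyper_policy)
  for (j in seq_len(n)) {
    Xt <- X[-j, , drop = FALSE]; yt <- y[-j]
    m <- tryCatch({
      if (hyper_policy == "fixed") {
        Zt <- .apply_standardizer(Xt, .standardizer(Xt))
        kpls(Xt, yt, sigma_k = sigma_mult * median_heuristic(Zt),
             n_components = min(n_components, nrow(Xt) - 1L))
      } else {
        .kpls_nested_fit(Xt, yt)
      }
    }, error = function(e) stop("LOO fold ", j, " (id ", ids[j], "): ",
                                conditionMessage(e), call. = FALSE))
    y_hat[j] <- predict_kpls(m, X[j, , drop = FALSE])
  }
  q2 <- 1 - sum((y - y_hat)^2) / sum((y - mean(y))^2)
  if (hyper_policy == "fixed")
    hp <- c(hp, list(sigma_mult = sigma_mult, n_components = n_components))
  structure(list(q2 = q2,
                 predictions = data.frame(id = ids, y = y, y_hat = y_hat,
                                          stringsAsFactors = FALSE),
                 hyperparams = hp),
            class = "q2_result")
}

# Inner-LOO hyperparameter selection for one outer fold.
.kpls_nested_fit <- function(X, y, sigma_grid = c(0.25, 0.5, 1, 2, 4),
                             max_components = 10L) {
  Z <- .apply_standardizer(X, .standardizer(X))
  med <- median_heuristic(Z)
  comps <- seq_len(min(max_components, length(y) - 2L))
  best <- NULL
  for (sm in sigma_grid) {
    for (nc in comps) {
      press <- 0
      ok <- TRUE
      for (i in seq_along(y)) {
        fit_i <- tryCatch(
          kpls(X[-i, , drop = FALSE], y[-i], sigma_k = sm * med,
               n_components = min(nc, length(y) - 2L)),
          error = function(e) NULL)
        if (is.null(fit_i)) { ok <- FALSE; break }
        press <- press + (y[i] - predict_kpls(fit_i, X[i, , drop = FALSE]))^2
      }
      if (ok && (is.null(best) || press < best$press))
        best <- list(press = press, sigma_mult = sm, n_components = nc)
    }
  }
  kpls(X, y, sigma_k = best$sigma_mult * med,
       n_components = best$n_components)
}

#' @export
print.q2_result <- function(x, ...) {
  cat("q2_result: Q2 =", format(x$q2, digits = 4), "over",
      nrow(x$predictions), "LOO predictions\n")
  invisible(x)
}

#' Exhaustive regression subset search by cross-validated Q2
#'
#' Evaluates every predictor combination of each size 1..\code{k_max} by
#' \code{\link{loo_q2}} and keeps the best per size (the cross-validated-R2
#' versus panel-size curve of the regression analysis).
#'
#' @param ds a \code{focm_dataset}.
#' @param k_max largest subset size.
#' @param variables candidate pool (default full panel).
#' @param hyper_policy,n_components,sigma_mult passed to \code{\link{loo_q2}}.
#' @param sizes subset sizes to evaluate (default \code{1:k_max}).
#' @return List keyed by size: each element has \code{variables} and
#'   \code{q2}.
#' @export
regression_search <- function(ds, k_max, variables = ds$panel,
                              hyper_policy = "fixed", n_components = 4L,
                              sigma_mult = 1, sizes = seq_len(k_max)) {
  variables <- .canonical_order(ds, variables)
  stopifnot(k_max >= 1L, k_max <= length(variables),
            all(sizes >= 1L), all(sizes <= length(variables)))
  out <- list()
  for (k in sizes) {
    best <- NULL
    for (combo in utils::combn(variables, k, simplify = FALSE)) {
      r <- loo_q2(ds, combo, hyper_policy = hyper_policy,
                  n_components = n_components, sigma_mult = sigma_mult)
      if (is.null(best) || r$q2 > best$q2)
        best <- list(variables = combo, q2 = r$q2)
    }
    out[[as.character(k)]] <- best
  }
  out
}
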