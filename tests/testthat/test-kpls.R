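test_that("kernel_matrix: diagonal, direct substitution, PSD, errors", {
  set.seed(111)
  A <- matrix(rnorm(15), 5)
  K <- kernel_matrix(A, A, sigma_k = 1.3)
  expect_equal(diag(K), rep(1, 5))
  expect_equal(K, t(K))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  expect_true(all(K > 0 & K <= 1))

  # two points at distance sigma_k -> exp(-1/2)
  B <- rbind(c(0, 0), c(0.7, 0))
  expect_equal(kernel_matrix(B, B, sigma_k = 0.7)[1, 2], exp(-0.5))

  expect_error(kernel_matrix(A, A, sigma_k = 0), "positive")
  expect_error(kernel_matrix(A, matrix(0, 2, 5), 1), "dimension mismatch")
})

test_that("linear-kernel KPLS reproduces textbook NIPALS PLS", {
  set.seed(113)
  for (i in 1:5) {
    X <- matrix(rnorm(30), 10, 3)
    y <- rnorm(10)
    K <- tcrossprod(X) # linear kernel
    Kc <- center_kernel(K)
    for (ncomp in 1:3) {
      fit <- fit_kpls(Kc, y, ncomp)
      oracle <- nipals_pls1(X, y, ncomp)
      expect_equal(fit$fitted, oracle$predict(X), tolerance = 1e-8)
    }
  }
})

test_that("full-component KPLS interpolates the training responses", {
  set.seed(127)
  X <- matrix(rnorm(24), 8, 3)
  y <- rnorm(8)
  m <- kpls(X, y, sigma_k = 1.5, n_components = 7)
  expect_equal(m$fitted, y, tolerance = 1e-6)
  # predicting training points equals fitted values
  expect_equal(predict_kpls(m, X), m$fitted, tolerance = 1e-8)
})

test_that("degenerate fits are rejected", {
  K <- center_kernel(diag(5) * 0.5 + 0.5)
  expect_error(fit_kpls(K, rep(2, 5), 2), "zero-variance response")
  expect_error(fit_kpls(K, rnorm(5), 0), "n_components")
  expect_error(fit_kpls(K, rnorm(5), 5), "n_components")
})

test_that("prediction limits: far points revert to the mean, flat kernel approaches linear PLS", {
  set.seed(131)
  X <- matrix(rnorm(60), 20, 3)
  y <- drop(X %*% c(1, -0.5, 0.2)) + rnorm(20, sd = 0.1)
  m <- kpls(X, y, sigma_k = 1, n_components = 3)
  # far from all training points the kernel vanishes and the prediction
  # collapses to the model constant: y_center minus the dual coefficients
  # applied to the (centered) training kernel column means
  far1 <- matrix(50, 1, 3); far2 <- matrix(-60, 1, 3)
  b <- m$y_center -
    sum(m$dual_coef * (colMeans(m$K_train) - mean(m$K_train)))
  expect_lt(abs(predict_kpls(m, far1) - b), 1e-6 * sd(y))
  expect_equal(predict_kpls(m, far1), predict_kpls(m, far2),
               tolerance = 1e-8)
  expect_lt(abs(predict_kpls(m, far1) - m$y_center), 0.5 * sd(y))

  # sigma_k -> large: Gaussian KPLS approaches linear PLS behaviour
  Z <- scale(X)
  big <- 1e3 * median(dist(Z))
  mflat <- kpls(X, y, sigma_k = big, n_components = 2)
  oracle <- nipals_pls1(Z, y, 2)
  Xnew <- matrix(rnorm(15), 5, 3)
  Znew <- sweep(sweep(Xnew, 2, attr(Z, "scaled:center")), 2,
                attr(Z, "scaled:scale"), "/")
  expect_lt(max(abs(predict_kpls(mflat, Xnew) - oracle$predict(Znew))),
            0.05 * sd(y))
})

test_that("loo_q2: formula consistency, null behaviour, planted signal", {
  # delta = 0: keep the cohorts overlapping so the logistic link spans its
  # range instead of saturating against the clipping bounds
  g <- synthetic_dataset(synthetic_config(
    n_asd = 45, n_sib = 0, n_neu = 10, panel = recovery_panel(),
    delta = c("8-OHG" = 0), regression_variables = recovery_planted(),
    vineland_fraction = 1, vineland_noise_sd = 3, seed = 137))
  ds <- g$dataset

  r <- loo_q2(ds, recovery_planted())
  # Q2 formula holds on the returned predictions (full-sample mean denominator)
  manual <- 1 - sum((r$predictions$y - r$predictions$y_hat)^2) /
    sum((r$predictions$y - mean(r$predictions$y))^2)
  expect_equal(r$q2, manual)
  expect_equal(nrow(r$predictions), sum(!is.na(ds$vineland)))
  expect_lte(r$q2, 1)
  # planted smooth link with modest noise is recoverable
  expect_gte(r$q2, 0.5)

  # pure-noise response: Q2 at or below chance across seeds
  q2_null <- vapply(1:10, function(s) {
    ds2 <- ds
    set.seed(1000 + s)
    ds2$vineland[!is.na(ds2$vineland)] <-
      sample(ds2$vineland[!is.na(ds2$vineland)])
    loo_q2(ds2, c("Methionine", "SAM"))$q2
  }, numeric(1))
  expect_lt(median(q2_null), 0.1)
})

test_that("Q2 is invariant to predictor rescaling and response affine maps", {
  g <- synthetic_dataset(synthetic_config(
    n_asd = 30, n_sib = 0, n_neu = 5, panel = recovery_panel(),
    delta = c("8-OHG" = 0), regression_variables = recovery_planted(),
    vineland_fraction = 1, seed = 139))
  ds <- g$dataset
  r0 <- loo_q2(ds, recovery_planted())

  ds_x <- ds
  ds_x$data[["8-OHG"]] <- 500 * ds_x$data[["8-OHG"]] + 2
  expect_equal(loo_q2(ds_x, recovery_planted())$q2, r0$q2, tolerance = 1e-8)

  ds_y <- ds
  ds_y$vineland <- 3 * ds_y$vineland - 10
  expect_equal(loo_q2(ds_y, recovery_planted())$q2, r0$q2, tolerance = 1e-8)
})

test_that("regression search: identity case and noise-variable decline", {
  g <- synthetic_dataset(synthetic_config(
    n_asd = 35, n_sib = 0, n_neu = 5, panel = recovery_panel()[1:6],
    delta = c("8-OHG" = 0), regression_variables = c("8-OHG", "Glu.-Cys."),
    vineland_fraction = 1, vineland_noise_sd = 3, seed = 149))
  ds <- g$dataset

  one <- regression_search(ds, k_max = 1, variables = "8-OHG")
  expect_equal(one[["1"]]$variables, "8-OHG")

  rs <- regression_search(ds, k_max = 2, variables = ds$panel[1:6])
  expect_equal(sort(rs[["2"]]$variables), sort(c("8-OHG", "Glu.-Cys.")))

  # adding a pure-noise variable does not improve on the planted pair
  q2_best <- rs[["2"]]$q2
  q2_noisy <- loo_q2(ds, c("8-OHG", "Glu.-Cys.", "Methionine"))$q2
  expect_lte(q2_noisy, q2_best + 0.05)
})

test_that("nested hyperparameter policy runs and returns sane output", {
  g <- synthetic_dataset(synthetic_config(
    n_asd = 14, n_sib = 0, n_neu = 5, panel = recovery_panel()[1:4],
    regression_variables = c("8-OHG"), vineland_fraction = 1, seed = 151))
  r <- loo_q2(g$dataset, "8-OHG", hyper_policy = "nested")
  expect_lte(r$q2, 1)
  expect_equal(r$hyperparams$policy, "nested")
})
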