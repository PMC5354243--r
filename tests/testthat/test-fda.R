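toy_1d <- function() {
  make_toy_dataset(list(ASD = data.frame(m = c(10, 11)),
                        NEU = data.frame(m = c(0, 1))))
}

test_that("1-D toy: oriented w = +1, large J, perfect separation", {
  m <- fit_fda(toy_1d(), variables = "m")
  expect_equal(unname(m$w), 1)
  expect_gt(m$fit$J, 50)
  s <- project_scores(m, data.frame(m = c(10, 11, 0, 1)))
  expect_true(min(s[1:2]) > max(s[3:4]))
  # criterion is invariant to scaling of w
  J_of <- function(w) drop(crossprod(w, m$fit$SB %*% w) /
                             crossprod(w, m$fit$SW %*% w))
  expect_equal(J_of(m$w), J_of(-3.7 * m$w))
})

test_that("2-D fits agree with the brute-force direction-grid maximizer", {
  set.seed(21)
  for (i in 1:5) {
    delta <- runif(2, 0.5, 3)
    A <- matrix(rnorm(40), 20) + rep(delta, each = 20)
    B <- matrix(rnorm(40), 20)
    ds <- make_toy_dataset(list(ASD = as.data.frame(A),
                                NEU = as.data.frame(B)))
    m <- fit_fda(ds, variables = ds$panel)
    w_oracle <- brute_fda_direction_2d(rbind(A, B),
                                       rep(c("ASD", "NEU"), each = 20))
    expect_lt(angle_between_deg(m$w, w_oracle), 1)
  }
})

test_that("closed form matches the generalized eigenvector on random instances", {
  set.seed(31)
  for (i in 1:8) {
    p <- sample(2:5, 1)
    A <- matrix(rnorm(30 * p), 30) %*% matrix(rnorm(p * p), p)
    B <- sweep(matrix(rnorm(30 * p), 30) %*% matrix(rnorm(p * p), p),
               2, runif(p, -2, 2))
    ds <- make_toy_dataset(list(ASD = as.data.frame(A),
                                NEU = as.data.frame(B)))
    m <- fit_fda(ds, variables = ds$panel)
    # generalized eigenproblem on the standardized scatter
    ev <- eigen(solve(m$fit$SW) %*% m$fit$SB)
    w_eig <- Re(ev$vectors[, which.max(Re(ev$values))])
    expect_lt(angle_between_deg(m$w, w_eig), 1e-4)
    # two-class rank deficiency: exactly one nonzero generalized eigenvalue
    lam <- sort(abs(Re(ev$values)), decreasing = TRUE)
    expect_gt(lam[1], 1e-8)
    expect_lt(lam[2] / lam[1], 1e-8)
    expect_equal(sqrt(sum(m$w^2)), 1)
  }
})

test_that("projection semantics: class means, orientation, declared standardizer", {
  g <- synthetic_dataset(synthetic_config(n_asd = 15, n_sib = 0, n_neu = 15,
                                          seed = 5))
  m <- fit_fda(g$dataset)
  X <- dataset_matrix(g$dataset, cohorts = c("ASD", "NEU"))
  cls <- g$dataset$cohort[g$dataset$cohort != "SIB"]
  s <- project_scores(m, X)
  expect_gt(mean(s[cls == "ASD"]), mean(s[cls == "NEU"]))
  # projecting the ASD training mean recovers the stored class score mean
  Z <- sweep(sweep(X, 2, m$standardizer$center), 2, m$standardizer$scale, "/")
  asd_mean_score <- drop(crossprod(colMeans(Z[cls == "ASD", ]), m$w))
  expect_equal(asd_mean_score, unname(m$class_score_means["ASD"]))

  # hand arithmetic with a declared standardizer (1-D, w = 1)
  m1 <- fit_fda(toy_1d(), variables = "m")
  m1$standardizer <- list(center = c(m = 5.5), scale = c(m = 5.244))
  expect_equal(project_scores(m1, data.frame(m = 10)), (10 - 5.5) / 5.244)

  expect_error(project_scores(m1, data.frame(other = 1)))
})

test_that("LOO scores: single-fold cross-check, determinism, order invariance", {
  set.seed(8)
  ds <- make_toy_dataset(list(
    ASD = as.data.frame(matrix(rnorm(9, 2), 3)),
    NEU = as.data.frame(matrix(rnorm(9), 3))))
  cv <- loo_scores(ds, ds$panel)
  expect_equal(nrow(cv), 6L)
  expect_equal(attr(cv, "fold_count"), 6L)

  # fold 1 equals an explicit refit without sample 1
  rest <- new_focm_dataset(ds$data[-1, ], ds$cohort[-1], panel = ds$panel)
  m <- fit_fda(rest, rest$panel)
  expect_equal(cv$score[1],
               unname(project_scores(m, ds$data[1, , drop = FALSE])),
               tolerance = 1e-10)

  # bitwise determinism
  expect_identical(cv$score, loo_scores(ds, ds$panel)$score)

  # permutation invariance w.r.t. row order
  perm <- c(4, 1, 6, 2, 5, 3)
  dsp <- new_focm_dataset(ds$data[perm, ], ds$cohort[perm], id = ds$id[perm],
                          panel = ds$panel)
  cvp <- loo_scores(dsp, dsp$panel)
  expect_equal(cvp$score[order(cvp$id)], cv$score[order(cv$id)],
               tolerance = 1e-12)
})

test_that("affine rescaling of a variable leaves LOO scores unchanged", {
  g <- synthetic_dataset(synthetic_config(n_asd = 20, n_sib = 0, n_neu = 20,
                                          seed = 13))
  ds <- g$dataset
  vars <- c("8-OHG", "GSSG", "Tyrosine")
  cv <- loo_scores(ds, vars)
  ds$data[["GSSG"]] <- 1000 * ds$data[["GSSG"]] + 3
  expect_equal(loo_scores(ds, vars)$score, cv$score, tolerance = 1e-9)
})

test_that("overlapping classes yield chance-level separation downstream", {
  g <- generate_cohorts(synthetic_config(n_asd = 50, n_sib = 0, n_neu = 50,
                                         delta = c("8-OHG" = 0), seed = 17))
  cv <- loo_scores(g$dataset, c("Methionine", "SAM", "GSSG"))
  auc <- rank_auc(cv$score[cv$cohort == "ASD"], cv$score[cv$cohort == "NEU"])
  expect_gt(auc, 0.35)
  expect_lt(auc, 0.65)
})

test_that("planted single-variable shift concentrates w on that variable", {
  cfg <- synthetic_config(n_asd = 400, n_sib = 0, n_neu = 400,
                          panel = recovery_panel(), rho = 0,
                          delta = c("8-OHG" = 3), seed = 23)
  g <- generate_cohorts(cfg)
  m <- fit_fda(g$dataset)
  expect_gt(abs(m$w[match("8-OHG", g$dataset$panel)]), 0.9)
})

test_that("external projection reuses the trained standardizer", {
  g <- synthetic_dataset(synthetic_config(n_asd = 20, n_sib = 10, n_neu = 20,
                                          seed = 19))
  m <- fit_fda(g$dataset)
  sib <- project_external(m, g$dataset, "SIB")
  expect_equal(nrow(sib), 10L)
  # same code path as project_scores on the training cohort
  neu <- project_external(m, g$dataset, "NEU")
  Xn <- dataset_matrix(g$dataset, cohorts = "NEU")
  expect_identical(neu$score, unname(project_scores(m, Xn)))
  # NEU-like siblings sit nearer the NEU median than the ASD median
  cvm <- fit_fda(g$dataset)
  s_asd <- project_scores(m, dataset_matrix(g$dataset, cohorts = "ASD"))
  s_neu <- neu$score
  expect_lt(abs(median(sib$score) - median(s_neu)),
            abs(median(sib$score) - median(s_asd)))
  expect_error(project_external(m, g$dataset, "XYZ"), "cohort absent")
})

test_that("degenerate inputs are rejected", {
  ds <- make_toy_dataset(list(ASD = data.frame(m = c(1, 1, 1)),
                              NEU = data.frame(m = c(1, 1, 1))))
  expect_error(fit_fda(ds, "m"), "degenerate scatter")
  ds2 <- make_toy_dataset(list(ASD = data.frame(m = c(1, 2)),
                               NEU = data.frame(m = numeric(0))))
  expect_error(fit_fda(ds2, "m"))
  m <- fit_fda(toy_1d(), "m")
  expect_silent(write_discriminant_model(
    m, withr::local_tempfile(fileext = ".json")))
})
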