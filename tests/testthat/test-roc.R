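test_that("C-statistic endpoints: identical PDFs give 0.5, disjoint give 1", {
  set.seed(61)
  x <- rnorm(50)
  p <- estimate_pdf(x, 0.3)
  expect_equal(roc_c_statistic(p, p)$c_statistic, 0.5, tolerance = 1e-6)

  p_hi <- estimate_pdf(x + 100, 0.3)
  expect_equal(roc_c_statistic(p_hi, p)$c_statistic, 1, tolerance = 1e-6)

  # reversed orientation is auto-corrected and flagged
  r <- roc_c_statistic(p, p_hi)
  expect_equal(r$c_statistic, 1, tolerance = 1e-6)
  expect_true(r$flipped)
  expect_true(all(r$fpr >= 0 & r$fpr <= 1 & r$tpr >= 0 & r$tpr <= 1))
})

test_that("N(0,1) vs N(2,1) reproduces the closed-form C = pnorm(sqrt(2))", {
  pdf_neg <- gaussian_pdf_fixture(0, 1)
  pdf_pos <- gaussian_pdf_fixture(2, 1)
  r <- roc_c_statistic(pdf_pos, pdf_neg)
  expect_equal(r$c_statistic, pnorm(2 / sqrt(2)), tolerance = 0.005)
})

test_that("ROC curve is monotone as tpr(fpr)", {
  set.seed(67)
  p <- estimate_pdf(rnorm(40, 1), 0.4)
  q <- estimate_pdf(rnorm(40), 0.4)
  r <- roc_c_statistic(p, q)
  o <- order(r$fpr)
  expect_true(all(diff(r$tpr[o]) >= -1e-9))
})

test_that("PDF C-statistic tracks the empirical rank statistic on pipeline scores", {
  # n = 100/cohort keeps the KDE smoothing bias of the PDF-based C well
  # inside the 0.02 cross-estimator band at any effect size
  deltas <- c(0.5, 1, 2)
  for (i in seq_along(deltas)) {
    g <- generate_cohorts(synthetic_config(
      n_asd = 100, n_sib = 0, n_neu = 100, panel = recovery_panel(),
      delta = c("8-OHG" = deltas[i]), seed = 70 + i))
    cv <- loo_scores(g$dataset, c("8-OHG", "GSSG"))
    sp <- cv$score[cv$cohort == "ASD"]; sn <- cv$score[cv$cohort == "NEU"]
    c_pdf <- roc_c_statistic(
      estimate_pdf(sp, select_bandwidth(sp)$sigma_star),
      estimate_pdf(sn, select_bandwidth(sn)$sigma_star))$c_statistic
    c_rank <- max(rank_auc(sp, sn), 1 - rank_auc(sp, sn))
    expect_lt(abs(c_pdf - c_rank), 0.02)
  }
})

test_that("decision threshold: symmetric crossing, analytic crossing, fallback", {
  # equal-variance Gaussians centered at 0 and 2 cross at 1
  p0 <- gaussian_pdf_fixture(0, 1)
  p2 <- gaussian_pdf_fixture(2, 1)
  t12 <- decision_threshold(p2, p0)
  expect_equal(as.numeric(t12), 1, tolerance = 0.02)
  expect_false(attr(t12, "fallback"))

  # N(0,1) vs N(3, 2^2): compare with the analytic equal-density crossing
  pa <- gaussian_pdf_fixture(0, 1)
  pb <- gaussian_pdf_fixture(3, 2)
  t_ana <- uniroot(function(x) dnorm(x, 0, 1) - dnorm(x, 3, 2),
                   c(0, 3), tol = 1e-12)$root
  expect_equal(as.numeric(decision_threshold(pb, pa)), t_ana,
               tolerance = 0.02)

  # equal means -> midpoint fallback with warning
  set.seed(79)
  x <- rnorm(40)
  pc <- estimate_pdf(x, 0.5)
  pd <- estimate_pdf(sample(x), 0.5) # same scores, same mean
  expect_warning(tf <- decision_threshold(pc, pd), "coincide|fallback")
  expect_equal(as.numeric(tf), mean(x))
})

test_that("confusion matrix counts and rates match hand enumeration", {
  cv <- data.frame(id = as.character(1:6),
                   cohort = c("ASD", "ASD", "ASD", "NEU", "NEU", "NEU"),
                   score = c(1, 2, 3, -1, 0, 2.5))
  cm <- confusion_at(cv, positive = "ASD", threshold = 1.5)
  expect_equal(c(cm$TP, cm$FN, cm$FP, cm$TN), c(2, 1, 1, 2))
  expect_equal(cm$TPR, 2 / 3)
  expect_equal(cm$FPR, 1 / 3)
  expect_equal(cm$PPV, 2 / 3)
  expect_equal(cm$NPV, 2 / 3)
  expect_equal(cm$TP + cm$FP + cm$TN + cm$FN, 6)

  # perfect separation
  sep <- data.frame(id = as.character(1:6),
                    cohort = c("ASD", "ASD", "ASD", "NEU", "NEU", "NEU"),
                    score = c(1, 2, 3, -1, 0, -2))
  cmp <- confusion_at(sep, positive = "ASD", threshold = 0.5)
  expect_equal(c(cmp$TPR, cmp$FPR, cmp$PPV, cmp$NPV), c(1, 0, 1, 1))

  # boundary ties classify negative
  cmt <- confusion_at(cv, positive = "ASD", threshold = 3)
  expect_equal(cmt$TP, 0)

  # zero denominators reported undefined, not zero
  cmu <- confusion_at(cv, positive = "ASD", threshold = 10)
  expect_true(is.na(cmu$PPV))
  expect_true("PPV" %in% cmu$undefined)

  # invariance to score order and joint increasing transform
  perm <- sample(6)
  cmperm <- confusion_at(cv[perm, ], positive = "ASD", threshold = 1.5)
  expect_equal(unclass(cmperm), unclass(cm))
  cv2 <- cv; cv2$score <- exp(cv2$score)
  cm2 <- confusion_at(cv2, positive = "ASD", threshold = exp(1.5))
  expect_equal(c(cm2$TP, cm2$FN, cm2$FP, cm2$TN), c(2, 1, 1, 2))

  expect_silent(write_confusion_summary(
    cm, withr::local_tempfile(fileext = ".json")))
})

test_that("error curves behave at extremes and cross at the equal-error point", {
  set.seed(83)
  cv <- data.frame(id = as.character(1:40),
                   cohort = rep(c("ASD", "NEU"), each = 20),
                   score = c(rnorm(20, 1.5), rnorm(20)))
  ec <- error_curves(cv)
  expect_equal(ec$type1[1], 1)  # threshold below all scores
  expect_equal(ec$type2[1], 0)
  n <- nrow(ec)
  expect_equal(ec$type1[n], 0)  # threshold above all scores
  expect_equal(ec$type2[n], 1)
  expect_true(all(diff(ec$type1) <= 1e-12))
  expect_true(all(diff(ec$type2) >= -1e-12))

  # crossing point matches a brute scan for the equal-error threshold
  i_cross <- which.min(abs(ec$type1 - ec$type2))
  brute <- ec$threshold[which.min(vapply(ec$threshold, function(t)
    abs(mean(cv$score[cv$cohort == "NEU"] > t) -
          mean(cv$score[cv$cohort == "ASD"] <= t)), numeric(1)))]
  expect_equal(ec$threshold[i_cross], brute)
})
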