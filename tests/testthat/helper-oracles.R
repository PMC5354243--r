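# Independent oracles and fixture builders. These deliberately re-derive
# results by brute force / textbook algorithms so they never share code with
# the implementation paths they check.

# Small in-memory dataset on an arbitrary toy panel.
make_toy_dataset <- function(values_by_cohort, panel = NULL, vineland = NULL) {
  data <- do.call(rbind, lapply(values_by_cohort, as.data.frame))
  if (!is.null(panel)) colnames(data) <- panel
  cohort <- rep(names(values_by_cohort),
                vapply(values_by_cohort, function(m) nrow(as.data.frame(m)),
                       integer(1)))
  new_focm_dataset(as.data.frame(data, check.names = FALSE), cohort,
                   vineland = vineland,
                   provenance = list(source = "synthetic", note = "toy"))
}

# Reduced canonical panel used by the planted-recovery benchmarks: three
# planted variables in distinct correlation blocks plus five noise variables
# (some sharing blocks with planted ones, so the noise is correlated).
recovery_panel <- function() {
  c("Methionine", "SAM", "Homocysteine", "8-OHG", "Glu.-Cys.", "GSSG",
    "Chlorotyrosine", "Tyrosine")
}
recovery_planted <- function() c("8-OHG", "Glu.-Cys.", "Chlorotyrosine")

# Brute-force 2-D FDA direction: maximize J over a fine grid of unit
# directions on the standardized data (0.1 degree resolution).
brute_fda_direction_2d <- function(X, cls, step_deg = 0.1) {
  Z <- scale(X)
  groups <- split(seq_len(nrow(Z)), cls)
  xbar <- colMeans(Z)
  SB <- matrix(0, 2, 2); SW <- matrix(0, 2, 2)
  for (idx in groups) {
    Zg <- Z[idx, , drop = FALSE]
    mg <- colMeans(Zg)
    SB <- SB + length(idx) * tcrossprod(mg - xbar)
    SW <- SW + crossprod(sweep(Zg, 2, mg))
  }
  th <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  J <- vapply(th, function(a) {
    w <- c(cos(a), sin(a))
    drop(crossprod(w, SB %*% w) / crossprod(w, SW %*% w))
  }, numeric(1))
  a <- th[which.max(J)]
  c(cos(a), sin(a))
}

angle_between_deg <- function(u, v) {
  cs <- abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2)) # sign-agnostic
  acos(min(1, cs)) * 180 / pi
}

# Textbook single-response NIPALS PLS on column-centered predictors
# (no scaling), with the standard regression-coefficient reconstruction.
nipals_pls1 <- function(X, y, ncomp) {
  X <- as.matrix(X)
  xm <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2, xm); f <- y - ym
  W <- P <- matrix(0, ncol(X), ncomp)
  q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(E, f)); w <- w / sqrt(sum(w^2))
    t <- drop(E %*% w)
    p <- drop(crossprod(E, t)) / sum(t^2)
    qa <- sum(f * t) / sum(t^2)
    E <- E - tcrossprod(t, p)
    f <- f - t * qa
    W[, a] <- w; P[, a] <- p; q[a] <- qa
  }
  B <- W %*% solve(crossprod(P, W), q)
  list(xm = xm, ym = ym, B = B,
       predict = function(Xn)
         drop(sweep(as.matrix(Xn), 2, xm) %*% B) + ym)
}

# Brute-force LSCV: numerical integration of fhat^2 on a fine grid plus the
# direct leave-one-out density sum.
brute_lscv <- function(scores, sigma, n_grid = 20001L) {
  grid <- seq(min(scores) - 8 * sigma, max(scores) + 8 * sigma,
              length.out = n_grid)
  n <- length(scores)
  fh <- vapply(grid, function(g)
    sum(dnorm((g - scores) / sigma)) / (n * sigma), numeric(1))
  int_f2 <- sum(diff(grid) * (head(fh^2, -1) + tail(fh^2, -1))) / 2
  loo <- vapply(seq_len(n), function(i)
    sum(dnorm((scores[i] - scores[-i]) / sigma)) / ((n - 1) * sigma),
    numeric(1))
  int_f2 - 2 * mean(loo)
}

# Empirical rank C-statistic (Mann-Whitney U / (n1 n2), ties counted half).
rank_auc <- function(pos, neg) {
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# A score_distribution representing a target density almost exactly:
# deterministic quantile atoms scaled so the KDE mixture has the target mean
# and variance (for N(mu, sd): atoms ~ N(mu, sd^2 - sigma^2), kernel sigma).
gaussian_pdf_fixture <- function(mu, sd, n = 2000L, sigma = 0.1) {
  stopifnot(sd > sigma)
  q <- qnorm((seq_len(n) - 0.5) / n)
  estimate_pdf(mu + sqrt(sd^2 - sigma^2) * q, sigma)
}
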