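# Wald ratio ----------------------------------------------------------------

test_that("the Wald ratio is Gamma/gamma with first-order SE", {
  h <- HarmonizedSet(0.05, 0.01, 0.025, 0.005)
  est <- waldRatio(h)
  expect_equal(estimate(est), 0.5)
  expect_equal(stdErr(est), 0.1)
  h0 <- HarmonizedSet(0.05, 0.01, 0, 0.005)
  expect_equal(estimate(waldRatio(h0)), 0)
  hz <- HarmonizedSet(0, 0.01, 0.01, 0.005)
  expect_error(waldRatio(hz), "zero SNP-exposure effect")
})

test_that("the first-order Wald SE agrees with a parametric bootstrap for strong instruments", {
  # |gamma|/se_exp = 25 (> 10, the strong-instrument regime)
  g <- 0.05; sx <- 0.002; G <- 0.025; sy <- 0.005
  est <- waldRatio(HarmonizedSet(g, sx, G, sy))
  set.seed(202)
  draws <- rnorm(1e5, G, sy) / rnorm(1e5, g, sx)
  expect_lt(abs(stdErr(est) - sd(draws)) / sd(draws), 0.05)
})

# IVW -----------------------------------------------------------------------

test_that("IVW with one instrument equals the Wald ratio exactly", {
  h <- HarmonizedSet(0.05, 0.01, 0.025, 0.005)
  ivw <- ivwRandomEffects(h)
  wald <- waldRatio(h)
  expect_identical(estimate(ivw), estimate(wald))
  expect_identical(stdErr(ivw), stdErr(wald))
})

test_that("exactly proportional instruments give the common ratio with zero Q", {
  g <- c(0.05, 0.1, 0.2)
  h <- HarmonizedSet(g, rep(0.01, 3), 0.5 * g, rep(0.01, 3))
  est <- ivwRandomEffects(h)
  expect_equal(estimate(est), 0.5)
  expect_equal(est@q, 0)
})

test_that("IVW equals the hand-rolled weighted least squares through the origin", {
  set.seed(31)
  g <- runif(5, 0.03, 0.1)
  sy <- runif(5, 0.005, 0.02)
  G <- 0.4 * g + rnorm(5, 0, sy)
  h <- HarmonizedSet(g, rep(0.002, 5), G, sy)
  est <- ivwRandomEffects(h)
  # normal equations of Gamma ~ gamma (no intercept), weights 1/sy^2
  beta_o <- sum(g * G / sy^2) / sum(g^2 / sy^2)
  se_fix <- sqrt(1 / sum(g^2 / sy^2))
  q_o <- sum((G / g - beta_o)^2 * g^2 / sy^2)
  se_o <- se_fix * sqrt(max(1, q_o / 4))
  expect_equal(estimate(est), beta_o, tolerance = 1e-12)
  expect_equal(stdErr(est), se_o, tolerance = 1e-12)
  expect_equal(est@q, q_o, tolerance = 1e-12)
})

# Cochran's Q ---------------------------------------------------------------

test_that("Cochran's Q hand arithmetic and degenerate cases", {
  expect_error(cochranQ(1, 1, 1), "at least 2")
  same <- cochranQ(c(0.3, 0.3, 0.3), c(1, 1, 1), 0.3)
  expect_equal(same$q, 0)
  expect_equal(same$p, 1)
  two <- cochranQ(c(0, 1), c(1, 1), 0.5)
  expect_equal(two$q, 0.5)
  expect_equal(two$df, 1L)
})

test_that("Q is calibrated against chi-square(J-1) under homogeneity", {
  set.seed(3)
  reps <- 2000
  rej <- logical(reps)
  for (i in seq_len(reps)) {
    se <- runif(5, 0.5, 2)
    r <- rnorm(5, 0, se)
    w <- 1 / se^2
    center <- sum(w * r) / sum(w)
    rej[i] <- cochranQ(r, se, center)$p < 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 0.013)
})

# MR-Egger ------------------------------------------------------------------

test_that("Egger recovers exact linear data and enforces its preconditions", {
  g <- c(0.05, 0.1, 0.2, 0.3)
  G <- 0.02 + 0.4 * g
  h <- HarmonizedSet(g, rep(0.002, 4), G, rep(0.01, 4))
  est <- mrEgger(h)
  expect_equal(estimate(est), 0.4, tolerance = 1e-10)
  expect_equal(est@eggerIntercept, 0.02, tolerance = 1e-10)
  expect_error(mrEgger(HarmonizedSet(c(0.1, 0.1), c(0.01, 0.01),
                                     c(0.1, 0.1), c(0.01, 0.01))),
               "at least 3")
  # no spread after re-signing to positive exposure effects
  h_col <- HarmonizedSet(c(0.1, 0.1, -0.1), rep(0.01, 3),
                         c(0.03, 0.04, -0.03), rep(0.01, 3))
  expect_error(mrEgger(h_col), "collinear")
})

test_that("Egger intercept orientation follows the positive-gamma convention", {
  # flipping an instrument's reported allele must not move the fit
  g <- c(0.05, 0.1, 0.2, 0.3)
  G <- 0.02 + 0.4 * g
  h1 <- mrEgger(HarmonizedSet(g, rep(0.002, 4), G, rep(0.01, 4)))
  g2 <- g; G2 <- G
  g2[2] <- -g2[2]; G2[2] <- -G2[2]
  h2 <- mrEgger(HarmonizedSet(g2, rep(0.002, 4), G2, rep(0.01, 4)))
  expect_equal(estimate(h2), estimate(h1), tolerance = 1e-12)
  expect_equal(h2@eggerIntercept, h1@eggerIntercept, tolerance = 1e-12)
})

test_that("the Egger pleiotropy test is calibrated under balanced pleiotropy", {
  # Design under the method's assumptions: equal outcome SEs (fixed maf) so
  # the weighted residuals are exactly homoscedastic, no causal effect (no
  # regression-dilution intercept bias), J = 50.
  reps <- 2000
  rej <- logical(reps)
  for (i in seq_len(reps)) {
    cfg <- big_case_control_config(
      n_snps = 50, beta_causal = 0, maf_range = c(0.5, 0.5),
      pleiotropy = list(mode = "balanced", mean_alpha = 0, sd_alpha = 0.01,
                        invalid_fraction = 1), seed = i)
    est <- mrEgger(hset_from_sim(simulateTwoSample(cfg)))
    rej[i] <- est@eggerInterceptP < 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 0.013)
})

# Weighted median -----------------------------------------------------------

test_that("the weighted median of three equally weighted ratios is the middle one", {
  g <- rep(1, 3)
  h <- HarmonizedSet(g, rep(0.01, 3), c(0.2, 0.5, 0.9), rep(0.01, 3))
  est <- weightedMedian(h, n_boot = 200, seed = 1L)
  expect_equal(estimate(est), 0.5)
  expect_error(weightedMedian(h, n_boot = 99), "configuration error")
})

test_that("the weighted median tracks the valid majority with 3 of 10 invalid instruments", {
  set.seed(77)
  J <- 10
  g <- runif(J, 0.05, 0.1)
  sy <- rep(0.004, J)
  alpha <- c(rep(0, 7), rep(0.05, 3))  # large positive direct effects
  G <- 0.3 * g + alpha + rnorm(J, 0, sy)
  h <- HarmonizedSet(g, rep(0.002, J), G, sy)
  wm <- weightedMedian(h, n_boot = 500, seed = 2L)
  expect_lt(abs(estimate(wm) - 0.3), 0.05)
})

test_that("the interpolated weighted median equals a brute-force CDF scan", {
  set.seed(12)
  for (i in 1:25) {
    J <- sample(3:15, 1)
    b <- rnorm(J)
    w <- runif(J, 0.1, 5)
    h <- HarmonizedSet(rep(1, J), rep(0.01, J), b, 1 / sqrt(w))
    est <- weightedMedian(h, n_boot = 100, seed = 1L)
    expect_equal(estimate(est), wm_oracle(b, w), tolerance = 1e-12)
  }
})

# Mode-based estimate -------------------------------------------------------

test_that("MBE returns the common value for identical ratios and the majority mode otherwise", {
  g <- rep(1, 4)
  h_same <- HarmonizedSet(g, rep(0.01, 4), rep(0.5, 4), rep(0.01, 4))
  expect_equal(estimate(modeBasedEstimate(h_same, n_boot = 200)), 0.5)

  set.seed(15)
  J <- 10
  gg <- rep(1, J)
  ratios <- c(0.3 + rnorm(7, 0, 0.01), 1.2 + rnorm(3, 0, 0.01))
  h_bi <- HarmonizedSet(gg, rep(0.01, J), ratios, rep(0.02, J))
  est <- modeBasedEstimate(h_bi, n_boot = 300, seed = 4L)
  expect_lt(abs(estimate(est) - 0.3), 0.05)
  expect_error(modeBasedEstimate(h_bi, phi = 0), "phi")
  expect_error(modeBasedEstimate(h_bi, n_boot = 10), "configuration error")
})

test_that("the MBE grid maximizer matches a 10x finer independent evaluation", {
  set.seed(21)
  for (i in 1:10) {
    J <- 12
    b <- rnorm(J, 0.4, 0.3)
    w <- runif(J, 0.5, 2)
    h <- HarmonizedSet(rep(1, J), rep(0.01, J), b, 1 / sqrt(w))
    est <- modeBasedEstimate(h, n_boot = 100, seed = 1L)
    bw <- 0.9 * min(sd(b), mad(b)) * J^(-1 / 5)
    lo <- min(b) - 2 * bw; hi <- max(b) + 2 * bw
    step <- (hi - lo) / 511
    fine <- seq(lo, hi, length.out = 5120)
    oracle <- fine[which.max(kde_oracle(fine, b, w, bw))]
    expect_lt(abs(estimate(est) - oracle), step + 1e-12)
  }
})

# MR-PRESSO -----------------------------------------------------------------

test_that("MR-PRESSO flags a planted tenfold outlier and corrects toward truth", {
  set.seed(8)
  J <- 12
  g <- runif(J, 0.05, 0.1)
  sy <- rep(0.004, J)
  G <- 0.3 * g + rnorm(J, 0, sy)
  G[5] <- 3.0 * g[5]                 # ratio 10x the others
  h <- HarmonizedSet(g, rep(0.002, J), G, sy)
  est <- mrPresso(h, n_sim = 2000, seed = 1L)
  expect_true("snp5" %in% est@outliers)
  expect_lt(abs(estimate(est) - 0.3), 0.05)
  expect_lt(est@pressoGlobalP, 0.01)
  expect_true(est@distortionP >= 0 && est@distortionP <= 1)
  raw_ivw <- ivwRandomEffects(h)
  expect_gt(abs(estimate(raw_ivw) - 0.3), abs(estimate(est) - 0.3))
})

test_that("MR-PRESSO enforces its preconditions", {
  g <- runif(4, 0.05, 0.1)
  h <- HarmonizedSet(g, rep(0.002, 4), 0.3 * g, rep(0.004, 4))
  expect_error(mrPresso(h, n_sim = 999), "configuration error")
  h3 <- HarmonizedSet(g[1:3], rep(0.002, 3), 0.3 * g[1:3], rep(0.004, 3))
  expect_error(mrPresso(h3), "at least 4")
})

# MR-Robust -----------------------------------------------------------------

test_that("robust regression matches IVW on clean data and resists a gross outlier", {
  g <- c(0.05, 0.1, 0.2, 0.3)
  h_clean <- HarmonizedSet(g, rep(0.002, 4), 0.4 * g, rep(0.01, 4))
  expect_lt(abs(estimate(mrRobust(h_clean)) -
                estimate(ivwRandomEffects(h_clean))), 1e-6)

  set.seed(19)
  J <- 20
  gg <- runif(J, 0.05, 0.1)
  sy <- rep(0.004, J)
  G <- 0.3 * gg + rnorm(J, 0, sy)
  G[7] <- G[7] + 0.2                  # gross outlier
  h <- HarmonizedSet(gg, rep(0.002, J), G, sy)
  rob <- mrRobust(h)
  ivw_19 <- ivwRandomEffects(HarmonizedSet(gg[-7], rep(0.002, J - 1),
                                           G[-7], sy[-7]))
  expect_lt(abs(estimate(rob) - estimate(ivw_19)), 0.02)
  expect_gt(abs(estimate(ivwRandomEffects(h)) - estimate(ivw_19)), 0.02)
})

test_that("robust regression is deterministic and a fixed point on re-fit", {
  set.seed(23)
  J <- 15
  g <- runif(J, 0.05, 0.1)
  G <- 0.3 * g + rnorm(J, 0, 0.004)
  h <- HarmonizedSet(g, rep(0.002, J), G, rep(0.004, J))
  a <- mrRobust(h)
  b <- mrRobust(h)
  expect_identical(estimate(a), estimate(b))
  expect_identical(stdErr(a), stdErr(b))
})

# MR-RAPS -------------------------------------------------------------------

test_that("RAPS recovers noiseless proportional data with zero overdispersion", {
  g <- c(0.05, 0.1, 0.2, 0.3)
  h <- HarmonizedSet(g, rep(0.002, 4), 0.4 * g, rep(0.01, 4))
  est <- mrRaps(h)
  expect_equal(estimate(est), 0.4, tolerance = 1e-8)
  expect_equal(attr(est, "tau2"), 0)
})

test_that("RAPS and IVW agree in the overdispersion-free limit", {
  # Huber winsorization leaves a small finite-J wobble, so the agreement is
  # assessed across seeds: on clean data the two estimates should typically
  # sit well within half an IVW standard error of each other
  rel <- vapply(1:25, function(s) {
    sim <- simulateTwoSample(big_case_control_config(n_snps = 50,
                                                     beta_causal = 0.3,
                                                     seed = s))
    h <- hset_from_sim(sim)
    ivw <- ivwRandomEffects(h)
    abs(estimate(mrRaps(h)) - estimate(ivw)) / stdErr(ivw)
  }, numeric(1))
  expect_gte(mean(rel < 0.5), 0.8)
  expect_lt(median(rel), 0.3)
})

test_that("the RAPS solution matches a 2-D brute-force grid over (beta, tau2)", {
  sim <- simulateTwoSample(big_case_control_config(
    n_snps = 15, beta_causal = 0.2,
    pleiotropy = list(mode = "balanced", mean_alpha = 0, sd_alpha = 0.01,
                      invalid_fraction = 1), seed = 60L))
  h <- hset_from_sim(sim)
  est <- mrRaps(h)
  tau2_hat <- attr(est, "tau2")
  df <- instruments(h)
  g <- df$beta_exp; G <- df$beta_out
  sx2 <- df$se_exp^2; sy2 <- df$se_out^2
  J <- length(g)
  psi <- function(t) pmax(-1.345, pmin(1.345, t))
  delta <- 2 * pnorm(1.345) - 1
  score_norm <- function(beta, tau2) {
    v <- sy2 + beta^2 * sx2 + tau2
    t <- (G - beta * g) / sqrt(v)
    s1 <- sum(psi(t) * g / sqrt(v)) / sqrt(sum(g^2 / sy2))
    s2 <- (sum(psi(t) * t) - J * delta) / J
    s1^2 + s2^2
  }
  b_grid <- seq(estimate(est) - 0.05, estimate(est) + 0.05,
                length.out = 101)                  # step 0.001
  t_grid <- seq(0, max(2 * tau2_hat, 4 * median(sy2)),
                length.out = 81)
  vals <- outer(b_grid, t_grid, Vectorize(score_norm))
  idx <- which(vals == min(vals), arr.ind = TRUE)[1, ]
  expect_lt(abs(b_grid[idx[1]] - estimate(est)), diff(b_grid[1:2]) + 1e-12)
  expect_lt(abs(t_grid[idx[2]] - tau2_hat), diff(t_grid[1:2]) + 1e-12)
})

# Multivariable IVW ---------------------------------------------------------

test_that("multivariable IVW solves exact data and reduces to IVW for one exposure", {
  set.seed(44)
  J <- 8
  g1 <- runif(J, 0.05, 0.1)
  g2 <- runif(J, 0.02, 0.08)
  sy <- runif(J, 0.004, 0.01)
  G <- 0.3 * g1 + 0 * g2
  mv <- multivariableIVW(cbind(vitc = g1, smoking = g2), G, sy)
  expect_equal(estimate(mv$vitc), 0.3, tolerance = 1e-10)
  expect_equal(estimate(mv$smoking), 0, tolerance = 1e-10)

  Gn <- 0.3 * g1 + rnorm(J, 0, sy)
  uni <- multivariableIVW(cbind(g1), Gn, sy)[[1]]
  ivw <- ivwRandomEffects(HarmonizedSet(g1, rep(0.002, J), Gn, sy))
  expect_equal(estimate(uni), estimate(ivw), tolerance = 1e-12)
  expect_equal(stdErr(uni), stdErr(ivw), tolerance = 1e-12)
})

test_that("multivariable IVW matches hand-rolled normal equations on random designs", {
  set.seed(45)
  for (i in 1:5) {
    J <- 20
    X <- cbind(runif(J, 0.05, 0.1), runif(J, 0.02, 0.08))
    sy <- runif(J, 0.004, 0.01)
    G <- X %*% c(0.3, -0.1) + rnorm(J, 0, sy)
    mv <- multivariableIVW(X, as.numeric(G), sy)
    W <- diag(1 / sy^2)
    beta_o <- solve(t(X) %*% W %*% X, t(X) %*% W %*% G)
    expect_equal(estimate(mv[[1]]), beta_o[1], tolerance = 1e-10)
    expect_equal(estimate(mv[[2]]), beta_o[2], tolerance = 1e-10)
  }
  X <- cbind(1:5 / 10, 2 * (1:5) / 10)   # rank deficient
  expect_error(multivariableIVW(X, rnorm(5), rep(0.01, 5)), "collinear")
  expect_error(multivariableIVW(cbind(1:2 / 10, 2:3 / 10), rnorm(2),
                                rep(0.01, 2)), "at least")
})

# Estimator suite -----------------------------------------------------------

test_that("a single-instrument set yields IVW only, others not applicable", {
  h <- HarmonizedSet(0.05, 0.01, 0.025, 0.005)
  suite <- runEstimatorSuite(h)
  tab <- suite$table
  expect_equal(tab$status[tab$method == "ivw_re"], "ok")
  expect_true(all(tab$status[tab$method != "ivw_re"] == "not_applicable"))
  expect_equal(tab$beta[tab$method == "ivw_re"], 0.5)
})

test_that("all seven methods recover a clean simulated effect within 2 SE", {
  sim <- simulateTwoSample(big_case_control_config(n_snps = 10,
                                                   beta_causal = 0.3,
                                                   seed = 7L))
  suite <- runEstimatorSuite(hset_from_sim(sim))
  tab <- suite$table
  expect_equal(tab$status, rep("ok", 7))
  expect_true(all(abs(tab$beta - 0.3) < 2 * tab$se))
})

test_that("suite ordering, schema, and stochastic members are reproducible", {
  sim <- simulateTwoSample(big_case_control_config(n_snps = 10,
                                                   beta_causal = 0.1,
                                                   seed = 2L))
  h <- hset_from_sim(sim)
  s1 <- runEstimatorSuite(h, suiteConfig(n_boot = 300, presso_n_sim = 1000))
  s2 <- runEstimatorSuite(h, suiteConfig(n_boot = 300, presso_n_sim = 1000))
  expect_identical(s1$table, s2$table)
  expect_equal(s1$table$method, c("ivw_re", "egger", "weighted_median",
                                  "mbe", "presso", "robust", "raps"))
  expect_equal(names(s1$table),
               c("method", "status", "n_snps", "beta", "se", "or", "ci_low",
                 "ci_high", "or_ci_low", "or_ci_high", "p", "q", "q_p",
                 "egger_intercept", "egger_intercept_p", "presso_global_p",
                 "outliers"))
})

test_that("stochastic estimators leave the caller's RNG stream untouched", {
  sim <- simulateTwoSample(big_case_control_config(n_snps = 10, seed = 2L))
  h <- hset_from_sim(sim)
  set.seed(1234)
  before <- rnorm(1)
  set.seed(1234)
  invisible(weightedMedian(h, n_boot = 100))
  invisible(mrPresso(h, n_sim = 1000))
  after <- rnorm(1)
  expect_identical(before, after)
})

# Equivariance properties ----------------------------------------------------

test_that("all estimators are scale equivariant in the outcome units", {
  sim <- simulateTwoSample(big_case_control_config(n_snps = 12,
                                                   beta_causal = 0.2,
                                                   seed = 33L))
  df <- instruments(hset_from_sim(sim))
  cc <- 2.5
  h1 <- HarmonizedSet(df$beta_exp, df$se_exp, df$beta_out, df$se_out)
  h2 <- HarmonizedSet(df$beta_exp, df$se_exp, cc * df$beta_out,
                      cc * df$se_out)
  cfg <- suiteConfig(n_boot = 300, presso_n_sim = 1000)
  t1 <- runEstimatorSuite(h1, cfg)$table
  t2 <- runEstimatorSuite(h2, cfg)$table
  expect_equal(t2$beta, cc * t1$beta, tolerance = 1e-6)
  expect_equal(t2$se, cc * t1$se, tolerance = 1e-6)
})

test_that("deterministic estimators are sign equivariant in the outcome", {
  sim <- simulateTwoSample(big_case_control_config(n_snps = 12,
                                                   beta_causal = 0.2,
                                                   seed = 34L))
  df <- instruments(hset_from_sim(sim))
  h1 <- HarmonizedSet(df$beta_exp, df$se_exp, df$beta_out, df$se_out)
  h2 <- HarmonizedSet(df$beta_exp, df$se_exp, -df$beta_out, df$se_out)
  for (fn in list(ivwRandomEffects, mrEgger, mrRobust, mrRaps)) {
    e1 <- fn(h1); e2 <- fn(h2)
    expect_equal(estimate(e2), -estimate(e1), tolerance = 1e-6)
    expect_equal(stdErr(e2), stdErr(e1), tolerance = 1e-6)
  }
  # point estimates of the ratio-based robust methods negate exactly too
  expect_equal(estimate(weightedMedian(h2, n_boot = 100)),
               -estimate(weightedMedian(h1, n_boot = 100)),
               tolerance = 1e-12)
  expect_equal(estimate(modeBasedEstimate(h2, n_boot = 100)),
               -estimate(modeBasedEstimate(h1, n_boot = 100)),
               tolerance = 1e-9)
})
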