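test_that("Wald ratio arithmetic, degenerate cases and SE conventions", {
  expect_equal(wald_ratio(0.1, 0.01, 0.05, 0.02)$beta, 0.5)
  expect_equal(wald_ratio(0.1, 0.01, 0, 0.02)$beta, 0)
  expect_error(wald_ratio(0, 0.01, 0.05, 0.02), "inestimable")
  # first-order (NOME) SE ignores the exposure error; second order adds it
  w1 <- wald_ratio(0.2, 0.05, 0.1, 0.02)
  expect_equal(w1$se, 0.02 / 0.2)
  w2 <- wald_ratio(0.2, 0.05, 0.1, 0.02, second_order = TRUE)
  expect_gt(w2$se, w1$se)
})

test_that("IVW reduces to the Wald ratio for one SNP and averages symmetric pairs", {
  s1 <- data.frame(snp_id = "a", beta_exposure = 0.2, se_exposure = 0.02,
                   beta_outcome = 0.08, se_outcome = 0.03)
  expect_equal(mr_ivw(s1)$beta, wald_ratio(0.2, 0.02, 0.08, 0.03)$beta)
  expect_equal(mr_ivw(s1, random_effects = FALSE)$se, 0.03 / 0.2)
  s2 <- data.frame(snp_id = c("a", "b"),
                   beta_exposure = c(0.1, 0.1), se_exposure = 0.01,
                   beta_outcome = c(0.04, 0.06), se_outcome = 0.02)
  expect_equal(mr_ivw(s2)$beta, 0.5)
})

test_that("IVW matches a weighted-least-squares-through-origin oracle", {
  ss <- toy_summary_stats(L = 10, slope = 0.3, noise_y = 0.02)
  est <- mr_ivw(ss, random_effects = FALSE)
  # brute-force WLS through the origin with weights 1/se_outcome^2
  w <- 1 / ss$se_outcome^2
  b_oracle <- sum(w * ss$beta_exposure * ss$beta_outcome) /
    sum(w * ss$beta_exposure^2)
  se_oracle <- sqrt(1 / sum(w * ss$beta_exposure^2))
  expect_lt(abs(est$beta - b_oracle), 1e-10)
  expect_lt(abs(est$se - se_oracle), 1e-10)
})

test_that("IVW is invariant to allele reorientation and drops zero-effect SNPs", {
  ss <- toy_summary_stats(L = 8, slope = 0.4, noise_y = 0.03)
  flip <- ss
  flip$beta_exposure[c(2, 5)] <- -flip$beta_exposure[c(2, 5)]
  flip$beta_outcome[c(2, 5)] <- -flip$beta_outcome[c(2, 5)]
  expect_equal(mr_ivw(flip)$beta, mr_ivw(ss)$beta, tolerance = 1e-12)
  ss$beta_exposure[3] <- 0
  expect_warning(est <- mr_ivw(ss), "zero SNP-exposure")
  expect_equal(est$n_snps, 7)
})

test_that("MR-Egger recovers an exact proportional relationship with zero intercept", {
  ss <- toy_summary_stats(L = 8, slope = 0.7, noise_y = 0)
  e <- mr_egger(ss)
  expect_equal(e$beta, 0.7, tolerance = 1e-8)
  expect_lt(abs(e$intercept), 1e-10)
  # with a zero fitted intercept the slope equals the IVW slope
  expect_equal(e$beta, mr_ivw(ss)$beta, tolerance = 1e-8)
  expect_error(mr_egger(ss[1:2, ]), "at least 3")
})

test_that("MR-Egger intercept is centred on zero without pleiotropy", {
  set.seed(30)
  n_rep <- 200
  icpt <- vapply(seq_len(n_rep), function(r) {
    L <- 12
    bx_true <- runif(L, 0.1, 0.3)
    ss <- data.frame(snp_id = seq_len(L),
                     beta_exposure = bx_true + rnorm(L, 0, 0.01),
                     se_exposure = 0.01,
                     beta_outcome = 0.3 * bx_true + rnorm(L, 0, 0.02),
                     se_outcome = 0.02)
    mr_egger(ss)$intercept
  }, 0)
  expect_lt(abs(mean(icpt)), 2 * sd(icpt) / sqrt(n_rep))
})

test_that("weighted median interpolates cumulative weights correctly", {
  eq <- data.frame(snp_id = 1:3, beta_exposure = 1, se_exposure = 0.01,
                   beta_outcome = c(0.1, 0.5, 0.9), se_outcome = 0.05)
  expect_equal(mr_weighted_median(eq, n_boot = 50, seed = 1)$beta, 0.5)
  cc <- data.frame(snp_id = 1:4, beta_exposure = c(0.1, 0.2, 0.3, 0.4),
                   se_exposure = 0.01,
                   beta_outcome = 0.25 * c(0.1, 0.2, 0.3, 0.4),
                   se_outcome = 0.05)
  expect_equal(mr_weighted_median(cc, n_boot = 50, seed = 1)$beta, 0.25)
  # 7-ratio instance against a brute-force cumulative-weight oracle
  ss <- toy_summary_stats(L = 7, slope = 0.3, noise_y = 0.05, seed = 44)
  est <- mr_weighted_median(ss, n_boot = 50, seed = 2)
  r <- ss$beta_outcome / ss$beta_exposure
  w <- (ss$beta_exposure / ss$se_outcome)^2
  o <- order(r); r <- r[o]; w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  k <- max(which(s < 0.5))
  oracle <- r[k] + (r[k + 1] - r[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
  expect_lt(abs(est$beta - oracle), 1e-12)
  expect_error(mr_weighted_median(ss[1:2, ]), "at least 3")
})

test_that("weighted mode finds the dominant cluster of ratios", {
  cc <- data.frame(snp_id = 1:5, beta_exposure = 0.2, se_exposure = 0.01,
                   beta_outcome = 0.2 * 0.6, se_outcome = 0.02)
  expect_equal(mr_weighted_mode(cc, n_boot = 50, seed = 3)$beta, 0.6,
               tolerance = 1e-8)
  set.seed(31)
  L <- 15
  bx <- runif(L, 0.15, 0.3)
  by <- 0.5 * bx
  by[1:3] <- by[1:3] + 0.8   # a minority of pleiotropic outliers
  ss <- data.frame(snp_id = seq_len(L), beta_exposure = bx,
                   se_exposure = 0.01, beta_outcome = by + rnorm(L, 0, 0.005),
                   se_outcome = 0.02)
  est <- mr_weighted_mode(ss, n_boot = 100, seed = 4)
  expect_lt(abs(est$beta - 0.5), 0.1)
  expect_error(mr_weighted_mode(ss[1:2, ]), "at least 3")
})

test_that("bootstrap standard errors are reproducible under a fixed seed", {
  ss <- toy_summary_stats(L = 9, slope = 0.4, noise_y = 0.03, seed = 46)
  m1 <- mr_weighted_median(ss, n_boot = 200, seed = 99)
  m2 <- mr_weighted_median(ss, n_boot = 200, seed = 99)
  expect_identical(m1$se, m2$se)
  k1 <- mr_weighted_mode(ss, n_boot = 200, seed = 99)
  k2 <- mr_weighted_mode(ss, n_boot = 200, seed = 99)
  expect_identical(k1$se, k2$se)
  expect_true(m1$se > 0 && k1$se > 0)
})

test_that("Cochran's Q matches its direct-sum oracle and closed-form cases", {
  cc <- data.frame(snp_id = 1:4, beta_exposure = 0.2, se_exposure = 0.01,
                   beta_outcome = 0.1, se_outcome = 0.02)
  q0 <- cochran_q(cc)
  expect_equal(q0$Q, 0)
  expect_equal(q0$p, 1)
  # two estimates differing by exactly 1.96 joint standard errors
  est2 <- data.frame(beta = c(0, 1.959964 * sqrt(0.1^2 + 0.15^2)),
                     se = c(0.1, 0.15))
  pooled <- with(est2, sum(beta / se^2) / sum(1 / se^2))
  q2 <- cochran_q(est2)
  expect_equal(q2$p, 0.05, tolerance = 1e-4)
  ss <- toy_summary_stats(L = 5, slope = 0.3, noise_y = 0.05, seed = 48)
  q5 <- cochran_q(ss)
  r <- ss$beta_outcome / ss$beta_exposure
  w <- (ss$beta_exposure / ss$se_outcome)^2
  b <- sum(w * r) / sum(w)
  expect_lt(abs(q5$Q - sum(w * (r - b)^2)), 1e-10)
  expect_equal(q5$df, 4)
})

test_that("the difference test between MR estimates behaves like a z-test", {
  a <- list(beta = 0.5, se = 0.1)
  expect_equal(mr_pdiff(a, a), 1)
  b <- list(beta = 0.5 + 1.959964 * sqrt(0.1^2 + 0.2^2), se = 0.2)
  expect_equal(mr_pdiff(a, b), 0.05, tolerance = 1e-4)
})

test_that("the split-half difference test is uniform under the null", {
  set.seed(32)
  n_rep <- 200
  pvals <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    coh <- simulate_cohort(sim_config(n_families = 800, n_snps = 6,
                                      v_gx = 0.4, seed = 5000 + r,
                                      b_xy = 0))
    fams <- unique(coh$ped$family_id)
    half <- sample(fams, length(fams) / 2)
    ea <- local({
      h <- subset_families(coh, half)
      sc <- assoc_scan(h, c("x", "y"), "family_fe")
      mr_ivw(summary_stats(sc$x, sc$y))
    })
    eb <- local({
      h <- subset_families(coh, setdiff(fams, half))
      sc <- assoc_scan(h, c("x", "y"), "family_fe")
      mr_ivw(summary_stats(sc$x, sc$y))
    })
    pvals[r] <- mr_pdiff(ea, eb)
  }
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})
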