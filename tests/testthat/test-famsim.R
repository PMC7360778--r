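test_that("configuration rejects invalid variance shares and frequencies", {
  expect_error(sim_config(100, v_gx = 0.6, c_x = 0.5), "exposure")
  expect_error(sim_config(100, b_xy = 0.5, b_ux = 0.3, c_y = 0.3), "outcome")
  expect_error(sim_config(100, v_gx = -0.1), "non-negative")
  expect_error(sim_config(100, allele_freq = 1), "allele_freq")
  expect_error(sim_config(100, allele_freq = 0), "allele_freq")
  expect_error(sim_config(100, assort_rho = 1), "assort_rho")
  expect_error(sim_config(100, strat = list(af_offset = 0.6, y_offset = 0,
                                            prop = 0.5)), "af_offset")
  expect_silent(sim_config(100, n_snps = 5, allele_freq = rep(0.3, 5)))
})

test_that("a cohort has two parents and the configured siblings per family", {
  coh <- toy_cohort(n_families = 10)
  expect_equal(nrow(coh$ped), 40)
  expect_equal(as.vector(table(coh$ped$role)), rep(10L, 4))
  per_fam <- table(coh$ped$family_id, coh$ped$role)
  expect_true(all(per_fam == 1))
  expect_true(all(dosages(coh) %in% 0:2))
})

test_that("offspring alleles reproduce exactly from parents and indicators", {
  coh <- toy_cohort(n_families = 60, seed = 7)
  ped <- coh$ped
  off <- ped[!(ped$role %in% c("mother", "father")), ]
  for (k in seq_len(nrow(off))) {
    id <- off$individual_id[k]
    tm <- coh$trans$mother[id, ]
    tf <- coh$trans$father[id, ]
    ma <- ifelse(tm == 1, coh$geno$a1[off$mother_id[k], ],
                 coh$geno$a2[off$mother_id[k], ])
    fa <- ifelse(tf == 1, coh$geno$a1[off$father_id[k], ],
                 coh$geno$a2[off$father_id[k], ])
    expect_identical(unname(coh$geno$a1[id, ]), unname(as.integer(ma)))
    expect_identical(unname(coh$geno$a2[id, ]), unname(as.integer(fa)))
  }
})

test_that("identical configurations give bit-identical cohorts", {
  a <- toy_cohort(n_families = 50, seed = 33, b_xy = 0.02, b_ux = 0.1,
                  c_x = 0.1, c_y = 0.1)
  b <- toy_cohort(n_families = 50, seed = 33, b_xy = 0.02, b_ux = 0.1,
                  c_x = 0.1, c_y = 0.1)
  expect_identical(a$geno, b$geno)
  expect_identical(a$trans, b$trans)
  expect_identical(a$pheno, b$pheno)
})

test_that("transmission is deterministic for homozygotes and fair for heterozygotes", {
  n <- 10000
  hom1 <- transmit(matrix(1L, n, 1), matrix(1L, n, 1))
  expect_true(all(hom1$allele == 1L))
  hom0 <- transmit(matrix(0L, n, 1), matrix(0L, n, 1))
  expect_true(all(hom0$allele == 0L))
  set.seed(9)
  het <- transmit(matrix(1L, n, 1), matrix(0L, n, 1))
  # binomial oracle: freq 0.5 within 3 * sqrt(0.25 / n)
  expect_lt(abs(mean(het$allele) - 0.5), 3 * sqrt(0.25 / n))
  expect_true(all(het$which %in% 1:2))
  expect_error(transmit(matrix(2L, 2, 2), matrix(0L, 2, 2)), "0/1")
})

test_that("allele frequency is conserved from parents to offspring", {
  coh <- big_cohort()
  par <- coh$ped$role %in% c("mother", "father")
  dos <- dosages(coh)
  p_par <- mean(dos[par, ]) / 2
  p_off <- mean(dos[!par, ]) / 2
  n_alleles <- sum(!par) * ncol(dos) * 2
  expect_lt(abs(p_off - p_par), 3 * sqrt(0.25 / n_alleles))
})

test_that("phenotypes are standardized: mean ~ 0, variance within [0.95, 1.05] per role", {
  coh <- big_cohort()
  ph <- coh$pheno
  for (r in unique(ph$role)) {
    for (v in c("x", "y")) {
      vals <- ph[[v]][ph$role == r]
      expect_lt(abs(mean(vals)), 0.05)
      expect_gt(var(vals), 0.95)
      expect_lt(var(vals), 1.05)
    }
  }
})

test_that("SNPs jointly explain v_gx of exposure variance", {
  coh <- simulate_cohort(sim_config(n_families = 5000, n_snps = 90,
                                    seed = 17, v_gx = 0.1))
  off <- !(coh$ped$role %in% c("mother", "father"))
  score <- drop(dosages(coh)[off, ] %*% coh$snps$beta_x)
  r2 <- summary(lm(coh$pheno$x[off] ~ score))$r.squared
  expect_lt(abs(r2 - 0.10), 0.02)
})

test_that("the fully null model gives uncorrelated offspring exposure and outcome", {
  coh <- simulate_cohort(sim_config(n_families = 4000, n_snps = 12,
                                    seed = 19))
  off <- !(coh$ped$role %in% c("mother", "father"))
  n <- sum(off)
  expect_lt(abs(cor(coh$pheno$x[off], coh$pheno$y[off])), 3 / sqrt(n))
})

test_that("the dynastic path explains b_ux of offspring outcome variance", {
  coh <- simulate_cohort(sim_config(n_families = 5000, n_snps = 12,
                                    seed = 23, b_ux = 0.1))
  ph <- coh$pheno
  s_par <- ph$x[ph$role == "mother"] + ph$x[ph$role == "father"]
  off <- ph[!(ph$role %in% c("mother", "father")), ]
  s_rep <- rep(s_par, 2)   # sib1 block then sib2 block, family-aligned
  r2 <- summary(lm(off$y ~ s_rep))$r.squared
  expect_lt(abs(r2 - 0.10), 0.02)
})

test_that("the causal slope of outcome on exposure is sqrt(b_xy)", {
  # 100,000 offspring with no dynastic or assortment paths
  coh <- simulate_cohort(sim_config(n_families = 50000, n_snps = 12,
                                    n_sibs = 2, seed = 29, b_xy = 0.01))
  off <- !(coh$ped$role %in% c("mother", "father"))
  fit <- lm(coh$pheno$y[off] ~ coh$pheno$x[off])
  expect_lt(abs(unname(coef(fit)[2]) - 0.1), 0.01)
})

test_that("assortative mating realizes the target spousal exposure correlation", {
  coh <- simulate_cohort(sim_config(n_families = 5000, n_snps = 12,
                                    seed = 37, assort_rho = 0.4))
  ph <- coh$pheno
  r <- cor(ph$x[ph$role == "mother"], ph$x[ph$role == "father"])
  expect_lt(abs(r - 0.4), 0.05)
  coh0 <- simulate_cohort(sim_config(n_families = 5000, n_snps = 12,
                                     seed = 37))
  r0 <- cor(coh0$pheno$x[coh0$pheno$role == "mother"],
            coh0$pheno$x[coh0$pheno$role == "father"])
  expect_lt(abs(r0), 0.05)
})

test_that("two-deme stratification shifts allele frequency and outcome mean", {
  coh <- simulate_cohort(sim_config(
    n_families = 4000, n_snps = 12, seed = 41,
    strat = list(af_offset = 0.2, y_offset = 0.5, prop = 0.5)))
  ph <- coh$pheno
  expect_setequal(unique(ph$deme), c("A", "B"))
  par <- ph$role %in% c("mother", "father")
  pA <- mean(dosages(coh)[par & ph$deme == "A", ]) / 2
  pB <- mean(dosages(coh)[par & ph$deme == "B", ]) / 2
  expect_gt(pB - pA, 0.15)
  expect_gt(mean(ph$y[ph$deme == "B"]) - mean(ph$y[ph$deme == "A"]), 0.3)
  expect_lt(abs(mean(ph$y)), 0.05)
})

test_that("the confounder-routed dynastic path feeds both offspring phenotypes", {
  coh <- simulate_cohort(sim_config(n_families = 4000, n_snps = 12,
                                    seed = 43, b_ux = 0.2, c_x = 0.2,
                                    c_y = 0.2,
                                    dynastic_path = "confounder"))
  ph <- coh$pheno
  s_par <- ph$x[ph$role == "mother"] + ph$x[ph$role == "father"]
  off <- ph[!(ph$role %in% c("mother", "father")), ]
  s_rep <- rep(s_par, 2)
  expect_gt(cor(off$confounder, s_rep), 0.3)
  expect_gt(cor(off$x, s_rep), 0.05)  # absent under the direct routing
  expect_gt(cor(off$y, s_rep), 0.05)
})

test_that("sibling IBD proportions follow the transmission indicators exactly", {
  coh <- toy_cohort(n_families = 30, seed = 53)
  s1 <- coh$ped$individual_id[coh$ped$role == "sib1"]
  s2 <- coh$ped$individual_id[coh$ped$role == "sib2"]
  # identical indicators -> IBD 1; fully opposite -> IBD 0
  coh$trans$mother[s2, ] <- coh$trans$mother[s1, ]
  coh$trans$father[s2, ] <- coh$trans$father[s1, ]
  expect_true(all(sibling_ibd(coh)$pairs$ibd == 1))
  coh$trans$mother[s2, ] <- 3L - coh$trans$mother[s1, ]
  coh$trans$father[s2, ] <- 3L - coh$trans$father[s1, ]
  expect_true(all(sibling_ibd(coh)$pairs$ibd == 0))
})

test_that("IBD requires sibling pairs with transmission indicators", {
  solo <- simulate_cohort(sim_config(n_families = 20, n_snps = 5,
                                     n_sibs = 1, seed = 59))
  expect_error(sibling_ibd(solo), "sibling pairs")
  coh <- toy_cohort(n_families = 10)
  coh$trans <- NULL
  expect_error(sibling_ibd(coh), "transmission")
})
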