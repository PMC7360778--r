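# Shared fixture builders. All cohorts are generated in code at test time.

# One large null cohort (90 SNPs, 10,000 families) shared across the
# moment/IBD tests; built once per test run.
.fixture_cache <- new.env()
big_cohort <- function() {
  if (is.null(.fixture_cache$big))
    .fixture_cache$big <- simulate_cohort(
      sim_config(n_families = 10000, n_snps = 90, seed = 20260921))
  .fixture_cache$big
}

# Small default cohort: sibling pairs, no confounding paths.
toy_cohort <- function(n_families = 200, seed = 101, ...) {
  simulate_cohort(sim_config(n_families = n_families, n_snps = 12,
                             seed = seed, ...))
}

# A hand-built cohort of two-sibling families with fully controlled
# genotypes and phenotypes, for exact-value tests. `dos` is a matrix of
# offspring dosages (2 rows per family: sib1, sib2 interleaved by family
# blocks); parents get dosage 1 everywhere (heterozygous).
manual_cohort <- function(dos_sib1, dos_sib2, y_sib1, y_sib2,
                          x_sib1 = y_sib1, x_sib2 = y_sib2) {
  nf <- nrow(dos_sib1)
  L <- ncol(dos_sib1)
  fam <- sprintf("fam%06d", seq_len(nf))
  roles <- c("mother", "father", "sib1", "sib2")
  ids <- lapply(roles, function(r) paste0(fam, "_", r))
  ped <- data.frame(individual_id = unlist(ids),
                    family_id = rep(fam, 4),
                    father_id = c(rep("0", 2 * nf), rep(ids[[2]], 2)),
                    mother_id = c(rep("0", 2 * nf), rep(ids[[1]], 2)),
                    sex = c(rep(2L, nf), rep(1L, nf), rep(1L, 2 * nf)),
                    role = rep(roles, each = nf),
                    stringsAsFactors = FALSE)
  snp_ids <- sprintf("snp%03d", seq_len(L))
  split_geno <- function(d) list(a1 = pmin(d, 1L), a2 = pmax(d - 1L, 0L))
  par1 <- matrix(1L, nf, L); par0 <- matrix(0L, nf, L)
  a1 <- rbind(par1, par1, pmin(dos_sib1, 1L), pmin(dos_sib2, 1L))
  a2 <- rbind(par0, par0, pmax(dos_sib1 - 1L, 0L), pmax(dos_sib2 - 1L, 0L))
  dimnames(a1) <- dimnames(a2) <- list(ped$individual_id, snp_ids)
  pheno <- data.frame(individual_id = ped$individual_id,
                      family_id = ped$family_id, role = ped$role,
                      x = c(rep(0, 2 * nf), x_sib1, x_sib2),
                      y = c(rep(0, 2 * nf), y_sib1, y_sib2),
                      confounder = 0, deme = "A",
                      stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = snp_ids, allele_freq = 0.5,
                     effect_allele = "A", other_allele = "G",
                     beta_x = 0, beta_y_direct = 0,
                     stringsAsFactors = FALSE)
  structure(list(ped = ped, geno = list(a1 = a1, a2 = a2), trans = NULL,
                 pheno = pheno, snps = snps,
                 config = sim_config(n_families = nf, n_snps = L),
                 dos = a1 + a2),
            class = "family_cohort")
}

# Synthetic summary statistics with a known causal slope and optional noise.
toy_summary_stats <- function(L = 10, slope = 0.5, seed = 5,
                              noise_y = 0) {
  set.seed(seed)
  bx <- runif(L, 0.05, 0.3)
  sex <- runif(L, 0.01, 0.03)
  sey <- runif(L, 0.01, 0.03)
  by <- slope * bx + if (noise_y > 0) rnorm(L, 0, noise_y) else 0
  data.frame(snp_id = sprintf("snp%03d", seq_len(L)),
             beta_exposure = bx, se_exposure = sex,
             beta_outcome = by, se_outcome = sey,
             stringsAsFactors = FALSE)
}
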