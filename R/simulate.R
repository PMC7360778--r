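#' Simulation configuration for family cohorts
#'
#' Collects and validates every generative parameter of the forward-in-time
#' family simulator. All path parameters are *variance shares*: the structural
#' slope applied to a standardized source is the square root of the share, so
#' e.g. \code{b_xy = 0.01} means the exposure explains 1\% of outcome variance
#' and the structural slope is 0.1.
#'
#' @param n_families Number of mother-father-offspring families (>= 1).
#' @param n_snps Number of independently segregating biallelic loci.
#' @param allele_freq Effect-allele frequency, scalar or length-\code{n_snps}
#'   vector, strictly inside (0, 1). Parents are drawn under
#'   Hardy-Weinberg equilibrium at these frequencies.
#' @param v_gx Variance share of the exposure explained jointly by all SNPs.
#'   Each SNP carries an equal share \code{v_gx / n_snps}.
#' @param b_xy Variance share of the offspring outcome explained by the
#'   offspring exposure (the causal path; structural slope \code{sqrt(b_xy)}).
#' @param b_ux Variance share of the offspring outcome explained by the
#'   standardized sum of the two parents' exposures (the dynastic path).
#' @param c_x,c_y Variance shares of exposure/outcome explained by an
#'   individual-level normal confounder.
#' @param n_sibs Number of offspring per family (>= 1; 2 gives sibling pairs).
#' @param assort_rho Target spousal correlation of exposures in [0, 1).
#'   0 means random mating; positive values rank-match spouses on exposure
#'   plus calibrated noise.
#' @param strat Optional two-deme population-stratification spec: a list with
#'   \code{af_offset} (allele-frequency offset of deme B), \code{y_offset}
#'   (outcome mean offset of deme B, applied mean-centred) and \code{prop}
#'   (proportion of families in deme B). Mating is within deme.
#' @param dynastic_path Either \code{"outcome"} (default; parental exposures
#'   act directly on the offspring outcome) or \code{"confounder"} (parental
#'   exposures load on the offspring's confounder, which then feeds both
#'   offspring exposure and outcome through \code{c_x}, \code{c_y}).
#' @param pleio_y Variance share of the outcome explained by direct SNP
#'   effects (directional horizontal pleiotropy; default 0, i.e. none).
#' @param seed Integer RNG seed; \code{NULL} leaves the RNG state untouched.
#'
#' @return An object of class \code{sim_config} (a validated list).
#' @examples
#' cfg <- sim_config(n_families = 100, seed = 1)
#' @export
sim_config <- function(n_families, n_snps = 90, allele_freq = 0.5,
                       v_gx = 0.1, b_xy = 0, b_ux = 0, c_x = 0, c_y = 0,
                       n_sibs = 2, assort_rho = 0, strat = NULL,
                       dynastic_path = c("outcome", "confounder"),
                       pleio_y = 0, seed = NULL) {
  dynastic_path <- match.arg(dynastic_path)
  stopifnot(length(n_families) == 1L, n_families >= 1,
            length(n_snps) == 1L, n_snps >= 1,
            length(n_sibs) == 1L, n_sibs >= 1)
  if (!length(allele_freq) %in% c(1L, n_snps))
    stop("allele_freq must have length 1 or n_snps")
  if (any(allele_freq <= 0 | allele_freq >= 1))
    stop("allele_freq must lie strictly inside (0, 1)")
  shares <- c(v_gx = v_gx, b_xy = b_xy, b_ux = b_ux, c_x = c_x, c_y = c_y,
              pleio_y = pleio_y)
  if (any(shares < 0)) stop("variance shares must be non-negative")
  if (v_gx + c_x >= 1)
    stop("variance shares for the exposure (v_gx + c_x) sum to >= 1")
  if (b_xy + b_ux + c_y + pleio_y >= 1)
    stop("variance shares for the outcome (b_xy + b_ux + c_y + pleio_y) sum to >= 1")
  if (assort_rho < 0 || assort_rho >= 1) stop("assort_rho must lie in [0, 1)")
  if (!is.null(strat)) {
    if (!all(c("af_offset", "y_offset", "prop") %in% names(strat)))
      stop("strat must be a list with af_offset, y_offset and prop")
    if (strat$prop <= 0 || strat$prop >= 1)
      stop("strat$prop must lie strictly inside (0, 1)")
    if (any(allele_freq + strat$af_offset <= 0 |
            allele_freq + strat$af_offset >= 1))
      stop("strat$af_offset pushes an allele frequency outside (0, 1)")
  }
  structure(list(n_families = as.integer(n_families),
                 n_snps = as.integer(n_snps),
                 allele_freq = rep_len(allele_freq, n_snps),
                 v_gx = v_gx, b_xy = b_xy, b_ux = b_ux,
                 c_x = c_x, c_y = c_y, n_sibs = as.integer(n_sibs),
                 assort_rho = assort_rho, strat = strat,
                 dynastic_path = dynastic_path, pleio_y = pleio_y,
                 seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Family simulation configuration\n")
  cat(sprintf("  families: %d (%d sibs each), SNPs: %d\n",
              x$n_families, x$n_sibs, x$n_snps))
  cat(sprintf("  shares: v_gx=%.3g b_xy=%.3g b_ux=%.3g c_x=%.3g c_y=%.3g\n",
              x$v_gx, x$b_xy, x$b_ux, x$c_x, x$c_y))
  cat(sprintf("  dynastic path: %s; assort_rho=%.2f; stratified: %s\n",
              x$dynastic_path, x$assort_rho, !is.null(x$strat)))
  invisible(x)
}

## Bernoulli allele draws at per-entry frequencies (matrix in, matrix out).
.draw_alleles <- function(n, pmat) {
  m <- stats::runif(length(pmat)) < pmat
  storage.mode(m) <- "integer"
  dim(m) <- dim(pmat)
  m
}

## Transmission without input validation, for the simulator's hot path.
.transmit_fast <- function(a1, a2) {
  wh <- (stats::runif(length(a1)) < 0.5) + 1L
  dim(wh) <- dim(a1)
  list(allele = a1 * (wh == 1L) + a2 * (wh == 2L), which = wh)
}

#' Mendelian transmission of parental alleles
#'
#' At each locus each parent passes one of its two allele copies to the
#' offspring with probability 1/2, independently across loci and offspring.
#' The indicator of which copy was transmitted is retained so that
#' identity-by-descent sharing between siblings can be computed exactly.
#'
#' @param a1,a2 Integer matrices (individuals x loci) of 0/1 allele indicators
#'   for the parent's first and second allele copy.
#' @return A list with \code{allele} (the transmitted 0/1 allele matrix) and
#'   \code{which} (matrix of 1/2 indicators of the transmitted copy).
#' @examples
#' tr <- transmit(matrix(1L, 2, 3), matrix(0L, 2, 3))
#' stopifnot(all(tr$allele == (tr$which == 1L)))
#' @export
transmit <- function(a1, a2) {
  if (!is.matrix(a1) || !is.matrix(a2) || !all(dim(a1) == dim(a2)))
    stop("a1 and a2 must be matrices of identical dimension")
  if (!all(a1 %in% 0:1) || !all(a2 %in% 0:1))
    stop("allele matrices must contain 0/1 indicators only")
  .transmit_fast(a1, a2)
}

## Centred per-individual genetic score and its per-allele weights.
## Weights are equal-share: each SNP explains v_gx/L of exposure variance at
## the base allele frequency, so w_j = sqrt((v_gx/L) / (2 p_j q_j)).
.score_weights <- function(config) {
  p <- config$allele_freq
  sqrt((config$v_gx / config$n_snps) / (2 * p * (1 - p)))
}

## Draw a phenotype with unit theoretical variance: systematic part `sys`
## plus a normal residual whose variance is 1 minus the realized variance of
## `sys`. Errors (naming the phenotype) when the systematic variance reaches 1.
.add_residual <- function(sys, what) {
  v <- stats::var(sys)
  if (v >= 1)
    stop(sprintf("systematic variance of the %s reaches %.3f >= 1; reduce its variance shares",
                 what, v))
  sys + stats::rnorm(length(sys), sd = sqrt(1 - v))
}

## Parental exposure given centred genetic score and confounder.
.parent_exposure <- function(g_centred, conf, config) {
  .add_residual(g_centred + sqrt(config$c_x) * conf, "exposure")
}

#' Simulate a family cohort under dynastic effects
#'
#' Forward-in-time simulation of families of two unrelated parents and
#' \code{n_sibs} full siblings. Parental genotypes are drawn under
#' Hardy-Weinberg equilibrium, spouses are paired at random (or rank-matched
#' on exposure under assortative mating), alleles are transmitted to the
#' offspring with stored transmission indicators, and phenotypes are built
#' from the variance-share paths of the configuration: SNPs -> exposure,
#' exposure -> outcome, confounder -> both, and parental exposures ->
#' offspring outcome (the dynastic path). All phenotypes have mean ~0 and
#' theoretical variance 1.
#'
#' @param config A \code{\link{sim_config}} object.
#' @return An object of class \code{family_cohort}: a list with elements
#'   \code{ped} (pedigree table: individual_id, family_id, father_id,
#'   mother_id, sex, role), \code{geno} (list of 0/1 allele matrices
#'   \code{a1}, \code{a2}), \code{trans} (offspring transmission indicator
#'   matrices \code{mother}, \code{father}), \code{pheno} (individual_id,
#'   family_id, role, x, y, confounder, deme), \code{snps} (snp_id,
#'   allele_freq, effect/other allele, true per-allele exposure effect
#'   \code{beta_x}, direct outcome effect \code{beta_y_direct}) and
#'   \code{config}.
#' @examples
#' coh <- simulate_cohort(sim_config(n_families = 50, n_snps = 10, seed = 1))
#' table(coh$ped$role)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  nf <- config$n_families
  L <- config$n_snps
  ns <- config$n_sibs
  p <- config$allele_freq

  ## deme assignment (families); allele frequencies per parent row
  if (is.null(config$strat)) {
    deme <- rep("A", nf)
    pmat <- matrix(p, nrow = nf, ncol = L, byrow = TRUE)
  } else {
    deme <- ifelse(stats::runif(nf) < config$strat$prop, "B", "A")
    pmat <- matrix(p, nrow = nf, ncol = L, byrow = TRUE)
    pmat[deme == "B", ] <- pmat[deme == "B", ] +
      rep(rep_len(config$strat$af_offset, L), each = sum(deme == "B"))
  }

  ## parents: genotypes, confounders, exposures (exposure needed for mating)
  m_a1 <- .draw_alleles(nf, pmat); m_a2 <- .draw_alleles(nf, pmat)
  f_a1 <- .draw_alleles(nf, pmat); f_a2 <- .draw_alleles(nf, pmat)
  w <- .score_weights(config)
  g_m <- drop((m_a1 + m_a2) %*% w); g_m <- g_m - mean(g_m)
  g_f <- drop((f_a1 + f_a2) %*% w); g_f <- g_f - mean(g_f)
  conf_m <- stats::rnorm(nf)
  conf_f <- stats::rnorm(nf)
  x_m <- .parent_exposure(g_m, conf_m, config)
  x_f <- .parent_exposure(g_f, conf_f, config)

  ## spouse pairing: within deme, random or rank-matched on exposure + noise.
  ## Noise sd sqrt(1/rho - 1) makes the rank-matched correlation ~ rho.
  ford <- seq_len(nf)
  for (d in unique(deme)) {
    idx <- which(deme == d)
    if (config$assort_rho > 0) {
      s <- sqrt(1 / config$assort_rho - 1)
      mo <- order(x_m[idx] + s * stats::rnorm(length(idx)))
      fo <- order(x_f[idx] + s * stats::rnorm(length(idx)))
      ford[idx[mo]] <- idx[fo]
    } else {
      ford[idx] <- idx[sample.int(length(idx))]
    }
  }
  f_a1 <- f_a1[ford, , drop = FALSE]; f_a2 <- f_a2[ford, , drop = FALSE]
  g_f <- g_f[ford]; conf_f <- conf_f[ford]; x_f <- x_f[ford]

  ## transmission to each offspring
  o_a1 <- o_a2 <- t_m <- t_f <- vector("list", ns)
  for (s in seq_len(ns)) {
    trm <- .transmit_fast(m_a1, m_a2)
    trf <- .transmit_fast(f_a1, f_a2)
    o_a1[[s]] <- trm$allele
    o_a2[[s]] <- trf$allele
    t_m[[s]] <- trm$which
    t_f[[s]] <- trf$which
  }

  ## identifiers; row order is mothers, fathers, sib1..sibK (block layout)
  fam <- sprintf("fam%06d", seq_len(nf))
  roles <- c("mother", "father", paste0("sib", seq_len(ns)))
  ids <- lapply(roles, function(r) paste0(fam, "_", r))
  ped <- data.frame(
    individual_id = unlist(ids),
    family_id = rep(fam, length(roles)),
    father_id = c(rep("0", 2 * nf), rep(ids[[2]], ns)),
    mother_id = c(rep("0", 2 * nf), rep(ids[[1]], ns)),
    sex = c(rep(2L, nf), rep(1L, nf),
            1L + (stats::runif(nf * ns) < 0.5)),
    role = rep(roles, each = nf),
    stringsAsFactors = FALSE)

  a1 <- do.call(rbind, c(list(m_a1, f_a1), o_a1))
  a2 <- do.call(rbind, c(list(m_a2, f_a2), o_a2))
  snp_ids <- sprintf("snp%03d", seq_len(L))
  dimnames(a1) <- dimnames(a2) <- list(ped$individual_id, snp_ids)
  tmat_m <- do.call(rbind, t_m)
  tmat_f <- do.call(rbind, t_f)
  off_ids <- unlist(ids[-(1:2)])
  dimnames(tmat_m) <- dimnames(tmat_f) <- list(off_ids, snp_ids)

  pleio_w <- if (config$pleio_y > 0) {
    sqrt((config$pleio_y / L) / (2 * p * (1 - p)))
  } else rep(0, L)
  snps <- data.frame(snp_id = snp_ids, allele_freq = p,
                     effect_allele = "A", other_allele = "G",
                     beta_x = w, beta_y_direct = pleio_w,
                     stringsAsFactors = FALSE)

  cohort <- structure(list(ped = ped,
                           geno = list(a1 = a1, a2 = a2),
                           trans = list(mother = tmat_m, father = tmat_f),
                           pheno = NULL, snps = snps, config = config,
                           dos = a1 + a2),
                      class = "family_cohort")
  assign_phenotypes(cohort, config,
                    parent_exposure = c(x_m, x_f),
                    parent_confounder = c(conf_m, conf_f),
                    deme = rep(deme, length(roles)))
}

#' Assign phenotypes to a simulated cohort
#'
#' Builds exposures and outcomes from the genotypes of a cohort under the
#' variance-share paths of \code{config}. Parental exposure/confounder values
#' can be supplied (as done by \code{\link{simulate_cohort}}, where they must
#' exist before spouse pairing); otherwise they are drawn afresh. The
#' offspring outcome receives the dynastic component: the standardized sum of
#' the two parents' exposures scaled to explain \code{b_ux} of its variance,
#' either directly (default) or routed through the offspring confounder.
#'
#' @param cohort A \code{family_cohort} with genotypes and pedigree present.
#' @param config A \code{\link{sim_config}}.
#' @param parent_exposure,parent_confounder Optional numeric vectors for the
#'   parent rows (mothers then fathers, in pedigree order).
#' @param deme Optional character vector of deme labels per individual.
#' @return The cohort with its \code{pheno} table filled.
#' @export
assign_phenotypes <- function(cohort, config, parent_exposure = NULL,
                              parent_confounder = NULL, deme = NULL) {
  stopifnot(inherits(cohort, "family_cohort"), inherits(config, "sim_config"))
  ped <- cohort$ped
  nf <- config$n_families
  ns <- config$n_sibs
  w <- .score_weights(config)
  dos <- dosages(cohort)
  if (is.null(deme)) deme <- rep("A", nrow(ped))

  is_mother <- ped$role == "mother"
  is_father <- ped$role == "father"
  is_off <- !(is_mother | is_father)

  if (is.null(parent_confounder)) parent_confounder <- stats::rnorm(2 * nf)
  conf_m <- parent_confounder[seq_len(nf)]
  conf_f <- parent_confounder[nf + seq_len(nf)]
  if (is.null(parent_exposure)) {
    g_m <- drop(dos[is_mother, , drop = FALSE] %*% w)
    g_f <- drop(dos[is_father, , drop = FALSE] %*% w)
    x_m <- .parent_exposure(g_m - mean(g_m), conf_m, config)
    x_f <- .parent_exposure(g_f - mean(g_f), conf_f, config)
  } else {
    x_m <- parent_exposure[seq_len(nf)]
    x_f <- parent_exposure[nf + seq_len(nf)]
  }

  ## standardized combined parental exposure, per family
  s_par <- x_m + x_f
  s_par <- (s_par - mean(s_par)) / stats::sd(s_par)

  ## deme outcome offset, mean-centred so the population mean stays 0
  y_off <- numeric(nrow(ped))
  if (!is.null(config$strat)) {
    b <- deme == "B"
    y_off <- config$strat$y_offset * (as.numeric(b) - mean(b))
  }

  ## direct SNP -> outcome pleiotropy component (centred)
  pleio <- numeric(nrow(ped))
  if (config$pleio_y > 0) {
    pw <- sqrt((config$pleio_y / config$n_snps) /
                 (2 * config$allele_freq * (1 - config$allele_freq)))
    pl <- drop(dos %*% pw)
    pleio <- pl - mean(pl)
  }

  ## parents' outcomes
  sys_y_m <- sqrt(config$b_xy) * x_m + sqrt(config$c_y) * conf_m +
    pleio[is_mother] + y_off[is_mother]
  sys_y_f <- sqrt(config$b_xy) * x_f + sqrt(config$c_y) * conf_f +
    pleio[is_father] + y_off[is_father]
  y_m <- .add_residual(sys_y_m, "outcome")
  y_f <- .add_residual(sys_y_f, "outcome")

  ## offspring: confounder (optionally carrying the dynastic path), exposure,
  ## outcome (with the direct dynastic component under the default routing)
  n_off <- nf * ns
  s_rep <- rep(s_par, ns)                       # per offspring, family order
  if (config$dynastic_path == "confounder" && config$b_ux > 0) {
    conf_o <- sqrt(config$b_ux) * s_rep +
      sqrt(1 - config$b_ux) * stats::rnorm(n_off)
  } else {
    conf_o <- stats::rnorm(n_off)
  }
  g_o <- drop(dos[is_off, , drop = FALSE] %*% w)
  g_o <- g_o - mean(g_o)
  x_o <- .add_residual(g_o + sqrt(config$c_x) * conf_o, "exposure")
  sys_y_o <- sqrt(config$b_xy) * x_o + sqrt(config$c_y) * conf_o +
    pleio[is_off] + y_off[is_off]
  if (config$dynastic_path == "outcome" && config$b_ux > 0)
    sys_y_o <- sys_y_o + sqrt(config$b_ux) * s_rep
  y_o <- .add_residual(sys_y_o, "outcome")

  pheno <- data.frame(
    individual_id = ped$individual_id,
    family_id = ped$family_id,
    role = ped$role,
    x = c(x_m, x_f, x_o),
    y = c(y_m, y_f, y_o),
    confounder = c(conf_m, conf_f, conf_o),
    deme = deme,
    stringsAsFactors = FALSE)
  cohort$pheno <- pheno
  cohort
}

#' Additive dosage matrix of a cohort
#'
#' @param cohort A \code{family_cohort}.
#' @return Integer matrix (individuals x SNPs) of effect-allele counts 0/1/2.
#' @export
dosages <- function(cohort) {
  stopifnot(inherits(cohort, "family_cohort"))
  if (!is.null(cohort$dos)) cohort$dos else cohort$geno$a1 + cohort$geno$a2
}

#' @export
print.family_cohort <- function(x, ...) {
  cat(sprintf("Family cohort: %d individuals in %d families, %d SNPs\n",
              nrow(x$ped), length(unique(x$ped$family_id)), nrow(x$snps)))
  print(table(x$ped$role))
  invisible(x)
}

#' Identity-by-descent sharing between siblings
#'
#' Scores, for every sibling pair, each locus as sharing 0, 1 or 2 parental
#' allele copies identical by descent (each parent contributes a shared copy
#' when its transmission indicator is equal in the two siblings), and averages
#' the per-locus proportion over loci. For L independent loci the per-pair
#' mean has expectation 1/2 and standard deviation sqrt(0.125 / L); at L = 90
#' this is 0.0373.
#'
#' @param cohort A \code{family_cohort} containing sibling pairs with
#'   transmission indicators.
#' @return An object of class \code{ibd_summary}: list with \code{pairs}
#'   (data.frame family_id, sib1, sib2, ibd) and \code{mean}, \code{sd}
#'   across pairs.
#' @export
sibling_ibd <- function(cohort) {
  stopifnot(inherits(cohort, "family_cohort"))
  if (is.null(cohort$trans))
    stop("cohort has no transmission indicators (file-based cohorts carry dosages only)")
  ped <- cohort$ped
  off <- ped[!(ped$role %in% c("mother", "father")), ]
  n_per_fam <- table(off$family_id)
  if (!any(n_per_fam >= 2))
    stop("cohort has no family with >= 2 offspring; IBD requires sibling pairs")
  tm <- cohort$trans$mother
  tf <- cohort$trans$father
  if (all(n_per_fam == 2)) {
    ## fast path: exactly one pair per family, block row layout
    fams <- names(n_per_fam)
    split_ids <- split(off$individual_id, off$family_id)
    id1 <- vapply(split_ids, `[`, "", 1L)
    id2 <- vapply(split_ids, `[`, "", 2L)
    shared <- (tm[id1, , drop = FALSE] == tm[id2, , drop = FALSE]) +
      (tf[id1, , drop = FALSE] == tf[id2, , drop = FALSE])
    ibd <- rowMeans(shared) / 2
    pairs <- data.frame(family_id = fams, sib1 = id1, sib2 = id2,
                        ibd = unname(ibd), stringsAsFactors = FALSE)
  } else {
    res <- lapply(split(off$individual_id, off$family_id), function(ids) {
      if (length(ids) < 2) return(NULL)
      cmb <- utils::combn(ids, 2)
      data.frame(sib1 = cmb[1, ], sib2 = cmb[2, ],
                 ibd = vapply(seq_len(ncol(cmb)), function(k) {
                   mean((tm[cmb[1, k], ] == tm[cmb[2, k], ]) +
                          (tf[cmb[1, k], ] == tf[cmb[2, k], ])) / 2
                 }, 0), stringsAsFactors = FALSE)
    })
    keep <- !vapply(res, is.null, TRUE)
    pairs <- do.call(rbind, res[keep])
    pairs <- data.frame(family_id = rep(names(res)[keep],
                                        vapply(res[keep], nrow, 0L)),
                        pairs, row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(pairs = pairs, mean = mean(pairs$ibd),
                 sd = stats::sd(pairs$ibd)),
            class = "ibd_summary")
}

#' @export
print.ibd_summary <- function(x, ...) {
  cat(sprintf("Sibling IBD over %d pairs: mean %.4f, SD %.4f\n",
              nrow(x$pairs), x$mean, x$sd))
  invisible(x)
}
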