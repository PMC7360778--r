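#' Shrinkage of total to within-family SNP-phenotype associations
#'
#' For every SNP, jointly estimates the total association (OLS of the
#' phenotype on dosage across all siblings, ignoring family) and the
#' within-family association (family fixed effects), together with their
#' cross-equation covariance from a stacked estimating-equation sandwich
#' clustered by family — a seemingly-unrelated-regression treatment of the
#' two equations fitted on the same sample. The per-SNP percent shrinkage is
#' 100 * (total - within) / total with a delta-method standard error, and an
#' inverse-variance fixed-effect pool across SNPs summarises the average
#' attenuation of associations once family-level confounding is removed.
#'
#' SNPs whose total association is indistinguishable from zero
#' (|beta_total| < 2 SE) give unstable ratios; their shrinkage is reported
#' as NA and they are excluded from the pooled estimate with a warning.
#'
#' @param cohort A \code{family_cohort} with sibling pairs.
#' @param snps Optional subset of SNP identifiers.
#' @param phenotype Phenotype column (\code{"x"} or \code{"y"}).
#' @return An object of class \code{shrinkage_result}: list with
#'   \code{per_snp} (snp_id, beta_total, se_total, beta_within, se_within,
#'   cov_tw, shrinkage, shrinkage_se) and \code{pooled} (est, se, ci_low,
#'   ci_high, p, n_snps, n_excluded).
#' @export
shrinkage_sur <- function(cohort, snps = NULL, phenotype = "y") {
  stopifnot(inherits(cohort, "family_cohort"))
  sel <- if (is.null(snps)) cohort$snps$snp_id else
    vapply(snps, function(s) .snp_name(cohort, s), "")
  ped <- cohort$ped
  off <- which(.offspring_rows(ped))
  fam <- ped$family_id[off]
  keep <- fam %in% names(which(table(fam) >= 2))
  off <- off[keep]; fam <- fam[keep]
  if (!length(off)) stop("cohort contains no families with >= 2 siblings")
  G <- dosages(cohort)[off, sel, drop = FALSE]
  storage.mode(G) <- "double"
  y <- .pheno_vec(cohort, phenotype, off)
  n <- length(off)

  nfam <- as.vector(table(fam)[fam])
  Gc <- sweep(G, 2, colMeans(G))
  yc <- y - mean(y)
  Gd <- G - rowsum(G, fam)[fam, , drop = FALSE] / nfam
  fmy <- rowsum(y, fam)[, 1] / as.vector(table(fam))
  yd <- y - fmy[fam]

  sxx_t <- colSums(Gc^2)
  sxx_w <- colSums(Gd^2)
  ok <- sxx_t > 0 & sxx_w > 0
  bt <- bw <- rep(NA_real_, length(sel))
  bt[ok] <- colSums(Gc[, ok, drop = FALSE] * yc) / sxx_t[ok]
  bw[ok] <- colSums(Gd[, ok, drop = FALSE] * yd) / sxx_w[ok]
  ut <- yc - Gc * rep(ifelse(ok, bt, 0), each = n)
  uw <- yd - Gd * rep(ifelse(ok, bw, 0), each = n)
  st <- rowsum(Gc * ut, fam)
  sw <- rowsum(Gd * uw, fam)
  g <- nrow(st)
  adj <- g / (g - 1)
  v_tt <- adj * colSums(st^2) / sxx_t^2
  v_ww <- adj * colSums(sw^2) / sxx_w^2
  v_tw <- adj * colSums(st * sw) / (sxx_t * sxx_w)

  shr <- 100 * (1 - bw / bt)
  ## delta method on R(t, w) = 100 (1 - w/t): grad = (100 w/t^2, -100/t)
  g1 <- 100 * bw / bt^2
  g2 <- -100 / bt
  shr_se <- sqrt(g1^2 * v_tt + 2 * g1 * g2 * v_tw + g2^2 * v_ww)

  weak <- ok & abs(bt) < 2 * sqrt(v_tt)
  shr[weak] <- NA_real_
  shr_se[weak] <- NA_real_
  if (any(weak))
    warning(sprintf("shrinkage inestimable for %d SNP(s) with total association ~ 0; excluded from pooling",
                    sum(weak)))

  per_snp <- data.frame(snp_id = sel, beta_total = bt,
                        se_total = sqrt(v_tt), beta_within = bw,
                        se_within = sqrt(v_ww), cov_tw = v_tw,
                        shrinkage = shr, shrinkage_se = shr_se,
                        row.names = NULL, stringsAsFactors = FALSE)
  use <- is.finite(shr) & is.finite(shr_se) & shr_se > 0
  if (!any(use)) {
    pooled <- list(est = NA_real_, se = NA_real_, ci_low = NA_real_,
                   ci_high = NA_real_, p = NA_real_, n_snps = 0L,
                   n_excluded = sum(!use))
  } else {
    wgt <- 1 / shr_se[use]^2
    est <- sum(wgt * shr[use]) / sum(wgt)
    se <- sqrt(1 / sum(wgt))
    pooled <- list(est = est, se = se,
                   ci_low = est - stats::qnorm(0.975) * se,
                   ci_high = est + stats::qnorm(0.975) * se,
                   p = 2 * stats::pnorm(-abs(est / se)),
                   n_snps = sum(use), n_excluded = sum(!use))
  }
  structure(list(per_snp = per_snp, pooled = pooled),
            class = "shrinkage_result")
}

#' @export
print.shrinkage_result <- function(x, ...) {
  p <- x$pooled
  cat(sprintf("SUR shrinkage over %d SNPs (%d excluded): %.1f%% (95%% CI %.1f to %.1f), p = %.3g\n",
              p$n_snps, p$n_excluded, p$est, p$ci_low, p$ci_high, p$p))
  invisible(x)
}
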