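#' Harmonize score weights to a target allele coding
#'
#' Aligns a table of per-SNP weights (effect allele, other allele, weight) to
#' the allele coding of a target genotype table. SNPs whose alleles match
#' pass through; SNPs with swapped effect/other alleles have their weight
#' sign flipped; SNPs whose allele pairs cannot be reconciled are dropped and
#' reported. Palindromic SNPs (A/T or C/G) are kept and flagged.
#'
#' @param weights data.frame with columns snp_id, effect_allele,
#'   other_allele, weight.
#' @param target data.frame with columns snp_id, effect_allele, other_allele
#'   giving the coding of the dosage data (e.g. \code{cohort$snps}).
#' @return The aligned weights data.frame (snp_id, effect_allele,
#'   other_allele, weight, palindromic), restricted to reconcilable SNPs,
#'   with attribute \code{"dropped"}: a data.frame of the discarded SNPs and
#'   the reason.
#' @export
harmonize_weights <- function(weights, target) {
  need <- c("snp_id", "effect_allele", "other_allele")
  stopifnot(all(c(need, "weight") %in% names(weights)),
            all(need %in% names(target)))
  if (anyDuplicated(weights$snp_id)) stop("duplicate snp_id in weights")
  m <- match(weights$snp_id, target$snp_id)
  reason <- rep(NA_character_, nrow(weights))
  reason[is.na(m)] <- "absent from target"
  same <- !is.na(m) & weights$effect_allele == target$effect_allele[m] &
    weights$other_allele == target$other_allele[m]
  swapped <- !is.na(m) & weights$effect_allele == target$other_allele[m] &
    weights$other_allele == target$effect_allele[m]
  reason[!is.na(m) & !same & !swapped] <- "irreconcilable alleles"
  keep <- same | swapped
  out <- weights[keep, need, drop = FALSE]
  out$weight <- ifelse(swapped[keep], -weights$weight[keep],
                       weights$weight[keep])
  ## report in the target's coding
  out$effect_allele <- target$effect_allele[m[keep]]
  out$other_allele <- target$other_allele[m[keep]]
  pal <- c(A = "T", T = "A", C = "G", G = "C")
  out$palindromic <- !is.na(pal[out$effect_allele]) &
    pal[out$effect_allele] == out$other_allele
  dropped <- data.frame(snp_id = weights$snp_id[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  if (nrow(dropped))
    message(sprintf("harmonize_weights: dropped %d of %d SNPs",
                    nrow(dropped), nrow(weights)))
  attr(out, "dropped") <- dropped
  rownames(out) <- NULL
  out
}

#' Weighted polygenic score
#'
#' Per-individual weighted sum of effect-allele dosages,
#' score_i = sum_j w_j dosage_ij. Weights must already be harmonized to the
#' dosage allele coding (see \code{\link{harmonize_weights}}).
#'
#' @param dosage Matrix of allele counts (individuals x SNPs) with SNP ids
#'   as column names, or a \code{family_cohort}.
#' @param weights data.frame with columns snp_id and weight.
#' @return Named numeric vector of scores. SNPs absent from the dosage
#'   matrix are skipped and reported via a message and the
#'   \code{"skipped"} attribute.
#' @export
build_prs <- function(dosage, weights) {
  if (inherits(dosage, "family_cohort")) dosage <- dosages(dosage)
  stopifnot(is.matrix(dosage), all(c("snp_id", "weight") %in% names(weights)))
  present <- weights$snp_id %in% colnames(dosage)
  if (!any(present)) stop("no usable SNPs: none of the weight SNPs are in the dosage matrix")
  if (any(!present))
    message(sprintf("build_prs: skipped %d SNPs absent from dosages",
                    sum(!present)))
  w <- weights$weight[present]
  sc <- drop(dosage[, weights$snp_id[present], drop = FALSE] %*% w)
  names(sc) <- rownames(dosage)
  attr(sc, "skipped") <- weights$snp_id[!present]
  sc
}

#' Two-stage least squares with optional family fixed effects
#'
#' Instrumental-variable estimation of the effect of an exposure on an
#' outcome. With \code{family_fe = TRUE} all variables (outcome, exposure,
#' instruments, covariates) are within-transformed by family before
#' estimation, which absorbs family-level confounding (dynastic effects,
#' assortative mating, population structure shared by siblings). Standard
#' errors are CR1 cluster-robust; the first-stage strength is reported as a
#' cluster-robust Wald F on the excluded instruments.
#'
#' @param outcome Numeric response vector.
#' @param exposure Numeric endogenous exposure vector.
#' @param instruments Numeric vector or matrix of instruments (e.g. a
#'   polygenic score).
#' @param covariates Optional exogenous covariate matrix.
#' @param clusters Cluster labels (families). Required when
#'   \code{family_fe = TRUE}, where they define the demeaning groups.
#' @param family_fe Apply the within transformation by cluster.
#' @param intercept Include an intercept (ignored under \code{family_fe},
#'   where demeaning removes it; set \code{FALSE} for difference-on-
#'   difference regressions through the origin).
#' @return An object of class \code{iv_estimate}: list with beta, se, p, n,
#'   first-stage F (\code{f_stat}), and method tag.
#' @examples
#' z <- rnorm(200); x <- z + rnorm(200); y <- 0.5 * x + rnorm(200)
#' tsls(y, x, z)
#' @export
tsls <- function(outcome, exposure, instruments, covariates = NULL,
                 clusters = NULL, family_fe = FALSE, intercept = TRUE) {
  Z <- as.matrix(instruments)
  if (ncol(Z) < 1) stop("at least one instrument is required")
  n <- length(outcome)
  stopifnot(length(exposure) == n, nrow(Z) == n)
  if (family_fe) {
    if (is.null(clusters))
      stop("family_fe = TRUE requires cluster (family) labels")
    dm <- function(v) v - stats::ave(v, clusters)
    outcome <- dm(outcome); exposure <- dm(exposure)
    Z <- apply(Z, 2, dm)
    if (!is.null(covariates)) covariates <- apply(as.matrix(covariates), 2, dm)
    exog <- NULL
  } else {
    exog <- if (intercept) cbind(`(Intercept)` = rep(1, n)) else NULL
  }
  if (!is.null(covariates)) exog <- cbind(exog, as.matrix(covariates))
  W1 <- cbind(Z, exog)                      # first-stage design
  if (all(abs(Z) < 1e-12))
    stop("inestimable: instruments have no (within-family) variance")
  qrw <- qr(W1)
  if (qrw$rank < ncol(W1)) stop("inestimable: first-stage design is rank deficient")
  fs_beta <- qr.coef(qrw, exposure)
  xhat <- drop(W1 %*% fs_beta)
  if (stats::var(xhat) < 1e-14)
    stop("inestimable: exposure has no (within-family) instrumented variance")
  X2 <- cbind(x = xhat, exog)
  b <- qr.coef(qr(X2), outcome)
  ## residuals use the actual exposure, not its projection
  Xact <- cbind(x = exposure, exog)
  u <- outcome - drop(Xact %*% b)
  cl <- if (is.null(clusters)) seq_len(n) else clusters
  V <- cluster_robust_cov(X2, u, cl)
  g <- length(unique(cl))
  ## cluster-robust first-stage F on the excluded instruments
  fs_u <- exposure - drop(W1 %*% fs_beta)
  Vfs <- cluster_robust_cov(W1, fs_u, cl)
  zi <- seq_len(ncol(Z))
  f_stat <- drop(t(fs_beta[zi]) %*%
                   solve(Vfs[zi, zi, drop = FALSE], fs_beta[zi])) / ncol(Z)
  se <- sqrt(V["x", "x"])
  beta <- unname(b["x"])
  structure(list(beta = beta, se = se,
                 p = 2 * stats::pt(-abs(beta / se), df = g - 1),
                 n = n, n_clusters = g, f_stat = unname(f_stat),
                 method = if (family_fe) "tsls_family_fe" else "tsls"),
            class = "iv_estimate")
}

#' @export
print.iv_estimate <- function(x, ...) {
  cat(sprintf("2SLS (%s): beta = %.4g (SE %.4g), p = %.3g, n = %d, first-stage F = %.1f\n",
              x$method, x$beta, x$se, x$p, x$n, x$f_stat))
  invisible(x)
}
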