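#' Assemble per-SNP summary statistics for MR
#'
#' Joins a SNP-exposure and a SNP-outcome association table (e.g. two
#' \code{\link{assoc_scan}} outputs) on snp_id into the aligned summary-data
#' format used by the pooled estimators.
#'
#' @param exposure,outcome data.frames with columns snp_id, beta, se.
#' @param sample_tag Optional label recording the sample(s) of origin.
#' @return data.frame with columns snp_id, beta_exposure, se_exposure,
#'   beta_outcome, se_outcome (class \code{summary_stats}).
#' @export
summary_stats <- function(exposure, outcome, sample_tag = NA_character_) {
  stopifnot(all(c("snp_id", "beta", "se") %in% names(exposure)),
            all(c("snp_id", "beta", "se") %in% names(outcome)))
  m <- match(exposure$snp_id, outcome$snp_id)
  keep <- !is.na(m)
  out <- data.frame(snp_id = exposure$snp_id[keep],
                    beta_exposure = exposure$beta[keep],
                    se_exposure = exposure$se[keep],
                    beta_outcome = outcome$beta[m[keep]],
                    se_outcome = outcome$se[m[keep]],
                    sample_tag = sample_tag,
                    stringsAsFactors = FALSE)
  out <- out[stats::complete.cases(out[, 2:5]), ]
  class(out) <- c("summary_stats", "data.frame")
  out
}

.mr_estimate <- function(method, beta, se, n_snps, p = NULL, df = NULL,
                         extra = NULL) {
  if (is.null(p)) {
    if (se == 0) {
      p <- if (beta == 0) 1 else 0   # noiseless limit
    } else {
      p <- if (is.null(df)) 2 * stats::pnorm(-abs(beta / se)) else
        2 * stats::pt(-abs(beta / se), df = df)
    }
  }
  structure(c(list(method = method, beta = beta, se = se, p = p,
                   ci_low = beta - stats::qnorm(0.975) * se,
                   ci_high = beta + stats::qnorm(0.975) * se,
                   n_snps = n_snps), extra),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate (%s): beta = %.4g (SE %.4g, 95%% CI %.4g to %.4g), p = %.3g, SNPs = %d\n",
              x$method, x$beta, x$se, x$ci_low, x$ci_high, x$p, x$n_snps))
  if (!is.null(x$Q))
    cat(sprintf("  heterogeneity Q = %.2f (df %d), p = %.3g\n",
                x$Q, x$Q_df, x$Q_p))
  if (!is.null(x$intercept))
    cat(sprintf("  Egger intercept = %.4g (SE %.4g), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_p))
  invisible(x)
}

#' Wald ratio causal estimate for a single SNP
#'
#' Ratio of the SNP-outcome to the SNP-exposure association. The default
#' standard error is the first-order delta approximation se_y/|beta_x|,
#' which treats the SNP-exposure association as known (the NOME convention);
#' \code{second_order = TRUE} adds the beta_x sampling term.
#'
#' @param beta_x,se_x SNP-exposure association and its SE.
#' @param beta_y,se_y SNP-outcome association and its SE.
#' @param second_order Use the second-order delta SE.
#' @return An \code{mr_estimate} with method \code{"wald"}.
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y, second_order = FALSE) {
  if (beta_x == 0)
    stop("inestimable: SNP-exposure association is exactly zero")
  beta <- beta_y / beta_x
  se <- if (second_order)
    sqrt(se_y^2 / beta_x^2 + beta_y^2 * se_x^2 / beta_x^4)
  else se_y / abs(beta_x)
  .mr_estimate("wald", beta, se, 1L)
}

## Ratios and IVW weights (NOME first-order); drops zero-beta_x SNPs.
.ratio_table <- function(stats) {
  bad <- stats$beta_exposure == 0
  if (any(bad)) {
    warning(sprintf("excluding %d SNP(s) with zero SNP-exposure association",
                    sum(bad)))
    stats <- stats[!bad, , drop = FALSE]
  }
  if (!nrow(stats)) stop("no usable SNPs")
  list(ratio = stats$beta_outcome / stats$beta_exposure,
       w = (stats$beta_exposure / stats$se_outcome)^2,
       se_ratio = stats$se_outcome / abs(stats$beta_exposure),
       stats = stats)
}

#' Inverse-variance weighted MR estimate
#'
#' Weighted mean of per-SNP Wald ratios with first-order inverse-variance
#' weights (beta_x/se_y)^2, equivalent to weighted least squares of
#' beta_outcome on beta_exposure through the origin. Under multiplicative
#' random effects the standard error is inflated by
#' max(1, sqrt(Q/(L-1))) when the heterogeneity statistic exceeds its
#' degrees of freedom.
#'
#' @param stats A \code{\link{summary_stats}} table.
#' @param random_effects Apply the multiplicative overdispersion scaling.
#' @return An \code{mr_estimate} with method \code{"ivw"} carrying Q, Q_df
#'   and Q_p.
#' @export
mr_ivw <- function(stats, random_effects = TRUE) {
  rt <- .ratio_table(stats)
  L <- length(rt$ratio)
  if (any(is.infinite(rt$w))) {
    ## noiseless limit: zero-SE SNPs carry infinite weight and dominate
    inf <- is.infinite(rt$w)
    beta <- mean(rt$ratio[inf])
    disagree <- stats::var(rt$ratio[inf]) > 0 && sum(inf) > 1
    return(.mr_estimate("ivw", beta, 0, L,
                        extra = list(Q = if (isTRUE(disagree)) Inf else 0,
                                     Q_df = L - 1L,
                                     Q_p = if (isTRUE(disagree)) 0 else 1)))
  }
  beta <- sum(rt$w * rt$ratio) / sum(rt$w)
  se <- sqrt(1 / sum(rt$w))
  Q <- sum(rt$w * (rt$ratio - beta)^2)
  if (random_effects && L > 1) se <- se * max(1, sqrt(Q / (L - 1)))
  .mr_estimate("ivw", beta, se, L,
               extra = list(Q = Q, Q_df = L - 1L,
                            Q_p = if (L > 1)
                              stats::pchisq(Q, L - 1, lower.tail = FALSE)
                            else NA_real_))
}

#' MR-Egger regression
#'
#' Weighted regression of SNP-outcome on SNP-exposure associations with an
#' intercept, weights 1/se_outcome^2, after orienting all SNPs to positive
#' SNP-exposure association. The slope is the pleiotropy-adjusted causal
#' estimate; the intercept tests directional pleiotropy. Standard errors use
#' multiplicative random effects (residual scale bounded below by 1);
#' p-values use t with L - 2 degrees of freedom.
#'
#' @param stats A \code{\link{summary_stats}} table with at least 3 SNPs.
#' @return An \code{mr_estimate} with method \code{"egger"} and fields
#'   \code{intercept}, \code{intercept_se}, \code{intercept_p}.
#' @export
mr_egger <- function(stats) {
  if (nrow(stats) < 3) stop("MR-Egger requires at least 3 SNPs")
  flip <- sign(stats$beta_exposure)
  flip[flip == 0] <- 1
  bx <- stats$beta_exposure * flip
  by <- stats$beta_outcome * flip
  w <- 1 / stats$se_outcome^2
  X <- cbind(1, bx)
  A <- crossprod(X * sqrt(w))
  b <- solve(A, crossprod(X * w, by))
  u <- by - drop(X %*% b)
  L <- length(bx)
  sigma2 <- sum(w * u^2) / (L - 2)
  V <- solve(A) * max(1, sigma2)
  beta <- b[2]; se <- sqrt(V[2, 2])
  icpt <- b[1]; icpt_se <- sqrt(V[1, 1])
  .mr_estimate("egger", beta, se, L, df = L - 2,
               extra = list(intercept = icpt, intercept_se = icpt_se,
                            intercept_p = 2 * stats::pt(-abs(icpt / icpt_se),
                                                        df = L - 2)))
}

## Weight-interpolated 50th percentile of ordered values.
.weighted_median <- function(b, w) {
  o <- order(b)
  b <- b[o]; w <- w[o]
  s <- (cumsum(w) - 0.5 * w) / sum(w)
  if (s[1] >= 0.5) return(b[1])
  if (s[length(s)] <= 0.5) return(b[length(b)])
  k <- max(which(s < 0.5))
  b[k] + (b[k + 1] - b[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

## Parametric bootstrap SE over resampled summary statistics.
.boot_se <- function(stats, estimator, n_boot, seed) {
  if (!is.null(seed)) set.seed(seed)
  L <- nrow(stats)
  reps <- vapply(seq_len(n_boot), function(i) {
    s <- stats
    s$beta_exposure <- stats::rnorm(L, stats$beta_exposure, stats$se_exposure)
    s$beta_outcome <- stats::rnorm(L, stats$beta_outcome, stats$se_outcome)
    estimator(s)
  }, 0)
  stats::sd(reps)
}

#' Weighted median MR estimate
#'
#' Weight-interpolated median of the per-SNP Wald ratios with first-order
#' inverse-variance weights; consistent when SNPs contributing at least half
#' the weight are valid instruments. The standard error comes from a seeded
#' parametric bootstrap of the summary statistics.
#'
#' @param stats A \code{\link{summary_stats}} table with at least 3 SNPs.
#' @param n_boot Bootstrap replicates for the SE.
#' @param seed Optional seed making the bootstrap reproducible.
#' @return An \code{mr_estimate} with method \code{"weighted_median"}.
#' @export
mr_weighted_median <- function(stats, n_boot = 1000, seed = NULL) {
  if (nrow(stats) < 3) stop("weighted median requires at least 3 SNPs")
  point <- function(s) {
    rt <- .ratio_table(s)
    .weighted_median(rt$ratio, rt$w)
  }
  beta <- point(stats)
  se <- .boot_se(stats, point, n_boot, seed)
  .mr_estimate("weighted_median", beta, se, nrow(stats))
}

#' Weighted mode MR estimate
#'
#' Kernel-density mode of the per-SNP Wald ratios with inverse-variance
#' weights; consistent when the largest group of SNPs with the same causal
#' estimate are valid instruments. The smoothing bandwidth is
#' \code{bandwidth} times the median-absolute-deviation scale of the ratios;
#' the standard error comes from a seeded parametric bootstrap.
#'
#' @inheritParams mr_weighted_median
#' @param bandwidth Bandwidth multiplier on the standardized-ratio scale.
#' @return An \code{mr_estimate} with method \code{"weighted_mode"}.
#' @export
mr_weighted_mode <- function(stats, bandwidth = 1, n_boot = 1000,
                             seed = NULL) {
  if (nrow(stats) < 3) stop("weighted mode requires at least 3 SNPs")
  point <- function(s) {
    rt <- .ratio_table(s)
    sc <- stats::mad(rt$ratio)
    if (sc == 0) sc <- stats::sd(rt$ratio)
    if (!is.finite(sc) || sc == 0) return(rt$ratio[1])
    d <- stats::density(rt$ratio, weights = rt$w / sum(rt$w),
                        bw = bandwidth * sc)
    d$x[which.max(d$y)]
  }
  beta <- point(stats)
  se <- .boot_se(stats, point, n_boot, seed)
  .mr_estimate("weighted_mode", beta, se, nrow(stats))
}

#' Cochran's Q heterogeneity statistic
#'
#' Q = sum w_j (est_j - pooled)^2 with a chi-square reference on L - 1
#' degrees of freedom. Accepts either a \code{\link{summary_stats}} table
#' (per-SNP Wald ratios with IVW weights) or a table of study estimates with
#' columns \code{beta} and \code{se} (weights 1/se^2).
#'
#' @param stats Summary statistics or study-estimate table (>= 2 rows).
#' @param pooled Pooled estimate; defaults to the fixed-effect
#'   inverse-variance mean.
#' @return List with Q, df and p.
#' @export
cochran_q <- function(stats, pooled = NULL) {
  if (all(c("beta_exposure", "beta_outcome") %in% names(stats))) {
    rt <- .ratio_table(stats)
    est <- rt$ratio; w <- rt$w
  } else {
    stopifnot(all(c("beta", "se") %in% names(stats)))
    est <- stats$beta; w <- 1 / stats$se^2
  }
  if (length(est) < 2) stop("Cochran's Q requires at least 2 estimates")
  if (is.null(pooled)) pooled <- sum(w * est) / sum(w)
  Q <- sum(w * (est - pooled)^2)
  df <- length(est) - 1L
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' Test the difference between two independent MR estimates
#'
#' z-test of the difference between two causal estimates, e.g. the
#' unrelated-sample estimate against the within-family split-sample
#' estimate. The estimates must come from non-overlapping samples for the
#' independence assumption to hold.
#'
#' @param est_a,est_b \code{mr_estimate} objects (or lists with \code{beta}
#'   and \code{se}).
#' @return Two-sided normal p-value.
#' @export
mr_pdiff <- function(est_a, est_b) {
  z <- (est_a$beta - est_b$beta) / sqrt(est_a$se^2 + est_b$se^2)
  2 * stats::pnorm(-abs(z))
}
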