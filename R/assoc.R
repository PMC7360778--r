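#' Cluster-robust sandwich covariance (CR1)
#'
#' Clustered sandwich covariance of OLS coefficients with the CR1
#' finite-sample factor G/(G-1) * (N-1)/(N-K), where G is the number of
#' clusters, N the number of observations and K the number of columns of the
#' design. With every observation its own cluster this reduces to the HC1
#' heteroskedasticity-robust estimator.
#'
#' @param X Design matrix (N x K) as used in the fit.
#' @param residuals OLS residual vector of length N.
#' @param clusters Cluster labels of length N (families); at least 2 distinct.
#' @return K x K covariance matrix (symmetric, positive semidefinite).
#' @examples
#' x <- cbind(1, rnorm(8)); y <- rnorm(8)
#' b <- qr.coef(qr(x), y)
#' cluster_robust_cov(x, y - x %*% b, rep(1:4, each = 2))
#' @export
cluster_robust_cov <- function(X, residuals, clusters) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- ncol(X)
  stopifnot(length(residuals) == n, length(clusters) == n)
  clusters <- as.character(clusters)
  g <- length(unique(clusters))
  if (g < 2) stop("cluster-robust covariance requires at least 2 clusters")
  bread <- solve(crossprod(X))
  scores <- rowsum(X * as.numeric(residuals), clusters)
  meat <- crossprod(scores)
  adj <- g / (g - 1) * (n - 1) / (n - k)
  v <- adj * bread %*% meat %*% bread
  (v + t(v)) / 2
}

## Single-coefficient association result container.
.assoc_result <- function(snp_id, method, beta, se, n, df, extra = NULL) {
  p <- 2 * stats::pt(-abs(beta / se), df = df)
  structure(c(list(snp_id = snp_id, method = method, beta = beta, se = se,
                   p = p, n = n, df = df), extra),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("%s association (%s): beta = %.4g (SE %.4g), p = %.3g, n = %d\n",
              x$snp_id, x$method, x$beta, x$se, x$p, x$n))
  if (!is.null(x$beta_mother))
    cat(sprintf("  mother: %.4g (SE %.4g)  father: %.4g (SE %.4g)\n",
                x$beta_mother, x$se_mother, x$beta_father, x$se_father))
  invisible(x)
}

## OLS with CR1 clustered errors; clusters default to one per observation.
.ols_cr <- function(X, y, clusters = NULL) {
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X))
    stop("inestimable: design matrix is rank deficient")
  if (is.null(clusters)) clusters <- seq_len(nrow(X))
  beta <- qr.coef(qr(X), y)
  u <- y - drop(X %*% beta)
  v <- cluster_robust_cov(X, u, clusters)
  list(beta = beta, vcov = v, resid = u, n = nrow(X),
       g = length(unique(clusters)))
}

## Resolve a snp argument (id or index) to a column name of the genotype
## matrices, and a phenotype argument to a pheno column.
.snp_name <- function(cohort, snp) {
  ids <- cohort$snps$snp_id
  if (is.numeric(snp)) return(ids[snp])
  if (!snp %in% ids) stop(sprintf("unknown SNP '%s'", snp))
  snp
}

.pheno_vec <- function(cohort, phenotype, rows) {
  if (!phenotype %in% names(cohort$pheno))
    stop(sprintf("unknown phenotype '%s'", phenotype))
  cohort$pheno[[phenotype]][rows]
}

## Offspring rows (logical) of a cohort pedigree.
.offspring_rows <- function(ped) !(ped$role %in% c("mother", "father"))

## First offspring per family by stable individual-ID order.
.first_sib_ids <- function(ped) {
  off <- ped[.offspring_rows(ped), ]
  off <- off[order(off$individual_id), ]
  off$individual_id[!duplicated(off$family_id)]
}

#' Per-SNP association in an unrelated sample
#'
#' OLS of a phenotype on an additive genotype dosage with optional covariates.
#' Standard errors are heteroskedasticity-robust (HC1) by default, or CR1
#' cluster-robust when cluster labels are supplied; p-values use a t
#' reference with G - 1 degrees of freedom.
#'
#' @param dosage Numeric vector of allele counts.
#' @param phenotype Numeric outcome vector.
#' @param covariates Optional numeric matrix/data.frame of covariates.
#' @param clusters Optional cluster labels (e.g. family identifiers).
#' @param snp_id Label carried into the result.
#' @return An \code{assoc_result} (beta, se, p, n, method tag).
#' @export
assoc_unrelated <- function(dosage, phenotype, covariates = NULL,
                            clusters = NULL, snp_id = NA_character_) {
  if (length(dosage) < 3) stop("need at least 3 observations")
  if (stats::var(dosage) == 0)
    stop("inestimable: genotype dosage is constant")
  X <- cbind(`(Intercept)` = 1, g = dosage)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  fit <- .ols_cr(X, phenotype, clusters)
  .assoc_result(snp_id, "unrelated", unname(fit$beta["g"]),
                sqrt(fit$vcov["g", "g"]), fit$n, fit$g - 1)
}

## Enumerate all within-family offspring pairs; returns index pairs into the
## cohort row order plus the family of each pair.
.sib_pairs <- function(cohort) {
  ped <- cohort$ped
  off_idx <- which(.offspring_rows(ped))
  by_fam <- split(off_idx, ped$family_id[off_idx])
  by_fam <- by_fam[vapply(by_fam, length, 0L) >= 2]
  if (!length(by_fam)) stop("cohort contains no sibling pairs")
  prs <- lapply(by_fam, function(ix) {
    ix <- ix[order(ped$individual_id[ix])]
    utils::combn(ix, 2)
  })
  cbindall <- do.call(cbind, prs)
  list(i1 = cbindall[1, ], i2 = cbindall[2, ],
       family = rep(names(prs), vapply(prs, ncol, 0L)))
}

#' Sibling-difference association
#'
#' Regresses the within-pair phenotype difference on the within-pair dosage
#' difference, through the origin. Every within-family pair of siblings
#' enters as a separate pseudo-independent pair; standard errors are
#' clustered on family, which makes the pseudo-pairs from families with more
#' than two siblings share a cluster.
#'
#' @param cohort A \code{family_cohort} with sibling pairs and phenotypes.
#' @param snp SNP identifier or index.
#' @param phenotype Phenotype column name (e.g. \code{"x"} or \code{"y"}).
#' @param intercept Include an intercept (diagnostics only; the difference
#'   model has none).
#' @return An \code{assoc_result} with method tag \code{"sib_diff"}.
#' @export
sib_diff_assoc <- function(cohort, snp, phenotype = "y", intercept = FALSE) {
  sn <- .snp_name(cohort, snp)
  prs <- .sib_pairs(cohort)
  g <- dosages(cohort)[, sn]
  y <- cohort$pheno[[phenotype]]
  if (is.null(y)) stop(sprintf("unknown phenotype '%s'", phenotype))
  d <- g[prs$i1] - g[prs$i2]
  dy <- y[prs$i1] - y[prs$i2]
  if (all(d == 0))
    stop("inestimable: no within-pair genotype differences at this SNP")
  X <- if (intercept) cbind(`(Intercept)` = 1, g = d) else cbind(g = d)
  fit <- .ols_cr(X, dy, prs$family)
  .assoc_result(sn, "sib_diff", unname(fit$beta["g"]),
                sqrt(fit$vcov["g", "g"]), length(d), fit$g - 1)
}

#' Family fixed-effects association
#'
#' Within transformation (subtracting family means over siblings) followed by
#' OLS, equivalent to including an indicator for every family. Standard
#' errors are CR1 cluster-robust by family; p-values use t with G - 1
#' degrees of freedom. With \code{between = TRUE} the family mean dosage is
#' added as a regressor instead of demeaning, which additionally returns the
#' between-family coefficient.
#'
#' @inheritParams sib_diff_assoc
#' @param covariates Optional covariate matrix (rows = all cohort
#'   individuals; the sibling subset is taken internally), within-transformed
#'   alongside the dosage.
#' @param between Also estimate the between-family coefficient by adjusting
#'   for the family-mean dosage rather than demeaning.
#' @return An \code{assoc_result} with method tag \code{"family_fe"}; when
#'   \code{between = TRUE} it carries \code{beta_between}/\code{se_between}.
#' @export
family_fe_assoc <- function(cohort, snp, phenotype = "y", covariates = NULL,
                            between = FALSE) {
  sn <- .snp_name(cohort, snp)
  ped <- cohort$ped
  off <- which(.offspring_rows(ped))
  fam <- ped$family_id[off]
  keep <- fam %in% names(which(table(fam) >= 2))
  off <- off[keep]; fam <- fam[keep]
  if (!length(off)) stop("cohort contains no families with >= 2 siblings")
  g <- dosages(cohort)[off, sn]
  y <- .pheno_vec(cohort, phenotype, off)
  fmean <- function(v) stats::ave(v, fam)
  gd <- g - fmean(g)
  if (all(gd == 0))
    stop("inestimable: no within-family genotype variance at this SNP")
  if (between) {
    X <- cbind(`(Intercept)` = 1, g = g, g_fam = fmean(g))
    if (!is.null(covariates))
      X <- cbind(X, as.matrix(covariates)[off, , drop = FALSE])
    fit <- .ols_cr(X, y, fam)
    return(.assoc_result(sn, "family_fe", unname(fit$beta["g"]),
                         sqrt(fit$vcov["g", "g"]), length(off), fit$g - 1,
                         extra = list(
                           beta_between = unname(fit$beta["g"] + fit$beta["g_fam"]),
                           se_between = sqrt(sum(fit$vcov[c("g", "g_fam"),
                                                          c("g", "g_fam")])))))
  }
  X <- cbind(g = gd)
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)[off, , drop = FALSE]
    X <- cbind(X, apply(cv, 2, function(v) v - fmean(v)))
  }
  fit <- .ols_cr(X, y - fmean(y), fam)
  .assoc_result(sn, "family_fe", unname(fit$beta["g"]),
                sqrt(fit$vcov["g", "g"]), length(off), fit$g - 1)
}

#' Trio association adjusted for parental genotype
#'
#' OLS of the offspring phenotype on the offspring, mother and father
#' dosages. The offspring coefficient is the within-family (transmission-
#' randomized) association; the conditional parental coefficients capture
#' dynastic paths.
#'
#' @inheritParams sib_diff_assoc
#' @param offspring \code{"first"} (default) analyses one offspring per
#'   family, chosen by stable individual-ID order; \code{"all"} uses every
#'   offspring with family-clustered standard errors.
#' @return An \code{assoc_result} with method tag \code{"trio_adjusted"} and
#'   fields \code{beta_mother}, \code{se_mother}, \code{beta_father},
#'   \code{se_father}.
#' @export
trio_assoc <- function(cohort, snp, phenotype = "y",
                       offspring = c("first", "all")) {
  offspring <- match.arg(offspring)
  sn <- .snp_name(cohort, snp)
  ped <- cohort$ped
  ids <- if (offspring == "first") .first_sib_ids(ped) else
    ped$individual_id[.offspring_rows(ped)]
  row <- match(ids, ped$individual_id)
  mrow <- match(ped$mother_id[row], ped$individual_id)
  frow <- match(ped$father_id[row], ped$individual_id)
  if (anyNA(mrow) || anyNA(frow))
    stop("trio analysis requires complete mother-father-offspring triples")
  dos <- dosages(cohort)[, sn]
  X <- cbind(`(Intercept)` = 1, g = dos[row], g_m = dos[mrow],
             g_f = dos[frow])
  if (qr(X)$rank < 4L)
    stop("inestimable: offspring, mother and father dosages are collinear (rank deficient)")
  y <- .pheno_vec(cohort, phenotype, row)
  fit <- .ols_cr(X, y, ped$family_id[row])
  .assoc_result(sn, "trio_adjusted", unname(fit$beta["g"]),
                sqrt(fit$vcov["g", "g"]), length(row), fit$g - 1,
                extra = list(beta_mother = unname(fit$beta["g_m"]),
                             se_mother = sqrt(fit$vcov["g_m", "g_m"]),
                             beta_father = unname(fit$beta["g_f"]),
                             se_father = sqrt(fit$vcov["g_f", "g_f"])))
}
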