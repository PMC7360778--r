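#' Per-SNP association scan over a cohort
#'
#' Vectorized per-SNP association estimates for a whole cohort, one row per
#' SNP, using the same estimators as \code{\link{assoc_unrelated}},
#' \code{\link{sib_diff_assoc}}, \code{\link{family_fe_assoc}} and
#' \code{\link{trio_assoc}} (the scan and the single-SNP functions agree on
#' beta and SE to machine precision; the scan reports normal-reference
#' p-values for use as summary statistics). Used by the simulation study
#' driver, where 90 SNPs are scanned per iteration.
#'
#' @param cohort A \code{family_cohort}.
#' @param phenotype Phenotype column (\code{"x"} or \code{"y"}), or a vector
#'   of columns, in which case a list of scans sharing the genotype-side
#'   computation is returned.
#' @param method One of \code{"unrelated"} (OLS on one sibling per family,
#'   HC1 errors), \code{"sib_diff"} (within-pair differences, family
#'   clusters), \code{"family_fe"} (within transformation, family clusters)
#'   or \code{"trio"} (parental-genotype adjustment, one offspring per
#'   family).
#' @param snps Optional subset of SNP identifiers.
#' @return data.frame with columns snp_id, method, beta, se, p, n (plus
#'   beta_mother/se_mother/beta_father/se_father for trios); a named list of
#'   such data.frames when several phenotypes are requested. SNPs without
#'   usable genotype variation get NA estimates.
#' @export
assoc_scan <- function(cohort, phenotype = "y",
                       method = c("unrelated", "sib_diff", "family_fe",
                                  "trio"),
                       snps = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(cohort, "family_cohort"))
  sel <- if (is.null(snps)) cohort$snps$snp_id else
    vapply(snps, function(s) .snp_name(cohort, s), "")
  res <- switch(method,
                unrelated = .scan_unrelated(cohort, phenotype, sel),
                sib_diff = .scan_pairs(cohort, phenotype, sel, "sib_diff"),
                family_fe = .scan_fe(cohort, phenotype, sel),
                trio = .scan_trio(cohort, phenotype, sel))
  if (length(phenotype) == 1L) res[[1]] else res
}

## ---- shared row-selection helpers -------------------------------------

## Index of the first sibling per family: the sib1 block when the cohort has
## the simulator's aligned row layout, otherwise by stable individual-ID
## order.
.first_sib_rows <- function(ped) {
  s1 <- which(ped$role == "sib1")
  off_fams <- ped$family_id[.offspring_rows(ped)]
  if (length(s1) && length(s1) == length(unique(off_fams)))
    return(s1)
  match(.first_sib_ids(ped), ped$individual_id)
}

## Aligned sibling-pair row indices (i1, i2, family), or NULL when the
## cohort is not made of exactly-two-sibling families in aligned blocks.
.pair_rows <- function(ped) {
  s1 <- which(ped$role == "sib1")
  s2 <- which(ped$role == "sib2")
  roles <- unique(ped$role)
  if (!length(s1) || length(s1) != length(s2) ||
      length(setdiff(roles, c("mother", "father", "sib1", "sib2"))) > 0)
    return(NULL)
  if (!identical(ped$family_id[s1], ped$family_id[s2])) return(NULL)
  list(i1 = s1, i2 = s2, family = ped$family_id[s1])
}

.scan_frame <- function(sel, method, beta, se, n) {
  data.frame(snp_id = sel, method = method, beta = beta, se = se,
             p = 2 * stats::pnorm(-abs(beta / se)), n = n,
             row.names = NULL, stringsAsFactors = FALSE)
}

## ---- simple-regression scans (unrelated sample) -----------------------

## After centring, the slope sandwich element is sum(gc^2 u^2) / Sxx^2
## (cluster-summed scores when clusters are supplied), with CR1 at K = 2.
.scan_unrelated <- function(cohort, phenotypes, sel) {
  row <- .first_sib_rows(cohort$ped)
  G <- dosages(cohort)[row, sel, drop = FALSE]
  n <- length(row)
  gc_ <- sweep(G, 2, colMeans(G))
  sxx <- colSums(gc_^2)
  ok <- sxx > 0
  adj <- n / (n - 2L)
  out <- lapply(phenotypes, function(ph) {
    y <- .pheno_vec(cohort, ph, row)
    yc <- y - mean(y)
    beta <- se <- rep(NA_real_, length(sel))
    beta[ok] <- colSums(gc_[, ok, drop = FALSE] * yc) / sxx[ok]
    u <- yc - gc_ * rep(ifelse(ok, beta, 0), each = n)
    meat <- colSums((gc_ * u)^2)
    se[ok] <- sqrt(adj * meat[ok] / sxx[ok]^2)
    .scan_frame(sel, "unrelated", beta, se, n)
  })
  names(out) <- phenotypes
  out
}

## ---- within-family scans (pair differences / general demeaning) -------

## Through-origin regression on within-pair or within-family contrasts with
## family-clustered scores; CR1 at K = 1.
.scan_contrast <- function(D, sel, cohort, phenotypes, i1, i2, groups,
                           method, n_report) {
  npair <- nrow(D)
  sxx <- colSums(D^2)
  ok <- sxx > 0
  one_group_per_row <- is.null(groups)
  out <- lapply(phenotypes, function(ph) {
    yv <- cohort$pheno[[ph]]
    if (is.null(yv)) stop(sprintf("unknown phenotype '%s'", ph))
    dy <- yv[i1] - yv[i2]
    beta <- se <- rep(NA_real_, length(sel))
    beta[ok] <- colSums(D[, ok, drop = FALSE] * dy) / sxx[ok]
    u <- dy - D * rep(ifelse(ok, beta, 0), each = npair)
    if (one_group_per_row) {
      meat <- colSums((D * u)^2)
      g <- npair
    } else {
      sc <- rowsum(D * u, groups)
      meat <- colSums(sc^2)
      g <- nrow(sc)
    }
    adj <- g / (g - 1)
    se[ok] <- sqrt(adj * meat[ok] / sxx[ok]^2)
    .scan_frame(sel, method, beta, se, n_report)
  })
  names(out) <- phenotypes
  out
}

## Fixed-effects scan. For families of exactly two siblings the within
## estimator, its clustered score sum and the CR1 factor coincide with the
## through-origin pair-difference regression (demeaned values are +/- half
## the differences), so the cheaper pair form is used; general sibship
## sizes go through explicit demeaning.
.scan_fe <- function(cohort, phenotypes, sel) {
  ped <- cohort$ped
  pr <- .pair_rows(ped)
  if (is.null(pr)) {
    off <- which(.offspring_rows(ped))
    fam <- ped$family_id[off]
    tab <- table(fam)
    keep <- fam %in% names(which(tab >= 2))
    off <- off[keep]; fam <- fam[keep]
    if (!length(off)) stop("cohort contains no families with >= 2 siblings")
    if (all(tab[tab >= 2] == 2)) {
      o <- order(fam)
      pr <- list(i1 = off[o[seq(1, length(o), 2)]],
                 i2 = off[o[seq(2, length(o), 2)]],
                 family = fam[o[seq(1, length(o), 2)]])
    } else {
      return(.scan_fe_general(cohort, phenotypes, sel, off, fam))
    }
  }
  dos <- dosages(cohort)
  D <- dos[pr$i1, sel, drop = FALSE] - dos[pr$i2, sel, drop = FALSE]
  storage.mode(D) <- "double"
  .scan_contrast(D, sel, cohort, phenotypes, pr$i1, pr$i2, groups = NULL,
                 method = "family_fe", n_report = 2L * length(pr$i1))
}

.scan_fe_general <- function(cohort, phenotypes, sel, off, fam) {
  G <- dosages(cohort)[off, sel, drop = FALSE]
  storage.mode(G) <- "double"
  n <- length(off)
  nfam <- as.vector(table(fam)[fam])
  Gd <- G - rowsum(G, fam)[fam, , drop = FALSE] / nfam
  sxx <- colSums(Gd^2)
  ok <- sxx > 0
  out <- lapply(phenotypes, function(ph) {
    y <- .pheno_vec(cohort, ph, off)
    fmy <- rowsum(y, fam)[, 1] / as.vector(table(fam))
    yd <- y - fmy[fam]
    beta <- se <- rep(NA_real_, length(sel))
    beta[ok] <- colSums(Gd[, ok, drop = FALSE] * yd) / sxx[ok]
    u <- yd - Gd * rep(ifelse(ok, beta, 0), each = n)
    sc <- rowsum(Gd * u, fam)
    g <- nrow(sc)
    adj <- g / (g - 1)
    se[ok] <- sqrt(adj * colSums(sc^2)[ok] / sxx[ok]^2)
    .scan_frame(sel, "family_fe", beta, se, n)
  })
  names(out) <- phenotypes
  out
}

## Sibling-difference scan over all within-family pseudo-independent pairs.
.scan_pairs <- function(cohort, phenotypes, sel, method) {
  pr <- .pair_rows(cohort$ped)
  if (is.null(pr)) {
    p <- .sib_pairs(cohort)
    pr <- list(i1 = p$i1, i2 = p$i2, family = p$family)
  }
  dos <- dosages(cohort)
  D <- dos[pr$i1, sel, drop = FALSE] - dos[pr$i2, sel, drop = FALSE]
  storage.mode(D) <- "double"
  groups <- if (anyDuplicated(pr$family)) pr$family else NULL
  .scan_contrast(D, sel, cohort, phenotypes, pr$i1, pr$i2, groups = groups,
                 method = method, n_report = length(pr$i1))
}

## ---- trio scan ---------------------------------------------------------

.scan_trio <- function(cohort, phenotypes, sel) {
  ped <- cohort$ped
  row <- .first_sib_rows(ped)
  mo <- which(ped$role == "mother")
  fa <- which(ped$role == "father")
  if (length(mo) == length(row) && length(fa) == length(row) &&
      identical(ped$family_id[mo], ped$family_id[row]) &&
      identical(ped$family_id[fa], ped$family_id[row])) {
    mrow <- mo; frow <- fa
  } else {
    mrow <- match(ped$mother_id[row], ped$individual_id)
    frow <- match(ped$father_id[row], ped$individual_id)
  }
  if (anyNA(mrow) || anyNA(frow))
    stop("trio analysis requires complete mother-father-offspring triples")
  dos <- dosages(cohort)
  n <- length(row)
  Go <- dos[row, sel, drop = FALSE]; storage.mode(Go) <- "double"
  Gm <- dos[mrow, sel, drop = FALSE]; storage.mode(Gm) <- "double"
  Gf <- dos[frow, sel, drop = FALSE]; storage.mode(Gf) <- "double"
  ## cross-moments of the per-SNP design [1, g_o, g_m, g_f]
  s_o <- colSums(Go); s_m <- colSums(Gm); s_f <- colSums(Gf)
  s_oo <- colSums(Go^2); s_mm <- colSums(Gm^2); s_ff <- colSums(Gf^2)
  s_om <- colSums(Go * Gm); s_of <- colSums(Go * Gf); s_mf <- colSums(Gm * Gf)
  Ainv <- vector("list", length(sel))
  for (j in seq_along(sel)) {
    A <- matrix(c(n, s_o[j], s_m[j], s_f[j],
                  s_o[j], s_oo[j], s_om[j], s_of[j],
                  s_m[j], s_om[j], s_mm[j], s_mf[j],
                  s_f[j], s_of[j], s_mf[j], s_ff[j]), 4, 4)
    Ainv[[j]] <- tryCatch(solve(A), error = function(e) NULL)
  }
  est <- !vapply(Ainv, is.null, TRUE)
  adj <- n / (n - 4L)
  out <- lapply(phenotypes, function(ph) {
    y <- .pheno_vec(cohort, ph, row)
    sy <- sum(y)
    s_oy <- colSums(Go * y); s_my <- colSums(Gm * y); s_fy <- colSums(Gf * y)
    B <- matrix(0, 4, length(sel))
    for (j in which(est))
      B[, j] <- Ainv[[j]] %*% c(sy, s_oy[j], s_my[j], s_fy[j])
    U <- y - rep(B[1, ], each = n) - Go * rep(B[2, ], each = n) -
      Gm * rep(B[3, ], each = n) - Gf * rep(B[4, ], each = n)
    P2 <- Go * U; P3 <- Gm * U; P4 <- Gf * U
    m11 <- colSums(U^2); m12 <- colSums(P2 * U); m13 <- colSums(P3 * U)
    m14 <- colSums(P4 * U); m22 <- colSums(P2^2); m23 <- colSums(P2 * P3)
    m24 <- colSums(P2 * P4); m33 <- colSums(P3^2); m34 <- colSums(P3 * P4)
    m44 <- colSums(P4^2)
    res <- .scan_frame(sel, "trio_adjusted", NA_real_, NA_real_, n)
    res$beta_mother <- res$se_mother <- NA_real_
    res$beta_father <- res$se_father <- NA_real_
    for (j in which(est)) {
      M <- matrix(c(m11[j], m12[j], m13[j], m14[j],
                    m12[j], m22[j], m23[j], m24[j],
                    m13[j], m23[j], m33[j], m34[j],
                    m14[j], m24[j], m34[j], m44[j]), 4, 4)
      v <- adj * Ainv[[j]] %*% M %*% Ainv[[j]]
      res$beta[j] <- B[2, j]; res$se[j] <- sqrt(v[2, 2])
      res$beta_mother[j] <- B[3, j]; res$se_mother[j] <- sqrt(v[3, 3])
      res$beta_father[j] <- B[4, j]; res$se_father[j] <- sqrt(v[4, 4])
    }
    res$p <- 2 * stats::pnorm(-abs(res$beta / res$se))
    res
  })
  names(out) <- phenotypes
  out
}
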