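#' Simulation grid specification
#'
#' Describes a Cartesian grid of generative conditions for the false
#' discovery rate / power / bias study comparing Mendelian randomization
#' designs. Every combination of sample size, causal effect, dynastic effect
#' and confounding is simulated \code{iterations} times and analysed with
#' each requested design.
#'
#' @param n_families Vector of family counts (sibling pairs).
#' @param b_xy Vector of causal-effect variance shares.
#' @param b_ux Vector of dynastic-effect variance shares.
#' @param confounding Vector of confounder variance shares, applied to both
#'   exposure and outcome (c_x = c_y).
#' @param iterations Simulation iterations per cell.
#' @param designs Subset of \code{c("unrelated_ivw", "sibling_fe", "trio")}.
#' @param seed Base seed; per-cell seeds are derived deterministically from
#'   it and the cell index, so any cell can be reproduced in isolation.
#' @param n_snps,v_gx Genetic architecture shared by all cells.
#' @return An object of class \code{grid_spec}.
#' @export
grid_spec <- function(n_families, b_xy = 0, b_ux = 0, confounding = 0,
                      iterations = 100,
                      designs = c("unrelated_ivw", "sibling_fe", "trio"),
                      seed = 1, n_snps = 90, v_gx = 0.1) {
  designs <- match.arg(designs, several.ok = TRUE)
  stopifnot(iterations >= 1, all(n_families >= 1))
  ## validate every combination through the config constructor
  for (b in b_xy) for (u in b_ux) for (cc in confounding)
    sim_config(n_families = min(n_families), n_snps = n_snps, v_gx = v_gx,
               b_xy = b, b_ux = u, c_x = cc, c_y = cc)
  structure(list(n_families = n_families, b_xy = b_xy, b_ux = b_ux,
                 confounding = confounding, iterations = iterations,
                 designs = designs, seed = seed, n_snps = n_snps,
                 v_gx = v_gx),
            class = "grid_spec")
}

## Scan methods behind each study design; the unrelated design takes one
## sibling per family so that all designs are compared at equal family counts.
.design_method <- c(unrelated_ivw = "unrelated", sibling_fe = "family_fe",
                    trio = "trio")

## One design applied to one simulated cohort: per-SNP scans of exposure and
## outcome pooled by IVW.
.design_estimate <- function(cohort, design) {
  method <- .design_method[[design]]
  sc <- assoc_scan(cohort, c("x", "y"), method)
  mr_ivw(summary_stats(sc$x, sc$y))
}

#' Run one cell of the simulation study
#'
#' Simulates \code{iterations} cohorts under one configuration and, for each
#' design, estimates the causal effect by per-SNP association scans pooled
#' with IVW, recording the estimate and whether p < 0.05. Under a null
#' causal effect the rejection proportion is the false discovery rate; under
#' a non-null effect it is power. Bias is the mean estimate minus the true
#' standardized slope sqrt(b_xy). Iterations where a design is inestimable
#' are excluded from the proportions and counted.
#'
#' @param config A \code{\link{sim_config}} for the cell.
#' @param designs Subset of \code{c("unrelated_ivw", "sibling_fe", "trio")}.
#' @param iterations Number of simulated cohorts.
#' @param seed Seed for the cell; per-iteration seeds are drawn from it.
#' @return An object of class \code{grid_cell}: list with \code{summary}
#'   (one row per design: rejection rate with Monte Carlo SE, mean estimate,
#'   bias with MC SE, iteration accounting) and \code{estimates} (one row
#'   per iteration x design).
#' @export
run_cell <- function(config,
                     designs = c("unrelated_ivw", "sibling_fe", "trio"),
                     iterations = 100, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  designs <- match.arg(designs, several.ok = TRUE)
  set.seed(seed)
  it_seeds <- sample.int(2147483646L, iterations)
  rows <- vector("list", iterations)
  for (i in seq_len(iterations)) {
    cfg <- config
    cfg$seed <- it_seeds[i]
    cohort <- tryCatch(simulate_cohort(cfg), error = function(e) NULL)
    ests <- lapply(designs, function(d) {
      tryCatch({
        if (is.null(cohort)) stop("cohort simulation failed")
        e <- .design_estimate(cohort, d)
        data.frame(iteration = i, design = d, beta = e$beta, se = e$se,
                   p = e$p, estimable = TRUE, stringsAsFactors = FALSE)
      }, error = function(err)
        data.frame(iteration = i, design = d, beta = NA_real_,
                   se = NA_real_, p = NA_real_, estimable = FALSE,
                   stringsAsFactors = FALSE))
    })
    rows[[i]] <- do.call(rbind, ests)
  }
  estimates <- do.call(rbind, rows)
  true_slope <- sqrt(config$b_xy)
  summ <- do.call(rbind, lapply(designs, function(d) {
    e <- estimates[estimates$design == d & estimates$estimable, ]
    n_ok <- nrow(e)
    rej <- mean(e$p < 0.05)
    data.frame(design = d, n_families = config$n_families,
               b_xy = config$b_xy, b_ux = config$b_ux,
               c_x = config$c_x, c_y = config$c_y,
               iterations = iterations, n_used = n_ok,
               n_excluded = iterations - n_ok,
               reject_rate = rej,
               reject_mc_se = sqrt(rej * (1 - rej) / n_ok),
               mean_estimate = mean(e$beta),
               bias = mean(e$beta) - true_slope,
               bias_mc_se = stats::sd(e$beta) / sqrt(n_ok),
               stringsAsFactors = FALSE)
  }))
  structure(list(summary = summ, estimates = estimates, seed = seed),
            class = "grid_cell")
}

#' @export
print.grid_cell <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Run a full simulation grid
#'
#' Runs \code{\link{run_cell}} over the Cartesian product of the grid
#' specification, with per-cell seeds derived deterministically from the
#' base seed and cell index. Cell failures are recorded and do not abort the
#' grid.
#'
#' @param spec A \code{\link{grid_spec}}.
#' @return data.frame: the stacked per-design cell summaries with a
#'   \code{cell} index and \code{cell_seed} column (class
#'   \code{grid_result}). Failed cells appear with NA results and the error
#'   message in \code{error}.
#' @export
run_grid <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  cells <- expand.grid(n_families = spec$n_families, b_xy = spec$b_xy,
                       b_ux = spec$b_ux, confounding = spec$confounding,
                       KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    cell_seed <- as.integer((spec$seed + 7919 * k) %% 2147483646L) + 1L
    res <- tryCatch({
      cfg <- sim_config(n_families = cells$n_families[k],
                        n_snps = spec$n_snps, v_gx = spec$v_gx,
                        b_xy = cells$b_xy[k], b_ux = cells$b_ux[k],
                        c_x = cells$confounding[k],
                        c_y = cells$confounding[k])
      s <- run_cell(cfg, spec$designs, spec$iterations, cell_seed)$summary
      s$error <- NA_character_
      s
    }, error = function(e) {
      data.frame(design = spec$designs, n_families = cells$n_families[k],
                 b_xy = cells$b_xy[k], b_ux = cells$b_ux[k],
                 c_x = cells$confounding[k], c_y = cells$confounding[k],
                 iterations = spec$iterations, n_used = 0L,
                 n_excluded = spec$iterations, reject_rate = NA_real_,
                 reject_mc_se = NA_real_, mean_estimate = NA_real_,
                 bias = NA_real_, bias_mc_se = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res$cell <- k
    res$cell_seed <- cell_seed
    out[[k]] <- res
  }
  res <- do.call(rbind, out)
  class(res) <- c("grid_result", "data.frame")
  res
}

#' Plot power/FDR or bias against sample size by design
#'
#' Companion plots for \code{\link{run_grid}} output: rejection rate (power
#' under non-null effects, false discovery rate under the null) or bias
#' against the number of families, one line per design. Requires ggplot2.
#'
#' @param grid A \code{grid_result}.
#' @param metric \code{"reject_rate"} or \code{"bias"}.
#' @return A ggplot object.
#' @export
plot_grid_results <- function(grid, metric = c("reject_rate", "bias")) {
  metric <- match.arg(metric)
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_grid_results requires the ggplot2 package")
  df <- as.data.frame(grid)
  df$metric_value <- df[[metric]]
  g <- ggplot2::ggplot(df, ggplot2::aes(x = n_families, y = metric_value,
                                        colour = design))
  g + ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_grid(b_ux ~ b_xy, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "families", y = metric)
}

#' Subset a cohort to a set of families
#'
#' @param cohort A \code{family_cohort}.
#' @param families Character vector of family identifiers to keep.
#' @return A \code{family_cohort} restricted to those families.
#' @export
subset_families <- function(cohort, families) {
  stopifnot(inherits(cohort, "family_cohort"))
  keep <- cohort$ped$family_id %in% families
  if (!any(keep)) stop("no individuals left after family subsetting")
  ids <- cohort$ped$individual_id[keep]
  trans <- NULL
  if (!is.null(cohort$trans)) {
    tkeep <- rownames(cohort$trans$mother) %in% ids
    trans <- list(mother = cohort$trans$mother[tkeep, , drop = FALSE],
                  father = cohort$trans$father[tkeep, , drop = FALSE])
  }
  structure(list(ped = cohort$ped[keep, , drop = FALSE],
                 geno = list(a1 = cohort$geno$a1[ids, , drop = FALSE],
                             a2 = cohort$geno$a2[ids, , drop = FALSE]),
                 trans = trans,
                 pheno = cohort$pheno[keep, , drop = FALSE],
                 snps = cohort$snps, config = cohort$config,
                 dos = dosages(cohort)[ids, , drop = FALSE]),
            class = "family_cohort")
}

#' Split-sample two-sample Mendelian randomization
#'
#' Families are split at random into two halves; SNP-exposure associations
#' are estimated in one half and SNP-outcome associations in the other,
#' pooled by IVW; the role-swapped estimate is computed the same way; and
#' the two (independent) estimates are combined by fixed-effect
#' inverse-variance meta-analysis. Estimating the two association sets in
#' disjoint samples removes the weak-instrument / sample-overlap bias of
#' same-sample summary MR.
#'
#' @param cohort A \code{family_cohort}.
#' @param snps Optional subset of SNP identifiers.
#' @param exposure,outcome Phenotype columns.
#' @param method Association design for both halves: one of
#'   \code{"family_fe"}, \code{"sib_diff"}, \code{"unrelated"},
#'   \code{"trio"}.
#' @param seed Seed for the family split.
#' @return An \code{mr_estimate} with method \code{"meta"} and the two
#'   half-estimates in fields \code{half_a} and \code{half_b}.
#' @export
split_sample_mr <- function(cohort, snps = NULL, exposure = "x",
                            outcome = "y",
                            method = c("family_fe", "sib_diff", "unrelated",
                                       "trio"),
                            seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(cohort, "family_cohort"))
  fams <- unique(cohort$ped$family_id)
  if (!is.null(seed)) set.seed(seed)
  fams <- fams[sample.int(length(fams))]
  nh <- floor(length(fams) / 2)
  if (nh < 2 || length(fams) - nh < 2)
    stop("each half of the split must contain at least 2 families")
  half_a <- subset_families(cohort, fams[seq_len(nh)])
  half_b <- subset_families(cohort, fams[-seq_len(nh)])
  one_way <- function(h_exp, h_out) {
    sx <- assoc_scan(h_exp, exposure, method, snps = snps)
    sy <- assoc_scan(h_out, outcome, method, snps = snps)
    mr_ivw(summary_stats(sx, sy))
  }
  e1 <- one_way(half_a, half_b)
  e2 <- one_way(half_b, half_a)
  if (e1$se == 0 || e2$se == 0) {       # noiseless limit
    zb <- c(e1$beta, e2$beta)[c(e1$se, e2$se) == 0]
    beta <- mean(zb)
    se <- 0
  } else {
    w <- c(1 / e1$se^2, 1 / e2$se^2)
    beta <- sum(w * c(e1$beta, e2$beta)) / sum(w)
    se <- sqrt(1 / sum(w))
  }
  .mr_estimate("meta", beta, se, e1$n_snps,
               extra = list(half_a = e1, half_b = e2))
}
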