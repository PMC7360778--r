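## Tab-separated I/O helpers shared by the cohort and summary-data formats.
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a cohort to pedigree, dosage and phenotype files
#'
#' Writes three tab-separated files: \code{<prefix>.ped.tsv} (FAM-style
#' columns family_id, individual_id, father_id, mother_id, sex, role),
#' \code{<prefix>.dosage.tsv} (individual_id plus one 0/1/2 column per SNP)
#' and \code{<prefix>.pheno.tsv} (individual_id, x, y, confounder, deme);
#' plus \code{<prefix>.snps.tsv} carrying the allele coding needed for
#' weight harmonization.
#'
#' @param cohort A \code{family_cohort}.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  stopifnot(inherits(cohort, "family_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ped <- cohort$ped[, c("family_id", "individual_id", "father_id",
                        "mother_id", "sex", "role")]
  dos <- as.data.frame(dosages(cohort))
  dos <- cbind(individual_id = cohort$ped$individual_id, dos)
  paths <- file.path(dir, paste0(prefix, c(".ped.tsv", ".dosage.tsv",
                                           ".pheno.tsv", ".snps.tsv")))
  .write_tsv(ped, paths[1])
  .write_tsv(dos, paths[2])
  .write_tsv(cohort$pheno[, c("individual_id", "x", "y", "confounder",
                              "deme")], paths[3])
  .write_tsv(cohort$snps, paths[4])
  invisible(paths)
}

#' Read a cohort from pedigree, dosage and phenotype files
#'
#' Reconstructs a \code{family_cohort} from the file trio written by
#' \code{\link{write_cohort}} (or user-supplied files in the same layout).
#' Only additive dosages are recoverable from files, so the allele-pair
#' split is arbitrary and no transmission indicators are available:
#' every dosage-based estimator works, but \code{\link{sibling_ibd}} does
#' not.
#'
#' @param dir Directory holding the files.
#' @param prefix File-name prefix used when writing.
#' @return A \code{family_cohort}.
#' @export
read_cohort <- function(dir, prefix = "cohort") {
  ped <- .read_tsv(file.path(dir, paste0(prefix, ".ped.tsv")))
  dos <- .read_tsv(file.path(dir, paste0(prefix, ".dosage.tsv")))
  pheno <- .read_tsv(file.path(dir, paste0(prefix, ".pheno.tsv")))
  snp_path <- file.path(dir, paste0(prefix, ".snps.tsv"))
  m <- as.matrix(dos[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- dos$individual_id
  if (!all(m %in% 0:2)) stop("dosages must be 0, 1 or 2")
  ped <- ped[, c("individual_id", "family_id", "father_id", "mother_id",
                 "sex", "role")]
  m <- m[ped$individual_id, , drop = FALSE]
  snps <- if (file.exists(snp_path)) .read_tsv(snp_path) else
    data.frame(snp_id = colnames(m), allele_freq = NA_real_,
               effect_allele = NA_character_, other_allele = NA_character_,
               stringsAsFactors = FALSE)
  a1 <- pmin(m, 1L); a2 <- m - a1
  pheno <- pheno[match(ped$individual_id, pheno$individual_id), ]
  pheno$family_id <- ped$family_id
  pheno$role <- ped$role
  structure(list(ped = ped, geno = list(a1 = a1, a2 = a2), trans = NULL,
                 pheno = pheno, snps = snps, config = NULL),
            class = "family_cohort")
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file holds fields named as in \code{\link{sim_config}} (including an
#' optional nested \code{strat} block); values are validated by the
#' constructor.
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A \code{sim_config}.
#' @export
read_sim_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  fields <- switch(ext,
                   yaml = , yml = yaml::read_yaml(path),
                   json = jsonlite::fromJSON(path),
                   stop("config must be a .yaml/.yml or .json file"))
  if (!is.null(fields$strat)) fields$strat <- as.list(fields$strat)
  do.call(sim_config, fields)
}

#' Read a SNP weight file
#'
#' Tab-separated with columns snp_id, effect_allele, other_allele, weight.
#'
#' @param path File path.
#' @return data.frame of score weights.
#' @export
read_score_weights <- function(path) {
  w <- .read_tsv(path)
  need <- c("snp_id", "effect_allele", "other_allele", "weight")
  if (!all(need %in% names(w)))
    stop("weight file must have columns snp_id, effect_allele, other_allele, weight")
  w
}

#' Write an association table as summary statistics
#'
#' Writes an \code{\link{assoc_scan}} result (plus the allele coding from
#' the cohort SNP table, if given) as a tab-separated summary-statistic
#' file: snp_id, effect_allele, other_allele, beta, se, p, n, method.
#'
#' @param scan data.frame from \code{\link{assoc_scan}}.
#' @param path Output file.
#' @param snps Optional SNP table supplying allele columns.
#' @return Invisibly, the path.
#' @export
write_assoc_table <- function(scan, path, snps = NULL) {
  out <- scan
  if (!is.null(snps)) {
    m <- match(out$snp_id, snps$snp_id)
    out$effect_allele <- snps$effect_allele[m]
    out$other_allele <- snps$other_allele[m]
    lead <- c("snp_id", "effect_allele", "other_allele")
    out <- out[, c(lead, setdiff(names(out), lead))]
  }
  .write_tsv(out, path)
  invisible(path)
}

#' Read a summary-statistic association table
#'
#' @param path Tab-separated file with at least snp_id, beta, se.
#' @return data.frame.
#' @export
read_assoc_table <- function(path) {
  a <- .read_tsv(path)
  if (!all(c("snp_id", "beta", "se") %in% names(a)))
    stop("association table must have columns snp_id, beta, se")
  a
}

#' Write an MR estimate (or several) to JSON
#'
#' @param estimates A single \code{mr_estimate} or a list of them.
#' @param path Output .json path.
#' @return Invisibly, the path.
#' @export
write_mr_json <- function(estimates, path) {
  if (inherits(estimates, "mr_estimate")) estimates <- list(estimates)
  flat <- lapply(estimates, function(e)
    e[vapply(e, function(v) is.numeric(v) || is.character(v), TRUE) &
        lengths(e) == 1])
  names(flat) <- vapply(estimates, function(e) e$method, "")
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
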