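# The SNP filter cascade. Stage order is fixed and asserted by tests:
# biallelic -> presence -> depth floor -> paralog depth -> mapping quality ->
# quality bias (Mann-Whitney) -> minor allele frequency -> one SNP per contig.
# Every stage records (sites_in, sites_removed, sites_out) in the ledger.

#' Presence filter
#'
#' Keeps sites genotypable in at least `ceiling(min_fraction * n)`
#' individuals (depth >= 1). Ceiling rounding is the stricter reading of
#' "at least 80% of individuals": with n = 14 a site present in 11
#' individuals is removed (ceiling(11.2) = 12 required).
#'
#' @param x A `snp_table`.
#' @param min_fraction Minimum fraction of individuals with data.
#' @return The filtered `snp_table`.
#' @export
presence_filter <- function(x, min_fraction = 0.8) {
  need <- ceiling(min_fraction * x$n_ind)
  st_subset(x, colSums(x$ref_depth + x$alt_depth >= 1L) >= need)
}

#' Depth-floor filter
#'
#' Keeps sites whose total depth summed over individuals is at least
#' `min_mean_depth * n` -- i.e. a mean per-individual depth of at least
#' `min_mean_depth` (default 2, the "2 x n" floor). The bound is inclusive:
#' with n = 14, total depth 28 is kept, 27 removed.
#'
#' @param x A `snp_table`.
#' @param min_mean_depth Minimum mean per-individual depth.
#' @return The filtered `snp_table`.
#' @export
depth_floor_filter <- function(x, min_mean_depth = 2) {
  st_subset(x, colSums(x$ref_depth + x$alt_depth) >= min_mean_depth * x$n_ind)
}

#' Paralog (excess-depth) filter
#'
#' Collapsed duplicated loci show up as sites with anomalously high depth.
#' Removes sites whose per-site mean depth strictly exceeds the assembly-wide
#' mean + `n_sd` * SD of per-site mean depths, computed once before any
#' removal (single pass). With fewer than two sites the SD is undefined and
#' the table passes through with a warning.
#'
#' @param x A `snp_table`.
#' @param n_sd SD multiplier (default 2).
#' @return The filtered `snp_table`.
#' @export
paralog_depth_filter <- function(x, n_sd = 2) {
  L <- nrow(x$sites)
  if (L < 2L) {
    if (L > 0L) warning("fewer than 2 sites; paralog filter passed through")
    return(x)
  }
  m <- colSums(x$ref_depth + x$alt_depth) / x$n_ind
  st_subset(x, m <= mean(m) + n_sd * sd(m))
}

#' Mapping-quality filter
#'
#' Keeps sites whose RMS mapping quality is at least `min_mq` (a minimum
#' score of 30 keeps a site at exactly 30).
#'
#' @param x A `snp_table`.
#' @param min_mq Minimum site mapping quality.
#' @return The filtered `snp_table`.
#' @export
mapping_quality_filter <- function(x, min_mq = 30) {
  st_subset(x, x$sites$mq >= min_mq)
}

#' Mann-Whitney rank-sum z-score
#'
#' Two-sided normal approximation of the Mann-Whitney U statistic with
#' midrank tie handling and the tie-corrected variance
#' `n1*n2/12 * ((N+1) - sum(t^3 - t) / (N*(N-1)))`. Used on per-allele base
#' and mapping qualities to detect alleles supported only by low-quality
#' evidence. Identical groups (zero variance) give z = 0.
#'
#' @param values_ref,values_alt Numeric observations for the two groups
#'   (reference-allele and alternative-allele reads).
#' @param continuity Apply a 0.5 continuity correction?
#' @return The z-score (of the reference group's U).
#' @export
#' @examples
#' mann_whitney_z(c(1, 2, 3), c(4, 5, 6))  # -1.964: complete separation
mann_whitney_z <- function(values_ref, values_alt, continuity = FALSE) {
  n1 <- length(values_ref)
  n2 <- length(values_alt)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty", call. = FALSE)
  N <- n1 + n2
  r <- rank(c(values_ref, values_alt))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  t <- table(c(values_ref, values_alt))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(t^3 - t) / (N * (N - 1)))
  if (sigma2 <= 0) return(0)
  d <- U - mu
  if (continuity) d <- d - sign(d) * 0.5
  d / sqrt(sigma2)
}

#' Quality-bias filter (Mann-Whitney on ref vs alt qualities)
#'
#' Applies [mann_whitney_z()] twice per site -- pooled base qualities and
#' pooled mapping qualities of reference- vs alternative-allele reads -- and
#' removes sites where either |z| strictly exceeds `z_cutoff`. Sites where
#' one allele has no quality observations skip that test (treated as pass).
#' The z-scores are stored in `sites$bqz` / `sites$mqz`.
#'
#' @param x A `snp_table`.
#' @param z_cutoff Removal threshold on |z| (default 1.96).
#' @param continuity Continuity correction flag passed through.
#' @return The filtered `snp_table`.
#' @export
quality_bias_filter <- function(x, z_cutoff = 1.96, continuity = FALSE) {
  L <- nrow(x$sites)
  zf <- function(a, b) {
    if (length(a) == 0L || length(b) == 0L) return(NA_real_)
    mann_whitney_z(a, b, continuity)
  }
  bqz <- vapply(seq_len(L), function(s) zf(x$bq_ref[[s]], x$bq_alt[[s]]),
                numeric(1))
  mqz <- vapply(seq_len(L), function(s) zf(x$mq_ref[[s]], x$mq_alt[[s]]),
                numeric(1))
  x$sites$bqz <- bqz
  x$sites$mqz <- mqz
  bad <- (abs(bqz) > z_cutoff & !is.na(bqz)) | (abs(mqz) > z_cutoff & !is.na(mqz))
  st_subset(x, !bad)
}

#' Minor allele frequency filter
#'
#' Estimates the alternative allele frequency by EM ([estimate_allele_freq()])
#' and keeps sites with `min(f, 1 - f) >= min_maf` (the complement of the
#' strict "< 0.05 removed": a site at exactly 0.05 is kept). The estimate is
#' stored in `sites$af`.
#'
#' @param x A `snp_table`.
#' @param min_maf Minimum minor allele frequency (default 0.05).
#' @param error_rate Per-read error rate for the likelihoods.
#' @return The filtered `snp_table`.
#' @export
maf_filter <- function(x, min_maf = 0.05, error_rate = 0.01) {
  if (nrow(x$sites) == 0L) return(x)
  f <- as.numeric(estimate_allele_freq(gl_array(x, error_rate)))
  x$sites$af <- f
  st_subset(x, pmin(f, 1 - f) >= min_maf)
}

#' Random thinning to one SNP per contig
#'
#' Keeps a single uniformly random site per contig to damp linkage
#' disequilibrium among SNPs on the same fragment. The per-contig choice is
#' seeded by hashing the contig id together with `seed`, so the surviving set
#' is stable under reordering of contigs or sites; the caller's RNG stream is
#' left untouched. Output is sorted by (contig, position).
#'
#' @param x A `snp_table`.
#' @param seed Integer seed.
#' @return The thinned `snp_table`.
#' @export
thin_one_per_contig <- function(x, seed = 1L) {
  L <- nrow(x$sites)
  if (L == 0L) return(x)
  seed <- check_count(seed, "seed")
  keep <- with_local_rng({
    unlist(lapply(split(seq_len(L), x$sites$contig_id), function(idx) {
      idx <- idx[order(x$sites$pos[idx])]
      set.seed(hash_string(x$sites$contig_id[idx[1L]], seed))
      idx[sample.int(length(idx), 1L)]
    }), use.names = FALSE)
  })
  keep <- sort(keep)
  st_subset(x, seq_len(L) %in% keep)
}

#' Apply the full SNP filter cascade
#'
#' Runs, in order: biallelic, presence, depth floor, paralog depth, mapping
#' quality, quality bias (Mann-Whitney), minor allele frequency, and
#' one-SNP-per-contig thinning, recording a per-stage ledger. The ledger
#' conserves counts at every stage (`sites_in = sites_removed + sites_out`).
#'
#' @param x A `snp_table` from [call_variant_sites()].
#' @param params Named list overriding stage parameters: `min_fraction`
#'   (0.8), `min_mean_depth` (2), `paralog_sd` (2), `min_mq` (30), `z_cutoff`
#'   (1.96), `continuity` (FALSE), `min_maf` (0.05), `error_rate` (0.01).
#' @param seed Seed for the thinning stage.
#' @return A list of class `filter_result`: `snps` (the final `snp_table`)
#'   and `ledger` (a `filter_ledger` data frame).
#' @export
apply_cascade <- function(x, params = list(), seed = 1L) {
  stopifnot(inherits(x, "snp_table"))
  p <- modifyList(list(min_fraction = 0.8, min_mean_depth = 2,
                       paralog_sd = 2, min_mq = 30, z_cutoff = 1.96,
                       continuity = FALSE, min_maf = 0.05,
                       error_rate = 0.01), params)
  stages <- list(
    biallelic = list(fun = function(z) st_subset(z, z$sites$biallelic),
                     par = ""),
    presence = list(fun = function(z) presence_filter(z, p$min_fraction),
                    par = sprintf("min_fraction=%g", p$min_fraction)),
    depth_floor = list(fun = function(z) depth_floor_filter(z, p$min_mean_depth),
                       par = sprintf("min_mean_depth=%g", p$min_mean_depth)),
    paralog_depth = list(fun = function(z) paralog_depth_filter(z, p$paralog_sd),
                         par = sprintf("n_sd=%g", p$paralog_sd)),
    mapping_quality = list(fun = function(z) mapping_quality_filter(z, p$min_mq),
                           par = sprintf("min_mq=%g", p$min_mq)),
    quality_bias = list(fun = function(z)
      quality_bias_filter(z, p$z_cutoff, p$continuity),
      par = sprintf("z_cutoff=%g", p$z_cutoff)),
    maf = list(fun = function(z) maf_filter(z, p$min_maf, p$error_rate),
               par = sprintf("min_maf=%g", p$min_maf)),
    thin = list(fun = function(z) thin_one_per_contig(z, seed),
                par = sprintf("seed=%d", check_count(seed, "seed"))))
  ledger <- data.frame(stage = names(stages),
                       parameters = vapply(stages, `[[`, "", "par"),
                       sites_in = NA_integer_, sites_removed = NA_integer_,
                       sites_out = NA_integer_, row.names = NULL,
                       stringsAsFactors = FALSE)
  cur <- x
  for (i in seq_along(stages)) {
    n_in <- nrow(cur$sites)
    cur <- suppressWarnings(stages[[i]]$fun(cur))
    ledger$sites_in[i] <- n_in
    ledger$sites_out[i] <- nrow(cur$sites)
    ledger$sites_removed[i] <- n_in - nrow(cur$sites)
  }
  class(ledger) <- c("filter_ledger", "data.frame")
  structure(list(snps = cur, ledger = ledger), class = "filter_result")
}

#' @export
print.filter_ledger <- function(x, ...) {
  cat("SNP filter ledger:\n")
  print.data.frame(x)
  invisible(x)
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("filter_result: %d -> %d sites\n",
              x$ledger$sites_in[1L], x$ledger$sites_out[nrow(x$ledger)]))
  print(x$ledger)
  invisible(x)
}

#' Write a filter ledger as TSV
#' @param ledger A `filter_ledger`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ledger <- function(ledger, path) write_tsv(ledger, path)
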