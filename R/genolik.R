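# Read mapping, candidate-site extraction and biallelic genotype likelihoods.
# The mapper is a simplified best-identity ungapped placement (stands in for a
# short-read aligner at stack scale); the likelihood is the standard symmetric
# -error biallelic model used by consensus callers.

#' Map sample reads to reference contigs
#'
#' Places each read at its best-identity ungapped offset on the contig set,
#' requiring identity (matches / read length) of at least `min_identity`.
#' Reads tied between two contigs at the top identity are left unmapped
#' (ambiguous). The mapping-quality surrogate is
#' `round(-10 * log10(err))` capped at 60, where `err` is the posterior
#' probability the placement is wrong under a symmetric per-base mismatch
#' model of rate `map_eps` across the candidate contigs.
#'
#' @param x A `demux_result`, list of `sample_read_set`s, or a single
#'   `sample_read_set`.
#' @param reference A `contig_set` from [greedy_cluster()] /
#'   [build_reference()].
#' @param min_identity Minimum identity over the read (default 0.9).
#' @param map_eps Per-base mismatch rate used by the mapping-quality model.
#' @return An object of class `read_alignments` holding the pooled reads,
#'   their sample index, contig/offset/mismatch/MAPQ per read (contig 0 =
#'   unmapped), and a per-sample mapping report.
#' @export
map_reads <- function(x, reference, min_identity = 0.9, map_eps = 0.01) {
  stopifnot(inherits(reference, "contig_set"))
  if (nrow(reference$contigs) == 0L) stop("reference has no contigs")
  if (inherits(x, "demux_result")) x <- x$samples
  if (inherits(x, "sample_read_set")) x <- list(x)
  check_scalar_num(min_identity, "min_identity", 0, 1, lo_open = TRUE)
  sample_id <- vapply(x, `[[`, character(1), "sample_id")
  nr <- vapply(x, function(s) length(s$seq), integer(1))
  reads <- unlist(lapply(x, `[[`, "seq"), use.names = FALSE)
  quals <- unlist(lapply(x, `[[`, "qual"), use.names = FALSE)
  ind <- rep.int(seq_along(x), nr)
  aln <- if (length(reads))
    cpp_map_reads(reads, reference$contigs$seq, min_identity, map_eps)
  else list(contig = integer(0), offset = integer(0),
            mismatches = integer(0), mapq = integer(0))
  report <- data.frame(
    sample_id = sample_id,
    n_reads = nr,
    n_mapped = as.integer(tapply(aln$contig > 0L, factor(ind, seq_along(x)),
                                 sum, default = 0L)),
    stringsAsFactors = FALSE, row.names = NULL)
  report$n_mapped[is.na(report$n_mapped)] <- 0L
  structure(list(reads = reads, quals = quals, ind = ind,
                 sample_id = sample_id, contig = aln$contig,
                 offset = aln$offset, mismatches = aln$mismatches,
                 mapq = aln$mapq, reference = reference, report = report),
            class = "read_alignments")
}

#' @export
print.read_alignments <- function(x, ...) {
  cat(sprintf("read_alignments: %d reads from %d samples on '%s' (%d contigs); %d mapped\n",
              length(x$reads), length(x$sample_id), x$reference$label,
              nrow(x$reference$contigs), sum(x$contig > 0L)))
  invisible(x)
}

#' Extract candidate variant sites with per-individual allele depths
#'
#' Piles mapped reads onto the contigs and keeps columns where at least two
#' distinct alleles are each supported by `min_allele_count` reads overall.
#' The reference allele is the major allele across all mapped reads
#' (lexicographic tie-break), the alternative the runner-up; columns with a
#' third allele at or above `min_allele_count` are flagged non-biallelic and
#' removed by the first stage of [apply_cascade()]. Per-allele base-quality
#' and mapping-quality observations are pooled across individuals for the
#' quality-bias tests; the site mapping quality is the RMS MAPQ of covering
#' reads.
#'
#' @param aln A [map_reads()] result.
#' @param min_allele_count Minimum supporting reads per allele (default 2).
#' @return An object of class `snp_table`: `sites` (contig, 1-based position,
#'   ref/alt, biallelic flag, site MQ), depth matrices `ref_depth` /
#'   `alt_depth` (individuals x sites), and pooled per-allele quality lists.
#' @export
call_variant_sites <- function(aln, min_allele_count = 2L) {
  stopifnot(inherits(aln, "read_alignments"))
  min_allele_count <- check_count(min_allele_count, "min_allele_count", 1L)
  n_ind <- length(aln$sample_id)
  ps <- cpp_pileup_sites(aln$reads, aln$quals, aln$ind, aln$contig,
                         aln$offset, aln$mapq, aln$reference$contigs$seq,
                         n_ind, min_allele_count)
  sites <- data.frame(
    contig_id = aln$reference$contigs$contig_id[ps$contig],
    pos = ps$pos0 + 1L,
    ref = ps$ref, alt = ps$alt,
    biallelic = ps$n_alleles == 2L,
    mq = ps$mq,
    stringsAsFactors = FALSE)
  dimnames(ps$ref_depth) <- dimnames(ps$alt_depth) <-
    list(aln$sample_id, site_key(sites))
  structure(list(sites = sites, ref_depth = ps$ref_depth,
                 alt_depth = ps$alt_depth,
                 bq_ref = ps$bq_ref, bq_alt = ps$bq_alt,
                 mq_ref = ps$mq_ref, mq_alt = ps$mq_alt,
                 sample_id = aln$sample_id, n_ind = n_ind),
            class = "snp_table")
}

site_key <- function(sites) sprintf("%s:%d", sites$contig_id, sites$pos)

#' @export
print.snp_table <- function(x, ...) {
  cat(sprintf("snp_table: %d sites x %d individuals (%d biallelic)\n",
              nrow(x$sites), x$n_ind, sum(x$sites$biallelic)))
  if (nrow(x$sites)) {
    td <- colSums(x$ref_depth + x$alt_depth)
    cat(sprintf("  per-site mean depth: %.2f +/- %.2f\n",
                mean(td / x$n_ind), sd(td / x$n_ind)))
  }
  invisible(x)
}

#' Number of sites in a snp_table
#' @param x A `snp_table`.
#' @return Integer site count.
#' @export
n_sites <- function(x) nrow(x$sites)

# subset sites of a snp_table, preserving all companions
st_subset <- function(x, keep) {
  x$sites <- x$sites[keep, , drop = FALSE]
  rownames(x$sites) <- NULL
  x$ref_depth <- x$ref_depth[, keep, drop = FALSE]
  x$alt_depth <- x$alt_depth[, keep, drop = FALSE]
  for (f in c("bq_ref", "bq_alt", "mq_ref", "mq_alt"))
    x[[f]] <- x[[f]][keep]
  x
}

#' Biallelic genotype likelihood from allele depths
#'
#' The standard symmetric-error model: a read carries the alternative allele
#' with probability `g/2 * (1 - e) + (1 - g/2) * e` for dosage
#' `g` in 0,1,2 and per-read error rate `e`. Returns the unnormalized
#' likelihood product for each dosage; with both depths zero the triplet is
#' flat (1, 1, 1).
#'
#' @param ref_depth,alt_depth Non-negative read counts (vectorized).
#' @param error_rate Per-read allele error rate, in (0, 0.5).
#' @param log Return natural-log likelihoods?
#' @return A matrix with columns `g0`, `g1`, `g2` (one row per input pair).
#' @export
#' @examples
#' genotype_likelihood(1, 1, error_rate = 0.01)
genotype_likelihood <- function(ref_depth, alt_depth, error_rate = 0.01,
                                log = FALSE) {
  check_scalar_num(error_rate, "error_rate", 0, 0.5, lo_open = TRUE,
                   hi_open = TRUE)
  if (any(ref_depth < 0) || any(alt_depth < 0))
    stop("depths must be non-negative", call. = FALSE)
  p_alt <- c(error_rate, 0.5, 1 - error_rate)  # P(read shows alt | g)
  ll <- vapply(p_alt, function(p)
    alt_depth * base::log(p) + ref_depth * base::log(1 - p),
    numeric(length(ref_depth)))
  ll <- matrix(ll, ncol = 3L, dimnames = list(NULL, c("g0", "g1", "g2")))
  if (log) ll else exp(ll)
}

#' Genotype-likelihood array for a snp_table
#'
#' Per-cell likelihood triplets, normalized to a maximum of 1 per cell (so
#' deep sites do not underflow); zero-depth cells are flat.
#'
#' @param x A `snp_table`.
#' @param error_rate Per-read allele error rate.
#' @return A numeric array `individuals x sites x 3` on the linear scale.
#' @export
gl_array <- function(x, error_rate = 0.01) {
  stopifnot(inherits(x, "snp_table"))
  n <- x$n_ind
  L <- nrow(x$sites)
  ll <- genotype_likelihood(as.vector(x$ref_depth), as.vector(x$alt_depth),
                            error_rate, log = TRUE)
  ll <- ll - apply(ll, 1L, max)
  array(exp(ll), dim = c(n, L, 3L),
        dimnames = list(x$sample_id, site_key(x$sites), c("g0", "g1", "g2")))
}

#' Maximum-likelihood allele frequency by EM under Hardy-Weinberg
#'
#' Iterates posterior genotype responsibilities against a Hardy-Weinberg
#' prior; converged when `|delta f| < tol` or after `max_iter` iterations.
#' Individuals with flat likelihoods contribute their prior mean and so do
#' not bias the estimate; a site where every individual is flat is returned
#' as 0.5 and flagged in the `no_data` attribute.
#'
#' @param gl A likelihood matrix (individuals x 3, one site) or array
#'   (individuals x sites x 3), linear scale as from [gl_array()].
#' @param tol Convergence tolerance on the frequency (default 1e-8).
#' @param max_iter Iteration cap (default 200).
#' @return Numeric vector of alternative-allele frequencies, with attributes
#'   `no_data` (logical per site) and `n_iter`.
#' @export
estimate_allele_freq <- function(gl, tol = 1e-8, max_iter = 200L) {
  if (length(dim(gl)) == 2L) gl <- array(gl, dim = c(nrow(gl), 1L, 3L))
  stopifnot(length(dim(gl)) == 3L, dim(gl)[3] == 3L)
  n <- dim(gl)[1]
  L <- dim(gl)[2]
  if (L == 0L)
    return(structure(numeric(0), no_data = logical(0), n_iter = 0L))
  l0 <- matrix(gl[, , 1L], n, L)
  l1 <- matrix(gl[, , 2L], n, L)
  l2 <- matrix(gl[, , 3L], n, L)
  flat <- l0 == l1 & l1 == l2
  no_data <- colSums(!flat) == 0L
  f <- rep(0.5, L)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    p0 <- (1 - f)^2; p1 <- 2 * f * (1 - f); p2 <- f^2
    w0 <- l0 * rep(p0, each = n)
    w1 <- l1 * rep(p1, each = n)
    w2 <- l2 * rep(p2, each = n)
    tot <- w0 + w1 + w2
    f_new <- colSums((w1 + 2 * w2) / tot) / (2 * n)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol || iter >= max_iter) break
  }
  f[no_data] <- 0.5
  structure(f, no_data = no_data, n_iter = iter)
}

#' Write a snp_table as VCF
#'
#' Emits a minimal VCF 4.2: INFO holds site depth, RMS mapping quality, the
#' EM allele frequency and (when the quality-bias stage has run) the
#' Mann-Whitney z-scores for base and mapping quality; FORMAT carries
#' per-individual allele depths, depth and log10-scaled genotype likelihoods.
#' No genotype calls are written -- downstream analysis runs on genotype
#' probabilities, not called genotypes.
#'
#' @param x A `snp_table`.
#' @param path Output path.
#' @param error_rate Error rate for the GL field.
#' @return The path, invisibly.
#' @export
write_vcf <- function(x, path, error_rate = 0.01) {
  stopifnot(inherits(x, "snp_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=gbsconcord",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total site depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"EM alternative allele frequency\">",
    "##INFO=<ID=BQBZ,Number=1,Type=Float,Description=\"Mann-Whitney z, base quality ref vs alt\">",
    "##INFO=<ID=MQBZ,Number=1,Type=Float,Description=\"Mann-Whitney z, mapping quality ref vs alt\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GL,Number=G,Type=Float,Description=\"Log10 genotype likelihoods\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$sample_id), collapse = "\t")), con)
  L <- nrow(x$sites)
  if (L == 0L) return(invisible(path))
  gl <- gl_array(x, error_rate)
  af <- x$sites$af %||% as.numeric(estimate_allele_freq(gl))
  dp <- colSums(x$ref_depth + x$alt_depth)
  for (s in seq_len(L)) {
    info <- sprintf("DP=%d;MQ=%.2f;AF=%.4f", dp[s], x$sites$mq[s], af[s])
    if (!is.null(x$sites$bqz))
      info <- paste0(info, sprintf(";BQBZ=%.3f;MQBZ=%.3f",
                                   x$sites$bqz[s], x$sites$mqz[s]))
    fmt <- sprintf("%d,%d:%d:%.3f,%.3f,%.3f",
                   x$ref_depth[, s], x$alt_depth[, s],
                   x$ref_depth[, s] + x$alt_depth[, s],
                   log10(gl[, s, 1L]), log10(gl[, s, 2L]), log10(gl[, s, 3L]))
    writeLines(paste(c(x$sites$contig_id[s], x$sites$pos[s], ".",
                       x$sites$ref[s], x$sites$alt[s], ".", "PASS",
                       info, "AD:DP:GL", fmt), collapse = "\t"), con)
  }
  invisible(path)
}
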