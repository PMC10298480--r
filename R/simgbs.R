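# Synthetic GBS data with known truth: a kin-structured set of diploid
# individuals genotyped at short restriction-fragment loci, read out under two
# "method profiles" that differ in total read yield, locus capture breadth and
# per-locus depth (tissue-biopsy-like vs visceral-swab-like).

#' Simulation configuration
#'
#' Defines the study conditions for the synthetic GBS generator: 14 diploid
#' individuals from two collection localities with no allele-frequency
#' divergence, ~2,000 loci of 84--86 bp (the post-trim read length of a
#' 300--400 bp size-selected single-end GBS library), and minor allele
#' frequencies uniform on \[0.05, 0.5\].
#'
#' Individuals are drawn from a small founder-haplotype pool rather than as
#' fully independent Hardy--Weinberg draws. Each individual inherits two
#' distinct founder haplotypes (sampled with geometrically decaying weights,
#' so a few founders dominate, as in a mussel bed seeded by few successful
#' breeders), and each locus switches to a random pool haplotype at rate
#' `pool_recomb_rate`. Marginally every genotype is still a Hardy--Weinberg
#' draw at the site's allele frequency, but individuals share realized
#' haplotypes, giving the consistent individual-level signal that makes
#' ordinations reproducible across independently recovered SNP subsets.
#' `n_founders = 0` disables this and draws individuals iid.
#'
#' @param n_individuals Number of diploid individuals sampled by both methods.
#' @param n_loci Number of GBS loci in the genome model.
#' @param locus_length Length range (bp) of a locus, inclusive; reads span the
#'   whole locus, as in single-digest GBS stacks.
#' @param maf_range Range of the uniform distribution the per-site minor
#'   (alternative) allele frequency is drawn from.
#' @param p_polymorphic Probability a locus carries any variable site.
#' @param max_snps_per_locus Variable sites per polymorphic locus are uniform
#'   on `1:max_snps_per_locus`.
#' @param n_founders Size of the founder-haplotype pool (0 = iid individuals).
#' @param founder_weight_decay Geometric decay of founder sampling weights.
#' @param pool_recomb_rate Per-locus probability a gamete switches to a random
#'   pool haplotype (decouples individuals from being exact founder copies).
#' @param base_error_rate Per-base sequencing error probability.
#' @param barcode_length Multiplex identifier length in bp (10--20).
#' @param fragment_size Size-selection window in bp; recorded as metadata.
#' @param site_sizes Individuals per collection locality (labels only; the
#'   localities share allele frequencies). Must sum to `n_individuals`.
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @return An object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 4, n_loci = 20, seed = 1)
#' truth <- simulate_truth(cfg)
sim_config <- function(n_individuals = 14L, n_loci = 2000L,
                       locus_length = c(84L, 86L), maf_range = c(0.05, 0.5),
                       p_polymorphic = 0.7, max_snps_per_locus = 2L,
                       n_founders = 8L, founder_weight_decay = 0.65,
                       pool_recomb_rate = 0.1, base_error_rate = 0.005,
                       barcode_length = 10L, fragment_size = c(300L, 400L),
                       site_sizes = NULL, seed = 1L) {
  n_individuals <- check_count(n_individuals, "n_individuals", 1L)
  n_loci <- check_count(n_loci, "n_loci", 0L)
  if (length(locus_length) == 1L) locus_length <- rep(locus_length, 2L)
  if (length(locus_length) != 2L || any(locus_length < 1L) ||
      locus_length[1] > locus_length[2])
    stop_config("locus_length", "must be an increasing positive range")
  if (length(maf_range) != 2L || any(maf_range < 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop_config("maf_range", "must lie within [0, 0.5]")
  check_scalar_num(p_polymorphic, "p_polymorphic", 0, 1)
  max_snps_per_locus <- check_count(max_snps_per_locus, "max_snps_per_locus", 1L)
  n_founders <- check_count(n_founders, "n_founders", 0L)
  if (n_founders == 1L) stop_config("n_founders", "must be 0 (iid) or >= 2")
  check_scalar_num(founder_weight_decay, "founder_weight_decay", 0, 1, lo_open = TRUE)
  check_scalar_num(pool_recomb_rate, "pool_recomb_rate", 0, 1)
  check_scalar_num(base_error_rate, "base_error_rate", 0, 1, hi_open = TRUE)
  barcode_length <- check_count(barcode_length, "barcode_length", 1L)
  if (barcode_length < 10L || barcode_length > 20L)
    stop_config("barcode_length", "must be in [10, 20]")
  if (is.null(site_sizes)) {
    a <- max(1L, round(n_individuals * 6 / 14))
    site_sizes <- if (n_individuals >= 2L) c(a, n_individuals - a) else n_individuals
  }
  if (sum(site_sizes) != n_individuals || any(site_sizes < 1L))
    stop_config("site_sizes", "must be positive and sum to n_individuals")
  seed <- check_count(seed, "seed")
  structure(list(n_individuals = n_individuals, n_loci = n_loci,
                 locus_length = as.integer(locus_length),
                 maf_range = maf_range, p_polymorphic = p_polymorphic,
                 max_snps_per_locus = max_snps_per_locus,
                 n_founders = n_founders,
                 founder_weight_decay = founder_weight_decay,
                 pool_recomb_rate = pool_recomb_rate,
                 base_error_rate = base_error_rate,
                 barcode_length = barcode_length,
                 fragment_size = as.integer(fragment_size),
                 site_sizes = as.integer(site_sizes), seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("GBS simulation config: %d individuals, %d loci (%d-%d bp), MAF U[%.2f, %.2f]\n",
              x$n_individuals, x$n_loci, x$locus_length[1], x$locus_length[2],
              x$maf_range[1], x$maf_range[2]))
  cat(sprintf("  founder pool: %s; base error %.4g; barcode %d bp; seed %d\n",
              if (x$n_founders > 0)
                sprintf("%d haplotypes (decay %.2f, recomb %.2f)", x$n_founders,
                        x$founder_weight_decay, x$pool_recomb_rate)
              else "none (iid individuals)",
              x$base_error_rate, x$barcode_length, x$seed))
  invisible(x)
}

#' Method read-yield profile
#'
#' Describes how a DNA sampling method turns a library into reads: total
#' per-individual read yield (truncated normal, so printed mean +/- SD yields
#' are directly representable), the fraction of loci that receive any reads
#' (capture breadth), and a Dirichlet concentration controlling how unevenly
#' reads are spread over captured loci.
#'
#' @param name Profile label, e.g. `"tissue"` or `"swab"`.
#' @param mean_reads,sd_reads Mean and SD of per-individual total reads.
#' @param capture_breadth Fraction of loci receiving any reads, in (0, 1].
#' @param depth_overdispersion Symmetric Dirichlet concentration for per-locus
#'   read allocation; smaller values concentrate reads on fewer loci.
#' @return An object of class `method_profile`.
#' @seealso [gbs_profiles()] for the two default profiles.
#' @export
method_profile <- function(name, mean_reads, sd_reads, capture_breadth,
                           depth_overdispersion = 2) {
  if (!is.character(name) || length(name) != 1L)
    stop_config("name", "must be a single string")
  check_scalar_num(mean_reads, "mean_reads", 0, lo_open = TRUE)
  check_scalar_num(sd_reads, "sd_reads", 0)
  check_scalar_num(capture_breadth, "capture_breadth", 0, 1, lo_open = TRUE)
  check_scalar_num(depth_overdispersion, "depth_overdispersion", 0, lo_open = TRUE)
  structure(list(name = name, mean_reads = mean_reads, sd_reads = sd_reads,
                 capture_breadth = capture_breadth,
                 depth_overdispersion = depth_overdispersion),
            class = "method_profile")
}

#' Default tissue-like and swab-like profiles
#'
#' The two default profiles mirror the contrast between tissue biopsies and
#' visceral swabs at desk scale (total yields scaled down by a common factor
#' of ~86.5 from the study means of 1,608,863 vs 518,985 reads, preserving
#' both the (a - b)/b = 2.1 yield contrast and the coefficients of
#' variation): tissue reads spread broadly over loci at low depth, swab reads
#' concentrate on a small fraction of loci at high depth.
#'
#' @return A named list with `method_profile` objects `tissue` and `swab`.
#' @export
gbs_profiles <- function() {
  list(tissue = method_profile("tissue", mean_reads = 18600, sd_reads = 3550,
                               capture_breadth = 0.9),
       swab = method_profile("swab", mean_reads = 6000, sd_reads = 2750,
                             capture_breadth = 0.15))
}

#' Simulate ground truth: loci, variants, genotypes
#'
#' Draws locus sequences, variable sites with their allele frequencies, and
#' per-individual diploid genotypes (dosage of the alternative allele), plus
#' collection-locality labels. Deterministic given `config$seed`. Under the
#' founder-pool model every variable site is guaranteed biallelic within the
#' pool (monomorphic founder draws are rejected and redrawn).
#'
#' @param config A [sim_config()].
#' @return An object of class `truth_set` with elements `individuals`,
#'   `loci`, `variants`, `genotypes` (individuals x variants dosage matrix)
#'   and `founders`.
#' @export
simulate_truth <- function(config) {
  if (!inherits(config, "sim_config")) stop("`config` must be a sim_config")
  set.seed(config$seed)
  n <- config$n_individuals
  ind_id <- sprintf("ind%02d", seq_len(n))
  site <- sample(rep(paste0("site", seq_along(config$site_sizes)),
                     config$site_sizes))
  individuals <- data.frame(ind_id = ind_id, site = site,
                            stringsAsFactors = FALSE)
  nl <- config$n_loci
  if (nl == 0L) {
    return(structure(list(config = config, individuals = individuals,
                          loci = data.frame(locus_id = character(),
                                            length = integer(),
                                            seq = character()),
                          variants = empty_variants(),
                          genotypes = matrix(0L, n, 0,
                                             dimnames = list(ind_id, NULL)),
                          founders = NULL),
                     class = "truth_set"))
  }
  len <- sample(seq(config$locus_length[1], config$locus_length[2]),
                nl, replace = TRUE)
  loci <- data.frame(locus_id = sprintf("locus%05d", seq_len(nl)),
                     length = len, seq = random_dna(len),
                     stringsAsFactors = FALSE)
  poly <- runif(nl) < config$p_polymorphic
  nsit <- integer(nl)
  nsit[poly] <- sample.int(config$max_snps_per_locus, sum(poly), replace = TRUE)
  vloc <- rep(seq_len(nl), nsit)
  vpos <- unlist(lapply(seq_len(nl)[nsit > 0L], function(i)
    sort(sample.int(len[i], nsit[i]))), use.names = FALSE)
  nv <- length(vloc)
  ref <- substring(loci$seq[vloc], vpos, vpos)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                character(1), USE.NAMES = FALSE)
  maf <- runif(nv, config$maf_range[1], config$maf_range[2])
  FND <- config$n_founders
  if (FND == 0L) {
    G <- matrix(rbinom(n * nv, 2L, rep(maf, each = n)), n, nv)
    founders <- NULL
  } else {
    A <- matrix(rbinom(FND * nv, 1L, rep(maf, each = FND)), FND, nv)
    fixable <- maf > 0 & maf < 1
    for (it in seq_len(1000L)) {
      mono <- which(fixable & (colSums(A) == 0L | colSums(A) == FND))
      if (!length(mono)) break
      A[, mono] <- rbinom(FND * length(mono), 1L, rep(maf[mono], each = FND))
    }
    w <- config$founder_weight_decay^(seq_len(FND) - 1L)
    pairs <- t(vapply(seq_len(n), function(i) sample.int(FND, 2L, prob = w),
                      integer(2)))
    H1 <- A[pairs[, 1L], , drop = FALSE]
    H2 <- A[pairs[, 2L], , drop = FALSE]
    r <- config$pool_recomb_rate
    if (r > 0 && nv > 0) {
      for (H in c("H1", "H2")) {
        M <- get(H)
        sw <- which(matrix(runif(n * nv) < r, n, nv), arr.ind = TRUE)
        if (nrow(sw)) {
          M[sw] <- A[cbind(sample.int(FND, nrow(sw), replace = TRUE), sw[, 2L])]
          assign(H, M)
        }
      }
    }
    G <- H1 + H2
    founders <- list(alleles = A, pairs = pairs, weights = w)
  }
  variant_id <- sprintf("%s_%d", loci$locus_id[vloc], vpos)
  dimnames(G) <- list(ind_id, variant_id)
  variants <- data.frame(variant_id = variant_id,
                         locus_id = loci$locus_id[vloc], pos = vpos,
                         ref = ref, alt = alt, maf = maf,
                         freq_pool = if (FND > 0L && nv > 0) colMeans(founders$alleles) else maf,
                         freq_sample = if (nv > 0) colMeans(G) / 2 else numeric(),
                         stringsAsFactors = FALSE)
  structure(list(config = config, individuals = individuals, loci = loci,
                 variants = variants, genotypes = G, founders = founders),
            class = "truth_set")
}

empty_variants <- function() {
  data.frame(variant_id = character(), locus_id = character(), pos = integer(),
             ref = character(), alt = character(), maf = numeric(),
             freq_pool = numeric(), freq_sample = numeric(),
             stringsAsFactors = FALSE)
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("truth_set: %d individuals, %d loci, %d variable sites\n",
              nrow(x$individuals), nrow(x$loci), nrow(x$variants)))
  if (nrow(x$variants))
    cat(sprintf("  realized sample MAF: median %.3f (range %.3f-%.3f)\n",
                median(pmin(x$variants$freq_sample, 1 - x$variants$freq_sample)),
                min(pmin(x$variants$freq_sample, 1 - x$variants$freq_sample)),
                max(pmin(x$variants$freq_sample, 1 - x$variants$freq_sample))))
  invisible(x)
}

# unique same-length barcodes with pairwise Hamming distance >= 3, so
# 1-mismatch demultiplexing stays unambiguous
make_barcodes <- function(n, len) {
  out <- character(0)
  while (length(out) < n) {
    cand <- random_dna(len)
    ok <- all(vapply(out, function(b)
      sum(utf8ToInt(b) != utf8ToInt(cand)) >= 3L, logical(1)))
    if (ok) out <- c(out, cand)
  }
  out
}

#' Simulate multiplexed reads for one sampling-method arm
#'
#' Generates a multiplexed single-end FASTQ (barcode + locus fragment per
#' read, Phred+33 qualities) and a barcode map for all individuals of a truth
#' set under one method profile. Per-individual totals are truncated-normal
#' draws from the profile; a method-level random subset of loci of size
#' `capture_breadth * n_loci` receives reads; reads are allocated over
#' captured loci by a Dirichlet-multinomial with concentration
#' `depth_overdispersion` (locus weights are drawn once per arm, emulating
#' locus-intrinsic amplification bias shared by all individuals).
#'
#' Sequencing errors are substitutions at `base_error_rate` per base. Base
#' qualities follow a two-component model: each read draws a high quality
#' level (Q34--Q40) for correct bases, and error positions are written with a
#' low quality (Q10--Q25), so quality-bias filters downstream have signal.
#'
#' @param truth A [simulate_truth()] result.
#' @param profile A [method_profile()].
#' @param seed Integer seed for this arm.
#' @param dir Output directory (created if needed).
#' @param arm Arm label used in file and sample names; defaults to the
#'   profile name.
#' @return An object of class `sim_reads`: paths to the FASTQ/barcode-map
#'   files, the barcode map, per-individual read totals, and captured loci.
#' @export
simulate_method_reads <- function(truth, profile, seed = 1L,
                                  dir = tempfile("simgbs_"),
                                  arm = profile$name) {
  if (!inherits(truth, "truth_set")) stop("`truth` must be a truth_set")
  if (!inherits(profile, "method_profile"))
    stop("`profile` must be a method_profile")
  set.seed(check_count(seed, "seed"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- truth$config
  n <- nrow(truth$individuals)
  sample_id <- paste0(truth$individuals$ind_id, "_", arm)
  barcode <- make_barcodes(n, cfg$barcode_length)
  n_reads <- round(rtrunc_norm(n, profile$mean_reads, profile$sd_reads))
  nl <- nrow(truth$loci)
  ncap <- round(profile$capture_breadth * nl)
  captured <- if (nl > 0L) sort(sample.int(nl, ncap)) else integer(0)
  fastq <- file.path(dir, paste0(arm, ".fastq"))
  bcfile <- file.path(dir, paste0(arm, "_barcodes.tsv"))
  if (ncap == 0L || sum(n_reads) == 0) {
    write_fastq(character(0), character(0), character(0), fastq)
    write_tsv(data.frame(sample_id = sample_id, barcode = barcode), bcfile)
    return(structure(list(arm = arm, fastq = fastq, barcode_file = bcfile,
                          barcode_map = data.frame(sample_id = sample_id,
                                                   barcode = barcode,
                                                   stringsAsFactors = FALSE),
                          read_totals = setNames(n_reads, sample_id),
                          captured_loci = character(0), total_reads = 0L,
                          seed = seed),
                     class = "sim_reads"))
  }
  lw <- rgamma(ncap, shape = profile$depth_overdispersion)
  lw <- lw / sum(lw)
  depth <- vapply(seq_len(n), function(i)
    rmultinom(1L, n_reads[i], lw)[, 1L], integer(ncap))  # ncap x n
  vb <- split(seq_len(nrow(truth$variants)), truth$variants$locus_id)
  reads_l <- vector("list", ncap)
  owner_l <- vector("list", ncap)
  het_i <- het_p <- integer(0)
  het_b <- character(0)
  offset <- 0L
  for (j in seq_len(ncap)) {
    li <- captured[j]
    d <- depth[j, ]
    tot <- sum(d)
    if (tot == 0L) next
    vh <- vb[[truth$loci$locus_id[li]]]
    seqs_i <- rep(truth$loci$seq[li], n)
    if (length(vh)) {
      for (v in vh) {
        hom <- truth$genotypes[, v] == 2L
        if (any(hom))
          substr(seqs_i[hom], truth$variants$pos[v], truth$variants$pos[v]) <-
            truth$variants$alt[v]
      }
    }
    owner <- rep(seq_len(n), d)
    reads_l[[j]] <- rep(seqs_i, d)
    owner_l[[j]] <- owner
    if (length(vh)) {
      for (v in vh) {
        het <- which(truth$genotypes[owner, v] == 1L)
        if (length(het)) {
          flip <- het[runif(length(het)) < 0.5]
          if (length(flip)) {
            het_i <- c(het_i, offset + flip)
            het_p <- c(het_p, rep(truth$variants$pos[v], length(flip)))
            het_b <- c(het_b, rep(truth$variants$alt[v], length(flip)))
          }
        }
      }
    }
    offset <- offset + tot
  }
  reads <- unlist(reads_l, use.names = FALSE)
  owner <- unlist(owner_l, use.names = FALSE)
  nr <- length(reads)
  if (length(het_i))
    reads <- cpp_apply_edits(reads, het_i, het_p, het_b)
  # sequencing errors: substitution to one of the three other bases
  rl <- nchar(reads)
  n_err <- rbinom(nr, rl, cfg$base_error_rate)
  ei <- rep.int(which(n_err > 0L), n_err[n_err > 0L])
  qual <- strrep(phred_chars(sample(34:40, nr, replace = TRUE)), rl)
  if (length(ei)) {
    ep <- ceiling(runif(length(ei)) * rl[ei])
    cur <- substring(reads[ei], ep, ep)
    bmap <- c(A = 0L, C = 1L, G = 2L, T = 3L)
    eb <- c("A", "C", "G", "T")[(bmap[cur] + sample.int(3L, length(ei),
                                                        replace = TRUE)) %% 4L + 1L]
    reads <- cpp_apply_edits(reads, ei, ep, eb)
    qual <- cpp_apply_edits(qual, ei, ep,
                            phred_chars(sample(10:25, length(ei), replace = TRUE)))
  }
  reads <- paste0(barcode[owner], reads)
  qual <- paste0(strrep("I", cfg$barcode_length), qual)
  ord <- sample.int(nr)
  write_fastq(sprintf("%s_%07d", arm, seq_len(nr)), reads[ord], qual[ord], fastq)
  bm <- data.frame(sample_id = sample_id, barcode = barcode,
                   stringsAsFactors = FALSE)
  write_tsv(bm, bcfile)
  write_tsv(data.frame(ind_id = truth$individuals$ind_id,
                       sample_id = sample_id,
                       reads = as.integer(n_reads)),
            file.path(dir, paste0(arm, "_read_totals.tsv")))
  structure(list(arm = arm, fastq = fastq, barcode_file = bcfile,
                 barcode_map = bm,
                 read_totals = setNames(as.integer(n_reads), sample_id),
                 captured_loci = truth$loci$locus_id[captured],
                 total_reads = nr, seed = seed),
            class = "sim_reads")
}

#' @export
print.sim_reads <- function(x, ...) {
  cat(sprintf("sim_reads arm '%s': %d reads over %d samples, %d captured loci\n",
              x$arm, x$total_reads, length(x$read_totals),
              length(x$captured_loci)))
  cat(sprintf("  fastq: %s\n", x$fastq))
  invisible(x)
}
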