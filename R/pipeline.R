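# End-to-end orchestration: simulate both sampling arms from one truth,
# demultiplex and screen, build references, genotype, filter, estimate
# genotype probabilities, and evaluate concordance. All stage seeds derive
# deterministically from one pipeline seed.

derive_seed <- function(seed, k) as.integer((as.double(seed) * 48271 + k) %% 2147483629 + 1)

#' Run one sampling arm through genotyping
#'
#' Maps demultiplexed reads to a reference, extracts candidate sites, applies
#' the SNP filter cascade, runs the admixture Gibbs sampler, and averages
#' genotype probabilities across chains.
#'
#' @param reads A `demux_result` for the arm (already contaminant-screened).
#' @param reference A `contig_set`.
#' @param arm Arm label.
#' @param individual_ids Optional individual ids (one per sample, in sample
#'   order) used as row names so arms of the same individuals are comparable.
#' @param mcmc An [mcmc_config()].
#' @param seed Integer seed (thinning and MCMC chains derive from it).
#' @param min_identity,map_eps Mapper settings, see [map_reads()].
#' @param filter_params Cascade overrides, see [apply_cascade()].
#' @param error_rate Per-read error rate for genotype likelihoods.
#' @param rhat_threshold Diagnostic R-hat threshold recorded per arm, see
#'   [average_genotype_probs()].
#' @param dosage_tol Convergence gate: maximum tolerated between-chain
#'   difference in posterior mean dosage at any cell (default 0.2). The
#'   pipeline gates on this label-invariant summary rather than on raw
#'   p/q R-hat, which is legitimately inflated when k exceeds the real
#'   number of populations (chains freeze in different arbitrary
#'   partitions while the genotype probabilities agree).
#' @return An object of class `gbs_arm`: the alignments report, the filter
#'   result (`filter`), genotype probabilities (`geno`), read totals and
#'   labels.
#' @export
run_arm <- function(reads, reference, arm = "arm", individual_ids = NULL,
                    mcmc = mcmc_config(), seed = 1L, min_identity = 0.9,
                    map_eps = 0.01, filter_params = list(),
                    error_rate = 0.01, rhat_threshold = 1.2,
                    dosage_tol = 0.2) {
  stopifnot(inherits(reads, "demux_result"), inherits(reference, "contig_set"))
  aln <- map_reads(reads, reference, min_identity, map_eps)
  st <- call_variant_sites(aln)
  fr <- apply_cascade(st, filter_params, seed = derive_seed(seed, 1L))
  if (nrow(fr$snps$sites) == 0L)
    stop(sprintf("arm '%s': no SNPs survive the filter cascade", arm),
         call. = FALSE)
  fit <- gibbs_admixture(fr$snps, mcmc, seed = derive_seed(seed, 2L),
                         error_rate = error_rate)
  geno <- average_genotype_probs(fit, rhat_threshold, override = TRUE)
  if (!is.null(geno$dosage_agreement) &&
      geno$dosage_agreement$max_abs_diff > dosage_tol)
    stop(sprintf(
      "arm '%s': chains disagree on posterior dosages (max |diff| %.3f > %.2f); increase iterations",
      arm, geno$dosage_agreement$max_abs_diff, dosage_tol), call. = FALSE)
  ids <- individual_ids %||% fr$snps$sample_id
  rownames(geno$dosage) <- ids
  dimnames(geno$prob)[[1]] <- ids
  rownames(geno$q) <- ids
  structure(list(arm = arm, reference_label = reference$label,
                 map_report = aln$report, n_candidate_sites = nrow(st$sites),
                 filter = fr, geno = geno,
                 read_totals = setNames(reads$report$n_reads,
                                        reads$report$sample_id)),
            class = "gbs_arm")
}

#' @export
print.gbs_arm <- function(x, ...) {
  cat(sprintf("gbs_arm '%s' on %s reference: %d candidate sites -> %d SNPs\n",
              x$arm, x$reference_label, x$n_candidate_sites,
              nrow(x$filter$snps$sites)))
  invisible(x)
}

#' Run the full two-arm concordance pipeline on simulated data
#'
#' Simulates ground truth and two method arms (tissue-like and swab-like)
#' sharing the same genotypes, demultiplexes and screens both, builds de novo
#' references, genotypes and filters each arm, estimates genotype
#' probabilities, and reports PCA + Procrustes concordance.
#'
#' Two reference designs are available, mirroring the three-assembly layout
#' of method-comparison studies: `"own"` maps each arm to its own de novo
#' assembly (tissue-only / swab-only); `"control"` maps both arms to a shared
#' control reference built from an independently simulated tissue-like read
#' pool of the same truth; `"both"` runs both designs.
#'
#' @param config A [sim_config()] (its `seed` is overridden by `seed`).
#' @param profiles Named list with `method_profile`s `tissue` and `swab`
#'   (default [gbs_profiles()]).
#' @param seed Master integer seed; all stage seeds derive from it.
#' @param design `"own"`, `"control"` or `"both"`.
#' @param mcmc An [mcmc_config()].
#' @param threshold Concordance criterion on Procrustes R (default 0.95).
#' @param workdir Directory for FASTQ/TSV artifacts.
#' @param contaminant_fasta Contaminant screen input; defaults to the bundled
#'   synthetic control sequence. `NULL` disables the screen.
#' @param filter_params,error_rate,min_identity Stage settings, passed down.
#' @param independent_truths Simulate each arm from its own independently
#'   drawn truth (negative control: arms share nothing but the study design).
#' @return An object of class `gbs_pipeline`: the truth, per-arm results, and
#'   one `gbs_concordance` per requested design (`concordance$own`,
#'   `concordance$control`).
#' @export
run_gbs_pipeline <- function(config = sim_config(), profiles = gbs_profiles(),
                             seed = 1L, design = c("own", "control", "both"),
                             mcmc = mcmc_config(), threshold = 0.95,
                             workdir = tempfile("gbsrun_"),
                             contaminant_fasta = phix_like_fasta(),
                             filter_params = list(), error_rate = 0.01,
                             min_identity = 0.9,
                             independent_truths = FALSE) {
  design <- match.arg(design)
  seed <- check_count(seed, "seed")
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  config$seed <- derive_seed(seed, 10L)
  truth <- simulate_truth(config)
  truths <- list(tissue = truth, swab = truth)
  if (independent_truths) {
    cfg2 <- config
    cfg2$seed <- derive_seed(seed, 11L)
    truths$swab <- simulate_truth(cfg2)
  }
  arms <- list()
  demuxed <- list()
  for (nm in c("tissue", "swab")) {
    sim <- simulate_method_reads(truths[[nm]], profiles[[nm]],
                                 seed = derive_seed(seed, 20L + match(nm, c("tissue", "swab"))),
                                 dir = file.path(workdir, nm), arm = nm)
    dmx <- demultiplex(sim$fastq, sim$barcode_map)
    dmx <- screen_contaminants(dmx, contaminant_fasta)$reads
    demuxed[[nm]] <- list(sim = sim, dmx = dmx)
  }
  out_conc <- list()
  ind_ids <- truth$individuals$ind_id
  if (design %in% c("own", "both")) {
    for (nm in c("tissue", "swab")) {
      ref <- build_reference(demuxed[[nm]]$dmx, label = paste0(nm, "-only"))
      arms[[paste0(nm, "_own")]] <- run_arm(
        demuxed[[nm]]$dmx, ref, arm = nm, individual_ids = ind_ids,
        mcmc = mcmc, seed = derive_seed(seed, 30L + match(nm, c("tissue", "swab"))),
        min_identity = min_identity, filter_params = filter_params,
        error_rate = error_rate)
    }
    out_conc$own <- concordance_report(arms$tissue_own, arms$swab_own,
                                       threshold)
  }
  if (design %in% c("control", "both")) {
    ctl_sim <- simulate_method_reads(truths$tissue, profiles$tissue,
                                     seed = derive_seed(seed, 40L),
                                     dir = file.path(workdir, "control"),
                                     arm = "control")
    ctl_dmx <- demultiplex(ctl_sim$fastq, ctl_sim$barcode_map)
    ctl_dmx <- screen_contaminants(ctl_dmx, contaminant_fasta)$reads
    ctl_ref <- build_reference(ctl_dmx, label = "control")
    for (nm in c("tissue", "swab")) {
      arms[[paste0(nm, "_control")]] <- run_arm(
        demuxed[[nm]]$dmx, ctl_ref, arm = nm, individual_ids = ind_ids,
        mcmc = mcmc, seed = derive_seed(seed, 50L + match(nm, c("tissue", "swab"))),
        min_identity = min_identity, filter_params = filter_params,
        error_rate = error_rate)
    }
    out_conc$control <- concordance_report(arms$tissue_control,
                                           arms$swab_control, threshold)
  }
  structure(list(truth = truth, arms = arms, concordance = out_conc,
                 config = config, profiles = profiles, seed = seed,
                 workdir = workdir),
            class = "gbs_pipeline")
}

#' @export
print.gbs_pipeline <- function(x, ...) {
  cat(sprintf("gbs_pipeline (seed %d): %d individuals, %d loci\n", x$seed,
              x$config$n_individuals, x$config$n_loci))
  for (nm in names(x$concordance)) {
    cat(sprintf("-- %s-reference design --\n", nm))
    print(x$concordance[[nm]])
  }
  invisible(x)
}
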