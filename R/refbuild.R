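# De novo reference construction: tally unique reads, apply the copy/sharing
# retention rule, then CD-HIT-style greedy incremental clustering at 80%
# ungapped identity. The external CD-HIT/dDocent binaries are not called; the
# comparator is a best-ungapped-offset identity (reads are near-identical
# 84-86 bp stacks, so gaps add nothing at this scale).

#' Tally unique reads across samples
#'
#' @param samples A `demux_result`, a list of `sample_read_set`s, or a single
#'   `sample_read_set`.
#' @return A `unique_read_table`: data frame with columns `sequence`,
#'   `copies` (total read copies) and `n_individuals` (samples sharing the
#'   sequence), with the number of contributing samples as an attribute.
#' @export
unique_read_table <- function(samples) {
  if (inherits(samples, "demux_result")) samples <- samples$samples
  if (inherits(samples, "sample_read_set")) samples <- list(samples)
  seqs <- unlist(lapply(samples, `[[`, "seq"), use.names = FALSE)
  ind <- rep.int(seq_along(samples),
                 vapply(samples, function(s) length(s$seq), integer(1)))
  dt <- data.table::data.table(sequence = seqs, ind = ind)
  ut <- dt[, list(copies = .N,
                  n_individuals = data.table::uniqueN(ind)),
           by = "sequence"]
  out <- as.data.frame(ut)
  attr(out, "n_samples") <- length(samples)
  class(out) <- c("unique_read_table", "data.frame")
  out
}

#' Retention rule for de novo assembly input
#'
#' Retains sequences seen in at least `min_copies` total read copies AND
#' shared by at least `min_individuals` samples. The conventional reading of
#' the copy/sharing rule treats both bounds as inclusive at 4, so e.g. a
#' sequence with 10 copies in 2 individuals is removed.
#'
#' @param table A [unique_read_table()].
#' @param min_copies,min_individuals Inclusive retention thresholds.
#' @return The filtered `unique_read_table`.
#' @export
retention_filter <- function(table, min_copies = 4L, min_individuals = 4L) {
  stopifnot(inherits(table, "unique_read_table"))
  keep <- table$copies >= min_copies & table$n_individuals >= min_individuals
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_samples") <- attr(table, "n_samples")
  class(out) <- class(table)
  out
}

#' Greedy identity clustering into reference contigs
#'
#' CD-HIT-style greedy incremental clustering: sequences are processed in
#' descending (abundance, length, lexicographic) order; each joins the first
#' existing representative whose best ungapped-offset identity
#' (matches / shorter length) reaches `identity_threshold`, else founds a new
#' cluster. Representatives become the reference contigs.
#'
#' @param x A [unique_read_table()] (possibly retention-filtered) or a
#'   character vector of ACGT sequences.
#' @param identity_threshold Clustering identity threshold (default 0.80).
#' @param abundance Optional copy counts when `x` is a character vector
#'   (defaults to 1 each).
#' @param label Assembly label, e.g. `"tissue-only"`, `"swab-only"` or
#'   `"control"`.
#' @return A `contig_set`: contigs (`contig_id`, `seq`, `length`,
#'   `member_count` = reads absorbed, `n_unique` = unique sequences absorbed)
#'   plus the per-sequence cluster `assignments`.
#' @export
greedy_cluster <- function(x, identity_threshold = 0.8, abundance = NULL,
                           label = "control") {
  check_scalar_num(identity_threshold, "identity_threshold", 0, 1,
                   lo_open = TRUE)
  if (inherits(x, "unique_read_table")) {
    seqs <- x$sequence
    abundance <- x$copies
  } else {
    seqs <- as.character(x)
    abundance <- abundance %||% rep(1L, length(seqs))
  }
  if (length(seqs) == 0L) {
    return(structure(list(contigs = data.frame(contig_id = character(),
                                               seq = character(),
                                               length = integer(),
                                               member_count = integer(),
                                               n_unique = integer()),
                          assignments = data.frame(sequence = character(),
                                                   contig_id = character()),
                          label = label,
                          identity_threshold = identity_threshold),
                     class = "contig_set"))
  }
  bad <- grep("[^ACGT]", seqs)
  if (length(bad))
    stop(sprintf("sequence contains non-ACGT characters: %s",
                 seqs[bad[1L]]), call. = FALSE)
  ord <- order(-abundance, -nchar(seqs), seqs)
  seqs_o <- seqs[ord]
  ab_o <- abundance[ord]
  rep_idx <- cpp_greedy_cluster(seqs_o, identity_threshold)
  reps <- sort(unique(rep_idx))
  cid <- sprintf("tig%05d", seq_along(reps))
  names(cid) <- as.character(reps)
  contig_of <- cid[as.character(rep_idx)]
  contigs <- data.frame(
    contig_id = cid,
    seq = seqs_o[reps],
    length = nchar(seqs_o[reps]),
    member_count = as.integer(tapply(ab_o, contig_of, sum)[cid]),
    n_unique = as.integer(table(contig_of)[cid]),
    stringsAsFactors = FALSE, row.names = NULL)
  assignments <- data.frame(sequence = seqs_o, contig_id = unname(contig_of),
                            stringsAsFactors = FALSE)
  structure(list(contigs = contigs, assignments = assignments, label = label,
                 identity_threshold = identity_threshold),
            class = "contig_set")
}

#' Build a de novo reference from demultiplexed samples
#'
#' Convenience wrapper: [unique_read_table()] then [retention_filter()] then
#' [greedy_cluster()].
#'
#' @inheritParams unique_read_table
#' @inheritParams retention_filter
#' @inheritParams greedy_cluster
#' @return A `contig_set`.
#' @export
build_reference <- function(samples, min_copies = 4L, min_individuals = 4L,
                            identity_threshold = 0.8, label = "control") {
  ut <- unique_read_table(samples)
  ut <- retention_filter(ut, min_copies, min_individuals)
  greedy_cluster(ut, identity_threshold, label = label)
}

#' @export
print.contig_set <- function(x, ...) {
  cat(sprintf("contig_set '%s': %d contigs (identity threshold %.2f)\n",
              x$label, nrow(x$contigs), x$identity_threshold))
  if (nrow(x$contigs))
    cat(sprintf("  lengths %d-%d bp; reads absorbed %d\n",
                min(x$contigs$length), max(x$contigs$length),
                sum(x$contigs$member_count)))
  invisible(x)
}

#' Write reference contigs to FASTA
#'
#' @param contig_set A [greedy_cluster()] result.
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_contigs <- function(contig_set, path) {
  stopifnot(inherits(contig_set, "contig_set"))
  write_fasta(setNames(contig_set$contigs$seq, contig_set$contigs$contig_id),
              path)
}
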