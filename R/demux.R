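# Barcode demultiplexing and contaminant screening.

validate_barcodes <- function(barcode_map, max_mismatches = 0L) {
  bc <- barcode_map$barcode
  if (anyDuplicated(bc))
    stop("duplicate barcodes in barcode map: ",
         paste(unique(bc[duplicated(bc)]), collapse = ", "), call. = FALSE)
  if (length(bc) > 1L) {
    for (i in seq_along(bc)) {
      pref <- bc[-i][startsWith(bc[-i], bc[i])]
      if (length(pref))
        stop(sprintf("barcode %s is a prefix of %s", bc[i], pref[1L]),
             call. = FALSE)
    }
    if (max_mismatches > 0L) {
      # same-length barcodes must be > 2*max_mismatches apart to stay unique
      for (i in seq_along(bc)) for (j in seq_along(bc)) {
        if (i < j && nchar(bc[i]) == nchar(bc[j])) {
          d <- sum(utf8ToInt(bc[i]) != utf8ToInt(bc[j]))
          if (d <= 2L * max_mismatches)
            stop(sprintf(
              "barcodes %s and %s are ambiguous at %d mismatches (distance %d)",
              bc[i], bc[j], max_mismatches, d), call. = FALSE)
        }
      }
    }
  }
  invisible(barcode_map)
}

#' Demultiplex a multiplexed FASTQ by barcode
#'
#' Assigns each read to the sample whose barcode matches the read prefix
#' within `max_mismatches` substitutions, trims the barcode, and reports
#' per-sample and unassigned counts. Barcodes must be unique and prefix-free;
#' with `max_mismatches > 0` same-length barcodes must additionally be more
#' than `2 * max_mismatches` substitutions apart so assignment stays unique.
#'
#' @param fastq Path to a multiplexed FASTQ file (Phred+33).
#' @param barcode_map Data frame with columns `sample_id` and `barcode`, or a
#'   path readable by [read_barcode_map()].
#' @param max_mismatches Substitutions tolerated within the barcode
#'   (default 0; the strictest reading of barcode matching).
#' @return An object of class `demux_result`: `samples` (a named list of
#'   `sample_read_set`s with trimmed `seq`/`qual`), `report` (per-sample read
#'   counts), `unassigned` and `n_input`.
#' @export
demultiplex <- function(fastq, barcode_map, max_mismatches = 0L) {
  if (is.character(barcode_map) && length(barcode_map) == 1L)
    barcode_map <- read_barcode_map(barcode_map)
  max_mismatches <- check_count(max_mismatches, "max_mismatches")
  validate_barcodes(barcode_map, max_mismatches)
  fq <- read_fastq(fastq)
  n_input <- length(fq$seq)
  if (nrow(barcode_map) == 0L) {
    return(structure(list(samples = list(),
                          report = data.frame(sample_id = character(),
                                              barcode = character(),
                                              n_reads = integer()),
                          unassigned = n_input, n_input = n_input),
                     class = "demux_result"))
  }
  hit <- if (n_input)
    cpp_assign_barcodes(fq$seq, barcode_map$barcode, max_mismatches)
  else integer(0)
  bl <- nchar(barcode_map$barcode)
  samples <- lapply(seq_len(nrow(barcode_map)), function(j) {
    k <- which(hit == j)
    structure(list(sample_id = barcode_map$sample_id[j],
                   seq = unname(substring(fq$seq[k], bl[j] + 1L)),
                   qual = unname(substring(fq$qual[k], bl[j] + 1L))),
              class = "sample_read_set")
  })
  names(samples) <- barcode_map$sample_id
  report <- data.frame(sample_id = barcode_map$sample_id,
                       barcode = barcode_map$barcode,
                       n_reads = vapply(samples, function(s) length(s$seq),
                                        integer(1)),
                       stringsAsFactors = FALSE, row.names = NULL)
  structure(list(samples = samples, report = report,
                 unassigned = sum(hit == 0L), n_input = n_input),
            class = "demux_result")
}

#' @export
print.demux_result <- function(x, ...) {
  cat(sprintf("demux_result: %d reads -> %d samples (%d unassigned)\n",
              x$n_input, length(x$samples), x$unassigned))
  if (nrow(x$report)) print(head(x$report, 10L))
  invisible(x)
}

#' @export
print.sample_read_set <- function(x, ...) {
  cat(sprintf("sample_read_set '%s': %d reads\n", x$sample_id, length(x$seq)))
  invisible(x)
}

#' Screen reads against contaminant sequences
#'
#' Removes reads whose best ungapped full-length placement inside any
#' contaminant sequence reaches `min_identity`. This is a sliding-window
#' identity screen, not a full aligner: adequate at desk scale for removing
#' spike-in control reads (the role PhiX screening plays in an Illumina run).
#' Surviving reads keep their order.
#'
#' @param x A `sample_read_set` or a `demux_result` (screens every sample).
#' @param contaminant_fasta Path to a FASTA of contaminant sequences, e.g.
#'   [phix_like_fasta()]; `NULL` returns the input unchanged.
#' @param min_identity Identity over the full read length required to call a
#'   read contaminant (default 0.9).
#' @return A list with `reads` (same class as `x`, screened) and `n_removed`
#'   (for a `demux_result`, a named per-sample vector).
#' @export
screen_contaminants <- function(x, contaminant_fasta = NULL,
                                min_identity = 0.9) {
  check_scalar_num(min_identity, "min_identity", 0, 1, lo_open = TRUE)
  if (is.null(contaminant_fasta))
    return(list(reads = x,
                n_removed = if (inherits(x, "demux_result"))
                  setNames(integer(length(x$samples)), names(x$samples))
                else 0L))
  contam <- read_fasta(contaminant_fasta)
  if (inherits(x, "sample_read_set")) {
    bad <- if (length(x$seq))
      cpp_screen_reads(x$seq, unname(contam), min_identity) else logical(0)
    x$seq <- x$seq[!bad]
    x$qual <- x$qual[!bad]
    return(list(reads = x, n_removed = sum(bad)))
  }
  if (inherits(x, "demux_result")) {
    removed <- integer(length(x$samples))
    for (j in seq_along(x$samples)) {
      r <- screen_contaminants(x$samples[[j]], contaminant_fasta, min_identity)
      x$samples[[j]] <- r$reads
      removed[j] <- r$n_removed
    }
    names(removed) <- names(x$samples)
    x$report$n_reads <- x$report$n_reads - removed
    return(list(reads = x, n_removed = removed))
  }
  stop("`x` must be a sample_read_set or demux_result")
}
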