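# FASTQ/FASTA/TSV plumbing shared by the pipeline stages. Sequence I/O goes
# through Biostrings; internally reads travel as plain character vectors.

read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  list(id = names(x) %||% sprintf("read_%07d", seq_along(x)),
       seq = as.character(x),
       qual = as.character(S4Vectors::mcols(x)$qualities))
}

write_fastq <- function(id, seq, qual, path) {
  x <- Biostrings::DNAStringSet(setNames(seq, id))
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a barcode map
#'
#' A barcode map is a two-column TSV (`sample_id`, `barcode`) assigning each
#' multiplexed sample its 10--20 bp multiplex identifier (MID).
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `sample_id` and `barcode`.
#' @export
read_barcode_map <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "barcode") %in% names(df)))
    stop("barcode map must have columns `sample_id` and `barcode`", call. = FALSE)
  df[c("sample_id", "barcode")]
}

#' Locate the bundled synthetic contaminant sequence
#'
#' Returns the path to a synthetic 1.5 kb control-library-like sequence shipped
#' with the package. It stands in for the PhiX spike-in control genome when
#' exercising [screen_contaminants()]; it is a random sequence, not PhiX.
#'
#' @return Path to a FASTA file.
#' @export
phix_like_fasta <- function() {
  system.file("extdata", "contaminant_phix_like_synthetic.fa",
              package = "gbsconcord", mustWork = TRUE)
}
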