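# Plain-text interchange: FASTA/FASTQ via Biostrings, truth tables and
# marker matrices as TSV.

#' Write named sequences to FASTA
#' @param seqs Named character vector of DNA sequences.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read FASTA into a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*", "", names(x)))
}

#' Write a read-pair table as a pair of FASTQ files
#'
#' Sanger Phred+33 encoding, mates interleave by record order with suffixes
#' `_1` / `_2` in the file names.
#'
#' @param pairs A `rad_read_pairs` table (see [simulate_rad_library()]).
#' @param dir Output directory.
#' @param prefix File prefix; defaults to the (single) sample id.
#' @return Character vector of the two paths.
#' @export
write_fastq_pairs <- function(pairs, dir, prefix = NULL) {
  if (is.null(prefix)) {
    prefix <- unique(pairs$sample_id)
    stopifnot(length(prefix) == 1)
  }
  f1 <- file.path(dir, paste0(prefix, "_1.fastq"))
  f2 <- file.path(dir, paste0(prefix, "_2.fastq"))
  fq <- function(id, seq, qual, path) {
    writeLines(paste0("@", id, "\n", seq, "\n+\n", qual), path)
  }
  fq(paste0(pairs$read_id, "/1"), pairs$se_seq, pairs$se_qual, f1)
  fq(paste0(pairs$read_id, "/2"), pairs$pe_seq, pairs$pe_qual, f2)
  c(f1, f2)
}

#' Read paired FASTQ files into a read-pair table
#' @param file1,file2 Mate FASTQ paths (`_1` = restriction-anchored single end).
#' @param sample_id Sample label to attach.
#' @export
read_fastq_pairs <- function(file1, file2, sample_id) {
  r1 <- Biostrings::readDNAStringSet(file1, format = "fastq", with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(file2, format = "fastq", with.qualities = TRUE)
  stopifnot(length(r1) == length(r2))
  data.table::data.table(
    read_id = sub("/1$", "", sub("\\s.*", "", names(r1))),
    sample_id = sample_id,
    se_seq = as.character(r1),
    pe_seq = as.character(r2),
    se_qual = as.character(S4Vectors::mcols(r1)$qualities),
    pe_qual = as.character(S4Vectors::mcols(r2)$qualities))
}

#' Write simulation truth tables as TSV
#' @param truth `derive_accessions()$truth`.
#' @param dir Output directory.
#' @return Paths of `truth_variants.tsv` and `truth_loci.tsv`.
#' @export
write_truth_tables <- function(truth, dir) {
  pv <- file.path(dir, "truth_variants.tsv")
  pl <- file.path(dir, "truth_loci.tsv")
  write.table(truth$variants, pv, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(truth$loci, pl, sep = "\t", quote = FALSE, row.names = FALSE)
  c(pv, pl)
}
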