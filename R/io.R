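# FASTA / FASTQ input-output, via Biostrings

#' Read and write read sets as FASTQ (Sanger Phred+33)
#'
#' Read sets are plain data.frames with columns `id`, `seq`, `qual`
#' (quality as a Phred+33 encoded string of the same length as `seq`).
#'
#' @param reads read-set data.frame
#' @param path file path (`.gz` allowed on read)
#' @return `read_fastq` returns a read-set data.frame; `write_fastq`
#'   returns the path invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$seq),
    Biostrings::PhredQuality(reads$qual))
  names(x) <- reads$id
  # Biostrings warns about dropping its own internal metadata columns here
  suppressWarnings(Biostrings::writeQualityScaledXStringSet(x, path))
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(id = names(x),
             seq = unname(as.character(x)),
             qual = unname(as.character(Biostrings::quality(x))),
             stringsAsFactors = FALSE)
}

#' Read and write sequence sets as FASTA
#'
#' @param seqs named character vector of sequences (or a data.frame with
#'   `id` and `seq` columns)
#' @param path file path
#' @return `read_fasta` returns a named character vector.
#' @export
write_fasta <- function(seqs, path) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$seq, seqs$id)
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Extract unmapped reads from a SAM/BAM file
#'
#' Pulls records flagged unmapped (and, for paired data, with unmapped
#' mate) into a read-set data.frame, the entry point for host-aligned
#' input. Requires the Rsamtools package.
#'
#' @param path SAM or BAM file
#' @param require_mate_unmapped for paired records, keep only reads whose
#'   mate is also unmapped (default TRUE)
#' @return read-set data.frame (`id`, `seq`, `qual`)
#' @export
read_unmapped_sam <- function(path, require_mate_unmapped = TRUE) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stopf("read_unmapped_sam() requires the Rsamtools package")
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = TRUE),
    what = c("qname", "seq", "qual", "flag"))
  b <- Rsamtools::scanBam(path, param = param)[[1]]
  keep <- rep(TRUE, length(b$qname))
  if (require_mate_unmapped) {
    paired <- bitwAnd(b$flag, 1L) > 0L
    mate_unmapped <- bitwAnd(b$flag, 8L) > 0L
    keep <- !paired | mate_unmapped
  }
  data.frame(id = b$qname[keep],
             seq = as.character(b$seq)[keep],
             qual = as.character(b$qual)[keep],
             stringsAsFactors = FALSE)
}
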