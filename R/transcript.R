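#' Construct a coding transcript
#'
#' A `transcript` bundles a coding DNA sequence with its translation. The
#' CDS must be a positive multiple of 3 nucleotides over `{A,C,G,T}` and
#' must not contain an in-frame internal stop codon; a single terminal
#' stop codon is permitted and is excluded from the protein sequence.
#'
#' @param id Transcript identifier.
#' @param cds Coding DNA string.
#' @return An object of class `transcript` with elements `id`, `cds`,
#'   `protein` and `has_terminal_stop`.
#' @examples
#' tx <- transcript("T1", "ATGAAATGA")
#' tx$protein  # "MK"
#' @export
transcript <- function(id, cds) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  aa <- translate_cds(cds)  # validates alphabet and length
  stops <- which(strsplit(aa, "")[[1]] == "*")
  n_aa <- nchar(aa)
  if (any(stops < n_aa)) {
    stop("transcript '", id, "': internal stop codon at protein position ",
         stops[stops < n_aa][1])
  }
  has_stop <- length(stops) == 1L && stops == n_aa
  protein <- if (has_stop) substr(aa, 1L, n_aa - 1L) else aa
  if (nchar(protein) == 0L) {
    stop("transcript '", id, "': empty protein (CDS is a bare stop codon)")
  }
  structure(
    list(id = id, cds = cds, protein = protein, has_terminal_stop = has_stop),
    class = "transcript"
  )
}

#' @export
print.transcript <- function(x, ...) {
  cat("<transcript>", x$id, "\n")
  cat("  CDS:    ", nchar(x$cds), "nt\n")
  cat("  protein:", nchar(x$protein), "aa",
      if (x$has_terminal_stop) "(+ terminal stop)" else "", "\n")
  invisible(x)
}

#' Read coding sequences from a FASTA file
#'
#' Each record becomes one [transcript()]; record ids are transcript ids.
#'
#' @param path Path to a (multi-record) FASTA file of CDS.
#' @return Named list of `transcript` objects.
#' @export
read_cds_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  txs <- lapply(seq_along(seqs), function(i) transcript(ids[i], as.character(seqs[[i]])))
  names(txs) <- ids
  txs
}

#' Write transcripts to a FASTA file
#'
#' @param transcripts List of `transcript` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(transcripts, path) {
  seqs <- Biostrings::DNAStringSet(vapply(transcripts, `[[`, "", "cds"))
  names(seqs) <- vapply(transcripts, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
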