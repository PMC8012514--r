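#' Translate codons under the standard genetic code
#'
#' Translates one or more DNA codons to single-letter amino acids. Stop
#' codons translate to the distinguished marker `"*"`, never to an amino
#' acid letter.
#'
#' @param codon Character vector of 3-letter DNA codons over `{A,C,G,T}`.
#' @return Character vector of single amino-acid letters, with `"*"` for
#'   stop codons.
#' @examples
#' translate_codon("ATG")          # "M"
#' translate_codon(c("TAA", "AAA")) # "*" "K"
#' @export
translate_codon <- function(codon) {
  if (!is.character(codon) || length(codon) == 0) {
    stop("`codon` must be a non-empty character vector")
  }
  bad <- !grepl("^[ACGT]{3}$", codon)
  if (any(bad)) {
    stop("invalid codon(s): ", paste(unique(codon[bad]), collapse = ", "),
         " (expected exactly 3 letters over A/C/G/T)")
  }
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Translate a coding sequence
#'
#' @param cds DNA string whose length is a positive multiple of 3.
#' @return Single string of amino-acid letters (stops as `"*"`).
#' @keywords internal
translate_cds <- function(cds) {
  n <- nchar(cds)
  if (n == 0L || n %% 3L != 0L) {
    stop("CDS length must be a positive multiple of 3, got ", n)
  }
  starts <- seq.int(1L, n - 2L, by = 3L)
  paste(translate_codon(substring(cds, starts, starts + 2L)), collapse = "")
}

# Split a CDS into its codons (character vector).
split_codons <- function(cds) {
  n <- nchar(cds)
  starts <- seq.int(1L, n - 2L, by = 3L)
  substring(cds, starts, starts + 2L)
}
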