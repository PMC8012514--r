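# Shared fixtures and independent oracles.

# Independent brute-force oracle for nsSNV enumeration of one codon:
# tries all 9 single-nucleotide substitutions, translates with seqinr
# (an implementation path the package does not use), and keeps the
# amino-acid-changing, non-stop ones.
oracle_enumerate_codon <- function(codon) {
  tr <- function(cdn) toupper(seqinr::translate(strsplit(tolower(cdn), "")[[1]]))
  ref_aa <- tr(codon)
  out <- list()
  for (off in 1:3) {
    for (alt in c("A", "C", "G", "T")) {
      if (substr(codon, off, off) == alt) next
      alt_codon <- codon
      substr(alt_codon, off, off) <- alt
      alt_aa <- tr(alt_codon)
      if (alt_aa == "*" || alt_aa == ref_aa) next
      out[[length(out) + 1L]] <- data.frame(
        aa_pos = 1L, codon_offset = off,
        ref_nt = substr(codon, off, off), alt_nt = alt,
        ref_aa = ref_aa, alt_aa = alt_aa, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(res)
  res <- res[order(res$aa_pos, res$codon_offset, res$alt_nt), ]
  rownames(res) <- NULL
  res
}

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# A single-codon transcript (codon must be a sense codon).
single_codon_tx <- function(codon, id = "T1") transcript(id, codon)

# Build an ortholog_alignment over the default 20-species panel from a
# matrix of ortholog rows (species x columns, characters) and a human row.
panel_alignment <- function(human_row, ortholog_rows, transcript_id = "T1") {
  panel <- default_species_panel()
  stopifnot(nrow(ortholog_rows) == nrow(panel))
  rows <- c(human = human_row,
            stats::setNames(apply(ortholog_rows, 1, paste, collapse = ""),
                            panel$species))
  ortholog_alignment(
    transcript_id, rows,
    clade = stats::setNames(panel$clade, panel$species),
    divergence_mya = stats::setNames(panel$divergence_mya, panel$species)
  )
}

# Minimal SAV data frame.
sav_row <- function(transcript_id = "T1", aa_pos = 1L, ref_aa = "A",
                    alt_aa = "V", category = "rare") {
  data.frame(transcript_id = transcript_id, aa_pos = aa_pos,
             ref_aa = ref_aa, alt_aa = alt_aa,
             category = factor(category, levels = sav_strata()),
             stringsAsFactors = FALSE)
}
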