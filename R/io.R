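#' Read and write the package's tab-separated interchange tables
#'
#' Plain TSV readers/writers for the pipeline's external interfaces:
#' allele-count tables (`transcript_id aa_pos codon_offset alt_nt AC AN`),
#' nsSNV tables, SAV tables, effect-score tables
#' (`transcript_id aa_pos ref_aa alt_aa score`), position profiles
#' (`transcript_id aa_pos consurf psic funtrp_class`) and species
#' metadata (`species clade divergence_mya`).
#'
#' @param path File path.
#' @param x Data frame to write.
#' @return Readers return a data frame; writers return `path` invisibly.
#' @name tsv_io
NULL

read_tsv_checked <- function(path, required) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss)) {
    stop(basename(path), " lacks column(s): ", paste(miss, collapse = ", "))
  }
  d
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname tsv_io
#' @export
read_allele_table <- function(path) {
  read_tsv_checked(path, c("transcript_id", "aa_pos", "codon_offset",
                           "alt_nt", "AC", "AN"))
}

#' @rdname tsv_io
#' @export
read_score_table <- function(path) {
  read_tsv_checked(path, c("transcript_id", "aa_pos", "ref_aa", "alt_aa", "score"))
}

#' @rdname tsv_io
#' @export
read_profile_table <- function(path) {
  read_tsv_checked(path, c("transcript_id", "aa_pos", "consurf", "psic",
                           "funtrp_class"))
}

#' @rdname tsv_io
#' @export
read_species_metadata <- function(path) {
  read_tsv_checked(path, c("species", "clade", "divergence_mya"))
}

#' @rdname tsv_io
#' @export
write_nssnv_table <- function(x, path) {
  write_tsv(x[, c("transcript_id", "aa_pos", "codon_offset", "ref_nt",
                  "alt_nt", "ref_aa", "alt_aa", "AC", "AN")], path)
}

#' @rdname tsv_io
#' @export
write_sav_table <- function(x, path) {
  out <- x[, c("transcript_id", "aa_pos", "ref_aa", "alt_aa",
               "agg_count", "AN", "freq", "category")]
  write_tsv(out, path)
}

#' Read one ortholog alignment from aligned FASTA
#'
#' Record ids are species names; the human (anchor) row must come first.
#'
#' @param path Aligned multi-FASTA file.
#' @param transcript_id Transcript the alignment belongs to.
#' @param species_meta Species metadata data frame (see
#'   [read_species_metadata()]).
#' @return An [ortholog_alignment()].
#' @export
read_ortholog_msa <- function(path, transcript_id, species_meta) {
  seqs <- Biostrings::readAAStringSet(path)
  rows <- stats::setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
  ortholog_alignment(
    transcript_id, rows,
    clade = stats::setNames(species_meta$clade, species_meta$species),
    divergence_mya = stats::setNames(species_meta$divergence_mya,
                                     species_meta$species)
  )
}

#' Write a simulated cohort's input bundle to a directory
#'
#' Emits everything a downstream analysis needs as plain text:
#' `cds.fasta`, one `msa_<transcript>.fasta` per transcript,
#' `allele_counts.tsv`, `effect_scores.tsv`, `position_profiles.tsv`,
#' `species.tsv`, and the ground truth as `truth_sav_strata.tsv` and
#' `truth_csv_events.tsv`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cds_fasta(cohort$transcripts, file.path(dir, "cds.fasta"))
  for (id in names(cohort$alignments)) {
    aln <- cohort$alignments[[id]]
    seqs <- Biostrings::AAStringSet(aln$rows)
    Biostrings::writeXStringSet(seqs, file.path(dir, paste0("msa_", id, ".fasta")))
  }
  write_tsv(cohort$allele_table, file.path(dir, "allele_counts.tsv"))
  write_tsv(cohort$scores, file.path(dir, "effect_scores.tsv"))
  write_tsv(cohort$profiles, file.path(dir, "position_profiles.tsv"))
  write_tsv(cohort$species, file.path(dir, "species.tsv"))
  write_tsv(cohort$truth$sav_strata, file.path(dir, "truth_sav_strata.tsv"))
  write_tsv(cohort$truth$csv_events, file.path(dir, "truth_csv_events.tsv"))
  invisible(dir)
}
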