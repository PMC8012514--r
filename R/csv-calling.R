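#' Construct a human-anchored ortholog alignment
#'
#' Holds one transcript's protein multiple sequence alignment across a
#' species panel, with the human row first, plus per-species clade
#' membership and divergence time from human (million years ago).
#'
#' @param transcript_id Transcript identifier.
#' @param rows Named character vector of equal-length aligned amino-acid
#'   strings (gap character `-`); the first element must be the human row.
#' @param clade Named character vector mapping each non-human species to
#'   `"ape"`, `"mammal"` or `"other"`.
#' @param divergence_mya Named numeric vector of divergence times (MYA)
#'   for each non-human species.
#' @return An object of class `ortholog_alignment`.
#' @export
ortholog_alignment <- function(transcript_id, rows, clade, divergence_mya) {
  stopifnot(is.character(rows), length(rows) >= 2L, !is.null(names(rows)))
  if (length(unique(nchar(rows))) != 1L) {
    stop("alignment rows of '", transcript_id, "' differ in length")
  }
  orthologs <- names(rows)[-1]
  miss <- setdiff(orthologs, names(clade))
  if (length(miss)) stop("species without clade assignment: ", paste(miss, collapse = ", "))
  miss <- setdiff(orthologs, names(divergence_mya))
  if (length(miss)) stop("species without divergence time: ", paste(miss, collapse = ", "))
  if (any(divergence_mya[orthologs] <= 0)) stop("divergence times must be positive")
  structure(
    list(transcript_id = transcript_id, species = names(rows), rows = rows,
         clade = clade[orthologs], divergence_mya = divergence_mya[orthologs]),
    class = "ortholog_alignment"
  )
}

#' @export
print.ortholog_alignment <- function(x, ...) {
  cat("<ortholog_alignment>", x$transcript_id, "\n")
  cat("  ", length(x$species), " species (anchor: ", x$species[1], "), ",
      nchar(x$rows[1]), " columns\n", sep = "")
  invisible(x)
}

#' Map human protein positions to alignment columns
#'
#' @param aln An [ortholog_alignment()].
#' @return Integer vector: element `p` is the 1-based alignment column of
#'   human protein position `p`. Strictly increasing; length equals the
#'   human protein length.
#' @export
map_protein_to_msa <- function(aln) {
  human <- strsplit(aln$rows[[1]], "")[[1]]
  which(human != "-")
}

# Alignment as a species x column character matrix.
alignment_matrix <- function(aln) {
  m <- matrix(unlist(strsplit(aln$rows, ""), use.names = FALSE),
              nrow = length(aln$rows), byrow = TRUE)
  rownames(m) <- aln$species
  m
}

#' Annotate SAVs with cross-species variant status
#'
#' A SAV is a cross-species variant (CSV) when its variant amino acid is
#' the aligned reference residue of at least one non-human ortholog at
#' the same protein position (e.g. human L at position 3 with a mouse G
#' at the aligned column makes the SAV L3G a CSV supported by mouse).
#' Orthologs gapped at the column support neither a CSV call nor the
#' shared-reference count.
#'
#' @param savs `sav_table` rows belonging to `aln`'s transcript.
#' @param aln An [ortholog_alignment()] covering the transcript.
#' @return Object of class `csv_annotations`: a list with `table` (one
#'   row per SAV: `transcript_id`, `aa_pos`, `ref_aa`, `alt_aa`,
#'   `category`, `is_csv`, `supporting_species`, `shared_ref_species`),
#'   `residues` (SAV x ortholog character matrix of aligned residues),
#'   `clade` and `divergence_mya`.
#' @export
annotate_csvs <- function(savs, aln) {
  stopifnot(is.data.frame(savs))
  if (nrow(savs) > 0 && !all(savs$transcript_id == aln$transcript_id)) {
    stop("SAVs and alignment refer to different transcripts")
  }
  colmap <- map_protein_to_msa(aln)
  if (nrow(savs) > 0 && any(savs$aa_pos > length(colmap))) {
    stop("SAV position beyond human protein length in alignment")
  }
  m <- alignment_matrix(aln)
  cols <- colmap[savs$aa_pos]
  human_res <- m[1, cols]
  bad <- human_res != savs$ref_aa
  if (any(bad)) {
    i <- which(bad)[1]
    stop("reference mismatch at ", aln$transcript_id, ":", savs$aa_pos[i],
         " (alignment has ", human_res[i], ", SAV has ", savs$ref_aa[i], ")")
  }
  res <- m[-1, cols, drop = FALSE]  # orthologs x SAVs
  supp <- res == matrix(savs$alt_aa, nrow(res), ncol(res), byrow = TRUE)
  shared <- res == matrix(savs$ref_aa, nrow(res), ncol(res), byrow = TRUE)
  orth <- rownames(res)
  tab <- data.frame(
    transcript_id = savs$transcript_id,
    aa_pos = savs$aa_pos, ref_aa = savs$ref_aa, alt_aa = savs$alt_aa,
    category = if ("category" %in% names(savs)) savs$category else NA,
    is_csv = colSums(supp) > 0L,
    supporting_species = apply(supp, 2, function(z) paste(orth[z], collapse = ",")),
    shared_ref_species = apply(shared, 2, function(z) paste(orth[z], collapse = ",")),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  structure(
    list(table = tab, residues = t(res),
         clade = aln$clade, divergence_mya = aln$divergence_mya),
    class = "csv_annotations"
  )
}

#' @rdname annotate_csvs
#' @param sav A single-row SAV (one element of a `sav_table`).
#' @export
call_csv <- function(sav, aln) {
  ann <- annotate_csvs(sav, aln)
  out <- as.list(ann$table[1, ])
  out$aligned_residues <- ann$residues[1, ]
  out$supporting_species <- strsplit(out$supporting_species, ",")[[1]]
  out$shared_ref_species <- strsplit(out$shared_ref_species, ",")[[1]]
  out
}

#' Combine per-transcript CSV annotations
#'
#' @param anns List of `csv_annotations` over the same species panel.
#' @return A single `csv_annotations` object.
#' @export
combine_annotations <- function(anns) {
  stopifnot(length(anns) >= 1L)
  sp <- colnames(anns[[1]]$residues)
  for (a in anns) stopifnot(identical(colnames(a$residues), sp))
  structure(
    list(table = do.call(rbind, lapply(anns, `[[`, "table")),
         residues = do.call(rbind, lapply(anns, `[[`, "residues")),
         clade = anns[[1]]$clade, divergence_mya = anns[[1]]$divergence_mya),
    class = "csv_annotations"
  )
}

#' @export
print.csv_annotations <- function(x, ...) {
  cat("<csv_annotations> ", nrow(x$table), " SAVs x ",
      ncol(x$residues), " orthologs; ", sum(x$table$is_csv), " CSVs\n", sep = "")
  invisible(x)
}

# Species selected by a clade filter. Clade labels are the finest class:
# "ape" species are also mammals.
clade_species <- function(ann, clade_filter = c("all", "ape", "mammal")) {
  clade_filter <- match.arg(clade_filter)
  cl <- ann$clade[colnames(ann$residues)]
  switch(clade_filter,
         all = names(cl),
         ape = names(cl)[cl == "ape"],
         mammal = names(cl)[cl %in% c("ape", "mammal")])
}

#' Pooled reference-amino-acid prevalence across orthologs
#'
#' Across a set of annotated variants, computes the fraction of aligned
#' (non-gap) in-clade ortholog residues that equal the human reference
#' amino acid, pooled over variants — i.e. the ratio of summed counts,
#' not the mean of per-variant fractions. With one variant sharing its
#' reference in 10 of 15 aligned orthologs and another in 4 of 20, the
#' pooled prevalence is 14/35 = 40%.
#'
#' @param ann A `csv_annotations` object, optionally pre-filtered with
#'   `subset_annotations()`.
#' @param clade_filter One of `"all"`, `"ape"`, `"mammal"` (apes are
#'   included among mammals).
#' @return Fraction in \[0,1\], with attributes `n_shared` and
#'   `n_aligned`; `NA` (with a warning) when no in-clade ortholog residue
#'   is aligned at any variant position.
#' @export
reference_prevalence <- function(ann, clade_filter = c("all", "ape", "mammal")) {
  sp <- clade_species(ann, clade_filter)
  res <- ann$residues[, sp, drop = FALSE]
  ref <- matrix(ann$table$ref_aa, nrow(res), ncol(res))
  aligned <- res != "-"
  n_shared <- sum(res == ref & aligned)
  n_aligned <- sum(aligned)
  if (n_aligned == 0L) {
    warning("no aligned ortholog residues in the selected clade; prevalence undefined")
    return(structure(NA_real_, n_shared = 0L, n_aligned = 0L))
  }
  structure(n_shared / n_aligned, n_shared = n_shared, n_aligned = n_aligned)
}

#' Subset a `csv_annotations` object by variant
#'
#' @param ann A `csv_annotations` object.
#' @param keep Logical or integer index over its variants.
#' @return A `csv_annotations` object with the selected rows.
#' @export
subset_annotations <- function(ann, keep) {
  structure(
    list(table = ann$table[keep, , drop = FALSE],
         residues = ann$residues[keep, , drop = FALSE],
         clade = ann$clade, divergence_mya = ann$divergence_mya),
    class = "csv_annotations"
  )
}

#' Partition variants by shared reference amino acid per species
#'
#' For each ortholog species, returns the indices of variants whose human
#' reference amino acid equals that species' aligned (non-gap) residue.
#' Subsets may overlap across species.
#'
#' @param ann A `csv_annotations` object.
#' @param species Character vector of species to report (default: all
#'   orthologs in the annotation).
#' @return Named list of integer vectors (row indices into `ann$table`).
#' @export
shared_reference_partition <- function(ann, species = colnames(ann$residues)) {
  miss <- setdiff(species, colnames(ann$residues))
  if (length(miss)) stop("unknown species: ", paste(miss, collapse = ", "))
  out <- lapply(species, function(s) {
    which(ann$residues[, s] == ann$table$ref_aa & ann$residues[, s] != "-")
  })
  names(out) <- species
  out
}
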