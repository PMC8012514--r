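#' Enumerate all possible non-synonymous SNVs of a transcript
#'
#' Considers, for every codon of the protein, all nine single-nucleotide
#' substitutions and keeps exactly those that change the encoded amino
#' acid without creating a stop codon (nonsense variants are not single
#' amino acid variants and are excluded; so are changes at a terminal
#' stop codon). Rows are ordered by `aa_pos`, then `codon_offset`, then
#' `alt_nt` alphabetically, so two calls on the same transcript return
#' identical tables.
#'
#' @param tx A [transcript()].
#' @return A data frame with columns `transcript_id`, `aa_pos` (1-based
#'   protein position), `codon_offset` (1..3 within the codon), `ref_nt`,
#'   `alt_nt`, `ref_aa`, `alt_aa`, `AC` (allele count, initialised to 0)
#'   and `AN` (total sequenced alleles, initialised to `NA` until
#'   [attach_allele_counts()] runs).
#' @examples
#' enumerate_nssnvs(transcript("K1", "AAA"))  # 7 rows, 6 distinct changes
#' @export
enumerate_nssnvs <- function(tx) {
  if (!inherits(tx, "transcript")) tx <- transcript(tx$id, tx$cds)
  codons <- split_codons(tx$cds)
  n_aa <- nchar(tx$protein)
  codons <- codons[seq_len(n_aa)]  # drop terminal stop codon if present
  ref_aa <- translate_codon(codons)

  nts <- c("A", "C", "G", "T")
  cmat <- matrix(unlist(strsplit(codons, ""), use.names = FALSE),
                 ncol = 3L, byrow = TRUE)

  out <- vector("list", 12L)
  k <- 0L
  for (off in 1:3) {
    for (alt in nts) {
      keep <- cmat[, off] != alt
      if (!any(keep)) next
      alt_codon <- cmat[keep, , drop = FALSE]
      alt_codon[, off] <- alt
      alt_codon <- paste0(alt_codon[, 1], alt_codon[, 2], alt_codon[, 3])
      alt_aa <- translate_codon(alt_codon)
      ok <- alt_aa != "*" & alt_aa != ref_aa[keep]
      if (!any(ok)) next
      k <- k + 1L
      out[[k]] <- data.frame(
        transcript_id = tx$id,
        aa_pos        = which(keep)[ok],
        codon_offset  = off,
        ref_nt        = cmat[keep, off][ok],
        alt_nt        = alt,
        ref_aa        = ref_aa[keep][ok],
        alt_aa        = alt_aa[ok],
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  if (is.null(res)) {
    res <- data.frame(transcript_id = character(), aa_pos = integer(),
                      codon_offset = integer(), ref_nt = character(),
                      alt_nt = character(), ref_aa = character(),
                      alt_aa = character(), stringsAsFactors = FALSE)
  }
  res <- res[order(res$aa_pos, res$codon_offset, res$alt_nt), , drop = FALSE]
  rownames(res) <- NULL
  res$AC <- 0L
  res$AN <- NA_integer_
  res
}

#' Attach observed allele counts to enumerated nsSNVs
#'
#' Joins a site-keyed allele-count table (emulating exome-cohort AC/AN
#' records) onto an enumerated nsSNV table. Matching is at nucleotide-site
#' resolution: `(transcript_id, aa_pos, codon_offset, alt_nt)`. Variants
#' without a matching record keep `AC = 0`; their `AN` is taken from any
#' other record at the same nucleotide site, or from `default_an`
#' otherwise. No nsSNV is ever dropped.
#'
#' @param nssnvs Data frame from [enumerate_nssnvs()] (one or several
#'   transcripts row-bound together).
#' @param allele_table Data frame with columns `transcript_id`, `aa_pos`,
#'   `codon_offset`, `alt_nt`, `AC`, `AN`.
#' @param default_an Cohort allele number used for sites with no record
#'   at all. The default matches a large exome cohort of ~125,000
#'   individuals.
#' @return `nssnvs` with `AC` and `AN` filled in.
#' @export
attach_allele_counts <- function(nssnvs, allele_table, default_an = 251496L) {
  stopifnot(is.data.frame(nssnvs))
  need <- c("transcript_id", "aa_pos", "codon_offset", "alt_nt", "AC", "AN")
  if (is.null(allele_table) || nrow(allele_table) == 0L) {
    nssnvs$AC <- 0L
    nssnvs$AN <- as.integer(default_an)
    return(nssnvs)
  }
  miss <- setdiff(need, names(allele_table))
  if (length(miss)) stop("allele_table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(allele_table$AC > allele_table$AN)) {
    stop("allele_table has AC > AN")
  }

  site_key <- function(d) paste(d$transcript_id, d$aa_pos, d$codon_offset, sep = "\r")
  full_key <- function(d) paste(site_key(d), d$alt_nt, sep = "\r")

  # a record whose alt equals the transcript's reference base contradicts it
  ref_by_site <- nssnvs$ref_nt[!duplicated(site_key(nssnvs))]
  names(ref_by_site) <- site_key(nssnvs)[!duplicated(site_key(nssnvs))]
  tab_ref <- ref_by_site[site_key(allele_table)]
  clash <- !is.na(tab_ref) & tab_ref == allele_table$alt_nt
  if (any(clash)) {
    i <- which(clash)[1]
    stop("allele_table alt allele equals the reference base at site ",
         allele_table$transcript_id[i], ":", allele_table$aa_pos[i],
         " offset ", allele_table$codon_offset[i])
  }

  idx <- match(full_key(nssnvs), full_key(allele_table))
  unmatched_records <- setdiff(seq_len(nrow(allele_table)), idx[!is.na(idx)])
  if (length(unmatched_records)) {
    warning(length(unmatched_records),
            " allele record(s) do not correspond to any nsSNV ",
            "(synonymous or stop-gain changes); ignored")
  }
  nssnvs$AC <- ifelse(is.na(idx), 0L, as.integer(allele_table$AC[idx]))

  # AN for unmatched variants: borrow from any record at the same site
  an_site <- tapply(allele_table$AN, site_key(allele_table), max)
  site_an <- an_site[site_key(nssnvs)]
  nssnvs$AN <- as.integer(ifelse(!is.na(idx), allele_table$AN[idx],
                          ifelse(!is.na(site_an), site_an, default_an)))
  nssnvs
}
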