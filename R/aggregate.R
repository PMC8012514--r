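#' Aggregate nucleotide-level nsSNVs into single amino acid variants
#'
#' All nsSNVs causing the same amino-acid substitution at the same
#' protein position are collapsed into one SAV. The SAV frequency is
#'
#' \deqn{freq(SAV) = \sum_{i=1}^{k} n_i / N}
#'
#' where \eqn{n_1 \ldots n_k} are the allele counts of the contributing
#' nucleotide routes and \eqn{N} is the number of sequenced alleles at
#' the codon. When the contributing sites report different allele numbers
#' (uneven coverage), \eqn{N} is by default the maximum across sites — the
#' conservative, frequency-lowering choice; `an_rule = "mean"` uses the
#' mean instead. Frequency strata are assigned *after* aggregation, so
#' two single-allele nucleotide routes yield an observed (count 2) SAV.
#'
#' @param nssnvs nsSNV data frame with allele counts attached
#'   (see [attach_allele_counts()]).
#' @param an_rule How to reconcile differing AN across contributing
#'   sites: `"max"` (default) or `"mean"`.
#' @param common_threshold Frequency at or above which an observed SAV is
#'   `common` (default 0.01, inclusive).
#' @return A data frame of class `sav_table` with columns
#'   `transcript_id`, `aa_pos`, `ref_aa`, `alt_aa`, `n_routes`,
#'   `contributing_counts` (list column of per-route allele counts),
#'   `agg_count`, `AN`, `freq`, `category`.
#' @examples
#' tx <- transcript("T1", "AAA")
#' nss <- attach_allele_counts(enumerate_nssnvs(tx), NULL, default_an = 1000)
#' aggregate_to_savs(nss)
#' @export
aggregate_to_savs <- function(nssnvs, an_rule = c("max", "mean"),
                              common_threshold = 0.01) {
  an_rule <- match.arg(an_rule)
  stopifnot(is.data.frame(nssnvs), !anyNA(nssnvs$AN))

  pos_key <- paste(nssnvs$transcript_id, nssnvs$aa_pos, sep = "\r")
  ref_per_pos <- tapply(nssnvs$ref_aa, pos_key, function(x) length(unique(x)))
  if (any(ref_per_pos > 1L)) {
    bad <- names(ref_per_pos)[ref_per_pos > 1L][1]
    stop("inconsistent reference amino acid at position ",
         gsub("\r", ":", bad))
  }

  key <- paste(pos_key, nssnvs$ref_aa, nssnvs$alt_aa, sep = "\r")
  ord <- order(nssnvs$transcript_id, nssnvs$aa_pos, nssnvs$ref_aa, nssnvs$alt_aa)
  nssnvs <- nssnvs[ord, , drop = FALSE]
  key <- key[ord]
  first <- !duplicated(key)
  grp <- match(key, key[first])

  counts <- split(nssnvs$AC, grp)
  an_fun <- if (an_rule == "max") max else mean
  an <- vapply(split(nssnvs$AN, grp), an_fun, 0)
  agg <- vapply(counts, sum, 0L)

  savs <- data.frame(
    transcript_id = nssnvs$transcript_id[first],
    aa_pos        = nssnvs$aa_pos[first],
    ref_aa        = nssnvs$ref_aa[first],
    alt_aa        = nssnvs$alt_aa[first],
    n_routes      = lengths(counts),
    agg_count     = as.integer(agg),
    AN            = an,
    stringsAsFactors = FALSE
  )
  savs$contributing_counts <- unname(counts)
  savs$freq <- savs$agg_count / savs$AN
  savs$category <- classify_sav(savs, common_threshold = common_threshold)
  class(savs) <- c("sav_table", "data.frame")
  savs
}

#' Assign population-frequency strata to SAVs
#'
#' Strata form a disjoint, exhaustive partition:
#' `synthetic` (aggregated allele count 0 — genetically possible but never
#' observed), `singleton` (count exactly 1), and observed SAVs (count > 1)
#' split into `common` (frequency >= `common_threshold`, inclusive) and
#' `rare` (below it).
#'
#' @param sav A `sav_table` (or any data frame with `agg_count` and
#'   `freq` columns).
#' @param common_threshold Common/rare frequency cutoff (default 0.01).
#' @return Factor with levels `synthetic`, `singleton`, `rare`, `common`.
#' @export
classify_sav <- function(sav, common_threshold = 0.01) {
  count <- sav$agg_count
  freq <- sav$freq
  stopifnot(all(count >= 0), all(freq >= 0 & freq <= 1))
  out <- ifelse(count == 0L, "synthetic",
         ifelse(count == 1L, "singleton",
         ifelse(freq >= common_threshold, "common", "rare")))
  factor(out, levels = sav_strata())
}

#' @rdname classify_sav
#' @export
sav_strata <- function() c("synthetic", "singleton", "rare", "common")

#' Census of SAV frequency strata
#'
#' @param savs A classified `sav_table`.
#' @return Named integer vector of counts over the four strata; counts
#'   always sum to `nrow(savs)`.
#' @export
stratum_census <- function(savs) {
  tab <- table(factor(savs$category, levels = sav_strata()))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' @export
print.sav_table <- function(x, ...) {
  cat("<sav_table> ", nrow(x), " SAVs in ",
      length(unique(x$transcript_id)), " transcript(s)\n", sep = "")
  print(stratum_census(x))
  invisible(x)
}
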