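#' Severity thresholds for variant effect scores
#'
#' Effect scores live in roughly \[-94, +88\]: negative scores predict a
#' neutral variant, non-negative scores an effect variant, and magnitude
#' tracks effect size. The default severity cut points follow the common
#' convention: mild effects below 23, moderate from 25 upward, severe
#' from 50 upward (inclusive bounds on the right-hand categories).
#'
#' @param mild_upper Upper (exclusive) score limit of a mild effect.
#' @param moderate Score at or above which an effect counts as at least
#'   moderate (used for "moderate or worse" tallies).
#' @param severe Score at or above which an effect is severe.
#' @return Object of class `severity_bins`.
#' @export
severity_bins <- function(mild_upper = 23, moderate = 25, severe = 50) {
  stopifnot(0 < mild_upper, mild_upper <= severe, moderate <= severe)
  structure(list(mild_upper = mild_upper, moderate = moderate, severe = severe),
            class = "severity_bins")
}

#' Binned relative frequencies of effect scores
#'
#' Bins are half-open intervals `[k*width, (k+1)*width)` anchored at 0
#' (so a score of exactly 10 falls in `[10, 20)` at the default width).
#' All bins between the lowest and highest occupied bin are reported,
#' including empty ones; frequencies sum to 1.
#'
#' @param scores Numeric vector of effect scores (non-empty).
#' @param width Bin width (default 10).
#' @return Data frame with `bin_lower`, `bin_center`, `count`, `freq`.
#' @export
binned_frequency <- function(scores, width = 10) {
  stopifnot(width > 0)
  if (length(scores) == 0L) stop("empty score vector: no distribution to bin")
  bin <- floor(scores / width)
  rng <- seq.int(min(bin), max(bin))
  counts <- tabulate(bin - min(bin) + 1L, nbins = length(rng))
  data.frame(
    bin_lower = rng * width,
    bin_center = rng * width + width / 2,
    count = counts,
    freq = counts / length(scores)
  )
}

#' Severity composition of a score sample
#'
#' Partitions scores into `neutral` (score < 0), `mild`
#' (`0 <= score < mild_upper`), `moderate` (`mild_upper <= score <
#' severe`) and `severe` (`score >= severe`); the four fractions sum
#' to 1. The additional element `ge_moderate` reports the fraction of
#' *effect* scores at or above the `moderate` threshold, the form in
#' which "moderate or worse" enrichment is usually quoted.
#'
#' @param scores Numeric vector (non-empty).
#' @param bins A [severity_bins()].
#' @return Named list: `fractions` (length-4 named numeric), `n`,
#'   `ge_moderate`.
#' @export
severity_fractions <- function(scores, bins = severity_bins()) {
  if (length(scores) == 0L) stop("empty score vector")
  n <- length(scores)
  f <- c(
    neutral  = sum(scores < 0),
    mild     = sum(scores >= 0 & scores < bins$mild_upper),
    moderate = sum(scores >= bins$mild_upper & scores < bins$severe),
    severe   = sum(scores >= bins$severe)
  ) / n
  n_eff <- sum(scores >= 0)
  list(fractions = f, n = n,
       ge_moderate = if (n_eff > 0) sum(scores >= bins$moderate) / n_eff else NA_real_)
}

#' Mild-effect threshold as the observed/expected histogram crossing
#'
#' Finds the score where the fraction of genetically possible but
#' unobserved ("synthetic") variants starts to exceed the fraction of
#' observed variants: the smallest grid score `t >= 0` at which the
#' synthetic sample's per-bin relative frequency strictly exceeds the
#' observed sample's, and stays at or above it in every later bin where
#' either sample still has mass. Effects below the returned score are
#' regarded as mild (population-compatible); above it, purifying
#' selection visibly depletes the observed spectrum.
#'
#' @param observed_scores Scores of variants observed in the population.
#' @param synthetic_scores Scores of never-observed possible variants.
#' @param resolution Grid/bin step (default 1).
#' @return The crossing score, or `NA` (no-crossing) when the synthetic
#'   frequencies never strictly exceed the observed ones in a sustained
#'   way.
#' @export
find_mild_threshold <- function(observed_scores, synthetic_scores, resolution = 1) {
  if (length(observed_scores) == 0L || length(synthetic_scores) == 0L) {
    stop("both score samples must be non-empty")
  }
  stopifnot(resolution > 0)
  hi <- max(observed_scores, synthetic_scores)
  if (hi < 0) stop("no effect-range (score >= 0) scores in either sample")
  grid <- seq(0, hi, by = resolution)
  f_obs <- vapply(grid, function(t)
    sum(observed_scores >= t & observed_scores < t + resolution), 0) /
    length(observed_scores)
  f_syn <- vapply(grid, function(t)
    sum(synthetic_scores >= t & synthetic_scores < t + resolution), 0) /
    length(synthetic_scores)
  occupied <- f_obs > 0 | f_syn > 0
  for (i in seq_along(grid)) {
    later <- occupied & seq_along(grid) > i
    if (f_syn[i] > f_obs[i] && all(f_syn[later] >= f_obs[later])) {
      return(grid[i])
    }
  }
  NA_real_
}

#' Per-subset conservation score lists with position deduplication
#'
#' Within one variant subset, each protein position contributes its
#' conservation score at most once, however many of the subset's
#' variants it hosts; a position hosting variants of several subsets
#' contributes once to each subset's distribution. Variant positions
#' without a profile are skipped and counted.
#'
#' @param savs SAV data frame (needs `transcript_id`, `aa_pos`).
#' @param profiles Position profile data frame with `transcript_id`,
#'   `aa_pos` and the requested `metric` column.
#' @param subsets Named list defining the subsets: each element either a
#'   logical/integer index over `savs` rows or a predicate function of
#'   the `savs` data frame returning one.
#' @param metric Profile column to extract (default `"consurf"`).
#' @return Named list of numeric score vectors (one per subset), with
#'   attribute `n_missing` counting profile-less positions per subset.
#' @export
conservation_by_subset <- function(savs, profiles, subsets, metric = "consurf") {
  stopifnot(metric %in% names(profiles), is.list(subsets), !is.null(names(subsets)))
  prof_key <- paste(profiles$transcript_id, profiles$aa_pos, sep = "\r")
  n_missing <- integer(length(subsets))
  names(n_missing) <- names(subsets)
  out <- vector("list", length(subsets))
  names(out) <- names(subsets)
  for (nm in names(subsets)) {
    sel <- subsets[[nm]]
    if (is.function(sel)) sel <- sel(savs)
    sub <- savs[sel, , drop = FALSE]
    pos <- unique(paste(sub$transcript_id, sub$aa_pos, sep = "\r"))
    idx <- match(pos, prof_key)
    n_missing[nm] <- sum(is.na(idx))
    out[[nm]] <- profiles[[metric]][idx[!is.na(idx)]]
  }
  if (any(n_missing > 0)) {
    message("positions without a conservation profile, skipped: ",
            paste(names(n_missing), n_missing, sep = "=", collapse = ", "))
  }
  attr(out, "n_missing") <- n_missing
  out
}

#' Cross-tabulate variant strata against position tolerance classes
#'
#' Position tolerance classes come from per-residue predictions of the
#' achievable range of variant effects: `neutral` positions (most
#' variants weak or no effect), `rheostat` positions (full range of
#' effects) and `toggle` positions (most variants severe). For each
#' stratum the class fractions over its variants are reported together
#' with the rheostat share among the non-neutral ("effect") positions,
#' `rheostat / (rheostat + toggle)`.
#'
#' @param savs SAV data frame.
#' @param profiles Profile data frame with `funtrp_class` in
#'   `{neutral, rheostat, toggle}`.
#' @param strata Factor (or vector) over `savs` rows defining strata, or
#'   the name of a `savs` column.
#' @return Data frame: one row per stratum with `n`, fractions
#'   `neutral`, `rheostat`, `toggle`, and `rheostat_share_effect`.
#' @export
funtrp_crosstab <- function(savs, profiles, strata = "category") {
  if (is.character(strata) && length(strata) == 1L) strata <- savs[[strata]]
  stopifnot(length(strata) == nrow(savs))
  prof_key <- paste(profiles$transcript_id, profiles$aa_pos, sep = "\r")
  cls <- profiles$funtrp_class[match(paste(savs$transcript_id, savs$aa_pos, sep = "\r"),
                                     prof_key)]
  keep <- !is.na(cls)
  cls <- factor(cls[keep], levels = c("neutral", "rheostat", "toggle"))
  strata <- factor(strata[keep])
  res <- lapply(levels(strata), function(s) {
    tab <- table(cls[strata == s])
    n <- sum(tab)
    fr <- if (n > 0) as.numeric(tab) / n else rep(NA_real_, 3)
    eff <- tab[["rheostat"]] + tab[["toggle"]]
    data.frame(stratum = s, n = n,
               neutral = fr[1], rheostat = fr[2], toggle = fr[3],
               rheostat_share_effect = if (eff > 0) tab[["rheostat"]] / eff else NA_real_)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Mean effect score versus evolutionary distance of the shared reference
#'
#' For each ortholog species, collects the effect variants (score >= 0)
#' whose human reference amino acid equals that species' aligned residue
#' and reports their mean score, separately for CSVs and non-CSVs and
#' per frequency stratum. Species are ordered by divergence time, so the
#' result traces how predicted effect grows with the evolutionary age of
#' the reference residue. Empty species/stratum cells are reported as
#' `NA`, not 0.
#'
#' @param ann A `csv_annotations` object covering the variants.
#' @param scores Data frame with `transcript_id`, `aa_pos`, `ref_aa`,
#'   `alt_aa`, `score`.
#' @param strata Vector over annotation rows collapsing categories
#'   (default: `synthetic`/`singleton`/`observed` from the annotation's
#'   `category`).
#' @param profiles Optional profile data frame; with `min_consurf` set,
#'   only positions of conservation score >= `min_consurf` (i.e. weakly
#'   conserved positions) are kept — a sensitivity filter showing the
#'   trend is not driven by conservation alone.
#' @param min_consurf Optional lower bound on the position's
#'   conservation score.
#' @return Data frame: `species`, `divergence_mya`, `csv_status`,
#'   `stratum`, `n`, `mean_score`, ordered by divergence.
#' @export
distance_effect_curve <- function(ann, scores, strata = NULL,
                                  profiles = NULL, min_consurf = NULL) {
  tab <- ann$table
  if (is.null(strata)) {
    strata <- as.character(tab$category)
    strata[strata %in% c("rare", "common")] <- "observed"
  }
  stopifnot(length(strata) == nrow(tab))
  sk <- paste(scores$transcript_id, scores$aa_pos, scores$ref_aa, scores$alt_aa,
              sep = "\r")
  score <- scores$score[match(paste(tab$transcript_id, tab$aa_pos, tab$ref_aa,
                                    tab$alt_aa, sep = "\r"), sk)]
  keep <- !is.na(score) & score >= 0
  if (!is.null(min_consurf)) {
    stopifnot(!is.null(profiles))
    pk <- paste(profiles$transcript_id, profiles$aa_pos, sep = "\r")
    consurf <- profiles$consurf[match(paste(tab$transcript_id, tab$aa_pos,
                                            sep = "\r"), pk)]
    keep <- keep & !is.na(consurf) & consurf >= min_consurf
  }
  sp <- colnames(ann$residues)[order(ann$divergence_mya[colnames(ann$residues)])]
  shared <- shared_reference_partition(ann, sp)
  rows <- list()
  for (s in sp) {
    idx <- intersect(shared[[s]], which(keep))
    for (cs in c(TRUE, FALSE)) {
      for (st in unique(strata)) {
        i <- idx[tab$is_csv[idx] == cs & strata[idx] == st]
        rows[[length(rows) + 1L]] <- data.frame(
          species = s, divergence_mya = unname(ann$divergence_mya[s]),
          csv_status = if (cs) "CSV" else "non-CSV", stratum = st,
          n = length(i),
          mean_score = if (length(i)) mean(score[i]) else NA_real_
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
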