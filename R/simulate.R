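#' Default 20-species ortholog panel
#'
#' A eukaryote-spanning panel of 20 species with clade membership and
#' approximate divergence times from human (million years to the shared
#' ancestor). Clade labels are the finest applicable class: `ape`
#' species are mammals too. Divergence times are round figures in the
#' range published timetrees report; they are configuration, not
#' estimates.
#'
#' @return Data frame with columns `species`, `clade`, `divergence_mya`.
#' @export
default_species_panel <- function() {
  data.frame(
    species = c("chimpanzee", "bonobo", "gorilla", "gibbon",
                "tarsier", "tree_shrew", "rabbit", "mouse",
                "dolphin", "pig", "dog", "opossum", "platypus",
                "chicken", "anole_lizard", "xenopus", "zebrafish",
                "fruitfly", "worm", "yeast"),
    clade = c(rep("ape", 4), rep("mammal", 9), rep("other", 7)),
    divergence_mya = c(6.4, 6.4, 8.6, 19.5,
                       69, 82, 87, 87,
                       94, 94, 94, 160, 180,
                       319, 319, 352, 429,
                       736, 736, 1105),
    stringsAsFactors = FALSE
  )
}

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Configuration for the synthetic cohort generator
#'
#' Defines every tunable of the simulated study: cohort size, protein
#' lengths, the species panel and its divergence-dependent substitution
#' model, the target site-frequency-spectrum composition, the
#' stratum-and-CSV-status-specific effect-score distributions, and the
#' conservation/tolerance model.
#'
#' The per-branch substitution probability is saturating in divergence
#' time `d`: `p(d) = p_max * (1 - exp(-d / tau))`, i.e. roughly clock-like
#' for close species and bounded by `p_max` for distant ones. Effect
#' scores are drawn from normal distributions truncated to
#' `score_range`, with location depending on the variant's collapsed
#' stratum (synthetic / singleton / observed) and a constant negative
#' shift for cross-species variants (CSVs score more neutral).
#'
#' @param n_transcripts Number of transcripts in the cohort.
#' @param protein_length Integer range (min, max) of protein lengths in
#'   residues.
#' @param species_panel Data frame as in [default_species_panel()].
#' @param p_max,tau Parameters of the substitution-probability curve.
#' @param gap_rate Per-residue, per-species probability of an alignment
#'   gap (kept low by default so planted-truth checks are exact).
#' @param stratum_props Target proportions of the four frequency strata,
#'   summing to 1.
#' @param an Cohort allele number used for every site.
#' @param common_threshold Common/rare frequency cutoff.
#' @param score_location Named numeric: truncated-normal location per
#'   collapsed stratum for non-CSVs.
#' @param csv_shift Additive location shift applied to CSVs (negative:
#'   CSVs skew neutral).
#' @param score_scale Truncated-normal scale.
#' @param score_range Score support (defaults to the conventional
#'   \[-94, 88\] effect-score range).
#' @param consurf_noise,psic_slope,psic_noise Conservation model
#'   parameters (see [generate_position_profiles()]).
#' @param seed Root seed; one seed reproduces the full cohort exactly.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_transcripts = 50,
                       protein_length = c(80, 200),
                       species_panel = default_species_panel(),
                       p_max = 0.75, tau = 300,
                       gap_rate = 0.01,
                       stratum_props = c(synthetic = 0.80, singleton = 0.10,
                                         rare = 0.08, common = 0.02),
                       an = 10000L,
                       common_threshold = 0.01,
                       score_location = c(synthetic = -5, singleton = -15,
                                          observed = -20),
                       csv_shift = -30,
                       score_scale = 25,
                       score_range = c(-94, 88),
                       consurf_noise = 1.0,
                       psic_slope = -0.4, psic_noise = 0.3,
                       seed = 1L) {
  stopifnot(n_transcripts >= 1,
            length(protein_length) == 2, protein_length[1] >= 2,
            protein_length[1] <= protein_length[2],
            all(c("species", "clade", "divergence_mya") %in% names(species_panel)),
            nrow(species_panel) >= 1,
            all(species_panel$divergence_mya > 0),
            p_max >= 0, p_max <= 1, tau > 0,
            gap_rate >= 0, gap_rate < 1,
            abs(sum(stratum_props) - 1) < 1e-9, all(stratum_props >= 0),
            identical(sort(names(stratum_props)), sort(sav_strata())),
            an > 0, common_threshold > 0, common_threshold < 1,
            all(c("synthetic", "singleton", "observed") %in% names(score_location)),
            score_scale >= 0, score_range[1] < score_range[2])
  # rare needs an integer count c with 1 < c and c/an < threshold
  if (stratum_props[["rare"]] > 0 && ceiling(common_threshold * an) - 1 < 2) {
    stop("allele number ", an, " too small to represent rare (non-singleton) ",
         "variants below the common threshold")
  }
  structure(
    list(n_transcripts = as.integer(n_transcripts),
         protein_length = as.integer(protein_length),
         species_panel = species_panel,
         p_max = p_max, tau = tau, gap_rate = gap_rate,
         stratum_props = stratum_props, an = as.integer(an),
         common_threshold = common_threshold,
         score_location = score_location, csv_shift = csv_shift,
         score_scale = score_scale, score_range = score_range,
         consurf_noise = consurf_noise,
         psic_slope = psic_slope, psic_noise = psic_noise,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Substitution probability at divergence d (MYA).
substitution_prob <- function(config, d) {
  config$p_max * (1 - exp(-d / config$tau))
}

#' Generate random valid coding transcripts
#'
#' Each CDS starts with ATG, continues with uniformly drawn sense
#' codons (so no internal stop can occur) and ends with a random stop
#' codon.
#'
#' @param config A [sim_config()].
#' @param seed Seed (defaults to the config's root seed).
#' @return Named list of [transcript()] objects (`tx001`, `tx002`, ...).
#' @export
generate_transcripts <- function(config, seed = config$seed) {
  set.seed(seed)
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  stops <- codons[Biostrings::GENETIC_CODE == "*"]
  n <- config$n_transcripts
  rng <- seq.int(config$protein_length[1], config$protein_length[2])
  lens <- rng[sample.int(length(rng), n, replace = TRUE)]
  txs <- lapply(seq_len(n), function(i) {
    body <- sample(sense, lens[i] - 1L, replace = TRUE)
    cds <- paste(c("ATG", body, sample(stops, 1L)), collapse = "")
    transcript(sprintf("tx%03d", i), cds)
  })
  names(txs) <- vapply(txs, `[[`, "", "id")
  txs
}

#' Generate ortholog alignments with planted cross-species residues
#'
#' For every transcript and every panel species, each human residue is
#' independently substituted with the species' divergence-dependent
#' probability (see [sim_config()]) by a uniformly drawn different amino
#' acid; every substitution event is recorded as ground truth. Gaps are
#' then injected at `gap_rate` per residue per species and remove the
#' corresponding events from the truth (a gapped residue can support
#' nothing). There are no indels, so alignment columns equal human
#' protein positions.
#'
#' @param transcripts List of [transcript()] objects.
#' @param config A [sim_config()].
#' @param seed Seed.
#' @return List with `alignments` (named list of [ortholog_alignment()])
#'   and `events` (data frame `transcript_id`, `species`, `aa_pos`,
#'   `residue` of planted non-gap cross-species residues).
#' @export
generate_ortholog_msas <- function(transcripts, config, seed = config$seed) {
  set.seed(seed)
  panel <- config$species_panel
  clade <- stats::setNames(panel$clade, panel$species)
  div <- stats::setNames(panel$divergence_mya, panel$species)
  p_sub <- substitution_prob(config, div)
  alignments <- vector("list", length(transcripts))
  events <- vector("list", length(transcripts))
  for (t in seq_along(transcripts)) {
    tx <- transcripts[[t]]
    human <- strsplit(tx$protein, "")[[1]]
    L <- length(human)
    rows <- character(nrow(panel) + 1L)
    rows[1] <- tx$protein
    ev <- list()
    for (s in seq_len(nrow(panel))) {
      sp <- panel$species[s]
      res <- human
      hit <- which(stats::runif(L) < p_sub[[sp]])
      if (length(hit)) {
        # uniform over the 19 alternatives at each hit position
        res[hit] <- vapply(human[hit], function(a)
          sample(setdiff(AA_LETTERS, a), 1L), "")
      }
      gap <- which(stats::runif(L) < config$gap_rate)
      if (length(gap)) res[gap] <- "-"
      sub_kept <- setdiff(hit, gap)
      if (length(sub_kept)) {
        ev[[length(ev) + 1L]] <- data.frame(
          transcript_id = tx$id, species = sp, aa_pos = sub_kept,
          residue = res[sub_kept], stringsAsFactors = FALSE)
      }
      rows[s + 1L] <- paste(res, collapse = "")
    }
    names(rows) <- c("human", panel$species)
    alignments[[t]] <- ortholog_alignment(tx$id, rows, clade, div)
    events[[t]] <- if (length(ev)) do.call(rbind, ev) else NULL
  }
  names(alignments) <- names(transcripts)
  ev_all <- do.call(rbind, events[!vapply(events, is.null, TRUE)])
  if (is.null(ev_all)) {
    ev_all <- data.frame(transcript_id = character(), species = character(),
                         aa_pos = integer(), residue = character(),
                         stringsAsFactors = FALSE)
  }
  list(alignments = alignments, events = ev_all)
}

#' Ground-truth CSV status of SAVs from planted substitution events
#'
#' @param savs SAV data frame.
#' @param events Planted-event table from [generate_ortholog_msas()].
#' @return Logical vector: `TRUE` where some species' planted (non-gap)
#'   residue at the SAV's position equals the variant amino acid.
#' @export
planted_csv_status <- function(savs, events) {
  key <- paste(savs$transcript_id, savs$aa_pos, savs$alt_aa, sep = "\r")
  key %in% paste(events$transcript_id, events$aa_pos, events$residue, sep = "\r")
}

#' Generate an allele-count table realising target frequency strata
#'
#' Assigns each SAV of the cohort a frequency stratum by largest-remainder
#' apportionment of the target proportions (exact when the SAV count is
#' divisible), randomly permuted, then emits one allele record per
#' non-synthetic SAV on one of its nucleotide routes: singletons get
#' allele count 1, rare SAVs a count drawn uniformly from the open rare
#' band, common SAVs a count in \[threshold, 5 x threshold\] x AN. AN is
#' constant across the cohort.
#'
#' @param nssnvs Enumerated nsSNV table for the whole cohort
#'   (allele counts not yet attached).
#' @param config A [sim_config()].
#' @param seed Seed.
#' @return List with `table` (allele records: `transcript_id`, `aa_pos`,
#'   `codon_offset`, `alt_nt`, `AC`, `AN`) and `strata` (data frame
#'   keyed by SAV with the planted `category`).
#' @export
generate_allele_counts <- function(nssnvs, config, seed = config$seed) {
  set.seed(seed)
  key <- paste(nssnvs$transcript_id, nssnvs$aa_pos, nssnvs$ref_aa,
               nssnvs$alt_aa, sep = "\r")
  first <- !duplicated(key)
  savs <- nssnvs[first, c("transcript_id", "aa_pos", "ref_aa", "alt_aa")]
  n <- nrow(savs)

  # largest-remainder apportionment of the stratum targets
  props <- config$stratum_props[sav_strata()]
  quota <- props * n
  counts <- floor(quota)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  category <- sample(rep(sav_strata(), times = counts))
  savs$category <- factor(category, levels = sav_strata())

  an <- config$an
  lo_common <- ceiling(config$common_threshold * an)
  ac <- integer(n)
  ac[category == "singleton"] <- 1L
  n_rare <- sum(category == "rare")
  if (n_rare) ac[category == "rare"] <- sample(2:(lo_common - 1L), n_rare,
                                               replace = TRUE)
  n_common <- sum(category == "common")
  if (n_common) ac[category == "common"] <- sample(lo_common:(5L * lo_common),
                                                   n_common, replace = TRUE)

  # one record per non-synthetic SAV, on its first nucleotide route
  pick <- which(first)[ac > 0]
  table <- data.frame(
    transcript_id = nssnvs$transcript_id[pick],
    aa_pos        = nssnvs$aa_pos[pick],
    codon_offset  = nssnvs$codon_offset[pick],
    alt_nt        = nssnvs$alt_nt[pick],
    AC            = ac[ac > 0],
    AN            = rep(an, length(pick)),
    stringsAsFactors = FALSE
  )
  rownames(savs) <- rownames(table) <- NULL
  list(table = table, strata = savs)
}

# Truncated-normal draws by inversion.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), length.out = n))
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Generate effect scores with stratum- and CSV-dependent locations
#'
#' Scores are drawn from normal distributions truncated to the score
#' range, located at `score_location[stratum]` plus `csv_shift` for
#' CSVs. Defaults place never-observed (synthetic) variants above
#' observed ones (more predicted effect) and CSVs well below non-CSVs
#' (more neutral).
#'
#' @param savs SAV data frame with a planted or realised `category`.
#' @param is_csv Logical vector over `savs` rows (ground-truth CSV
#'   status).
#' @param config A [sim_config()].
#' @param seed Seed.
#' @return Data frame `transcript_id`, `aa_pos`, `ref_aa`, `alt_aa`,
#'   `score`, with attribute `location` (the per-row planted location).
#' @export
generate_effect_scores <- function(savs, is_csv, config, seed = config$seed) {
  set.seed(seed)
  stopifnot(length(is_csv) == nrow(savs))
  collapsed <- as.character(savs$category)
  collapsed[collapsed %in% c("rare", "common")] <- "observed"
  loc <- config$score_location[collapsed] + ifelse(is_csv, config$csv_shift, 0)
  score <- rtruncnorm(nrow(savs), loc, config$score_scale,
                      config$score_range[1], config$score_range[2])
  out <- data.frame(
    transcript_id = savs$transcript_id, aa_pos = savs$aa_pos,
    ref_aa = savs$ref_aa, alt_aa = savs$alt_aa, score = score,
    stringsAsFactors = FALSE
  )
  attr(out, "location") <- unname(loc)
  out
}

#' Generate per-position conservation and tolerance profiles
#'
#' Conservation is tied to the planted substitution process: a
#' position's raw score is its planted cross-species substitution count
#' plus Gaussian noise, standardised within each protein to mean 0 and
#' standard deviation 1 (the usual per-protein normalisation; lower =
#' more conserved). The companion weight `psic` decreases linearly in
#' the standardised score (higher = more conserved) with its own noise.
#' Position tolerance classes (`neutral`/`rheostat`/`toggle`) are drawn
#' from a multinomial logit in which the toggle probability increases
#' with conservation.
#'
#' @param transcripts List of transcripts.
#' @param events Planted-event table from [generate_ortholog_msas()].
#' @param config A [sim_config()].
#' @param seed Seed.
#' @return Data frame `transcript_id`, `aa_pos`, `consurf`, `psic`,
#'   `funtrp_class`, with attribute `sub_count` (planted substitution
#'   counts).
#' @export
generate_position_profiles <- function(transcripts, events, config,
                                       seed = config$seed) {
  set.seed(seed)
  out <- lapply(transcripts, function(tx) {
    L <- nchar(tx$protein)
    ev <- events[events$transcript_id == tx$id, , drop = FALSE]
    sub_count <- tabulate(ev$aa_pos, nbins = L)
    raw <- sub_count + stats::rnorm(L, 0, config$consurf_noise)
    consurf <- as.numeric(scale(raw))
    psic <- 1 + config$psic_slope * consurf + stats::rnorm(L, 0, config$psic_noise)
    z <- -consurf  # higher = more conserved
    u <- cbind(neutral = 0.6 - z, rheostat = 0, toggle = -1.2 + z)
    p <- exp(u) / rowSums(exp(u))
    cls <- vapply(seq_len(L), function(i)
      sample(colnames(p), 1L, prob = p[i, ]), "")
    data.frame(transcript_id = tx$id, aa_pos = seq_len(L),
               consurf = consurf, psic = psic, funtrp_class = cls,
               sub_count = sub_count, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  sub_count <- out$sub_count
  out$sub_count <- NULL
  attr(out, "sub_count") <- sub_count
  out
}

#' Simulate a complete synthetic cohort with ground truth
#'
#' Runs every generator in sequence under sub-seeds derived from the
#' config's root seed and returns the full input bundle (transcripts,
#' allele table, ortholog alignments, effect scores, position profiles,
#' species metadata) together with the planted ground truth (per-SAV
#' strata, cross-species substitution events, per-row score locations).
#' One root seed reproduces the entire cohort exactly.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_cohort` (a list; see Details).
#' @export
simulate_cohort <- function(config = sim_config()) {
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, 5)
  transcripts <- generate_transcripts(config, seeds[1])
  nssnvs <- do.call(rbind, lapply(transcripts, enumerate_nssnvs))
  rownames(nssnvs) <- NULL
  alleles <- generate_allele_counts(nssnvs, config, seeds[2])
  msas <- generate_ortholog_msas(transcripts, config, seeds[3])
  is_csv <- planted_csv_status(alleles$strata, msas$events)
  scores <- generate_effect_scores(alleles$strata, is_csv, config, seeds[4])
  profiles <- generate_position_profiles(transcripts, msas$events, config,
                                         seeds[5])
  structure(
    list(config = config,
         transcripts = transcripts,
         allele_table = alleles$table,
         alignments = msas$alignments,
         scores = scores,
         profiles = profiles,
         species = config$species_panel,
         truth = list(sav_strata = alleles$strata,
                      csv_events = msas$events,
                      is_csv = is_csv,
                      score_location = attr(scores, "location"))),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort> ", length(x$transcripts), " transcripts, ",
      nrow(x$species), " ortholog species, ",
      nrow(x$truth$sav_strata), " SAVs\n", sep = "")
  invisible(x)
}

#' Run the analysis pipeline on raw cohort inputs
#'
#' Enumerates nsSNVs from the transcripts, attaches the allele table,
#' aggregates to SAVs with frequency strata, and annotates each SAV's
#' cross-species status against its ortholog alignment.
#'
#' @param transcripts Named list of [transcript()] objects.
#' @param allele_table Allele-count table (may be `NULL`).
#' @param alignments Named list of [ortholog_alignment()], one per
#'   transcript.
#' @param default_an Cohort allele number for unrecorded sites.
#' @param common_threshold Common/rare cutoff passed to aggregation.
#' @return List with `nssnvs`, `savs` (a `sav_table`) and `annotations`
#'   (a combined `csv_annotations`).
#' @export
run_pipeline <- function(transcripts, allele_table, alignments,
                         default_an = 251496L, common_threshold = 0.01) {
  nssnvs <- do.call(rbind, lapply(transcripts, enumerate_nssnvs))
  rownames(nssnvs) <- NULL
  nssnvs <- attach_allele_counts(nssnvs, allele_table, default_an = default_an)
  savs <- aggregate_to_savs(nssnvs, common_threshold = common_threshold)
  anns <- lapply(split(seq_len(nrow(savs)), savs$transcript_id), function(i) {
    annotate_csvs(savs[i, , drop = FALSE], alignments[[savs$transcript_id[i[1]]]])
  })
  annotations <- combine_annotations(anns[unique(savs$transcript_id)])
  list(nssnvs = nssnvs, savs = savs, annotations = annotations)
}
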