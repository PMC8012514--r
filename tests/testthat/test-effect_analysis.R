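test_that("score binning uses half-open intervals anchored at zero", {
  b <- binned_frequency(c(0, 5, 9))
  expect_identical(nrow(b), 1L)
  expect_equal(b$bin_lower, 0)
  expect_equal(b$bin_center, 5)
  expect_equal(b$freq, 1)

  b <- binned_frequency(c(10))
  expect_equal(b$bin_lower, 10)   # exactly 10 falls in [10, 20)

  set.seed(41)
  x <- runif(4000, -20, 20)
  b <- binned_frequency(x)
  expect_identical(nrow(b), 4L)
  expect_equal(sum(b$freq), 1)
  expect_true(all(abs(b$freq - 0.25) < 0.03))

  expect_error(binned_frequency(numeric(0)), "empty")
})

test_that("severity fractions partition the sample with inclusive cut points", {
  sf <- severity_fractions(c(-10, 10, 30, 60))
  expect_equal(unname(sf$fractions),
               c(0.25, 0.25, 0.25, 0.25))
  expect_equal(sum(sf$fractions), 1)

  expect_equal(unname(severity_fractions(c(-1, -5, -90))$fractions[1]), 1)
  # boundary scores are inclusive on the right-hand class
  expect_equal(unname(severity_fractions(50)$fractions[["severe"]]), 1)
  expect_equal(unname(severity_fractions(0)$fractions[["mild"]]), 1)
})

test_that("severity fractions agree with aligned-bin histogram sums", {
  set.seed(43)
  bins <- severity_bins(mild_upper = 20, moderate = 20, severe = 50)
  for (rep in 1:5) {
    x <- runif(500, -60, 80)
    sf <- severity_fractions(x, bins)
    b <- binned_frequency(x, width = 10)
    expect_equal(sum(b$freq[b$bin_lower < 0]), sf$fractions[["neutral"]])
    expect_equal(sum(b$freq[b$bin_lower >= 0 & b$bin_lower < 20]),
                 sf$fractions[["mild"]])
    expect_equal(sum(b$freq[b$bin_lower >= 20 & b$bin_lower < 50]),
                 sf$fractions[["moderate"]])
    expect_equal(sum(b$freq[b$bin_lower >= 50]), sf$fractions[["severe"]])
  }
})

test_that("fractions are permutation- and duplication-invariant", {
  set.seed(44)
  x <- runif(300, -60, 80)
  sf <- severity_fractions(x)
  expect_equal(severity_fractions(sample(x))$fractions, sf$fractions)
  expect_equal(severity_fractions(rep(x, 2))$fractions, sf$fractions)
  expect_equal(binned_frequency(sample(x))$freq, binned_frequency(x)$freq)
})

test_that("the mild threshold is the sustained observed/synthetic crossing", {
  # observed uniform on [0,23), synthetic uniform on [0,60): the synthetic
  # per-bin frequency (1/60) is below the observed (1/23) until the observed
  # histogram runs out at 23
  obs <- rep(0:22, each = 4) + 0.5
  syn <- rep(0:59, each = 4) + 0.5
  expect_equal(find_mild_threshold(obs, syn), 23)

  # synthetic dominates everywhere above zero -> crossing at 0
  obs2 <- c(rep(-10, 99), 0.5)
  expect_equal(find_mild_threshold(obs2, syn), 0)

  # identical samples never strictly exceed -> no crossing
  expect_true(is.na(find_mild_threshold(syn, syn)))

  expect_error(find_mild_threshold(numeric(0), syn), "non-empty")
})

test_that("the crossing scan matches a brute-force oracle on random instances", {
  oracle <- function(obs, syn, res = 1) {
    hi <- max(obs, syn)
    grid <- seq(0, hi, by = res)
    fo <- sapply(grid, function(t) mean(obs >= t & obs < t + res))
    fs <- sapply(grid, function(t) mean(syn >= t & syn < t + res))
    for (i in seq_along(grid)) {
      ok <- TRUE
      for (j in seq_along(grid)) {
        if (j <= i || (fo[j] == 0 && fs[j] == 0)) next
        if (fs[j] < fo[j]) { ok <- FALSE; break }
      }
      if (fs[i] > fo[i] && ok) return(grid[i])
    }
    NA_real_
  }
  set.seed(47)
  for (rep in 1:100) {
    obs <- rnorm(80, sample(-10:20, 1), sample(5:25, 1))
    syn <- rnorm(80, sample(-10:20, 1), sample(5:25, 1))
    if (max(obs, syn) < 0) next
    expect_identical(find_mild_threshold(obs, syn), oracle(obs, syn),
                     info = paste("instance", rep))
  }
})

test_that("conservation scores enter once per position per subset", {
  profiles <- data.frame(transcript_id = "T1", aa_pos = 1:5,
                         consurf = c(-1.2, 0.3, 0.8, -0.5, 1.1),
                         psic = c(2, 1, 0.5, 1.5, 0.2),
                         funtrp_class = "neutral")
  savs <- rbind(
    sav_row(aa_pos = 1L, alt_aa = "V", category = "rare"),
    sav_row(aa_pos = 1L, alt_aa = "W", category = "rare"),   # same position
    sav_row(aa_pos = 2L, alt_aa = "V", category = "rare"),
    sav_row(aa_pos = 2L, alt_aa = "W", category = "common"), # cross-subset
    sav_row(aa_pos = 3L, alt_aa = "V", category = "common")
  )
  subsets <- list(rare = function(s) s$category == "rare",
                  common = function(s) s$category == "common")
  got <- conservation_by_subset(savs, profiles, subsets)
  # two rare SAVs at position 1 contribute its score once
  expect_equal(sort(got$rare), sort(c(-1.2, 0.3)))
  # position 2 hosts a rare and a common SAV: once in each list
  expect_equal(sort(got$common), sort(c(0.3, 0.8)))
  # disjoint positions: lengths equal position counts
  expect_identical(lengths(got), c(rare = 2L, common = 2L))
  # missing profiles are skipped and counted
  savs2 <- rbind(savs, sav_row(aa_pos = 99L, category = "rare"))
  expect_message(got2 <- conservation_by_subset(savs2, profiles, subsets),
                 "skipped")
  expect_identical(attr(got2, "n_missing")[["rare"]], 1L)
  expect_equal(sort(got2$rare), sort(got$rare))
})

test_that("position-class crosstabs report fractions and the rheostat share", {
  profiles <- data.frame(
    transcript_id = "T1", aa_pos = 1:100, consurf = 0, psic = 0,
    funtrp_class = rep(c("neutral", "rheostat", "toggle"), c(50, 30, 20)))
  savs <- do.call(rbind, lapply(1:100, function(p)
    sav_row(aa_pos = p, category = "rare")))
  ct <- funtrp_crosstab(savs, profiles)
  expect_equal(ct$neutral + ct$rheostat + ct$toggle, 1)
  expect_equal(ct$neutral, 0.5)
  expect_equal(ct$rheostat_share_effect, 30 / 50)

  all_neutral <- funtrp_crosstab(savs, transform(profiles,
                                                 funtrp_class = "neutral"))
  expect_equal(c(all_neutral$neutral, all_neutral$rheostat, all_neutral$toggle),
               c(1, 0, 0))
  expect_true(is.na(all_neutral$rheostat_share_effect))
})

test_that("planted tolerance-class compositions are recovered exactly", {
  cfg <- sim_config(n_transcripts = 4, seed = 17)
  co <- simulate_cohort(cfg)
  savs <- co$truth$sav_strata
  ct <- funtrp_crosstab(savs, co$profiles,
                        strata = rep("all", nrow(savs)))
  # oracle: per-variant class lookup tallied by hand
  cls <- co$profiles$funtrp_class[match(
    paste(savs$transcript_id, savs$aa_pos),
    paste(co$profiles$transcript_id, co$profiles$aa_pos))]
  expect_equal(ct$neutral, mean(cls == "neutral"))
  expect_equal(ct$toggle, mean(cls == "toggle"))
})

test_that("distance-effect curves are flat under uniform sharing and scores", {
  panel <- default_species_panel()
  rows <- matrix("A", nrow(panel), 3)
  rows[, 2] <- "K"; rows[, 3] <- "L"
  aln <- panel_alignment("AKL", rows)
  savs <- rbind(sav_row(aa_pos = 1L, ref_aa = "A", alt_aa = "V",
                        category = "synthetic"),
                sav_row(aa_pos = 2L, ref_aa = "K", alt_aa = "N",
                        category = "synthetic"))
  ann <- annotate_csvs(savs, aln)
  scores <- data.frame(transcript_id = "T1", aa_pos = 1:2,
                       ref_aa = c("A", "K"), alt_aa = c("V", "N"), score = 7)
  curve <- distance_effect_curve(ann, scores)
  filled <- curve[curve$n > 0, ]
  expect_true(all(filled$mean_score == 7))
  expect_true(all(filled$csv_status == "non-CSV"))
  # species come out ordered by divergence, empty cells are NA not zero
  expect_true(!is.unsorted(curve$divergence_mya))
  expect_true(all(is.na(curve$mean_score[curve$n == 0])))
})

test_that("effect grows with reference age on suitably generated cohorts", {
  cfg <- sim_config(n_transcripts = 15, seed = 23)
  co <- simulate_cohort(cfg)
  res <- run_pipeline(co$transcripts, co$allele_table, co$alignments,
                      default_an = cfg$an)
  savs <- res$savs
  ann <- res$annotations
  # plant scores increasing in position conservation (old residues conserved):
  # effect score = planted substitution-count deficit + noise
  pk <- paste(co$profiles$transcript_id, co$profiles$aa_pos)
  consurf <- co$profiles$consurf[match(paste(savs$transcript_id, savs$aa_pos), pk)]
  set.seed(1)
  scores <- data.frame(transcript_id = savs$transcript_id, aa_pos = savs$aa_pos,
                       ref_aa = savs$ref_aa, alt_aa = savs$alt_aa,
                       score = 20 - 15 * consurf + rnorm(nrow(savs), 0, 5))
  curve <- distance_effect_curve(ann, scores)
  noncsv <- curve[curve$csv_status == "non-CSV" & curve$stratum == "synthetic" &
                    curve$n > 0, ]
  rho <- cor(noncsv$divergence_mya, noncsv$mean_score, method = "spearman")
  expect_gt(rho, 0)
  # the low-conservation sensitivity filter keeps the CSV/non-CSV separation
  filt <- distance_effect_curve(ann, scores, profiles = co$profiles,
                                min_consurf = 0.5)
  agg <- tapply(filt$mean_score[filt$n > 0], filt$csv_status[filt$n > 0], mean)
  expect_true(all(c("CSV", "non-CSV") %in% names(agg)))
})
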