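---
title: "Methods: SAV enumeration, cross-species variants and stratified effect analysis"
author: "crossvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SAV enumeration, cross-species variants and stratified effect analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossvar)
```

# The analysis in one paragraph

Human protein-coding variation is dominated by non-synonymous single
nucleotide variants (nsSNVs), whose protein-level consequence is a single
amino acid variant (SAV). `crossvar` implements a desk-scale version of a
common population-proteomics workflow: (1) enumerate *every genetically
possible* nsSNV of a coding sequence, (2) aggregate nucleotide routes into
SAVs and stratify them by population frequency, (3) call *cross-species
variants* (CSVs) — SAVs whose variant residue is the reference residue of
some ortholog — from a human-anchored multiple sequence alignment over a
20-species panel, (4) compare variant effect-score and conservation
distributions across the resulting strata, and (5) test distribution
differences with a resampled two-sample Kolmogorov–Smirnov protocol. A
synthetic cohort generator with full planted ground truth stands in for
the external resources (exome allele-frequency databases, ortholog
alignments, effect predictors, conservation pipelines) that the real
workflow consumes.

# Enumeration and aggregation

## All possible nsSNVs

For each codon of a transcript's protein (a valid ORF: length a multiple
of three, no internal stop, optional terminal stop), all nine
single-nucleotide substitutions are tried; those that change the amino
acid *and* do not create a stop codon are kept. Stop-gains are excluded
because a nonsense variant is not a single amino acid variant, and
stop-loss changes at the terminal codon are excluded for the same reason.
Output order is deterministic (position, codon offset, alternate base),
and codons containing non-ACGT symbols are a hard error rather than a
silent skip — synthetic fixtures stay honest that way.

## SAV frequencies

Observed allele counts attach at nucleotide-site resolution
`(transcript, aa_pos, codon_offset, alt_nt)`; genome-coordinate liftover
is deliberately out of scope. Aggregation then collapses the \(k \le 9\)
nucleotide routes to the same amino-acid change:

\[
\mathrm{freq}(\mathrm{SAV}) \;=\; \frac{\sum_{i=1}^{k} n_i}{N},
\]

with \(n_i\) the per-route allele counts and \(N\) the number of
sequenced alleles at the codon. When routes report different allele
numbers (uneven coverage), \(N\) is the *maximum* across contributing
sites — the conservative choice, since it can only lower the frequency;
`an_rule = "mean"` is available for sensitivity analyses. Strata are
assigned **after** aggregation:

* `synthetic` — aggregated count 0 (possible, never observed);
* `singleton` — aggregated count exactly 1;
* observed (count > 1), split into `common` (freq ≥ 0.01, inclusive at
  the boundary) and `rare` (below).

Assigning after aggregation matters: two single-allele nucleotide routes
to the same substitution produce an *observed* SAV, not a singleton.

# Cross-species variants

A SAV `L3G` is a CSV when at least one non-human ortholog carries `G` at
the alignment column of human position 3. Gap handling is strict: a
gapped ortholog contributes no evidence at that column — it can neither
support a CSV call nor count toward shared-reference tallies, in either
numerator or denominator. Protein positions map to alignment columns by
skipping human gap columns; the package reports 1-based columns,
following R indexing conventions.

Reference prevalence — "how often do orthologs still carry the human
reference at these variant positions?" — is **pooled**, not averaged per
variant: the ratio of summed shared-reference counts to summed aligned
(non-gap) counts across all variants. The two statistics genuinely
differ (one variant sharing 10/15 and another 4/20 pools to 14/35 = 40%
but averages to ≈43.3%), and pooling is what the package asserts in its
tests. The clade filters use apes = {gibbon, gorilla, bonobo,
chimpanzee}, mammals = apes plus the nine non-primate mammals of the
panel, and all = the full panel; the rosters are configuration because
reasonable analysts disagree on, e.g., whether a lesser ape belongs with
the great apes.

# Effect-score analysis

Effect scores live in roughly \([-94, 88]\): negative = neutral,
non-negative = effect (a score of exactly 0 is an effect), magnitude
tracks effect size. Severity uses mild < 23 ≤ moderate < 50 ≤ severe
(right-inclusive thresholds); the extra ≥ 25 cut is kept for "moderate
or worse" summaries. Histograms use half-open bins \([10k, 10(k+1))\)
anchored at zero, so a score of exactly 10 belongs to the second effect
bin.

The *mild-effect threshold* is found as a histogram crossing: the
smallest grid score at which the never-observed ("synthetic") sample's
per-bin relative frequency strictly exceeds the observed sample's and
never drops below it again in any later occupied bin. The sustained-
exceedance tie-break is this package's rule; a single-bin crossing rule
would be noise-prone at desk-scale sample sizes. When no sustained
crossing exists (e.g. identical samples) the result is `NA`, not a
number.

Conservation comparisons follow a once-per-position-per-subset rule:
however many of a subset's SAVs share a protein position, that
position's conservation score enters the subset's distribution once —
but a position hosting SAVs of two different subsets contributes once to
*each*. Positions lacking a profile are skipped and counted in a
coverage attribute rather than imputed.

Distance–effect curves take, per ortholog species, the effect variants
whose human reference equals that species' aligned residue
("shared-reference" variants) and report their mean score by CSV status
and stratum, with species ordered by divergence time. Empty cells are
reported as `NA`, never as zero. An optional filter to weakly conserved
positions (conservation score ≥ 0.5) exists to show the trend is not
purely a conservation artefact.

# Resampled Kolmogorov–Smirnov protocol

Score strata differ in size by orders of magnitude, and the two-sample
KS test's p-value is dominated by sample size. The protocol therefore
draws 1,000 observations per side, tests, and repeats 1,000 times,
reporting the **median** p-value. Draws are without replacement when the
source has at least 1,000 elements (preserving the empirical
distribution exactly) and with replacement otherwise. P-values use the
asymptotic two-sample formula via `stats::ks.test(exact = FALSE)` —
exact small-sample computation is unnecessary at this subsample size. A
single root seed derives per-iteration seeds, so a result is exactly
reproducible and symmetric in its two arguments' bookkeeping.

# The synthetic cohort and what it does (not) show

`sim_config()` / `simulate_cohort()` generate every input the pipeline
consumes, with planted ground truth:

* **Transcripts** — ATG + uniform sense codons + terminal stop;
  default 50 transcripts of 80–200 residues. These sizes keep the full
  enumeration at roughly 40–60 thousand SAVs, enough for stable stratum
  statistics while the whole pipeline runs in seconds.
* **Ortholog alignments** — per species, each residue is substituted
  independently with probability
  \(p(d) = p_{\max}(1 - e^{-d/\tau})\) of its divergence time \(d\)
  (defaults \(p_{\max} = 0.75\), \(\tau = 300\) MYA: ~1.6% for
  chimpanzee, ~73% for yeast, a plausible protein-identity gradient).
  Substituted residues are uniform over the 19 alternatives; every event
  is recorded, and those later hidden by gap injection (default rate 1%,
  kept low so planted-truth checks are exact) are removed from the
  truth. There are no indels, so columns equal positions — real
  alignments are messier, and the exact-recovery results here do not
  claim alignment-error robustness.
* **Allele counts** — each SAV gets a stratum by largest-remainder
  apportionment of the target composition (default 80/10/8/2%
  synthetic/singleton/rare/common — a rough site-frequency-spectrum
  shape, deliberately coarser than any real exome cohort), then a count:
  1 for singletons, uniform in the open rare band, uniform in
  \([1, 5] \times\) the common threshold for common SAVs, at a constant
  allele number (default 10,000).
* **Effect scores** — truncated normals on \([-94, 88]\), located by
  collapsed stratum (defaults −5 synthetic, −15 singleton, −20
  observed) with a −30 shift for CSVs and scale 25. Only the *ordering*
  (synthetic more effect-shifted than observed; CSVs more neutral than
  non-CSVs) is treated as meaningful; the locations themselves are
  configuration.
* **Conservation profiles** — a position's raw conservation is its
  planted substitution count plus Gaussian noise, standardised per
  protein to mean 0 / sd 1 (lower = more conserved); the companion
  weight decreases in that score; tolerance classes
  (neutral/rheostat/toggle) come from a multinomial logit whose toggle
  probability rises with conservation.

Passing the end-to-end tests therefore shows that the *pipeline
machinery* is correct — exact CSV recovery, exact stratum bookkeeping,
correctly ordered and significant score separations, clade-nested
prevalence — under a generative model that matches the pipeline's
assumptions. It does not validate any biological claim about real
cohorts, real alignments or real effect predictors.

# Numerical and degenerate-input choices

* Fractions are computed as exact ratios; per-stratum fraction sets sum
  to 1 to within 1e−9 by construction.
* `reference_prevalence` with an empty denominator returns `NA` with a
  warning — an undefined prevalence is not 0.
* `find_mild_threshold` on identical samples returns `NA`
  (no-crossing); empty inputs are errors, as are empty score vectors in
  binning and severity functions.
* Allele records that match no nsSNV (synonymous or stop-gain changes)
  are ignored with a warning; records whose alternate base equals the
  transcript's reference base are an error naming the site.
* The simulator refuses allele numbers too small to represent a
  non-singleton rare count below the common threshold.

# Known limitations

* One transcript per gene, no splice isoforms, no indels or
  multi-nucleotide variants, no genome-coordinate handling.
* No population substructure in frequencies; one allele number per
  cohort in the simulator.
* CSV calling trusts the input alignment; ortholog inference and
  alignment quality are upstream concerns.
* The simulator's site-frequency spectrum is a four-stratum caricature,
  not a population-genetics model.

# A worked end-to-end run

```{r pipeline}
cfg <- sim_config(n_transcripts = 10, seed = 42)
cohort <- simulate_cohort(cfg)
res <- run_pipeline(cohort$transcripts, cohort$allele_table,
                    cohort$alignments, default_an = cfg$an)
stratum_census(res$savs)
round(c(ape    = as.numeric(reference_prevalence(res$annotations, "ape")),
        mammal = as.numeric(reference_prevalence(res$annotations, "mammal")),
        all    = as.numeric(reference_prevalence(res$annotations, "all"))), 3)
```

```{r ks}
key <- function(d) paste(d$transcript_id, d$aa_pos, d$ref_aa, d$alt_aa)
sc <- cohort$scores$score[match(key(res$savs), key(cohort$scores))]
is_csv <- res$annotations$table$is_csv
resampled_ks(sc[is_csv], sc[!is_csv], iterations = 200,
             sample_size = 1000, seed = 42)
```
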