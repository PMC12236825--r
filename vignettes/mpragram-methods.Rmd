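---
title: "Models and methods in mpragram"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mpragram}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpragram)
```

# The measurement model

A lentiviral MPRA integrates a library of 100-bp candidate regulatory
elements into the genome of a cell population. Two kinds of readout are
quantified per element:

* **Transcriptional activity.** Each element is coupled to many random
  15-bp barcodes. The activity of an element is the ratio of its RNA
  barcode counts to its DNA barcode counts; averaging over barcodes
  corrects for integration-site effects.
* **Epigenetic activity.** Tn5-tagmented fragments of the integrated
  elements are enriched by targeted amplification and counted by unique
  molecular identifiers (UMIs): the *enriched* count. The *inserted*
  count — UMIs amplified from input genomic DNA with the same primers —
  estimates each element's integration frequency. Epigenetic activity is
  the enriched/inserted ratio, computed once per accessibility (ATAC) and
  once per histone-mark (H3K27ac CUT&Tag) channel.

Both scores are reported as log~2~ ratios after two normalization steps:

1. **CPM.** Counts in every (replicate, channel) are scaled to sum to
   10^6^, removing sequencing-depth differences.
2. **Control-anchored TMM.** A scaling factor $f$ is computed from the
   random-genomic negative controls only, as the unweighted doubly
   trimmed mean of M-values: with $M_i = \log_2(e_i/i_i)$ and
   $A_i = \tfrac12\log_2(e_i \cdot i_i)$ over control CPM pairs, the
   extreme 30 % of M-ranks and 5 % of A-ranks on each side are discarded
   and $f = 2^{\bar M}$ over the rest. All enriched (or RNA) values are
   divided by $f$, so the expected control log~2~ activity is exactly 0
   in every sample. We deliberately use the plain trimmed mean without
   the inverse-variance weights of the full TMM estimator: with only
   ~50 control elements the weights add variance themselves, and the
   anchoring property (recomputing the factor after division yields 1,
   to machine precision) holds exactly for the unweighted form.

Replicates are pooled by *summing* raw counts per channel first and then
recomputing the normalized ratio. For UMI-level scores this matters: the
per-replicate ratios are noisy at tens-to-hundreds of UMIs per element,
and the sum-then-divide estimator weights replicates by their evidence.
Regression analyses, by contrast, always consume the per-replicate
scores, and the two design templates of the grammar library count as
additional replicates (2 × 3 observations per arrangement when
complete).

Zero handling: an element with zero *inserted* (or DNA) count in a
replicate has no defined activity and is reported missing there; pooled
scores additionally require a pooled inserted count of at least
`min_inserted = 10` (configurable). An element with positive inserted
but zero enriched count receives +0.5 pseudocounts on both channels (on
the CPM scale) so genuinely silent elements stay in the distributions
rather than vanishing.

For the MPRA score the per-element aggregate is the **mean of
per-barcode log~2~ ratios** (the log geometric mean), which is
variance-stabilizing; a ratio-of-sums mode is available
(`aggregate = "ratio_of_sums"`). The both-channels rule — a barcode must
be seen in the DNA *and* RNA pool of a replicate — guarantees both
counts are ≥ 1, so no pseudocount is needed on this path.

# Library designs

**Class 1 (homotypic).** "Evenly spaced" placement puts $n$ copies of a
motif at centers $\mathrm{round}(100\,(i - \tfrac12)/n)$,
$i = 1 \ldots n$; template bases outside the motif footprints are kept.
The identity of the element (motif, copy number, template) is recorded in an
`arrangement` string of `name:copy:start` triples.

**Class 2 (pairwise).** For each unordered pair the four slot patterns
`AABB`, `ABAB`, `ABBA`, `BBAA` are written into the Class-1 $n = 4$
slots, a 2:2 copy ratio per motif. The published library size (288)
pins down the *count* of patterns per pair (4, over both templates) but
not their identity; this particular set covers adjacent, alternating and
nested configurations while keeping the 2:2 ratio, and is configurable
via `grammar_design_spec(patterns = ...)`.

**Class 3 (orderings).** Every 4-motif subset appears in all 4! slot
orders on both templates; slot 1 is distal and slot 4 proximal to the
minimal promoter.

**Substitution library.** Each of the 100 positions is mutated to the
three alternative bases: 300 variants plus the wild type.

**Window library.** Windows of 6 bp, shifted by 1 bp (95 windows),
randomized twice independently (190 variants). "Random mutation" is
implemented as redrawing every window position uniformly from the three
non-wild-type bases: this guarantees all six positions differ from the
wild type, which makes the window-containment invariant testable, and
maximizes disruption, which is the purpose of the library. To prevent
randomization from *creating* binding sites, the mutated site plus 6 bp
of context on each side (18 bp total, truncated at the ends) is scanned
against a motif set on both strands and hits trigger a redraw, up to
1,000 attempts per window (the recursion needs a bound; at motif
densities seen in practice one draw almost always suffices). Scanning
uses exact IUPAC-consensus matching — a deliberate stand-in for a PWM
scanner, since no score threshold is published for the screen — and
`build_window_library()` accepts a `hit_caller` hook for plugging in an
external scanner.

The shipped motif set (`liver_tf_motifs()`) holds package-curated A/C/G/T
consensus cores for the nine liver TFs. Only motif identity and width
enter any quantity under test; the curated bases matter solely for
sequence-level outputs such as FASTA export and the window screen.

# The inference battery

**Copy-number trend.** Spearman's ρ between motif copy number (1/2/4)
and per-replicate activity, per motif and assay; BH within assay,
FDR 0.05. Constant activities make ρ undefined and are reported missing
rather than zero.

**Synergy regression.** Per motif pair, OLS of per-replicate activity on
the two copy counts plus the interaction term $k$, which is 0 for
Class 1 elements and the per-motif copy count (2 under the 2:2 patterns)
for Class 2. The published definition of $k$ ("1 or 2" for Class 2) is
ambiguous between a copy count and an arrangement subclass; we default
to the copy count, under which a planted synergy δ on Class-2 elements
is estimated as $\beta_k = \delta/2$, and provide
`k_mode = "indicator"` for the 0/1 reading. A pair with no Class 2 data
leaves $k$ constant and is not identifiable; the function errors if no
pair is estimable and skips (with a warning) individual incomplete
pairs. Significance: two-sided t-test on $\beta_k$, BH across pairs
within assay, FDR 0.01; the sign distinguishes synergy from antagonism.

**Order ANOVA.** One-way ANOVA with the 24 orderings as the factor, per
four-motif set and assay; 70 sets when 8 motifs survive filtering. An
all-constant set returns $F = 0$, $p = 1$ by convention rather than
0/0. The activity range (max − min of per-ordering means) accompanies
each test.

**Positional enrichment.** All Class 3 elements pooled across templates
are ranked by pooled MPRA activity (enrichment is defined for
transcriptional activity); ties at the selection boundary are broken by
element id, deterministically. For motif $m$ at slot $q$ in a tail of
size $n$: $x$ = selected elements with $m$ at $q$, $K$ = all such
elements, $N$ = all ranked elements, upper-tail hypergeometric
$p = P(X \ge x)$ and odds ratio
$\frac{x/(n-x)}{(K-x)/((N-K)-(n-x))}$ (0 when $x = 0$); BH across
motif × position within each tail, with star annotations at
0.05/0.01/10^-3^/10^-4^.

**Motif exclusion.** A motif whose elements have median pooled inserted
count below threshold (e.g. never amplified from genomic DNA) is dropped
wholesale — all elements containing it leave both the design and the
activity set — mirroring how a systematically unclonable motif must be
handled to avoid ratio artifacts.

**Variant-effect regression.** Per CRE and assay, one joint OLS over all
(element × replicate) observations:
$\log_2(\mathrm{enriched} + 0.5) \sim \log_2(\mathrm{inserted} + 0.5) + N$,
with $N$ a 0/1 indicator per variant and the wild type as baseline. The
"offset" term of this model family is read as a free intercept; the
alternative reading — an exposure term fixing the coefficient of
log~2~(inserted) at 1 — is one flag away (`offset_mode = "exposure"`),
and the free-slope fit recovers a slope of 1 on proportional channels
anyway, which is the observable difference between the readings. The
0.5 pseudocount keeps zero-enriched variants in the design matrix.
Significance is the raw two-sided $p < 0.01$ per indicator, with no
multiple-testing correction — matching how such per-variant effect maps
are conventionally annotated. Wild-type count anomalies (the WT sequence
amplifying an order of magnitude above the variants) can be capped at a
variant quantile with `winsorize_wt()`; this is off by default because
the anomaly is handled at the reference level in the site caller.

# Functional-site calling

The window-perturbation analysis runs in three stages:

1. **Positional effect.** Effect at position $i$ = median pooled
   activity of all window variants covering $i$. With two randomization
   replicates an interior position is covered by up to 12 sequences; the
   six-sequences-per-position reading (one replicate set) is available
   as `coverage = "per_replicate"`. We default to all covering
   sequences because the median over 12 is strictly more stable and the
   two randomizations are exchangeable. Uncovered positions are linearly
   interpolated (with a message) before smoothing.
2. **MAD score.** $\mathrm{mad} = \mathrm{median}_i\,|e_i - r|$ and
   $s_i = (e_i - r)/\mathrm{mad}$, with no 1.4826 normality constant —
   the score is defined directly as deviation over MAD. The reference
   $r$ is the WT activity for the MPRA; for the epigenetic assays, where
   the WT count anomaly corrupts the WT score, $r$ is the median of the
   300 substitution-variant activities (`reference = "snv_median"`),
   which is invariant to any WT inflation by construction. A profile
   with $\mathrm{mad} = 0$ is degenerate and errors.
3. **1-D Canny.** Gaussian smoothing (σ = 1.5 positions, kernel
   truncated at 4σ, reflect padding — σ of about a quarter of the 6-bp
   window keeps single-window features resolvable), central-difference
   derivative, non-maximum suppression on |derivative| (ties survive:
   ≥ both neighbours), hysteresis with both thresholds at the **median
   of absolute derivative values** (a signed median would be ≈ 0 and
   admit half of all positions), recursive promotion of weak edges
   adjacent (distance 1) to strong ones, and peak candidates at local
   extrema of the smoothed score with |smoothed| > 0.75. Each peak is
   extended to the nearest strong edge on each side to form a site;
   extrema at the vector ends are eligible peaks; a profile with no
   strong edge yields no sites (this is how a constant profile exits);
   overlapping sites merge, keeping the direction of the dominant peak.

Because the MAD score divides by the *median* absolute deviation, half
of all positions exceed |score| = 1 by construction. On profiles whose
deviations are spatially correlated (the positional effect is already a
running median over 6-bp windows), this can promote noise plateaus past
the 0.75 peak threshold when the profile contains little true signal.
The detector's operating characteristics are therefore specified at the
score level: with score-scale noise of sd 0.2 and a planted
10-position depression of depth 2, the caller finds an overlapping site
in ≥ 95 % of runs and stays silent on ≥ 90 % of matched noise-only
profiles (both measured in the test suite at 100 runs). Profiles whose
null deviations approach the MAD scale itself will produce spurious
peaks — a property of the published score definition, not of this
implementation — and should be interpreted alongside the per-position
effect sizes that `perturbation_profile()` reports.

# The synthetic-data generator

`plant_effects()` composes latent log~2~ activities additively: motif
effects × copies, synergy deltas for co-occurring pairs, variant and
window effects, plus element-level Gaussian noise; elements of the
control categories are pinned to exactly 0. `simulate_counts()` then
draws, per replicate:

* inserted UMIs ~ Negative Binomial (mean 300, dispersion 0.15) —
  lentiviral integration counts are overdispersed across elements;
* enriched UMIs ~ Poisson(inserted × 0.25 × 2^latent + replicate
  offset^) — conditional on integration, tagmentation and amplification
  are treated as thinning, giving the UMI-level error propagation that
  makes epigenetic replicate correlations visibly weaker than MPRA
  ones;
* per element, a fixed barcode set of ~Poisson(80) barcodes (≥ 1), with
  per-barcode DNA ~ NB(20, 0.15) and RNA ~ Poisson(DNA × 2^latent^).

The depth defaults (80 barcodes/element, 300 inserted, ~75 enriched
UMIs/element) follow the order of magnitude a well-loaded experiment of
this type reports. The generator does **not** model sequencing errors,
PCR jackpots, or GC bias; a motif dropout like the NR2F2 failure is
injected directly as zero inserted counts rather than mechanistically.
Consequently, passing recovery tests demonstrate the statistical
identifiability of the planted structure under realistic counting
noise — they do not certify robustness to artifacts the generator omits.

Two modelling notes that affect calibration testing. First, the
element-level latent noise is a *true* effect shared across an
element's replicates; a null-calibration simulation must set it to 0,
otherwise the fixed-effect variant regression sees pseudo-replication
and its false-flag rate roughly doubles — visible, and intended, when
exploring the model's limits. Second, the per-replicate depth offset
(sd 0.05 log~2~ units) is absorbed by the per-replicate TMM anchoring,
which is precisely the anchoring's job.

# Numerical choices and problem sizes

* TMM trimming uses rank-based cuts (`floor(n·trim) + 1` …
  `n + 1 − floor(n·trim)`) with first-occurrence tie-breaking, so equal
  M-values trim deterministically; idempotence (factor 1 after
  division) holds to machine precision.
* BH families: within assay, separately per analysis (trend, synergy,
  ANOVA, each enrichment tail).
* Hypergeometric tails come from `phyper`; the suite cross-checks them
  against exhaustive enumeration for N ≤ 25, NMS against brute-force
  local-maximum search for length ≤ 20, and BH against the hand-written
  step-up formula.
* Directional UMI collapse merges one-mismatch UMIs when the larger
  count ≥ 2 × smaller − 1, greedily from the most abundant UMI.
* Statistical checks in the suite run at: 500 null-synergy datasets,
  40 null substitution libraries (12,000 variants), 100 runs each for
  trend recovery, variant recovery and site-caller operating
  characteristics — sizes chosen to bound the Monte-Carlo error of each
  rate well below its acceptance margin while keeping the suite quick
  on a laptop core.

# Known limitations

* The consensus-matching motif screen is binary; weak PWM matches pass.
* The MAD-score caveat above: profiles with near-null signal can yield
  spurious peaks by construction of the score.
* Synergy and trend tests treat per-replicate scores as independent
  observations; element-level random effects are not modelled (the
  published model family makes the same choice).
* The generator's Poisson-thinning enrichment model has no
  extra-Poisson noise within replicate × element; real CUT&Tag
  replicates are somewhat noisier than the simulation at equal depth.
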