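---
title: "Branch point prediction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Branch point prediction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(lariatr)
library(dplyr)
```

## The problem

During pre-mRNA splicing the branch point (BP) adenosine attacks the 5'
splice site and forms the lariat intermediate. In mammals the BP motif is
highly degenerate — essentially a TNA core (branch A with a T two bases
upstream) inside a weak 9-mer signal — so it cannot be located reliably by
consensus matching, and only a few dozen mammalian BPs have been mapped
experimentally. `lariatr` implements a prediction strategy that combines
three observations:

1. the BP normally lies inside the **AG exclusion zone (AGEZ)**, the
   3'-terminal intron region devoid of competing AG dinucleotides;
2. the degenerate motif is better described by a **position-dependent
   first-order Markov model (MM1)** than by an independent-position PWM,
   because adjacent signal positions carry weak dependencies;
3. BP recognition leans on the downstream **polypyrimidine tract (PPT)**,
   so PPT features rescue candidates whose motif score alone is
   unconvincing.

A linear SVM combines four features per candidate 9-mer — MM1 log-odds,
pyrimidine content between the branch A and the 3SS, distance to the
closest downstream PPT, and that tract's score — and the top-scoring
candidate inside the first AGEZ is the predicted BP of the intron.

## Coordinate frame

Everything is anchored at the 3' splice site: the last intron nucleotide is
position −1, the acceptor AG occupies −2,−1, and "a BP at −23" means the
branch adenosine is the 23rd nucleotide from the intron end. This makes
positions directly comparable across introns regardless of length.

## AGEZ delimitation

Scanning 5'-ward from the acceptor, AG dinucleotides whose A lies within
the last `grace = 12` nt are ignored: such AGs compete with the acceptor
itself rather than bounding the BP search space. The first AG beyond the
grace region is the *defining AG*; the zone runs from just 3' of its A up
to position −3. With no defining AG within `max_extent = 500` nt the zone
is truncated there. Two conventions here were genuinely open and are worth
stating:

* **Zone boundary.** The zone starts at `defining_ag + 1` (the G of the
  defining AG), so a defining AG with its A at −30 yields a zone of length
  27. The alternative (starting at `defining_ag + 2`) differs by one
  nucleotide; the returned `defining_ag` and `agez_start` columns let users
  apply either convention.
* **Upstream zones** (`rank ≥ 1`, used to ask how predictive the *second*
  AGEZ is): no published rule exists, so the rank-0 rule is applied
  recursively with the previous defining AG's A as the anchor — AGs within
  `grace` of the anchor are ignored and the next zone ends at `anchor − 1`.

Candidate BPs are canonical 9-mers (T at position 4, A at position 6) whose
adenosine lies in the search region at least `min_dist = 15` nt from the
intron end; windows containing N are skipped rather than scored.

## Motif models

`fit_frequency_model()` estimates Laplace-smoothed per-position frequencies
(pseudocount 1 by default; configurable — the choice only matters for rare
nucleotides at nearly-fixed positions). Information content uses the
standard per-position form `IC_i = 2 + Σ p log2 p`, so the two fixed
positions contribute 2 bits each; mutual information uses unsmoothed
empirical joint frequencies and reports the fixed positions as `NA`.

The MM1 chain is `1 → 2 → 3 → 5 → 7 → 8 → 9`: positions 4 and 6 are fixed,
and the dependency "across" them is realized by conditioning position 5 on
position 3 and position 7 on position 5. This is one of two defensible
readings of a second-order skip; the chain is stored in the model object,
and because both MM1 and PWM log-odds are computed over the same seven free
positions the two scores are directly comparable (and coincide exactly when
the transitions factorize). Log base 2 throughout; the base only rescales
the feature, which the SVM absorbs.

`u2_duplex_energy()` is an optional check of motif quality against U2 snRNA
binding stability. It shells out to ViennaRNA's `RNAcofold`, folding each
9-mer against the U2 branch-recognition strand GUGUUAGUA with the
constraint `(((((x(((` & `(((x(((((` — every base forced to pair except the
branch adenosine, which bulges. The function fails loudly when the backend
is missing; there is no approximate fallback.

## Polypyrimidine tracts

`find_ppts()` reports maximal tracts under five rules: pyrimidine ends; no
three contiguous purines; a purine run of length L needs pyrimidine flanks
of length ≥ L on both sides totalling ≥ 4L (keeping local pyrimidine
content above 2/3); `T(GT)n` stretches are exempt; and a tract must be ≥ 9
nt long or contain ≥ 5 T's. Because extending a tract leftwards within a
pyrimidine run can only lengthen flanks, maximal tracts always begin at
pyrimidine-run starts, which is what the scanner exploits. Overlapping
maximal tracts are resolved greedily — longest first, ties to the 3'-most —
and each selected tract walls off the remainder, which is re-scanned.

The tract score is linear in composition, `Σ w_n f_n`, with defaults
`w_T = 3, w_C = 2, w_G = −1, w_A = −2`. The numeric weights of the
published scheme this emulates are not legible in the source material, so
these are documented stand-ins satisfying its qualitative constraints
(T-richness dominates; purines penalized). Any affine rescaling is absorbed
when the SVM is retrained, so downstream behavior is robust to the exact
values; pass your own via the `weights` arguments to reproduce a specific
parameterization.

One subtlety matters a lot in practice: the branch adenosine is a purine
and can be *absorbed into* a long tract as an allowed isolated
interruption. A tract list computed globally would then start upstream of
the candidate and not count as "downstream", wrongly assigning the
candidate a no-PPT sentinel. `closest_downstream_ppt()` therefore trims any
tract overlapping the adenosine to its downstream part and counts it if the
remainder still passes all rules. The sentinel for a genuinely absent
downstream tract is `distance = 500` (the scan-window length) with score 0.

## The SVM

Features are standardized to mean 0 / sd 1 on the training set (statistics
stored in the model); classes are balanced by seeded downsampling of the
majority class; the kernel is linear with `C = 1` by default (four
low-dimensional features; interpretable weights via `tidy()`), with an RBF
kernel selectable. The original tool's kernel and parameters are not
published, so no equivalence is claimed — `cv_bp_models()` reports how
accuracy and AUC respond to these choices. The decision threshold is 0:
positive decision values are labeled branch points. Per intron, AGEZ
candidates are ranked by decision value with ties going to the candidate
closer to the 3SS (the field's proximal-preference convention), and each
intron lands in exactly one of four categories: `no_candidates`,
`none_in_agez`, `negative_scoring`, `positive_scoring`. Predictions more
than `dbp_threshold = 100` nt from the 3SS (four times the typical BP–3SS
distance) are flagged as distant BPs.

## Conserved-pentamer training pipeline

With alignment blocks covering the last 300 nt of orthologous introns in 7
mammals, `classify_pentamers()` sorts the 184 TNA-containing pentamers by
the positional behavior of their cross-species-conserved instances:

1. Kolmogorov–Smirnov test against uniformity over the scanned 300 nt —
   positions are treated as draws on the continuous interval, a deliberate
   approximation at integer resolution;
2. one-sided binomial test for enrichment of start positions in the BP
   window (−55, −15), expected proportion = window width / scan width
   (41/300), with no edge correction — the window sits far from the scan
   boundaries, so the correction would be third-order;
3. the peak — mode of a 5-nt-binned histogram after a centered 3-bin moving
   average, ties towards the 3SS — must fall inside the window.

Failing 1 or 2 gives `none` (tested jointly so that rare pentamers whose
few instances happen to sit in the window are not called); passing both
with the peak downstream of the window gives `ppt`; otherwise `bp`. The
"peak" definition is ours: the source describes the idea but not the
estimator, and a smoothed binned mode is the simplest estimator that is
stable at the observed instance counts.

`build_cons_tna()` then collects introns with exactly one conserved TNA,
positioned in the window, as 9-mers with the TNA central; `filter_bp5()`
keeps those overlapped by a BP-associated pentamer in *every* species.
"Overlap" defaults to sharing at least one position with the TNA
trinucleotide (`overlap = "tna"`); the looser any-overlap-with-the-9-mer
reading is selectable (`overlap = "ninemer"`). Conservation of a k-mer
instance requires its k reference bases to sit in k consecutive, gap-free,
cross-species-identical alignment columns — insertions inside the instance
disqualify it.

## What the synthetic generator emulates — and what it does not

`synth_config()` plants, in each background intron: a canonical 9-mer
sampled from YTNAY-consistent marginals; a branch position drawn from a
mixture — 96% a discretized normal peaking at −24 truncated to (−55, −15)
by rejection (no boundary pile-up), the rest spread over (−100, −56) and
(−300, −101) so distant BPs exist at a realistic sub-percent rate; a
rule-satisfying PPT starting 0–2 nt after the 9-mer (the PPT adjacent to
the BP, as observed for real acceptors); and an AG-free corridor between
the branch A and the grace region so the planted BP falls inside the first
AGEZ. Intron lengths are log-normal (median 700 nt, clipped to 320–3000).

Two generator choices deserve emphasis:

* **Dependencies.** Adjacent free positions co-vary in pyrimidine/purine
  class via `P(b|a) = m(b)(1 + ε s(a)(s(b) − E[s]))` with ε = 0.35. This
  preserves the stated marginals exactly — the planted consensus stays
  YTNAY with T rare at the central position — while giving the chain
  first-order structure that an MM1 can exploit and a PWM cannot, mirroring
  the weak adjacent-position dependencies seen in real BP sets. (An earlier
  draft copied the previous nucleotide outright; that inflates poly-T cores
  and contradicts the marginals, so it was replaced.)
* **Conservation.** Alignment blocks mutate non-reference species at 10%
  per site, while the planted central pentamer survives intact per species
  with probability 0.95 — high functional constraint over a diverged
  background, which is the signal the pentamer pipeline is designed to
  detect.

What the generator does **not** emulate: GC-content strata and
composition gradients along the intron, indel-rich alignments (gaps are
optional and sparse), non-TNA branch points, multiple true BPs per intron
(real introns demonstrably use several), splicing kinetics, and EST
sampling. Passing the synthetic experiments therefore demonstrates that
the implementation recovers signals of the planted kind at realistic
degeneracy — not that real-genome accuracy matches any published figure.
`synth_detectability()` reports the planted-vs-background mean log2-odds
gap (about 1.3 bits under the defaults) so the difficulty of the planted
problem is measurable rather than asserted.

## Problem sizes used by the test-suite experiments

The shipped experiments use 5,000 introns for the recovery/cross-validation
study and 2,000 alignment blocks for the pentamer-recovery study — large
enough that the binomial noise on the reported rates is a few tenths of a
percent, small enough to run comfortably on a laptop. Oracle-equivalence
fuzzing uses 1,000 random instances per scanner against literal
reimplementations of each definition.

## Reproducing reference-set statistics on real data

Users with real intron coordinates (e.g. the published training/benchmark
coordinate sets) and the matching genome build can run the same pipeline on
real data: `read_intron_table()` extracts stranded intron sequences from a
BED-like table plus genome FASTA; the resulting 9-mer set feeds
`fit_frequency_model()` / `information_content()` (for the motif IC),
`fit_mm1()` and `train_bp_model()`. Nothing in the package downloads
genomes; those inputs are supplied by the user.

## Known limitations

* Introns whose BP lacks the canonical TNA (a small minority, analogous to
  non-canonical splice sites) are invisible to the candidate enumerator by
  design and are reported in the `no_candidates` category.
* The PPT weights and the consensus baselines' strictness cutoff
  (`max_dist = 2`) are documented assumptions, not published values; both
  are configurable and affect only the affected feature/baseline columns.
* `filter_bp5` assumes deletions relative to the reference are the dominant
  gap mode in the blocks; alignments with heavy reference-side insertions
  reduce the set of scorable instances rather than producing wrong ones.
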