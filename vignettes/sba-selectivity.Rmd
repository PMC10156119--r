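---
title: "Scoring antibody selectivity on suspension bead arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring antibody selectivity on suspension bead arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multiplexed suspension bead arrays (SBA) couple each antibody of a panel to
a color-coded bead population and expose the mixed beads to lysates of
cells overexpressing one epitope-tagged receptor per well, alongside mock
(empty-vector) lysates. The readout is one median fluorescence intensity
(MFI) per bead population per well. The scientific question per antibody is
blunt: does it capture the receptor it was raised against, something else,
both, or nothing? For G protein-coupled receptors — solubilized,
detergent-laden, seven-transmembrane proteins with closely related
subfamily members — this question is hard, and the answer has to come from
the data itself, because no external gold standard exists for most targets.

`sbaselect` implements the full desk side of such a screen: input
validation, quality control, expression assessment against mock, robust
Z-scoring with an antibody-specific data-driven threshold, a four-class
selectivity annotation, deconvolution of cross-reactivity into abundance-
and homology-driven causes, agreement between antibodies sharing a target,
and antigen-level structural features. A synthetic-data generator with a
ground-truth ledger makes every stage testable end to end.

## The scoring model

**Robust Z-scores.** Each antibody's MFI vector `x` over the wells of its
subfamily panel is scaled as

    rz_i = (x_i - median(x)) / (1.4826 * MAD(x)),   MAD = median(|x_i - median(x)|)

computed separately per antibody. Median and MAD are used precisely because
the interesting observations — true binding events — are outliers that
would corrupt a mean/SD scaling. The transform is affine invariant:
rescaling an antibody's raw fluorescence (detector gain, conjugation batch)
changes neither its profile nor any downstream call. A zero MAD is reported
as a degenerate-distribution error naming the antibody; it is never
silently patched, because it means the well set cannot support outlier
detection at all.

**The antibody-specific threshold.** Most wells do not contain an
antibody's binding partner, so the bulk of its score distribution is a
negative population centered at the mode. The threshold is

    threshold = peak + k * sigma_neg,   k = 12 by default

where `peak` is the mode of a Gaussian kernel density estimate of the
scores (Silverman's rule-of-thumb bandwidth, 512-point grid spanning the
data range) and `sigma_neg` estimates the SD of the negative population.
The estimator for `sigma_neg` is the package's central free choice, since
only the construction's intent is fixed by the screen's description: we use
the reflected lower tail,

    sigma_neg = 1.4826 * median(|r - peak|)  over  {r <= peak},

i.e. the lower half of the distribution mirrored around the peak. True
binding inflates only the upper tail, which this estimator never sees; on
symmetric data it is consistent for the ordinary SD (on 10,000
standard-normal draws it lands within a few percent of 1). If fewer than
three points lie at or below the peak the full-vector MAD-based SD is used
with a warning. The working multiplier `k = 12` is kept as a config value,
and `threshold_sweep()` reproduces the count-versus-k curve used to judge
it: on-target counts peak and cross-reactivity counts plateau as `k`
grows.

**Four-way classification.** At its threshold, an antibody is
`on_target` if the *mean* score of the wells expressing its intended
receptor exceeds the threshold and no other receptor's well does;
`co_target` if the intended receptor is detected but some *single*
unintended well also exceeds the threshold; `off_target` if only
unintended wells exceed it; `no_target` otherwise. The asymmetry is
deliberate and conservative: intended recognition is averaged over
replicates, while one unintended well anywhere brands the antibody
cross-reactive. Mock wells participate in the score vector (they are
honest members of the negative population) but can never constitute an
off-target event. Wells failing QC are excluded from every statistic,
never imputed. A panel containing no well for an antibody's intended
target is a design error, not a `no_target` call.

## Quality control and expression

Wells with fewer than 32 bead events are masked. Beads whose coupling
signal (a per-bead anti-IgG measurement, modelled as a separate vector
because coupling is physically a property of the bead, not of any well)
falls below a floor are excluded from scoring entirely.

Expression of each construct is assessed on the anti-tag capture bead
(FLAG capture for most constructs, HA for the frizzled-type constructs,
with the constant C-terminal 1D4 tag on the detection side): log2 MFI
(floored at 1 unit to avoid `-Inf` while preserving order), a per-panel
one-way ANOVA gate at `alpha = 0.05`, then Dunnett's multiple-comparison
contrast of each construct against mock. Expression is *supported* iff the
Dunnett p-value is below `alpha` **and** the construct mean exceeds the
mock mean — the direction gate is enforced on top of the two-sided test, so
"supported" can never point downward. Constructs with fewer than two usable
replicates are reported `uncertain` with `NA` p-values and are retained in
summary denominators (the screen's own tables do not say otherwise, and
dropping them would silently inflate success rates). Dunnett p-values come
from the single-step multivariate-t distribution; because that integral is
computed by randomized quasi-Monte-Carlo, the call runs under a fixed local
RNG state so identical inputs give identical outputs. The test suite checks
the p-values against a max-|t| label-permutation oracle.

## Deconvolving cross-reactivity

Each (antibody, off-target) event is annotated with two candidate causes:

- **abundance** — the off-target's mean linear capture level is at least
  `ratio_cut = 2` times the on-target's (the literal twofold line; linear,
  not log2, so the boundary means what it says). The ratio is refused
  (reported `NA`) when the on-target's expression is unsupported, because
  a denominator indistinguishable from background is not a measurement.
- **homology** — the antigen sequence (not the full on-target protein)
  locally aligned against the off-target protein scores an E-value below
  `evalue_cut = 1`. Alignment is Smith-Waterman with affine gaps
  (BLOSUM62, gap open 11, extend 1) and the E-value is Karlin-Altschul
  `E = K m n exp(-lambda S)` with fixed constants
  `lambda = 0.267, K = 0.041` stated in config — decision-boundary
  semantics, not parity with any particular BLAST release.

Both flags may co-occur; an event explained by neither is `promiscuous`.
An event is *consistent* when every QC-passing well containing the
off-target exceeds the threshold. One property of correct E-values is
worth knowing when reading synthetic results: for two unrelated sequences
the best local alignment has `P(E < 1)` of roughly `1 - 1/e`, so the
homology flag co-occurs on many abundance-driven events; planted
homologous pairs, by contrast, score `E` in the 1e-20 range and are never
missed. Production BLAST tools suppress weak hits heuristically, which is
why `E < 1` reads stricter in the literature than it is in theory.

## Paired antibodies and antigen structure

Antibodies sharing a target are compared by Pearson correlation of their
robust-Z profiles over the wells both observed (at least three), on the
view that each antibody's own scale has already been divided out; a config
switch allows raw-MFI correlations instead. Summaries count targets with
two or more antibodies and, among them, targets recognized (on- or
co-target — both detect the intended receptor above threshold) by at least
two.

Antigen features come from predicted full-length models (PDB or mmCIF,
single chain, per-residue confidence read from the B-factor field, the
convention of predicted-structure repositories): per-residue pLDDT as a
graded disorder proxy (no binary cutoff is imposed), solvent accessibility
by a Shrake-Rupley implementation (deterministic Fibonacci point lattice,
960 points, probe 1.4 Å; the two-sphere closed form and lattice-refinement
convergence are tested), relative accessibility against the Tien et
al. (2013) theoretical maxima shipped in the package, and a three-state
secondary structure from backbone dihedrals (helix `phi` in (-100, -30),
`psi` in (-80, -5), runs of 4+; sheet `phi` in (-180, -90), `psi` above 90
or below -150, runs of 3+; else coil). The dihedral assignment
intentionally replaces DSSP's hydrogen-bond logic — only three-state
fractions feed the statistics, and precomputed per-residue strings are
accepted wherever profiles are built. Antigen spans reaching outside the
resolved model are flagged incomplete and excluded from group statistics
with a warning. Group comparisons use Kruskal-Wallis plus pairwise
two-sided Wilcoxon tests for antigen length, and independent Student's t
tests for the structural metrics.

## The synthetic screen

`generate_dataset()` emulates the study conditions end to end and returns
the ground truth alongside the data:

- **Library.** Random amino-acid sequences (default 300 residues) in six
  subfamily panels; members of a subfamily share a common ancestral
  segment (90 residues, 5% per-residue mutation) so homology-driven
  cross-reactivity is plantable and recoverable by alignment.
- **Samples.** Four biological replicates per construct, one technical
  replicate each, four mock wells per panel. Technical replicates are
  retained as separate wells for classification (the rule is stated over
  wells); a config flag allows averaging.
- **Expression.** Lognormal abundance, expressed constructs 100-fold over
  the mock-like level with `sdlog = 0.35`; per-subfamily failure
  probabilities of 0.07-0.26 (averaging ~15%, chosen to mirror the
  screen's own per-subfamily success rates), with failed constructs drawn
  from the mock distribution itself.
- **Signal.** `MFI = min(S, b + sum_g affinity * level) * exp(eps)` with
  background `b = 100` AU, saturation `S = 60,000` AU (bead-reader
  dynamic-range order of magnitude) and multiplicative lognormal noise
  `sdlog = 0.15`. The noise level is a free choice — the assay publishes
  no quantitative noise model — set so that expressed on-target wells sit
  ~50-100 robust SDs above background, comfortably separating planted
  classes without making recovery trivial at `k = 12`.
- **Antibody classes.** Planted fractions {on 0.61, co 0.04, off 0.08,
  none 0.27}, matching the screen's reported marginals so summary outputs
  resemble the real ones. Cross-reactivity is planted through two
  mechanisms: homology (antigen inside the shared segment of a same-panel
  partner) and abundance (dissimilar antigen; the off-target construct
  expressed 4-fold higher). Abundance off-targets are never drawn from the
  intended targets of other cross-reactive antibodies — boosting such a
  construct would cancel that other antibody's own off/on ratio and make
  the planted condition self-contradictory. Bead counts sit above the
  32-event floor except for a configurable dropout fraction; a small
  fraction of beads fail coupling.

What the generator does **not** emulate: plate-position effects, batch
drift, detergent chemistry, saturation of the capture tags, epitope
masking, or real sequence composition. Passing recovery tests therefore
demonstrates that the scoring machinery identifies what it is designed to
identify under a faithful signal model — not that any particular real
antibody is well classified.

**Recovery accounting.** Parameter-recovery rates are measured against the
truth ledger with one conditioning rule: a planted on-target antibody whose
construct failed to express is unrecoverable by any scoring method (there
is nothing in the well to capture), so on-target recovery is counted among
antibodies whose target expressed; likewise the abundance-flag rate is
counted among events whose on-target expressed, since the expression ratio
is deliberately refused otherwise. No-binder recovery is unconditional.
This mirrors the screen's own separation of expression evidence from
capture evidence.

## Numerical and formatting choices

- KDE: Gaussian kernel, `bw.nrd0`, 512 grid points on `[min, max]`.
- Robust-Z and threshold computations drop masked wells; they never
  interpolate.
- Percentages in summary tables carry one decimal (`round(100k/n, 1)`);
  the narrative breakdown of non-on-target antibodies is the integer
  rounding of those one-decimal values, which is how a table-precision
  intermediate turns 19.497% into the reported 20%.
- Local alignment scores are floored at 0 (the empty alignment); E-values
  are monotone decreasing in score and proportional to `m * n`.
- The pipeline replays byte-identically: fixed seeds cover every
  stochastic step, including the multivariate-t integration inside the
  Dunnett contrasts.

## Problem sizes

The default synthetic screen is 24 receptors across six panels, 40
antibodies, 120 wells — small enough that the full recovery suites (20
simulated screens per property) and the acceptance script run in about a
minute each on one core, while leaving every planted effect far from
marginal. The structural group-comparison suite uses 50 synthetic
structures per class of 60 pseudo-residues each. All sizes are config
values; scaling the screen up changes nothing in the code paths.

## Known limitations

- The negative-population SD estimator is a reconstruction of an
  under-documented procedure; it is validated on its stated properties
  (calibration on normal data, immunity to upper-tail contamination), not
  against the original implementation.
- E-value semantics are theoretical Karlin-Altschul, not BLAST-heuristic;
  see the deconvolution section.
- The dihedral secondary-structure assignment disagrees with DSSP near
  helix caps and irregular strands; only class fractions are consumed
  downstream.
- With a single technical replicate per biological replicate the
  technical/biological variance split is not identifiable and is not
  modelled.
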