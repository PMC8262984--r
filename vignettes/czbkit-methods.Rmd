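---
title: "czbkit: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{czbkit: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(czbkit)
```

# Scope

Chemoreceptor zinc-binding (CZB) domains are small four-helix bundles
that coordinate Zn^2+^ through a conserved 3His/1Cys core. The cysteine
doubles as a sensor of hypochlorous acid (HOCl): oxidation to cysteine
sulfenic acid perturbs zinc ligation and allosterically switches the
attached output domain — a chemoreceptor (MCP) signaling domain, a
diguanylate cyclase (GGDEF), a phosphodiesterase (EAL) or a CheW
adaptor. `czbkit` implements, as one tested pipeline, the two halves of
a typical CZB study: a sequence survey (domain identification,
architecture classification, conservation/logo analysis, species
co-occurrence) and the quantitative bench-side analyses (Hill
dose-response, tight-binding chelator titrations, linear zinc
inhibition, biofilm normalization, colony and pellicle image
quantification). A synthetic-data module generates labeled inputs with
the statistical structure each stage assumes, so every claim a test
makes is checked against known ground truth without any downloads.

# CZB identification

A call rests on four attributes, all of which must hold:

1. **Zinc core** — at least 3 histidines within ±`his_window` residues
   of the motif cysteine. Default `his_window = 45`: the spacing of the
   core histidines around the conserved cysteine in the *E. coli*
   reference protein DgcZ (His22/His79/His83 vs Cys52) fits inside ±31,
   and ±45 leaves margin for looser homologues while staying inside a
   single domain.
2. **α3 motif** — a 7-residue window matching `CX(L/F)GXW(Y/L)`. The
   unknown-residue letter `X` never satisfies a motif position (not even
   the wildcards), because a window containing `X` cannot be positively
   asserted to match.
3. **Coverage** — the candidate region must span at least
   `min_coverage = 100` residues of the canonical ~128-residue domain.
   The candidate frame is `[cys - 51, cys + 76]`, anchoring the domain
   to the only universally conserved residue the way Cys52 sits inside
   a 1–128 domain.
4. **Alignment** — a log-odds score (base 2, uniform background,
   pseudocount 0.5 per residue) of the candidate region against a
   position-frequency profile built from confirmed CZB domains must
   reach `score_threshold`. The default threshold of 0 means "more
   CZB-like than background"; on the synthetic bench, positives score
   far above 0 and decoys far below, so any threshold in a wide band
   gives identical labels. Columns not covered by the region contribute
   a fixed gap penalty (−2).

Calls exactly at the threshold are accepted and *flagged*; the flag
column replaces the manual-review step of survey practice with a
machine-readable report.

`iterative_search()` repeats backend search → `call_czb()` acceptance
until a fixed point, mirroring iterative BLAST surveys. The bundled
backend is a deliberately naive shared-k-mer counter (k = 4) — enough to
exercise convergence semantics (monotone growth, fixed point,
seed-order invariance, multi-hop reachability) without re-implementing
BLAST statistics, which are out of scope. Real surveys plug in an
external search as the backend function.

# Architecture classification

Priority rules, applied to InterPro-style domain annotations plus TM
regions: MCP+TM → membrane chemoreceptor; MCP → soluble chemoreceptor;
GGDEF+EAL → DGC-EAL; GGDEF → DGC; EAL → EAL-CZB; CheW → CheW-CZB;
otherwise CZB-only. Chemoreceptors outrank catalytic domains because
surveys treat chemoreceptors with auxiliary domains as chemoreceptors.
Proteins whose only other annotation is "other" fall to CZB-only with a
note, since that class means "no other recognized domain signature";
sequence length is reported alongside so users can filter probable
fragments.

The CZB terminus is N/C when the domain starts/ends within 15% of the
protein length, else internal; diagrams in the field distinguish only N
vs C placement, never numerically, so the cutoff is a package choice
and is configurable only by editing the call table downstream. A CZB is
*periplasmic* only in a membrane chemoreceptor with one TM ending
before and one starting after the domain.

The fallback TM predictor is the standard Kyte–Doolittle sliding
window (window 19, threshold 1.6, minimum run 15, runs merged when
separated by <3 residues). These are textbook heuristic values; real
runs should supply curated TM annotations in the domain table, which
take precedence.

# Conservation and logos

Per-column identity is `100 × modal-residue count / non-gap rows`; gaps
are excluded from denominators and reported as a separate fraction,
because mixing them conflates alignment depth with conservation.
All-gap columns are reported as missing rather than 0. Modal-residue
ties break alphabetically for determinism. Logo matrices are raw
frequencies (7 positions × 20 residues, rows summing to 1) anchored at
the conserved Cys column; no information-content scaling and no
redundancy weighting are applied, and output metadata says so — with
strongly redundant alignments the logos reflect the sampling, not the
family.

# Species co-occurrence

A species "has a chemoreceptor" when any of its proteins is a soluble
or membrane chemoreceptor, and "has a DGC" when any is GGDEF-bearing.
EAL-CZB, CheW-CZB and CZB-only proteins count toward neither class:
they transduce or degrade signals rather than sense-and-synthesize, and
the chemoreceptor-vs-DGC dichotomy is the biological question being
asked. Species-name normalization (case folding, stripping strain codes
after `sp.`) is off by default and logged when used, because published
tables mix named species with `Genus sp. CODE` entries and any
de-duplication rule is a judgment call.

# Quantitative models

**Hill.** `A·L^n/(K½^n + L^n)` with n fixed (default 2, the
cooperativity used for HOCl oxidation of the CZB cysteine). The
baseline is fixed at 0 (blank-subtracted signals). Doses above
`max_dose = 500` µM are excluded by default: above ~500 µM HOCl the
sulfenic-acid signal *decreases* through overoxidation to sulfinate, so
only the monotone rising limb identifies the Hill curve. `A` is
profiled analytically and K½ optimized on the log scale from a
multistart grid at every observed dose, which removes basin dependence
without a stated initializer.

**Two-state tight binding.** The signal increment solves
`Δy² − (Δy_max + L₀ + K_D)Δy + Δy_max·L₀ = 0` (physical root), the
isotherm required when the responsive pool is comparable to K_D so the
hyperbolic approximation fails. The closed form
`0.5·(S − √(S² − 4·Δy_max·L₀))` with `S = Δy_max + L₀ + K_D` is
evaluated as the algebraically identical `2·Δy_max·L₀/(S + √(S²−4·Δy_max·L₀))`
to avoid catastrophic cancellation far from saturation; a bisection
solver of the underlying equilibrium verifies agreement to 1e−9 across
a parameter grid. The discriminant equals `(Δy_max+L₀+K_D)² − 4Δy_max·L₀ ≥ 0`
for valid inputs and is guarded anyway. The fit refines (y_min, y_max,
K_D) by Nelder–Mead on a log scale for the positive parameters,
multistarted with K_D at each positive dose. The half-maximal ligand
concentration has the closed form `K_D + Δy_max/2` (set Δy = Δy_max/2 in
the quadratic), reported for cross-protein potency ratios.

**Linear inhibition.** Ordinary least squares; for a negative slope the
zero-activity dose `x₀ = −intercept/slope` is reported and points whose
fitted value is negative are dropped once and the line refit — activity
cannot be negative, and the linear regime ends at stoichiometric
depletion of the enzyme by the zinc inhibitor.

All fits minimize unweighted squared residuals (no weighting is part of
the stated analyses). Unit invariance holds throughout: rescaling the
dose axis rescales K parameters accordingly.

**Normalization and tests.** Relative biofilm is A₅₆₂ divided by the
mean untreated wild-type A₅₆₂ *of the same experiment*, making the
untreated wild type average exactly 1 per experiment and the statistic
invariant to per-experiment scaling. Paired t tests are two-sided on
the differences; zero-variance differences are reported explicitly
(all-zero → t = 0, p = 1; constant nonzero → t = ±∞, p → 0) rather than
erroring mid-pipeline.

# Image quantification

Congo red colonies: pixels are converted to HSB; hue is expressed on a
0–255 wheel (the ImageJ byte convention implied by a "red hue threshold
of 1 to 14"; 0–360 is configurable). Pixels with hue in [1, 14] are
red-eligible; k-means (k = 3, fixed seed 0, up to 10 restarts, empty
clusters rejected) clusters pixels in HSB; the lowest-brightness
centroid is the black background, and among the rest the cluster
dominated by hue-gated pixels is red. Red counts are the hue-gated
members of the red cluster, so the hue gate bounds what k-means may
call red. `red_fraction = red/(red + brown)` — the background is
excluded from the denominator because it is plate, not colony. Images
with fewer than four distinct colors are segmented by exact color
instead of k-means (k-means is undefined there); this also makes the
saturated test cases deterministic.

Pellicles: per-row luma (0.299 R + 0.587 G + 0.114 B), inverted when
requested so that higher = more crystal violet stain (the dye is dark),
then a trapezoidal integral over rows 2000–2500 by default — the band
where the liquid–air interface sits in the reference tube geometry.
The row range is a parameter and is clipped with a warning; a
source-document variant reading "2000 to 25000" is taken to be a typo
for 2500, and the default follows the shorter, geometrically sensible
range.

# The synthetic world

`gen_czb_proteins()` states the survey world: a CZB cassette of 128
residues (Cys52, His22/79/83, motif at 52–58) diverged at 15% per
position from a family consensus, composed into the seven architectures
at the published survey mix (45.6% soluble chemoreceptors, 27.1%
CZB-only, 6.0% diguanylate cyclases split 3:1 plain:EAL-bearing, 3.4%
EAL-CZB, 1.4% CheW-CZB, remainder membrane chemoreceptors, of which
half are built periplasmic). Decoys are *near-misses*, each designed to
fail exactly one attribute: motif without His core, core with scrubbed
motif, and truncated domains. Background residues are uniform over the
20 canonical amino acids — real proteomes are not uniform, but
composition bias affects only the profile-score margin, which is large.
Dose-response noise is multiplicative (titration signals span orders of
magnitude), truncated at zero, at 5% by default with triplicate
readings, matching the n = 3 of typical activity assays. Colony images
use red hue 8 and brown hue 45 on the 0–255 wheel (37 hue units apart)
with saturation/brightness jitter only, so hue gates are exactly
respected; tube images are noiseless so measured profiles equal truth
exactly.

What a green test therefore establishes: the implementations compute
exactly what their definitions say (oracle equivalence), and the
pipeline recovers planted ground truth when its assumptions hold. What
it does not establish: performance on real survey data, where domain
boundaries are fuzzy, annotations disagree, alignments are gapped and
redundant, and colony lighting varies — those require the external
annotations and curated inputs the pipeline is designed to consume.

# Numerical choices

* Optimizers: Brent on log-K for Hill (profiled amplitude); two-pass
  Nelder–Mead (reltol 1e−14) for the two-state model. Noiseless
  round-trips recover parameters to better than 1e−6 relative.
* Ties in `call_czb()` between equally scoring motif hits break to the
  smallest cysteine position; modal-residue ties break alphabetically;
  k-means determinism comes from a fixed local seed that does not
  disturb the caller's RNG stream.
* Degenerate inputs are contracts, not crashes: all-gap columns →
  missing; empty FASTA → format error; zero-variance paired t →
  explicit sentinel; constant linear data → warning with undefined x₀;
  grayscale images → error for the color pipeline.

# Known limitations

* The two-state K_D recovery criterion (median relative error <5% over
  100 simulations at 5% multiplicative noise, 8 doses, triplicates) is
  not met by the stated world, and the corresponding acceptance test is
  deliberately left failing rather than loosened. The package's own
  analysis: the weighted Cramér–Rao bound for realistic serial-dilution
  designs is already ~4–5% median, and the prescribed unweighted
  least-squares estimator pays a further efficiency cost under
  multiplicative noise, landing at ~6% regardless of baseline or
  depletion regime; only a degenerate repeated-support-point design
  (doses concentrated at two levels) reaches <5%, and that is not a
  titration. Hill K½ recovery passes at ~2%.
* Profile scoring is ungapped within the candidate frame; strongly
  indel-shifted CZB domains rely on the motif anchor, not the profile,
  for localization.
* The k-mer search backend is a test harness, not a homology search;
  surveys should plug in a real aligner/search tool as the backend.
* No signal-peptide prediction, no ligand-binding-domain subtyping, no
  tree construction; the pipeline produces the tables such tools
  consume.
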