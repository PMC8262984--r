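# czbkit

Survey and quantitative analysis toolkit for **chemoreceptor
zinc-binding (CZB) domains** — the bacterial four-helix bundles whose
conserved 3His/1Cys zinc core doubles as a hypochlorous-acid (HOCl)
sensor and allosterically regulates chemoreceptors and c-di-GMP
enzymes.

It is written for two audiences: bioinformaticians running CZB
sequence surveys (who need reproducible domain calls, architecture
classes and species summaries from FASTA + annotation tables), and
bench scientists quantifying CZB biochemistry and biofilm phenotypes
(who need the standard fits and image quantifications with honest
diagnostics).

## What it computes

**Survey side.** A CZB call requires four attributes: the 3His/1Cys
core (≥3 His within ±45 residues of the motif Cys), the seven-residue
α3 motif `CX(L/F)GXW(Y/L)`, ≥100 residues of coverage across the
~128-residue domain frame, and a position-frequency profile log-odds
score above threshold. Accepted proteins are classified into the seven
canonical architectures (soluble/membrane chemoreceptor, DGC, DGC-EAL,
EAL-CZB, CheW-CZB, CZB-only), periplasmic N-terminal CZBs are flagged,
per-column conservation and 7×20 motif logo matrices are computed from
alignments, and architecture calls aggregate to species-level
chemoreceptor/DGC co-occurrence and phylum distributions.

**Bench side.**

* Hill dose-response `A·Lⁿ/(K½ⁿ + Lⁿ)` with n fixed (default 2), for
  HOCl oxidation titrations; doses above 500 µM are excluded by
  default (overoxidation regime).
* Quadratic two-state tight binding
  `Δy = ½[(Δy_max+L₀+K_D) − √((Δy_max+L₀+K_D)² − 4Δy_max·L₀)]`,
  `y = y_min + Δy`, for chelator titrations where ligand depletion
  invalidates the hyperbolic approximation.
* Linear zinc inhibition with zero-activity dose `x₀ = −b/m`.
* Relative biofilm: A₅₆₂ / mean untreated wild-type A₅₆₂ per
  experiment; paired two-sided t tests with explicit zero-variance
  handling.
* Congo red colony segmentation: HSB hue gate 1–14 (0–255 wheel) +
  k-means (k = 3) into red/brown/background; `red_fraction =
  red/(red+brown)`; fold dye uptake vs wild type.
* Pellicle quantification: per-row luma profiles of tube images,
  trapezoidal integral over rows 2000–2500.

A synthetic-data module (`gen_czb_proteins`, `gen_dose_response`,
`gen_colony_image`, `gen_tube_image`, `gen_species_table`) generates
labeled inputs for every stage, so the full pipeline is testable with
no downloads. See `vignettes/czbkit-methods.Rmd` for the models,
defaults and design decisions.

## Worked example

```r
library(czbkit)

## survey on a labeled synthetic bench
sim     <- gen_czb_proteins(n_positive = 120, n_decoy_per_type = 15,
                            config = generator_config(seed = 42))
profile <- build_profile(sim$seed_alignment)
calls   <- call_czb_set(sim$proteins, profile)
sum(calls$accepted)                       # 120 of 165 (45 decoys rejected)
arch    <- classify_set(sim$proteins, sim$domains, calls)
summarize_subgroups(arch)
#>                 subgroup count   fraction
#> 1  soluble_chemoreceptor    55 0.45833333
#> 2 membrane_chemoreceptor    20 0.16666667
#> 3                    dgc     5 0.04166667
#> 4                dgc_eal     2 0.01666667
#> 5                eal_czb     4 0.03333333
#> 6               chew_czb     2 0.01666667
#> 7               czb_only    32 0.26666667

## HOCl dose-response (truth: K_half = 122 uM, Hill n = 2)
ds <- gen_dose_response("hill", list(K_half = 122, n = 2, A = 1),
                        c(15, 30, 60, 90, 122, 180, 300, 480), reps = 3,
                        config = generator_config(seed = 42, noise_sd = 0.05))
fit_hill(ds)[c("K_half", "A")]
#> K_half = 119.4 uM, A = 0.973

## Congo red fold dye uptake (truth: 0.44 vs 0.10 -> 4.4-fold)
mut <- segment_congo_red(gen_colony_image(0.44,
         config = generator_config(seed = 42))$image)$red_fraction
wt  <- segment_congo_red(gen_colony_image(0.10,
         config = generator_config(seed = 43))$image)$red_fraction
normalize_dye_uptake(mut, wt)
#> 4.54
```

The numbers read as: all 120 planted CZB proteins are accepted and all
45 near-miss decoys rejected; subgroup fractions reproduce the
generator's mix exactly; the Hill fit recovers the planted half-maximal
HOCl concentration within noise (119.4 vs 122 µM); segmentation
recovers the planted red fractions, giving 4.5-fold dye uptake against
a 4.4-fold truth.

## Command line

An installed `czbkit` script (in the package's `exec/` directory)
exposes subcommands `scan`, `classify`, `cooccur`, `fit`, `quantify`,
`simulate` and `survey`, e.g.

```sh
Rscript -e 'czbkit::czbkit_main(c("survey",
  "--fasta", "proteins.fa", "--domains", "domains.tsv",
  "--taxonomy", "taxonomy.tsv", "--profile", "seed.aln",
  "--out", "survey_out"))'
```

which writes `calls.tsv`, `arch.tsv`, `profiles.tsv`,
`logos/<subgroup>.tsv`, `species.tsv` and a provenance-bearing
`summary.json`. Images are read/written as ASCII PPM everywhere, and
as PNG when the `png` package is installed.

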