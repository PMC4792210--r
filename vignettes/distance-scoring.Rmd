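---
title: "Distance scoring analysis of 7TM bundles: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance scoring analysis of 7TM bundles: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsa7tm)
```

## The method

Distance scoring analysis (DSA) asks, for every pair of Cα atoms in a
fixed set of residue positions, how conserved their spacing is across an
ensemble of experimentally determined structures. For pair $(i, j)$ with
distances $d_{ij}^{(1)}, \dots, d_{ij}^{(M)}$ over $M$ chains, the score is
the inverse of the coefficient of variation:

$$ s_{ij} \;=\; \frac{\bar d_{ij}}{\sigma_{ij}}, $$

dimensionless and large when the spacing varies little. The appeal of the
statistic is its bluntness: it needs no superposition (pair distances are
isometry-invariant), no reference structure, and no model of motion. Around
a dozen chains are enough to separate structurally conserved regions from
variable ones, both within single helices (intrahelical pairs) and between
helices (interhelical pairs).

The unit of comparison is a *bundle*: a fixed-length selection of
common-numbered Cα positions — for microbial rhodopsins, 170 residues in 7
transmembrane helices of 22, 24, 22, 24, 28, 25 and 25 residues, giving
$\binom{170}{2} = 14{,}365$ pairs, of which 1,992 are intrahelical and
12,373 interhelical. Each helix is anchored at its most conserved position,
labelled `h.50` (e.g. `7.50` is the retinal-binding lysine, 100% conserved
among retinal proteins), and other positions count down toward the amino
terminus and up toward the carboxyl terminus. This mirrors the
Ballesteros–Weinstein convention familiar from GPCRs and is what makes
bundles of different proteins comparable position-by-position.

## Workflow and containers

Everything user-facing is a tibble. A *chain bundle* is one row per bundle
position (`position`, `helix`, `label`, `x`, `y`, `z`, `present`); an
*ensemble* is several chain bundles bound together, keyed by a `chain`
column. `pair_statistics()` returns one row per canonical pair;
`dsa()` wraps the whole computation into a fitted object with `tidy()`,
`glance()` and `autoplot()` methods.

```{r workflow, eval = FALSE}
bundle <- mr_bundle()                        # curated 170-residue definition
maps <- read_residue_mappings("mappings.tsv")
ens <- read_ensemble("structures/", maps, bundle)
fit <- dsa(ens, bundle)
glance(fit)
autoplot(fit)                                # score vs mean distance
```

The canonical pair order is row-major over bundle positions 1..N in helix
order A→G: $(1,2), (1,3), \dots, (1,N), (2,3), \dots$ All ranking
tie-breaks, output files and distance vectors use this order, so every run
is bit-reproducible.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `std` | `"population"` | Divide squared deviations by $n$ (population) or $n-1$ (sample). At equal per-pair coverage the choice rescales all finite scores by one factor and cannot change a ranking; it is exposed because conventions differ between tools. |
| `min_chains` | 3 | Pairs defined in fewer chains get an undefined (`NA`) score: a coefficient of variation over two points is noise. Undefined pairs are excluded from ranking and counted. |
| `zero_sd_tol` | 1e-12 | Relative floor below which the spread counts as exactly zero and the score becomes `Inf` (ranked above all finite scores, ties broken by pair order). Rigid copies of one structure rotated by different matrices differ only by ~1e-13 relative round-off, so an exact `sd == 0` test would misclassify them. |
| `top_n` | 1000 | Depth of the cumulative-ratio curves. |
| `denominator` | `"group"` | Cumulative ratios are normalised by each group's own pair total, so a curve reaching 1 means "all of this helix's pairs rank in the top $r$". `"grand"` normalises by the total over all groups instead; the per-group reading is the default because it is the one under which the curves are comparable across helices of different lengths. |
| `exclude_gaps` | `FALSE` | Conservation percentages count gaps in the denominator by default, which is the conservative choice; excluding them inflates percentages in gappy columns. |

Scores can drift with the mean pair distance; no correction is applied
automatically, but `detrend_scores()` offers an explicit linear one (score
residuals about a least-squares fit on mean distance, recentred at the
grand mean) for comparisons spanning wide distance ranges.

## Structure input policy

Coordinates are read from PDB or mmCIF with author residue numbering (so
bacteriorhodopsin's Lys216 really is residue 216). One Cα per residue is
kept; alternate locations resolve to the highest occupancy, ties to the
first altloc identifier. Insertion codes are rejected outright — none occur
in the microbial rhodopsin entries the reference bundle targets, and a
silent guess would corrupt the position mapping. A residue that the mapping
expects but the file lacks is masked with a warning (missing density is a
fact of crystallography, and bundles that lack a residue at a helix
terminus are routinely tolerated); an author range that runs beyond the
chain's observed span is a hard error, because that is a mapping bug rather
than missing density.

Pairs spanning a masked position are computed over the chains that do have
both residues; `n_chains` records the per-pair coverage.

## The synthetic generator

Testing DSA against real ensembles would require downloading and curating
crystal structures, so the package generates its own: seven regular helices
(rise 1.5 Å/residue, 100° turn/residue, helix radius 2.3 Å — consecutive Cα
≈ 3.83 Å apart) placed on an 11 Å circle with alternating up/down
orientation, the topology of a transmembrane bundle. An ensemble adds, per
chain, independent isotropic Gaussian noise per residue (per-helix σ) and
one random rigid-body motion (up to 15° / 3 Å by default).

Defaults are chosen to emulate an ensemble of near-identical experimental
structures of one protein: 13 chains and σ = 0.5 Å, under which two chains
differ by about $\sigma\sqrt 6 \approx 1.2$ Å Cα RMSD and their distance
vectors correlate at ≈ 0.993 — the regime in which DSA is informative. The
rigid jitter is deliberately immaterial to the statistics (they are
isometry-invariant); it exists to exercise the superposition and I/O paths.

What the generator does **not** emulate: correlated backbone motion along a
helix, crystal-contact-induced local deformation, sequence-dependent
variation, π-bulges or other irregular helix geometry, side chains, or any
ligand. Passing tests on synthetic ensembles therefore demonstrate the
statistical and geometric correctness of the machinery — that noisier
helices score lower, that scores are invariant to how chains are posed,
that counts and rankings are exact — not that any particular biological
conclusion about a real family holds. Real analyses still depend on a
curated bundle definition and mapping, which ship as data
(`inst/extdata`) for the microbial rhodopsin case.

The synthetic MSA generator plants a designated top residue per column with
a stated probability (others drawn uniformly from the remaining 19 amino
acids), so the expected top-residue fraction equals the planted level
exactly; anchor recovery is tested at the reference family's own anchor
conservation levels (64–100%).

## Numerical choices and degenerate inputs

* Superposition is the closed-form SVD solution with reflection correction
  (determinant forced to +1): mirror images are never "matched" by an
  improper rotation. Fewer than 3 common positions, or collinear point
  sets (second singular value below 1e-10 of scale), are errors.
* Correlation entries over fewer than 2 overlapping defined pairs are
  undefined (`NA`) and flagged, not silently dropped.
* Common labels are stored as (helix, integer position) and rendered
  `h.pp` with two digits; no floating-point label arithmetic exists
  anywhere, so `3.50` never meets `3.5000000001`.
* Anchor ties in a conservation window resolve to the lowest column index,
  with a warning.
* All randomness flows from one explicit seed per generator call; there is
  no hidden global state beyond R's RNG, which is always set immediately
  before use.

## Test problem sizes

The shipped tests run the full 170-position bundle wherever counts matter
(14,365-row tables, 1,000-rank curves) and deliberately small bundles
(9–30 positions, 2–6 chains) wherever a brute-force oracle double-loop
verifies the vectorised path to 1e-9. Stochastic properties — noisier
helices scoring lower, RMSD growing with σ — are averaged over 20 seeds at
6 chains, sizes at which the effects are far larger than their Monte-Carlo
error.

## Known limitations

* No per-entry quality weighting: chains at 1.8 Å and 3.5 Å resolution, or
  from cryo-EM, enter the statistics with equal weight.
* Insertion codes are unsupported; families that need them need a mapping
  extension first.
* Helix windows and bundle ranges are user input; the package neither
  detects secondary structure nor aligns sequences. Both are solved
  problems best left to dedicated tools, and the bundle definition is
  exactly the kind of curation that should be data under version control,
  not code.
* With around ten chains, removing a single outlier chain can visibly
  change which pairs rank highest; small-ensemble results deserve a
  leave-one-out sanity check, which the tidy per-pair output makes easy.
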