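# dsa7tm

Distance scoring analysis (DSA) of seven-transmembrane (7TM) helix bundles
in R.

## The problem

Given a dozen or so crystal (or cryo-EM) structures of one membrane protein
— or of evolutionarily related proteins in one family — which parts of the
fold keep a fixed geometry and which parts flex with crystallisation
conditions or sequence variation? Microbial rhodopsins (bacteriorhodopsin,
halorhodopsins, sensory rhodopsins, proteorhodopsins, ...) are the classic
test case: 7TM retinal proteins whose helix arrangement is conserved but
whose individual helices respond differently to lattice packing, solvent
and mutation. The same question arises for GPCRs and any family with a
reliable structural alignment.

## The method

For every pair of Cα positions *(i, j)* in a fixed residue bundle, over an
ensemble of *M* chains, the DSA score is the inverse of the coefficient of
variation of the pair distance:

  s(i,j) = mean(d_ij) / sd(d_ij)

High score = conserved spacing. The statistic needs no superposition
(distances are isometry-invariant) and no reference structure. Pairs are
classified as **intrahelical** (both residues in one helix) or
**interhelical**, ranked by score, and summarised as cumulative-ratio
curves over the top ranks to show which helices (or helix pairs) dominate
the conserved core.

Positions are identified family-wide by common numbering: each helix is
anchored at its most conserved position, labelled `h.50` (for microbial
rhodopsins, `7.50` is the retinal-binding lysine), and neighbours count
down/up from it. The curated 170-residue microbial rhodopsin bundle (7
helices of 22, 24, 22, 24, 28, 25, 25 residues → 14,365 pairs: 1,992
intrahelical + 12,373 interhelical) ships with the package
(`mr_bundle()`), together with the bacteriorhodopsin author-numbering map
(`mr_bR_mapping()`), a conservation profiler for building anchors from a
multiple sequence alignment, Kabsch superposition RMSD / distance-vector
correlation matrices, and a synthetic 7TM bundle generator so everything is
testable without downloading a single structure.

## Worked example

A synthetic ensemble of 13 chains with 0.5 Å per-residue noise emulates a
set of near-identical experimental structures:

```r
library(dsa7tm)

spec <- synthetic_spec(n_chains = 13, seed = 42)
ens  <- make_ensemble(spec)
fit  <- dsa(ens, synthetic_bundle(spec$helix_lengths))
fit
#> <dsa> 13 chains, 14365 pairs (1992 intra / 12373 inter), std = population
#>   defined scores: 14365 (of which 0 infinite), undefined: 0
#>   median finite score: 30.61
```

A median score near 30 means a typical pair distance varies by ~3% of its
mean across chains. Rank the intrahelical pairs and look at the top:

```r
ranked <- rank_pairs(dplyr::filter(tidy(fit), class == "intra"))
head(ranked[, c("rank", "label_i", "label_j", "group", "mean", "sd", "score")], 3)
#>    rank label_i label_j group  mean    sd score
#> 1     1 5.39    5.64    E      37.8 0.424  89.2
#> 2     2 5.38    5.64    E      39.2 0.490  79.9
#> 3     3 1.40    1.60    A      30.1 0.379  79.6
```

The top pair's spacing (37.8 Å between positions 5.39 and 5.64) varies by
only 0.42 Å across the 13 chains. With uniform noise every helix's
cumulative-ratio curve reaches ~0.5 by rank 1,000 (1,000 of 1,992
intrahelical pairs); lowering one helix's noise makes its curve dominate —
that separation is what the method detects in real ensembles. Ensemble
diagnostics agree with the regime the score is designed for:

```r
max(pairwise_to_matrix(pairwise_rmsd(ens)))
#> 1.288          # Å, Kabsch RMSD over 170 Cα
min(pairwise_to_matrix(distance_correlation(ens, synthetic_bundle(spec$helix_lengths))))
#> 0.9898         # Pearson r between chains' 14,365 distances
```

Common numbering on real bacteriorhodopsin ranges:

```r
common_number(216, c(202, 226), c("7.36", "7.60"))   # retinal-binding Lys216
#> "7.50"
```

A thin command-line front end (`inst/exec/dsa`) wraps the same functions:
`dsa simulate`, `dsa score`, `dsa rank`, `dsa rmsd`, `dsa corr`,
`dsa number`, `dsa plot`; every plot command also writes the plotted
numbers as TSV.

See `vignettes/distance-scoring.Rmd` for the model, parameter and design
discussion.

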