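# screenrank

Multi-criteria profiling and consensus ranking of compound screening
libraries.

## The problem

Drug-discovery projects that start from experimental screening must first
choose *which* library to screen. Vendors offer many, and the choice
matters: a library riddled with salts, duplicates, frequent HTS hitters or
compounds with poor ADME/T properties wastes screening capacity, while a
library with low internal diversity undersamples chemical space.
`screenrank` is for computational chemists making that call. It profiles
each candidate library on quantitative criteria and aggregates them into a
single ranking:

1. **Curation** — salt stripping to the parent structure, removal of
   inorganics, mixtures, bad-valence structures and duplicates, rule-based
   protonation at pH 7.4 and one canonical tautomer per compound, with
   per-category removal percentages.
2. **ADME/T** — percent failing the Lipinski rule-of-five filter
   (more than one of HBD > 5, MW > 500, CLogP > 5, HBA > 10), percent
   failing the Veber filter (RotB ≤ 10 and (TPSA ≤ 140 Å² or H-bond
   count ≤ 12)), and percent predicted blood-brain-barrier impermeable by
   the shipped linear-plus-spline model
   log BB = 1.2827 + 0.17977·AlogP98 − 0.0033777·DPSA1 − 0.18676·N_HBA +
   0.1557·S_sssN − 0.022135·⟨4.6743 − S_ssCH2⟩, with ⟨x⟩ = max(0, x) and
   log BB ≥ 0 classed permeable.
3. **Promiscuity** — percent of compounds matching a named SMARTS alert
   catalog (PAINS-style chemotype families; user-replaceable).
4. **Internal diversity** — mean pairwise Tanimoto similarity (lower =
   more diverse) over circular (ECFP/FCFP), structural-key (166 public
   keys) and topological pharmacophore fingerprints.
5. **Similarity to known actives** (optional) — threshold, ranked and
   substructure searches with enrichment curves.
6. **Overlap with an in-house collection** (optional) — percent of
   candidate compounds with Tanimoto ≥ 0.7 (ECFP_4) to any in-house
   compound.

Per-criterion values become **dense ranks** (best = 1, ties share a rank,
next distinct value gets the next integer); ranks are summed within
criterion blocks and the sums dense-ranked again; block ranks sum to grand
totals whose dense ranks are the final ranking. A genetic function
approximation (GFA) engine with Friedman's lack-of-fit fitness, kNN
outlier filtering, diversity/random train-test splits and Y-scrambling
rebuilds QSAR models in the same parameter format the logBB model ships
in.

## Worked example

The package bundles a benchmark profile of nine commercial screening
libraries. Reconstructing its consensus ranking:

```r
library(screenrank)
bc <- benchmark_consensus()
data.frame(library     = names(bc$three_block$final_rank),
           admet       = as.integer(bc$adme$block_rank),
           promiscuity = as.integer(bc$promiscuity_rank),
           total       = as.numeric(bc$three_block$totals),
           final       = as.integer(bc$three_block$final_rank))
#>                        library admet promiscuity total final
#>                Elite libraries     4           2    13     4
#>            Platinum collection     6           1    15     5
#>                    DIVERSet-CL     3           5    15     5
#>                   DIVERSet-EXP     1           4    10     1
#>                  Drug-like set     3           6    12     3
#>  Pharmacological diversity set     2           3    11     2
#> Maybridge screening collection     3           7    13     4
#>     Prestwick Chemical Library     7           9    17     6
#>              MSII full library     5           8    15     5
```

The `admet` column is itself a two-level consensus over the Lipinski,
Veber and logBB failure percentages; `total` sums the three block ranks
and `final` dense-ranks the totals — DIVERSet-EXP wins with total 10.
Evaluating the shipped blood-brain-barrier model on a descriptor vector:

```r
m <- read_logbb_model()
d <- data.frame(alogp98 = 2, dpsa1 = 100, num_h_acceptors = 3,
                s_sssN = 0, s_ssCH2 = 6)
predict_logbb(d, m)
#> [1] 0.74419
classify_bbb(predict_logbb(d, m))
#> [1] permeable
```

(The spline argument 4.6743 − 6 is negative, so the spline term
contributes nothing here.) Running the full pipeline on your own files:

```r
cfg <- workflow_config(libraries = list(
  libA = list(path = "vendorA.sdf", format = "sdf"),
  libB = list(path = "vendorB.sdf", format = "sdf")))
res <- run_workflow(cfg, out_dir = "results/")
res$best_library
```

A thin command-line wrapper ships at `inst/scripts/screenrank.R`
(`Rscript screenrank.R run --config cfg.yml --out results/`; subcommands
`curate`, `admet`, `alerts`, `diversity`, `similarity`, `compare`, `rank`,
`benchmark-descriptors`, `build-qsar`).

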