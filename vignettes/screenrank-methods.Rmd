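---
title: "Methods: multi-criteria profiling and consensus ranking of screening libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-criteria profiling and consensus ranking of screening libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenrank)
```

## The problem

Experimental screening campaigns start from a compound library, and the
choice of library shapes everything downstream: a library full of salts,
duplicates, promiscuous binders or compounds with poor ADME/T properties
wastes screening capacity, while a library with low internal diversity
undersamples chemical space. When several vendor libraries are candidates,
the practical question is which one to buy. `screenrank` answers it by
profiling each candidate on a set of quantitative criteria and aggregating
the per-criterion results into a single consensus ranking. The workflow is
aimed at phenotypic screening, where neither a target structure nor active
compounds may be known, but it can fold in similarity to known actives and
overlap with an in-house collection when those are available.

## Curation

Vendor files routinely contain salts, mixtures, inorganics and duplicate
entries. Curation proceeds in a fixed order per record:

1. **Salt stripping** (`largest_fragment()`). A multi-fragment record is
   reduced to its largest fragment when every discarded fragment is either
   on the shipped counter-ion list (`inst/extdata/counterions.smi`,
   matched by canonical SMILES in both neutral and charged protonation
   forms) or has at most 6 heavy atoms and opposite-or-zero net charge
   relative to the parent. Equal-size largest fragments are never treated
   as salts. The 6-heavy-atom fallback deliberately also strips small
   neutral adducts (water, ammonia); fragments above it that are not listed
   counter-ions make the record a mixture.
2. **Classification** (`classify_record()`), first match wins:
   *inorganic* when the parent fragment has no carbon or contains an
   element outside {C, H, N, O, S, P, F, Cl, Br, I, B, Se}; *mixture* when
   more than one fragment survives stripping; *bad valence* when any
   atom's bond-order sum plus hydrogens exceeds its standard valence for
   its formal charge (C 4; N 3, N⁺ 4; O 2, O⁻ 1; S 2/4/6; P 3/5; halogens
   1; B 3; Se 2/4/6). Element/charge combinations outside the table are
   tolerated rather than guessed at.
3. **Standardization** (`standardize()`). Protonation at pH 7.4 is
   rule-based and auditable rather than predicted: carboxylic, sulfonic
   and sulfuric OH groups are deprotonated (pKa well below 7.4),
   phosphate-type groups lose a single proton (the second pKa sits near
   7), aliphatic amines and amidine/guanidine groups are protonated;
   anilines, amides, sulfonamides and heteroaromatic nitrogens are left
   neutral. One tautomer per compound is kept via two deterministic
   rewrites applied to a fixed point: enol → ketone and iminol → amide.
   Each rule's product no longer matches the rule, so standardization is
   idempotent — a property the test suite checks directly.
4. **Deduplication** (`deduplicate()`) keeps the first occurrence of each
   canonical key. The canonical key is the canonical SMILES (OpenBabel) of
   the standardized parent structure, so a free base and any of its salts
   collapse to one entry.

Unparseable records are counted and logged at read time, never fatal:
removal rates are themselves a library-quality statistic, reported per
category as percentages of the input size.

## ADME/T profiling

Three per-library percentages are computed. A compound **fails the
Lipinski filter** when more than one of {H-bond donors > 5, molecular
weight > 500 Da, CLogP > 5, H-bond acceptors > 10} holds (strict
inequalities; boundary values are not violations). A compound **fails the
Veber filter** unless rotatable bonds ≤ 10 and (topological polar surface
area ≤ 140 Å² or total H-bond count ≤ 12), with H-bond count = donors +
acceptors. MW, logP, TPSA and donor/acceptor counts come from OpenBabel;
rotatable bonds are counted as single, acyclic, non-amide bonds between
two non-terminal heavy atoms.

Blood-brain-barrier permeation uses a linear-plus-spline model over five
descriptors:

$$\log BB = 1.2827 + 0.17977\,\mathrm{AlogP98} - 0.0033777\,\mathrm{DPSA1}
- 0.18676\,N_{\mathrm{HBA}} + 0.1557\,S_{sssN}
- 0.022135\,\langle 4.6743 - S_{ssCH2}\rangle$$

where ⟨x⟩ = max(0, x) is the truncated-power spline basis: the last term
is zero whenever the methylene E-state sum reaches the knot at 4.6743 and
linear below it. Compounds with logBB ≥ 0 are classed permeable (the
boundary is inclusive), logBB < 0 impermeable; the per-library statistic
is the percentage predicted impermeable. The model ships as a plain-text
parameter file (`inst/extdata/logbb_model.txt`) so the equation is
auditable and replaceable, and `as_logbb_model()` converts any freshly
evolved GFA model into the same format.

Descriptor implementations: AlogP98 is the OpenBabel atom-contribution
logP; DPSA1 is the difference between the solvent-accessible surface area
of positively and negatively partially charged atoms (Gasteiger charges)
computed by a Shrake–Rupley sweep (96 golden-spiral points per atom,
probe 1.4 Å) over a single OpenBabel-embedded conformer; S_sssN and
S_ssCH2 are Kier–Hall E-state sums over trisubstituted amine nitrogens
and methylene carbons, zero when no such atom exists. These
implementations are documented rather than claimed to agree numerically
with any proprietary engine; what the workflow consumes is the binary
permeable/impermeable classification, which is far less sensitive to
descriptor-level differences than the raw logBB value. Records whose 3D
embedding fails are excluded from the BBB percentages with a logged count.

## Promiscuity alerts

Frequent HTS hitters are flagged by substructure matching against a named
SMARTS catalog (`name<TAB>SMARTS`, `#` comments). The shipped catalog
covers the canonical pan-assay-interference chemotype families — quinones,
catechols, rhodanines and ene-rhodanines, acyclic Michael-acceptor enones,
nitroaromatics, aromatic azo compounds, reactive alkyl halides, thioureas,
phenylhydrazones, isothiazolones, 2-acylphenols — as hand-written,
individually validated patterns; any in-house catalog can be substituted
via `load_catalog()`. The library statistic counts each compound once no
matter how many alerts it matches. Compounds are flagged, never removed:
the workflow scores libraries, it does not edit them.

## Fingerprints and similarity

Three fingerprint families are implemented, all as sparse feature sets so
that Tanimoto similarity needs no bit folding:

* **Circular fingerprints** (`ECFP_2/4/6`, `FCFP_2/4/6`): iterated
  neighborhood hashing to radius = diameter/2. Atom invariants are
  element, heavy degree, hydrogen count, charge, aromaticity and ring
  membership (ECFP) or the six pharmacophoric classes (FCFP). Feature
  identifiers are 32-bit FNV-1a hashes of canonical invariant strings —
  stable across runs and platforms by construction, with no
  process-dependent salt. Because features of iteration *k* are always
  retained alongside iteration *k+1*, the feature set of a smaller
  diameter is contained in that of a larger one; the test suite asserts
  this nesting for every molecule it touches.
* **Structural keys** (`MDL_keys`): the 166-key public key set, via
  OpenBabel's MACCS implementation.
* **Topological pharmacophore fingerprints** (`PH*F{P,C}_{2,3,4}`):
  features are canonicalized n-tuples of pharmacophore feature types plus
  binned shortest-path distances (bins 1, 2–3, 4–6, 7–10, >10). Feature
  typing is rule-based on the molecular graph: donors (N/O with H),
  acceptors (O; non-amide, non-pyrrole N), positive/negative ionizable
  (formal charge after standardization), aromatic systems and aliphatic
  hydrophobic patches collapsed to one representative atom per connected
  component. Three palettes distinguish the dialect families: the base
  six types (`PHFP`/`PHFC`), a coarse four-type palette merging
  donor/acceptor and the ionizable pair (`PHPF*`), and a ring-aware
  seven-type palette adding aliphatic ring systems (`PHRF*`). The final
  letter selects binary (`P`) or count (`C`) form. The palettes are this
  package's documented reading of the dialect family; the tags are kept
  so configurations remain portable. Molecules with fewer features than
  the tuple size get an empty, flagged fingerprint and are excluded from
  fingerprint statistics, with counts logged.

Tanimoto similarity is |A∩B|/|A∪B| for binary features and
Σmin/Σmax for counts; two empty fingerprints are defined to have
similarity 0 (with a warning). Internal diversity is the mean Tanimoto
over all unordered pairs — lower is more diverse — with an unbiased
uniform pair sample (seeded, sample size reported) above a configurable
pair cap.

Default dialects follow the package's benchmark calibration: diversity
uses `ECFP_2`, `MDL_keys`, `PHRFC_2`; similarity uses `ECFP_4`, `ECFP_6`,
`MDL_keys`, `PHFP_3`, with `ECFP_4` the workhorse for cross-library
overlap at Tanimoto ≥ 0.7.

## Diverse subsets, coverage and enrichment

`maxmin_select()` is the greedy MaxMin picker: each pick maximizes its
minimum Tanimoto distance to the already-selected set, ties broken by
input order. The first pick is the compound with maximal mean distance to
all others — deterministic, so repeated runs agree — and can be
overridden explicitly. `coverage_curve()` reports the percentage of
distinct labels (targets or indications) covered by MaxMin subsets of
increasing size, with a seeded random-selection baseline averaged over 10
replicates by default. Label sets drop multi-label records and labels
with fewer than a configurable minimum of members (default 2).

`rank_by_similarity()` orders a library by similarity to a reference
compound (stable tie order, ties marked). `enrichment_curve()` converts a
ranked list plus activity flags into cumulative percent-actives versus
percent-screened; within a tied-score block the curve is the straight
line between block endpoints, because tied compounds cannot be ordered.
The scalar summary is the area under the curve on the unit square by the
trapezoid rule: 0.5 for random ranking, 1 for ideal early recovery.

`substructure_search()` accepts a list of SMARTS patterns; variable-atom
queries are written as a template with `{X}` placeholders expanded by
`expand_variable_query()` into one concrete pattern per allowed element,
a record matching when any instantiation matches.

## Consensus ranking

Each criterion's per-library values are converted to **dense ranks**: the
best value gets rank 1, tied values share a rank, and the next distinct
value gets the previous rank plus one. Within a criterion block the ranks
are summed per library (optionally weighted; equal weights by default)
and the sums are dense-ranked again to give block ranks; block ranks sum
to grand totals whose dense ranks are the final ranking, and an overlap
criterion can be folded into a prior ranking the same way. Dense ranking
at both levels is the tie rule under which the bundled benchmark
profile's reference rank tables are reproduced cell-for-cell, which is
why it is the package's default and only rule. Ranks depend only on value
order, so any strictly monotone transform of a criterion leaves the
result unchanged.

The bundled benchmark (`benchmark_tables()`, `benchmark_consensus()`)
profiles nine commercial screening libraries. One caveat is recorded in
the code: the benchmark's diversity block ranking was originally computed
from unrounded mean similarities, and the three-decimal similarity table
that ships cannot reproduce it under any standard tie rule, so the
reference diversity block ranks are carried as inputs while the
recomputed-from-rounded-values ranks remain available for inspection.
Library size is reported but never ranked: screening capacity is a
budget question, not a quality criterion.

## The GFA engine

`gfa_evolve()` rebuilds models of the logBB family from data. Individuals
are sets of regression terms — plain descriptors or truncated-power
splines ⟨knot − x⟩ / ⟨x − knot⟩ — with coefficients fitted by least
squares and fitness given by Friedman's lack-of-fit score
LOF = (SSE/m) / (1 − (c + d·p)/m)², where m is the sample size, c the
number of basis functions, p the number of parameters and d a smoothness
factor (default 1). Crossover exchanges term sublists, mutation
adds/removes/replaces a term or redraws a spline knot; knots are drawn
from the 5th–95th percentile of the observed descriptor so spline hinges
stay inside data support. Singular least-squares systems penalize the
individual rather than aborting the run. Defaults (population 60, 40
generations, 1–6 terms) recover a planted linear model at n = 200 with
coefficients within ±0.1 and test R² above 0.9.

Preprocessing offers a k-nearest-neighbour outlier filter — mean
Euclidean distance to the k nearest neighbours on standardized
descriptors, removing compounds beyond mean + z·sd of the score
distribution — and random or MaxMin-diversity train/test splits.
`y_scramble()` refits on permuted training responses (10 repeats by
default); near-zero scrambled R² indicates the unscrambled fit is not a
chance correlation. The whole module is deterministic under fixed seeds.

## Synthetic fixtures

`generate_fixture_library()` builds toy libraries with planted categories
— clean drug-like compounds, salt forms, inorganics, mixtures, duplicate
pairs (free base plus salt), and alert-matching chemotypes — as a pure
function of (spec, seed), returning a ground-truth manifest alongside.
The pools are hand-curated SMILES chosen so that each category triggers
exactly its intended pipeline stage: clean compounds pass every filter,
alert compounds each match the shipped catalog, mixture partners exceed
the 6-heavy-atom salt fallback, duplicate pairs collapse under
standardization. What the generator emulates is the *bookkeeping* of
vendor libraries (removal rates, alert fractions, rank arithmetic), not
their chemistry: fixture libraries are tiny, contain no stereochemistry,
no tautomeric ambiguity beyond the planted cases, and no property
distributions resembling a 50,000-compound vendor catalog. Passing tests
therefore certify the machinery — parsing, curation rules, fingerprint
algebra, rank aggregation — on known ground truth; they do not certify
descriptor accuracy on real vendor chemistry.

## Numerical choices and problem sizes

Stochastic steps (pair sampling, random baselines, GA evolution,
Y-scrambling, train/test splits) all take explicit seeds and restore the
caller's RNG state. Ties break by input order everywhere a choice is
needed (MaxMin, similarity ranking, dense ranking via value matching).
The test suite and the reproduction script use deliberately small problem
sizes — fixture libraries of 10–60 compounds, a 200-compound planted
regression with 10 descriptors, 200 enrichment shuffles, 5 scrambling
repeats at reduced GA settings — chosen so the full suite completes in
well under a minute while still giving the stochastic checks comfortable
margins (the planted-recovery R² exceeds 0.99 against a 0.9 criterion;
scrambled R² sits near 0.03 against a 0.3 ceiling).

## Known limitations

* Protonation and tautomer handling are rule-based; exotic acidic/basic
  groups (tetrazoles, N-oxides) and long-range tautomerism are out of
  scope, as is stereochemistry enumeration.
* The DPSA1 conformer comes from a single force-field embedding; no
  conformer averaging is attempted, and absolute logBB values should not
  be compared against other descriptor engines — only the
  permeable/impermeable split is consumed downstream.
* The pharmacophore dialect palettes are documented analogues of a
  vendor family whose exact definitions are not public.
* 3D pharmacophore modelling is deliberately absent; the 2D pharmacophore
  fingerprints are the pharmacophore-flavored similarity surrogate.
* The MaxMin picker is greedy, not optimal; coverage curves inherit its
  deterministic seeding.
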