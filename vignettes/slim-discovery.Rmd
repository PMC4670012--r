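---
title: "Homology-aware discovery of short linear motifs: models and methods"
author: "slimscout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homology-aware discovery of short linear motifs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Short linear motifs (SLiMs) are degenerate sequence patterns of roughly 2-15
residues — a handful of defined positions separated by wildcard spacers —
that mediate transient protein-protein interactions, typically from within
intrinsically disordered regions. Because they are short, they arise readily
by convergent evolution, and pathogens exploit this by mimicking host motifs
(the HIV Vpu phosphodegron targeting the SCF(beta-TrCP) ubiquitin ligase is
the classic example). The same property that makes motifs easy to evolve
makes them statistically treacherous to discover: any short pattern recurs
in a protein set by chance, and shared patterns among homologous proteins
are evidence of common descent, not of convergence.

`slimscout` implements the discovery strategy built around that observation:
look for patterns that recur in proteins that share *no* detectable
homology, score the recurrence against a composition-aware chance model, and
restrict the evidence to the disordered, unannotated, (optionally) locally
unconserved parts of each sequence where functional motifs live. The package
provides three engines:

* `slimfinder()` — de novo discovery of over-represented patterns;
* `qslimfinder()` — discovery restricted to patterns present in one query
  protein (e.g. a viral interactor suspected of mimicry);
* `slimprob()` — occurrence statistics for known motifs supplied as SLiM
  regular expressions (`DSG.{2,3}[ST]`).

## Motif patterns

Patterns use the SLiM regular-expression dialect: fixed residues (`D`),
ambiguity classes (`[ST]`), wildcards (`.`) with optional repeat ranges
(`.{2,3}`), and optional `^`/`$` anchors. Negated classes are rejected.
A pattern with variable wildcard repeats expands into fixed-length
*variants*; `DSG.{2,3}[ST]` has variants of length 6 and 7. Matching is
per-variant: every distinct `(start, end)` span matched by any variant is an
occurrence, overlapping occurrences are all reported, and two variants
matching the same span count once.

The information content of a pattern sums per-position contributions
`1 - log(|class|)/log(20)`: a fixed residue contributes 1, `[ST]`
contributes `1 - log(2)/log(20) ≈ 0.77`, wildcards contribute 0. This
per-position base-20 normalisation is the package's declared definition; it
ranks patterns sensibly by specificity but is not guaranteed to match any
other tool's IC column numerically.

## Masking

Masking removes residues from the *evidence* — masked residues are rendered
`X`, never match a defined position, and are excluded from the effective
composition — but wildcards may still span them, and full sequence length is
retained for start counting (configurable via `problen`).

* **Disorder masking** (`iucut`, default 0.2): residues with a disorder
  score below the threshold are masked. The inequality is strict, so
  `iucut = 0` masks nothing. Scores are consumed, not computed: supply any
  per-residue disorder prediction on `[0, 1]`.
* **Feature masking** (`ftmask`, default `DOMAIN`, `TRANSMEM`): residues
  inside annotated intervals of the listed types are masked — globular
  domains and transmembrane segments are where a match is least likely to be
  a true SLiM.
* **Conservation masking** (off by default): given a user-supplied
  orthologue alignment, per-residue conservation `s_i` is the fraction of
  non-gap orthologue rows matching the query residue. The *relative local*
  conservation is a windowed z-score, `r_i = (s_i - mean_w(s)) / sd_w(s)`
  over a centred window (default 30 columns, sd floored at `1e-6`), and
  residues with `r_i < 0` are masked. The window and threshold are exposed
  because the underlying idea — a residue should be conserved *relative to
  its local context* — admits several formalisations; this windowed z-score
  is the package's documented one. Orthologue retrieval and alignment are
  out of scope by design: alignments are inputs.

Masks combine by union, which makes masking idempotent and
order-independent. Composition is computed per sequence over unmasked
residues (the stricter null for composition-biased proteins); a pooled
dataset-wide composition is available via `compmask = "pool"`.

## Unrelated Protein Clusters

All enrichment statistics count support in *Unrelated Protein Clusters*
(UPCs): connected components of the pairwise-homology graph at
`E < 1e-4`. A motif shared by twenty homologous kinases is one observation,
not twenty.

Homology is scored with true Smith-Waterman local alignment (BLOSUM62,
affine gaps 11/1, via `Biostrings::pairwiseAlignment`) on the raw unmasked
sequences — homology is a property of the whole protein. Scores convert to
E-values with the Karlin-Altschul form `E = K·m·n·exp(-λS)`.

**Calibration of λ and K.** The widely quoted gapped BLOSUM62/11/1 constants
(λ = 0.267, K = 0.041) describe the score statistics of heuristic BLAST
searches against natural-composition databases. Applied to exhaustive
Smith-Waterman scores they understate chance similarity by about an order of
magnitude: in simulation, unrelated uniform-composition 300-mers exceed the
`E < 1e-4` threshold in ~0.13-0.2% of pairs under those constants, which
silently fuses unrelated proteins into common clusters and deflates every
downstream statistic. The package therefore ships constants fitted for its
own scoring regime: Smith-Waterman scores were simulated for thousands of
unrelated random protein pairs at lengths 150, 300 and 500, the exceedance
tail `P(S ≥ x) = K·m·n·e^{-λx}` was fitted by log-linear regression, and the
defaults λ = 0.195, K = 0.010 were chosen slightly conservatively so the
per-pair chance rate at `E < 1e-4` is at or below nominal across that length
range. True homologs are unaffected — even 60%-identical 300-mers score
several hundred, far beyond any plausible threshold. Both constants are
arguments of `pairwise_homology()`; a 12-column tabular hit file from an
external aligner can replace the internal path entirely
(`read_homology_hits()`).

Clustering is plain connected components with deterministic ordering
(clusters by smallest member accession). Singletons are their own UPC.

## Candidate enumeration

`slimbuild_enumerate()` generates candidates from the data rather than from
the pattern space: every word of 2..`max_defined` defined positions actually
present in unmasked sequence, with exact wildcard spacers of
0..`max_wildcard` between consecutive defined positions. Enumeration is
apriori-style — dimers first, filtered by UPC support, then extended
rightwards one defined position at a time — which is valid because extending
a word can never increase its support. Candidates are retained if they occur
in at least `min_upc_support` distinct UPCs (default 3, the smallest count
for which "recurrence in unrelated proteins" is meaningfully convergent;
the threshold is configurable).

Two generalisation passes follow:

* **Variable spacers.** Exact-spacer words with identical defined residues
  that differ in a single spacer by contiguous amounts additionally yield a
  merged `.{m,n}` candidate (the route by which `DSG.{2,3}[ST]`-shaped
  patterns emerge from data). The merged candidate's occurrences are the
  union of its parents'; parents remain candidates in their own right, and
  all of them are scored — the merged pattern simply competes in the
  ranking.
* **Ambiguity** (off by default). A defined position may generalise to its
  residue equivalence group (defaults `{ILMV} {KR} {DE} {ST} {FYW}`) when
  that strictly raises UPC support.

## The chance model

For one sequence with unmasked composition `f` and length `L`, a
fixed-length variant `v` with defined-position classes `C_1..C_k` matches at
a given start with probability `p_v = Π_j Σ_{a∈C_j} f_a`; with
`n_v = max(0, L - len(v) + 1)` candidate starts, the sequence contains the
motif with probability

```
p_seq = 1 - Π_v (1 - p_v)^(n_v)
```

computed in log space. This treats every variant-at-start as an independent
trial. For single-variant patterns that is accurate to well within
Monte-Carlo resolution at moderate `p_v` (the test suite checks 3-SE
agreement against 100,000 simulated sequences per pattern). For
variable-spacer patterns the variants share anchor residues, so the product
over variants overstates `p_seq` somewhat (a few percent relative, in
simulation); the bias is in the conservative direction for enrichment —
expected support is overstated, so significance is understated — and is
accepted as part of the declared model.

A UPC's probability of containing the motif aggregates its members:
`upc_mode = "max"` (default) takes the most motif-prone member, which is
conservative under homology and exactly invariant to adding homolog copies;
`"independent"` treats members as independent trials and is available for
sensitivity analysis.

Support is then a sum of independent Bernoulli trials over clusters — one
per UPC, with heterogeneous probabilities — and the exact Poisson-binomial
distribution is computed by dynamic-programming convolution
(`poisson_binomial_tails()`), giving the expected support `E_UPC = Σ p_i`
and the inclusive tails `p_UPC = P(X ≥ N_UPC)` and
`pUnd_UPC = P(X ≤ N_UPC)`. Both tails include the observed point mass, so
they sum to at least 1 by definition; that double counting is faithful to
the fields' definitions and left as-is.

## Correcting for the searched motif space

A de novo run scores the best of an enormous implicit space of patterns, so
a raw tail probability for the top candidate is meaningless. The corrected
significance uses the Šidák form over the enumerable motif space:

```
Sig = 1 - (1 - p_UPC)^N,   N = Σ_{k=2}^{max_defined} 20^k (max_wildcard+1)^(k-1)
```

(`N ≈ 2.6 × 10^8` at the defaults). `N` counts every pattern the enumeration
*could* have produced, not only those it did: correcting over observed,
support-filtered candidates alone is circular — any rare pattern that
passes the support filter does so precisely because it beat its own null,
so the observed-candidate count dramatically understates the multiplicity
and produces "significant" motifs in pure-noise datasets. With the
full-space correction, null datasets of twenty unrelated 300-mers yield a
significant top motif in well under 5% of runs (checked over 200 seeded
replicates in the test suite), while a motif planted in twelve of them is
recovered at rank one with `Sig` in the 10^-3 regime or better.

Query-restricted discovery changes the space, not the formula: the
candidate set is restricted to patterns with at least one occurrence in the
(masked) query protein, `N` becomes the number of distinct patterns
constructible from the query sequence under the same enumeration limits
(typically a few tens of thousands — this is where the sensitivity gain
comes from), and support is counted over the UPCs *excluding the query's
own cluster*, so the query and its homologs contribute no evidence to
their own hypothesis. Ranking is deterministic: ascending `Sig`, ties broken
by descending IC, then pattern text. `slimprob()` applies no ranking and no
correction — the motifs were chosen by the user, not searched for — and
reports the Table-style summary (`N_Occ`, `N_Seq`, `N_UPC`, `E_UPC`,
`p_UPC`, `pUnd_UPC`, `IC`) in input order.

## Reporting and networks

Every run returns a classed result object whose summary table carries the
standard fields (`Rank`, `Sig`, `Pattern`, `IC`, `N_Occ`, `N_Seq`, `N_UPC`,
`E_UPC`, `p_UPC`, `pUnd_UPC`); `write_tables()` renders the
`main.tsv`/`occ.tsv` pair with exactly the fields that apply to the engine
that produced it (discovery runs have no `Motif`/`E_UPC`/`p_UPC`/`pUnd_UPC`
columns filled; known-motif searches have no `Rank`/`Sig`).

Results map back onto interaction networks: `read_network()` ingests SIF or
edge TSV, `shared_interactors()` performs the hub-intersection reduction
used to assemble discovery datasets, `annotate_results()` sets a
`slim_count` attribute per node and the conventional styling — red diamond
for one motif, dark red for two or more, untouched otherwise — and
`homology_network()` materialises the UPC structure as a graph
(`type = "homology"` edges; its connected components equal the UPC partition
by construction) that `merge_networks()` overlays on the interaction
network (default name `SLiMOutput`). `mark_conserved()` flags occurrences
that survive a conservation-masked rerun as a plain `conserved` column,
leaving shape conventions to the viewer. GraphML output carries all
attributes as plain key-value data rather than any renderer's syntax.

## The synthetic benchmark generator

`generate_dataset()` builds the fixtures every test and the acceptance
script run on, and its defaults are the package's declared study
conditions: 20 unrelated sequences of 300 residues drawn i.i.d. from a
uniform amino-acid composition; when a motif is planted, an exact count
`round(planted_fraction × n_seq)` of sequences (default 12 of 20) receive
one instance at a uniform position, with class positions sampled uniformly
within the class and wildcard positions from the background. Optional
homolog copies are substitution-only at a stated identity (default 95%), so
planted coordinates survive and UPC tests stay interpretable. Disorder
tracks are Beta(2,2) baseline — about 10% of residues fall below the 0.2
masking threshold — with planted spans raised to 0.5-0.95, mimicking motifs
residing in disordered regions; orthologue alignment rows, when requested,
are ungapped mutated copies with planted spans conserved exactly.

What the generator does *not* emulate: realistic amino-acid composition,
indels, length variation within families, compositional bias (low-complexity
regions), or correlated disorder structure. Passing tests therefore
demonstrate the statistical machinery — calibration under the declared null,
recovery of convergent signal, homology invariance — not performance on real
proteomes, where masking quality and dataset construction dominate.

## Numerical and design choices

* All products over many positions/variants/clusters run in log space
  (`log1p`/`expm1`); probabilities are clamped to `[0, 1]`.
* The Poisson-binomial DP is exact (no Poisson or normal approximation);
  equality with brute-force `2^n` enumeration is asserted to `1e-12` for
  `n ≤ 12`.
* Coordinates are 1-based inclusive everywhere; conversion happens only at
  format boundaries.
* Candidate start counts use the full sequence length (`problen = "full"`):
  masking already suppresses `p_v` through the defined positions, and
  removing starts as well would double-count the penalty. `problen =
  "masked"` is available.
* Determinism: identical dataset + configuration give byte-identical
  results apart from the run timestamp; cluster ordering, candidate
  ordering and tie-breaks are all fully specified.
* Sequences shorter than 10 residues are skipped (with a warning) in
  homology scoring — local-alignment statistics are meaningless there; such
  sequences become singleton UPCs.
* The unknown residue `X` never matches a defined position, matches
  wildcards, and is excluded from composition estimates.
* Problem sizes in the test suite — 20×300-mer fixtures, 200 null
  replicates, 20 recovery replicates, 100,000-sequence Monte-Carlo
  calibration — were chosen as the smallest sizes at which the checked
  properties are statistically resolvable.

## Known limitations

* The significance correction assumes the unambiguous base space; enabling
  ambiguity enlarges the effective space slightly beyond `N`, making
  reported `Sig` marginally anticonservative in that mode.
* `p_seq` overstates occurrence probability for variable-spacer patterns
  (conservative direction; see above) and ignores clumping of
  self-overlapping patterns.
* The internal aligner's E-value calibration targets unrelated sequences of
  roughly uniform composition at lengths 150-500; for strongly biased
  compositions or very long proteins, supply external hits via
  `read_homology_hits()`.
* Conservation masking presumes a trustworthy, query-complete alignment; a
  query-only alignment disables it with a warning rather than failing the
  run.
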