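# slimscout

Homology-aware discovery of short linear motifs (SLiMs) in protein
sequences.

SLiMs are short (2–15 residue), degenerate sequence patterns — a few defined
positions separated by wildcard spacers, e.g. the phosphodegron
`DSG.{2,3}[ST]` — that mediate protein–protein interactions, typically from
intrinsically disordered regions. Because they are short, they evolve
convergently, and a pattern recurring in proteins that share **no** common
ancestry is evidence of function. `slimscout` is for researchers who have a
set of proteins suspected of sharing an interaction mechanism (for example,
the interactors of a common hub in a PPI network) and want to know which
patterns recur there more often than chance allows.

## The model

Evidence is restricted by **masking**: residues that are predicted ordered
(disorder score < `iucut`, default 0.2), fall inside annotated
`DOMAIN`/`TRANSMEM` features, or (optionally) are unconserved relative to
their local alignment context are replaced by `X` and cannot support a
defined motif position.

Proteins are clustered into **Unrelated Protein Clusters (UPCs)** —
connected components of the pairwise Smith–Waterman homology graph at
Karlin–Altschul `E < 1e-4` — and all support is counted per cluster, so
homologs contribute one observation, not many.

For a motif with fixed-length variants *v* and defined-position classes
*C₁..C_k*, a sequence with unmasked composition *f* and length *L* contains
the motif with probability

    p_seq = 1 − Π_v (1 − Π_j Σ_{a∈C_j} f_a)^(L − len(v) + 1)

A UPC inherits the maximum *p_seq* of its members; support across clusters
is then Poisson-binomial, computed exactly by dynamic programming, giving
the expected support `E_UPC = Σ p_i` and tails `p_UPC = P(X ≥ N_UPC)`,
`pUnd_UPC = P(X ≤ N_UPC)`. De novo discovery corrects the tail for the full
enumerable motif space via the Šidák form
`Sig = 1 − (1 − p_UPC)^N`, with
`N = Σ_k 20^k (max_wildcard+1)^(k−1) ≈ 2.6 × 10⁸` at the defaults.

Three engines share this machinery:

| function        | what it does                                            |
|-----------------|---------------------------------------------------------|
| `slimfinder()`  | de novo discovery of over-represented patterns          |
| `qslimfinder()` | discovery restricted to patterns in one query protein; statistics exclude the query's own UPC |
| `slimprob()`    | occurrence/enrichment statistics for known motifs       |

## A worked example

Generate a synthetic benchmark — 20 unrelated 300-residue proteins, with the
degron core `DSG` planted in 12 of them in a disordered region — and run de
novo discovery:

```r
library(slimscout)

ds  <- generate_dataset(20, planted_pattern = "DSG",
                        planted_fraction = 0.6, seed = 1)
res <- slimfinder(ds)
res
#> slimfinder run: 20 proteins in 20 UPCs; 2733 motif(s) scored
#>   correction space: 263,593,200 patterns
#>   significant at sig < 0.05: 1
#>  rank       sig pattern ic n_occ n_seq n_upc
#>     1 4.175e-07     DSG  3    13    13    13
```

The planted motif is recovered at rank 1: it occurs in 13 of 20 unrelated
clusters (12 planted instances plus one chance occurrence) against an
expectation of ~0.7, and survives a correction over the 2.6 × 10⁸ patterns
the search could have produced. Roughly 2,700 candidate patterns found in
≥3 UPCs were scored; none of the background ones comes close
(`summary(res)` lists them all).

Searching known motifs works on the same dataset:

```r
rp <- slimprob(ds, "DSG,DSG.{2,3}[ST]")
rp
#> slimprob run: 20 proteins in 20 UPCs; 2 motif(s) scored
#>          motif       pattern    ic n_occ n_seq n_upc  e_upc     p_upc p_und_upc
#>            DSG           DSG 3.000    13    13    13 0.6693 1.584e-15    1.0000
#>  DSG.{2,3}[ST] DSG.{2,3}[ST] 3.769     3     2     2 0.1351 7.859e-03    0.9997
```

Here `DSG` is planted and massively enriched (13 unrelated proteins
observed, 0.67 expected, `p_UPC ≈ 2e-15`); the stricter phosphodegron
matches only chance-level background occurrences of its longer pattern.
`write_tables(rp, "out/")` writes the standard `main.tsv`/`occ.tsv` result
tables, and networks can be read (SIF), annotated (red diamonds for
motif-bearing nodes, dark red for 2+ motifs) and written to GraphML via
`read_network()`, `annotate_results()`, `homology_network()`,
`merge_networks()` and `write_network()`.

A thin command-line front end is installed with the package
(`exec/slimscout`): subcommands `slimfinder`, `qslimfinder`, `slimprob`,
`annotate` and `fixtures` with flags mirroring the configuration keys
(`--iucut`, `--ftmask`, `--maxdef`, `--maxwild`, `--minupc`, `--sigcut`,
`--upc-mode`, `--seed`, `--custom key=value[,...]`).

See the methods vignette (`vignettes/slim-discovery.Rmd`) for the full
model, the E-value calibration of the internal aligner, and the design
decisions.

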