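# bbcscreen

Large-scale identification of protease substrates by the bead-based
cleavage (BBC) strategy, as an analysis pipeline for R.

In a BBC screen a whole cell proteome is covalently immobilized on beads
and incubated with a purified protease — caspase-3, the executioner
protease of apoptosis, is the reference application. Fragments of genuine
substrates are cut free of the beads, trypsin-digested and quantified by
heavy/light (H/L) dimethyl ratios against a protease-free control arm, so
that protease-released peptides stand out from the background shed by trace
endogenous proteases. `bbcscreen` is for proteomics analysts working with
such screens (or evaluating their statistics): it provides the quantified
peptide table I/O, the substrate-calling criteria, the cleavage-site and
motif analysis, the reference-set overlap arithmetic, and an end-to-end
simulator of the experiment with planted ground truth.

## The method

* **Dual-threshold substrate calling.** Protein *p* is called a substrate
  iff the number of distinct peptide sequences from *p* with
  log2(H/L) ≥ *c* is at least *m*; the optimized operating point is
  *c* = 1.8, *m* = 2. Calls with ≥ 5 supporting peptides are *hot*, 2–4
  *warm*. Threshold optimization curves (`known_percentage_by_ratio_cutoff`,
  `known_percentage_by_count`) score cutoffs by the percentage of known
  substrates they retain, against a curated database such as CASBAH.
* **Cleavage-site readout from semi-tryptic termini.** Every non-terminal
  up-regulated peptide boundary is a cleavage site: P1 ∈ {K, R} with
  non-proline P1′ is tryptic, P1 = D is caspase (aspartate) cleavage, the
  rest is other proteolysis. Aspartate sites are classified into caspase
  motif families by the P4–P1 window (DXXD, with P3 sub-families
  DEXD/DLXD/DDXD) and summarized as a P5..P5′ position frequency matrix for
  sequence logos.
* **Overlap statistics.** Exact set arithmetic (intersection, union,
  percent-of-A, Jaccard %) between call sets and reference lists, overall
  and per hot/warm tier, including reconstruction from printed counts via
  inclusion–exclusion (`overlap_from_counts`).
* **Synthetic degradome.** `simulate_experiment()` generates a random
  library, plants DXXD-family sites in a substrate subset, samples bead
  attachment per primary amine, applies paired background cuts plus treated
  arm protease cuts, releases attachment-free fragments, digests with the
  trypsin KR/P rule, and emits a quantified table plus ground truth — the
  test bed for the calling criteria. See the methods vignette
  (`vignettes/bbc-screening.Rmd`) for the model and parameter rationale.

## Worked example

```r
library(bbcscreen)

sim <- simulate_experiment(sim_params())   # 300 proteins, seed 42
sim$table
#> Quantified peptide table: 1613 peptides, 82 proteins
#>   log2(H/L): median 0.51, 45.1% above 1

calls <- call_substrates(sim$table, log2_cutoff = 1.8, min_peptides = 2,
                         known = sim$truth$substrates)
calls
#> Substrate calls: 32 (log2 >= 1.80, >= 2 peptides)
#>   hot: 29, warm: 3
#>   known substrates: 32 (100.0%)

unlist(call_performance(calls, sim$truth))
#>  precision     recall    n_calls     n_true
#>  1.0000000  0.7804878 32.0000000 41.0000000

sites <- extract_sites(sim$table, sim$proteome, log2_cutoff = 1.8)
summarize_sites(sites, substrates = calls$accession)
#> Cleavage sites: 446 unique
#>   tryptic 349 (78.3%), aspartate 93 (20.9%), other 4 (0.9%)
#>   DXXD motifs among D sites: 100.0% (DEXD 54, DLXD 0, DDXD 22, other DXXD 17)
#>   substrates with >= 1 D site: 31 of 32 (96.9%)
```

Reading: 45% of simulated peptides are up-regulated; the dual thresholds
call 32 of 41 planted substrates with no false positives (precision 1.0,
recall 0.78 — recall is bounded by substrates whose fragments never escape
the beads); most read-out cleavage sites are tryptic because the protease
fragments are re-digested, and the aspartate minority pinpoints the planted
caspase sites.

A command-line front end over the same functions lives in `inst/cli/bbc.R`
(`simulate`, `call`, `sites`, `overlap` subcommands).

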