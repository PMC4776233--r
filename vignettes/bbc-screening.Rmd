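---
title: "Bead-based cleavage screening: model, simulator and calling criteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bead-based cleavage screening: model, simulator and calling criteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbcscreen)
```

## The experiment this package models

In a bead-based cleavage (BBC) degradomics screen, a whole cell proteome is
covalently immobilized on activated beads and incubated with a purified
protease (the reference application is caspase-3, the executioner protease
of apoptosis). Only fragments of genuine substrates are cut free of the
beads; they are collected, digested with trypsin to MS-friendly peptides,
and quantified against a protease-free control arm via heavy/light (H/L)
dimethyl labels, with H the treated arm. Because trace endogenous proteases
on the beads also release background fragments in both arms, a peptide's H/L
ratio is what separates protease-released material (high ratio) from
background degradation (ratio near 1).

Three downstream analyses follow, and `bbcscreen` implements all of them:

1. **Substrate calling.** A protein is called a substrate when at least
   `min_peptides` distinct peptide sequences reach the ratio cutoff. The
   standard operating point is `log2(H/L) >= 1.8` with `>= 2` peptides;
   calls with `>= 5` supporting peptides are tiered *hot*, 2–4 *warm*.
   `known_percentage_by_ratio_cutoff()` and `known_percentage_by_count()`
   reproduce the curves used to optimize those two thresholds against a
   curated known-substrate database (CASBAH-style list).
2. **Cleavage-site readout.** Trypsin cleaves after K/R unless the next
   residue is proline, so any up-regulated peptide terminus that is *not*
   explained by trypsin or by a protein end reads out a protease cleavage
   site. Each non-terminal peptide yields up to two sites (N-side at
   `start − 1`, C-side at `end`); sites with P1 ∈ {K, R} and non-proline
   successor are attributed to trypsin, P1 = D to the caspase, and the rest
   to other proteolysis. Aspartate sites are scanned for the caspase DXXD
   motif (P4 = P1 = D) and its P3-defined sub-families DEXD/DLXD/DDXD, and
   summarized as a position frequency matrix over the P5..P5' window for
   logo rendering.
3. **Overlap statistics.** Calls are compared against reference accession
   sets (known substrates; in vivo apoptosis degradome lists) with exact
   set arithmetic: intersection, union, percent-of-A and Jaccard
   percentage, overall and per tier.

## The synthetic degradome generator

Raw data from published BBC screens are not available in reusable form, so
the package ships a generative model of the experiment
(`simulate_experiment()`) that preserves its statistical structure and
keeps the ground truth, enabling parameter-recovery tests of the calling
criteria.

Per protein, the simulator:

1. draws a random sequence from an average proteome composition
   (`aa_background()`), length ~ Normal(`length_mean`, `length_sd`)
   truncated at 50 residues;
2. with probability `substrate_fraction`, plants cleavage sites: the count
   is a shifted Poisson with mean `sites_per_substrate_mean` and each site
   overwrites the P4–P1 window with a motif drawn from `motif_weights`
   (so every planted P1 is D);
3. samples bead attachments independently at each primary amine — the
   N-terminal residue and every lysine — with probability `coupling_prob`,
   mirroring amine-directed coupling chemistry without modelling kinetics;
4. cuts: the control arm receives background cuts at `background_rate` per
   peptide bond, positionally uniform (background proteolysis has no stated
   specificity); the treated arm receives the *same* background cuts (a
   paired design, which is what centres the background log2 ratio at 0)
   plus each planted site with probability `cleavage_efficiency`;
5. releases every fragment that contains no attachment (an unattached,
   uncut protein is released whole — the wash background), digests released
   fragments with trypsin (KR/P rule, up to `max_missed_cleavages` missed
   cleavages) and keeps peptides of `min_pep_len`–`max_pep_len` residues;
6. quantifies each distinct peptide: one abundance unit per released
   occurrence, the simplest model that makes ratios a deterministic
   function of release events before noise. Peptides present in both arms
   get `log2(H/L) = log2(n_treated/n_control) + N(0, log2_bg_sd)`. Peptides
   detected only in the treated arm — the substrate signal — draw
   `log2(H/L) ~ N(log2_sub_mean, log2_sub_sd)` capped at 10: in a real
   dimethyl experiment the light channel of a treated-only peptide is
   noise-floor intensity, giving a large but finite, dispersed ratio, and
   the cap keeps the table finite while preserving "strongly up-regulated"
   status under any cutoff up to 10. Control-only peptides (destroyed by a
   planted cut) get the mirrored treatment floored at −10.

The output is a quantified-peptide table with per-arm occurrence counts and
a `caspase_released` provenance flag, the edited protein library, and a
`ground_truth()` object (substrate accessions, planted P1 positions,
background-degraded proteins).

### Defaults and why

| parameter | default | rationale |
|---|---|---|
| `n_proteins` | 300 | yields ~10^3–10^4 quantified peptides in seconds |
| `length_mean`, `length_sd` | 400, 120 | typical MS-observable protein lengths |
| `substrate_fraction` | 0.15 | a permissive protease with a broad in vitro substrate range |
| `sites_per_substrate_mean` | 4 | see the release-probability argument below |
| `motif_weights` | DEVD .4, DELD .2, DDXD .2, DQXD .2 | canonical caspase-3 preferences, strongest mass on DEVD |
| `coupling_prob` | 0.2 | several attachment points per average protein, none for a short fragment, matching the observed 60–70% capture without modelling kinetics |
| `background_rate` | 0.001 /bond | sub-one background cut per protein; trace endogenous activity |
| `cleavage_efficiency` | 0.9 | 2 h incubation with excess protease |
| `log2_bg_sd`, `log2_sub_mean`, `log2_sub_sd` | 0.4, 3.0, 0.8 | background ratios tight around 0; substrate peptides ~8-fold up with realistic spread |
| `min_pep_len`–`max_pep_len` | 7–35 | standard identifiable-peptide window |
| `max_missed_cleavages` | 2 | standard search setting |

The number of planted sites interacts strongly with the coupling density: a
fragment is released only if it carries no attachment, so the release
probability of a fragment with *k* lysines is about `0.8^k`. With 400-residue
proteins (~23 lysines) and mean 4 sites, fragments average ~80 residues
(~5 lysines), giving per-fragment release probability ≈ 0.3 and a ≥ 75%
chance that a substrate sheds at least one fragment — the regime in which a
screen of this design is informative. With only 1–2 sites per substrate,
fragments stay long, rarely escape the beads, and no threshold choice can
recover the planted substrates; that is a property of the chemistry being
modelled, not of the caller. Under these defaults roughly 40–50% of
quantified peptides are up-regulated (`log2 > 1`), matching the regime
reported for caspase-3 BBC screens.

### What the simulator does not emulate

No isotope envelopes, retention times, spectra, identification error or
FDR, peptide-level detectability bias (flyability), protein abundance
differences, shared (non-proteotypic) peptides, or post-translational
modifications. Passing parameter-recovery tests therefore shows the
criteria behave correctly on an idealized screen with known truth — not
that real screens achieve those precision/recall values, since real data
add identification noise and abundance bias the generator omits.

## Numerical and design choices

* **Cutoff semantics.** The ratio cutoff is inclusive (`log2 >= 1.8`); the
  conventional up-regulation standard is strict (`log2 > 1`). Both are
  deliberate and documented to avoid off-by-one ambiguity.
* **Distinct-sequence counting.** Supporting peptides are counted as
  distinct sequences per protein; charge states, modified forms and
  repeated locations of the same sequence collapse.
* **Terminal peptides.** A peptide flush with the protein N-terminus (or
  C-terminus) yields no site on the flush side, but the other side still
  counts — terminal-ness silences one boundary, not the peptide.
* **Site deduplication and tie-breaks.** Sites are unique per
  (protein, position); a boundary read from both a peptide's N-side and
  another's C-side keeps the N-side record, a value-based rule that makes
  the output invariant to input order. A K/R site is attributed to trypsin
  even when the protease could also have produced it, mirroring how such
  screens report the tryptic majority.
* **Multi-position peptides.** A peptide matching its protein at several
  positions takes the smallest start, with a warning.
* **Empty denominators.** A cutoff-curve point or tier with an empty
  denominator reports `NA` with a message — never a silent 0, since 0% is a
  real observation.
* **Identifier matching.** Overlap statistics use exact string matching
  after whitespace stripping; mapping between identifier namespaces is a
  curation problem upstream of this package.
* **The "overlap ratio" denominator.** Between a 1159-protein call set and
  a 1064-protein in vivo degradome with 509 shared, the published 29.7%
  corresponds to the Jaccard denominator (1159 + 1064 − 509 = 1714); the
  package labels the quantity `jaccard_pct` and additionally reports
  percent-of-A, under which the same comparison gives 43.9%.

## Worked example

```{r example}
sim <- simulate_experiment(sim_params())   # 300 proteins, seed 42
sim$table
calls <- call_substrates(sim$table, log2_cutoff = 1.8, min_peptides = 2)
calls
unlist(call_performance(calls, sim$truth))

sites <- extract_sites(sim$table, sim$proteome, log2_cutoff = 1.8)
summarize_sites(sites, substrates = calls$accession)
```

The bundled `caspase_context_examples()` embeds three canonical caspase-3
cleavage contexts (PAK2 D148 and D212, BCAS2 D14) in synthetic carrier
sequences; extracting sites from their reported semi-tryptic peptides
recovers one aspartate and one tryptic boundary per peptide, with the
expected dot-notation contexts:

```{r contexts}
ex <- caspase_context_examples()
extract_sites(ex$table, ex$proteome, log2_cutoff = 1.8)
```

## Problem sizes

The shipped defaults (300 proteins, ~1500 quantified peptides) run the full
pipeline in a few seconds; the test suite's property checks use 200 random
digestion cases and 10 independent 150-protein screens for the
threshold-optimization trend, sizes at which every check is comfortably
stable across seeds.

## Limitations

Recall is bounded by the chemistry: substrates whose fragments all carry an
attachment are invisible, so the caller's recall measures the released
fraction as much as the thresholds. The enzyme classification is
deliberately simple (P1/P1' rules) and will mislabel a protease cut at K/R
as tryptic. Motif families cover only the P3-defined DXXD sub-families;
P'-side specificity is summarized only through the frequency matrix.
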