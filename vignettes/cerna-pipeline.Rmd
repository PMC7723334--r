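---
title: "Inferring ceRNA networks from multi-species expression profiles"
author: "cernet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring ceRNA networks from multi-species expression profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernet)
```

## The problem

Competing endogenous RNAs (ceRNAs) are transcripts — long non-coding RNAs
(lncRNAs) or circular RNAs (circRNAs) — that share miRNA recognition
elements with an mRNA and compete for the same miRNA, de-repressing the mRNA
when the sponge is abundant. A common experimental design profiles four RNA
species (lncRNA, circRNA, miRNA, mRNA) on a shared sample set across a
parental cell line and resistant derivatives (three conditions, three
biological replicates each) and asks which sponge–miRNA–mRNA triplets are
consistent with ceRNA regulation, which genes the differential lncRNAs may
regulate in *cis* or in *trans*, and which transcription factors may drive
the differential lncRNAs.

`cernet` implements that whole inference chain as composable, tested
functions, together with a synthetic-data generator that plants known
structure so every stage can be validated end to end without external data.

## The inference chain

1. **Differential expression.** Per species and comparison (each resistant
   condition against the parental line), an unpaired two-sided Student's
   t-test with pooled variance (`differential_test()`; Welch optional —
   at n = 3 per group the pooled test is the classical default). Fold
   changes are signed ratios, never inside (−1, 1): log2fc +1 is FC +2.
   The default gates (`threshold_policy()`) are |FC| ≥ 2 with
   Benjamini–Hochberg adjusted p < 0.05 for lncRNA and mRNA, |FC| ≥ 2 with
   raw t-test p < 0.05 for circRNA, and |FC| ≥ 1.5 with q < 0.05 for miRNA
   (the laxer ratio reflecting the small number of differential miRNAs on
   such platforms). Adjustment families are per species × comparison —
   pooling across platforms would mix unrelated test families. The *merged*
   group is the direction-consistent intersection of the two comparisons:
   a feature must be differential in both with the same direction.
   Conflicting directions are excluded; this matches reporting merged
   up- and down-regulated counts separately.

2. **Co-expression networks.** Pearson correlation between differential
   features of two species, with the two-sided p-value from
   $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom. An edge
   requires |r| ≥ 0.99 and p < 0.05 (defaults, configurable). miRNA–target
   edges are restricted to negative correlations; lncRNA/circRNA–mRNA edges
   keep both signs with the sign recorded. By default correlations run over
   the six samples of the comparison at hand (merged-group networks use all
   nine) — which samples enter the correlation is genuinely open in such
   designs, so it is a config switch (`correlation_samples`).

3. **miRNA target sites.** A transparent canonical-seed scanner
   (`find_seed_sites()`) replaces alignment/energy tools: sites are
   classified 8mer > 7mer-m8 > 7mer-A1 > 6mer by Watson–Crick
   complementarity to miRNA positions 2–8, with class weights 4/3/2/1 and
   a default minimum class of 7mer-A1. Each occurrence of the 6mer core
   anchors at most one site, reported at its highest class. No
   thermodynamic duplex energy or conservation scoring is attempted; the
   module boundary is such that an external predictor could be swapped in.

4. **ceRNA triplets.** `assemble_triplets()` emits (sponge, miRNA, mRNA)
   exactly when (i) a positive sponge–mRNA co-expression edge exists,
   (ii) the miRNA has predicted sites in both the sponge and the mRNA
   3'UTR, and (iii) negative miRNA–sponge and miRNA–mRNA edges pass the
   same correlation gate. The miRNA's own differential direction is
   recorded but not gated — ceRNA networks legitimately contain both up-
   and down-regulated miRNAs.

5. **Cis/trans lncRNA targets and TF networks.** Cis candidates are
   protein-coding genes within 10 kb of a differential lncRNA, classified
   with the precedence intronic > sense > antisense > divergent > neighbor
   ("divergent" covers head-to-head/bidirectional arrangements with
   TSS-to-TSS gap ≤ 1 kb), then filtered by positive r ≥ 0.99 with
   Holm-adjusted p < 0.5 across the candidate family (the permissive 0.5
   is this pipeline's convention for the cis/trans correlation filter; it
   is a default, not hard-coded). Trans candidates are co-expressed
   lncRNA–mRNA pairs whose sequences share a high-identity segment:
   Smith–Waterman local alignment (match +1, mismatch −1, gap −2) followed
   by extraction of the best-scoring contiguous segment with identity
   ≥ 0.9 and length ≥ 20 — gating on the refined segment rather than the
   full optimum matters because the optimal alignment can dilute an exact
   core with low-identity extensions. TF prediction scans the promoter
   window (2000 bp upstream to 500 bp downstream of the lncRNA TSS,
   strand-aware) with user-supplied position weight matrices (+1
   pseudocount, log2-odds against uniform background, both strands, hits
   at ≥ 0.8 of the maximum attainable score).

6. **Enrichment.** Hypergeometric upper-tail over-representation of
   differential mRNAs against GMT collections, BH-adjusted within each
   namespace (BP/CC/MF/pathway separately), with top-30 reporting per
   namespace. The background defaults to all genes on the platform. Terms
   are flat sets; no GO-hierarchy propagation is modelled.

`run_pipeline()` orchestrates all stages, writes TSV outputs plus a JSON
manifest with stage fingerprints, output checksums and row counts, skips
stages whose inputs are unchanged on a rerun, and is bit-identical for a
fixed (config, seed).

## What the generator emulates

`generate_dataset()` builds a complete fake study: three conditions × three
replicates, four species, a single linear chromosome `chrS` carrying all
features, sequences, gene sets, and JASPAR-style motifs.

* **Expression** is per-feature baseline `N(8, 1.5)` plus condition effect
  plus Gaussian replicate noise on the log2 scale — the standard microarray
  log-intensity convention. Defaults: effect 2 log2 units, noise sd 0.25
  (replicate-level variance of such arrays is rarely published; 0.25 is a
  calibration choice giving clearly detectable but not trivial signal at
  n = 3).
* **Planted correlated pairs** (triplet legs, cis pairs) share a latent
  condition-driven profile with per-sample jitter (sd 0.25) plus small
  private noise (sd 0.04), giving within-pair r ≈ 0.995–0.999 — above the
  0.99 gate but below 1, so the correlation-p code paths are exercised.
  The jitter also keeps distinct planted units identifiable: members of
  *different* units share the condition profile, and their cross-unit
  correlation ≈ var_cond/(var_cond + jitter²) ≈ 0.94 sits clearly below
  the gate. At n = 9 the sampling distribution of r is wide, so an
  occasional cross-unit combination still slips over 0.99; with the
  additional seed-site requirement this produces at most a rare spurious
  triplet.
* **Planted differential features**: structural members (triplet sponges ↑,
  mRNAs ↑, miRNAs ↓; cis pairs; motif-bearing lncRNAs) respond in both
  resistant conditions. `de_fraction` adds generic background DE on top,
  split 2:1:1 between shared and condition-specific responses so each
  resistant line carries its own signature — this is what makes principal
  components separate all three conditions, as in the emulated design.
* **Geometry**: mRNA genes (2 kb, two exons flanking a 1 kb intron),
  lncRNAs (400 nt), miRNA loci (22 nt) are placed non-overlapping with a
  12 kb default spacing; planted cis lncRNAs are placed relative to their
  partner gene in each of the five positional categories; circRNAs are
  subsequences of host genes (back-splicing is not modelled). Planted
  triplets get an exact 8mer site (reverse complement of seed positions
  2–8 plus A) written into the sponge body and the mRNA 3'UTR; lncRNA
  sponges additionally carry an exact 30-nt copy of their partner 3'UTR as
  planted trans signal; motif consensus sequences are written into
  promoter windows upstream of the lncRNA body.

Features real data has that the generator does not: probe effects, batch
and dye biases, heavy-tailed noise, correlated nulls, isoform structure,
genome-wide sequence composition. Passing tests therefore demonstrate that
the inference chain recovers the structure it is designed to detect under
its stated model — not that the thresholds are optimal for any particular
laboratory dataset.

## Numerical and design choices

* **Normalisation.** `quantile_normalize()` (ties averaged) is the
  package's stand-in for platform-level normalisation of unnormalised
  input. The pipeline does **not** re-apply it to the generator's output:
  those values are already final log2 intensities, and re-normalising
  small panels in which a sizeable fraction of features truly changes
  (e.g. a 60-feature miRNA panel with 13% strongly down-regulated)
  visibly inflates within-group variance and compresses effects — the
  classic failure mode of quantile normalisation when its
  "most-features-unchanged" assumption is violated. `median_center_rows()`
  is provided for heatmap-style displays.
* **Degenerate tests.** Zero pooled variance with equal means gives p = 1;
  with unequal means p = 0 and a degeneracy flag. Constant vectors are an
  error for correlation (undefined), and features constant across the
  correlated samples are skipped in network construction.
* **Determinism.** One master seed; per-species child seeds at fixed
  offsets; UPGMA (`stats::hclust`, average linkage) and all orderings are
  deterministic, with ties broken lexically. The generator restores the
  caller's RNG state. Expression values are rounded to 10 decimal places
  so the TSV serialisation round-trips exactly.
* **Promoter windows.** For a + feature the window is genomic
  [TSS−2000, TSS+500); for a − feature the mirror [TSS−500, TSS+2000),
  reverse complemented. Windows are clipped at chromosome ends with a
  flag.
* **Local alignment.** `local_align()` wraps the Smith–Waterman
  implementation in `Biostrings::pairwiseAlignment` under the stated
  scores; a non-positive optimum returns the empty alignment. The reported
  alignment is the library's deterministic optimum; when several optima
  exist the choice among them does not affect the score/identity/length
  gates the pipeline consumes.
* **Problem sizes.** Module tests run on a reduced study (40/30/20/60
  features, 4 triplets, 5 cis pairs) chosen so the whole suite exercises
  every stage in a couple of minutes; the acceptance checks use the
  default scale (120/100/60/200 features, 8 triplets, 10 cis pairs, 4
  motifs), the package's reference study condition.

## Known limitations

* The seed scanner is deliberately simpler than alignment/energy-based
  miRNA target predictors; no 3'-compensatory sites.
* Cis classification is coordinate-based only; "intergenic" positional
  subclasses of lncRNAs are not separately modelled beyond the `neighbor`
  relation.
* Enrichment treats terms as flat sets with a platform background.
* The triplet assembly uses hard gates; statistical ceRNA tests
  (hypergeometric shared-site tests, partial/sensitivity correlation) are
  intentionally out of scope.
* At n = 9 samples a |r| ≥ 0.99 gate is extremely stringent for null pairs
  (tail probability < 1e−4) but has wide sampling variability for truly
  correlated pairs; bounds on recovery rates are calibrated accordingly.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipeline_config(simulate = simulation_config(seed = 1),
                       out_dir = "cernet_run")
manifest <- run_pipeline(cfg)
names(manifest$stages)
#> [1] "simulate"  "de"        "coexpress" "targets"   "cerna"
#> [6] "cis"       "trans"     "tf"        "enrich"
```

The results directory contains `data/` (the generated study), `de/`,
`coexpression/`, `targets/`, `cerna/`, `regulation/`, `enrichment/` TSV
tables and `manifest.json`.
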