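# cernet

Competing-endogenous-RNA (ceRNA) network inference from multi-species
expression profiles.

## What it does, and for whom

Transcriptome studies of drug resistance commonly profile four RNA species
— lncRNA, circRNA, miRNA and mRNA — on a shared sample set across a parental
cell line and resistant derivatives (three conditions × three biological
replicates), then chain together differential expression, co-expression
networks, miRNA target prediction, ceRNA triplet assembly, cis/trans lncRNA
target prediction, transcription-factor prediction and gene-set enrichment.
`cernet` implements that chain as tested, composable R functions for
computational biologists who want each step explicit, deterministic and
verifiable, plus a synthetic-data generator with planted ground truth so the
whole pipeline can be validated end to end without any downloads.

## The core model

* **Differential expression**: per species and comparison, unpaired
  Student's t (pooled variance; Welch optional), signed fold changes
  (FC = 2^log2fc for log2fc ≥ 0, −2^(−log2fc) otherwise). Default gates:
  |FC| ≥ 2 with BH-adjusted p < 0.05 (lncRNA, mRNA), |FC| ≥ 2 with raw
  p < 0.05 (circRNA), |FC| ≥ 1.5 with q < 0.05 (miRNA). The *merged* group
  is the direction-consistent intersection of the two comparisons.
* **Co-expression edge**: Pearson |r| ≥ 0.99 with two-sided
  p < 0.05 from t = r·√((n−2)/(1−r²)); miRNA–target edges must be negative.
* **ceRNA triplet** (sponge, miRNA, mRNA): positive sponge–mRNA edge,
  predicted seed sites (8mer/7mer-m8/7mer-A1/6mer canonical classes,
  default minimum 7mer-A1) of the shared miRNA in *both* sponge and mRNA
  3'UTR, and negative miRNA–sponge and miRNA–mRNA edges.
* **Cis relation**: protein-coding gene within 10 kb of a lncRNA,
  classified intronic > sense > antisense > divergent > neighbor, filtered
  by positive r ≥ 0.99 and Holm-adjusted p < 0.5.
* **Trans hit**: co-expressed lncRNA–mRNA pair whose Smith–Waterman local
  alignment (match +1, mismatch −1, gap −2) contains a segment with
  identity ≥ 0.9 and length ≥ 20.
* **TF edge**: PWM hit (log2-odds ≥ 0.8 of the maximum attainable score,
  both strands) in the lncRNA promoter window [TSS−2000, TSS+500).
* **Enrichment**: hypergeometric upper tail P(X ≥ k) against a platform
  background, BH-adjusted within namespace (BP/CC/MF/pathway).

See `vignettes/cerna-pipeline.Rmd` for assumptions, parameter rationale and
limitations.

## Worked example

```r
library(cernet)

ds <- generate_dataset(simulation_config(seed = 1))
b  <- ds$bundle
b$expression$mRNA
#> <expr_matrix> mRNA: 200 features x 9 samples (control n=3, resistantA n=3, resistantAB n=3)

de <- run_de_analysis(b$expression, b$conditions)
t(sapply(c("lncRNA","circRNA","miRNA","mRNA"), function(sp)
  sapply(de$de_sets[[sp]], nrow)))
#>         AvsCtrl BvsCtrl merged
#> lncRNA       35      35     32
#> circRNA      14      11     11
#> miRNA        13      13     12
#> mRNA         29      36     27
```

Each row counts the differential features per comparison; `merged` is the
direction-consistent intersection — features differential in both resistant
conditions with the same direction, the candidates most likely tied to the
shared resistance phenotype. Building the merged-group ceRNA network:

```r
ids  <- function(sp) de$de_sets[[sp]]$merged$feature_id
rule     <- correlation_rule()                            # |r| >= 0.99, p < 0.05
rule_neg <- correlation_rule(required_sign = "negative")
sm <- rbind(build_pair_network(b$expression$lncRNA,  b$expression$mRNA, ids("lncRNA"),  ids("mRNA"), rule),
            build_pair_network(b$expression$circRNA, b$expression$mRNA, ids("circRNA"), ids("mRNA"), rule))
ms <- rbind(build_pair_network(b$expression$miRNA, b$expression$lncRNA,  ids("miRNA"), ids("lncRNA"),  rule_neg),
            build_pair_network(b$expression$miRNA, b$expression$circRNA, ids("miRNA"), ids("circRNA"), rule_neg))
mm <- build_pair_network(b$expression$miRNA, b$expression$mRNA, ids("miRNA"), ids("mRNA"), rule_neg)
sites <- predict_targets(b$sequences$miRNA[ids("miRNA")],
                         c(b$sequences$lncRNA[ids("lncRNA")],
                           b$sequences$circRNA[ids("circRNA")],
                           b$sequences$utr3[ids("mRNA")]))
tri <- assemble_triplets(sm, ms, mm, sites)
head(tri[, c("sponge_id","sponge_species","mirna_id","mrna_id","sponge_mrna_r","mirna_mrna_r")], 3)
#>   sponge_id sponge_species mirna_id   mrna_id sponge_mrna_r mirna_mrna_r
#> 1 circ_0001        circRNA mir_0002 mrna_0002     0.9986330   -0.9966737
#> 2 circ_0002        circRNA mir_0004 mrna_0004     0.9991265   -0.9989924
#> 3 circ_0003        circRNA mir_0006 mrna_0006     0.9988544   -0.9980952
```

Every triplet satisfies the sign pattern: sponge and mRNA rise together
(r > 0) while both anticorrelate with the shared miRNA (r < 0), and the
miRNA has seed sites in both partners. Enrichment of the merged DE mRNAs
recovers the gene set planted among them:

```r
res <- enrich(ids("mRNA"), b$gene_sets)
head(res[, c("term","namespace","k","K","p","q","fold_enrichment")], 3)
#>           term namespace  k  K            p            q fold_enrichment
#> 1 MF:planted01        MF 10 11 3.797197e-09 2.278318e-08        6.734007
#> 2 BP:planted01        BP  9 12 6.716825e-07 4.030095e-06        5.555556
#> 3 CC:planted01        CC  8 12 1.377251e-05 8.263506e-05        4.938272
```

Here `k` of the `K` genes in each term are among the differential mRNAs;
`q` is the BH-adjusted hypergeometric p within the term's namespace. Or run
everything at once:

```r
run_pipeline(pipeline_config(simulate = simulation_config(seed = 1),
                             out_dir = "cernet_run"))
```

which writes `data/`, `de/`, `coexpression/`, `targets/`, `cerna/`,
`regulation/`, `enrichment/` and `manifest.json` (stage fingerprints,
checksums, row counts; reruns skip unchanged stages, and a fixed
config + seed reproduces the directory bit for bit).

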