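# IRkit

Comparative analysis of **intron retention (IR)** from RNA-seq
coverage, for transcriptomics researchers studying IR as a mechanism
of post-transcriptional gene regulation — e.g. across vertebrate
granulocytes, where the fraction of expressed genes affected by IR
anti-correlates strongly with the number of protein-coding genes in
the genome.

## What it computes

For every annotated intron, the **IR ratio**

```
IR = min(1, median intron depth / median flanking-exon depth)
```

with the calling filters: IR ≥ 0.1, splicing depth ≥ 4 (junction reads
matching both intron boundaries exactly), splicing depth + trimmed
mean intron depth ≥ 10, and no internal splicing. Genes aggregate by
their maximum measurable intron IR; a gene is an *IR gene* if it is
expressed (FPKM ≥ 1, union-exon model) and has a retained intron.

Around that core:

* **Retained-intron characteristics** — length, GC, intron phase, PTC
  density, relative intron position, and donor/acceptor strength from
  a maximum-entropy splice-site model (marginal constraints on single
  positions plus adjacent and skip-one pairs, fitted by iterative
  proportional scaling with exact transfer-matrix marginals; scores in
  log2-odds bits).
* **Host-gene regulation** — 3' UTR lengths, miRNA seed-site scanning
  (exact reverse complement of miRNA positions 2–8), Sylamer-style
  6-mer enrichment by upper-tail cumulative hypergeometric with
  Bonferroni E-values, and bidirectional (head-to-head, < 1 kb)
  promoter gene-pair analysis.
* **Cross-species conservation** — ortholog × species IR matrices,
  quantile normalization, k-means and 1 − Pearson average-linkage
  clustering (Newick out), n-way IR ortholog intersection counts, and
  the IR-fraction vs protein-coding-gene-count correlation.
* **miRNA-sponge kinetics** — a mass-action ceRNA ODE model of
  intron-retaining transcripts titrating miRNAs, with steady-state
  dose–response curves.
* **Synthetic data** — a generator that plants all of the above
  (retention fractions, class-specific intron length/GC/site strength,
  UTR lengths and collision-free seed sites, gene-pair orientations,
  conserved-IR cores across pseudo-species) with exact ground truth.

## Worked example

```r
library(IRkit)

cfg  <- simConfig(n_genes = 120, seed = 1)     # planted 20% IR genes
sim  <- simulateAnnotation(cfg)                # GenomeAnnotation + genome
ev   <- simulateEvidence(sim, cfg)             # coverage + junctions

calls <- irCalls(sim$annotation, ev$coverage, ev$junctions)
fpkm  <- computeFPKM(ev$gene_counts, mergedExonicKbp(sim$annotation),
                     ev$total_reads)
genes <- aggregateGeneIR(calls, fpkm)

table(calls$category)
#> not_retained     retained unmeasurable
#>          434           48          181
attr(genes, "fraction_ir")
#> [1] 0.2
correlateIRComplexity(speciesGenomeSummary())
#> [1] -0.95
```

`calls` is the per-intron table (coordinates, IR ratio, splicing
depth, trimmed intron depth, filter verdicts); `fraction_ir` is the
fraction of expressed genes with at least one retained intron — here
exactly the planted 20%. The last line computes the Pearson
correlation between the five species' published IR-gene fractions and
their protein-coding gene counts from the bundled summary table.
`runPipeline(pipelineConfig(out_dir = "out"))` runs the full
multi-species demo (IR calling per pseudo-species, intron features,
splice-site scores, seed-site enrichment, gene pairs, conservation
clustering, sponge dose–response) and writes every table plus a JSON
report.

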