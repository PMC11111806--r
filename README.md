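# mtacr

NDR-centric interaction calling for proximity-methylation chromosome
architecture capture data.

## The problem

Proximity-methylation capture maps the contacts of a single genomic
locus (the *viewpoint*) against the rest of the genome: a GC
methyltransferase fused to an operator-binding protein is recruited to
an operator array inserted at the viewpoint, methylates physically
proximal accessible DNA in *cis* and in *trans*, and the methylation is
read out by enrichment sequencing. A control strain carries the free
enzyme without the array and measures background methylation. Because
the enzyme acts almost exclusively in nucleosome-depleted regions
(NDRs), integrating fragment counts over each annotated NDR — rather
than over fixed genomic bins — preserves the highly localized signal
that makes single-NDR resolution possible.

`mtacr` implements the full computational pipeline for such
experiments, for researchers analyzing targeted-methylation capture
(or DamID-like proximity labeling) count data in yeast-scale genomes:

* fragment counting over NDRs with multi-overlap semantics, plus CPM
  tracks;
* a negative-binomial Wald test per NDR of targeted vs control
  (median-of-ratios normalization, trend-stabilized method-of-moments
  dispersions, Benjamini–Hochberg adjustment), calling interactions at
  the double threshold log2FC > 0.7 and padj < 0.05;
* classification of calls relative to the viewpoint — `local`,
  `far_cis` (same chromosome, midpoint distance > 30 kb), `trans` — and
  exponential distance-decay fits `S(d) = A · 2^(−d/h)` whose scale `h`
  is literally the half-distance in bp;
* feature association and enrichment statistics (intersection and
  proximity flags, two-proportions z-test, permutation overlap test,
  nearest-feature distance summaries);
* multi-viewpoint analysis: the NDR × viewpoint signal matrix, its
  Pearson correlation matrix, Ward hierarchical clustering, and
  per-cluster summaries with local > far-cis > trans precedence;
* absolute methylation rates from bisulfite Sanger-trace intensities
  (`I_C/(I_C + I_T)` at each GC-dinucleotide cytosine);
* a ground-truth simulator (genome, contacts, NB counts, latent
  multi-viewpoint compartments, fragments, traces) so every stage is
  verifiable without external data.

The model at the core: per-NDR counts `K_ij ~ NB(mu_ij, alpha_i)` with
`mu_ij = s_j exp(b0_i + b1_i x_j)`, where `x_j` indicates the targeted
strain; the MTAC signal is `log2FC = b1_i / ln 2`, tested two-sided by
Wald with the SE from the Fisher information. The methods vignette
(`vignettes/mtac-methods.Rmd`) documents every numerical choice.

## Worked example

Simulate a study-condition dataset (~2,000 NDRs on five 1 Mb
chromosomes, 50 planted long-range contacts at fold 4, two replicates
per group), call and classify interactions, and test the calls for
feature enrichment:

```r
library(mtacr)

cfg <- sim_config()
ds  <- simulate_mtac(cfg, seed = 7)
ds$counts
#> mtac_counts: 1979 NDRs x 4 samples (2 targeted, 2 control)

res   <- diff_methylation(ds$counts, ndrs = ds$truth$ndrs)
calls <- call_interactions(res, vp = ds$truth$vp, ndrs = ds$truth$ndrs)
cls   <- classify_interactions(calls, ds$truth$vp)
table(cls$class)
#>   local far_cis   trans
#>       1       9      41

head(cls[order(cls$padj),
  c("ndr_id", "chrom", "baseMean", "log2FC", "padj", "class")], 3)
#>       ndr_id chrom baseMean   log2FC         padj class
#> 11 ndr_00488 chr02 145.3868 2.483233 3.749900e-09 trans
#> 45 ndr_01777 chr05 123.7952 2.348818 5.526619e-08 trans
#> 15 ndr_00619 chr02 111.0464 2.301678 1.219600e-07 trans

long  <- cls$ndr_id[cls$class %in% c("far_cis", "trans")]
truth <- ds$truth$contacts$ndr_id
c(sensitivity = mean(truth %in% long), fdr = mean(!(long %in% truth)))
#> sensitivity         fdr
#>        0.94        0.06

flags <- ds$truth$npc_flags
enrichment_ztest(sum(flags[long]), length(long), sum(flags), length(flags))
#> enrichment: 30/50 (60.0%) vs 256/1979 (12.9%), z = 9.445, p = 3.55e-21
```

The 50 long-range calls recover 47 of the 50 planted contacts
(sensitivity 0.94) with 3 false calls (empirical FDR 0.06), and the
calls are strongly enriched for the planted NPC-like feature (60.0% vs
12.9% genome-wide) — the structure the simulator plants and the
pipeline is built to detect.

A thin command-line wrapper over the same functions is installed at
`inst/cli/mtac.R` (subcommands `simulate`, `call`, `count`, `decay`,
`bs-rate`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/mtac.R", package="mtacr"))')" \
  call --counts counts.tsv --design design.tsv \
       --ndrs ndrs.bed --sizes chrom.sizes --vp viewpoint.tsv --out out/
```

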