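# nifhdiv

Diversity analysis of *nifH* amplicon pyrosequencing surveys, with
frame-aware denoising for protein-coding reads.

## The problem

*nifH*, the gene for the nitrogenase iron protein, is the standard marker
for surveying nitrogen-fixing microorganisms. Amplicon surveys of *nifH* on
homopolymer-error-prone platforms (454 pyrosequencing and kin) face three
compounding problems that 16S-style pipelines do not solve:

1. **Frameshift errors.** Homopolymer miscalls insert or delete single
   bases. In a protein-coding gene these shift the reading frame, turning
   the downstream translation into nonsense that inflates apparent
   diversity. Because the gene codes for protein, frameshifts are
   *detectable*: they create in-frame stop codons or stretches of residues
   that no longer align to the protein family model.
2. **Reagent contamination.** *nifH*-like sequences from *Alpha*- and
   *Betaproteobacteria* occur in PCR reagents; without screening they are
   misread as environmental diazotrophs.
3. **Microdiversity vs. phylotypes.** Unique-sequence counts mix true
   microdiversity with residual noise, so diversity is analysed at several
   amino-acid identity thresholds (100/96/92%) with complete-linkage
   clustering, which guarantees that every pair inside a cluster meets the
   threshold (the diameter property).

`nifhdiv` implements the full pipeline:

- **QC / denoising**: primer trimming (frame anchored at the forward-primer
  boundary), length (>= 200 nt) and ambiguity filters, clipping to 180 nt
  (60 codons), translation, rejection of in-frame stops, and a
  position-specific profile alignment filter that rejects peptides whose
  optimal glocal alignment forces residues into insert states ("unaligned
  characters", the frameshift signature).
- **Contaminant screening**: removal of peptides with >= 96% global-alignment
  identity to a contaminant reference set.
- **Clustering**: exact complete-linkage clustering at 100/96/92% identity
  (one dendrogram cut at all thresholds, so levels nest), pruning of
  clusters under 10 reads, cluster x sample abundance matrices.
- **Diversity**: random subsampling to a common depth (default 2883 reads),
  analytic (hypergeometric) rarefaction E[S_n] = sum_i (1 - C(N-N_i, n)/C(N, n)),
  Chao1 (bias-corrected S_obs + F1(F1-1)/(2(F2+1)) and classic forms),
  Shannon H = -sum p_i ln p_i, and a pooled "mixed" sample.
- **Between-sample comparison**: Sorensen index Cs = 2j/(a+b) x 100 at the
  96% level, neighbor-joining phylogeny of 92% cluster representatives on
  p-distances, raw and normalized weighted UniFrac
  (sum_i b_i |A_i/A_T - B_i/B_T|), and principal coordinates analysis.
- **Synthetic data with ground truth**: a generator that emulates the whole
  observation process — consensus-anchored variant families with designed
  cluster structure at every threshold, skewed abundances, back-translated
  ~358 bp amplicons, per-run homopolymer indels, substitutions, ambiguous
  bases, short reads and contaminant spike-ins — so every stage is testable
  against known truth without any external download.

## Worked example

```r
library(nifhdiv)

cfg <- sim_config(n_samples = 3, variants_per_sample = 8,
                  reads_per_sample = 2000, shared_variant_fraction = 0.5,
                  contaminant_fraction = 0.05, rng_seed = 42)
sim <- simulate_dataset(cfg)
res <- run_pipeline(sim$reads, sim$profile, sim$contaminant_db,
                    config = pipeline_config(subsample_depth = 1000, seed = 42))

res$qc$attrition
#>   sample input after_trim after_length after_ambiguity after_clip
#> 1    S01  2000       1955         1936            1863       1863
#> 2    S02  2000       1928         1909            1841       1841
#> 3    S03  2000       1936         1911            1865       1865
#>   after_stop_filter after_profile_filter
#> 1              1438                 1276
#> 2              1461                 1308
#> 3              1496                 1312
```

About 35% of reads are lost to denoising, almost entirely at the stop and
profile filters — the expected fate of homopolymer-indel reads (roughly 45%
of simulated reads carry at least one indel at the default 1% per-run
rate; only indels inside the 180 nt analysis window are detectable, the
rest are harmless).

```r
res$screen$report
#>   sample n_in n_removed   fraction
#> 1    S01 1276        80 0.06269592
#> 2    S02 1308        50 0.03822630
#> 3    S03 1312        63 0.04801829
```

The 5% contaminant spike-in is flagged per sample (the simulation labels
each read, so screening accuracy is directly checkable against truth).

```r
subset(res$diversity$table, threshold == 92)
#>  threshold sample    N S_obs F1 F2 chao1 chao1_classic  shannon
#>         92    S01 1000     9  0  0     9             9 1.820933
#>         92    S02 1000    11  0  0    11            11 1.992878
#>         92    S03 1000    10  0  0    10            10 1.922784
#>         92  mixed 1000    20  0  0    20            20 2.447765
```

Each sample was designed with 8 true 92% families; the pipeline recovers
9-11 phylotypes per sample after subsampling (residual inflation comes from
compensating double-indel reads, see the methods vignette). The pooled
"mixed" sample sees the union of communities.

```r
round(res$comparison$sorensen, 1)
#>       S01   S02   S03
#> S01 100.0  56.4  63.2
#> S02  56.4 100.0  56.4
#> S03  63.2  56.4 100.0
```

Half of each community is shared by design (true Cs = 50); the recovered
Sorensen matrix sits a few points above because shared artifact clusters
count as overlap. `res$comparison` also carries the NJ tree (`ape::phylo`),
the weighted UniFrac matrix and the PCoA projection; `run_pipeline(...,
outdir =)` writes every table as TSV, trees as Newick, sequences as FASTA.

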