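---
title: "Methods: frame-aware denoising and diversity analysis of nifH amplicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frame-aware denoising and diversity analysis of nifH amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the methods it implements:
the model behind each stage, the parameters that matter, the design
decisions taken where the design was genuinely open, and what the synthetic
benchmark does and does not demonstrate about real data.

## 1. The observation model

A *nifH* amplicon read is modelled as

    forward primer + back-translated protein fragment + reverse-complemented
    reverse primer,

corrupted by the dominant error modes of homopolymer-limited
pyrosequencing: per-base substitutions, per-homopolymer-run single-base
insertions/deletions, undetermined bases ('N'), and premature read
truncation. The analysed unit is the first 60 codons of the insert; the
full insert is longer (~324 nt, so the emitted read is ~358 bp), which
matters because indels downstream of the 180 nt analysis window cannot
shift the analysed frame and are therefore invisible to — and harmless
for — the denoising filters.

Key assumption: the reading frame is fixed by the forward-primer boundary.
Trimming anchors the frame, so the forward primer is mandatory (at most one
mismatch), while the reverse primer is trimmed when present but its absence
is tolerated.

## 2. Frame-aware denoising

Order of filters, each justified by what it can see:

1. **Primer trim** — establishes frame; mismatch tolerance 1 (exposed as
   `max_primer_mismatch`).
2. **Length >= 200 nt, no 'N'** — removes truncated and ambiguous reads.
3. **Clip at 180 nt, translate, reject in-frame stops** — a frameshift
   randomises downstream codons, and a random codon is a stop with
   probability 3/64, so long garbled tails are usually caught here.
4. **Profile alignment filter** — the backstop for frameshifts that escape
   a stop codon. Unique peptides are aligned to a position-specific profile
   (one score row per match column, affine interior deletions, flat insert
   penalty, glocal terminal gaps). A peptide is removed iff **every**
   optimal alignment assigns at least one residue to an insert state — the
   strictest reading of removing "sequences with unaligned characters".

### Profile scoring, by break-even analysis

Defaults: match 0, mismatch -5, insert -2, gap open -3, gap extension -1.
These are chosen so that the filter separates the two error signatures from
ordinary biological variation:

- an *isolated interior* unexpected residue scores -5, while routing it
  through an insert state costs insert + gap open + extension = -6: a
  single substitution is kept as a mismatch;
- a *run of two or more* interior unexpected residues scores -10 or worse,
  while the insert route costs -3k - 3: the run is routed to insert states
  and the peptide is rejected;
- at the *termini* gaps are glocal (extension only, as in profile-HMM
  entry/exit transitions), so a single unexpected terminal residue already
  prefers the insert route (-2 - 1 = -3 vs -5). This is deliberate: a
  frameshift garbles the translation through the final residue, so the
  C-terminus is where every frameshifted read leaves a trace, whereas a
  legitimate substitution lands on the terminal column only ~1/60 of the
  time.

The profile itself is built from a reference alignment (in the synthetic
benchmark: the variant pool plus the contaminant set, the analogue of a
curated NifH reference alignment): residues observed at a column score
`match`, all others `mismatch`. Conserved columns therefore discriminate
strongly and variable columns are permissive, exactly as in a profile HMM.

What the filter cannot do: reads carrying *compensating* indel pairs
(deletion plus insertion a few codons apart) regain frame after a short
interior garbage stretch. When that stretch contains only isolated
unexpected residues it is information-theoretically indistinguishable from
1-2 legitimate substitutions, and no threshold setting can reject it
without also rejecting the large fraction of reads carrying one real
substitution. These residues of the error process are what the <10-read
cluster pruning is for (Section 4).

## 3. Contaminant screening

Peptides with maximum identity >= 96% (ties removed) to any entry of a
contaminant reference set are excluded. Identity is one definition
package-wide: global alignment, matches / alignment columns excluding
terminal gap columns. Full-length global alignment was preferred over
local (BLAST-style) HSP identity because all sequences are uniformly 60
residues, making the global value deterministic and toolkit-free while
preserving the threshold semantics; for equal-length sequences it reduces
to the Hamming fraction, which the implementation exploits for speed (the
equivalence is property-tested).

## 4. Clustering

Complete-linkage agglomeration on distance 100 - identity, cut at
100/96/92%. Complete linkage guarantees the diameter property - every
within-cluster pair meets the threshold - which makes cluster membership
auditable (tests re-check it exhaustively). Design choices:

- **Nestedness by construction**: one dendrogram is cut at all thresholds,
  so every 96% cluster lies inside exactly one 92% cluster.
- **Exactness at scale**: for large inputs, candidate near-pairs are found
  by pigeonhole blocking (a pair of length-60 peptides within the loosest
  threshold's mismatch budget must share one of d+1 exact blocks), the
  candidate graph is split into connected components, and exact
  complete linkage runs per component. All cross-component identities are
  below the loosest threshold, so no cluster can span components: this is
  an exact decomposition, not a heuristic (and is tested against the
  direct full-matrix path).
- **Determinism**: sequences enter clustering in sorted id order and
  `stats::hclust` performs the agglomeration, so reruns are identical. Tie
  configurations can admit several equally valid complete-linkage
  partitions; the acceptance oracle therefore checks the two properties any
  correct tie-break must satisfy (diameter validity and merge-maximality,
  verified against exhaustive partition enumeration) rather than one
  arbitrary tie-break's output.
- **Pruning**: clusters with fewer than 10 reads (dataset-wide count) are
  removed at the 96% and 92% levels, where between-sample comparison and
  the phylogeny live. The 100% level is left unpruned because
  unique-sequence microdiversity is itself a reported quantity. Pruning is
  the artifact control for the compensating-indel products of Section 2:
  they are rare per read but, for abundant families, recur often enough to
  form small satellite clusters that would otherwise inflate phylotype
  richness.
- Whether to cluster reads or unique sequences is under-determined in the
  field; we cluster unique sequences and carry read counts.

## 5. Diversity

All depth-sensitive statistics are computed on counts subsampled without
replacement to a common depth (default 2883 reads; samples below depth are
excluded, not an error). Choices:

- **Rarefaction** is analytic (hypergeometric expectation, log-gamma
  evaluation), not Monte Carlo; the subsampler is separately validated
  against it (mean over 1000 draws within 3 standard errors).
- **Chao1** defaults to the bias-corrected form
  S_obs + F1(F1-1)/(2(F2+1)), which is defined for all inputs; the classic
  form F1^2/(2 F2) is available by flag and falls back to the
  bias-corrected form when F2 = 0. Which variant a given legacy tool used
  is often unstated, so both are reported in the diversity table.
- **Shannon** uses the natural logarithm.
- The **"mixed" sample** draws the common depth from the pool of all
  subsampled communities, a composite that shows whether per-sample depth
  covers global diversity.
- Per (threshold, sample) subsampling seeds are derived deterministically
  from the pipeline seed, so the whole run is byte-reproducible.

## 6. Between-sample comparison

- **Sorensen index** Cs = 2j/(a+b) x 100 on cluster supports at the 96%
  level (0 for disjoint non-empty supports, NA when both are empty).
- **Phylogeny**: neighbor joining (Saitou-Nei, via ape) on p-distances
  (1 - identity/100) between 92% cluster representatives (most abundant
  member, ties to the smallest id). No substitution-model correction is
  applied: at 60 residues and the identity ranges involved, model
  correction adds variance without changing the groupings. Negative NJ
  branch estimates are clamped to zero with the deficit transferred to a
  sibling edge, preserving path lengths.
- **Weighted UniFrac**: raw form sum_i b_i |A_i/A_T - B_i/B_T| over
  branches of the midpoint-rooted tree (rooting is needed only for
  branch-descent bookkeeping; the paper-style normalized form, divided by
  the abundance-weighted tree depth, is available by flag and the raw form
  is the default used for ordination). Reference leaves without abundance
  carry zero weight; abundance rows without a leaf are an error.
- **PCoA**: Gower double-centering, eigendecomposition, coordinates from
  positive eigenvalues only (negative eigenvalues are reported, their axes
  dropped); axis signs are canonicalized for determinism.

## 7. The synthetic benchmark: what it emulates, and what it does not

The generator (`sim_config`, `generate_variant_pool`, `emit_reads`) builds
communities whose cluster structure at each threshold is known *by
construction*:

- **Consensus-anchored families.** A fixed fraction (default 0.4) of the 60
  analysed columns is invariant across the whole pool, emulating the motif
  conservation that makes a single profile HMM applicable to the gene
  family; the remaining columns vary freely per family, keeping family
  seeds below 80% mutual identity so designed cluster counts are
  unambiguous.
- **Designed microdiversity.** Each family carries `microdiversity` unique
  variants: the `"radial"` design (leaves one substitution from the seed,
  diameter 2) yields one 96% subcluster per family; the `"nested"` design
  (a second centre three substitutions away, diameter 4) yields two, giving
  distinct truth at all three thresholds.
- **Abundances** follow a discretized power law (default shape 1.0) with
  per-sample rank permutation - strongly uneven communities, as observed in
  real surveys - and a fixed within-family split.
- **Error model**: substitutions 0.002/base and homopolymer indels 0.01 per
  run of length >= 2 (both exposed; the indel model is +/-1 base per run,
  the dominant 454 mode), 'N' bases at 1e-4/base, 1% of reads truncated
  below the length filter. The nuisance rates are set so that the reference
  study design (5000 reads/sample subsampled to 2883) survives QC attrition
  with margin.
- **Contaminants** are drawn from the same consensus (real reagent
  contaminants are genuine *nifH*) but far (<80% identity) from every
  community variant, and are spiked in at a configurable fraction with
  per-read truth labels.
- **Outlier design**: `n_outlier_samples` samples receive only private
  families, reproducing the survey pattern of a station sharing no
  phylotypes with any other.

Not emulated: flowgram-level noise and quality scores, chimeras, PCR
abundance bias, and correlated (non-independent) error positions. Passing
the benchmark therefore demonstrates that the *algorithms* recover designed
truth through the modelled error channel; it does not certify performance
against error modes outside the model, chimeras being the most relevant
omission.

## 8. Numerical and degenerate-input conventions

- Threshold cuts use h = 100 - t + 1e-7 so identities exactly at a
  threshold merge (">= t" semantics) despite floating-point noise.
- Profile-filter retention compares the optimal score against the best
  no-insert score with a 1e-9 slack; for equal query/profile lengths the
  no-insert score is the plain diagonal sum.
- Empty inputs propagate as empty objects (empty FASTA, empty protein set,
  empty cluster set); a sample below the subsampling depth is flagged
  excluded per analysis level, never an exception; an all-zero distance
  matrix yields all-zero PCoA coordinates.
- Benchmark problem sizes in the shipped tests: the end-to-end recovery
  design is 10 samples x 5000 reads with 25 families per sample (one
  outlier), subsampled at 2883; detection power uses 1000 single-indel
  reads; clustering is verified against exhaustive partition enumeration on
  instances of up to 8 sequences and against the full-matrix path at scale.

## 9. Known limitations

- Complete linkage evicts part of an error cloud once a cluster's diameter
  saturates; with abundant families the evicted reads can exceed the
  10-read pruning threshold and appear as satellite phylotypes. This is a
  property of the prescribed diameter criterion (a centroid-radius
  clusterer would absorb them, at the cost of the diameter guarantee), and
  it makes per-sample phylotype recovery mildly sensitive to the error
  realisation; the satellites' combined weight stays small.
- The profile filter cannot reject short interior garbage from
  compensating indel pairs without also rejecting singly-substituted reads
  (Section 2).
- Identity is computed on full-length global alignments; for inputs of
  heterogeneous length (not produced by this QC, which fixes 60 residues)
  the BLAST-HSP identity convention would differ.
- Bootstrap support for the NJ tree is out of scope.
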