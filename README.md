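# kaspqc

Quality control and genetic-diversity analysis for low-density SNP
fingerprinting of inbred germplasm collections.

Germplasm banks and breeding programs fingerprint their inbred lines with
small panels (tens to a few hundred) of biallelic KASP-style SNP markers,
genotyping two or more independent biological replicates per line.  Those
data answer three routine questions: *is this seed lot pure* (residual
heterozygosity of a nominally homozygous inbred), *is it the line the
label says it is* (replicate-to-replicate identity, mislabel detection),
and *how is the collection structured* (genetic distances, subgroups,
heterotic pools).  `kaspqc` implements that whole workflow for maize-style
inbred panels — marker-level QC, sample-level purity/identity QC,
consensus reference-fingerprint construction with mislabel resolution, and
downstream diversity analysis — plus a synthetic panel generator with full
ground truth so every stage can be validated without any real dataset.

## The statistics at the core

* **Marker QC.** Per marker: minor allele frequency
  (MAF = minor-allele count / 2·n, heterozygotes contributing one copy of
  each allele), heterozygosity rate over non-missing calls, missing rate,
  and polymorphic information content by the biallelic Botstein formula
  `PIC = 1 − (p² + q²) − 2p²q²`.  The filter cascade retains a marker iff
  heterozygosity ≤ 5 %, missing rate ≤ 10 % and MAF ≥ 0.05 (thresholds
  configurable, boundary inclusivity configurable).
* **Allele-sharing similarity / IBS distance.** For two genotype vectors,
  over markers non-missing in both, each marker contributes two alleles
  and the shared count is the best pairing of the two allele multisets
  (identical calls share 2; a homozygote and a heterozygote carrying that
  allele share 1; disjoint calls share 0).  The similarity rate is
  shared / (2 · markers compared); the identity-by-state distance is
  `d = 1 − similarity`.
* **Purity and identity classes.** Replicates are PURE (het < 1 %),
  BASIC (1–5 %) or HETEROZYGOUS (> 5 %), with a re-genotyping trigger at
  3 %.  Replicate pairs are essentially identical (similarity > 99 %),
  identical with drift (95–99 %), or an identity ISSUE (≤ 95 %), with
  ISSUE pairs diagnosed as impurity vs likely mislabel from the 85 %
  similarity and 5 % heterozygosity rules.
* **Consensus merge.** Replicates merge marker-wise: consistent calls
  merge directly; a homozygote beats a heterozygote sharing its allele;
  conflicting calls become missing.  Mislabeled replicates (within-line
  distance exceeding the distance to another line, confirmed across all
  replicates and a neighbor-joining tree) are excluded before merging.
* **Diversity.** Pairwise IBS distance matrices; distance-distribution
  bins with a 0.05 relatedness guard; mean within/between subgroup and
  heterotic-group distances; PCA on centered minor-allele dosages;
  Saitou–Nei neighbor-joining trees (Newick export); parent–conversion
  distance tests.

## Worked example

```r
library(kaspqc)

panel <- simulate_panel(paper_like_preset(seed = 42))
panel
#> simulated_panel (seed 42)
#> genotype_matrix: 246 samples x 180 markers
#>   lines: 123; missing calls: 2155 (4.87%)
#>   planted issues: CONTAMINATED=3, MISLABEL=4, NONE=239

stats <- compute_marker_stats(panel$genotypes)
flt   <- filter_markers(stats)                    # 5% / 10% / 0.05 cascade
length(flt$retained)
#> [1] 153

purity <- classify_purity(panel$genotypes)
table(purity$purity_level)
#>        BASIC HETEROZYGOUS         PURE
#>          187           12           47

screen <- cross_line_similarity_screen(panel$genotypes)
screen$flags[screen$flags$flagged, 1:3]
#>     line_name max_within_dist min_between_dist
#> 16     SL016B       0.3666667      0.009202454
#> 91     SL091A       0.3353293      0.000000000
#> 99     SL099A       0.3433735      0.000000000
#> 108    SL108B       0.3445122      0.009202454

ref <- build_reference(panel$genotypes, flt$retained, purity,
                       resolve_mislabels(panel$genotypes))
ref
#> reference_dataset: 123 consensus fingerprints x 153 markers
#>   mean het 1.09%, mean missing 1.14%, mean MAF 0.305

dm <- distance_matrix(ref)
round(c(mean = bin_distances(dm)$mean_distance,
        bin_distances(dm)$pct_greater), 3)
#>   mean  >0.05   >0.1   >0.3   >0.5
#>  0.395 99.947 99.947 98.321  0.626
```

Reading the output: the two planted replicate swaps show up as four lines
whose within-line replicate distance (~0.34–0.37) exceeds their distance
to another line (~0–0.01); `resolve_mislabels()` excludes exactly the
swapped replicates before the consensus merge, so the reference keeps one
clean fingerprint per line.  The distance distribution (mean 0.395, 98 %
of pairs above 0.30) is the signature of a diverse, mostly unrelated
inbred collection.

Real data enter through `read_genotype_table()` (wide-calls CSV or HapMap
text) and the same functions, or through the staged pipeline runner
`run_pipeline(pipeline_config(...))`, which writes every stage's CSV/JSON
artifacts plus a reproducibility log.  A thin command-line wrapper lives
at `inst/scripts/kaspqc.R`.

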