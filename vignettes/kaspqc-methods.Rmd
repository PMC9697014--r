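---
title: "Methods: fingerprinting QC, consensus references, and diversity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fingerprinting QC, consensus references, and diversity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kaspqc)
```

`kaspqc` operates on low-density SNP fingerprints of inbred lines: a few
hundred lines, on the order of one or two hundred biallelic KASP-style
markers, and two to five independently sampled and genotyped biological
replicates per line.  This vignette is the package's own account of the
models and procedures it implements, the parameters that matter, and the
choices made where the design was genuinely open.

## Data model

A `genotype_matrix` holds unordered diploid calls `"X/Y"` (alleles sorted
alphabetically, `NA` for missing) over a sample table (line, replicate,
optional adaptation subgroup and heterotic group) and a marker table
(chromosome, 1-based position, reference allele pair, optional trait
tag).  Phase is never represented: the panel is inbred and KASP calls are
unphased.  Half-calls do not exist — a cell carries both alleles or none.
All missing-token variants (`"--"`, `"NN"`, `"NA"`, empty) are normalized
once, at the I/O boundary; the wide-calls CSV writes `"--"` and HapMap
writes `"NN"`.  Both file orientations are supported because deposited
KASP exports come in either; the reader validates every call against the
marker's reference allele pair and reports offending cells rather than
dropping them.

## Marker QC

Per marker the package reports MAF, heterozygosity rate, missing rate,
PIC and mutation class.

* MAF counts alleles over non-missing calls (a heterozygote contributes
  one copy of each allele): `maf = minor count / (2 n_called)`.
* The heterozygosity denominator is **non-missing calls**, not all
  samples.  The alternative (all samples) would let missingness dilute
  heterozygosity, conflating two unrelated failure modes; the two rates
  are reported separately instead.
* PIC uses the biallelic Botstein form
  `1 − (p² + q²) − 2p²q²`, the standard informativeness index when only
  allele frequencies are available.
* Mutation class collapses strand complements into the three classes
  A/G|T/C, A/C|G/T and A/T|C/G, assigned purely from the reference
  allele pair.

The filter cascade retains a marker iff `het ≤ 5 %`, `missing ≤ 10 %`
and `maf ≥ 0.05`.  Exclusion reports name the *first* failing criterion
in the order HET, MISS, MAF, matching how such panels are usually
triaged (assay chemistry first, then call rate, then informativeness).
Boundary markers are retained by default — the exclusion rules are read
as strict inequalities — with `inclusive = FALSE` available because the
boundary convention is not universal.

## Sample QC

**Purity.**  Residual heterozygosity of a replicate (over its non-missing
calls) classifies seed purity: PURE below 1 %, BASIC from 1 % to 5 %,
HETEROZYGOUS above 5 %.  These three levels partition [0, 100] exactly.
Independently, any replicate above 3 % flags its line for re-genotyping —
the trigger is per replicate, not per line average, because one bad
seed lot is enough to warrant a second round.

**Similarity.**  The similarity rate between two genotype vectors is the
number of shared alleles over the number of non-missing alleles, over
markers called in *both* vectors.  Shared alleles at a marker are counted
by the best pairing of the two allele multisets — allele-level, not
genotype-level, matching the definition of similarity over alleles:
hom/same-hom shares 2, hom/het-with-that-allele shares 1, disjoint calls
share 0.  Markers missing in either vector are excluded from numerator
and denominator (pairwise-complete); this is the only reading consistent
with a denominator of "non-missing alleles".  With strictly biallelic
markers two heterozygotes at the same marker are necessarily the same
call, so the het-vs-het mismatch convention that differs between external
programs is unobservable on this data model; the multiset rule (0 shared
for disjoint heterozygotes) applies in the general case and is fixed, not
configurable.

**Identity.**  Replicate pairs within a line are essentially identical
above 99 % similarity, identical-with-drift above 95 %, and an ISSUE at
or below 95 %.  ISSUE diagnosis uses two descriptive thresholds exposed
as arguments because they are field rules rather than theorems: an ISSUE
with similarity above 85 % and a replicate above 5 % heterozygosity is
attributed to seed impurity; at or below 85 % it is *likely* impurity if
a replicate is impure and *likely* a mislabel if both replicates look
like clean inbreds.  The "likely" hedge is deliberate: a definitive
mislabel verdict needs additional replicates (below).

**Cross-line screen.**  A line is flagged when the distance between its
own replicates exceeds the minimum distance from any of its replicates to
a different line's replicate — the signature of a swapped or mislabeled
sample.  Line pairs at distance zero both within and between (duplicated
seed sources, or relatives below the panel's resolution) are reported
separately as indistinguishable pairs, not as mislabels.

## Consensus reference construction

Replicates merge into one fingerprint per line, marker by marker:

1. all non-missing calls identical → that call;
2. one distinct homozygote plus heterozygotes sharing its allele → the
   homozygote (residual heterozygosity in one replicate never overwrites
   a clean homozygous call);
3. anything else (conflicting homozygotes, a heterozygote sharing no
   allele, two distinct heterozygotes) → missing.

When a site is called in some replicates and missing in others, the
default policy keeps the observed call: missingness in KASP data is
overwhelmingly technical dropout, and discarding a clean call because a
sibling replicate dropped out would only inflate reference missingness.
The literal alternative — any disagreement including dropout becomes
missing — is available as `missing_policy = "strict"`.  The merge is
invariant to replicate order, and generalizes beyond pairs by unanimity /
single-homozygote / conflict in the obvious way.

**Mislabel resolution.**  For a flagged line with at least three
replicates, a replicate is excluded as a mislabel when the remaining
replicates are mutually consistent (pairwise similarity above 95 %) and
the candidate's mean similarity to them is at or below 95 %.  When no
single exclusion restores consistency — e.g. a 2-vs-3 split of two
internally consistent but mutually distant replicate sets — the line is
UNRESOLVED and no consensus is emitted; that is a data-collection
problem, not one an algorithm should paper over.  A neighbor-joining
tree over all flagged-line replicates provides a cross-check: a genuine
mislabel attaches outside its line's cluster, so its nearest tip by tree
path length belongs to another line (for a swap, typically the line whose
genotype it carries; the line's *own* cluster legitimately contains the
swapped-in partner replicate, which is why naive monophyly of the
retained replicates is not the right criterion).  The tree is advisory by
default — the similarity rule decides — and `strict` mode demands both
signals agree.

**Assembly.**  Per line, excluded replicates are dropped; if any
replicate has heterozygosity below 3 % only those are merged (the rest
set aside as HIGH_HET), mirroring the preference for clean seed sources;
the merge is restricted to the retained marker set.  Lines typed on a
marker subset are accepted and their per-line coverage recorded.  Every
input replicate appears in the provenance table as used or excluded with
a reason; building the same inputs twice yields byte-identical output.

## Diversity analysis

The IBS distance is exactly `1 − similarity`, so it inherits the
allele-level, pairwise-complete convention documented above.  It is
symmetric with zero diagonal and lies in [0, 1]; the triangle inequality
is *not* asserted (pairwise-complete IBS distances need not be metric).

Distance distributions are summarized over unordered distinct pairs into
bins delimited by 0.05 / 0.10 / 0.30 / 0.50 by default, with exact-zero
pairs (indistinguishable fingerprints) and pairs under the 0.05
relatedness guard (the minimum distance a candidate line should keep from
every released line) counted separately.  Subgroup summaries use
unordered distinct pairs within a group and the full cross product
between groups; the same machinery serves heterotic groups.

PCA encodes genotypes as minor-allele dosage 0/1/2, imputes missing cells
to the marker mean, centers columns, and eigen-decomposes via
`stats::prcomp` — no variance scaling, since dosage columns share a
scale and scaling would up-weight rare alleles.  Explained-variance
fractions are each component's share of total variance and are therefore
non-increasing and sum to at most 1.

Neighbor-joining uses the Saitou–Nei agglomeration from `ape`.  NJ can
estimate negative branch lengths on non-additive matrices; these are
clamped to zero with the deficit transferred to the sibling edge so path
lengths are approximately preserved (clamping is presentational and never
changes the topology).  Trees serialize to standard Newick.

Parent–conversion tests look up the IBS distance for (recurrent parent,
converted line) pairs — a conversion produced by a few backcross or
marker-assisted introgression steps should stay near its parent — and
flag pairs above a closeness expectation (default 0.2, configurable;
genuine conversions with small introgressed fractions sit well below it,
and a large distance indicates a pedigree or identity problem).

## The synthetic panel generator

`simulate_panel()` emulates the statistical structure the analysis
assumes, with complete ground truth:

* **Frequencies.** Ancestral minor allele frequencies are uniform on
  (0.1, 0.5).  Subgroup frequencies follow Balding–Nichols drift:
  `q_g ~ Beta(p(1−F)/F, (1−p)(1−F)/F)`, variance `F·p(1−p)` — the
  standard, simple drift model with a single tunable parameter per
  subgroup.  An optional second level assigns subgroups to germplasm
  pools that themselves drift from the ancestor.  This hierarchy matters:
  with independent single-level drift the *expected* between-subgroup
  distance is F-free (only within-subgroup distances shrink), so a
  distant outgroup such as a temperate pool against tropical pools can
  only emerge from correlated (pooled) drift of the subgroups that are
  genuinely related.
* **Marker selection.** Real QC panels are pre-selected for panel-wide
  informativeness.  With `marker_maf_floor > 0` the generator redraws
  markers whose expected panel MAF falls below the floor, except the
  planted low-MAF defect markers, which model assay failures.
* **Lines and replicates.** Each inbred line is a homozygous draw from
  its subgroup frequencies; a per-line residual-heterozygosity target
  (exponential around the configured mean, capped at 0.2, so most lines
  fall well under 5 %) sets a fraction of markers heterozygous.
  Replicates copy the line genotype with allele-level call errors
  (homozygotes miscall to the heterozygote 80 % of the time, to the
  opposite homozygote 20 % — KASP errors are cluster mis-assignments —
  and heterozygotes miscall to a random homozygote) and independent
  missingness.
* **Planted issues.** Mislabels swap one replicate's content between two
  lines; contamination mixes, per marker with the configured probability,
  one allele from the line with one from a random other line (bulked
  leaf tissue with foreign seed or pollen); siblings share about half
  their genome through a common parent; conversions copy a parent and
  replace a stated fraction of markers from a donor.  Marker defects
  plant high-heterozygosity, high-missingness and low-MAF tails with
  configurable overlaps.
* **Determinism.** `simulate_panel()` seeds the RNG from
  `config$seed`; identical configurations are byte-identical.

`paper_like_preset()` fixes the study conditions the package is validated
under: 180 markers on chromosomes 1–10 plus one unplaced contig with
per-chromosome counts (21, 18, 19, 12, 19, 22, 15, 20, 13, 20, 1);
adaptation subgroups of 67 lowland-tropical, 46 subtropical/mid-altitude,
7 highland-tropical and 3 temperate lines — a one-fifth scaling of a
615-line collection, chosen so the full test suite and acceptance run
complete in seconds while keeping hundreds of samples; tropical subgroups
pooled (pool F = 0.15) against a separate temperate pool; defect tails of
8/16/10 markers with 3 + 4 overlaps; two replicates per line (five for
mislabel-resolution studies); residual heterozygosity mean 1.2 %, call
error 0.3 %, missingness 3 %; and an issue set of 2 mislabel swaps, 3
contaminated replicates, 2 sibling pairs and 2 conversions at 5 %
introgression.  These values were chosen once to land the panel marginals
in the realistic range for a tropical inbred collection (mean sample
heterozygosity ~2 %, mean missing ~3–5 %, mean MAF ~0.3, mean pairwise
distance ~0.4) and are not tuned per test.

What the generator does **not** emulate: linkage disequilibrium between
markers (panel SNPs are sparse — megabase spacing — and treated as
independent), genotype-calling cluster geometry, batch effects between
genotyping rounds, and pedigree structure beyond single shared parents.
Passing tests therefore demonstrate correctness of the algorithms under
realistic marginal statistics and planted truth, not robustness to every
artifact of a production genotyping lab.

## Numerical and degenerate-input choices

* Monomorphic markers get MAF 0 and PIC 0; all-missing markers keep a
  stats record (missing 100 %, MAF/het undefined) and fail the filter.
* All-missing samples are flagged for review, never classified.
* Similarity between vectors with no mutually called marker is an error
  (undefined comparison), and such pairs become `NA` with a warning in
  distance matrices.
* PCA errors on zero-variance matrices; NJ warns and returns a
  single-edge tree below three labels.
* Ties in similarity-based decisions do not arise in the rules (all
  comparisons are strict thresholds); NJ tie-breaking follows `ape`.
* Sub-seeds for multi-panel studies (e.g. the mislabel-recovery rate)
  are derived by small integer offsets from the master seed and stay
  within 32-bit range.

## Known limitations

* With ~150 markers, lines closer than a few percent IBS distance are
  genuinely indistinguishable; the package reports such pairs rather
  than guessing.
* Mislabel resolution requires at least three replicates and an internal
  majority; 2-vs-2 or 2-vs-3 conflicts stay UNRESOLVED by design.
* The advisory NJ cross-check summarizes placement by nearest path-length
  neighbor; it is a diagnostic aid, not an independent test.
* Consensus heterozygosity is bounded by every replicate's heterozygous
  call count, but as a *percentage* it can exceed a replicate's rate by
  a hair when missingness shifts denominators.
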