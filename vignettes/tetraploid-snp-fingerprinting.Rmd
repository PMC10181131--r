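---
title: "Dosage genotyping and SNP fingerprinting of autotetraploid varieties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosage genotyping and SNP fingerprinting of autotetraploid varieties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetrafinger)
```

## The problem

Autotetraploid crops such as potato carry four allele copies per locus. A
biallelic SNP therefore has five genotype classes, scored as the B-allele
dosage d ∈ {0, …, 4}: AAAA, AAAB, AABB, ABBB, BBBB. Variety collections of
such crops are plagued by synonyms (one clone distributed under several
names) and homonyms (one name attached to genetically different material),
because tubers and tissue-culture plantlets are exchanged and relabelled
freely. A small panel of informative SNPs, assayed by competitive
allele-specific PCR and called as dosages, provides a fingerprint that
resolves both problems. `tetrafinger` covers the full path: discovering
assay-convertible SNPs in a cohort VCF, calling dosages from raw
fluorescence, scoring marker informativeness, and running the
distance/clustering identity analysis.

## Marker discovery from a cohort VCF

Discovery operates on a cohort VCF with per-sample genotypes (GT, ploidy 2
or 4) and allele depths (AD). Two filter stages are applied, all thresholds
strict inequalities as they are conventionally quoted:

1. **High quality:** biallelic sites with cohort-wide minor-allele read
   support > 3 reads and call integrity (fraction of samples with a
   genotype) > 0.85. "Minor allele" is determined from summed read depths.
   The support criterion is cohort-wide by default because reduced-
   representation sequencing at ~10x depth rarely yields more than a
   handful of minor-allele reads in any single sample; a `per_sample`
   scope (a single sample must exceed the bound) is available in
   `run_config()` for deeper data.
2. **Assay-ready ("perfect") SNPs:** MAF > 0.4 (allele copies counted from
   called genotypes), miss rate < 0.2, heterozygous-sample fraction < 0.4,
   and no other variant record within ±100 bp (inclusive) on the same
   contig. The cohort VCF itself is the variation catalogue for the flank
   criterion — a flanking SNP segregating in the cohort would corrupt
   primer annealing in the downstream PCR assay. The four criteria are
   independent predicates, so the selected set is invariant to their order
   of application; the per-site report names every failed criterion.

The near-fixation MAF bound deserves a note: a marker intended for a
five-cluster dosage assay is most informative when both alleles are common,
so candidate selection demands allele frequencies close to 0.5.

Windowed summaries use 0-based half-open tiling; the final partial window
of a contig is kept and counted like any other. SNP density uses 1 Mb bins.
SNP-rich detection ranks 100 kb windows across all contigs and flags the
top 1% (at least `ceiling(0.01 · n_windows)` windows); windows tied with
the cutoff count are all flagged, and empty windows never are, which makes
the degenerate all-equal and all-empty cases behave sensibly.

## Dosage calling from two-channel fluorescence

The endpoint read of a PARMS/KASP assay is a FAM intensity (A allele) and a
HEX intensity (B allele). The caller works on the B signal fraction
r = HEX/(FAM + HEX), arcsine-square-root transformed: y = asin(√r). On this
variance-stabilised scale the five ideal cluster centres sit at
asin(√(d/4)) ≈ 0, 0.52, 0.79, 1.05, 1.57 — wider apart near the
homozygous classes, where the raw ratio compresses.

Per marker, one-dimensional Gaussian mixtures with k = 1..5 components,
tied variance and ordered means are fitted by EM; k is selected by BIC.
Numerical choices:

* **Initialisation is deterministic:** EM is started from every increasing
  subset of the five theoretical cluster positions (at most
  `choose(5, k) = 10` starts per k) plus one quantile-based start, and the
  best log-likelihood wins. Anchor starts matter: small dosage classes
  (a handful of simplex samples, say) are easily absorbed by a neighbouring
  cluster when EM starts from quantiles alone.
* Convergence at log-likelihood change < 1e-8, at most 500 iterations; a
  non-converged marker has its calls withheld. The tied standard deviation
  is floored at 1e-6 so degenerate single-value markers stay finite.
* **Class assignment:** fitted components are mapped to dosage classes by
  the increasing assignment minimising the weighted squared distance to the
  theoretical positions. This keeps the order constraint (component means
  strictly increasing in assigned dosage) while allowing unobserved
  classes — a marker segregating only as {1, 2, 3} is mapped to those
  classes, not to {0, 1, 2}.
* **Posterior thresholding:** a sample is assigned its maximum-posterior
  dosage only when that posterior strictly exceeds 0.6 (default);
  otherwise the call is missing. A sample exactly midway between two equal
  components has posterior 0.5 and stays uncalled. Lowering the threshold
  can only add calls, never remove them.
* **Peak threshold:** when the largest component's weight exceeds
  `peak_threshold` the marker is flagged non-segregating. The default of 1
  disables the flag, so monomorphic markers are instead caught downstream
  by `drop_monomorphic()`.
* **Channel orientation** (`fam-is-A` default) is a loud configuration
  flag: flipping it replaces every dosage d by 4−d and hence MA by 1−MA.

## Per-marker statistics

With class counts n₀..n₄ over the n called samples (missing calls excluded
from every denominator):

* MA = Σ_d (4−d)·n_d / (4n) — the A-allele share of scored allele copies;
* OH = (n₁+n₂+n₃)/n — the heterozygous-variety fraction;
* PIC = 1 − Σ_g f_g², f_g = n_g/n — gene diversity over the five genotype
  classes, maximal at 0.8 when all classes are equally frequent, 0 iff the
  marker is monomorphic.

This PIC is deliberately computed on genotype-class frequencies, not on the
classical allele-frequency-based marker-PIC formula: for a clonally
propagated autotetraploid the genotype class, not the allele, is the unit
that distinguishes varieties, and the shipped 71-marker reference table
only reproduces under the genotype-class form (the classical form gives
0.65 instead of the printed 0.70 for StSNP54). The identities
MA(counts) + MA(rev(counts)) = 1 and the reversal-invariance of OH and PIC
are property-tested.

`summarize_markers()` reports panel-level means on unrounded values;
printed comparisons round half away from zero to two decimals. On the
shipped reference panel the means reproduce as 67.20% (MA), 60% (OH) and
0.43 (PIC), with 2 monomorphic markers (69 of 71 retained) and 21
fingerprint loci at PIC > 0.6. One ambiguity in the published panel is
left as-is: a strict recount gives 56 markers with MA above 0.5 and 5
markers with all five classes observed, and the package reports its own
counts rather than forcing any published aggregate.

## Distances, clustering, fingerprints, identity

Pairwise distances are plain Euclidean distances on dosage vectors with
pairwise-complete deletion; the shared-locus count is recorded per pair and
pairs with no shared loci get a missing distance. Distances are **not**
rescaled by shared-locus count by default (`scale_by_shared = TRUE`
rescales to the full panel size) — with near-complete dosage matrices the
two conventions differ negligibly, and the unscaled form keeps the
"distance 0 means identical observed genotypes" reading used by the
synonym rule.

UPGMA is implemented directly (size-weighted average linkage, merge at half
the cluster distance, so the tree is ultrametric and the leaf-to-leaf path
equals the cluster distance; ties broken by lexicographically smallest
cluster label). The independent `stats::hclust(method = "average")` is used
as a test oracle only, never as the implementation. `as.hclust()` converts
with hclust's full-distance height convention, and Newick export writes
branch lengths at 6 significant digits.

PCA mean-imputes missing cells per marker, centres columns, and fixes each
component's sign so its largest-magnitude loading is positive.

Fingerprints are the dosage vectors over the PIC-selected loci (descending
PIC, then name — a deterministic order, since assay panels need a fixed
locus order), serialised as digit strings with `N` for missing. Identity
rules are conservative:

* **synonym**: differently named pair with distance 0 on the full
  post-`drop_monomorphic()` panel **and** identical fingerprints on at
  least `min_shared_loci = 10` mutually scored loci. Requiring both mirrors
  the two-step argument (dendrogram, then fingerprint) a curator would
  make, and the shared-locus floor prevents two half-missing profiles from
  being declared identical.
* **homonym**: identically named samples at any distance > 0; the
  differing loci are reported.
* same-name pairs at distance 0 are concordant replicates; distance-0
  pairs with too few comparable loci are reported unresolved.

## The synthetic-data generator

Because real breeding-panel genotypes are typically confidential, every
pipeline input can be simulated with known truth:

* `simulate_dosage_matrix()`: per marker, q drawn from a user-chosen distribution, dosages
  i.i.d. Binomial(4, q) — tetraploid Hardy–Weinberg. Real panels of related
  varieties are not in HWE, but all pipeline statistics are computed from
  observed class counts, not from HWE expectations, so the model only
  matters for recovery tests, where it provides closed-form oracles
  (e.g. mean dosage 4q, class frequencies from the binomial pmf).
* `simulate_signals()`: FAM = gain·(4−d)·exp(ε), HEX = gain·d·exp(ε),
  ε ~ N(0, sd²), plus a small positive background in both channels, so the
  signal fraction is strictly inside (0, 1) even at d = 0 and 4 —
  mirroring the multiplicative noise and optical background of endpoint
  PCR reads. Defaults (noise_sd = 0.05, background = 2% of gain) give the
  tight five-cluster geometry of a clean assay plate; the caller's
  accuracy criterion (≥ 99% correct, adjacent-class confusions only, at
  100 samples per class) is evaluated at exactly these settings. What the
  generator does **not** model — plate effects, no-template wells, allele-
  specific amplification bias — is precisely what passing tests cannot
  certify about real plates.
* `simulate_cohort_vcf()`: a 2 × 100 kb toy genome (two contigs so window
  tiling is exercised across contig boundaries) with planted
  perfect SNPs whose realised (not expected) MAF, miss rate and
  heterozygosity are constructed inside the criteria; flank violators pass
  criteria 1–3 but receive a companion variant within 100 bp; the
  remaining sites each violate at least one criterion (rare allele, excess
  missingness, or all-heterozygous). Depths are Poisson totals split
  binomially by the genotype's allele fraction, and background sites with
  zero depth lose their genotype — so `mean_depth = 1` produces the
  low-integrity wreckage a real shallow run would.
* `inject_identity_cases()` duplicates columns under new names (synonyms)
  and reassigns names across distinct columns (homonyms).

All generators are seed-deterministic: identical seeds give identical
output, byte for byte, through the whole pipeline.

## Problem sizes and limitations

The shipped tests run the caller at 500 samples × 1 marker and 150 × 5,
identity detection at 50 × 69 (matching the 69-marker working panel
scale), and the clustering oracles at 8–9 samples; a full 190 × 69 analysis
runs in seconds. Known limitations: multiallelic sites are partitioned out
rather than dosage-called; the caller assumes one marker per signal batch
and does no plate normalisation; homonym groups larger than two are
reported pairwise; and distances on very sparse matrices depend on the
missing-data convention, for which both options are exposed but no attempt
is made to pick one automatically.
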