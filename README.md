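# tetrafinger

SNP fingerprinting and allele-dosage genotyping for autotetraploid crops.

Autotetraploid species such as cultivated potato (*Solanum tuberosum* L.,
2n = 4x) carry up to four allele copies per locus, so a biallelic SNP has
five genotype classes — nulliplex (AAAA), simplex (AAAB), duplex (AABB),
triplex (ABBB) and quadruplex (BBBB), scored as the B-allele dosage
d ∈ {0, 1, 2, 3, 4}. Distinguishing the thousands of vegetatively propagated
varieties by morphology is unreliable; a small panel of informative SNP
markers, read out by competitive allele-specific PCR (KASP/PARMS chemistry,
FAM and HEX fluorescence channels), gives each variety a compact DNA
fingerprint that supports germplasm management, DUS testing and variety
protection. `tetrafinger` implements that whole workflow for breeders and
genebank curators:

* **Marker discovery from a cohort VCF** — high-quality SNP filtering
  (cohort minor-allele read support > 3, call integrity > 85%),
  biallelic/multiallelic partition, SNP density per 1 Mb bin, SNP-rich
  100 kb windows (top 1%), and selection of assay-ready "perfect" SNPs
  (MAF > 0.4, miss rate < 0.2, heterozygous fraction < 0.4, no other
  variant within 100 bp of flank).
* **Dosage calling** from two-channel endpoint fluorescence via
  order-constrained Gaussian mixtures on the arcsine-square-root signal
  fraction, BIC model selection, and posterior thresholding (calls assigned
  only when the posterior exceeds 0.6).
* **Per-marker statistics** over the n called samples with class counts
  n₀..n₄:
  * mean A frequency `MA = Σ_d (4−d)·n_d / (4n)`,
  * observed heterozygosity `OH = (n₁+n₂+n₃)/n`,
  * polymorphic information content `PIC = 1 − Σ_g f_g²` with
    `f_g = n_g/n`, the gene diversity over the five dosage classes
    (maximum 0.8).
* **Fingerprints and identity** — loci with PIC > 0.6 form the fingerprint
  panel; pairwise Euclidean distances on dosage vectors plus UPGMA
  (average-linkage, ultrametric) clustering detect synonyms (identical
  genotypes under different names) and homonyms (distinct genotypes under
  one name).
* **Synthetic data with known truth** — tetraploid Hardy–Weinberg dosage
  matrices (d ~ Binomial(4, q)), fluorescence signals, toy cohort VCFs with
  planted perfect SNPs, and planted synonym/homonym cases, so every stage
  is testable without confidential breeding data.

## Worked example

The package ships the dosage-class tallies of a published panel of 71
PARMS-SNP markers scored on 190 autotetraploid potato varieties:

```r
library(tetrafinger)

ref   <- potato_reference_markers()
stats <- marker_stats_from_counts(ref)
dplyr::select(stats, marker, n0:n4, n_missing, ma, oh, pic) |> head(3)
#>   marker     n0    n1    n2    n3    n4 n_missing    ma    oh   pic
#> 1 StSNP54     4    11    52    71    39        15 0.316 0.757 0.700
#> 2 StSNP57    78    46    43    18     0         7 0.749 0.578 0.697
#> 3 StSNP41     0    15    36    69    60        12 0.258 0.667 0.695

summarize_markers(stats) |>
  dplyr::select(n_markers, ma_mean, oh_mean, pic_mean, n_single_class)
#>   n_markers ma_mean oh_mean pic_mean n_single_class
#> 1        71   0.672   0.601    0.431              2

length(select_fingerprint_loci(stats))   # loci with PIC > 0.6
#> [1] 21
```

StSNP54's row reads: of 177 called varieties, 4 are AAAA, 11 AAAB, 52 AABB,
71 ABBB and 39 BBBB, giving MA = 224/708 ≈ 0.32 (a third of scored allele
copies are A), OH = 134/177 ≈ 0.76 (three quarters of varieties are
heterozygous) and PIC ≈ 0.70 (close to the 0.8 maximum — a highly
informative fingerprint locus). Panel-wide, 2 markers are monomorphic
(dropped before distance analysis, 69 remain) and 21 loci exceed the
PIC > 0.6 fingerprint threshold.

Identity analysis on simulated varieties with one planted synonym and one
planted homonym:

```r
sim <- simulate_dosage_matrix(40, 50, q_dist = function(n) runif(n, 0.2, 0.8),
                              seed = 7)
inj <- inject_identity_cases(sim$dosage, n_synonyms = 1, n_homonyms = 1,
                             seed = 8)
run_genotype_analysis(dosage = inj$dosage, names = inj$names)$identity
#> <identity_report> 1 synonym pair(s), 1 homonym pair(s), 0 replicate pair(s), 0 unresolved
#> Synonyms:
#>   sample_a sample_b variety_a variety_b        distance code
#> 1 S032     SYN01    S032      SynonymVariety01        0 0303012412033332232020...
#> Homonyms:
#>   variety sample_a sample_b distance differing_loci
#> 1 S034    S015     S034         10.1 M015;M044;M042;M037;M010;M017;...
```

Both planted cases are recovered: the synonym pair sits at distance 0 with
identical fingerprint codes, and the homonym pair shares a name but differs
at many loci (Euclidean distance 10.1).

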