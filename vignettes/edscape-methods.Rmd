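---
title: "Methods: mapping and structural interpretation of editing QTLs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping and structural interpretation of editing QTLs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edscape)
```

## The scientific problem

A-to-I RNA editing is catalysed by ADAR enzymes, which act on
double-stranded RNA: an edited adenosine sits in a duplex formed between
its flanking sequence and an *editing complementary sequence* (ECS)
elsewhere in the transcript. Because inosine is read as guanosine, the
*editing level* of a site is simply the fraction of sequencing reads
carrying G at that position. In a panel of inbred lines, editing levels
vary between genotypes, and genetic variants associated with that
variation — editing QTLs (edQTLs) — point at the cis-regulatory
architecture of editing: variants inside the edited duplex can change
its stability directly, while distal variants may act through additional
nearby dsRNA stems.

`edscape` implements this analysis as a reusable, fully testable
pipeline: editing-level quantification with the standard filters, cis
edQTL mapping with permutation calibration and q-value FDR control, ECS
prediction from folded RNA secondary structure, and structural
interpretation of edQTLs (allelic free-energy comparison, signed stem
positions, secondary stems). A synthetic-data module plants known
effects and duplexes so every stage can be validated against ground
truth without any external download.

## Editing-level quantification

The raw phenotype is a per-(site, strain, replicate) pair of counts
`(g_count, total_count)`. The cascade in `build_editing_matrix()` is:

* **Coverage floor.** A replicate contributes only when
  `total_count >= 50` reads; below that the measurement is missing
  rather than noisy (`compute_editing_level()`).
* **Replicate concordance.** Two biological replicates differing by more
  than 20 percentage points are considered unreliable and the strain's
  value at that site is dropped; a difference of exactly 0.20 is
  retained, reading the exclusion rule as strictly greater-than.
  Concordant replicates are combined by a coverage-weighted mean — the
  maximum-likelihood estimate under binomial read sampling. The
  filtering is per strain and site, not per site globally; a strain with
  only one usable replicate is treated as unmeasured, since a lone
  replicate cannot vouch for itself.
* **Strain support.** Sites measured in fewer than 35 strains are
  dropped from mapping.

Inter-strain variability is summarised two ways (`site_variability()`):
the plain sample variance across strains and a binomial-scaled score,
the variance divided by `p(1-p)` at the site's mean level `p`. The
scaled score compares sites at different mean levels on a common scale;
both are reported because either can be the quantity of interest when
ranking "most variable" sites.

`discover_sites_from_pileup()` reproduces the intronic-site filter
cascade on annotated pileups: at least 2 supporting reads after
discarding read positions 1–6 and base/mapping quality below 20, variant
frequency at least 3%, no homopolymer/simple-repeat context, distance to
a splice junction above a configurable threshold (default 4 nt, not
fixed by convention elsewhere), single-strand transcription, and zero
altered reads in an ADAR-null sample. Each failed filter is reported as
a reason code so attrition can be audited.

## edQTL mapping

For each editing site (`edqtl_map()`):

1. **Normalization.** Editing levels across strains are mapped onto
   standard-normal quantiles, `qnorm((rank - 0.5)/n)`, with ties sharing
   the average rank. This is a monotone transform of the ranks, so the
   subsequent linear model sees a Gaussian phenotype whatever the raw
   level distribution; centring and scaling beforehand would not change
   the result and is therefore folded into the rank map.
2. **Cis scan.** Covariate-free simple linear regressions of the
   normalized levels on each cis variant (same gene), haploid-coded
   {0, 1} for inbred lines. A variant is testable when its minor allele
   is carried by at least 4 strains with a measurement and at least 8
   complete observations remain; strains missing a call are dropped for
   that variant only. A genome-wide mode flags `p < 1e-8`
   (Bonferroni-style) instead of restricting to the gene.
3. **Permutation calibration.** The minimum nominal p over the site's
   variants is compared with the same minimum recomputed under
   permutations of the strain labels (10,000 by default). The empirical
   p-value uses the add-one estimator
   `(1 + #{null <= observed}) / (1 + n_perm)`, which can never return 0
   and counts ties conservatively. The permutation stream is seeded from
   (global seed, site ID), so single sites are reproducible in
   isolation.
4. **FDR.** Storey q-values across sites, with `pi0` estimated at fixed
   `lambda = 0.5` as `#{p > 0.5}/(0.5 m)`, floored at `1/m` and capped
   at 1. The fixed-`lambda` estimator is deterministic and adequate at
   the panel sizes involved; forcing `pi0 = 1` recovers
   Benjamini–Hochberg exactly, which the tests assert. Calls are made at
   FDR 5% and 10%.
5. **Secondary edQTLs.** For sites with a primary call, the primary
   genotype is regressed out (residuals exactly orthogonal to it) and
   the scan plus permutations rerun. The primary variant and its perfect
   proxies (r² = 1) are excluded from the rescan — testing them again
   could only re-discover the primary signal.
6. **Effect sizes.** Half the difference between the homozygote class
   means of the raw (non-normalized) editing levels, reported as a
   magnitude. Distances between variant and site are signed by
   transcript orientation (positive = downstream).

The fitted object is an S3 class with `print`, `summary`, `coef` and
`plot` methods, in the style of classic modelling functions.

## The folding engine

ECS prediction and allelic comparison need RNA secondary structure. The
reference analysis used a thermodynamic partition-function folder; exact
replication of that engine is deliberately out of scope. Instead
`fold_mfe()` provides a deterministic built-in minimum-free-energy
folder under a compact nearest-neighbour model, and every downstream
operation accepts externally computed structures through
`parse_dotbracket()`/`rna_structure()`, so a thermodynamic engine can be
plugged in without touching the analyses.

The built-in model (kcal/mol, model-relative):

| term | value |
|------|-------|
| G–C / A–U / G–U pair | −3 / −2 / −1 |
| stacking bonus per stacked pair | −1 |
| helix initiation per maximal helix | +4 |
| unpaired base in an internal/bulge/multibranch loop | +0.5 |
| hairpin loop | free, minimum 3 nt |

Pseudoknots are excluded; `N` and masked positions never pair. The
helix-initiation and loop-base terms matter: without them a
maximum-pairing fold chains incidental 2–3 bp helices across random
sequence into long bulged "stems", and stem extraction then reports
duplexes where none were planted. With them, isolated pairs and marginal
helices are unprofitable, planted helices dominate their loci, and the
spurious-stem rate on random 401-nt windows is a few percent. Energies
rank structures of the same locus and are comparable between alleles;
they are not calibrated against experimental folding energies — only
the *sign* of allelic differences is interpreted, never the magnitude in
physical units.

The dynamic program is O(n³) in C++ (sequences to ~4000 nt; the
401-nt windows used throughout fold in ~0.1 s), with a deterministic
traceback (fixed branch order on ties). The test suite checks the DP
against an independently written recurrence in R on sequences up to
60 nt and against exhaustive enumeration of *all* nested structures on
tiny sequences, and checks the traceback by re-scoring the returned
structure with two independent evaluators.

## Stems, ECS prediction and its two approaches

A *stem* is a maximal run of consecutive base pairs in which every
interruption (the unpaired run on either strand between consecutive
pairs) is at most the max-bulge parameter; an asymmetric internal loop
is sized by its longer strand. `extract_stem_at()` starts from the pair
at — or the innermost pair enclosing — the anchor position and accretes
pairs in both directions under that rule. The acceptance cutoffs are a
stem of at least 20 bp with max bulge at most 8 nt; the ECS is the
strand of the stem opposite the editing site, bounded by its first and
last paired bases.

**Proximal (Approach 1).** Fold the transcript-strand window 200 bp up-
and downstream of the site (401 nt, truncated at contig ends), anchor on
the site, extract the stem, map back to genomic coordinates.

**Distal (Approach 2).** Candidate regions are maximal runs of smoothed
conservation score ≥ 0.90 (centered 51-nt moving average, truncated at
the ends), at least 20 bases long, within 2,500 bp of the site, and
optionally restricted to introns. Each candidate is buffered by 30 nt,
joined to the site ± 60 nt flank through a 100-nt adenosine linker whose
positions are forbidden from pairing, folded, and accepted only if the
stem pairs the site flank to the candidate segment — flank-to-flank
pairing would just re-discover a proximal structure. The assembly order
(site flank, linker, candidate, all in transcript orientation) is a
package choice; the components, not their order, are fixed by the
method. When several candidates yield accepted ECSs all are reported,
ranked by stem length. Whether linker bases may pair is not specified
anywhere authoritative; they are masked here so the linker is inert by
construction.

**Enrichment score.** Predicted ECSs are merged per chromosome; each
merged interval receives one flank per side of its own length, and the
score is the ratio of known-editing-site density in ECSs to that in
flanks (with untruncated flanks this is sites-in-ECS over half the flank
total). The editing site anchoring each prediction is excluded from the
tallies — counting it would credit the prediction with its own anchor;
this choice is flagged in the output.

## Structural interpretation of edQTLs

Variants at sites with an accepted ECS are classified `within_duplex`
(inside the editing-side or ECS interval) or `distal`; sites without a
prediction are `unresolved` and excluded from structural analyses.

For within-duplex variants, `compare_alleles()` builds the allele
construct — editing-side strand + 100-nt inert linker + ECS — for both
alleles and folds each. The *higher-editing* allele is the one whose
homozygote class has the larger mean raw editing level (ties go to the
reference allele, with a warning). `delta_g` is the free energy of the
lower-edited allele subtracted from the higher-edited one, so negative
values mean the higher-editing allele is more stable. Comparisons with
effect size below 0.025 (a 5% homozygote difference) are flagged rather
than removed, so the gated headline set and the full set coexist.
`signed_position()` reports the variant's base-pair distance along the
stem from the editing site, 3′ positive, with ECS positions inheriting
the sign of their paired editing-side base. Group comparisons use
Fisher's exact test (two-sided; base R's exact implementation) for
base-pairing status and a one-sided Mann–Whitney test for `delta_g`
(exact for small untied samples, tie-corrected normal approximation
otherwise); both are cross-checked in the tests against exhaustive
enumeration oracles for all small inputs. Indels are out of scope: the
allele construct assumes a length-preserving substitution.

For distal edQTLs, `find_distal_stems()` folds ± 200 bp around the
variant and returns every maximal stem meeting the 20/8 cutoffs that
contains the variant; `editing_site_window_frequency()` counts editing
sites in centred windows for the positional enrichment summaries.
Control variants (`select_control_variants()`) must not be edQTLs and
must clear LD against every edQTL in the same gene at r² ≤ 0.05 — the
boundary is inclusive, matching the stated threshold; duplex controls
additionally lie inside predicted duplexes, distal-matched controls are
seeded random samples from the same genes outside the primary duplex.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure of a
mmPCR-seq-style study of a homozygous inbred panel:

* **Panel.** 131 strains and 2 biological replicates by default; calls
  are haploid-coded {0, 1} because inbred lines are effectively
  homozygous, and heterozygous or missing VCF calls map to missing.
* **Genotypes.** Per-variant alternate-allele frequencies drawn
  uniformly from `maf_range` (default 0.1–0.5), strain calls Bernoulli,
  so realized frequencies fluctuate binomially around the draw.
* **Editing levels.**
  `clamp(baseline + 2·effect·g + N(0, noise_sd), 0, 1)`. The additive
  Gaussian model is the simplest one matching the half-difference
  effect-size estimator, which recovers `effect` exactly at zero noise.
  Baselines are uniform on 0.2–0.8 by default: the per-site distribution
  of baseline editing is a free parameter of the generator, and a broad
  uniform keeps clamping rare while exercising the whole scale.
  `noise_sd` defaults to 0.05, the scale of strain-to-strain scatter
  that leaves planted effects of 0.1 clearly detectable at n = 100
  without being trivial. Stem-disrupting causal variants get negative
  effects — the disrupted allele loses pairing and with it editing — so
  the generative direction matches the structural hypothesis the
  analysis tests.
* **Coverage.** Totals Poisson around `coverage_mean` (default 500,
  deep targeted sequencing), G counts binomial in the level,
  independent per replicate.
* **Loci.** One hairpin locus per site: random flank, editing-side stem
  strand with the edited A forced mid-stem, loop, reverse-complement
  ECS, random flank. The loop and 10-nt buffers flanking the stem are
  poly-A — adenosine cannot pair with itself, so the planted helix ends
  are pinned and the recorded truth intervals are exact. Flanks are
  rejection-sampled against reverse-complement 8-mers of the core, and
  each locus (stems of 12+ bp) is verified by round-trip: it must fold
  into a stem matching the recorded truth within 2 nt, with flanks
  resampled deterministically until it does. The generator thereby
  *guarantees* its contract instead of merely making it likely.

What the generator does **not** emulate: sequencing error, PCR
duplicates, alignment artifacts, trans effects, relatedness structure in
the panel, realistic intron/exon architecture, or thermodynamically
calibrated folding landscapes. Passing tests therefore demonstrate that
the statistical machinery is correct and calibrated under its stated
model — not that the pipeline is robust to every artifact of real
mmPCR-seq data.

## Numerical and design choices

* Coordinates are 1-based inclusive throughout the R API (the native R
  and Bioconductor convention); BED is 0-based half-open at the file
  boundary only.
* Permutation sub-seeds are derived from (seed, site ID) with a small
  deterministic string hash kept below 2³¹.
* Degenerate inputs: zero-variance sites are skipped with a warning;
  variants with an empty genotype class give missing effect sizes;
  empty count tables give empty matrices, not errors; all-tied
  Mann–Whitney inputs return p = 1.
* Tie-breaks in the folding traceback follow a fixed branch order, so
  equal-energy structures resolve identically on every platform.
* The problem sizes in the validation suite (200 null sites × 1,000
  permutations for calibration; 100 seeds for power; 100 loci for
  duplex recovery; 500 loci for enrichment) were chosen so each
  property is measured with useful precision while the whole suite runs
  in minutes on a laptop.

## Known limitations

* The built-in energy model is ordinal, not calorimetric; allelic
  `delta_g` values should be read as directions, not physical energies.
* Only SNVs are handled in allelic comparisons.
* No kinship or population-structure correction is applied in the scan
  (the reference design excluded related lines upstream).
* Proximal search is capped at ± 200 bp by construction; farther ECSs
  are only reachable through the conserved-candidate route.
* The q-value `pi0` estimator uses a single fixed `lambda`; with very
  few sites it is noisy, which is why it is floored and capped.
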