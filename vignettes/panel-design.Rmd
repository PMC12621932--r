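---
title: "Designing and evaluating amplicon genotyping panels with panelsmith"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating amplicon genotyping panels with panelsmith}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Whole-genome sequencing is often cost-prohibitive for population-scale
genotyping of organisms with large, repeat-rich genomes — mosquito genomes
being a canonical example, with gigabase genomes that are mostly repetitive.
A targeted amplicon panel sidesteps this: a few hundred short loci (roughly
90–175 bp) are co-amplified in one multiplex PCR, barcoded per individual,
and sequenced shallowly. If the loci are chosen well, the panel reproduces
the population structure, admixture estimates and relatedness inference that
genome-wide data would give, at a small fraction of the cost.

Choosing the loci well is the hard part. A good marker locus is:

* **diverse** — it carries several common SNPs in a short stretch, so each
  amplicon yields a multi-allelic microhaplotype rather than one biallelic
  SNP;
* **anchored in conserved sequence** — its immediate flanks are nearly
  invariant, so one primer pair works across all populations;
* **single-copy** — primers must not amplify paralogs, and the locus must
  not be a collapsed duplication masquerading as a diverse region;
* **selectively neutral** — loci under selection or in inbred/structured
  stretches distort demographic inference;
* **well spaced on the genetic map** — linkage between markers wastes
  information, so spacing is optimized in centimorgans, not base pairs.

`panelsmith` implements this design pipeline, the post-sequencing filter
cascades, and the panel-evaluation analyses, together with a synthetic-data
module that generates data with exactly the structure the pipeline assumes.

## Candidate-region detection

Nucleotide diversity is computed in non-overlapping 50-bp windows
(`windowed_pi()`). Per site, with $n$ non-missing alleles of which $n_i$
carry allele $i$, the mean pairwise difference is

$$ d = \frac{n^2 - \sum_i n_i^2}{n\,(n-1)}, $$

and window $\pi$ is the sum of $d$ over the window's sites divided by the
full window length. The denominator deliberately includes monomorphic and
missing positions (no accessibility correction): it is the plain windowed
estimator, and it is what the detection thresholds below are calibrated
against. Multiallelic sites contribute through the full allele-pair sum;
phase is never used (the estimator depends on allele counts only).

`scan_candidates()` turns the track into candidates: a maximal run of
consecutive windows with $\pi >$ 0.005 whose total length is 50–150 bp
becomes a core, kept only if the windows covering at least 30 bp on each
side all have $\pi <$ 0.0001. The 30-bp minimum flank is this package's
choice — one primer footprint per side is the minimum conserved sequence a
primer pair needs; it is configurable (`min_flank_bp`). Cores at contig
ends, which lack a full flank, are rejected.

Three independent filters then flag candidates. Flags are computed from the
unfiltered region, so the filters commute and the final pass set is simply
the zero-flag set (`candidate_pass()`):

* **Repeat flag** (`apply_repeat_mask()`): the core or either flank
  overlaps a repeat annotation by ≥ 1 bp (half-open intervals; abutting
  does not overlap). Soft-masked runs recorded by `read_fasta()` can serve
  as the mask when no explicit annotation exists.
* **Copy-number/depth flag** (`cnv_depth_filter()`): per region, samples
  with mean core depth below 5,000× are excluded from the region's
  statistics (amplicon-scale units; depth is amplicon-local, so this is a
  per-region exclusion, not a global sample removal). With the remaining
  samples, the region is flagged when depth exceeds 20,000× in *all* of
  them, when core $\pi >$ 0.02, or when the core carries more than 25
  SNPs. Collapsed paralogs inflate depth, heterozygosity and apparent SNP
  count simultaneously, which is why these are ceilings: a region can be
  "too diverse" to be a single locus.
* **Selection/inbreeding flag** (`selection_filter()`): the region passes
  only if, in *every* labelled subpopulation, Tajima's D lies strictly in
  (−2, 2) and Malecot's f is below 0.25. A subpopulation with no
  segregating sites leaves D undefined; the conservative default fails the
  region (a region invariant in one subpopulation is a poor universal
  marker), switchable via `fail_null_d = FALSE`.

Tajima's D uses the standard constants for $n$ haplotypes
(`tajima_constants()`), with $n$ taken as twice the number of samples with
at least one genotyped call in the region, $k$ the summed per-site mean
pairwise differences and $S$ the segregating-site count:

$$ D = \frac{k - S/a_1}{\sqrt{e_1 S + e_2 S (S-1)}}. $$

Malecot's f is the ratio-of-sums heterozygote-deficit estimator over
polymorphic sites, $f = 1 - \sum H_{obs} / \sum 2\hat p(1-\hat p)n$,
clamped to $[-1, 1]$; multiallelic sites are collapsed major-vs-rest, as
the biallelic formula requires.

## Marker selection over the genetic map

The pass set is typically much larger than a panel. `gap_fill_select()`
draws `n_sets` pseudo-random sets of `m` loci each with a seeded greedy
gap-filling scheme of this package's own design: starting from
chromosome-end sentinels (the terminal cM values of each contig's map),
repeatedly locate the largest current cM gap over all contigs and score the
unchosen candidates inside it as

$$ w_{gap}\left(1 - \frac{|c - mid|}{gap/2}\right) + w_{snp}\frac{S}{\max S}, $$

with defaults $w_{gap} = 0.7$, $w_{snp} = 0.3$, then choose uniformly at
random among candidates within $\varepsilon = 0.05$ of the best score. The
ε-randomization is what makes the selection *pseudo*-random: sets differ
only through their seed (`seed + i - 1` for set $i$), each is reproducible,
and each is near-greedy. When the largest gap holds no candidate the next
largest is tried. The weights favour spacing over SNP content because a
marker's map position cannot be compensated later, whereas SNP content
varies modestly across the pass set.

`choose_final_set()` compares the sets by their maximum cM gap (the binding
constraint for linkage-based analyses; ties broken by median gap, then by
lower seed), truncates the winner to `final_m` loci by iteratively removing
the locus whose removal least increases the maximum gap, and finally drops
an exclusion list — loci that fail in the wet lab — without replacement.
Loci are placed on the map by linear interpolation of the core midpoint,
clamped to the terminal anchors (`interpolate_cm()`).

`dimer_screen()` is an explicit heuristic stand-in for thermodynamic dimer
prediction (which the field outsources to commercial design services): an
ordered pair (A, B) is flagged when the 3' end of A reverse-complements a
subsequence of B over ≥ 5 bases, or when any ≥ 8-base reverse-complement
run exists between them. Both thresholds are configurable; the screen's
purpose in this package is to give the pipeline a deterministic,
inspectable dimer-removal step, not to model hybridization energetics.

## In-silico PCR and off-target detection

`find_primer_hits()` reports every ungapped alignment of a primer (and its
reverse complement) with at most $\lfloor 0.05 \times \text{length}
\rfloor$ substitutions — one mismatch for a 20–26 bp primer. Indels are not
modelled, matching the substitution-only mismatch-percent model of the
classic primer-search tools; `N` in the genome counts as a mismatch.
`predict_products()` pairs convergent hits (plus-strand hit upstream of a
non-overlapping minus-strand hit, either primer on either strand) with
outer span ≤ 300 bp; "maximum distance" is interpreted as outer product
span, consistent with amplicon sizes well under that bound.
`flag_off_targets()` counts products per primer pair, intended target
included: more than one product flags putative off-target loci, zero flags
target-not-found. The implementation is checked for exact agreement with a
position-by-position brute-force scan in the test suite.

## Variant and sample filter cascades

Two profiles mirror the two sequencing regimes (`filter_profile()`):

| threshold                | amplicon | wgs  |
|--------------------------|----------|------|
| QD floor (site)          | > 5      | > 5  |
| FS ceiling (site)        | < 60     | < 60 |
| ReadPosRankSum floor     | > −8     | > −8 |
| GQ (genotype)            | ≥ 30     | > 20 |
| DP (genotype)            | ≥ 10×    | ≥ 5× |
| variant missingness      | ≤ 10%    | ≤ 10% |
| sample missingness       | ≤ 10%    | ≤ 50% |
| kinship ceiling (PI_HAT) | —        | 0.75 |

Two deliberate asymmetries are preserved exactly as the regimes'
conventions have them: the GQ bound is inclusive in amplicon mode and
strict in wgs mode, and the sample-missingness tolerance is much looser for
heterogeneous-depth WGS cohorts. Site annotations absent from a record
(e.g. ReadPosRankSum is undefined at sites without heterozygous calls)
never fail it — pass-by-absence — because failing them would discard valid
homozygous-difference sites; such records are counted in the report.
`missingness_filter()` is a single pass, variants first then samples, with
no iteration; `filter_variants()` chains the stages, produces a telescoping
report and states whether the output is at a fixed point of the
missingness stage.

Kinship pruning (`kinship_prune()`) estimates PI_HAT for every pair by
method-of-moments IBD (`ibd_pi_hat()`): observed IBS0/IBS1/IBS2 counts are
compared with their expectations given allele frequencies; $Z_0$ comes from
IBS0, $Z_1$ from IBS1 after removing the IBD-0 contribution, $Z_2 = 1 -
Z_0 - Z_1$, all clamped to $[0,1]$ and renormalized, and $\hat\pi = Z_2 +
Z_1/2$. Pairs above the 0.75 ceiling form a graph from which the
highest-degree sample is removed repeatedly (ties: more missing data, then
the lexicographically later id) until no edge remains. The direction of the
rule — *removing* members of highly related pairs and retaining the
unrelated remainder — is the only population-genetically sensible one, and
the implementation keeps a switch to invert it for pedigree-oriented uses.
Allele frequencies default to the full-matrix estimate, mirroring the
reference kinship method's default.

## Panel evaluation

`assign_reads()` assigns a read to a locus when ≥ 50% of the read interval
overlaps the locus interval — a rule chosen to be robust to primer-trimmed
read ends, since the upstream aligner is outside this package's scope.
Multimap-flagged reads are tallied but never counted (they are the
signature of off-target loci), and reads are conserved: assigned +
off-panel + multimap + rejected = input. `coverage_uniformity()` reports
per-locus shares, the top-locus share and the Gini coefficient;
`balancing_factors()` inverts observed shares into clamped per-primer
dilution factors (defaults 0.1–2.0), the quantity a lab applies to even out
a multiplex pool.

`rarefaction()` subsamples the observed read pool *without* replacement
(sequential conditional hypergeometrics, i.e. a multivariate
hypergeometric draw) — resampling a fixed pool with replacement would bias
low depths — and reports the mean and sd over replicates of the proportion
of loci at or above the genotyping threshold (default 10 reads; read-count
and per-base-depth readings coincide for reads spanning an amplicon). At
the full observed depth the curve equals the observed proportion exactly,
by construction. Depths beyond the observed total are reported as
unsupported rather than extrapolated.

`amplicon_size_stats()` derives the final library size per locus as
amplicon length plus a construct overhead computed from the supplied
adapter-tail and index-primer sequences, never hard-coded, so the
statistics adapt to any panel file. `extract_microhaplotypes()` is the one
phase-consuming operation in the package: per sample and locus it emits the
two allele strings across the locus's variants in position order, refusing
loci with any missing call or any unphased heterozygous call (unphased
homozygotes are unambiguous and accepted).

## The synthetic-data module

`simulate_reference()` / `simulate_population()` generate the study
conditions every test runs under. The defaults are fixed and are the
package's reference conditions:

* 3 contigs × 150 kb; 50 clean cores (80% 150 bp, 20% 100 bp, aligned to
  the 50-bp window grid) plus 5 decoy cores; 10 TE tracts of 2 kb (tandem
  50-mers); a 200-bp site-free flank zone around every core.
* Core site frequencies are drawn from the folded neutral frequency
  spectrum ($P(j) \propto 1/j$), *conditioned* on each 50-bp window's
  expected heterozygosity falling in [0.55, 1.0] (core $\pi \approx$
  0.013, ~11 SNPs per 150-bp core). The conditioning mirrors how
  high-diversity targets are ascertained from real data and is what makes
  the generator self-consistent: an unconditioned SFS leaves many core
  windows below the 0.005 detection floor, while Beta-distributed
  intermediate frequencies push Tajima's D to ≈ +1.7 and fail the
  neutrality filter for half the planted cores. The conditioned SFS keeps
  D centred near zero with ~95% of planted cores passing the full cascade
  at these sample sizes.
* Two subpopulations of 22 diploids diverged at Balding–Nichols F = 0.05,
  plus 6 half-admixed individuals drawing each allele from a parent
  population independently; 2 samples are deliberately low-depth (3,000×)
  to exercise the per-region depth exclusion.
* Decoy cores model collapsed duplications: their core + flanks are copied
  verbatim elsewhere in the reference (driving off-target detection and
  multimap labels), their depth is doubled, and they carry 6 paralogous
  sequence variants that appear heterozygous in every sample — jointly
  pushing them over the $\pi$/SNP ceilings of the copy-number screen.
* Background sites occur at 5 × 10⁻⁴ per bp with Beta(1, 30) (rare-skewed)
  frequencies. Occasionally a background site drifts to intermediate
  frequency and a single 50-bp window clears the core threshold; these
  single-SNP false candidates are what keeps the pipeline's false-discovery
  rate non-trivially above zero (~0–10% across seeds) and are left in
  deliberately — a detector tested only on clean separations proves little.
* Annotation spiking (`simulate_annotated_vcf()`) draws passing baseline
  QD/FS/ReadPosRankSum values and corrupts a known 5% of records per rule,
  returning truth labels so the hard filter can be scored for
  confusion-free behaviour.
* The read model (`simulate_read_table()`) draws a log-normal per-primer
  amplification bias (sd 0.5) that multiplies the balancing factor;
  the bias can be carried across calls to emulate technical replicates of
  the same primer pool. Reads from decoy loci are multimap-flagged with
  probability 0.9, others at 0.005; 5% of reads fall off-panel.

Everything is deterministic under the config seed; the RNG state of the
caller is restored after every generator call.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: linkage disequilibrium and coalescent
genealogies (sites are independent given their frequencies, so D's
*distribution* is narrower than in real genomes); base-level sequencing
error and indels; real TE families (tracts are clean tandem repeats);
reference bias and mappability structure; and laboratory noise in read
counts beyond the log-normal primer bias (the simulated run-to-run
correlation is accordingly higher than a wet replicate's would be). The
tests demonstrate that the *mechanics* — estimators, filters, selection,
matching — are correct against independent oracles under controlled
conditions, not that the thresholds are optimal for any particular
organism.

## Numerical and interface choices

* All internal coordinates are 0-based half-open; conversion happens only
  in readers/writers (VCF positions, Biostrings 1-based matches). One
  convention everywhere eliminates off-by-one drift.
* Windows tile contigs non-overlapping at the window size — the simplest
  reading of a fixed-window scan; a step parameter exists for sensitivity
  analysis.
* Degenerate inputs return `NA` with a reason (D with S = 0 or n < 4, f
  with no polymorphic site, r² with zero variance, PI_HAT with too few
  informative sites) and are never silently coerced to a passing or
  failing value.
* Ties are broken deterministically everywhere: kinship pruning (more
  missing data, then later id), final-set choice (median gap, then lower
  seed), truncation (first locus in order among equals).
* Test and acceptance problem sizes — 450 kb genome, 50 + 5 planted
  regions, 50 diploids, ~800 variants, 10⁵ reads, 100-trial oracle loops,
  1,000-site kinship pairs — are the package's chosen reference scale: big
  enough that every filter path and estimator regime is exercised with
  stable statistics, small enough to re-run on a laptop in well under a
  minute.

## Known limitations

* The windowed π denominator ignores accessibility; on real data with an
  accessibility mask the thresholds would need recalibration.
* Tajima's D sample-size constants use the region's genotyped sample
  count; with heavy, sample-biased missingness a per-site-n estimator
  would be preferable.
* The dimer screen is sequence-complementarity only — no ΔG, no hairpins.
* In-silico PCR is substitution-only by design; primers with indel-mediated
  off-targets will be missed, as they are by the mismatch-percent model it
  follows.
* `ld_prune()` is quadratic per window; it is meant for panel-scale and
  candidate-scale inputs, not genome-wide WGS matrices.
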