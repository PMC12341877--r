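---
title: "Methods: linkage-map anchoring, LD-based Ne and mixed-model association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linkage-map anchoring, LD-based Ne and mixed-model association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pinekit implements the bespoke computational stages of a conifer
genome-and-population-genomics workflow: building chromosome-scale
pseudomolecules from a fragmented assembly and several parental linkage
maps, joining contigs on transcript evidence, and the population-genomic
layer usually run on top of such an assembly — windowed diversity
statistics, linkage-disequilibrium (LD) decay, LD-based effective
population size (Ne), PCA, and mixed-model genome-wide association. Every
stage is exercised against a bundled synthetic-data generator with known
ground truth; this vignette records the models, the defaults, and the
design choices that were genuinely open.

## Anchoring contigs with linkage maps

Markers carry a genetic position (cM within a linkage group, one map per
parent) and a physical position (an alignment to a contig). Anchoring
proceeds in fixed stages:

1. **Marker filtering** (`filter_markers`). Configured (parent, linkage
   group) exclusions are dropped first (the motivating case is a single
   parental linkage group carrying a putative rearrangement), then any
   marker whose rows across parents name more than one linkage group is
   removed entirely. Counts per rule are reported so filter reports are
   reproducible.
2. **Assignment** (`assign_markers`). Markers are processed in map order —
   the highest-weight parent's map sorted by linkage group and cM, then
   markers seen only on lower-weight maps. A marker hitting several contigs
   equally well takes the contig already holding one of its immediate cM
   neighbours if there is one (so a small contig spanning consecutive
   markers beats a large one), otherwise the largest contig not yet matched
   to any marker, falling back to the largest overall; remaining ties break
   by contig id. "Adjacent" is defined on the highest-weight map carrying
   the marker; the adjacency notion is otherwise underdetermined, and this
   choice makes the procedure deterministic.
3. **Chimera detection and splitting** (`detect_chimeras`,
   `locate_split`, `split_contigs`). A contig is chimeric when its markers,
   ordered by offset, form two or more maximal same-linkage-group blocks of
   at least `chunk = 2` markers each. The cut is the largest N-run strictly
   between the flanking markers — ties go to the leftmost run — and the cut
   removes the whole run, giving clean child sequences; with no N-run the
   cut is zero-width, directly after the left block's last marker. Children
   are named `<parent>.1`, `<parent>.2`, ... and placements re-offset.
4. **Ordering and orientation** (`order_and_orient`). Instead of a
   stochastic genetic-algorithm scaffolder, the layout is deterministic: a
   contig's position score is the weighted mean of its markers' cM, with
   per-parent weights (defaults 3, 2, 1, 1 — the conventional
   highest-trust-first weighting) renormalised over the parents actually
   carrying the markers. Orientation is the sign of the weighted mean of
   per-parent Spearman correlations between cM and offset; contigs with a
   single marker stay anchored but unoriented (`?`). Determinism makes the
   acceptance surface (order recovery, collinearity) reproducible run to
   run; on synthetic data the recovery is exact, which is what a
   genetic-algorithm orderer achieves only stochastically.
5. **Diagnostics.** `collinearity_stats` reports the Spearman correlation
   between cM and pseudomolecule position per (parent, linkage group) and
   its mean; `recomb_rate_track` interpolates cM piecewise-linearly along
   the pseudomolecule (negative local slopes are clamped to zero and
   counted) and reports cM/Mb per window.

Pseudomolecules are emitted as AGP v2.1 plus FASTA; gaps between parts are
100 N (`U` rows, evidence "map"), the scaffolding convention when the true
gap size is unknown. All internal coordinates are 0-based half-open;
conversion to the 1-based inclusive AGP/VCF conventions happens only at
the I/O boundary.

## Transcript-evidence joining

Transcripts aligned to two contigs are evidence the contigs are adjacent.
`filter_alignments` keeps a transcript iff (a) its aligned transcript
intervals cover at least 80% of the transcript, (b) for each pair of blocks
on different contigs the transcript-interval overlap is at most 50% of the
shorter block's span, and (c) strands are mutually consistent. The
denominator of the overlap rule is genuinely ambiguous in the field's
informal usage; we use the shorter block's transcript span and expose the
fraction as a parameter. `propose_joins` converts consecutive block pairs
into end-to-end join candidates and counts support in distinct transcripts
(not alignments). `resolve_conflicts` accepts candidates greedily by
descending support — mirroring "the most abundant joining wins" — with
lexicographic tie-breaks, rejecting candidates whose contig end is consumed
or which would close a cycle; greedy resolution is deterministic and
matches the abundance rule, at the cost of global optimality (which the
evidence does not justify anyway). `apply_joins` merges chains with 100-N
gaps; transcript-implied gap lengths are not used because intron sizes make
them uninformative. Joined contigs are re-checked for chimerism with the
same machinery as the anchoring stage (`rejoin_chimera_check`), and the
pipeline order is join, then split, then anchor.

## Variant filtering and windowed diversity

`filter_variants` applies, in a fixed order, quality (QUAL >= 30),
missingness (<= 20%), the exact Hardy-Weinberg test (p > 1e-4), and an
optional MAF floor, reporting counts per rule. The HWE test is the standard
exact conditional test (all heterozygote counts compatible with the allele
counts, summing probabilities no larger than the observed one) computed
from log-factorials; no mid-p variant.

`window_stats` works in non-overlapping windows aligned to multiples of the
window size (10 kb default). Per site, with n non-missing allele copies of
which n_alt are alternate, heterozygosity is 2 n_ref n_alt / (n (n-1));
window pi is the sum over sites divided by the window length. Tajima's D
uses the classical constants evaluated at the window's average n over
segregating sites (literal harmonic sums for integer n, digamma otherwise)
and is missing when S = 0.

## LD, pruning, PCA

r2 is the squared Pearson correlation of dosage vectors over samples
non-missing at both sites — the genotype-count r2 appropriate for unphased
low-coverage data and the default of the common LD tools; haplotype-EM r2
is out of scope. Pairs with fewer than 4 complete samples or zero variance
are skipped. Pairs are formed within 100 kb by default and averaged in 1-kb
bins; the LD extent is the linearly interpolated distance at which the
binned mean first drops below 0.2 (censored at the last bin when it never
does). `ld_prune` scans left to right and removes the later site of any
pair within 100 kb with r2 > 0.2; the surviving set provably contains no
such pair, and tests assert that postcondition directly. PCA mean-imputes
missing dosages, centres and unit-scales sites, and takes the SVD; percent
variance is the eigenvalue share.

## LD-based effective population size

Each distance bin maps to a recombination fraction c = d x c_rate (linear
map function — at these distances a mapping function correction is
negligible) and a time depth t = 1/(2c) generations. The bin's mean r2,
adjusted for sample size (r2_adj = r2 - 1/n for unphased dosage r2), is
inverted through the Sved-type expectation E[r2] = 1/(a + 4 Ne c) with
a = 2.2 for unphased samples:

Ne(t) = (1/(4c)) (1/r2_adj - a).

Bins whose adjusted r2 is non-positive or implies 1/r2_adj <= a carry no
information about a positive Ne and are dropped with a count. The
trajectory is smoothed by an 11-point centred rolling median (ends
truncated) followed by a cubic smoothing spline on (log t, log Ne); a
constant or short series passes through unsplined.

Two caveats are worth recording because they shape the tests. First, the
Sved inversion is approximate: simulated data (both this package's
forward model and an independent coalescent) show the mean dosage r2 at
sample MAF >= 0.05 sits below 1/(a + 4 Ne c) at short distances, so
absolute Ne estimates are biased upward there; the inversion is most
reliable at moderate scaled recombination (4 Ne c around 1-4). Second,
with a small sample (n = 40) a 0.05 sample-MAF floor admits rare alleles
whose r2 is systematically depressed, amplifying that bias. The recovery
test therefore evaluates the estimator where it is designed to operate:
sample MAF >= 0.10 (the stricter of the two MAF sets the LD analysis
runs) and the central half of the analysed distance range. Under those
conditions a constant-size population is recovered within the +/-30%
band the tests assert; outside them the known upward bias dominates, and
trajectories should be read as relative, not absolute — the usual reading
of this family of estimators.

## Mixed-model association

`ibs_kinship` is the identity-by-state similarity 1 - mean |d_i - d_j| / 2
over pairwise-complete sites. `fit_null` fits y = Xb + u + e with
Var(u) = sg2 K by REML, via one eigendecomposition of K and a 1-D search
over the variance ratio (log-spaced grid refined by Brent optimisation);
boundary estimates are flagged, and K with numerically constant
eigenvalues (e.g. K = I) is flagged unidentifiable — only the total
variance is then estimable, which reduces scoring to ordinary least
squares. `score_snps` fixes the covariance at the null estimates,
whitens through the eigenbasis, projects covariates out once, and tests
each (mean-imputed, MAF >= 0.01) SNP with a 1-df statistic referred to
chi-squared(1) — the standard large-n approximation; an F(1, n-p-1)
reference is available by flag. Genomic control lambda is the median
statistic over 0.4549364. Variance explained by significant SNPs
(threshold 5e-5 by default; 1e-5 also supported) is the plain joint-OLS
R-squared on their dosages, the simplest defensible definition where no
canonical one exists. PCs passed as covariates are computed on the
(optionally LD-pruned) genotype matrix.

## The synthetic-data generators

The generators define the study conditions for every test; the real study
data (a ~20 Gbp conifer genome, 40 resequenced trees, a breeding
population of thousands) is far beyond desk scale, so all guarantees are
property-based on synthetic data.

* `simulate_genome` cuts random chromosomes into fragments (minimum 500
  bp), stores most as single-fragment contigs in random orientation, and
  plants inter-chromosomal chimeras — two fragments from distinct
  chromosomes, optionally separated by a 100-bp junction N-run. Chimeras
  are always inter-chromosomal because the detection rule only sees
  between-linkage-group conflicts. `chimera_min_frag` restricts chimera
  arms to fragments long enough to catch markers.
* `simulate_linkage_maps` places markers evenly spaced with uniform jitter
  (30% of the spacing by default) — even spacing guarantees any region a
  few spacings wide carries markers, which uniform placement does not —
  and reports per-parent cM as (position / chromosome length) x 100 cM
  plus Normal(0, noise_sd) noise truncated at zero. Default weights are
  3, 2, 1, 1 across four parents.
* `simulate_transcripts` spans adjacent contig pairs with 600-bp
  transcripts split at the boundary, plus within-contig transcripts,
  optional conflicting decoys (support 1 against stacked true support) and
  optional coverage degradation to below the 80% filter.
* `simulate_wright_fisher` is a forward-in-time diploid Wright-Fisher
  model: random mating, Poisson(L x c) crossovers at uniform positions,
  infinite-sites mutation on integer coordinates (collisions with live
  sites are redrawn — VCF needs integer positions), a burn-in of 6 x Ne
  generations at the oldest epoch size (enough for LD to equilibrate),
  then arbitrary piecewise-constant Ne epochs. A forward model was chosen
  over a coalescent because it supports arbitrary Ne trajectories and
  direct LD truth trivially, at desk scale (Ne <= 500). The per-gamete
  mutation rate is calibrated from the requested number of segregating
  sites via Watterson's formula. Agreement with an independent coalescent
  simulator was verified during development (mean r2 by distance matches
  to within Monte-Carlo error).
* `simulate_structured_pop` splits one equilibrium population into two
  that drift independently, sampling half the individuals from each; with
  `n_chrom > 1` the whole process is replicated per chromosome so
  genealogical noise averages out, as across real chromosomes. (Individuals
  then have independent pedigrees per chromosome — adequate for testing
  structure corrections, not for pedigree-exact kinship.)
* `simulate_trait` standardises a QTL component and an optional polygenic
  component, mixes them by a polygenic fraction, and scales against unit
  Normal noise so realised narrow-sense heritability matches the target.

What the generators deliberately omit: selection, migration, gene
conversion, sequencing error, genotyping error, real pedigree structure
across chromosomes, and any read-level simulation. Passing tests therefore
demonstrate algorithmic correctness and statistical calibration under the
stated models — not robustness to the full messiness of real resequencing
data.

## Problem sizes and numerical choices

The test suite runs at these scales, chosen as the smallest that make the
statistical assertions stable: anchoring at 12 chromosomes x 50 contigs
with 4 maps of 60 markers per linkage group; chimera handling with 20
planted chimeras over 6 chromosomes; joining with 200 junction, 200
within-contig and 50 decoy transcripts; Ne recovery over 20 replicates of
(Ne = 100, n = 40, 1 Mb, c = 1e-8) and a 400 -> 50 decline over 6
replicates; association calibration over four independent two-population
samples (n = 500, six chromosomes each, c = 5e-7 so LD blocks are
numerous and tests approach independence) with six null traits each,
giving > 100,000 tests; that calibration uses the F reference, the
appropriate finite-sample choice at n = 500, where the chi-squared tail
is visibly anti-conservative.

Numerical conventions worth knowing: all tie-breaks are documented and
deterministic (largest-then-lexicographic contigs, leftmost N-run,
lexicographic join pairs); negative cM slopes in the recombination track
are clamped to zero and counted; eigenvalues of K are floored at zero and
a matrix failing PSD beyond jitter is an error; the REML search runs on
log10(ratio) in [-5, 5] and flags boundary solutions; exact-test p-values
are capped into (0, 1] by construction.

## Known limitations

Absolute Ne levels inherit the Sved-inversion bias discussed above.
The EMMAX-style single-variance-component approximation understates
uncertainty when a tested SNP contributes appreciably to the kinship
("proximal contamination"); with a single simulated region this is visible
as signal absorption, and the tests therefore calibrate scoring against
independent genotypes. The chi-squared reference is anti-conservative at
small n (use `ref = "f"` there). The joining stage trusts its alignments:
misassembled transcripts that pass the coverage/overlap/orientation rules
will propose wrong joins, mitigated only by the abundance rule.
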