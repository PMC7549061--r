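---
title: "Genome-composition QC for Musa hybrids: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-composition QC for Musa hybrids: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musapaint)
```

## The problem

Cultivated bananas are diploid to tetraploid combinations of two
subgenomes: A from *Musa acuminata* and B from *M. balbisiana*. A
cultivar's label — AA, AAB, ABB, and so on — is a claim about how many
copies of each subgenome it carries. Sequencing data can check that
claim: when reads are aligned against the A reference, sites where the B
genome carries a fixed, divergent allele let every read be attributed to
a subgenome, and the fraction of B-supporting reads at such a site
estimates the B copy number over the ploidy. musapaint implements that
quality-control analysis end to end, together with a synthetic data
generator so each stage can be verified against known truth.

The pipeline has four analytical stages plus the generator, and this
vignette documents the model behind each stage, the tunable parameters
with their defaults, and the places where the design was genuinely open.

## The synthetic-data generator

`generate_subgenomes()` simulates an A reference and a B genome diverged
from it by independent per-base substitutions (default rate 0.005/bp).
The divergence rate is a free simulation parameter, not an empirical
estimate: real A/B divergence varies along the genome and no single
published figure maps onto this simulator's idealised geometry, so 0.005
was fixed once as a round value giving a realistic diagnostic-SNP
density (roughly one informative site per 200 bp before filtering).
Small (1–3 bp) indels private to one subgenome are simulated at a
default 2×10⁻⁴/bp; they exist to exercise the indel-aware filters, and
are recorded as annotations rather than applied to the sequences, so
both subgenomes stay in the A coordinate system (coordinates are 1-based
and intervals half-open throughout).

`compose_genotype()` builds an accession from a composition string
("AAB") plus optional homeologous-exchange segments, each replacing a
slice of one chromosome copy with the other subgenome's sequence.
`simulate_pileup()` then draws, per position, a Poisson read depth
(default mean 30, the centre of the 20–60× range the analysis targets),
assigns each read a uniformly chosen chromosome copy, and miscalls it to
a uniform other base with the error probability (default 0.005). The
expected B-read fraction at a site with true dosage *d* is therefore
*d*(1−*e*) + (1−*d*)*e*/3, which the tests check empirically.

What the generator deliberately does not model: read pairs and mapping
(the pipeline consumes pileups, so fragment structure adds nothing
testable), platform-specific error profiles, mapping ambiguity in
repeats, and within-subgenome heterozygosity. The last one matters for
interpretation: a composed "AAB" accession is heterozygous *only* at
A/B-divergent sites, all at dosage 1/3, whereas real accessions also
segregate within each subgenome. The frequency-level simulator
`simulate_allele_frequencies()` models that natural heterozygosity
directly (allelic copy number uniform on 1..ploidy−1) and is what the
ploidy-recovery checks use. Passing tests on these simulations show the
machinery is correct under the stated error model; they do not certify
performance on repeat-rich real alignments, where mis-mapping noise is
structured rather than uniform.

## Variant calling

`call_variants()` stands in for the mpileup-plus-multiallelic-caller
step. It emits a substitution call wherever at least `min_alt_reads`
(default 2) non-reference bases are seen, and an indel call wherever any
read supports an indel. QUAL is defined as the phred-scaled binomial
tail probability that the observed non-reference count arises from
sequencing error alone, −10·log₁₀ P(X ≥ n_alt) with
X ~ Binomial(depth, error_rate), capped at 999 (at the assumed error
rate of 0.005 the tail shrinks by roughly 23 phred per supporting read,
so the cap binds at depths ≥ 44 when every read is non-reference). This
is not the genotype-likelihood QUAL of the original caller, whose priors
are not reproduced here; it is monotone in the same quantities and fully
specified, so a brute-force summation oracle can check it exactly. A
diploid maximum-likelihood genotype is emitted for VCF completeness but
nothing downstream consumes it — dosage, not genotype, drives the
analysis.

## The diagnostic-SNP filter chain

`filter_variants()` applies the standard chain: QUAL ≥ 35, depth ≥ 5,
indel records excluded, and SNPs discarded when within 100 bp of a
credible indel, where "credible" means at least 2 indel-supporting reads
(IDV ≥ 2). Two boundary conventions needed fixing: "within 100 bp"
excludes the boundary case (distance exactly 100 is dropped), matching
the documented behaviour of the `--SnpGap` flag this rule mirrors; and
distance is measured to the indel's anchor position, ignoring indel
length — a deliberate simplification, acceptable because simulated
indels are 1–3 bp.

`identify_informative_snps()` then keeps the filtered sites at which a
pure B accession looks homozygous non-reference. The homozygosity
requirement (`hom_fraction`, default 0.9) is not quantified in the
analyses this package systematises; 0.9 tolerates up to 10%
contaminating reads at 20–60× depth while still excluding genuinely
heterozygous sites, whose alternate fraction concentrates near 0.5.
At multiallelic sites only the major alternate becomes the B allele;
minor alternates are ignored for dosage.

## Dosage painting

`quantify_b_fraction()` counts A- and B-allele reads at each diagnostic
SNP, keeping sites with depth in the inclusive window [10, 50]
("between 10 and 50" read inclusively, consistent with the MIN/MAX
style of the other filters). Reads carrying a third allele are excluded
from both numerator and denominator. Each kept site yields
pct_b = 100·b/(a+b).

`loess_smooth()` fits a locally weighted polynomial (tricube weights,
via `stats::loess`, exact "direct" surface) of pct_b against position,
per chromosome — per-chromosome rather than genome-wide because the
painted tracks are per-chromosome objects and smoothing across
chromosome boundaries would be meaningless. Span and degree are the
consequential unstated parameters of this stage; the defaults are span
0.5 and degree 2 (the `loess` default degree). The span is exposed
everywhere, because it sets the resolution of the painting: segment
boundaries blur over roughly span × chromosome-length. For
homeologous-exchange detection at megabase scale the examples use span
0.1. Smoothing is unweighted by depth by default (the percentages
themselves are smoothed); a depth-weighted variant sits behind
`weight_by_depth = TRUE`.

`classify_track()` paints smoothed values into the three standard
bands — A-like [0, 33), mixed [33, 66), B-like [66, 100] — using a
half-open convention at the internal boundaries (a value of exactly 33
is mixed, exactly 66 is B-like). `write_circos_track()` emits the
plain-text `chrom start end value` records a circular plotter consumes,
plus one highlight interval per run of same-class points; rendering the
figure itself is out of scope.

## Ploidy inference

At a heterozygous site in a sample of ploidy *p*, the non-reference
allele sits on *k* of *p* copies, so its read fraction clusters near
*k*/*p*: {1/2} for diploids, {1/3, 2/3} for triploids, {1/4, 1/2, 3/4}
for tetraploids. `extract_site_frequencies()` collects reference-
oriented allele fractions at biallelic sites with depth ≥ 10, both
alleles on ≥ 2 reads, and minor-allele fraction ≥ 0.1. The fraction
floor needs a word: recurrent sequencing errors (two identical miscalls
in a 30-read column) otherwise masquerade as heterozygosity at
fractions near 2/30 ≈ 0.07, well below any true allelic ratio for
ploidy 2–4 but close enough to 1/4 to distort model selection. The
floor must sit above that error regime and below 1/4 minus the binomial
spread at the lower end of the targeted depth range; 0.1 satisfies both
with margin, while a floor as high as 0.2 would truncate the tetraploid
1/4 and 3/4 clusters at 30× and cripple tetraploid recovery.

`denoise()` emulates the de-noising step that precedes model fitting:
a three-Gaussian-plus-uniform(0,1) mixture is fitted by EM and sites
with posterior mass above 0.5 on the uniform component are dropped. The
uniform component is the package's operationalisation of "noise from
mis-mapping in repetitive regions"; the reference tool's internal
scheme is not published in enough detail to clone, so the posterior cut
(default 0.5, exposed as `max_noise_posterior`) is documented as this
package's choice.

`fit_fixed_model()` fits, for each candidate ploidy, a Gaussian mixture
with means fixed at the *k*/*p* fractions, free weights, and one shared
standard deviation, by EM to an absolute tolerance of 10⁻⁸ nats
(maximum 500 iterations; the de-noising fit uses 10⁻⁶ and up to 2000
iterations, since free means covering a single cluster drift for
hundreds of iterations at likelihood changes that cannot move a 0.5
posterior cut). Gaussians are used unnormalised over (0,1) — truncation
is ignored, a good approximation for the sd ≤ 0.15 regime these data
occupy. The shared sd is floored at 10⁻⁴ (with a warning) to keep
degenerate point-mass inputs finite. `fit_free_model()` fits the
reference model — three Gaussians with free means, free weights, shared
sd — from several deterministic restarts: quantile-based starts plus
one start per fixed model constructed to reproduce that model's
converged density exactly (padding a mixture with a duplicated mean
changes nothing about its density), which guarantees, by EM
monotonicity, that the free fit never scores below any fixed fit.

`infer_ploidy()` reports the delta log-likelihood
logL(free) − logL(fixed) for each ploidy and selects the smallest. One
selection subtlety is handled explicitly: the tetraploid mean set
contains the diploid's, so on truly diploid data the tetraploid fit can
never score worse and typically edges ahead by a fraction of a nat of
pure overfitting — which is also the direction of the known tendency of
this model family to call heterozygous diploids tetraploid. Delta
differences below `tie_nats` (default 2, the free-parameter-count
difference between the most and least complex fixed models — the AIC
yardstick) are therefore treated as ties and resolved toward the lower
ploidy, with a warning. Genuinely different ploidies separate by
hundreds of nats at realistic site counts, so the margin only ever
arbitrates the nested near-ties. With fewer than 50 usable sites the
result is an explicit "undetermined", never a silent default — pure-A
or pure-B accessions land there by construction, since they have almost
no heterozygous sites.

## Reconciliation

`infer_composition()` turns a genome-wide median smoothed percent-B
into a composition: below `pure_threshold` percent (default 5) the call
is "exclusively A", above 100 − threshold "exclusively B", otherwise
k = round(ploidy · pct/100) B copies. The purity threshold is a
documented operational choice — "exclusively" is described, not
quantified, in the tables this reproduces — and it is logged in every
report header. The genome-wide statistic is the median of the smoothed
track, robust to a minority of exchanged or mis-painted segments.

`reconcile()` compares against the expected composition, with two rules
taken from the precedent of the published verdict table. First, a
ploidy discrepancy alone never flips a verdict to "No": verified
accessions exist with observed tetraploidy against an expected diploid
label and a consistent composition, so the verdict judges the B-copy
count at the *expected* ploidy, while the observed-ploidy composition
and a `ploidy_note` are reported alongside. Second, multi-alternative
expectations ("AAB or ABB") match if any alternative matches. An
expected hybrid whose dosage says pure A yields the specific verdict
string "No: appears to be exclusively A".

## Problem sizes used in the checks

The shipped verification suite exercises: filter-chain equivalence
against a brute-force oracle on 200 randomised calls; diagnostic-SNP
recovery on a 1 Mb simulation (expecting ≥ 95% of eligible divergent
sites recovered at < 1% false discovery); dosage recovery for AAB, ABB
and AA accessions at ≥ 1000 diagnostic sites and 30× depth; painting of
a 2 Mb homeologous exchange on a 5 Mb chromosome at span 0.1, with
breakpoints recovered within one bandwidth; ploidy recovery over 100
simulated accessions of 5000 heterozygous sites each; EM agreement with
a dense grid search within 10⁻³ nats on 2000 sites; and a 16-accession
panel with three deliberately mislabelled members, which must be
flagged exactly. These sizes were chosen as the smallest at which the
statistical assertions have comfortable margins.

## Known limitations

* QUAL values do not numerically match any specific external caller;
  only the filter semantics are reproduced.
* Indel lengths are ignored by the SNP-gap rule (anchor distance only).
* The ploidy model covers ploidy 2–4 only, genome-wide; per-chromosome
  aneuploidy is out of scope.
* The uniform-noise de-noising model is a stand-in for structured
  mis-mapping noise; on real repeat-rich data it under-describes the
  contamination.
* Truncation of the mixture Gaussians to (0,1) is ignored; fits with
  shared sd approaching 0.15 should be treated with caution.
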