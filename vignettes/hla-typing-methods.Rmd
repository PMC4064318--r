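---
title: "Two-digit HLA typing from RNA-Seq: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-digit HLA typing from RNA-Seq: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `hlatyper`, the
parameters that matter, the synthetic-data generator used throughout the
test suite, and the design decisions taken where the procedure admits more
than one reasonable reading.

## The problem

The classical HLA loci are extremely polymorphic, yet alleles are so
similar to one another (different two-digit groups of one locus typically
differ by only a few percent of positions over the peptide-binding exons)
that a short RNA-Seq read almost never identifies a single allele: most
reads map to many alleles, often to several groups, sometimes to several
loci. The package's diversity module quantifies this directly — on
realistic allele sets only a minority of alleles contain any length-37
substring unique to them, and almost none do once one mismatch is
tolerated. Typing therefore cannot rely on unique evidence; it must treat
ambiguous read counts as a distribution and ask which group is an
*outlier* of that distribution.

## Reference sub-transcripts

Typing aligns against exon-derived sub-transcripts rather than full
transcripts, concentrating signal on the polymorphic peptide-binding
region while keeping enough flanking sequence that reads straddling an
exon boundary still map:

* class I: exon 1 (73 nt canonically) + exon 2 + exon 3 + first 75 nt of
  exon 4 → 694 nt for canonical exon lengths;
* class II: last 75 nt of exon 1 + exon 2 + first 75 nt of exon 3 →
  400 nt (DQA1) and 421 nt (DQB1, DRB1) canonically.

Records lacking a required exon are rejected individually (with a reason)
rather than failing the whole reference build. A flanking exon shorter
than 75 nt is used in full and only flagged (`short_flank`): truncated
database entries are common enough that rejecting them would throw away
usable alleles, while the flag preserves the information that the record's
normalization length is nonstandard.

## Alignment contract

Alignment is ungapped and end-to-end with a fixed substitution budget
`v`, reported on both strands at all offsets. This is deliberate: the
calling algorithm was tuned on exactly this mapping behaviour, and indels
within the exonic reference are rare enough at two-digit resolution that a
Hamming placement model is adequate. `N` never matches anything, including
another `N` — conservative and easy to reason about.

Internally the aligner is pigeonhole seed-and-extend over an exact k-mer
index (k = ⌊min read length/(v+1)⌋): a placement with ≤ v mismatches must
contain one of v+1 disjoint exact seeds, so index lookups enumerate a
candidate superset that is then verified by capped mismatch counting. The
result is *identical* to brute-force enumeration — the test suite asserts
set equality against an independent exhaustive oracle — it is only faster.
For degenerate inputs (reads shorter than about 8·(v+1) nt) the aligner
falls back to the full scan.

Defaults are `v = 1` and report-all. One mismatch is optimal for ~37-nt
reads at the 1–2 % substitution error typical of the platform: `v = 0`
discards every read carrying an error, `v = 2` admits too much cross-group
noise. Unique-only reporting (`report_policy = "unique"`) is supported but
known to perform badly — near-identical alleles make almost every
informative read multi-mapping — and the acceptance tests confirm the
direction.

Paired-end fragments count as one sampling event. A fragment hits an
allele when both mates place on it on opposite strands; no insert-size or
ordering constraint is imposed, because the reference is short (≤ 694 nt)
and any concordant placement on one allele is informative. This permissive
rule is this package's choice where the original procedure leaves pairing
unspecified.

## The calling statistic

Per locus, counts are per allele; per group the representative value is
the maximal allele count within the group, so the vector of per-group
values R contains the quantity a = max R that defines the winner. This
makes the winner-selection rule, the "top count" used by the confidence
formulas, and the requirement that a be an element of its own background
mutually consistent.

The confidence of a call is

> p(a) = upper tail of Normal(mean(R), sd(R)) at a,
> p_outlier = 1 − (1 − p(a))^x,

the probability that at least one of x background draws reaches a. In
iteration 1 the top count is removed from R before fitting (x = |R| − 1);
in iteration 2 it is kept, which inflates mean and sd and makes the second
call's test strictly harsher — a property the test suite asserts. Note
that a *published* variant of this formula writes the lower binomial tail
`pbinom(0, x, p)`, which equals (1 − p)^x — the *complement* of the prose
definition and large for confident calls. The package implements the
prose (small p = confident, consistent with filtering at p < 0.1) and
exposes the printed form behind `printed_form = TRUE` for comparability.

Numerical choices:

* sd uses the sample (n−1) denominator, matching `stats::sd()`;
* sd = 0 backgrounds use the normal limit: tail 0 above the constant
  background, 0.5 at it, 1 below;
* 1 − (1 − p)^x is computed as `-expm1(x * log1p(-p))` so that tiny tail
  probabilities survive to the p-value without cancellation;
* ties anywhere break deterministically — lexicographic group order for
  equal maximal counts, and the median of an even-length list is the mean
  of the two central values;
* an empty background (after removal) yields p-value 1: with nothing to
  beat, the call carries no evidence of being an outlier.

## Zygosity

The decision threshold is the median per-allele count of iteration 1 —
the "typical" count an allele of this locus reaches through ambiguous
mapping alone. A second-iteration winner above the threshold is
heterozygous. For class II loci the threshold is halved: within-class
sequence similarity is higher, far more reads map ambiguously in
iteration 1, and the unmodified median is too demanding.

For second winners below the threshold the locus is homozygous, with a
certainty p-value computed by the same outlier machinery with the
threshold itself in the role of the top value, tested against the
iteration-2 per-group counts augmented by the threshold. The farther the
residual counts sit below the threshold, the smaller the p-value. The
orientation matters: testing the (small) second-winner count instead would
give confident homozygotes p ≈ 1 and flag every one of them as uncertain,
inverting the stated meaning of the score. With the threshold as the
tested value the p-value is small exactly when the locus is confidently
homozygous, and large when the second winner sits just under the
threshold — those borderline cases (including exact equality) are reported
as `ambiguous` ("likely homozygous or single allele expressed") whenever
the homozygosity p-value fails the call cutoff. That trigger is a
reconstruction of a narratively-described rule and is flagged as such in
the documentation.

Loci are processed independently over the full read set: cross-locus
ambiguous fragments contribute to every locus's background, and
winner-removal before iteration 2 is scoped to the locus being called.

## Expression

Every mapped fragment is assigned fractionally: 1/k to each of the k
*determined* groups (first winner, plus second winner if heterozygous) it
hits, so read mass is conserved exactly — the sum of fractional counts
equals the number of fragments hitting at least one determined group.
RPKM uses the mean sub-transcript length of the called groups' alleles by
default, or the canonical constants 694/694/694/400/421/421 nt on request.
The per-million denominator defaults to the number of input fragments,
with an override for an externally computed library-wide mapped total:
since the package maps only against HLA, neither choice is canonical, and
both are supported without asserting either as "the" original.

## The simulator

`sim_db_config()`/`make_allele_db()` generate an allele database by
hierarchical mutation: a class root sequence, locus ancestors mutated from
it at `cross_locus_divergence`, group founders at `inter_group_divergence`,
alleles at `intra_group_divergence`. All three are **per-lineage**
substitution rates relative to the immediate ancestor; expected pairwise
differing-site fractions are path sums with a collision correction
(p₁ + p₂ − 4/3·p₁p₂, since substitutions go to a random other base). The
defaults — intra 0.5 %, inter 3 %, cross 8 % — give ~1 % divergence within
a group, ~6–7 % between groups of one locus and ~85 % overall identity,
close to real two-digit HLA structure. The per-lineage reading is also the
one under which the two-iteration caller behaves as it does on real data;
interpreting the same numbers as pairwise distances would halve inter-group
divergence and push the second haplotype's reads below the zygosity
threshold of an 8-group locus, a regime real HLA does not occupy.

`simulate_reads()` draws fragments uniformly along the chosen allele's
sub-transcript (haplotypes 50/50), normal fragment lengths (default
120 ± 20 nt, truncated to the feasible range), opposite-strand mates from
the fragment ends, and per-base substitution errors (default 1 %).
Qualities are constant placeholders: the algorithm never reads them.

The simulator intentionally does **not** model indels or splicing noise
(the aligner contract is ungapped), GC or positional coverage bias,
quality-dependent errors, chimeric fragments, or a whole-transcriptome
background. Passing tests therefore demonstrate the correctness of the
counting statistics and the recoverability of genotypes under the stated
read model — not robustness to every artefact of real libraries, nor
performance on a real, far larger (thousands of alleles per locus) allele
database, where group backgrounds are richer and confidence p-values are
correspondingly smaller.

## Test problem sizes

The study-condition checks run a 6-locus reference with 8 groups × 5
alleles per locus, 37-nt paired-end reads at 1 % error, 2,000 fragments
per locus, and a cohort of 20 individuals (with an 8-individual subset for
the protocol-direction comparisons) under fixed seeds — small enough to
run in about a minute, large enough that heterozygous and homozygous
recovery rates are meaningful. Aligner-vs-oracle equivalence uses toy
databases of up to 10 alleles × 300 nt with a few hundred reads, where
exhaustive enumeration is feasible.

## Known limitations

* Two-digit resolution only; four-digit (protein-level) calling is out of
  scope and would require a different evidence model.
* Homozygosity vs a single expressed allele (severe allelic imbalance)
  cannot be distinguished from read counts alone; the `ambiguous` status
  is the honest output for that situation.
* Published percentage figures tied to specific allele-database releases
  (identity percentages, unique-tag fractions) are
  database-version-dependent and are not reproduction targets; the package
  reproduces the *methods* that compute them.
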