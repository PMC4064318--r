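# hlatyper

Two-digit HLA typing, zygosity and locus-level expression directly from
standard RNA-Seq reads.

The HLA loci (class I: HLA-A, -B, -C; class II: HLA-DQA1, -DQB1, -DRB1) are
the most polymorphic genes in the human genome, and the HLA type of a sample
matters for transplantation, immunotherapy, autoimmunity and
sample-identity QC. `hlatyper` determines the two-digit allele group
(e.g. `A*02`) expressed at each locus from bulk RNA-Seq FASTQ files —
without population priors and without any laboratory typing — and
simultaneously reports how strongly each locus is expressed. It is aimed at
anyone who already has RNA-Seq data and wants HLA types and HLA expression
as a by-product.

## Method

Reads are aligned ungapped and end-to-end against *sub-transcripts* of the
known HLA alleles: exons 2 and 3 (class I) or exon 2 (class II) encode the
peptide-binding site and carry most of the polymorphism, so the reference
for a class I allele is exon 1 + exon 2 + exon 3 + the first 75 nt of
exon 4 (694 nt for canonical exon lengths), and for class II the last 75 nt
of exon 1 + exon 2 + the first 75 nt of exon 3 (400/421/421 nt for
DQA1/DQB1/DRB1). Alignment allows at most *v* substitutions (default
*v* = 1, the optimum for ~37-nt reads at 1–2 % sequencing error) and
reports **all** placements — across near-identical alleles, ambiguous
mapping is signal, not noise.

Typing at locus *L* is a two-iteration procedure on the per-allele read
counts R<sub>L</sub>:

1. **First digital haplotype.** The winning group is the one containing
   the allele with the maximal count a = max R<sub>L</sub><sup>1</sup>.
   Its confidence is an outlier p-value: with p(a) the upper tail of a
   normal distribution fitted to the background per-group counts (mean and
   sample sd, the top count removed), the p-value is
   1 − (1 − p(a))<sup>x</sup> — the chance that at least one of the x
   background groups reaches a.
2. **Second digital haplotype.** All fragments touching the first winner
   are removed, counts are rebuilt, and the second winner is scored the
   same way except that the top count stays in the background (a stricter
   test).
3. **Zygosity.** The median per-allele count of iteration 1 (halved for
   class II, where ambiguous mapping inflates the background) is the
   decision threshold: a second winner above it means heterozygous; below
   it the locus is called homozygous, with a certainty p-value from the
   outlier test of the threshold against the residual iteration-2 counts.
   Borderline cases are reported as "likely homozygous or single allele
   expressed".

Expression assigns every mapped fragment fractionally (1/k to each of the
k determined groups it hits) and normalizes per locus to RPKM using the
sub-transcript length.

The package also ships the companion diversity analytics (per-position
Shannon variability of an allele alignment, intra-/inter-group Hamming
distance summaries, unique f-mer fractions as a function of tag length and
mismatch tolerance) and a fully seeded simulator of HLA-like allele
databases and diploid read sets, so the entire pipeline is testable with
known truth and no external downloads.

## Worked example

Simulate a diploid individual against a synthetic six-locus reference
(8 groups × 5 alleles per locus, 37-nt paired-end reads, 1 % error,
2,000 fragments per locus) and type it:

```r
library(hlatyper)

sim <- make_allele_db(sim_db_config(seed = 42))
gt  <- sim_genotype(sim, hom_prob = 0.25, seed = 7)   # truth
rd  <- simulate_reads(sim, gt, sim_read_config(), seed = 8)
ty  <- type_sample(rd$reads1, rd$reads2, sim$db, sample_id = "demo")
print(ty)
```

```
HLA type for sample demo
 locus allele1     p1 allele2     p2 zygosity_status
     A    A*03 0.0606    A*07 0.0551    heterozygous
     B    B*06 0.0738    B*02 0.0567    heterozygous
     C    C*03 0.0656    C*04 0.0532    heterozygous
  DQA1 DQA1*06 0.0513 DQA1*07 0.0543    heterozygous
  DQB1 DQB1*06 0.0732 DQB1*03 0.0525    heterozygous
  DRB1 DRB1*06 0.0756 DRB1*03 0.0537    heterozygous
```

All twelve called groups match the simulated truth; `p1`/`p2` are the
outlier p-values of the first and second digital haplotype (calls with
p < 0.1 are considered confident). Expression follows from the same
object:

```r
expression_profile(ty, sim$db)
```

```
HLA expression profile, demo
 locus fractional_count length_nt   rpkm
     A             1790       694 214900
     B             1786       694 214500
     C             1795       694 215500
  DQA1             1772       400 369200
  DQB1             1788       421 353900
  DRB1             1799       421 356100
class I total: 6.449e+05 RPKM, class II total: 1.079e+06 RPKM
```

Each locus recovers ~1,790 of its 2,000 simulated fragments as fractional
counts (the remainder failed the paired mismatch budget), and RPKM values
are equal across loci up to the sub-transcript length normalization, as
expected for uniform simulated expression.

A command-line wrapper with `simulate`, `build-ref`, `type`, `express` and
`diversity` subcommands is installed at `inst/scripts/hlatyper`:

```sh
Rscript inst/scripts/hlatyper simulate --seed 1 --out-dir demo --individuals 1
Rscript inst/scripts/hlatyper type --fastq1 demo/sim01_1.fastq \
    --fastq2 demo/sim01_2.fastq --reference demo/reference.fa --out-dir demo
```

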