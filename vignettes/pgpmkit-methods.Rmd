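---
title: "Fragment recruitment and consortium design with pgpmkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment recruitment and consortium design with pgpmkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(pgpmkit)
```

# The two problems

Developing a multi-strain inoculant for crops raises two computational
questions that this package addresses.

First, *environmental representation*: a candidate plant growth-promoting
microorganism (PGPM) is only useful if it can persist where it is applied.
Fragment recruitment estimates a genome's representation in soil, root or
rhizosphere shotgun metagenomes by counting reads that align to it at high
identity.

Second, *consortium assembly*: strains combined in one inoculant must be
able to coexist. Pairwise agar-diffusion assays classify strain pairs as
compatible (`+`), incompatible (`-`) or unclear (`nc`); consortium design
then becomes a graph problem on these verdicts.

# The recruitment model

## Hits and the identity threshold

A read of length $n$ is recruited to a genome when an ungapped,
full-length alignment to some genome window has identity
$\mathrm{matches}/n$ **strictly greater** than the threshold $t$ (default
$0.97$). The strict inequality follows the "> 97 %" convention for
restricting recruitment to closely related genomes: at $n = 100$, two
substitutions (identity $0.98$) pass, three (identity $0.97$) do not. The
threshold is a parameter of `recruitment_params()` so sensitivity analyses
can relax it.

Both strands are searched by default and coordinates are always reported
on the forward strand of the genome (0-based start, exclusive end).
Within one genome only the best hit per read is kept — highest identity,
ties broken by smallest start, then forward strand. The leftmost tie-break
matters: reads from identical repeat copies all stack onto the first copy,
which concentrates repeat-derived coverage into recognizable peaks instead
of diluting it (the peak filter below relies on exactly this behaviour).
Across genomes, reads are counted independently for every genome they hit;
recruitment abundances are per-genome quantities and no unique-mapping
arbitration is performed.

## The q-gram candidate filter

Scoring every window of every genome is quadratic. The recruiter instead
uses the q-gram lemma: two length-$n$ strings with at most $k$ mismatches
share at least $n - q + 1 - kq$ position-consistent substrings of length
$q$. With $k = \lfloor (1 - t)\, n \rfloor$ the largest mismatch count the
threshold can tolerate, any window sharing fewer q-grams with the read can
be skipped *without losing any admissible hit* — the filter is lossless,
which the test suite asserts by comparing candidate sets and final hit
sets against a brute-force sliding-window scan (`recruit_read_naive()`,
an independent code path with no q-gram logic). When
$n - q + 1 - kq < 1$ the filter carries no information and the recruiter
falls back to scoring all windows.

The q-gram length defaults to $q = 11$, common recruitment practice: long
enough to keep the index selective, short enough that a read at the
identity boundary still shares many q-grams with its template. Windows
containing `N` are never indexed, and a base matches only itself and only
when it is one of A/C/G/T — `N` never matches, including against another
`N`. Alignment is ungapped by design: the substitution-only error model of
the simulator and the exactness of the brute-force oracle both depend on
it, and gapped recruitment would change the meaning of the locus counts
downstream. Reads shorter than `min_align_len` (default 30) are skipped
and counted.

## Coverage peaks and their removal

Conserved repetitive elements — 16S rRNA operons above all — attract reads
from many taxa, so a handful of loci can collect a large share of all
recruited reads and inflate abundance estimates. The peak filter works on
the per-locus read-start counts of one genome: the dictionary $D$ maps
each alignment-start locus to its read count (one increment per read, not
per-base pileup depth — the literal reading of the procedure), and
$M$ and $SD$ are the mean and **population** standard deviation of $D$'s
values *over covered loci only*, because $D$ is built exclusively from
recruited reads. Reads at loci with $D(l) > M + 2\,SD$ are removed;
counts exactly at the threshold are kept. Uniform coverage ($SD = 0$)
therefore removes nothing.

The filter is a deliberate **single pass**. Re-running it on its own
output recomputes $M$ and $SD$ on the reduced profile and may remove
further loci; the pipeline never does this, and a test pins the
non-idempotence so the single-pass semantics cannot silently change. The
`sd_type` switch ("population" default, "sample" optional) exists because
the divisor convention is not observable from the procedure's name alone.

## Normalization and display

Qualified counts are scaled to reads-per-billion,
$N = R \times 10^9 / T$, with $T$ the sample's total read count (taken
from the sample metadata, not from the reads actually supplied — samples
are routinely subsampled to their first ten million reads). Environment
aggregation pools before normalizing:
$N_e = \sum_s R_s \times 10^9 / \sum_s T_s$, a ratio of sums. The
alternative (mean of per-sample ratios) differs as soon as totals are
unequal; pooling corresponds to treating an environment's samples as one
large sample, and with equal totals the two coincide (a tested property).

For display, rows can be autoscaled (centred, divided by the population
SD; constant rows map to zero with a warning) and rows and columns are
clustered by average linkage (UPGMA) on Euclidean distances. The
agglomeration is implemented in the package with a fixed tie-break —
among equal minimal distances the lexicographically smallest index pair
merges first — so leaf orders are deterministic and independent of input
row order up to relabelling. On tie-free data the merge heights and
cophenetic distances agree with `stats::hclust(method = "average")`,
which the tests use as an independent cross-check. Heatmaps (via
pheatmap) are presentation artifacts; no analysis result depends on them.

# The consortium model

## Tables, names and the alias map

The packaged fixtures transcribe the published strain list (25 selected
strains: 22 bacteria, one yeast, two *Trichoderma harzianum* strains),
the 23-strain pairwise bacteria/yeast compatibility matrix, the
bacteria/yeast versus *T. harzianum* table, the biostimulant response
table (compounds BS1–BS4 over the 12 consortium strains) and the three
published consortium definitions (MC_A: 6 members; MC_B and MC_C: 5
each).

The source tables are inconsistent in naming: the yeast appears both as
*Pichia* and *Komagataella pastoris*, one *Azospirillum* is misprinted as
*Azotobacter*, *Rahnella* as *Ranhella*, one strain code appears as both
LS163 and LS136, and two strains changed genus after 16S rDNA
reclassification. Silent string matching would drop strains, so the
strain table carries an explicit alias column and every loader
canonicalizes names through it; an unknown name is a load error naming
the offender. The printed matrix also duplicates one column
(*B. ambifaria* LMG 11351); the duplicated cells are value-identical, and
the fixture keeps a single column.

The lower-triangular matrix is closed to a symmetric one (conflicting
symmetric entries are a load error), the diagonal is `+` by convention
(self-compatibility is biologically vacuous but needed for clique logic),
and pairs never assayed — the fungus–fungus pair — are `missing`.

## Policies, validation and enumeration

Strain pairs with verdict `+` can coexist; `-` pairs cannot; `nc` pairs
are unresolved. The **strict** policy admits only `+` edges, the
**lenient** policy also admits `nc`. Lenient is the default because the
published consortium MC_A contains one pair assayed `nc`
(*P. tropica* MDIIIAzo225 with *T. harzianum* TH01) even though the
accompanying prose says unclear strains were set aside — the default
reproduces the published designs while `validate_consortium()` reports
the discrepancy (MC_A passes lenient, fails strict on exactly that pair;
MC_B and MC_C pass strict). Unassayed pairs block the strict flag only if
`strict_missing = TRUE`, since absence of an assay is not evidence of
antagonism.

Function coverage uses tags normalized from the strain table's free-text
property descriptions (nitrogen fixation, P solubilization, biocontrol,
amylolytic activity, IAA production, siderophore, phytase, generic PGP).
One tag is provenance-flagged: P solubilization for *P. fluorescens*
DR54 is reported from a field application rather than the property
column, and the strain table records that in its notes. Coverage is
*reported*, not enforced, by the validator: the published consortia do
not each cover the full function list (MC_B has no IAA producer), so a
hard failure would misrepresent the design intent. Candidate enumeration
(`enumerate_consortia()`) does enforce a required-function set when one
is given; the high-level pipeline default leaves it empty because the
sole IAA producer and the sole amylolytic strain are mutually
incompatible, making the full five-function requirement unsatisfiable by
any clique — a fact about the assay tables worth surfacing rather than
hiding behind an empty result.

Candidates are the inclusion-maximal cliques of the policy graph
(Bron–Kerbosch with pivoting via igraph), restricted to selected strains,
filtered by size and coverage, ordered by decreasing size then
lexicographic member list. Only maximal cliques are returned — every
compatible sub-consortium is a subset of one. The tests validate the
enumeration against an independent power-set search on instances up to 15
strains and check recovery of planted cliques in simulated matrices.

## Biostimulant scoring

For a consortium and compound, the score is the fraction of members with
a positive (prebiotic) response; `nc` contributes nothing to the
numerator but stays in the denominator, because an assay that could not
discriminate an effect earns no credit. Compounds are ranked by fraction,
ties broken by fewer unclear responses, then id. Against the packaged
table, BS2 scores 1.0 for all three published consortia and BS4 (all
`nc`) ranks last — both pinned by tests. Dose–response detail (the
assays span 10–10,000 ppm) is not modelled; the table is qualitative.

# The simulator

`generate_references()` mutates each genome independently from one random
ancestor. For a target pairwise divergence $p$, the per-genome
substitution rate $d$ solves $p = 2d(1-d) + \tfrac{2}{3}d^2$ (sites
mutated in exactly one genome always differ; sites mutated in both differ
with probability $2/3$ under uniform substitution). The model is
substitution-only — no indels — so the ungapped recruiter and its
brute-force oracle remain exact on simulated data. One shared repeat
element is written unmutated into every genome at random non-overlapping
positions, emulating a conserved rRNA-like element: it recruits across
genomes *and* stacks into coverage peaks, the exact failure mode the peak
filter targets.

`generate_sample()` draws reads uniformly from both strands, applies
per-base substitutions, mixes in off-target reads from an unrelated
random genome, and labels every read with its origin and whether it lies
entirely within a repeat copy. Qualities are constant Phred 40 and unused
downstream. All outputs are deterministic functions of the seed, and the
generators restore the caller's RNG state.

Defaults (5 genomes of 10 kb at 25 % pairwise divergence, 5000 reads of
100 b at 2 % read divergence, a 150 b repeat in 3 copies per genome, 10 %
off-target reads, two samples per environment) describe a study small
enough to verify exhaustively yet structured like the real task: the 25 %
reference divergence is far outside the > 97 % identity window, so
recruitment specificity is decidable from ground truth, and 2 % read
divergence places reads *near* the threshold, where the interesting
behaviour is. With threshold $0.97$ and $n = 100$, a read is recruited to
its source iff it carries at most 2 substitutions, so the on-target
recruitment rate should match the binomial tail
$P[\mathrm{Bin}(100, 0.02) \le 2] \approx 0.68$ — a calibration the
acceptance script reproduces within a few tenths of a percentage point.

What the simulator does **not** model: realistic community abundance
distributions, platform-specific error profiles, indels, GC bias and
paired-end structure. Passing tests on simulated data therefore
demonstrate algorithmic correctness (the computations do what their
definitions say), not field performance on real metagenomes, whose
headline recruitment fractions depend on terabyte-scale read sets that
are out of desk-scale scope.

# Numerical and scale choices

* Identity comparisons use exact double arithmetic on
  $\mathrm{matches}/n$; the boundary case (identity equal to the
  threshold) is rejected by the strict inequality.
* $k = \lfloor (1-t)n \rfloor$ is computed with a small epsilon guard
  against the representation of $1 - 0.97$.
* The verification problem sizes — 50 random recruiter instances with
  genomes of 1–4 kb and reads of 50–150 b, power-set clique checks up to
  15 strains, planted-clique recovery at 20 strains — were chosen so the
  whole suite runs in well under a minute while every oracle remains
  exhaustive at its instance size.
* Read subsampling takes the *first* `max_reads` records of a FASTQ file
  in file order (default $10^7$), matching the convention the pipeline
  is built around; `total_reads` in the metadata remains the full sample
  size and is the normalization denominator.

# Known limitations

* Ungapped alignment understates identity for indel-divergent relatives;
  the threshold semantics are only calibrated for substitution
  divergence.
* Coverage is counted at alignment-start loci. Per-base pileup depth
  would spread peaks over read-length windows and would need a different
  threshold convention.
* The compatibility tables are transcriptions of endpoint assays; the
  package propagates, but cannot resolve, their unclear and missing
  entries.
* `aggregate_by_environment()` requires raw counts; it deliberately
  refuses to pool already-scaled matrices.
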