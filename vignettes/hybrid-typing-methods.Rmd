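---
title: "Typing CYP2A7::CYP2A6 hybrid alleles from long reads and depth: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typing CYP2A7::CYP2A6 hybrid alleles from long reads and depth: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psvtyper)
```

## The problem

CYP2A6 encodes the main nicotine-metabolizing enzyme; its gene sits next
to the highly similar paralog CYP2A7 (>90% sequence identity over the
gene bodies). Structural alleles at this locus — whole-gene deletions,
duplications, and CYP2A7::CYP2A6 hybrids in which the 5' part of the
haplotype derives from CYP2A7 and the 3' part from CYP2A6 — change how
much functional CYP2A6 a person carries, and with it the metabolism of
nicotine and tobacco-derived carcinogens. Short reads map ambiguously
between the paralogs, so hybrids and their junctions are invisible to
standard small-variant pipelines; kilobase-scale reads can span the
junction, and read depth can count copies, but neither alone resolves a
diplotype.

`psvtyper` implements the combined inference: paralog-specific variants
(PSVs) turn each long read into a sequence of per-site votes for one
paralog or the other; a penalized changepoint segmentation of those votes
locates switch positions (SPs); read groups become allele candidates; and
integer copy-number segments from short-read depth arbitrate between the
allele-pair hypotheses that the reads alone cannot distinguish. A
downstream stage relates the resulting deletion/retained classification
to tumor mutation burden and mutational signatures.

## The voting and switch model

Let the PSV table hold positions $p_1 < \dots < p_m$ (on the shared gene
frame, paralog A's coordinates) with discriminating bases $(a_k, b_k)$.
A read overlapping sites $k \in K$ yields votes $v_k \in \{A, B,
\text{neither}\}$ by direct base comparison; `neither` marks a sequencing
error and is ignored downstream. For the informative votes, the switch
caller minimizes

$$\sum_k \mathbf{1}[v_k \ne s_k] \;+\; (\lambda + \varepsilon)\,
  \#\{k : s_k \ne s_{k+1}\}$$

over two-state sequences $s$, by exact dynamic programming. The penalty
$\lambda$ (default 2, in mismatch units) is chosen so that one error can
never pay for a switch; the infinitesimal $\varepsilon = 10^{-9}$ breaks
ties toward fewer changepoints, which makes the optimum objective unique
and lets tests compare the DP against exhaustive enumeration of all
$2^n$ state paths. A switch is only emitted when at least `min_flank`
(default 3) concordant votes flank it on each side, and a read in which
more than 20% of informative votes disagree with the optimal two-state
fit is flagged chimeric/ambiguous rather than called.

The flank rule has a blind spot: a junction close to a gene end may
leave fewer than `min_flank` PSVs on its short side — the geometry of
3'UTR-junction hybrids, whose downstream discriminating stretch is only
the UTR remainder. Such reads are recovered by the terminus re-alignment
step: a read with a long concordant prefix and a short discordant run
(at least 2 votes, so a single error still cannot fake a junction) at
its end has that terminus locally re-aligned against both paralog
references (`realign_terminus()`, the in-package analog of rescuing
ambiguous read ends with BLAT), and a confirmed opposite-paralog
placement at ≥0.9 identity supplies the switch call. A junction whose
short side contains no PSV at all remains uncallable from reads — by
design, since the switch position is only defined between discriminating
sites.

A switch position is reported as the *interval* between the last vote for
the upstream paralog and the first vote for the downstream one, never as
a base: between near-identical paralogs the true junction is
unidentifiable inside a PSV-free stretch. The interval midpoint is used
only for display and for predicting depth breakpoints. Reads supporting
the same (segment label, orientation) signature are grouped; groups with
at least `min_support` (default 3) reads become hybrid allele candidates,
and their consensus SP interval is the intersection of the per-read
intervals (every supporting read's interval contains the true junction).

## Copy-number integration

Windowed depth, normalized to a diploid control region (median depth of
the left flank — the median is robust to the occasional outlier window),
is rounded to integer states 0–4. Runs shorter than `min_windows`
(default 5) are absorbed into the neighboring state whose integer value
is closest to the run's own mean CN; merging into the *longer* neighbor
instead turns out to cascade at noisy boundaries, dragging whole
segments to the wrong state. A segment whose mean CN deviates from its
state by more than the guard band (0.35) keeps its state but carries a
low-confidence flag with the raw value — explicit auditability rather
than false precision, since printed gene-level CNV values like 1.4 exist
in real cohorts and no rounding rule can make them honest integers.

Integration enumerates allele-pair hypotheses: every supported hybrid
candidate must be used at least once; remaining slots draw from
wild-type, whole deletion, and (only when the depth shows a gain)
duplication. Each hypothesis predicts an integer CN profile over the
locus — a hybrid deletes the interval between its junction's two gene
copies — and the hypothesis explaining the most windows (excluding
windows adjacent to predicted breakpoints) wins; below 90% agreement the
sample is reported as inconsistent evidence, not silently called. Two
read-evidence guards apply: a biallelic whole-deletion hypothesis is
infeasible when supported paralog-B votes exist, and ties prefer fewer
structural alleles, flagged when they occur. Duplicated copies are
assigned to one allele (wild-type::dup) because read evidence cannot
phase tandem copies; this is recorded as an assumption, not an
inference.

The functional rule is fixed: *retained* if at least one allele carries
an intact downstream gene (wild-type or duplication), *deletion* if both
alleles are deletions or hybrids; an unresolved allele gives
`unclassifiable`. Small variants on an intact allele never change the
call. Applied to the shipped 20-patient reference cohort fixtures the
rule reproduces the reported genome class for all 20 patients; the
gene-level CNV value in those fixtures is used only as an audit — a
value whose integer state falls outside the range implied by the allele
structures (as for the two compound-hybrid patients, whose reported 1.9
conflicts with alleles implying CN ≤ 1 over the coding body) is listed
as a discrepancy and left unresolved.

## The synthetic locus generator

The generator is the package's test bed: two equal-length paralogs (gene
A mirrors CYP2A7, gene B mirrors CYP2A6) on one contig with flanks and an
intergenic gap, gene B differing from gene A by i.i.d. substitutions at
rate `psv_rate` (default `1 - identity`, identity 0.95). Defaults: 6 kb
genes with 9 exons and a terminal 3'UTR, a 4 kb gap, 2 kb flanks; reads
of 4.7 ± 2.9 kb (truncated normal, matching a kilobase-scale synthetic
long-read regime) at 30× per haplotype with 1% substitution errors;
depth windows of 100 bp with lognormal multiplicative noise (CV 0.1 —
strictly positive and CV-parameterized). Hybrid junctions are placed at
the midpoint of the chosen intron (or 3'UTR); since the base-level
junction is unobservable, truth records the junction and the flanking-PSV
interval. Both genes are simulated on the plus strand, with
`flip_pair()` providing the reverse-complemented locus (mirrored
coordinates, minus-strand gene models) to test strand safety.

Deliberate simplifications, and what they imply about the tests: read
errors are substitutions only (the inference consumes PSV matches, so
indel realism adds nothing to what is being validated — an indel-rich
platform would first need indel-aware voting); the paralogs have equal
length and no structural divergence besides the simulated event; read
placement comes from simulator truth rather than a genome-scale aligner
(commodity alignment is out of scope; only BLAT-style local terminus
re-alignment is implemented, in `realign_terminus()`). One geometric
consequence: with equal-length paralogs every deletion-type hybrid
haplotype has the same length regardless of junction, so amplicon *sizes*
cannot depend on the switch position. The in-silico PCR screen therefore
validates presence/absence — a paralog-A-specific primer between two
candidate junctions amplifies only when the switch lies downstream of it
— which is also how the real assay is used: a junction presence screen,
not a size discriminator. Passing tests show the inference machinery is
correct under these conditions; they do not certify performance on real
reads with indels, mapping ambiguity, or reference-divergent paralog
structure.

## Mutation analysis

Tumor mutation burden is the exonic somatic mutation count divided by the
callable footprint (default 40 Mb for synthetic exomes; always carried in
the output because TMB is footprint-dependent). Class comparisons use
Welch's unequal-variance t-test (`stats::t.test` wrapped; when both
groups are constant the statistic is degenerate and reported as t = 0 /
p = 1 or ±Inf / 0 with df = NA). Signature refitting solves non-negative
least squares of the normalized 96-channel catalog on the signature
columns (`pracma::lsqnonneg`), after dropping a configurable artifact
exclusion list; exposures are reported as fractions with the residual
norm. The merge rule pools unprotected signatures below 0.2 into
`others`, with the smoking-related signatures always reported at any
fraction. "Presence" in summaries means exposure > 0.05 — a detection
threshold the source material leaves unstated, so it is explicit,
config-exposed, and recorded in the output. Synthetic signature fixtures
(`flat`, `sbs4_like` concentrated on C>A, `sbs92_like` on T>C) are
deterministic stand-ins generated in code; COSMIC matrices are not
redistributed, and `read_signature_matrix()` loads a user-supplied
COSMIC v3.3 TSV. Genotype-conditioned cohorts fit signatures on
genome-scale catalogs (≈ 3000 Mb × TMB mutations) while TMB uses the
exonic count, mirroring the exon/whole-genome split of real pipelines;
with only exome-scale counts the NNLS exposures would be too noisy for a
0.05 presence threshold to mean anything.

## Problem sizes and numerical choices

The test suite and acceptance script size their simulations as follows:
unit tests run on a 2.5 kb-gene locus (alignment well under a second);
switch-point recovery uses 100 seeded replicates per hybrid type at the
full default locus (6 kb genes, 30×, 5 kb reads) in the test suite and
40 replicates in the acceptance script; changepoint optimality is checked
against exhaustive enumeration of all $2^{15}$ length-15 vote patterns;
NNLS recovery uses 50,000-mutation catalogs; Welch power uses 1000
simulated two-group designs; the cohort pattern uses 7 + 7 samples per
replicate. Alignment scoring is fixed (match 2, mismatch −3, gap open 5,
extend 2) and recorded in the PSV table metadata; indel columns between
paralogs are excluded from the PSV table, because per-read indel calls at
long-read error rates are unreliable and the switch logic needs only
discriminating bases. Copy-number rounding uses half-up rounding (R's
`round()` banker's rounding would map 2.5 to 2).

## Known limitations

- No genome-scale read alignment, no base-level breakpoint assembly, no
  phasing of small variants beyond PSVs, and at most two haplotypes
  (germline only — no tumor subclones or mosaicism).
- Only two paralogs; no support for larger pseudogene families.
- The simulator's intron-midpoint junction convention is a stand-in for
  unknown real junction positions and is flagged as such in truth
  metadata.
- Whether a duplication of intact CYP2A6 increases function is not
  modelled; duplications count as retained only.
- Real per-sample TMB values and cohort-level signature frequencies are
  not reproducible from synthetic data; the association stage validates
  machinery (recovery, power, qualitative pattern), not clinical effect
  sizes.
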