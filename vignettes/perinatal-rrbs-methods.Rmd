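---
title: "Methods: RRBS methylome profiling and sliding-window DMR calling"
author: "perimeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RRBS methylome profiling and sliding-window DMR calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and data model

`perimeth` implements the downstream half of a pooled two-group RRBS study:
it starts from per-cytosine methylation call tables (chromosome, 1-based
cytosine position, strand, context, methylated count, unmethylated count)
and ends at called, annotated, validated differentially methylated regions
(DMRs). Read alignment, deduplication and quality trimming are upstream of
the package; users should supply deduplicated counts.

Two coordinate conventions coexist deliberately. Interval objects
(fragments, genes, CGIs, DMR spans, BED files) are 0-based half-open, the
BED convention. Count tables carry 1-based cytosine positions, the
convention of aligner cytosine reports. Conversion happens only where the
two meet (e.g. restricting a table to an amplicon). A DMR span runs from the
first member C to one base past the last member's G, so a 10-CpG DMR over
tightly spaced CpGs comes out near the ~100 bp scale typical of RRBS windows.

CpG sites are canonicalized to the forward-strand C: `merge_strands()` folds
a reverse-strand record at position p+1 onto the forward C at p after
verifying against the genome that a CpG actually sits there. Total counts
are conserved exactly. Pooling the two strands is the default because the
window statistic treats a CpG as one biological unit; keeping strands
separate is possible by simply skipping the merge, and the candidate depth
filter then applies per strand.

## The window statistic

For each candidate CpG — covered at `min_depth` (default 5) or more in both
groups, off the excluded sex chromosomes — the two-sided Fisher exact test
compares methylated/unmethylated counts between groups. The two-sided
p-value is defined as the total probability of tables (with the observed
margins) no more probable than the observed one, with a relative tolerance
of 1e-7 on the probability comparison; this matches `stats::fisher.test`
exactly and is computed here by direct hypergeometric enumeration so that
a genome's worth of sites (10^5–10^6 tests) runs in seconds.

Per-site p-values are Benjamini–Hochberg adjusted across all candidate
sites of the comparison. Scanning left to right per chromosome, the first
site with adjusted p < 0.05 seeds a window whose direction is the sign of
its level difference. The window absorbs following candidate sites while
the inter-site distance stays ≤ 300 bp (the RRBS fragment scale) and the
site's difference has the window direction; sites with exactly zero
difference never break a window, count toward the size requirement, but can
never count as supporting sites. A window closes on a gap violation, a
direction flip, or the chromosome end; it becomes a candidate DMR when it
holds ≥ 5 candidate CpGs of which ≥ 3 have raw p < 0.05. Scanning resumes
at the first site after the closed window, which makes emitted windows
disjoint by construction and removes any need for tie-breaking.

Design choices worth stating, since the procedure leaves them open:

* **Seeding on the adjusted p-value.** "Automatically corrected" is read
  as BH adjustment across the comparison's candidate sites; `seed_on =
  "raw"` switches to raw-p seeding.
* **Rightward-only extension.** The window grows from the seed toward
  higher coordinates only. Since every site of a true DMR is a potential
  seed and the scan visits them in order, leftward extension changes
  results only when the left flank of a region is individually
  non-significant; the simpler rule is kept.
* **Aggregate test.** Each candidate window is re-tested on the per-group
  means of the member C and T counts. Fisher's test needs integers, and a
  mean like 7.5 has no canonical rounding; half-up rounding (7.5 → 8) is
  used, applied symmetrically to all four cells.
* **Retention.** Candidates are kept at BH-adjusted aggregate q < 0.05
  *and* |mean level difference| ≥ 0.20. The effect-size rule is stated
  inconsistently in descriptions of this procedure (once as `< 20%`, once
  as `> 20%`); the ≥ 20% reading is implemented — a "differentially
  methylated" region with a 5-point shift is not useful — and the
  threshold is a parameter.

Degenerate inputs: a seed with zero level difference cannot exist (equal
proportions give p = 1), sites with zero depth in either group never become
candidates, and an empty candidate list yields an empty, well-typed result.

## The synthetic-data generator

The generator exists so that every stage can be verified against known
truth; its defaults describe the operating conditions the package is tested
under.

* **Genome.** Background sequence at 40% GC with CpG dinucleotides thinned
  to an observed/expected ratio near 0.25, mimicking genome-wide CpG
  depletion; CpG islands are overwritten as 60% GC, o/e ≈ 1 stretches
  (defaults: 4 chromosomes × 1.2 Mb, 60 CGIs of ~1 kb). Genes (120, ~3 kb,
  1–3 exons) are placed without overlap; half anchor their TSS inside a
  CGI so promoter-CGI DMRs can arise.
* **Methylome.** Site levels are Beta-distributed (concentration 30)
  around 0.10 inside CGIs and 0.75 outside — the canonical unmethylated-CGI
  / methylated-background structure. Outside planted DMRs the two groups
  are *identical*, which is what makes false-positive accounting exact.
* **Planted DMRs.** 200 runs of 10 consecutive CpGs, shifted by +0.30 in
  group 2. Runs are eligible only if every baseline can absorb the full
  shift without clipping (so the planted effect is exactly the configured
  delta) and if inter-CpG gaps stay within 300 bp — a "region" spanning a
  CpG desert would not be a DMR under the region definition. For a positive
  delta this steers planting into CGIs, which is also where promoter DMRs
  live biologically.
* **Counts.** Depth is negative-binomial (mean 20, dispersion 0.1,
  truncated at 1); methylated counts are beta-binomial with overdispersion
  0.02 around the true level (0 recovers the pure binomial reads-from-a-
  level model). Three individuals per group are drawn and their counts
  summed, mirroring the pooling of 2–3 animals into one RRBS library; the
  pooled table is therefore ~60× deep, consistent with a pooled library
  sequenced at ≥ 12.5× per strand per animal-pool. Non-CpG cytosines are
  emitted with apparent methylation at the 0.5% bisulfite non-conversion
  rate, purely to exercise the context-breakdown conversion check.
* **Validation panels.** For each amplicon and individual, one methylation
  state per CpG is realized from the group truth (the beta-binomial
  biological draw, applied once), and both assays sample *that* state:
  HiSeq-BSP counts at ~1000×, Sanger-BSP as 20 Bernoulli clone calls. This
  models the fact that both assays sequence the same bisulfite-converted
  DNA; under it, deep direct sequencing (binomial error at 1000×, ~0.01
  mean absolute error) necessarily beats 20-clone sampling (~0.06), which
  is the accuracy claim the validation statistics exist to test.
* **Expression.** Ct values are baseline − log2(fold) + Gaussian noise,
  with the reference gene held at fold 1, so the ΔΔCt estimator recovers
  planted folds exactly at zero noise.

All generators are pure functions of (config, seed): the RNG state is
saved, seeded, and restored around every draw.

What the generator does **not** emulate: read-level artifacts (sequencing
error, mapping bias, incomplete conversion at CpG sites), inter-individual
biological differences beyond symmetric beta-binomial noise, copy-number
or SNP effects on apparent methylation, and chromosome-scale methylation
gradients. Tests passing on this generator therefore demonstrate that the
statistics and window logic are implemented correctly under the stated
model — not that the model captures every property of real RRBS libraries.

## Profiling conventions

* Quintile bins are left-closed with a closed top bin
  (`[0,.2) ... [.8,1]`), so a level of exactly 1 is counted once.
* The metagene profile uses 50 × 100 bp upstream bins, 20 equal body bins
  (5% of the gene each) and 50 × 100 bp downstream bins, orientation-
  normalized; bin means pool all site levels across genes without
  per-gene weighting (a `per_gene` flag averages within genes first).
  Genes shorter than 20 bp are skipped with a warning; empty bins are `NA`.
* Global per-context methylation is the read-weighted ratio of total
  methylated counts to total depth, which equals the depth-weighted mean
  of site levels (an identity the tests assert).
* Chromosome-level correlations need ≥ 3 chromosomes and a feature with
  nonzero variance; anything else is reported `NA` rather than guessed.
* Only plain pairwise distance matrices over shared CpGs are provided for
  clustering; multiscale-bootstrap support values are out of scope.

## In silico digestion and CGI detection

Digestion places a cut `cut_offset` bases into each occurrence of the
recognition site (C^CGG for MspI); fragments tile each chromosome exactly,
and the concatenation identity is asserted in tests. Size selection
defaults to the 40–220 bp RRBS window and, by default, requires enzymatic
cuts at both ends, since real RRBS fragments need MspI overhangs for
adapter ligation — terminal fragments can be kept with a flag. CpG recovery
is reported both as whole-fragment counts (the theoretical maximum) and as
read-covered counts for a given read length (2 × 50 bp paired-end
emulation), because which of the two a published "recovered CpGs" figure
means is generally ambiguous.

The CGI scanner slides a 200 bp window at 1 bp stride, requiring GC ≥ 0.5
and Gardiner-Garden–Frommer o/e = (#CpG·L)/(#C·#G) ≥ 0.6, merges
qualifying windows, trims non-C/G termini from merged regions (merging can
pad a dense core with AT flank; a padded 150 bp core correctly fails the
length floor after trimming) and re-checks each merged region against all
three criteria.

## Annotation and validation conventions

Feature assignment uses precedence promoter > exon > intron > downstream >
intergenic with ≥ 1 bp overlap. Promoters are the 2 kb upstream of the TSS
in gene orientation (for a minus-strand gene, the 2 kb past its highest
coordinate); downstream mirrors this with 2 kb for symmetry. Cross-matching
two DMR sets requires the shared CpGs to cover at least half of each DMR's
members, and the reported correlation is computed on the per-CpG group
differences of all shared CpGs pooled over matched pairs.

Amplicon re-validation pools the per-individual tables by summing counts
within each group and re-runs the identical caller restricted to amplicon
CpGs — per-individual testing is deliberately not invented. The CV report
ranks sites by sd/mean within each group of individuals and flags a
configurable top quantile (default 10%); no absolute "high CV" threshold is
assumed. ΔΔCt significance defaults to the stricter joint rule (Student's
t-test p < 0.01 *and* fold ≥ 2 in either direction); both thresholds are
parameters, and zero-variance fixtures yield `NA` p-values and a negative
call rather than a fabricated test.

## Problem sizes and numerical notes

The default simulated study (4 × 1.2 Mb, ~53,000 candidate CpGs, 200
planted DMRs) was chosen so that a full run — generation, profiling,
calling, annotation, digestion — completes in well under a minute on one
CPU while leaving enough planted regions for tight recovery estimates;
the null benchmark reuses one genome and redraws counts over five seeds.
Under these conditions the caller recovers ~95% of planted DMRs with zero
observed false calls, and the null configuration yields zero calls.

Fisher p-values use hypergeometric enumeration with the same 1e-7 relative
tolerance as `stats::fisher.test`; the suite verifies exact agreement with
both `fisher.test` and an independent binomial-coefficient oracle. BH
adjustment delegates to `stats::p.adjust`. Half-up rounding of aggregate
tables is implemented as `floor(x + 0.5)` because R's `round()` rounds
half to even, which would bias tables built from `.5` means. Known
limitations: the caller models no covariates, no smoothing and no
per-individual dispersion (the procedure is pooled by design), and the
CGI-anchored planting of positive-delta DMRs means recovery statistics
mostly reflect CGI-context performance.
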