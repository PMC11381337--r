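---
title: "Detecting A-to-I RNA editing from multi-strain pileups: methods and design"
author: "edicall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting A-to-I RNA editing from multi-strain pileups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

A-to-I editing converts adenosine to inosine in double-stranded RNA;
sequencers read inosine as guanosine, so editing surfaces in RNA-seq
pileups as A→G mismatches on the edited strand (T→C on the reference when
the edited adenosine sits on the reverse strand). The statistical problem
is separating a low-frequency, position-specific mismatch signal from three
confounders: sequencing error, genomic variation, and systematic artifacts
(misalignment, strand biases). `edicall` addresses each confounder with a
dedicated mechanism: a Phred quality floor, explicit DNA-variant masks, and
— the design centrepiece — subtraction against an *editing-null* (ADAR
mutant) strain in which any editing-like change is an artifact by
construction.

The pipeline starts at pileups (samtools 6-column dialect). Alignment,
trimming and read collapsing are upstream concerns; the synthetic-data
generator accordingly emits pileups directly.

# Pileup decoding

Each pileup column is decoded into per-read base calls. `.`/`,` resolve to
the reference base on the forward/reverse strand; letter case carries
strand for mismatches. Read-start marks (`^` plus a mapping-quality
character that is always discarded), read-end marks (`$`) and indel runs
consume base-string characters but no quality characters; deletion
placeholders (`*`), reference skips (`<`, `>`) and `N` calls consume one
quality character and emit nothing. The decoder verifies that the quality
string is exactly consumed and reports the offending line otherwise.

Two consequences of treating editing as a substitution phenomenon: indel
sequences are never counted as mismatches, and the depth denominator for
every fraction in the package is the count of quality-passing, base-called
A/C/G/T calls at the position — placeholders and skips are never part of
any denominator. Qualities are Phred+33; the offset is an explicit argument
rather than a guess.

Coordinates are 1-based closed intervals everywhere, matching the pileup
convention.

# Catalogued-site quantification

With `editingConfig()` defaults, calls below Phred 25 are removed before
any fraction is formed (Q25 ≈ 0.3% error, comfortably below the 1% calling
threshold). Replicas of one strain and stage are pooled — pooling at the
count level makes the site level exactly the coverage-weighted mean of the
per-replica levels. A catalogued site is *edited* when the target change
(A→G, or T→C for minus-strand sites) reaches at least 1% of the
quality-passing depth while the remaining mismatches stay at or below 1%.

Two interpretive choices here were genuinely open:

* **Aggregate purity.** The "no more than 1% of other nucleotides" bound is
  applied to the *sum* of non-target mismatch fractions, which is the
  conservative reading of an aggregate purity condition; a per-change
  variant is available via `perChangeOther = TRUE`.
* **Strictness at the boundaries.** The target bound is inclusive (≥ 1%),
  the editing-null blacklist bound exclusive (strictly above 3%), following
  the stated wording of each rule literally. Threshold comparisons are done
  on the ratio (`n/depth >= theta`), never on the cross-multiplied form:
  IEEE division is correctly rounded, so a printed boundary like 2/200
  versus 1% compares exactly, whereas `theta * depth` can land on the wrong
  side by one ulp.

A site with zero quality-passing depth is `not_expressed`, a distinct
outcome from `not_edited`; the unthresholded editing matrix
(`editingMatrix()`) preserves this distinction per sample, with
`minExpressedDepth` defaulting to 1 so that any covered site reports a raw
level. The editing-null blacklist is computed *after* quality filtering
(the screen should see the same evidence the caller sees); sites without
editing-null coverage cannot be assessed and are retained with an
`unassessable` flag rather than silently trusted.

# De-novo discovery

`denovoConfig()` encodes a five-part rule evaluated per replica after two
subtractions: genomic variants (position-wide for DNA-seq variant masks,
allele-specific for SNP catalogues) and *mutant changes* — any (position,
alternative) pair carried by at least one quality-passing read in the
pooled editing-null strain. The literal one-read erasure rule is
deliberate: it is the aggressive end of artifact removal and costs a few
percent sensitivity in the mutant strain (an editing-null error read at the
same position and allele erases a true site with probability ≈ depth ×
error/3), which the validation quantifies rather than hides. Subtraction is
idempotent by construction.

A candidate requires the most abundant remaining mismatch to have ≥ 2
supporting reads, ≥ 5% of the quality-passing depth, and every other
mismatch ≤ 1%. The denominator is the post-subtraction quality-passing
depth, chosen for internal consistency (all five fractions then refer to
the same read population). Ties for "most abundant" are resolved in fixed
A < C < G < T order and logged; under the ≤ 1% purity bound a tie can in
fact never be called (the runner-up carries the top count), so the
tie-break affects only the log, not the call set.

Sites recurring in ≥ 2 of the replicas of a strain and stage are kept,
pooled over their supporting replicas, and classified: *de-novo* when
edited in neither the wild-type catalogued-site analysis nor the wild-type
de-novo search. Only A→G / T→C signatures enter the editing report;
other surviving changes are emitted on a diagnostics channel, since they
are informative about residual artifacts but are not A-to-I events.

The editing-null pileups used for subtraction are pooled per stage (the
same pooling the blacklist uses); a per-replica union would be marginally
more aggressive but makes the subtraction depend on replica count.

# Region annotation

Gene models come from GFF3 (`readGeneModels()`); introns are derived as
gaps between consecutive exons of a transcript and UTRs from exon-minus-CDS
by transcriptional orientation. When several features overlap a position,
precedence is CDS exon > UTR > noncoding exon > intron, which maximizes
agreement with "exon" summaries whenever any isoform is coding at the
position; when genes on both strands overlap, the gene matching the site's
inferred editing strand wins before precedence applies. Remaining ties
break on gene identifier, so annotation is deterministic. UTR5 and UTR3 are
kept distinct internally and merged into a single "UTR" stratum in
summaries.

# Context profiles

`contextCounts()` extracts the ±w window around each site on the edited
strand (minus-strand sites are reverse-complemented, so offset −1 is always
the 5′ neighbor) and `probabilityMatrix()` applies
P[i,c] = (n[i,c] + λ)/(Σ n[i,c′] + Cλ) with C = 4. Defaults are w = 3 —
wide enough to show the nearest-neighbor structure that matters
biologically, small enough that every column stays well-populated on
strata of tens of sites — and λ = 1 (Laplace), which keeps logo cells
nonzero on small strata; λ = 0 recovers raw frequencies and is rejected
only when a column has no counts at all. Profiles are stratified into
all/exon/intron/UTR with random-adenosine controls matched per region and
count, sampled reproducibly from the annotation (an "adenosine" is A on
the transcribed strand, so minus-strand genes contribute reference-T
positions). Empty strata are omitted with a warning — probabilities from a
handful of sites are unstable, and the warning is the honest output.

# Secondary-structure windows

For each site, the 101-nt window (50 nt each side, `flank` configurable)
is extracted from the genome (unspliced form) and from the gene's mature
transcript (spliced form); for multi-isoform genes the isoform with the
longest mature sequence supplies the spliced coordinates. Minus-strand
sites are reverse-complemented so the window centre is always the edited
A. Sites that do not fit — end-proximal, intronic (for the spliced form),
or with ambiguous bases — become exclusion records rather than truncated
windows.

Folding uses a pluggable nearest-neighbor thermodynamics backend; the
built-in backend shells out to ViennaRNA's `RNAfold` (T→U transcription
applied first; default 37 °C). Because absolute ΔG values are
backend-dependent, the package's own validation asserts only
backend-independent properties: determinism, ΔG = 0 for unpairable
homopolymers, negativity for designed stems.

Group comparisons remove free-energy outliers first. The published form of
this rule ("above 100") is sign-ambiguous for a quantity that is almost
always negative; it is implemented as |ΔG| > 100 kcal/mol removal, with the
literal signed rule behind `signedOutlier = TRUE`. Either way the intent —
dropping numeric pathologies — is preserved. The test is the two-sided
Welch two-sample t-test (unequal variances, Welch–Satterthwaite degrees of
freedom) via `stats::t.test`; identical constant groups return t = 0, p = 1
by convention, and constant groups with unequal means are an error rather
than an infinite statistic.

# Expression statistics

Count tables are prefiltered to genes with ≥ 10 total reads and coefficient
of variation < 1 across samples (genes with zero mean have undefined CV and
are dropped). The editing-class shift statistic is the per-gene log2 ratio
of library-size-normalized (CPM) mean expression, mutant over reference,
with a pseudo-CPM of 1; the class (e.g. 3′UTR-edited genes, lncRNAs) is
tested against its *complement* rather than the full universe — testing a
class against a superset that contains it double-counts the class and
shrinks the apparent shift. Differential-expression flagging consumes
externally computed statistics (the DE engine itself is out of scope) and
applies strict inequalities: |log2FC| > 1 (embryo) or > 2 (L4) and
padj < 0.05. Set-overlap significance is the upper-tail hypergeometric
probability including the observed overlap, the standard enrichment
convention.

# The synthetic study design

`simProfile()` encodes the study the generator emulates: three strains
(wild-type, adbp-1-type mutant, ADAR-null), three biological replicas,
embryo and L4 stages. Defaults and their sources:

| parameter | default | rationale |
|---|---|---|
| region mix, wild-type | intron 0.80 / exon 0.10 / UTR 0.10 | intron share as reported for wild-type editing; remainder split evenly |
| region mix, mutant | exon 0.655 / UTR 0.23 / intron 0.115 | exon share as reported for the mislocalized mutant; remainder weighted toward UTR |
| sites per strain | 200 | enough for binomial CI checks at desk scale |
| editing levels | Uniform(0.05, 0.5) | spans weak to strong sites; keeps expected edited reads ≥ 3 per replica at 60× |
| coverage | NB(mean 60, size 10) | realistic bulk RNA-seq depth with moderate overdispersion |
| base error | 0.001 | Illumina-scale substitution error, split uniformly over the three alternatives |
| qualities | Q37 with 5% mass at Q15 | two-point model that exercises the Phred ≥ 25 filter |
| ADAR-null artifacts | 20 sites at 5–10% | exercise blacklist and mutant subtraction |
| variants | 150 SNPs (allele-specific) + 150 DNA variants (position-wide) | exercise both mask forms |

Editing is strand-correct (sites in minus-strand genes appear as T→C
plus-strand signatures), edited-read counts are Binomial(depth, level),
variants are homozygous, and every draw is reproducible from the master
seed with deterministic per-sample sub-seeds. A stage-level multiplier
(default 1) lets the two stages share sites at different intensities.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: alignment and mapping artifacts (the dominant
real-world false-positive source beyond genomic variants), positional
correlation of errors along reads, intron/exon coverage differences from
splicing dynamics (coverage here is uniform across gene bodies, which is
what makes region-recovery unbiased), strain-level expression differences,
and hyper-edited clustered regions. The validation demonstrates that the
*decision rules* are implemented exactly and recover a known truth under
the stated noise model; it cannot certify performance on a real aligner's
error profile.

# Validation scale and numerical choices

The packaged validation enumerates all mismatch compositions at depth ≤ 12
against brute-force re-implementations of both callers (exact agreement),
checks every printed threshold at its boundary, and runs the full pipeline
on the default synthetic study — embryo stage, ~259 kb genome, ~130,000
non-edited A/T positions screened for false positives — asserting ≥ 95%
sensitivity for sites with ≥ 3 expected edited reads per replica, a
false-positive rate ≤ 10⁻³, level recovery within twice the binomial
standard error, region fractions within 95% binomial confidence bands of
the injected mixes, and zero leakage of editing-null-only artifacts.
Statistical routines are checked against closed-form Welch formulas (1e−9
relative tolerance) and exhaustive hypergeometric enumeration for all
universes up to N = 20.

Fractions are compared as correctly-rounded ratios of integer counts (see
above); site tables serialize levels at 10 significant digits and recompute
them from the integer counts on read, so write→read is an exact identity.
Editing-site containers carry validity checks (level consistency, count
bounds, strand alphabet) at construction.

# Known limitations

* The one-read mutant-subtraction rule trades a few percent mutant-strain
  sensitivity for artifact removal; a minimum-count or fraction-based
  variant would be a natural extension.
* The spliced form uses one isoform per gene (longest mature sequence);
  sites whose isoform usage differs between strains fold against a single
  reference transcript.
* `RNAfold` must be on `PATH` for the folding step; all other stages run
  without it.
* The expression module consumes externally computed DE statistics and
  deliberately implements only the flagging thresholds, not the underlying
  negative-binomial model.
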