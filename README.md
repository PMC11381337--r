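# edicall

Detection and quantification of A-to-I RNA editing from multi-strain
RNA-seq pileup data.

## The problem

Adenosine deaminases acting on RNA (ADARs) convert adenosine to inosine in
double-stranded RNA. Inosine base-pairs like guanosine, so editing shows up
in RNA-seq as A→G mismatches against the reference — or T→C when the edited
adenosine lies on the reverse strand. Distinguishing genuine editing from
sequencing error, genomic variation and alignment artifacts is the central
difficulty, and the classic experimental lever is an *editing-null* strain
(an ADAR mutant): any "editing-like" change that survives in a strain with
no editing enzyme is an artifact by construction.

`edicall` implements this comparative calling strategy for a three-strain
design (wild-type, an *adbp-1*-type mutant in which the editing enzyme is
mislocalized to the cytoplasm, and an ADAR-null control), with two
developmental stages and ≥3 biological replicas per condition. It is aimed
at researchers analysing *C. elegans*-style editing data sets, but nothing
in the pipeline is organism-specific: the inputs are samtools-dialect
pileups, a genome FASTA, a GFF3-like annotation and plain TSV tables.

## What it computes

**Catalogued ("known") site quantification.** Base calls with Phred < 25
are discarded. At each catalogued site, pooled over the replicas of one
strain and stage, the site is *edited* when

    n(A→G) / depth ≥ 1%   and   Σ n(other mismatches) / depth ≤ 1%

(T→C for minus-strand sites). Sites whose target change exceeds 3% in the
pooled ADAR-null strain are blacklisted as artifacts. The editing *level*
is the target fraction; gene-level editing pools target and total counts
over all catalogued sites of a gene. An unthresholded site × sample matrix
distinguishes lack of editing from lack of expression.

**De-novo discovery.** After removing DNA-derived changes (DNA-seq variant
and SNP masks) and *every* change observed in the ADAR-null strain, a
position is a candidate in one replica when the most abundant mismatch has
≥ 2 supporting reads, makes up ≥ 5% of the quality-passing depth, and every
other mismatch stays ≤ 1%. A site is reported when it recurs in ≥ 2
biological replicas; it is *de-novo* when it is edited in no wild-type
analysis. Only A→G / T→C signatures enter the report (other surviving
changes go to a diagnostics channel).

**Characterisation.** Sites are annotated with strand-aware gene regions
(CDS exon > UTR > noncoding exon > intron precedence); nucleotide context
profiles around edited adenosines use the pseudocount probability matrix

    P[i,c] = (n[i,c] + λ) / (Σ_c' n[i,c'] + C·λ),   C = 4

with matched random-adenosine controls; 101-nt windows centred on each site
(spliced and unspliced forms) are folded to minimum free energy (ΔG,
kcal/mol, ViennaRNA backend) and compared across groups with the Welch
two-sample t-test; editing-class expression shifts use a CPM log-ratio
Welch test, stage-specific DE flagging (|log2FC| > 1 at embryo, > 2 at L4,
padj < 0.05) and upper-tail hypergeometric overlap tests.

**Synthetic data.** A seeded generator emits a complete fixture — genome,
annotation, truth tables, variant masks and per-replica pileups — with
intron-biased wild-type editing (80% of sites), exon-biased mutant editing
(65.5%), an editing-free ADAR-null strain carrying artifact changes,
negative-binomial coverage, binomial edited-read counts and Phred-distributed
qualities, so the whole pipeline is testable end to end at desk scale.

## Worked example

```r
library(edicall)

profile <- simProfile(nGenes = 40, nSitesWT = 60, nSitesAdbp1 = 60,
                      stages = "embryo")
fixture <- emitSampleSet("editing_fixture", profile, seed = 42)
res <- runPipeline("editing_fixture", "editing_results", stage = "embryo")

res$known_wild_type$calls
#> SiteCalls: 60 sites (60 known, 0 de_novo)

head(siteTable(res$known_wild_type$calls)[, c("chrom", "pos", "strand",
     "change", "level", "nTarget", "nTotal", "region")], 3)
#>       chrom  pos strand change     level nTarget nTotal region
#> 1 chrII_sim  639      +    A>G 0.1309524      22    168 intron
#> 2 chrII_sim  740      +    A>G 0.3445946      51    148 intron
#> 3 chrII_sim 1456      +    A>G 0.5031447      80    159 intron

regionSummary(res$known_wild_type$calls)
#>     region  n   fraction
#> 1 cds_exon  1 0.01666667
#> 2   intron 53 0.88333333
#> 3      utr  6 0.10000000

res$denovo_adbp1_mutant$calls
#> SiteCalls: 55 sites (0 known, 55 de_novo)
regionSummary(res$denovo_adbp1_mutant$calls)
#>     region  n   fraction
#> 1 cds_exon 38 0.69090909
#> 2   intron  4 0.07272727
#> 3      utr 13 0.23636364
```

All 60 injected wild-type sites are recovered at the catalogued-site stage
with their editing levels (`level` is the pooled target-read fraction; at
~170× pooled depth the binomial standard error at level 0.3 is about 0.035).
The wild-type set is intron-dominated while the mutant's de-novo set is
exon-dominated, mirroring the region biases the generator injects; none of
the ADAR-null artifact changes appear in either output.

A thin command-line wrapper is installed at `inst/scripts/edicall.R`
(`simulate` and `run` subcommands) for shell use.

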