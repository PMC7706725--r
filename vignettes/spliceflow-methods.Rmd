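---
title: "Methods: junction-centric splicing analysis with spliceflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction-centric splicing analysis with spliceflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

spliceflow quantifies alternative splicing directly from splice-junction
read counts, the natural unit of evidence in short-read RNA-seq of compact
genomes. It is built around tissue-enriched IP/input designs (TRAP-seq
style), where ribosome-associated mRNA is immunoprecipitated from a tissue
of interest and the pre-IP whole-animal lysate serves as the matched
control, but every stage accepts plain junction count tables and standard
annotation formats. This vignette explains the models and procedures, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical conventions.

## Coordinates and junction identity

All internal coordinates are 0-based half-open `[start, end)` on an
explicit strand; GTF, STAR `SJ.out.tab` and wiggle conventions are
converted at the I/O boundary and converted back on output, so the
conversion is an involution. A junction is identified by
`(chrom, start, end, strand)` over its intron; the annotated flag is
advisory and never part of identity. Only uniquely mapped reads are used as
junction support when reading STAR output; the multi-mapping column is
ignored. Junctions with an undefined strand code are retained (as `+`, with
a flag) rather than dropped, so read counts are conserved and downstream
filters can decide.

## Junction PSI over donor/acceptor groups

Each junction's percent spliced in (PSI, $\Psi$) is its count divided by
the summed counts of all junctions sharing its splice donor site, and
analogously for its acceptor site:

$$\Psi_{\text{donor}}(j, u) = \frac{c_{j,u}}{\sum_{k \in D(j)} c_{k,u}}$$

where $D(j)$ is the donor group of $j$ and $u$ the pooling unit. A side is
undefined when its denominator is below `min_group_reads` (default 10 per
pooled unit; the data's own support thresholds of 5 and 20 reads apply to
junction *detection*, not to the PSI denominator, so a separate floor is
needed and 10 keeps the binomial noise of a defined PSI below roughly 0.16
s.d. in the worst case). The summary PSI is the minimum of the two defined
sides — a conservative choice: whichever side offers more competing usage
bounds the junction's true inclusion frequency. Within one group and unit,
defined member PSIs sum to 1 by construction.

Pooling by tissue sums replicate counts before division rather than
averaging replicate PSIs; at the low counts where the two differ, the
summed estimator is the maximum-likelihood one and has strictly smaller
variance.

Tissue-enriched junctions are those whose pooled IP support reaches a
threshold while their summed count across *all* input samples is exactly 0.
"Absent" means zero reads, not "below a floor": a single input read
disqualifies. The 5-read threshold is inclusive (at least five reads); the
20-read threshold is strict (more than 20 reads), matching how such
thresholds are usually phrased, and both forms are exposed via the `strict`
flag. A splice-site group is called alternatively spliced in a unit when at
least two members have defined PSI and the minor (non-maximal) member
reaches `minor_psi_min` (default 0.05).

Saturation analysis uses binomial thinning: each count $c$ is replaced by a
$\mathrm{Binomial}(c, f)$ draw, which is exactly the distribution of
retained junction reads under uniform read subsampling at fraction $f$.

## Splice graphs and event classification

Per gene, exonic segments are the union of transcript exons split at every
splice-site boundary (annotated or observed); junctions become edges
between the segment ending at their start and the segment starting at
their end, and introns with intronic read support become retention edges.
Junctions with no matching exonic boundary are set aside as orphans and
counted, never silently dropped. A local splicing variation (event) is the
set of two or more edges leaving one segment's 3' side (source) or
entering one segment's 5' side (target); duplicate events over identical
edge sets are emitted once.

Classification tests fixed pattern templates in a fixed order:

1. **cassette** — two junctions from the anchor to a near internal segment
   E and a far segment B, with the connecting junction E→B present in the
   graph;
2. **alt3ss / alt5ss** — two junctions whose distal segments are contiguous
   extensions of a single exon; a source-side event varies the acceptor
   (alt3ss), a target-side event the donor (alt5ss), strand-aware;
3. **mutually exclusive** — two junctions to distinct internal segments
   that both join a common downstream segment, with no junction between
   them;
4. **alternative start/terminal exons** — both distal segments carry the
   first-exon (target events) or last-exon (source events) flag;
5. **intron retention** — a retention edge competing with a junction over
   exactly the same intron.

An event matching exactly one template receives that class. An event
matching two or more templates uses more than one mode of splicing and is
labelled `complex`, as is any event matching none — including events with
three or more junctions, and the unspecified two-junction residue, for
which `complex` is the honest label since no single canonical mode
describes them. Because templates are tested in a fixed order, the same
input always yields byte-identical event tables.

Event PSI divides each edge's pooled tissue count by the event total
(retention edges contribute their intronic support); an event is
quantifiable in a tissue when its total reaches `min_event_reads` (default
10, the same floor as junction PSI). $\Delta\Psi$ between two tissues is
computed on the event's reference junction — the edge with the maximal
summed count across the pair, the most reliably measured one — and flagged
`differential` at $|\Delta\Psi| \ge 0.20$ and `switch_like` at $\ge 0.80$
(0.15 is available for gene-set style summaries). The comparison uses a
$10^{-9}$ tolerance so values sitting exactly on a threshold up to
floating-point representation are flagged as stated. $\Delta\Psi$ is
antisymmetric in the tissue pair by construction.

Class-proportion shifts between event sets use Pearson's chi-squared on
the 2×2 (class vs rest) × (set a vs set b) table without continuity
correction, so the statistic is exactly $\sum (O-E)^2/E$; expected cells
below 1 attach a warning. The expression-vs-splicing analysis computes
per-gene log2 fold change over the median across tissues with a pseudocount
of 1 (needed because unexpressed tissues are legitimate zeros), flags genes
differentially expressed at a 5× maximal pairwise fold change among tissues
with at least 50 reads, and reports Spearman's rho between the expression
difference and $\Delta\Psi$ per tissue pair.

## Exon triplets and conservation

The unit of conservation analysis is the exon triplet: an internal exon
with its two flanking introns and exons. Cassette events supply the
alternative triplets (tissue-regulated when the event carries a
differential call in any tissue pair, otherwise non-tissue-regulated);
constitutive triplets are internal segments whose single flanking junctions
are the only junctions at their splice sites. Exons at transcript ends
yield no triplet.

Cross-species alignment uses a center-star scheme: every species is
aligned globally to the reference with affine gap penalties (match +1,
mismatch −1, gap open −2, gap extend −0.5 — a conventional DNA scoring in
which a 2-nt gap costs as much as three mismatches) and the pairwise
alignments are merged on the reference coordinate frame, taking the
maximum insertion length per reference position. A triplet is conserved in
a species when all three exons are present — at least half of each exon's
reference columns carry non-gap species characters — and all four internal
splice sites are aligned: non-gap characters at the two intron-terminal
reference columns (the GT/AG dinucleotide positions). The presence
threshold of 0.5 tolerates partial exon divergence while rejecting
wholesale loss; site alignment defaults to the exact columns
(`splice_site_window = 0`) because splice-site registration is the point of
the criterion, and a `require_canonical` switch additionally demands GT/AG
in the species. Triplets with no alignment block covering their span are
excluded from rate denominators — a gene with no homologous alignment
cannot be scored either way. Rates between classes are compared with the
two-sided Fisher exact test.

Windowed profiles average the per-base conservation score at intron
positions 1..23 from each splice site moving into the intron
(strand-aware; 23 still halves even ~40-nt introns, the shortest common
ones), then apply a centered rolling mean of width 3 truncated at the
edges, which preserves the profile mean up to edge effects and reduces to
the raw means at width 1. Introns shorter than twice the flank contribute
each position to only one half (split at the midpoint) and are flagged.
Class comparisons per region are reported two ways: a Wilcoxon signed-rank
test paired over the 23 position means (the default; position is the
natural pairing unit for profile shape) and an unpaired rank-sum test over
per-event mean scores (which respects the event as the sampling unit);
both are emitted because they answer slightly different questions.

## Exon features

Frame preservation is exactly `length %% 3 == 0`. Microexons are internal
exons of at most 27 nt — the boundary is inclusive, with a strict `<`
variant available since both phrasings circulate. Exon-to-protein mapping
converts a coding exon's overlap into 1-based amino-acid positions
(`aa_start = floor(offset/3) + 1`, `aa_end = ceiling((offset + len)/3)`),
attributing codon-spanning exons to every amino acid they touch, so
adjacent exons may share one amino acid and the spans of a transcript's
exons tile its protein exactly. Domain/IDR overlap requires at least one
shared amino acid; proteins absent from the feature annotation are
excluded from denominators by default (a flag includes them as
non-overlapping instead). Disorder and domain annotations are consumed as
intervals, never predicted.

## K-mer enrichment

Motif analysis is a transparent presence/absence scheme: for each k-mer
(k = 5..7 by default) the number of sequences containing at least one
exact occurrence is compared between target and background sets with the
exact hypergeometric upper-tail probability, corrected per k over all
observed k-mers of that length (Benjamini–Hochberg by default; Bonferroni
available — note that for identical target and background sets symmetry
forces every raw p ≥ 0.5, so Bonferroni clips them all to 1). Sequences
are the internal exon plus up to 200 nt of each flanking intron, truncated
at short introns and reverse-complemented for minus-strand events. There
is no de novo motif optimization, no degenerate positions and no PWMs;
matching enriched k-mers to known RBP consensus sequences is left to the
user.

## The synthetic-data generator

The generator produces the full input set — genome FASTA, GTF, IP/input
junction counts, intron-retention support, multi-species alignments (MAF),
a per-base conservation track (bedGraph), protein feature intervals and a
complete ground truth — under one master seed, bit-reproducibly.

Its default configuration *is* the study condition exercised by the test
suite: three broad tissues (mixture fractions 0.30/0.30/0.36) plus two
rare neuronal subtypes at 0.02 each; 78 event genes (30 cassette, 8 of
each other class) at junction-group depth 200 with two IP replicates;
half of each event class tissue-regulated (two-thirds of those switch-like
at roughly 0.9 vs 0.1, the rest moderate at 0.65 vs 0.35; non-regulated
events have a constant minor variant drawn from 0.05–0.20); microexons of
6, 15, 21 and 27 nt implanted as regulated cassette exons; 22 constitutive
and 30 housekeeping genes; and 35 genes exclusive to each subtype at depth
100. Event and constitutive genes are restricted to the broad tissues and
housekeeping genes are expressed everywhere at depth 600 — the realistic
arrangement: a rare cell type expresses a specialized subset, and genes
found in every tissue are the broadly, highly expressed ones.

IP counts are overdispersed Poisson draws around usage × depth, with a
beta-perturbed usage between replicates (dispersion 0.001; TRAP biological
replicates are highly concordant, and at depth 200 stronger dispersion
would make ±0.05 PSI recovery impossible for any estimator, not just this
one). Input samples model whole-animal dilution: each junction's expected
input count is `input_depth_factor` times the mixture-weighted sum of its
expected tissue counts, re-sampled as Poisson per input replicate. The
factor (default 0.012) encodes how much shallower per-transcript input
coverage is than enriched IP coverage — whole-animal libraries spread
reads over every gene of every tissue while the IP concentrates its reads
on one tissue's transcripts — and was fixed by a power analysis of the
dilution regime the design targets: subtype-exclusive junctions (mixture
0.02, depth 100) receive an expected 0.05 input reads and are therefore
absent from input about 95% of the time, while housekeeping junctions
(depth 600 at mixture weight 1) receive about 14 and are essentially never
absent. That separation is the phenomenon the IP/input comparison exists
to detect; a factor near 1 would abolish it for every junction.

The phylogeny simulator evolves each triplet region once per species with
branch-specific per-base substitution rates (0.05–0.35), Poisson-many
geometric-length (p = 0.5) indels, and an atomic internal-exon deletion
with per-species loss probabilities (0.05–0.55) scaled per class
(constitutive ×0.5, non-tissue alternative ×1.3, regulated ×0.9 — ordering
chosen so conservation decreases with divergence and regulated exons are
retained somewhat better than non-regulated alternatives). Splice-site
dinucleotides of regulated triplets substitute at one tenth the branch
rate. Ground-truth conservation is defined as "internal exon not lost";
substitutions and indels are noise against which the classifier is
assessed only in the noise-free setting. The conservation track is
standard normal per base over triplet spans with an additive elevation of
2 within 23 nt of regulated exons' splice sites — an effect size chosen by
a power check (at 2 s.d. with ≥15 events per class the signed-rank
separation is unambiguous, while a null run at effect 0 stays uniform).
IDR/domain intervals are placed to hit per-class overlap rates (IDR
0.4/0.6/0.8, domain 0.6/0.45/0.35 for constitutive/alternative/regulated),
with non-overlapping intervals confined to the protein's N-terminal region
upstream of every scored exon so one exon's interval cannot contaminate
another's measurement.

What the generator does *not* emulate: read-level alignment artifacts
(mismapping, overhang filters), library-preparation biases (GC,
positional), correlated expression structure across genes, realistic codon
evolution or exon shuffling, and IP contamination (the input is a pure
mixture; real IPs carry background). Passing the recovery tests therefore
shows the estimators are correct and well-calibrated under the stated
statistical model, not that the model captures every failure mode of real
TRAP-seq data.

## Pipeline and reproducibility

`run_pipeline()` executes PSI → tissue-enriched detection → splice-graph
events → quantification → differential calls → triplets → conservation
(rates and window profiles) → exon features → k-mer enrichment, writing
one TSV per stage, a summary whose every number is recomputable from the
stage tables, and a manifest with md5 digests of all inputs and outputs.
Output rows are deterministically ordered, so identical config and seed
give byte-identical tables; re-running against an unchanged manifest
performs no recomputation. All randomness flows from the single config
seed, from which each generator derives a fixed stream.

The test suite and the acceptance script run the default configuration
(200 genes, 274 triplets, 5 species, about 600 junctions over 12 samples)
plus smaller purpose-built configurations; these sizes were chosen so the
statistical checks (±0.05 PSI recovery at depth 200, detection sensitivity
at mixture 0.02, signed-rank separation at effect 2) have the power the
checks assume while a full run of everything stays in the minutes range on
one core.

## Known limitations

- PSI carries no uncertainty interval; the coverage floor is a hard gate,
  not a shrinkage prior. Posterior PSI estimation is out of scope.
- Intron retention requires an explicit intronic count input; retention is
  never inferred from coverage profiles.
- The splice-graph classifier describes local variations only; it does not
  assemble transcripts, and complex regions are labelled, not decomposed.
- The center-star aligner is a reference-anchored approximation to a full
  multiple alignment; between-species (non-reference) columns are only as
  good as the star merge.
- K-mer enrichment finds exact substrings; degenerate motifs spread across
  related k-mers and lose power accordingly.
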