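# spliceflow

Junction-centric analysis of alternative splicing across tissues from
splice-junction read counts.

spliceflow is aimed at transcriptomics researchers working with
tissue-enriched RNA-seq designs — in particular TRAP-seq style experiments,
where ribosome-associated mRNA is immunoprecipitated (IP) from a tissue or
cell type and the pre-IP whole-animal lysate serves as the matched "input"
control. In such designs, transcripts of rare cell types are diluted far
below detection in the input, so junction-level comparison of IP against
input reveals splicing that whole-animal sequencing cannot see.

## What it computes

**Junction PSI.** Each splice junction's percent spliced in is its read
count relative to all junctions sharing its splice donor or acceptor site:

    Ψ_donor(j) = c_j / Σ_{k ∈ donor group of j} c_k

computed per side, gated by a minimum pooled group total (default 10), and
summarized as the minimum of the defined sides. Within a group, defined
member PSIs sum to 1.

**Tissue-enriched junctions.** Junctions with pooled IP support at or above
a threshold (5; or strictly above 20) and exactly zero reads across all
input samples.

**Splicing events.** Per-gene splice graphs (exonic segments split at every
splice-site boundary, junction and intron-retention edges) yield local
splicing variations: sets of ≥ 2 edges diverging from or converging on one
segment. Events are classified into cassette, alt 3′/5′ splice site,
mutually exclusive, alternative start/terminal exon, intron retention, or
complex (more than one mode). Event PSI is the count share of each edge;
ΔPSI between tissues is taken on the event's best-covered junction and
flagged differential at |ΔPSI| ≥ 0.20 and switch-like at ≥ 0.80.

**Exon-triplet conservation.** Cassette exons with their flanking introns
and exons, classed constitutive / alternative / tissue-regulated, assessed
across species from alignments (all three exons present, all four splice
sites aligned), with Fisher exact rate comparisons and 23-nt windowed
conservation-score profiles (rolling 3-nt mean) over intron flanks.

**Exon features.** Frame preservation (length multiple of 3), microexons
(≤ 27 nt), exon→protein coordinate mapping, and overlap with protein
domains and intrinsically disordered regions.

**K-mer enrichment.** Exact hypergeometric presence/absence tests of all
k-mers (k = 5–7) between target and background event regions.

A fully ground-truthed synthetic-data generator (`simulation_config()`,
`run_simulation()`) emulates the whole design — tissue-mixture input
dilution included — so every stage is testable end to end with known
answers.

## Worked example

Simulate a study (five tissues: three broad plus two rare neuronal
subtypes at 2% mixture each), then run the main stages:

```r
library(spliceflow)
library(dplyr)

cfg <- simulation_config(seed = 42)
sim_dir <- tempfile()
run_simulation(cfg, sim_dir)

table <- read_junction_counts(file.path(sim_dir, "counts.tsv"), "generic_tsv")
table
#> <jct_table> 592 junctions x 12 samples
#> tissues: neurons, muscle, intestine, dopaminergic, serotonergic, whole_animal

psi <- compute_psi(table, min_group_reads = 10, pool_by = "tissue")
head(filter(psi, psi < 1, !is.na(psi)), 3)
#>   junction_id       unit      psi_donor psi_acceptor   psi group_total_donor
#> 1 gene001:169-306:+ intestine       0.1        1     0.1                 360
#> 2 gene001:169-444:+ intestine       0.9        0.893 0.893               360
#> 3 gene001:312-444:+ intestine       1          0.107 0.107                39
```

The first gene is a cassette exon: in intestine the inclusion path runs at
PSI 0.9 and the skipping junction at 0.1, and both sides of each junction
agree up to counting noise. Junctions detectable only in a rare subtype's
IP are found by requiring zero input reads:

```r
enr <- detect_tissue_enriched(table, "dopaminergic", min_ip_reads = 5)
nrow(enr)
#> [1] 102
head(enr, 2)
#>   junction_id       tissue       ip_support input_support threshold strict
#> 1 gene138:627-753:- dopaminergic        227             0         5 FALSE
#> 2 gene164:224-293:- dopaminergic        226             0         5 FALSE
```

102 of the 140 implanted subtype-exclusive junctions in this simulation are
dopaminergic (the rest serotonergic); their whole-animal expectation is
~0.05 reads, so they are almost always absent from input. Event discovery
and differential calls:

```r
models <- read_gene_models(file.path(sim_dir, "models.gtf"))
found <- find_splicing_events(models, junctions = table$junctions)
count(found$events, event_class)
#>   event_class            n
#> 1 alt3ss                 8
#> 2 alt5ss                 8
#> 3 alt_start_terminal     8
#> 4 cassette              60
#> 5 complex                8
#> 6 mutually_exclusive    16

ep <- quantify_events(found$events, table)
dc <- call_differential(ep, "neurons", "muscle")
c(differential = sum(dc$differential), switch_like = sum(dc$switch_like))
#> differential  switch_like
#>           34            9
```

A cassette exon appears as two events (the divergence at its upstream exon
and the convergence at its downstream one), a mutually exclusive pair
likewise; the class counts above are exactly the implanted structures. The
top differential events are the implanted switch-like cassettes, e.g.
neurons PSI 0.054 vs muscle 0.953 (ΔPSI −0.90).

`run_pipeline(sim_dir, report_dir)` chains all stages — PSI, enrichment,
events, ΔPSI, triplets, conservation rates and window profiles, exon
features, k-mer enrichment — into per-stage TSVs, a summary table and a
digest manifest; identical seed and config reproduce every table byte for
byte. `autoplot()` on window profiles and `plot_psi_heatmap()`,
`plot_class_proportions()`, `plot_kmer_enrichment()` cover the standard
figures.

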