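# mblsplice

Analysis toolkit for studying how deeply the splicing-regulatory activity
of Muscleblind (MBL/MBNL) proteins is conserved across metazoans.  It is
aimed at computational biologists working with junction-level splicing
quantifications from wild-type, MBNL1/2 double-knockout (DKO) and
homolog-reconstituted cell lines, plus genome sequence, multiple
alignments and GO annotations.

The package covers four analyses end to end:

1. **Psi quantification and regulated-event calling.**  Percent spliced in
   is estimated from junction read counts normalised by junction
   multiplicity, Psî = (I/j_I) / (I/j_I + E/j_E), with Beta/Jeffreys
   credible intervals.  An event is called regulated when a beta-binomial
   Bayes factor exceeds 5, |ΔΨ| > 0.1 and a Welch-type monotonicity
   Z-score exceeds 1.5 between replicate groups (single-replicate homolog
   lines are gated on BF and ΔΨ only).  Homolog agreement, activation
   bias (exact binomial) and rescue correlations (R²) summarise the
   comparisons, and `gelPsi()` / `relativeActivity()` reproduce the
   reporter-assay arithmetic.
2. **RNA-map motif enrichment.**  Around each skipped exon, five
   sense-strand regions (the exon and four 250-nt intronic windows) are
   scored for the MBNL-binding 4-mers GCTT/CGCT/TGCT/GCGC against control
   4-mers matched on A+T and CG-dinucleotide content;
   log2(enrichment in regulated / enrichment in unaffected) fills the
   RNA-map heatmap.
3. **Phylogenetic motif conservation.**  In 150-nt intronic flanks of
   internal exons, each motif occurrence gets the branch length of the
   minimal subtree spanning the species that conserve it exactly;
   δ_intron = mean(targets) − mean(controls), δ_gene = max over introns.
4. **GO enrichment.**  Per category, δ_gene inside vs outside by
   two-sided rank-sum test, Benjamini–Hochberg correction, a directional
   floor (p := 1 when the category mean is lower), and a cross-species
   intersection (adjusted p < 0.01 in ≥ 4 organisms).

A deterministic synthetic-data generator (`simulateStudy()`) produces
genomes, gene models, junction counts, MAF alignments, a species tree and
a GO map with known ground truth, so the whole pipeline is testable with
no downloads.

## Worked example

```r
library(mblsplice)

st <- simulateStudy(simulationConfig(seed = 1, n_genes = 60, n_planted = 5),
                    alignments = FALSE)
sc <- SpliceCounts(st$count_table, st$sample_sheet)
calls <- compareGroups(sc, "WT", "DKO")
table(calls$direction, truth = st$events$class)
#>             truth
#>              activated repressed unaffected
#>   activated          4         0          0
#>   repressed          0         2          1
#>   unaffected         0         0         53
```

All four truly activated and both truly repressed events are recovered
with the correct direction; one unaffected event slips through (the
false-discovery proportion the acceptance run quantifies at full scale).
Individual calls carry the three gated statistics:

```r
head(subset(calls, significant), 3)
#>    event_id comparison delta_psi      z       bf direction significant
#> 11   ev0011  WT-vs-DKO      0.29  10.33 1.47e+10 activated        TRUE
#> 30   ev0030  WT-vs-DKO     -0.14  -3.28 3.67e+01 repressed        TRUE
#> 32   ev0032  WT-vs-DKO     -0.35 -10.45 2.80e+15 repressed        TRUE
```

`delta_psi` is the WT-minus-DKO change in exon inclusion, `bf` the
Bayes factor for a Psi difference and `z` the replicate monotonicity
score.  The reporter-assay helper reproduces published arithmetic: a
homolog shifting inclusion to 44% on a reporter that mock leaves at 67%
and human MBNL1 represses to 19% has

```r
relativeActivity(0.44, 0.67, 0.19)
#> [1] 0.4791667
```

i.e. 48% of the human protein's repressive activity.

For the full pipeline (RNA map, conservation, GO) run
`runPipeline(pipelineConfig(...))` on files written by
`writeStudy()`, or see the methods vignette
(`vignettes/mbl-splicing-conservation.Rmd`).

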