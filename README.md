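# devdelay

Transcriptome profiling of a regulator-null mutant embryo typically turns up
thousands of differentially expressed genes. Before reading direct regulation
into that list, one confound has to be ruled out: a **developmental delay**.
A mutant collected at a fixed chronological age (say, 6–12 h embryos) that
develops more slowly will transcriptionally resemble *younger* wild-type
embryos, so every gene whose expression naturally falls or rises over that
developmental interval will look dys­regulated even if the mutant regulates it
perfectly well.

`devdelay` implements the downstream analysis that separates the two
explanations, for anyone comparing mutant vs. control gene-level RNA-seq
tables against a staged wild-type reference time-course (2-hour embryonic
bins, in the style of the public staged embryo expression atlases):

* **IO** for expression matrices (gene × replicate, FPKM or counts) and
  reference time-courses (gene × 2-h bin), with strict validation.
* **Differential expression**: a simple calibrated per-gene test (Welch's *t*
  on `log2(x + 1)`, Benjamini–Hochberg FDR) classifying each gene as
  `not_detected`, `detected_untested`, or `tested` with a direction call at
  `q < α`.
* **The delay rule.** For each significant gene, compare its wild-type
  reference expression in an early window *E* = [0, 6) h to a late window
  *L* = [6, 12) h. An up-regulated gene is *explainable by delay* iff
  mean(*E*) > mean(*L*); a down-regulated gene iff mean(*E*) < mean(*L*);
  ties count as **not** explainable. The unexplained remainder is the
  candidate set of direct effects.
* **Supporting checks**: derepression of reference-silent genes (all-zero
  reference rows), a low-expression filter (significant genes with control
  mean FPKM < 3), per-bin median developmental profiles of the up/down sets,
  and stage assignment (Spearman correlation of a sample against every
  reference bin; a delayed mutant matches an earlier bin).
* **Enrichment**: one-sided Fisher's exact (hypergeometric upper tail)
  overrepresentation with BH FDR and a most-specific-term filter over a
  parent→child term hierarchy.
* **Exact small-sample tests** used throughout such phenotype studies:
  Wilcoxon rank-sum and signed-rank by full enumeration (mid-rank ties,
  symmetric-deviation two-sided p), Kruskal–Wallis, Welch's *t*.
* **A seeded simulator** of staged embryo expression with known ground truth
  (injected delay, direct-effect genes, silent genes), so the whole pipeline
  is testable without any external download.

## Worked example

Simulate a 1000-gene experiment whose mutant carries both a 2 h
developmental delay and 50 genuine direct effects (25 up, 25 down, 4-fold),
then run the analysis:

```r
library(devdelay)

cfg <- simulation_config(n_genes = 1000, delay_hours = 2,
                         frac_direct_up = 0.025, frac_direct_down = 0.025,
                         seed = 12)
sim <- simulate_embryo_experiment(cfg)          # reference + control/mutant
de  <- differential_expression(sim$control, sim$mutant)

tally_expression_classes(de, n_annotated = 1000)
#> annotated 1000 | detected 808 | tested 641 | significant 159 (up 86, down 73)
#> significant: 24.8% of tested, 15.9% of annotated; up 54.1% / down 45.9% of significant

derepression_check(de, sim$reference)$n_silent_upregulated
#> [1] 0

cl <- classify_delay_explainability(de, sim$reference)
summary(cl)
#> delay classification of 159 dysregulated genes (86 up, 73 down)
#> not explainable by delay: 25 of 86 up, 25 of 73 down

sc <- stage_assignment(setNames(de$mean_control, de$gene_id), sim$reference)
sm <- stage_assignment(setNames(de$mean_mutant,  de$gene_id), sim$reference)
c(control = sc$best_bin_label, mutant = sm$best_bin_label)
#>  control   mutant
#>   "8-10"    "6-8"
```

Reading the output: 159 genes change significantly, but most of those calls
track the injected delay — the mutant stage-assigns to the 6–8 h bin while
its age-matched control matches 8–10 h. The window rule leaves exactly 50
genes unexplained by the delay, and they are precisely the 50 direct-effect
genes the simulator spiked in; no reference-silent gene was called
up-regulated. The unexplained sets are what one would carry into
`fisher_overrepresentation()` / `most_specific_terms()` to ask which
biological processes the regulator actually controls.

`run_pipeline(pipeline_config(...))` runs all of the above from TSV inputs
and writes `de.tsv`, `tally.json`, `delay_classification.tsv`,
`profile_summary.tsv`, `enrichment.tsv` and `run_metadata.json`. A thin
command-line wrapper with `simulate`, `de`, `delay`, `enrich`, `run` and
`stats` subcommands is installed at `inst/scripts/devdelay`.

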