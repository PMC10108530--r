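# mindep

Metabolic independence, module completeness and colonization phenotypes
from genome-resolved metagenomes.

## What this is for

After fecal microbiota transplantation (FMT), only some donor gut
populations colonize their recipients; during inflammatory bowel disease,
only some community members thrive. `mindep` is an R toolkit for testing
whether what separates the winners is **metabolic independence** — the
genomic capacity to synthesize essential metabolites (amino acids,
nucleotides, vitamins, cofactors) rather than acquire them from the
community. It is aimed at microbiome researchers working with
metagenome-assembled genomes (MAGs), their KEGG Ortholog (KO)
annotations, and read-recruitment results across sample time series.

The pipeline stages (each independently usable):

* **Pathwise module completeness.** A KEGG module definition is a
  boolean/sequential expression over KOs (space = sequential step,
  comma = alternatives, `+`/`-` = essential/non-essential complex
  subunits, `--` = KO-less reaction, `M#####` = nested module). For a
  genome with KO set *A*, completeness is the best route through the
  module:

  *C* = max over paths of (1/m) Σᵢ c(sᵢ, A),

  with atoms scoring 1 if annotated, complexes the fraction of essential
  subunits present, gaps 0.
* **Detection.** A genome is present in a metagenome when the fraction of
  its nucleotides covered by ≥ 1 read is ≥ 0.25; `q2q3_mean()` gives the
  outlier-robust interquartile mean coverage.
* **Colonization phenotyping.** Genome/recipient pairs become
  `colonized` / `not_colonized` / `undetermined` / `not_applicable` from
  detection timelines plus strain-level subpopulation evidence (filtered
  at 1% proportion and 10X single-copy-gene coverage); genomes become
  good colonizers (detected in donor stool and in all 5 recipients > 7
  days post-FMT) or poor colonizers (donor-detected but absent > 7 days
  post-FMT in ≥ 3 recipients).
* **Enrichment.** Per module, group occurrence (completeness ≥ 0.75) is
  tested with the binomial-GLM Rao score statistic
  R = Σ n_g (p̂_g − p̂)² / (p̂(1 − p̂)), chi-square with G − 1 df, BH-corrected;
  enriched means q < 0.05, ≥ 75% mean completeness and present in ≥ 50%
  of the associated group.
* **MI score.** Summed completeness over the enriched module set; genomes
  at ≥ 80% of the maximum are classified high metabolic independence
  (HMI), the rest LMI, with the threshold always reported.

A deterministic synthetic-data generator (`sim_config()`,
`gen_module_definitions()`, `gen_genome_annotations()`,
`gen_fmt_cohort()`) produces the entire input stack with planted truth,
so every stage is testable without any external download.

## Worked example

Parse one module and score a genome:

```r
library(mindep)
d <- parse_definition("M00018", "(K00928,K12524) K00133 (K00003,K12525)")
length(enumerate_paths(d))                      # 4 alternative routes
pathwise_completeness(d, c("K00928", "K00133")) # 0.6666667
```

Two of the three steps on the best route are annotated, so completeness
is 2/3.

Run the full analysis on a synthetic cohort (443 modules, 33 of them
planted to occur in 95% of good vs 10% of poor colonizers; one donor,
five recipients):

```r
cfg  <- sim_config(seed = 42)
defs <- gen_module_definitions(cfg)
coh  <- gen_fmt_cohort(cfg)
truth <- coh$truth$labels
grp  <- setNames(ifelse(truth$class %in% c("good", "poor"),
                        truth$class, "other"), truth$genome_id)
ann  <- gen_genome_annotations(cfg, defs, groups = grp)
res  <- run_fmt_analysis(coh, ann$annotations, defs)

res$summary$n_good           # 28 good colonizers (raw detection)
res$summary$n_poor           # 20 poor colonizers
res$summary$n_representatives # 20 most-prevalent good kept for enrichment
res$summary$n_enriched_good  # 33 modules enriched in good colonizers
res$group_test$p_value       # 6.7e-08: MI scores differ good vs poor
res$regression
#>    predictor     slope        se         z      p_value
#> 1 prevalence 7.6780623 1.4414565 5.3265999 1.000683e-07
#> 2 donor_dose 0.1992808 0.4330628 0.4601662 6.453970e-01
```

Reading the output: all 33 planted modules (and nothing else) are
recovered as enriched in good colonizers; the mean MI score is 31.7 (of a
maximum 33) in good vs 15.2 in poor colonizers against the reported
threshold 26.4; and a genome's prevalence across the reference metagenome
collection predicts its colonization outcome (Wald z = 5.3) while its
dose in the donor stool does not (z = 0.46).

`run_supplementary_reproduction()` recomputes the same group statistics
(genome counts, mean genome sizes, enriched-module counts, category
percentages, Wilcoxon contrasts) from long-format per-genome/per-module
tables, tolerating renamed headers via a column map.

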