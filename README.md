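# sigscreen

Signature-based screening for nuclear-receptor modulation in gene expression
compendia.

## The problem

Whether a chemical, diet, infection or genetic change activates or
suppresses a transcription factor — the motivating case is the hepatic
nuclear receptor PPARα — can be read out of transcriptomics data, but only
if the readout gene set is truly receptor-dependent. Classic "marker genes"
(e.g. *Cyp4a10*) fail this test: they respond to receptor agonists even in
receptor-null animals. `sigscreen` implements the knockout-anchored
alternative:

1. **Signature derivation.** For several structurally distinct agonists,
   treated wild-type and treated receptor-null animals are profiled. A gene
   enters the signature only if it responds in wild type (BH-adjusted
   p ≤ 0.01), does **not** respond in the same direction in the null, and
   differs between treated wild-type and treated null — for at least 2 of
   the 3 chemicals, in a consistent direction, with |average fold-change|
   ≥ 1.5, and without same-direction membership in signatures of competing
   transcription factors.
2. **Directional similarity (running Fisher test).** The signature is
   compared to a *bioset* — a statistically filtered gene list with signed
   fold-changes from one contrast. Each bioset half (up / down, ranked by
   descending |fold-change|) is scanned: at every rank where a signature
   member occurs, a one-sided Fisher exact (hypergeometric upper-tail)
   overlap p-value is computed; the minimum over scan points, Bonferroni
   corrected for the number of scan points, is the pair p-value. Summed
   −log10 evidence of the concordant pairs (sig-up·bio-up, sig-down·bio-down)
   versus the discordant pairs decides the correlation direction, and the
   winning pairs are combined by Fisher's method. The signed score is
   direction × −log10 p.
3. **Compendium screening.** Every bioset in an annotated compendium gets a
   call — *activated* (positive correlation, p ≤ 10⁻⁴), *suppressed*
   (negative, p ≤ 10⁻⁴) or *neutral* — plus per-category summaries,
   BH-derived cutoffs, and target-gene concordance tables.
4. **Evaluation.** Confusion-matrix accuracy (sensitivity, specificity,
   balanced accuracy) of calls against labeled truth.

A synthetic-data module generates the whole world with planted ground truth
(receptor-dependent program, receptor-independent responders, activator /
suppressor / null compendium biosets) so every stage is testable end to end.

## Worked example

```r
library(sigscreen)

sim <- simulate_ko_experiments(sim_config(n_genes = 5000, n_program = 131,
                                          effect_log2fc = c(2, 2.5),
                                          chemical_presence_prob = 1,
                                          seed = 42))
sig <- build_signature_from_matrices(sim$matrices, name = "PPARA_SYN")
sig
#> <gene_signature> 'PPARA_SYN': 122 up, 9 down

comp <- simulate_compendium(
  compendium_sim_config(n_activators = 20, n_suppressors = 10, n_nulls = 60,
                        n_genes = 5000, bioset_size = 200, seed = 43),
  sim$truth)
tab <- screen(sig, comp$biosets)
table(call = tab$call, truth = comp$labels)
#>             truth
#> call         activator null suppressor
#>   activated         20    0          0
#>   neutral            0   60          0
#>   suppressed         0    0         10

rf_compare(sig, comp$biosets[[1]])
#> <running_fisher_result> correlation: positive  p = 5.28e-122  score = 121.28  overlap = 78 genes
```

The signature recovered all 131 planted program genes (122 up / 9 down at
these strong effect sizes), every activator bioset is called `activated`,
every suppressor `suppressed`, and no null bioset crosses the 10⁻⁴
threshold. The `running_fisher_result` shows the first activator bioset
sharing 78 signature genes concordantly near the top of its fold-change
ranking — hence the large positive signed score.

Accuracy accounting works on any labeled call set:

```r
report <- evaluate_calls(labeled_calls(
  tab$bioset_id,
  ifelse(comp$labels == "null", "negative", "positive"),
  tab$call), positive_means = "activated_or_suppressed")
report
#> <accuracy_report> tp=30 fp=0 tn=60 fn=0
#>   sensitivity 1.0000 (100%)  specificity 1.0000 (100%)  balanced accuracy 1.0000 (100%)
```

## Command line

`exec/sigscreen` exposes the pipeline stages:

```sh
sigscreen degs     --matrix m.gct --groups groups.tsv --group-a wt_treated --group-b wt_ctrl --out bioset.tsv
sigscreen compare  --signature sig.gmt --fc sig_fc.tsv --bioset bioset.tsv --json out.json
sigscreen screen   --signature sig.gmt --fc sig_fc.tsv --biosets dir/ --threshold 1e-4 --out table.tsv
sigscreen evaluate --table table.tsv --truth truth.tsv --out report.json
```

## File formats

- **Biosets**: 3-column TSV (`gene`, `fold_change`, `adj_p`) or RNK;
  `# universe=N` header directive carries the platform gene count.
  Fold-changes are signed linear ratios (−2 = 2-fold down).
- **Signatures**: GMT (`<name>_UP`, `<name>_DOWN`) plus a companion
  fold-change TSV.
- **Matrices**: GCT 1.2 with a sample→group table.
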