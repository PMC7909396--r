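# halfsam

Differential-expression testing for **heterogeneous diseases** — conditions
whose case group mixes etiological subgroups, so that a gene may be
overexpressed in some patients and normal or underexpressed in others.
Such mixing inflates the case-group variance, and the classical pooled
two-sample t-test absorbs that inflation into its denominator and loses
power precisely on the genes that matter.

`halfsam` implements the **half-SAM score**, a moderated statistic whose
denominator uses only the *control*-group standard deviation plus a fudge
factor, alongside its three comparators, with permutation inference,
Benjamini–Hochberg FDR control, and a Monte Carlo engine for
type-I-error/power studies.

## The statistics

With case summaries $\bar X_1, s_1, n_1$ and control summaries
$\bar X_0, s_0, n_0$, and
$s_p^2 = \frac{(n_1-1)s_1^2 + (n_0-1)s_0^2}{n_1+n_0-2}$:

| score | definition | null |
|---|---|---|
| Student's t, $t_s$ | $(\bar X_1-\bar X_0)\,/\,s_p\sqrt{1/n_1+1/n_0}$ | $t_{n_1+n_0-2}$ |
| half t, $t_h$ | $(\bar X_1-\bar X_0)\,/\,s_0\sqrt{1/n_1+1/n_0}$ | $t_{n_0-1}$ |
| SAM, $d_{\mathrm{SAM}}$ | $(\bar X_1-\bar X_0)\,/\,(s_p\sqrt{1/n_1+1/n_0}+c_0)$ | permutation |
| **half SAM**, $d_h$ | $(\bar X_1-\bar X_0)\,/\,(s_0\sqrt{1/n_1+1/n_0}+c_0)$ | permutation |

The fudge factor $c_0$ is chosen on a percentile grid of the per-gene
denominator scatter to minimise the coefficient of variation of windowed
MADs of the scores — the standard SAM stabilisation of low-variance genes.
See the methods vignette (`vignettes/halfsam-methods.Rmd`) for the
estimator, the permutation conventions (per-gene vs pooled nulls), the
simulation models, and the package's calibration notes.

## Worked example

Simulate a 1000-gene dataset (10 case / 10 control samples, control SD 15)
with 5% of genes planted at a mean shift of 25 and a heterogeneous case
group (SD ratio 1.5), then call DEGs with half SAM at FDR 0.05:

```r
library(halfsam)

x <- simulate_dataset(sim_config(md = 25, r = 1.5, nonnull_fraction = 0.05,
                                 n_genes = 1000, seed = 1))
tab <- detect_degs(x, "half_sam", threshold_type = "fdr", level = 0.05,
                   B = 200, seed = 2, null = "pooled")
table(called = tab$significant, planted = attr(x, "nonnull"))
#>        planted
#> called  FALSE TRUE
#>   FALSE   949   26
#>   TRUE      1   24
head(tab[order(tab$padj), ], 3)
#>      gene_id   method    score       pvalue        padj significant
#> 4  gene_0004 half_sam 2.424601 4.999975e-06 0.002499988        TRUE
#> 42 gene_0042 half_sam 2.312412 4.999975e-06 0.002499988        TRUE
#> 15 gene_0015 half_sam 2.197339 9.999950e-06 0.002999985        TRUE
```

24 of the 25 discoveries are planted genes: the BH-controlled call set is
dominated by real signal.  The power comparison under case-group
heterogeneity (here $md = 10$, $r = 2$, $10^4$ gene-tests) shows why the
control-SD denominators matter:

```r
estimate_type1_power(sim_config(md = 10, r = 2, reps = 1e4, seed = 3))
#>      method metric rejection_rate       mc_se
#> 1 student_t  power         0.1465 0.003536068
#> 2    half_t  power         0.3453 0.004754660
#> 3       sam  power         0.1476 0.003547030
#> 4  half_sam  power         0.2271 0.004189577
```

The pooled-SD statistics pay for the inflated case variance; the half
variants do not.

Real data enters through `read_expression_matrix()` (tab-delimited genes ×
samples, with either signed-identifier tumour/normal labels or explicit
case/control tokens), `filter_positive_total_counts()` for RNA-seq count
tables, and `log_transform()`.  A command-line workflow is available:

```sh
Rscript inst/cli/halfsam.R test --matrix expr.tsv --labels labels.txt \
    --method half_sam --fdr 0.05 --B 1000 --seed 7 --out results/
Rscript inst/cli/halfsam.R simulate --scenario-config inst/extdata/example_scenarios.ini \
    --out power.tsv --seed 1
```

Each run writes a JSON manifest (configuration, seed, version, DEG counts)
so it can be replayed exactly.

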