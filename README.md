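# lipsite

Binding-site deconvolution from dose-resolved limited-proteolysis mass
spectrometry (LiP-MS), for chemical biologists who have identified (or want
to identify) a small molecule's protein target and need to know **where on
the structure it binds** — without crystallising the complex.

When a compound binds a protein in a native lysate, it locally changes how
accessible the backbone is to a broad-specificity protease. Across a
compound dilution series, the intensities of peptides near the binding
site therefore follow a sigmoidal dose–response, while the rest of the
proteome stays flat. `lipsite` implements the full deconvolution chain:

1. **Differential filter** — Welch tests of the high doses (2, 20, 100 µM)
   against vehicle on median-centred log2 peptide quantities;
   Benjamini–Hochberg FDR; candidates need *q* < 0.01 and |log2FC| > 0.46.
2. **Dose–response fit** — per-peptide four-parameter log-logistic model
   on the log2 scale,
   `f(d) = bottom + (top − bottom) / (1 + (EC50/d)^s)`,
   fitted in log10(EC50) with bounded Levenberg–Marquardt and multi-start;
   ranked by R² over replicate-level points.
3. **Top-k selection** — the three highest-R² peptides (the ones that in
   practice lie closest to the site, and show the lowest EC50s).
4. **Triangulation** — exact mapping of those peptides onto a PDB chain,
   pooling of their atoms, and the mass-weighted **centre of mass** as the
   predicted site, with the residues within a neighbour radius reported.

It also ranks targets from the upstream reverse-competition pulldown
(iTRAQ channels: vehicle, 8, 80, 800 µM free compound): per-channel median
normalisation, then ordering by the log2 fold-change at the highest dose,
significant above 2 in every replicate.

A seeded synthetic-data module (`simulate_lip_experiment()`,
`simulate_competition_experiment()`, `write_toy_structure()`) generates
both experiment types with known ground truth, so the whole pipeline is
testable offline.

## Worked example

```r
library(lipsite)

# a 500-peptide experiment, 10 peptides responding with EC50 = 1 µM,
# 3 replicates over the 10-point ladder (2 mM ... 2 nM + vehicle), 5% CV
sim <- simulate_lip_experiment(n_peptides = 500, n_responsive = 10, seed = 2)

run <- run_site_prediction(lip_config(quant = sim$quant,
                                      structure = sim$structure))
#> [..] stage=read peptides=500 rows=15000
#> [..] stage=differential tests=1500 candidates=10
#> [..] stage=dose_response fits=10 converged=10 above_r2=10
#> [..] stage=site top_k=3 atoms_pooled=146 nearby=81

run$top[, c("peptide", "ec50", "r_squared", "rank")]
#> # A tibble: 3 × 4
#>   peptide            ec50 r_squared  rank
#>   <chr>             <dbl>     <dbl> <int>
#> 1 QFCQHYGPEK  0.000000836     0.993     1
#> 2 TGGIWWPLYNK 0.000000979     0.992     2
#> 3 FDDGAPCLK   0.00000109      0.991     3

run$site
#> <lip_site> predicted binding site
#>   CoM (mass-weighted): (-1.067, 1.951, 1.994) A from 146 atoms
#>   3 contributing peptide(s); 81 residue(s) within 8.0 A
```

The three top-ranked peptides are all planted responders, their fitted
EC50s bracket the true 1 µM within ~20%, and the predicted centre of mass
lies 3.0 Å from the planted pocket centre (the simulation's ground truth,
`sim$truth$pocket_center`). `autoplot()` on a `fit_peptide()` result draws
the fitted curve; `tidy()`/`glance()` return the parameters and fit
summary as tibbles; `write_site_outputs()` emits a result TSV plus a PDB
with a pseudo-atom at the CoM for PyMOL-style inspection.

The competition arm works the same way:

```r
sc <- simulate_competition_experiment(seed = 7)   # planted target, log2FC 3
run_competition(lip_config(competition_table = sc$table))
#> # A tibble: 500 × 7
#>    rank protein_id log2_fc log2_fc_min log2_fc_max unique_peptides significant
#>   <int> <chr>        <dbl>       <dbl>       <dbl>           <int> <lgl>
#> 1     1 TARGET       2.94        2.94        3.01               25 TRUE
#> 2     2 P0249        0.614       0.614       0.629               7 FALSE
#> ...
```

A thin command-line wrapper with `simulate` / `site` / `compete` /
`validate` subcommands is installed at `inst/cli/lipsite.R`.

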