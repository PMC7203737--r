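# admotif

Transcription factors (TFs) bind DNA at short sequence motifs, often as
homo- or heterodimers whose two half-sites sit at a preferred relative
orientation and spacing. `admotif` models such motifs as **adjacent
dinucleotide matrices (ADMs)** — inhomogeneous first-order Markov chains,
$P(\text{site}) = \prod_h \theta_{a_{h-1}a_h,h}$ — and learns, from
enriched read sets such as HT-SELEX selection windows, a probabilistic
mixture containing one or more monomer motifs **and all their dimers**
simultaneously:

* per monomer pair, a **COB table** of mixing weights over orientations
  (HT/HH/TT/TH) × signed spacings (negative = overlapping half-sites);
* for closely spaced dimers (gap < δ = 4), a learned **bridging
  component** ψ whose **deviation** κ from the product-of-monomers model
  makes binding co-operativity explicit;
* a ZOOPS (zero-or-one occurrence per sequence) EM with IUPAC seed
  initialization, a Hamming-neighborhood restriction of matrix learning
  (radius ρ, default 3), weak-dimer pruning, isolated-occurrence monomer
  learning, and an 85% submodel post-processor.

A ZOOPS read simulator (`generate_reads()`) and a k-mer count/score
R² criterion (`count_kmers()`, `score_kmers()`, `r_squared()`) support
validation. The package is aimed at regulatory-genomics analysts working
with HT-SELEX (or similar enriched) read sets who need motif models that
capture adjacent-base dependence and dimer structure.

## Worked example

```r
library(admotif)

# a homodimer mixture around a synthetic HOXB13-like monomer:
# background 0.70 and dimers HT 4 / HH 4 / HH 2 / TT 2 / HH 5
gen <- build_sanity_model(hoxb13_standin_adm(), sanity_profile(),
                          total_signal = 0.30)
sim <- generate_reads(gen, 20000, 40, seed = 42)

fit <- run_em(sim$reads, "CYMRTAAAA",
              em_config(pairs = list(c(1L, 1L)), rho = 3))
glance(fit)
#> # A tibble: 1 × 8
#>   iterations converged    loglik distance n_monomers n_dimers n_pruned lambda0
#>        <dbl> <lgl>         <dbl>    <dbl>      <int>    <int>    <int>   <dbl>
#> 1         18 TRUE      -1057651. 0.000964          1       13       32   0.703

dplyr::filter(tidy(fit), lambda > 0.005)
#> # A tibble: 6 × 10
#>   component  kind      lambda signal_fraction    k1    k2 orientation     d
#> 1 background backgrou… 0.703          NA         NA    NA <NA>           NA
#> 2 1,1,HT,4   dimer     0.0582          0.196      1     1 HT              4
#> 3 1,1,HH,2   dimer     0.0681          0.229      1     1 HH              2
#> 4 1,1,HH,4   dimer     0.0526          0.177      1     1 HH              4
#> 5 1,1,HH,5   dimer     0.0809          0.272      1     1 HH              5
#> 6 1,1,TT,2   dimer     0.0335          0.113      1     1 TT              2

model_distance(gen, fit$model, strict = FALSE)
#> [1] 0.02269198
```

The learner starts from 46 candidate components (the monomer plus a full
HT/HH/TT × spacing grid), prunes 32 of them, and recovers exactly the five
generating dimers with weights close to the simulated ones (true values
0.061 / 0.068 / 0.055 / 0.082 / 0.034); the final model sits 0.023 from
the generating model in the weighted maximum norm (λ differences, and
matrix differences weighted by component strength).
`cob_tables(fit$model)` gives the orientation × spacing weight tables,
`deviations(fit$model)` the co-operativity matrices,
`save_model()/load_model()` a plain-text directory bundle, and
`autoplot(fit)` / `plot_cob()` quick diagnostics. A thin CLI over the same
functions lives at `inst/cli/admotif.R`
(`learn / simulate / evaluate / postprocess / logo-export`).

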