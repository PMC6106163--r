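# apparency

Are dominant plants more likely to host leaf-mining insects?
`apparency` implements the full analysis chain for that question at a
regional scale: it turns community plot surveys into per-species
importance values, ranks taxa into dominance groups, tabulates
leafminer host ratios by rank group and plant attribute, builds a
dated local phylogeny from a megatree, and fits phylogenetic and
ordinary logistic regressions of binary leaf-mine presence on plant
dominance. It is written for community ecologists and insect–plant
interaction researchers working with presence–absence host records.

## The models

A species' importance value in one community type is
`IV = (RD + RF + RG or RC) / 3` — its relative density, relative
frequency, and relative size (summed girth at breast height for
trees, summed cover for shrubs and herbs), each share computed within
the stratum. Across community types with area ratios `AR_i`,

    TIV_j  = Σ_i IV_ij × AR_i
    RTIV_j = 100 × TIV_j / Σ_k TIV_k

and a group's importance `GIV_m` is the sum of its members' TIVs
(`RGIV_m` as a percentage). Host incidence is then modelled three
ways, with TIV on a per-mille scale `x = 1000 × TIV`:

* **GLM** — ordinary logistic regression
  `logit P(mined) = a + B x`, Wald tests, AIC;
* **binary PGLMM** — the same mean model plus a phylogenetically
  correlated random effect `b ~ N(0, s² V)` (V = Brownian tip
  covariance, unit height), estimated by penalized quasi-likelihood;
  `s² = 0` means no phylogenetic signal, `p(s²)` comes from a
  boundary likelihood-ratio mixture test;
* **phyloglm** — phylogenetic logistic regression whose residual
  correlation decays with patristic distance as `ρ·exp(−α d)`;
  small α = strong signal, large α = none; Firth-penalized estimating
  equations keep coefficients finite under separation.

See the methods vignette (`vignettes/dominance-incidence-methods.Rmd`)
for the estimation details and design choices.

## Worked example

Everything below runs offline on the package's own synthetic
community generator (444 species, 6 community types by default):

```r
library(apparency)
library(dplyr)

cfg  <- sim_config(seed = 1)
phy  <- gen_phylogeny(cfg)
attrs <- gen_taxon_attributes(cfg, phy$taxonomy)
com  <- gen_communities(cfg, attrs)

dom <- total_importance(relative_metrics(com$surveys), com$areas,
                        species_pool = attrs$species)
head(dom, 3)
#>   species   TIV  RTIV
#> 1 sp148   0.380 12.7
#> 2 sp190   0.245  8.17
#> 3 sp192   0.223  7.45

pres <- gen_presence(cfg, transmute(dom, species, tiv = TIV * 1000),
                     phy$tree)
host_ratio_table(rank_and_bin(dom, 12), pres, quiet = TRUE) |>
  format_report() |> head(4)
#>    rank  RGIV n_taxa host_count host_ratio
#> 1     1 71.0      23          1      0.043
#> 2     2 11.1      23          0      0
#> 3     3  5.89     23          0      0
#> 4     4  4.12     23          1      0.043

d <- dom |> transmute(taxon = species, tiv = TIV * 1000) |>
  inner_join(pres, by = "taxon")
fit_binary_pglmm(d, tip_covariance(phy$tree, standardize = TRUE))
#> <mine_fit: pglmm, n = 444>
#>   B = 0.0038137 (p = 0.465), intercept = -3.077 (p = 1.19e-23)
#>   s2 = 0.2291 (p = 1.06e-10)
```

The top dominance group carries 71% of total importance (RGIV), and
the PGLMM slope estimate 0.0038 sits next to the generator's truth of
0.004 with a clearly detected phylogenetic signal (`p(s²) ≈ 1e-10`).
Fitted objects support `tidy()`, `glance()` and `autoplot()`; the
whole chain can also be driven by `run_pipeline(run_config(...))`,
which writes versioned CSV/Newick outputs plus a checksum manifest,
and `make_reports()` for publication-shaped tables and incidence
curves.

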