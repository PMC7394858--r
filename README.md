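# lizmet

Heavy-metal biomonitoring indices from lizard-tail tissue.

`lizmet` is an R package for ecotoxicological surveys that use lizard tails
— obtained non-lethally through autotomy — as a biomonitor of heavy-metal
pollution. From tidy per-sample concentration tables (mg kg⁻¹ of Pb, Cu,
Ni, Zn and Cd in tail tissue, putative prey and soil) it computes the three
standard site-level indices:

* **Bioaccumulation factor** — BAF(m) = C̄_tail(m) / C̄_soil(m); values
  above 1 imply net accumulation in the biomonitor tissue relative to soil.
* **Trophic transfer factor** — TTF(m) = C̄_tail(m) / C̄_prey(m); values
  above 1 indicate a possibility of biomagnification from food to consumer.
* **Hakanson potential ecological risk** — Er(m) = T_r(m) · C_i(m)/C_r(m)
  with toxic-response factors T_r = 30 (Cd), 5 (Cu, Ni, Pb), 1 (Zn) and
  background values C_r; RI = Σ_m Er(m), classified Low / Moderate /
  Considerable / High at thresholds 150 / 300 / 600.

All ratios are built on per-site arithmetic means of the raw samples.
The package also summarises stomach-content diet composition (frequency of
occurrence, percentage contribution by mass), runs an assumption-gated
site-comparison battery (Shapiro–Wilk + Levene, then ANOVA/Tukey or
Kruskal–Wallis/Dunn with Holm adjustment), and simulates site-structured
lognormal concentration data for validation.

A complete coastal Atacama Desert survey ships with the package as a
plain-CSV fixture: 72 tail records, 30 putative-prey records and 28 soil
records from a national park (PAZ), a cove with legacy mine tailings (PAL)
and an industrial port (CAL).

## Worked example

```r
library(lizmet)
fx <- load_fixture()          # bundled survey: $tail, $prey, $soil tibbles
res <- run_full_analysis(fx)  # BAF, TTF, RI with default configuration
res$BAF
#> BAF per site (values > 1 flagged):
#> # A tibble: 3 × 6
#>   site     Pb    Cu    Ni    Zn    Cd
#>   <chr> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1 PAZ    3.71  1.73 0.903  2.26 0.180
#> 2 PAL    5.56  2.83 1.34   5.04 0.258
#> 3 CAL    4.23  1.23 0.496  2.37 0.244
```

Pb bioaccumulates in tails at every site (BAF 3.7–5.6), strongest at the
mine-tailing site PAL; Cd does not (BAF ≤ 0.26) despite dominating the soil
risk index below, because tail tissue discriminates against it.

```r
res$RI
#> Potential ecological risk (background set: alloway1995 )
#> # A tibble: 3 × 8
#>   site  Er_Pb Er_Cu Er_Ni Er_Zn Er_Cd    RI risk_class
#>   <chr> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <chr>
#> 1 PAZ    2.44  8.26  3.87 0.171  281.  296. Moderate Risk
#> 2 PAL    2.67  8.63  3.81 0.139  270.  285. Moderate Risk
#> 3 CAL    2.12  8.03  3.67 0.158  276   290. Moderate Risk
```

All three sites fall in the Moderate Risk band (150 ≤ RI < 300), driven
almost entirely by cadmium (Er_Cd ≈ 270–281 of RI ≈ 285–296): soils across
the transect carry 8–9 mg kg⁻¹ Cd against a 1 mg kg⁻¹ world-soil
background, amplified by Cd's toxic-response factor of 30.

Site contrasts with the statistical battery:

```r
compare_sites(fx$tail, "Cd")
#> Site comparison: Cd in tail
#>   groups: CAL (n=20), PAL (n=22), PAZ (n=30)
#>   path: Kruskal-Wallis + Dunn (Holm)
#>   omnibus: Kruskal-Wallis statistic = 7.076, p = 0.02907
#> ...
```

The skewed concentrations fail the normality gate, so the battery takes the
rank-based path; tail Cd differs between sites (p = 0.029), with the
PAZ–PAL pair driving the signal after Holm adjustment (p = 0.032).

One-shot regeneration of the survey's published index tables, with a
cell-by-cell comparison report:

```r
out <- reproduce_tables("survey-tables")   # writes baf.csv, ttf.csv, ri.csv,
table(out$comparison$match)                # comparison.csv, manifest.json
```

Most cells reproduce the published tables exactly at 2 decimals and RI
agrees within 0.25%; a few cells differ in the last printed digit because
the published index tables were computed from unrounded laboratory values
while the published raw table prints 2 decimals (see the vignette,
"Reproduction fidelity").

A thin command-line wrapper over the same functions lives in
`inst/cli/lizmet` (subcommands `reproduce`, `indices`, `diet`, `stats`,
`simulate`).

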