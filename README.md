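# diabrisk

Dose-response risk models and Bayesian networks for diabetes
complications.

Chronic complications — retinopathy in its non-proliferative (NPDR) and
proliferative (PDR) forms, micro- and macroalbuminuria — carry most of the
burden of diabetes, and decades of clinical trials have quantified how
single risk factors (HbA1c, disease duration, albumin excretion rate,
blood pressure) move the risk of single complications. diabrisk is for
biostatisticians and clinical-informatics developers who want to turn that
published evidence into a patient-level risk advisor without access to the
original trial databases. It implements the full chain:

1. **Evidence tables → datasets.** Literature "from-to" records (factor
   moves from a to b, risk moves from r_a to r_b percent) are flattened
   into two-column dose-response datasets; helpers rescale
   relative-change-only studies against an anchored absolute risk and
   collapse blood pressure to MAP = DP + (SP − DP)/3.
2. **1-1 models.** Seven regression patterns per factor-complication pair
   — linear, logarithmic, quadratic, cubic, power (ln y = ln b₀ + b₁ ln x),
   S (ln y = b₀ + b₁/x) and exponential (ln y = ln b₀ + b₁x) — fitted by
   OLS with a full diagnostic block: R² = SS_M/SS_T, F = MS_M/MS_R with
   exact p, Wherry's adjusted R² = 1 − (1 − R²)(n−1)/(n−k−1), Stein's
   cross-validation adjusted R², the standard error of the estimate, and
   the Durbin-Watson statistic Σ(eₜ−eₜ₋₁)²/Σeₜ². The best pattern is
   selected by adjusted R². A seed-deterministic single-hidden-layer
   neural network is included as the baseline comparison arm.
3. **n-1 models.** Per-factor curves are read as q_k = P(C|f_k), inverted
   through Bayes' theorem, P(f_k|C) = P(f_k)P(C|f_k)/P(C), and combined
   under class-conditional independence into a normalized two-class
   posterior s_yes/(s_yes + s_no) with s_yes = p^(1−n)∏q_k.
4. **n-k model.** Factors are discretized into half-open bins ]lo, hi],
   complication CPTs are filled by the combiner at per-bin representative
   values, and the compiled network answers patient queries by exact
   enumeration — including complication-to-complication edges such as
   albuminuria feeding retinopathy.
5. **Evaluation and simulation.** Sensitivity/specificity/precision sweeps
   over probability cut-offs, and a seeded synthetic cohort generator with
   known dose-response ground truth for priors, parameter-recovery and
   end-to-end testing.

## Worked example

```r
library(diabrisk)

fits <- fit_all(hba1c_npdr())   # 16 literature points, HbA1c vs NPDR risk
fit_summary(fits)
#>      dataset     pattern r_squared durbin_watson wherry_adj stein_adj f_ratio
#> 1 HbA1c-NPDR      linear     0.542          2.10      0.509     0.438   16.55
#> 2 HbA1c-NPDR logarithmic     0.523          2.03      0.489     0.416   15.36
#> 3 HbA1c-NPDR   quadratic     0.546          2.13      0.476     0.351    7.82
#> 4 HbA1c-NPDR       cubic     0.569          2.28      0.461     0.272    5.28
#> 5 HbA1c-NPDR       power     0.457          2.74      0.419     0.335   11.80
#> 6 HbA1c-NPDR           s     0.447          2.67      0.407     0.321   11.29
#> 7 HbA1c-NPDR exponential     0.457          2.76      0.418     0.334   11.78

select_best(fits)
#> <fitted_curve> HbA1c-NPDR, pattern 'linear'
#>   coefficients: b0 = -26.8531, b1 = 4.89999
#>   R2 = 0.542, Wherry = 0.509, Stein = 0.438, F = 16.5, DW = 2.104 (n = 16)
```

The linear pattern wins on adjusted R² (0.509): each extra HbA1c point
raises NPDR risk by about 4.9 percentage points, the fit explains 54% of
the variance, and DW = 2.10 sits in the 1.5-2.5 band for independent
errors. Raw R² would always prefer the cubic (0.569) because the
polynomials are nested — which is why selection uses the adjusted value.

Combining curves for one complication and querying the compiled network:

```r
combine_posterior("micro", c(HbA1c = 7.8, Duration = 8),
                  default_truth_curves()$micro, p_yes = 0.15)
#> [1] 0.1406695

net <- default_compiled_network(n_patients = 5000, seed = 20)
infer(net, c(HbA1c = 7.8, AER = 21, Duration = 8))
#>   complication  probability
#> 1        micro 0.1316553866
#> 2        macro 0.0244546544
#> 3           DR 0.2702301007
#> 4         NPDR 0.0151761990
#> 5          PDR 0.0003597898
```

For this moderately controlled patient (HbA1c 7.8%, normal AER, 8 years'
duration, blood pressure unobserved and marginalized) the network puts the
any-retinopathy risk at 27% and the proliferative form well under 1%.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/diabrisk.R simulate --out cohort.csv --n 1000 --seed 1
Rscript inst/cli/diabrisk.R build-network --cohort cohort.csv --out net.json
Rscript inst/cli/diabrisk.R predict --network net.json --patients cohort.csv --out preds.csv
```

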