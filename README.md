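# huntniche

Do two neighbouring animal groups that share most of their home range
nevertheless prefer different prey? `huntniche` is an R package and analysis
workflow for answering that question with field-style data from two bonobo
groups (Ekalakala and Kokoalongo) hunting three prey types — anomalures,
duikers and squirrels. Because the groups' ranges overlap by about
two-thirds and the groups regularly associate, ecological explanations can
be measured and adjusted for rather than assumed away.

The pipeline takes three delimited text tables — GPS relocations, 30-minute
party-composition scans, and hunt records — and produces:

* **Kernel utilization distributions** per group, with percent-volume
  isopleths (95% home range, 50% core), home-range overlap, and a per-hunt
  **usage difference** score (the non-hunting group's kernel usage at the
  hunt location minus the hunting group's);
* **Dyadic association** via the simple ratio index,
  SRI = P_AB / (P_A + P_B − P_AB), per dyad and year, plus per-hunt social
  covariates (available male/female hunters, mean party association,
  intergroup-encounter classification) and seasonal sine/cosine terms;
* A **Bayesian categorical (multinomial) logit model** of prey type with
  reference category anomalure and reference group Ekalakala,

  P(y = k) = exp(η_k) / Σ exp(η_k'),  η_anomalure = 0,
  η_k = β_k0 + β_k1·group + x'β_k,

  with standardized numeric predictors, Student-t(3, 0, 2.5) priors on all
  coefficients, MCMC sampling (4 chains × 2000 iterations, 1000 warmup,
  4000 retained draws), split-Rhat diagnostics, equal-tailed 95% credible
  intervals, predicted category probabilities per group, and a VIF
  collinearity screen;
* A **synthetic-data generator** with known ground truth (calibrated ~65%
  kernel overlap, intergroup days on ~31% of days, group log-odds ≈ +4.5
  and +5.0) so the entire pipeline is testable by parameter recovery.

## Worked example

The numbered scripts under `analysis/` run the stages at field scale
(~3.5 years, ~60 hunts), writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R 1    # generate the synthetic study system
Rscript analysis/02_ranging.R      # kernel UDs, overlap, usage scores
Rscript analysis/03_covariates.R   # SRI matrices + hunt covariates
Rscript analysis/04_fit_model.R 1  # Bayesian categorical model
Rscript analysis/05_report.R       # tallies and summary
```

Stage 1 prints the hunt tally of the simulated system:

```
Successful hunts by group and prey type
           anomalure duiker squirrel Total
Ekalakala         21      1        0    22
Kokoalongo         3     16       20    39
Total             24     17       20    61
```

Ekalakala's hunts are almost all anomalures while Kokoalongo's are mostly
duikers and squirrels — the group-specific pattern the model is built to
quantify. Stage 2 reports the ranging context (`95% kernel overlap: 67% of
Ekalakala, 67% of Kokoalongo`), and stage 4 fits the model:

```
Category   Term                  Estimate      SE           95% CI
duiker     intercept                -2.66    1.07 [ -5.06,  -0.83]
duiker     group                     4.05    1.49 [  1.44,   7.42]
...
squirrel   group                     6.10    1.90 [  2.93,  10.33]
...
  max split-Rhat 1.005; mean acceptance 0.42
```

The group coefficients are the log-odds increase for a Kokoalongo hunt to
yield duiker (or squirrel) rather than anomalure, holding space use,
season, party size and cohesion at their means; intervals excluding zero
at only ~60 hunts reflect how strong the group signal is (the generative
truth here was +4.5 and +5.0). All other covariates have wide intervals
straddling zero. `predict_category_probs()` converts draws to predicted
prey probabilities per group, e.g. anomalure 0.88 for Ekalakala versus
0.11 for Kokoalongo in this run.

The same stages are callable as functions (`simulate_dataset()`,
`fit_kde_groups()`, `compute_sri()`, `hunt_party_covariates()`,
`fit_categorical()`), and `run_pipeline()` executes everything with a JSON
run manifest (timings, warnings, md5 content hashes). See the vignette in
`vignettes/prey-preference-pipeline.Rmd` for the model, priors, sampler and
generator in detail.

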