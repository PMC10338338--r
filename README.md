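# clockrace

Cell-cycle commitment as a race between two clocks.

When a cycling mammalian cell loses mitogen signalling after passing the
restriction point, two mutually exclusive fates compete. The cell can
still reach **mitosis** — it divides, and its daughters arrest in G0 — or
it can **exit the cell cycle** from S/G2 into a G0-like state (4N DNA, low
CDK2 activity, re-activated APC/C) without ever dividing. `clockrace`
implements the quantitative machinery behind the competing-clocks account
of this decision, for cell-cycle modellers and for anyone analysing
single-cell CDK2/APC-C reporter time series:

* a **synthetic-trace generator** producing populations of single-cell
  CDK2 activity, APC/C activity and cyclin A2 channels under cell-line
  presets (MCF10A, RPE1, degron-tagged RPE1 variants, U2OS) and treatment
  programs (vehicle, mitogen removal, MEKi, CDK4/6i, CDK1i, combinations,
  S-phase delay pulses, unregulated-promoter cyclin A2);
* **trace analysis**: debounced detection of S-phase entry (APC/C
  inactivation), mitosis and cell-cycle exit (sustained CDK2 < 0.6), fate
  classification, exit-probability-by-offset binning, and a per-cell
  logistic regression of exit outcome on cell-cycle position at treatment
  (two-sided Wald test);
* the **clock race**: log-normal or empirical pre-competition clock
  distributions, a seeded Monte Carlo competition, the closed-form win
  probability `P(T_exit < T_mit) = Φ((ln m_mit − ln m_exit) / √(s²_exit +
  s²_mit))` as an oracle, and Kolmogorov–Smirnov comparison of
  post-competition distributions;
* the **kinetic exit clock**: cyclin A2 mRNA shutoff (`M(t) = 2^(−t/h_m)`,
  `h_m = 2 h`) feeding protein decay `dA/dt = λ_p M − λ_p A`, whose
  threshold crossing predicts the exit time (≈ 15 h for the 12 h MCF-10A
  half-life); per-cell log-linear half-life estimation; and the
  cross-cell-line regression of exit time on half-life (slope ≈ 1);
* two **ODE architectures** of the mitogen→CDK2 pathway: a bistable
  CDK2–Rb–E2F feedback switch (irreversible after mitogen removal,
  hysteretic) and the feed-forward chain
  mitogen → CDK4/6 ⊣ p107/p130 ⊣ CCNA2 → cyclin A2 → CDK2
  (unique steady state, no hysteresis, but transiently "apparently
  irreversible" at the time cells would normally divide), with trajectory
  simulation, steady states, dose–response curves and hysteresis-width
  measurement.

Everything takes and returns tibbles, so the stages chain with the pipe;
fitted objects have `tidy()`/`glance()` methods and `plot_*()` helpers.

## Worked example

Simulate an MCF-10A population treated with a CDK4/6 inhibitor at 12 h,
classify fates, test how exit probability depends on cell-cycle position,
and compare the population against the clock-race model:

```r
library(clockrace)

preset   <- make_preset("MCF10A")
traces   <- generate_population(preset, treatment_program("CDK46I"),
                                n_cells = 500, seed = 1)
features <- classify_fates(traces)
table(features$fate)
#>    EXIT MITOSIS
#>      73     427

fit_exit_logistic(features)
#> <exit_logistic> slope = -0.4501 per h (SE 0.0883), Wald p = 3.4e-07, n = 500
```

73 of 500 post-R cells (14.6%) exit rather than divide, and the strongly
negative logistic slope says cells treated further from S-phase entry —
closer to mitosis — exit less often: each hour of progression multiplies
the odds of exit by `exp(-0.45) ≈ 0.64`.

The same exit frequency falls out of the clock race alone, with no
simulated traces at all:

```r
exit_clock <- clock_distribution("LOGNORMAL",
                                 median = predict_exit_time(preset),  # 15.12 h
                                 log_sd = preset$exit_clock_dispersion)
race <- simulate_competition(exit_clock, preset$mitosis_clock,
                             n = 1e5, seed = 1)
race$exit_fraction
#> [1] 0.1324
analytic_exit_probability(exit_clock, preset$mitosis_clock)
#> [1] 0.1315497
```

A 15.1 h exit clock racing an 11 h mitosis clock loses about 13% of the
time — the minority of cells seen exiting in S/G2 — and the Monte Carlo
fraction sits on the analytic value. `glance(race)` additionally shows the
selection effect: the exit times actually observed (median 11.5 h) are
faster than the 15.1 h pre-competition median, because only fast exit
clocks beat their own mitosis clock.

The two network hypotheses separate cleanly:

```r
ff <- build_network("FEEDFORWARD")
fb <- build_network("FEEDBACK")
hysteresis_width(ff, eval_time = Inf, dose_resolution = 0.02)$width  # 0
hysteresis_width(fb, eval_time = Inf, dose_resolution = 0.02)$width  # ~0.18
```

See `vignettes/competing-clocks.Rmd` for the model, its assumptions,
parameter provenance and known limitations.

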