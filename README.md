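# spikespline

Point-process generalized linear models (GLMs) for neural spike trains,
with cardinal-spline covariate bases and a **boundary-modified** variant
that assumes a flat derivative at the endpoint knots.

## The problem

Spike-train GLMs relate the log conditional intensity of a neuron to basis
expansions of covariates — here, an animal's linearized position (the place
field) and the neuron's own spiking history (refractoriness, bursting,
theta rhythmicity):

    log λ(t | θ, H(t)) = Σᵢ θᵢ gᵢ(c̄(t)) + Σⱼ γⱼ fⱼ(Hⱼ(t))

Cardinal splines are a popular choice for g and f because they are local,
smooth, and interpretable (the spline interpolates its control points, so
e^θᵢ is the intensity at knot i). But the standard construction estimates
the function's *derivative* at each covariate bound from two extra "ghost"
control points supported where data are thinnest. For bounded covariates —
position on a finite track, history lags bounded below by 0 — this produces
exploding confidence intervals, spurious derivative estimates, and
numerical instability near the bounds.

The modified basis drops the ghost knots and instead assumes the spline is
flat at the boundary knots: two fewer parameters, identical interior basis
functions, and boundary uncertainty that reflects only the genuine loss of
data near a bound. The package provides:

* cardinal / modified-cardinal spline bases (closed-form Hermite weights,
  partition of unity, interpolation), plus raised-cosine and indicator
  comparison bases under one `basis_matrix` contract;
* spike binning, nearest-time position resampling, spatial and
  spike-history design blocks (causal convolution, lags 1…L);
* Poisson IRLS maximum likelihood with observed Fisher information, Wald
  intervals for parameters and intensity/modulation curves, complete
  separation ("perfect prediction") detection, AIC/deviance, and
  time-rescaling Kolmogorov–Smirnov goodness-of-fit;
* the confidence-interval width ratio (CIWR) boundary diagnostic, parameter
  correlation matrices, occupancy-normalized rate maps, spike-train
  autocorrelation and ISI histograms;
* a self-contained synthetic CA1 place-cell simulator (Bernoulli thinning
  of a self-exciting conditional intensity with refractory, burst and
  theta-band history structure) and a population CIWR experiment;
* a CLI (`inst/cli/spikespline`) with `simulate`, `fit`, `ciwr`, `gof`
  subcommands operating on plain CSV/JSON files.

## Worked example

```r
library(spikespline)

cfg <- sim_config(duration = 600, seed = 1)   # 600 s synthetic place cell
session <- simulate_session(cfg)              # 2357 spikes (3.93 spikes/s)

design <- assemble_design(
  spatial_block(session$position, knot_grid(cfg$spatial_knots)),
  history_block(session$train, knot_grid(cfg$history_knots), L = 200)
)
fit <- fit_ppglm(design, session$train)
param_ci(fit)
```

```
         term estimate    se   rate rate_lower rate_upper
   spatial:k0   -0.055 0.094  0.947      0.788      1.138
  spatial:k75    0.089 0.073  1.093      0.947      1.261
 spatial:k150    3.197 0.056 24.450     21.908     27.287
 spatial:k225   -0.094 0.077  0.910      0.782      1.059
 spatial:k300   -0.210 0.102  0.810      0.664      0.989
   history:k1   -2.465 0.155  0.085      0.063      0.115
  history:k10    0.474 0.041  1.606      1.483      1.740
  history:k40    0.129 0.026  1.137      1.080      1.197
 history:k100   -0.170 0.022  0.843      0.808      0.881
 history:k200    0.019 0.026  1.019      0.969      1.072
```

Spatial coefficients are per-second intensities at the knots (`rate`):
the cell fires at ~24.5 spikes/s at the 150 cm field center against a
~1 spikes/s baseline (truth: 25 and 1). History coefficients are
multiplicative modulations per past spike: ×0.085 at 1 ms lag
(refractoriness), ×1.6 at 10 ms (bursting), mild positive modulation at
40 ms and suppression at 100 ms — all within a couple of SEs of the
generator's ground truth.

```r
hist_mod <- intensity_curve(fit, "history")   # modulation curve, lags 1..200 ms
ciwr(hist_mod)
#> <ciwr_report> (response scale) CIWR start = 0.555, end = 1.09
#>   endpoint widths 0.0525 / 0.103; mean interior width 0.0944 over 180 point(s)

time_rescaling_ks(fit)
#> KS = 0.0174 (95% band 0.0280, n = 2356 ISIs)   # model fits its own data
```

The end-lag CIWR of ~1.1 is the well-behaved boundary signature of the
modified basis (unmodified cardinal splines give ~2.5–15 on the same
sessions, raised cosines under-disperse below 1 at lag 200); the start
ratio sits below 1 because the refractory point estimate scales the width
(see the vignette).

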