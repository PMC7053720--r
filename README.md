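# levotap

Modelling and estimation of the levodopa (LD) motor response in
Parkinson disease.  The package is written for pharmacometricians and
computational neuroscientists who want a mechanistic - rather than
purely empirical - account of the alternate finger-tapping test: how an
oral LD dose travels through plasma and the brain effect site, and how
the resulting dopaminergic tone gates action selection in the basal
ganglia.

## What it computes

The forward model chains three stages:

1. **Plasma kinetics** - a two-compartment model with a first-order
   oral depot (clearance convention),
   `V1 c1' = ka A - (k12 + ketot) c1 + k21 c2`,
   `V2 c2' = k12 c1 - k21 c2`; the three clearances `k12`, `k21`,
   `ketot` (l/min) are estimated per patient.
2. **Pharmacodynamics** - an effect compartment
   `c3' = ke3 (c1 - c3)`, a pure delay `T`, and the sigmoid-Emax (Hill)
   law `D = D0 + Dmax c^ND / (Dc50^ND + c^ND)` producing the
   "dopaminergic input" `D(t)`.
3. **Basal ganglia network** - a two-channel Go/NoGo firing-rate model
   (cortex, striatum, GPe, GPi/SNr, thalamus, a cholinergic unit) that
   converts `D` into an alternate-tapping frequency; its calibrated
   steady-state frequency curve is sigmoid-like, saturating near
   250 taps/min and approximately 180 taps/min under the older
   neuron time constant (15 ms) and inter-movement lag (115 ms).

On top of the forward model the package provides the two-stage
automatic estimation of the 3 kinetic + 6 dynamic parameters
(multi-restart Nelder-Mead on a sum-of-squares + weighted-maximum-error
cost, `k = 10`), clinical response metrics (latency, duration,
stable/fluctuating classification at the 15 % band), exact rank-sum
group comparison with Bonferroni correction, dopamine-gated Hebbian
training experiments (reward = transient doubling of `D`, punishment =
transient nulling), and a synthetic-patient generator reproducing the
clinical sampling schedule.

## A worked example

```r
library(levotap)

patient <- generate_patient(archetype("fluctuating"), seed = 7)
patient
#> <patient_record> f7 (fluctuating): 10 plasma, 12 tapping samples, ground truth attached

pk_fit <- fit_pk(patient$plasma)
glance(pk_fit)
#> # A tibble: 1 × 4
#>       sse    r2 converged iterations
#>     <dbl> <dbl> <lgl>          <int>
#> 1 0.00243 0.994 TRUE              76

pd_fit <- fit_pd(patient, pk_fit, seed = 1)
pd_fit
#> <pd_fit>  cost = 210.2  R2 = 0.9211  best restart 7/10
#> <pd_parameters>
#>   ke3 = 0.1411 1/min  T = 5.167 min  D0 = 0.527
#>   Dmax = 1.603  Dc50 = 0.7147 mg/l  ND = 1.621

response_metrics(patient$tapping)
#> # A tibble: 1 × 5
#>   baseline latency_min duration_min classification no_onset
#>      <dbl>       <dbl>        <dbl> <chr>          <lgl>
#> 1     133.          15           45 fluctuating    FALSE

simulate_tapping_trial(D = 2)
#> <tapping_trial> D = 2: 20 taps, 224.5 taps/min (0 timeouts)
```

The plasma fit explains 99 % of the concentration variance; the
tapping fit (R² = 0.92, above the conventional 0.8 adequacy bar)
recovers a fast effect-site removal rate, and the response metrics
classify the patient as fluctuating: the tapping rate rises 15 % above
its pre-dose baseline at 15 min and returns within 45 min of onset.
`autoplot()` methods exist for patients, frequency curves and training
experiments, and `run_pipeline()` drives a whole cohort through both
stages plus the group statistics.  A thin command-line front end lives
at `inst/cli/levotap` (`synth`, `fit`, `compare`, `train`, `curve`,
`pipeline`).

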