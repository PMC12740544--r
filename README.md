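# ftpdosim

Few-time-point renal dosimetry for [177Lu]Lu-PSMA-617 therapy with
nonlinear mixed-effects models.

## What this is for

Individualized dosimetry in 177Lu radioligand therapy needs the kidneys'
**time-integrated activity** (TIA) — the integral of the activity-time
curve from injection to infinity — but estimating it classically takes
SPECT/CT imaging at several time points over about a week. This package
implements, end to end, the population-model route to sparse-sampling
dosimetry: kidney kinetics are described by a six-parameter
sum-of-exponentials curve, a nonlinear mixed-effects model (NLMEM) is
fitted to a patient cohort by Laplacian marginal likelihood, and each
patient's TIA is then recoverable from *few* — down to one — imaging
sessions by empirical-Bayes estimation under the population prior. The
package quantifies what that reduction costs in accuracy (RMSE/MAPE of
relative deviations against the all-time-points reference) and precision
(CV of each TIA), for every subset of the imaging schedule. It is aimed
at medical-physics and pharmacometrics researchers studying reduced
imaging schedules.

The kinetic model, with fixed physical decay rate
λ<sub>p</sub> = ln2/6.6443 d and blood-circulation rate
λ<sub>bc</sub> = ln2/1 min:

    f(t) = A1 e^-(λ1+λp)t + A2 e^-(λ2+λp)t − A3 e^-(λ3+λp)t
           − (A1+A2−A3) e^-(λbc+λp)t,          f(0) = 0

    TIA  = A1/(λ1+λp) + A2/(λ2+λp) − A3/(λ3+λp) − (A1+A2−A3)/(λbc+λp)

The mixed-effects layer puts log-normal inter-individual variability on
all six parameters (`p_j = θ_j exp(η_j)`, `η ~ N(0, diag(Ω))`) with a
proportional residual error — 6 + 6 + 1 = 13 estimated quantities.
Uncertainties are propagated to the TIA by the delta method, and a
leave-one-out protocol evaluates every session subset without letting a
patient's data shape the prior used for their own estimate. Since no
patient-level data are distributed, a virtual-patient simulator generates
cohorts at the study's sampling design (five sessions at 1.8, 18.7, 42.6,
66.3 and 160.3 h post-injection) with known ground truth.

## Worked example

```r
library(ftpdosim)

g  <- generate_cohort(simulation_config(n_subjects = 20, seed = 1))
st <- run_ftp_study(g$cohort, control = fit_control(n_starts = 5, seed = 1))
st
```

```
Few-time-point TIA study: 20 subjects, 32 methods evaluated
Best schedule per size (by RMSE):
  1TP: TP5     RMSE 8.5%  MAPE 6.9%
  2TP: TP45    RMSE 3.8%  MAPE 3.0%
  3TP: TP345   RMSE 1.9%  MAPE 1.5%
  4TP: TP1345  RMSE 1.2%  MAPE 1.0%
```

Each line is the most accurate schedule of its size: with a single
session (here the late one, TP5) the estimated TIAs deviate from the
all-session references by 8.5% root-mean-square, shrinking to 1.2% with
four sessions. `st$accuracy` holds the full per-method table — median and
range of the relative deviations, RMSE and MAPE with propagated SDs, the
counts of patients beyond 10%/20% deviation, and the eTIA-vs-rTIA
regression; `st$cv` holds the per-method precision (CV) summaries;
`st$tias` the individual TIA estimates with SDs. `write_report(st, ...)`
renders the accuracy and CV tables as CSV or markdown.

A command-line wrapper is installed with the package
(`system.file("scripts", "dosim", package = "ftpdosim")`) with
`simulate` and `run` subcommands over the same functions.

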