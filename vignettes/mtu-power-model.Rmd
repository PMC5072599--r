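---
title: "An EMG-driven model of plantarflexor MTU power during walking Push-off"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An EMG-driven model of plantarflexor MTU power during walking Push-off}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtupower)
```

## The problem

Inverse dynamics gives the *net joint* power at the ankle,
$P_{ank} = M_{ank}\,\omega_{ank}$. Reading that number as the net power of
the plantarflexor *muscle-tendon units* (MTUs) assumes every contributing MTU
crosses only the ankle. The flexor digitorum and hallucis longus (FDHL)
muscles violate this: they cross the ankle, run under the longitudinal arch,
and insert past the metatarsophalangeal (MTP) joints. During Push-off
(roughly 45–65% of the stride) the ankle plantarflexes while the toes
dorsiflex and the arch recoils, so a joint-by-joint analysis splits one
multiarticular MTU's power into positive power at the ankle and offsetting
negative power within the foot. Ankle joint power therefore *overestimates*
net plantarflexor MTU power, and the size of that overestimate matters for
anyone calibrating musculoskeletal simulations, prosthesis actuators, or
clinical interpretations against inverse-dynamics kinetics.

`mtupower` implements an EMG-driven model that quantifies the overestimate,
together with a synthetic gait generator that stands in for (non-deposited)
laboratory recordings while providing exact ground truth.

## The model

For each muscle $m$ (soleus, medial/lateral gastrocnemius, peroneus longus,
FDHL), mass-normalized MTU force is a linear map from the normalized EMG
envelope:

$$F'_m(t) = \mathrm{PCSA}_m \cos(\theta_m)\, \mathrm{EMG}_m(t-\tau)\, C$$

with $\mathrm{PCSA}_m$ the physiological cross-sectional area (cm²),
$\theta_m$ the fiber pennation angle, $\tau$ one electromechanical delay
(EMD) shared by all muscles, and $C$ one scaling constant
(N/(kg·cm²)) per subject and speed. The linear map is a deliberate
simplification: near Push-off at low-to-moderate walking speeds the
plantarflexor fibers operate close to isometrically, where force tracks
activation approximately linearly. No Hill-type force–length–velocity or
tendon-elasticity model is attempted, and the model does not partition MTU
power into fiber vs. tendon contributions.

Per-muscle ankle moments use constant published moment arms,
$M'_{m,ank} = F'_m\, r_{m,ank}$, and the model ankle power is

$$P'_{ank}(t) = \sum_m M'_{m,ank}(t)\, \omega_{ank}(t).$$

### Calibration

Two constants are fit per trial, in this order:

1. **EMD ($\tau$).** The summed unscaled MTU moment waveform is circularly
   shifted through a lag grid, multiplied by $\omega_{ank}$, and Pearson-
   correlated with the inverse-dynamics power $P_{ank}$; $\tau$ is the lag
   maximizing the correlation. Pearson correlation is location- and
   scale-free, so the estimate is independent of the unknown $C$. The search
   covers non-negative lags only (excitation precedes force), 0–200 ms, in
   steps of one stride-grid sample; shifting is circular because the
   stride-averaged waveform is periodic by construction. Ties (never observed
   in practice) resolve to the smallest lag.
2. **Scaling ($C$).** The ratio of the Push-off-window maxima,
   $C = \max(P_{ank}) / \max(P'_{ank}|_{C=1})$, so the scaled model peak
   matches the inverse-dynamics peak exactly. The window maximum (rather than
   the global maximum) prevents locking onto early-stance negative-power
   artifacts.

Model fidelity is reported as the squared Pearson correlation ($R^2$)
between $P'_{ank}$ and $P_{ank}$ over the full stride. A residual-based
$1 - SSE/SST$ variant would penalize the peak-matching scale choice; the
squared correlation is the measure the calibration is designed for.

### Multiarticular FDHL accounting

Two estimates bracket the net plantarflexor MTU power:

* **Isometric worst case.** If the FDHL MTU acts as a rigid cable it
  performs zero net power, and everything it contributes at the ankle is
  cancelled within the foot:
  $P'_{MTU,min} = P'_{ank} - P'_{fdhl,ank}$ with
  $P'_{fdhl,ank} = \omega_{ank} r_{fdhl,ank} F'_{fdhl}$.
* **Kinematic estimate.** FDHL power within the foot follows from MTP
  rotation and arch length change,
  $P'_{fdhl,foot} = -(\omega_{mtp} r_{fdhl,mtp} + \dot l_{arch}) F'_{fdhl}$,
  net FDHL MTU power is $P'_{fdhl} = P'_{fdhl,ank} + P'_{fdhl,foot}$, and the
  net plantarflexor MTU power is
  $P'_{MTU} = P'_{ank} + P'_{fdhl,foot}$. Every other MTU's net power is
  taken as its ankle power (`P'_m = P'_{m,ank}`) — appropriate for
  monoarticular muscles, and also applied to the gastrocnemius because during
  Push-off ankle plantarflexion and knee flexion both shorten it, so no
  sign-offsetting power split arises.

These definitions satisfy the bookkeeping identity
$P'_{MTU} - P'_{MTU,min} = P'_{fdhl}$ pointwise, which the test suite checks
at machine precision. (A literal reading of the combined net-MTU expression
with a *negative* FDHL-ankle term on one side is internally consistent only
for an isometric FDHL; the package uses the form above, which is consistent
with the component definitions.)

### Sign conventions

| quantity | positive direction |
|---|---|
| $M_{ank}$, $\omega_{ank}$ | plantarflexion |
| $\omega_{mtp}$ | toe dorsiflexion |
| $\dot l_{arch}$ | arch lengthening |
| MTU power | shortening under tension |

Toe dorsiflexion and arch lengthening both lengthen the FDHL path, hence the
minus sign in $P'_{fdhl,foot}$: lengthening under force absorbs energy. The
MTP convention is configurable in principle (flip the sign of
$\omega_{mtp}$); the default is chosen so the invariant "lengthening ⇒
negative power" holds with dorsiflexion-positive toe kinematics, which is how
MTP angles are usually reported.

The Push-off overestimates are reported relative to the MTU quantities:
$100\,(X_{ank} - X_{target})/X_{target}$ for $X \in$ {peak power, work} and
targets $P'_{MTU,min}$, $P'_{MTU}$. When per-MTU bursts peak simultaneously
and the FDHL contributes a fraction $f$ of peak model ankle power, the peak
overestimate against $P'_{MTU,min}$ is algebraically $100 f/(1-f)$.

## Signal conditioning

* **EMG chain**, in this exact order: demean, high-pass 150 Hz, full-wave
  rectify, low-pass 10 Hz. All filters are order-3 Butterworth applied
  forward–backward (`signal::filtfilt`), i.e. zero phase lag and a magnitude
  response equal to the squared single-pass response (effective order 6).
  The test suite pins the realized magnitude against the closed-form
  prewarped response $1/(1+r^6)$, $r = \tan(\pi f/f_s)/\tan(\pi f_c/f_s)$.
  Zero-phase filtering matters here: any phase lag would bias the EMD.
  The 10 Hz envelope smoothing is applied on the continuous signals *before*
  stride averaging (averaging is linear, so the order only affects stride
  boundaries; filtering first keeps the per-stride resampling smooth).
* **Kinematics / kinetics**: low-pass 6 Hz (marker-derived channels) and
  15 Hz (force-derived channels) before differentiation. One consequence
  worth knowing: the 6 Hz cutoff attenuates the brief MTP angular-velocity
  peak by roughly 10–15%, which propagates into the FDHL foot-power estimate.
* **EMG normalization**: each muscle's envelopes are divided by that
  muscle's maximum across all supplied trials (walking and
  maximum-voluntary-contraction alike), so the union peaks at exactly 1.
* **Stride segmentation**: footstrike at the upward 20 N crossing of
  vertical GRF, toe-off at the downward crossing, with a 100 ms debounce.
  The threshold and debounce are package choices (any instrumented-treadmill
  pipeline needs some rule); both are parameters.
* **Stride grid**: every stride is linearly resampled to 1000 points
  (footstrike to ipsilateral footstrike) and averaged pointwise. One grid
  step is then about 1 ms of a ~1.1 s stride — far below physiological
  electromechanical delays of tens of milliseconds — and sets the EMD search
  resolution.
* **Differentiation**: central differences, one-sided at the stride ends
  (angles are near-constant at footstrike, so the end treatment is benign).
* **Push-off window**: the last contiguous positive region of ankle power
  ending at or before toe-off. Two robustness rules guard the bounds: a
  positivity floor of 1% of the pre-toe-off maximum (zero-phase filter
  leakage otherwise smears a near-zero positive sliver ahead of the true
  burst onset) and a 2%-of-stride minimum region width (noise debounce).
* **Work**: trapezoidal integration of the positive part of the power
  waveform over the window.

## The synthetic gait generator

The generator produces forward-consistent trials: the ankle moment is built
*from the model's own force map* — Gaussian excitation bursts, delayed by a
known $\tau^\*$ and scaled by a known $C^\*$ — so that the downstream
pipeline, run on a noiseless trial, must recover $(\tau^\*, C^\*)$ (the
test suite requires $\tau$ within one grid step and $C$ within 2%).

Defaults, chosen once as study-like walking conditions:

| parameter | default | rationale |
|---|---|---|
| speeds / stride durations | 0.75 / 1.00 / 1.25 m/s, 1.35 / 1.20 / 1.08 s | typical adult treadmill stride times at those speeds |
| $\tau^\*$, $C^\*$ presets | 88/70/55 ms and 2.30/2.37/1.98 N/(kg·cm²) | speed-average calibration values typical of this model class |
| MTU shares of peak $P'_{ank}$ | soleus 0.544, med./lat. gastroc 0.232/0.114, peroneus 0.044, FDHL 0.066 | triceps surae ≈ 89%, FDHL ≈ 6.6%, peroneus ≈ 4.4% at 1.25 m/s |
| burst centers (width) | 51, 50, 50.5, 48, 54 (5–6) % stride | staggered the way plantarflexors fire; `aligned = TRUE` centers all at 53% |
| envelope peak | 0.2 of the MVC-inclusive maximum | walking EMG peaks well below MVC |
| stance / Push-off | toe-off 65%, positive power 45–65% | canonical gait events |
| MTP / arch excursion | 0.5 rad dorsiflexion bump; ±1% arch length, lengthen-then-recoil | small, Push-off-confined foot motion |
| noise | 0.05 W/kg (moment, expressed on the power scale at peak $\omega$), 0.005 (envelopes) | low-noise lab-grade recordings |
| subject mass | 88 kg | study-like cohort mean |

Envelope amplitudes are calibrated so that, with time-aligned bursts, each
muscle's share of peak model ankle power equals the requested share exactly
(amplitude $\propto$ share / (gain × moment arm)); with the default staggered
timing the realized shares deviate slightly, as they would in data. Raw EMG
(for exercising the conditioning chain end to end) is synthesized as
band-limited 150–500 Hz noise amplitude-modulated by the envelope.

What the generator does **not** emulate: EMG cross-talk, fatigue or
non-stationarity across strides, soft-tissue marker artifact, 3D or
frontal-plane mechanics, deformable-foot power beyond the single arch-length
degree of freedom, and stride-to-stride timing variability. Passing tests
therefore demonstrate the *estimator's* correctness and calibration behavior
under the model's own assumptions — not that those assumptions hold in any
particular laboratory dataset.

Two small systematic effects of the pipeline on synthetic truth are known and
tolerated in the tests: the 20 N footstrike threshold shifts the stride
origin by ~0.3% of the stride, and the 6 Hz kinematic filter widens the
plantarflexion onset, so the detected Push-off window start sits within
about 2% stride of the generated burst onset.

## Sensitivity analysis

Maximum-activation uncertainty is propagated by Monte Carlo: each iteration
draws an independent factor per muscle, uniform on [0.5, 1.5] of nominal
(the distribution is a package choice; only the range is prescribed by the
study design), divides that muscle's normalized envelope by the factor, and
recomputes net MTU Push-off work. Both $\tau$ and $C$ are refit each
iteration, since both are solved from the empirical data and co-vary with
re-normalized EMG; the refit policy is configurable. A direct consequence of
refitting $C$ (peak matching) is exact invariance of net MTU work under a
*common* factor applied to all muscles — $C$ absorbs global scale — which the
suite verifies; sensitivity therefore reflects *relative* activation errors
between muscles. Iterations with a degenerate fit are excluded, counted, and
warned about, never silently dropped. The Push-off window is located once,
from the inverse-dynamics power, which does not change under activation
perturbations.

## Problem sizes

The shipped tests and the acceptance script run on 3–10 stride trials at a
1 kHz trial clock, a 1000-point stride grid, and 1000 Monte Carlo
iterations — sizes at which every reported quantity is stable to well within
the tolerances asserted, while a full run stays under a minute.

## Limitations

Linear EMG-to-force mapping (no force–length–velocity or tendon dynamics);
constant, angle-independent moment arms; sagittal-plane, hinge-ankle
analysis; FDHL treated as one lumped MTU; no fiber-vs-tendon power
partition; other multiarticular muscles crossing the ankle (gastrocnemius at
the knee, extensor digitorum longus) are not given the FDHL treatment. The
overestimates quantified here concern multiarticular bookkeeping only;
rigid-foot assumptions in inverse dynamics itself can produce considerably
larger ankle-power overestimates and are out of scope.
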