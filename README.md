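# mtupower

EMG-driven estimation of plantarflexor muscle-tendon unit (MTU) power during
the Push-off phase of human walking.

## The problem

Inverse dynamics yields *net joint* power — at the ankle,
`P_ank = M_ank · ω_ank` — and that number is routinely read as the net power
of the plantarflexor MTUs. The flexor digitorum and hallucis longus (FDHL)
muscles break that reading: they cross the ankle *and* run under the
longitudinal arch to the toe (MTP) joints, so during Push-off a
joint-by-joint analysis books positive power at the ankle and offsetting
negative power within the foot for what is really one MTU. Ankle joint power
therefore overestimates net plantarflexor MTU power. This package is for
biomechanists, musculoskeletal modelers, and assistive-device designers who
need to know by how much.

## The model

For each modeled muscle `m` (soleus, medial/lateral gastrocnemius, peroneus
longus, FDHL), mass-normalized MTU force is a linear EMG-to-force map

    F'_m(t) = PCSA_m · cos(θ_m) · EMG_m(t − τ) · C

with exactly two constants fit per subject and speed: an electromechanical
delay `τ` (cross-correlation of the summed unscaled MTU moment, times ankle
angular velocity, against inverse-dynamics ankle power) and a scaling
constant `C` (Push-off peak matching). The model ankle power
`P'_ank = Σ_m F'_m r_m,ank ω_ank` is decomposed per MTU, and two estimates
bracket the net plantarflexor MTU power:

* `P'_MTU,min = P'_ank − P'_fdhl,ank` — worst case, FDHL isometric;
* `P'_MTU = P'_ank + P'_fdhl,foot` — kinematic estimate, with
  `P'_fdhl,foot = −(ω_mtp r_fdhl,mtp + d l_arch/dt) · F'_fdhl`.

The package also ships the standard conditioning chain (zero-lag order-3
Butterworth filtering, EMG demean/high-pass/rectify/low-pass, GRF-based
stride segmentation, stride averaging), a Monte Carlo sensitivity analysis
over per-muscle maximum-activation uncertainty, and a forward-consistent
synthetic treadmill-gait generator with exact ground truth, used throughout
the tests in place of laboratory recordings. See the vignette
(`vignettes/mtu-power-model.Rmd`) for the full model account, sign
conventions, and design choices.

## Worked example

```r
library(mtupower)

muscles <- make_muscle_set()                 # five-muscle plantarflexor set
cfg     <- trial_config(speed = 1.25, n_strides = 10, seed = 42)
sim     <- simulate_trial(muscles, cfg)      # trial + ground truth
report  <- run_pipeline(sim$trial, muscles,
                        sensitivity = sensitivity_config(n_iterations = 1000,
                                                         seed = 43))
print(report)
```

```
<run_report>
<model_fit> EMD = 55.1 ms, C = 1.973 N/(kg cm^2), R^2 = 0.9999 (speed 1.25 m/s)
  Push-off window 44.4-64.5% stride
  P'_ank overestimates p_mtu_min peak_power by 5.69%
  P'_ank overestimates p_mtu_min work by 6.01%
  P'_ank overestimates p_mtu peak_power by 0.63%
  P'_ank overestimates p_mtu work by -0.74%
<sensitivity_result> nominal 56.128 J, range [55.456, 57.202], max change 1.91% (1000 sample(s), 0 excluded)
```

Reading the output: the fitted electromechanical delay (55.1 ms) and scaling
constant (1.973 N/(kg·cm²)) recover the generator's ground truth (55 ms,
1.98); `R² = 0.9999` says the two-constant model reproduces the
inverse-dynamics ankle power waveform on this low-noise trial. The
overestimate lines quantify the headline result: peak ankle power exceeds the
worst-case (isometric-FDHL) net MTU power by ~6% on this trial — and by
7.07% when the per-MTU bursts are exactly time-aligned
(`trial_config(aligned = TRUE)`, the algebraic `100·f/(1−f)` with FDHL share
`f = 0.066`) — but exceeds the kinematic net MTU estimate by under 1%. The
sensitivity line shows net MTU Push-off work moves by at most ~2% when each
muscle's assumed maximum activation is independently varied by ±50%.

`report$metrics` carries the per-waveform Push-off peak powers and works
(per kg and absolute), and `write_report(report, dir)` exports everything as
delimited tables plus JSON.

A thin command-line wrapper covers the same stages:

```sh
exec/mtupower simulate --seed 7 -o out/
exec/mtupower decompose --trial out/trial_1.25ms.tsv -o out/run/
exec/mtupower report --dir out/run/
```

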