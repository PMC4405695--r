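# kinemetry

Quantitative analysis of fluorescence-microscopy assays of kinesin-driven
vesicle transport and its regulation by Rab GTPases — for cell biologists
and microscopists who need the numbers behind such experiments: how
confined a vesicle is, how fast and how persistently it moves, how many
motors decorate a microtubule and how many of them walk, how fragmented a
Golgi is, and how tightly two proteins bind.

The package implements, as tested reusable functions:

* **Single-particle motion statistics** — time-averaged MSD and its
  exponent α (slope of log MSD vs log lag; α≈2 directed, ≈1 diffusive,
  <1 confined), track classification at α<0.7 / α>1.3, confinement area
  as the **minimal enclosing circle** (Welzl's algorithm, oracle-verified),
  mean speed, pause rate (instantaneous speed < 0.1 µm/s, strict), and
  direction changes as sign flips of displacement projections on the
  track's first principal axis, excluding paused steps. Group contrasts by
  Wilcoxon rank-sum.
* **Single-molecule TIRF metrics** — microtubule length by skeleton step
  counting, motors/µm of microtubule, percent moving under the
  >0.12 µm/s, >0.2 µm, >0.9 s rule (strict inequalities), and lifespan
  statistics.
* **Golgi morphology** — threshold + 8-connected-component segmentation
  and a per-cell fragmentation score: the fraction of background-subtracted
  Golgi staining in objects larger than a preset area (4.11 µm² siRNA,
  2.74 µm² nocodazole), normalized by marker expression; Welch *t*
  contrasts; masked Pearson colocalization.
* **Binding curves** — one-site saturation fits
  S(L) = B·L/(K_D + L) and microtubule co-sedimentation fits
  f(M) = f·M/(K_D + M) by Levenberg–Marquardt, with flagged
  non-convergence and delta-method K_D-shift ratios.
* **Synthetic data with ground truth** — reflected-Brownian and
  run-and-reverse trajectories with pauses and localization noise,
  spot-decorated microtubule fields, two-channel cell images with
  disc-shaped Golgi objects, and noisy binding tables, so every estimator
  is verifiable by parameter recovery.

## Worked example

The `analysis/` directory is a numbered workflow over the package.
Stage 1 simulates two vesicle cohorts — a control and a "depleted"
condition whose confined vesicles wander over a twice-larger area, run
~30% faster and reverse more often; stage 2 measures all of that back:

```sh
Rscript analysis/01_simulate_cohorts.R
Rscript analysis/02_vesicle_motion.R
```

```
control: 120 tracks, 100% correctly classified
depleted: 120 tracks, 100% correctly classified
confinement area (um^2)      control 0.409 vs depleted 0.792 (x1.94), p = 3.6e-21
mean speed (um/s)            control 0.364 vs depleted 0.458 (x1.26), p = 2.2e-20
direction changes (/s)       control 0.033 vs depleted 0.053 (x1.63), p = 3.5e-15
pause rate (/s)              control 0.072 vs depleted 0.065 (x0.91), p = 0.075
```

The recovered fold changes track the generating parameters (×2 area,
×1.31 speed, ×1.74 reversal rate; pausing unchanged, and correctly not
significant). Speed and direction-change recovery sit slightly below
truth because pauses and frame sampling absorb part of the motion — the
same censoring a real video imposes. Stages 3–5 do the same for TIRF
motor metrics, Golgi fragmentation scoring, and binding fits, e.g.:

```
cbd_site: fitted K_D = 0.864 +/- 0.058 uM (truth 0.90)
cosed adp: K_D = 2.115 uM (truth 2.10); with regulator 22.03 uM -> 10.4-fold shift (truth 10)
```

Each stage writes its tables under `results/`.

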