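---
title: "Modelling inter-fraction pelvic organ motion with a conditional latent-variable diffeomorphism model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling inter-fraction pelvic organ motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Between radiotherapy treatment sessions the pelvic anatomy changes:
bladder and rectum filling vary from day to day, shifting and rotating
the prostate and seminal vesicles. For robust treatment planning one
wants, given only a new patient's planning image and organ contours, a
*distribution* over the anatomies that patient is likely to present at
later sessions — patient-specific in its magnitudes and correlations,
but learned from population data.

`organmotion` implements a probabilistic model of this kind. A planning
image $x$ and organ label map $s_x$ condition a Gaussian prior
$P(z \mid x, s_x)$ over a small number of latent variables $z \in
\mathbb{R}^N$. A generator maps a latent sample (together with a coarse
feature volume $r$ computed from the planning anatomy) to a stationary
velocity field $v$, whose exponential $\Phi = \exp v$ is a
diffeomorphic deformation; warping $(x, s_x)$ with $\Phi$ yields a
synthetic "repeat" anatomy. Each latent sample is one plausible day.

## Model and objective

Three parametric maps are trained jointly:

* **Encoder** $(x, s_x) \mapsto (r, \mu_\theta, \Sigma_\theta)$: the
  down-sampling half of a U-net (three conv blocks, each 3×3×3
  convolution + group normalisation + ReLU + 2× max-pool), a final
  4-channel convolution producing the coarse feature volume $r$ (input
  grid / 8), and two fully-connected heads producing the prior moments.
* **Inference network** $(x, s_x, y, s_y) \mapsto (\mu_\psi,
  \Sigma_\psi)$: identical topology with doubled input channels; during
  training it sees the real repeat and proposes the posterior over the
  latents explaining that pair's deformation.
* **Generator** $(r, z) \mapsto v$: latent injection at the coarse grid,
  three upsampling conv blocks, and two head convolutions ending in 3
  channels (a velocity vector per voxel).

The likelihood is $P(y \mid z, x, s_x) \propto \exp(\lambda\,
\mathrm{CC}(\hat y, y))$ with CC the local squared cross-correlation
over $n^3$ windows, and the minimised single-sample negative evidence
lower bound, with the two explicit regularisers, is

$$
\mathcal{L} = -\lambda\,\mathrm{CC}(\hat y, y)
  - \tfrac1K \sum_k \mathrm{DICE}(\hat s^k_y, s^k_y)
  + \kappa\,\overline{\lVert \nabla \Phi_u \rVert}_2
  + D_{KL}\!\left(Q_\psi \,\Vert\, P_\theta\right),
$$

where $\hat y = \Phi \circ x$, $\hat s_y$ are the soft one-hot warped
labels, and $\Phi_u$ denotes the displacement part of the map (the
identity incurs zero smoothness penalty). Larger image similarity and
contour overlap must lower the minimised loss, hence the negative signs
on the CC and DICE terms.

Defaults: $\lambda = 1000$, $\kappa = 0.1$, learning rate $10^{-3}$,
Adam with default moments. The CC and smoothness terms are averaged
over voxels rather than summed, which keeps these weights meaningful
relative to a DICE term of order one regardless of grid size; users who
switch to summed terms must retune $\lambda, \kappa$. Note that even
under this normalisation the similarity term outweighs the contour
term by roughly 60:1 in displacement-gradient norm and saturates once
the images align to within the texture correlation length; the loss
exposes a `dice_weight` (default 1, the printed objective) and the
benchmark uses `dice_weight = 50`, the value at which the two terms'
gradients are of comparable size.

### Numerical choices

* **Exponentiation**: scaling and squaring with $S = 7$ (scale $v$ by
  $2^{-7}$, then seven self-compositions with trilinear interpolation,
  clamp-to-edge boundaries). The accuracy is interpolation-limited, not
  step-limited: against a 128-step fourth-order Runge–Kutta integration
  of the same flow, the maximum interior displacement discrepancy stays below
  $10^{-2}$ voxels for fields with Gaussian correlation scale
  $\sigma = 8$ voxels and $\lvert v\rvert \le 2$ — the ensemble the
  accuracy tests assert on — and grows as the correlation scale
  shrinks, falling out of that tolerance around $\sigma \lesssim 6$;
  increasing $S$ does not change this, so the smoothness scale is part
  of the method's stated validity domain. The comparison excludes a
  two-voxel boundary shell: trajectories that hit the clamped boundary
  are handled differently by a continuous integrator and by discrete
  composition, which is a boundary-condition difference rather than an
  accuracy one. Exponentiated fields have everywhere-positive Jacobian
  determinants (zero folding) in all our tests.
* **Local CC windows** are clipped to the grid and divided by the true
  in-grid voxel count. On small grids more than half of all voxels sit
  within half a window of the boundary; zero padding with a fixed
  $n^3$ divisor would inject artificial correlation there that is
  insensitive to the deformation and (we found) dilutes the similarity
  gradient badly. Window default $n = 9$, $\epsilon = 10^{-5}$.
* **Label warping** uses one-hot channels, trilinear interpolation and
  an argmax for the hard map; the soft channels feed the differentiable
  DICE. The soft channels form a partition of unity by linearity.
* **Variance heads** produce log-variances clamped to $\pm 10$.
* **Gradients** of every term and layer are analytic (reverse mode,
  hand-written) and are verified against central finite differences in
  the test suite.

### Two design points that differ from the obvious first choice

Both emerged from watching the joint optimisation fail, and both are
choices a user can switch back:

* **Latent injection** (`network_config(latent_injection=)`): the
  default injects each latent coordinate as its own constant coarse
  channel ("tiled"); the alternative maps $z$ through a learned affine
  layer to a single coarse channel. With a single channel the generator
  can (and in our runs did) learn to suppress the initially-noisy
  latent channel entirely, locking the model into ignoring $z$.
* **Inference input encoding**: the inference stack is the planning
  stack plus the repeat-minus-planning *difference* stack — an
  invertible re-encoding of the same inputs. Static anatomy otherwise
  dominates the pooled features and the (small, often sub-voxel)
  deformation signal is buried.

### Training schedule

Whether the joint optimisation ever learns to *use* the latent — we
call this ignition — turned out to be the fragile part of the method at
desk scale, and four measures in `train_config()` address it:

* `warmup_epochs`: the first epochs run in near-deterministic
  autoencoder mode ($z = \mu_\psi$, KL down-weighted). Without it the
  single-sample training noise makes the latent channel look harmful
  and the generator suppresses it before learning to decode it.
* `warmup_kl_weight` (default 0.05): a small KL anchor during the
  warm-up. With the KL fully off, the posterior-mean codes can grow
  unboundedly and saturate the generator's group-norm blocks, which
  freezes learning just as reliably as collapse does.
* `latent_head_init = "pca"`: the posterior mean head starts on the
  whitened top principal directions of the inference features over the
  training pairs (the inference stack encodes the repeat as a
  difference image, so these directions are deformation-dominated).
  With a random head, ignition depended on the luck of the random
  projection; the data-driven initialisation removes that. The
  posterior sd starts sharp (~0.1).
* `ignition_min_gain` / `max_restarts`: a warm-up that fails to move
  the training similarity is restarted from a fresh derived seed.

After the warm-up the full single-sample variational objective is
optimised; the KL settles at a few nats (an informative posterior) and
the prior heads match the per-patient posterior clouds. Ignition also
depends on the data: cohorts whose realised motion is small offer a
proportionally small similarity payoff, and below roughly half the
benchmark's typical motion the desk-scale budget does not ignite at
all — the model then honestly degenerates to the identity baseline.

At inference time the package follows the mode convention: the
posterior mean latent and the deterministic warp (no likelihood
sampling) reconstruct a repeat; prior samples generate new anatomies.

## The synthetic phantom population

The clinical cohorts such models are trained on are not distributable,
so the package ships a generator of pelvic phantoms whose statistical
structure mirrors what the method needs to learn.

* **Anatomy**: spherical prostate (9–11 mm radius), a vesicle lobe
  superior-posterior to it, a larger bladder (10–12 mm) anterior-
  superior, a rectal tube (5–8 mm) posterior, placed with per-patient
  jitter; organ labels never overlap (precedence prostate > vesicles >
  bladder > rectum). Intensities are tissue plateaus in [0, 1] plus
  smooth texture noise; the rectum interior is set to the minimum
  intensity in planning and repeat scans alike, mirroring the clinical
  practice of overriding stochastic rectal content with a fixed low
  density; here the override is applied on the normalised scale.
* **Motion**: three correlated modes in velocity space — bladder
  filling (radial field, linear inside the organ so that a commanded
  fractional volume change $F$ is realised *exactly* by the
  exponential: boundary velocity $R \log F / 3$), rectum filling
  (axial-plane radial, $R \log F / 2$), and a localized prostate
  translation plus a left-right-axis rotation driven by rectal filling.
  Bladder filling additionally pushes the prostate posterior-inferior
  (coupling 0.45 of the bladder boundary velocity). Mode amplitudes
  follow a two-level law: patient means (anatomy-linked — the bladder
  and rectum mode means scale with the planning organ volumes) plus
  correlated within-patient draws sharing a common factor (0.6), all
  truncated at 2 sd so the composed speed respects $\lvert v \rvert
  \le 3$ voxels. Typical prostate COM shifts are a few tenths of a
  millimetre to ~2 mm — the range reported for clinical prostate
  cohorts.
* **Ground truth**: every repeat stores its generating velocity field
  and both displacement directions, so surface-point correspondences
  and deformation recovery can be evaluated exactly; repeat labels ARE
  the warped planning labels, making the model-facing task exactly the
  recovery of the warp.

What the phantoms do **not** emulate: bone/air heterogeneity, CT noise
spectra, FOV/couch artefacts, setup error, delineation variability
between planning and repeat contours. Passing the benchmark therefore
demonstrates that the method recovers known, well-posed deformations at
clinical grid resolution — not clinical-grade performance on real CT.

### Measuring sub-voxel motion

At 2 mm voxels with sub-voxel translations, the centre of mass of the
*hard* (argmax) warped mask moves in whole-voxel jumps: under a
coherent translation every leading boundary face flips together at half
a voxel. Hard-mask statistics (`deformation_stats`) follow the binary
contour definition; distribution-level comparisons therefore also use
the *soft-channel* statistics (first moment of the trilinearly warped
one-hot channels, exactly translation-equivariant), reported in
`sample_anatomy` and `generative_report` as `*_soft_*` columns. The
independent reference law for a patient's COM-shift scalar
(`com_shift_law_draws`) draws fresh amplitudes from the patient's law
and averages the exponentiated mode field over the prostate mask — it
never touches the label-warping, argmax or mask-measurement pipeline.

## The benchmark and its scale

The package's reference benchmark (used by the test suite and the
acceptance script) is 10 patients × 8 repeats at 32×32×24 voxels
(2 mm), the last 2 patients held out entirely; models use 8 conv
channels (4 GN groups), generator head (8, 3), batch size 1, a
20-epoch schedule (11 warm-up + 9 variational) for the N = 8 model and
a 12-epoch schedule (7 + 5) for the N = 1 companion, and a DICE weight
of 50 (the gradient-balance calibration above). These sizes were
chosen so that the entire suite — population generation, two
trainings, every evaluation — completes on a single desktop CPU core
in well under half an hour; the same code runs the clinical-scale
configuration (64×64×48, 32 channels, N up to 32, 1000 epochs)
unchanged.

Evaluated on the held-out phantoms, the trained model's posterior
reconstruction exceeds the identity (no-model) baseline on prostate
DICE and corresponding-point surface error; prior sampling produces
fold-free fields whose COM-shift distributions are compared to the
ground-truth law per patient with two-sample KS statistics; latent
traversal exposes the learned modes; and the posterior latents separate
deformation-magnitude labels better than static organ-size labels —
the package's quantitative form of the claim that the latents encode
deformations, not anatomy. The numbers themselves are produced by the
test suite and `scripts/acceptance.R`, not quoted here.

## Known limitations

* Trilinear composition limits exponentiation accuracy for fields
  rougher than a handful of voxels in correlation length (see above).
* The hard-mask COM quantisation at 2 mm voxels makes contour-based
  shift statistics coarse for sub-voxel motion; use the soft-channel
  statistics for distribution comparisons.
* The anatomy-conditioned prior is only as good as the population's
  anatomy-to-motion link; with very few training patients its variance
  calibration on unseen anatomies degrades first. At the benchmark
  scale the model recovers pair-specific deformations well enough to
  beat the no-model baseline clearly, but prior *samples* under-state
  the deformation magnitudes: the prior-mean latent decodes close to
  the identity rather than to the patient-mean deformation, and the
  superior-inferior motion component is largely unrecovered, so the
  sampled centre-of-mass-shift distribution sits well below the
  ground-truth law (the distribution-recovery KS check fails at this
  scale). Closing this gap needs substantially more capacity and
  training than the desk-scale budget allows.
* Training is CPU-bound R/C++ with exact gradients; it is sized for
  desk-scale experiments, not clinical-scale training runs.
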