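---
title: "Decoding visual stimuli from fMRI: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding visual stimuli from fMRI: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The decoding model

`bolddecode` implements a two-stage framework for reconstructing naturalistic
video stimuli from BOLD fMRI during movie viewing.

**Stage 1 — a latent space for video.** An encoder $E$ and decoder $D$ are
trained jointly on the stimulus frames $v_i$ to minimise the mean squared
reconstruction error

$$\min_{E,D} \sum_i L\!\left[v_i,\, D(E(v_i))\right],$$

so the bottleneck $e_i = E(v_i)$ is a compact per-frame code. Because
consecutive frames are strongly dependent, the encoder is *recurrent*: four
stages of 3×3 convolution + ReLU + batch normalisation + 2×2 max-pooling
reduce each frame to a feature vector, and a stateful tanh GRU turns the
per-frame features into a latent trajectory. The recurrent state persists
within a clip and is reset at every clip boundary — clips are independent
stimuli separated by rest. The decoder maps a latent vector through a dense
layer onto a coarse spatial grid and restores the frame with two rounds of
(4,4) nearest-neighbour upsampling + convolution, with a logistic output
bounding pixels to $[0,1]$ (inputs are normalised intensities). At full
scale the contract is 224×224×3 frames ↔ 1024-dimensional latents; the
desk-scale analogue used throughout the tests is 32×32×3 ↔ 32.

**Stage 2 — mapping brains into that space.** With the autoencoder frozen, a
second network $M$ maps the region-of-interest BOLD vector $f_i$ at each
acquisition to the latent code of the simultaneous frame:

$$\min_{M} \sum_i L'\!\left[e_i,\, M(f_i)\right].$$

$M$ is two stacked tanh GRU layers followed by a linear read-out, with
dropout 0.1 during training; a *memoryless* ablation (two dense tanh layers
of the same width) quantifies what the recurrence buys. Both stages use mean
squared error and Adam with learning rate 0.001, $\beta_1 = 0.99$,
$\beta_2 = 0.999$, $\epsilon = 10^{-7}$. Optimisation is deliberately
sequential — the autoencoder is never revisited after the map is trained —
so test-clip information cannot leak backwards into the decoder.

All networks are implemented from first principles in base R (im2col
convolutions, pooling, batch-norm, BPTT through the GRU, Adam), which keeps
every gradient auditable; the backward pass is verified against numerical
differentiation in the test suite.

## Preprocessing

*Video.* Frames are subsampled in time by nearest-timestamp **selection**
(never averaging) onto the acquisition grid $j \cdot \mathrm{TR}$, and
resized spatially with bilinear interpolation (`EBImage`). Selection rather
than pooling is the package's reading of a decimation design; averaging
would blur moving objects into ghosts. The aspect-ratio change implied by
resizing a 720×1024 frame to a square input is handled by stretching — a
documented convention, not a claim of optimality.

*fMRI.* Global signal regression removes, per voxel, the least-squares
projection onto the mean-across-voxels series plus an intercept; residuals
are exactly orthogonal to the global series. The region of interest is then
chosen *data-drivenly*: a per-voxel two-tailed Welch t-test of movie versus
rest values, keeping voxels with $p < 10^{-8}$. Welch rather than a pooled
t-test because there is no reason to expect equal variances across
conditions; no further multiplicity correction is applied beyond that
deliberately stringent fixed threshold. Timepoints within 2 TRs of a
condition boundary are excluded from the test by default
(`trim_boundary_tr`), since the haemodynamic response smears the
transition. GSR precedes selection, mirroring the preprocessing order of
movie-viewing pipelines.

## The synthetic data generator

The generator exists so that every downstream stage is testable end to end
with known ground truth; it emulates the *structure* of a movie-viewing
acquisition, not its content.

*Stimuli.* Each clip shows one or two coloured glyphs (circle, square,
triangle, face — the face glyph carries eyes and a mouth) moving smoothly
over a grey background, with counter-phase size pulsation so the dominant
object alternates within a clip and every class is dominant somewhere in
the training set. Classes are colour-coded deliberately: recovery of the
dominant class from a blurry decoder reconstruction is then well-posed, and
a simple colour-affinity classifier (`classify_glyphs`) plus a
colour-signature face scorer (`face_score_glyph`) can stand in for the
pretrained object classifier and the cascade face detector that real-data
work would plug into the same interfaces. The per-frame ground-truth
descriptor covers the full scene: two object slots in listing order, each a
class one-hot plus normalised centroid and scale, and a face flag (15
numbers). Covering *all* objects matters — an early dominant-object-only
descriptor left the secondary glyph visible to the encoder but absent from
the simulated BOLD, building irreducible map error into the generator.

*BOLD forward model.* The descriptor is resampled to the TR grid, augmented
with a stimulus-drive channel (1 whenever an object is on screen), mixed
into 200 of 1000 voxels through a random weight matrix, convolved with a
canonical double-gamma HRF (time-to-peak 6 s, undershoot 16 s, ratio 1/6 —
gamma lobes parameterised so the modes sit exactly at those delays), and
corrupted by stationary AR(1) voxel noise ($\phi = 0.3$) plus a shared
global signal. Rest blocks of 20 s separate clips (TR 0.72 s throughout),
and the haemodynamic tail spills naturally into them. The clean signal is
rescaled to unit average per-voxel standard deviation during the movie, so
`noise_sd` is the inverse SNR; the default 0.5 gives SNR 2.

Two generator choices deserve emphasis:

- **Signed sustained responses.** Each signal voxel's drive weight has
  magnitude $4 \times U(0.75, 1.5)$ and *random sign*: visually responsive
  voxels activate or deactivate. This matters doubly. A two-tailed selection
  test is only meaningful when responses go both ways; and if all responses
  shared one sign, the stimulus response *would be* the global signal, so
  GSR would remove the very contrast the ROI test needs (and null voxels
  would inherit an anti-correlated stimulus trace from the regressor).
  With signed responses the global regressor carries almost no stimulus
  signal and selection behaves: sensitivity ≥ 0.99 with zero false
  selections at $p < 10^{-8}$ across seeds, at SNR 2.
- **The noiseless limit.** Setting every noise source exactly to zero makes
  GSR degenerate (it regresses stimulus on stimulus) and gives the t-test
  noise-free inputs in which even the $10^{-3}$-magnitude stimulus leak in
  the global regressor is "significant". The operational noiseless limit
  therefore switches GSR off (there is no ubiquitous nuisance to remove)
  and runs selection on the raw series, where null voxels are identically
  zero and drop out exactly. This is the limit of the noisy pipeline's
  behaviour as noise → 0, which the exact-zero point itself does not attain.

What the generator does *not* emulate: photorealistic content, audio, eye
movements or attention, inter-subject variability, scanner drift, motion
artefacts. Passing tests on this generator demonstrates that the machinery
— selection, alignment, both networks, all evaluation statistics — is
correct and recovers known structure at desk scale; it does not certify
performance on real 7T data.

## Evaluation statistics

- **Cluster-structure agreement.** Encoder latents and map-predicted latents
  are clustered *independently* with k-means for $k = 3..20$ and compared by
  the Hubert–Arabie adjusted Rand index (authored in the package and checked
  exhaustively against brute-force pair counting for $n \le 6$). k-means
  uses 50 restarts by default: measured on identical point sets, 10 restarts
  leave ARI ≈ 0.86–0.92 of local-optimum noise at $k = 10$, while 50
  restarts reproduce the partition exactly — with fewer restarts the
  statistic measures the optimiser, not the decoding.
- **k-NN stimulus matching.** The fraction of timepoints whose own index is
  among the $k$ nearest encoder latents of the predicted latent (Euclidean;
  ties to the lower index, documented and deterministic).
- **Label overlap.** Test-frame top-1 label versus the top-$k$ labels of the
  latent-nearest training frame. With a 4-class vocabulary the package
  reports top-1 and top-2 (the desk analogue of top-1/top-5 over a large
  vocabulary), for both the test condition and the train-seen condition;
  at desk scale the map barely generalises across clips, so the test-
  condition overlap is honest but near its base rate.
- **Face ROC.** Detector confidences (scalar, or per-stage triples combined
  by the cascade convention: a face iff every stage clears its threshold)
  are swept over a grid; FPR/TPR/accuracy are obtained by direct counting.
  Following the reconstruction-based protocol, ground truth is the
  detector's verdict on the autoencoder's own reconstructions; the
  synthetic flags are also reported.

## The experiment protocol

`run_experiment()` wires the stages together: simulate → GSR + ROI →
leave-one-clip-out split (the unit of splitting is always the clip — frames
within a clip are autocorrelated, so frame-level splits would leak) → train
the autoencoder on training clips → freeze and encode everything → train
the map (plus one refit per cross-validation fold) → predict latents for
three conditions (train-seen by both networks; cv-holdout seen by the
encoder but not the map; test seen by neither) → evaluate → decode
reconstructions. Every stage's randomness derives from one master seed, and
the report records the derived seeds, a config checksum, and the clip ids
used at each training stage so leakage is auditable after the fact.

## Problem sizes and defaults

The desk-scale study conditions, fixed as the package's defaults: 4 clips of
30 s at 4 Hz render rate, 32×32 frames, latent dimension 32, encoder
channels (8, 16, 32, 64), 1000 voxels with 200 signal voxels, SNR 2,
autoencoder 80 epochs, map hidden width 96 and 500 epochs (800 in the
noiseless-limit analysis, where convergence of the map is the point).
These sizes keep a full experiment in the low minutes on a single core
while leaving every statistic far from its degenerate regime. Larger
configurations (224×224, latent 1024) are exercised for shape contracts;
training at that scale is GPU work and out of the package's scope.

Two auxiliary study designs complement the default experiment. The
*memory ablation* (`compare_map_architectures`) trains both map
architectures on the ground-truth scene descriptor (strongly
autocorrelated, reached only through the haemodynamic smear) for three
clips and scores the held-out fourth, averaged over five replicate
datasets: per-replicate MSE margins are modest, but the recurrent map's
ARI advantage is large and consistent. The *glyph-recovery* experiment
uses single-object 16×16 scenes (one class per clip, so the dominant class
is unambiguous), four 24 s clips, a 150-epoch autoencoder and the
lag-compensated noiseless pipeline; recovery is the fraction of fMRI-driven
reconstructions whose colour-classified class matches the ground truth.

## Numerical choices and degenerate inputs

- Max-pool ties break deterministically (top-left, below, right, diagonal).
- k-NN and nearest-frame ties go to the lower index.
- Batch normalisation uses batch statistics during training and running
  averages (momentum 0.9) at inference, so encoding is deterministic and
  clip-order independent.
- A constant global signal downgrades GSR to intercept-only with a warning;
  single-class face truth downgrades the ROC to accuracy-only with a
  warning; zero-variance voxels are guarded throughout.
- Dropout masks, mixing matrices, k-means initialisations and all generator
  draws flow from explicit seeds; identical seeds give byte-identical
  serialised reports.

## Known limitations

- The fMRI-to-frame lag is 0 TRs by default (simultaneous indices, the
  formal pairing convention). This asks a *causal* map to report stimulus
  content that has not yet reached the BOLD signal — the HRF peaks ~6 s
  after the stimulus — so at lag 0 the map succeeds only by exploiting the
  smoothness of the latent trajectory. The noiseless-limit analyses
  therefore compensate the known delay (`lag_tr = 8`, i.e. 8 × 0.72 s);
  measured on clean desk-scale data this cuts the map's residual variance
  about sixfold. On real data the optimal lag would be estimated, not
  assumed.
- Desk-scale test-condition (unseen clip) metrics are weak by construction:
  with three training clips the map cannot generalise the way a
  full-scale, multi-session fit can. The train-seen condition carries the
  recoverable signal at this scale.
- The memoryless-ablation margin in held-out MSE is modest per replicate
  (the ARI margin is large); the comparison is therefore defined as an
  average over seeds.
- Real-network adapters (an ImageNet classifier, a cascade face detector)
  are interface-compatible but not shipped: the package's classifiers are
  colour-template mocks backed by ground truth, sufficient for validating
  the statistics, not for real imagery.
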