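---
title: "Methods: cross-modal temporal-spectral graph networks for EEG spasm detection"
author: "spasmgraph authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-modal temporal-spectral graph networks for EEG spasm detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Epileptic spasms in infancy produce brief, stereotyped EEG events — a
high-amplitude slow transient with superimposed fast rhythms — against a
chaotic, high-variance background. Detecting them automatically from scalp
EEG means classifying short segments (here, 5-second epochs of the
16-channel referential 10–20 montage at 250 Hz) as spasm or non-spasm.
The signal of interest lives simultaneously in waveform morphology
(time domain), rhythm content (frequency domain) and in the way channels
co-vary (spatial/functional connectivity). `spasmgraph` models all three
jointly: each epoch becomes a pair of fully connected channel graphs — one
temporal, one spectral — processed by a graph neural network with anatomical
region pooling, bidirectional cross-modal attention and gated fusion.

## Preprocessing

The standardization pipeline runs in a fixed order: channel selection
(16 channels, canonical order Fp1…T6, with modern aliases T7/T8/P7/P8 mapped
to T3/T4/T5/T6), Fourier resampling to 250 Hz, a zero-phase Butterworth
bandpass of 0.7–40 Hz, common-average re-referencing, segmentation into
non-overlapping 5-second epochs, and per-epoch, per-channel z-scoring
$Z_{i,t} = (X_{i,t} - \mu_i)/(\sigma_i + \varepsilon)$ with
$\varepsilon = 10^{-8}$ guarding degenerate channels.

Choices the pipeline fixes that a user should know about:

* **Filter family and order.** A 4th-order Butterworth prototype transformed
  to a bandpass (8 poles), applied forward–backward so epochs keep their
  timing. No DSP package exists in the supported stack, so the design
  (bilinear transform) and the zero-phase filter (odd-extension padding with
  steady-state initial conditions) are implemented in the package and were
  validated coefficient-for-coefficient against an independent reference
  implementation during development; the shipped tests validate them against
  the designed filter's own frequency response, DC and stop-band behavior.
* **Population standard deviation** in the z-score (divisor $T$, not
  $T-1$), chosen for closed-form testability; at $T = 1250$ the difference
  is negligible.
* **Z-scoring is per epoch**, because the classifier consumes standardized
  per-segment matrices. A consequence worth noting: any per-recording or
  per-patient amplitude gain is removed at this stage.
* **Epoch labeling**: an epoch is positive if it overlaps an annotated event
  at all (`min_overlap_frac = 0`); the boundary-mapping rule is not dictated
  by the underlying method, so it is a configurable convention.
* A "dynamic gain control" beyond re-referencing and normalization is
  sometimes described for such pipelines without a formula; no such extra
  stage is implemented here.

## Graph construction

**Temporal graphs.** Node features are the standardized series themselves.
Edge weights are sliding-window Pearson correlations averaged over windows:
with window $L = 250$ samples (1 s) and step $S = 125$ (0.5 s), a 5-s epoch
gives $K = \lfloor (T-L)/S \rfloor + 1 = 9$ windows; the weight
$w_{ij} = \frac1K \sum_k r_{ij}^{(k)}$, $w_{ii}=0$. The window length and
step are tunable; the defaults balance temporal resolution of the dynamic
connectivity against the stability of a 250-sample correlation.

**Spectral graphs.** Edge weights are the weighted phase lag index (wPLI),
computed from Welch cross-spectra (1 s Hann segments, 50 % overlap) as
$|\mathrm{mean}\, \Im S_{ij}| / \mathrm{mean}\, |\Im S_{ij}|$ with the mean
pooled **jointly over segments and all frequency bins in 0.7–40 Hz**, and
$0/0 := 0$. The pooled form (rather than per-bin wPLI averaged across bins)
is what makes a constant-lag narrowband pair saturate at 1 and a zero-lag
pair vanish — the behavior a connectivity feature insensitive to volume
conduction should have. Node features are log **band-integrated** Welch
power in five bands (delta 0.7–4, theta 4–8, alpha 8–13, beta 13–30, gamma
30–40 Hz, half-open intervals): integrating (rather than averaging per bin)
makes a flat spectrum produce features ordered by bandwidth, which is the
natural null behavior and what the test suite pins down.

Both graphs are fully connected without self-loops; the spectral graph
mirrors the temporal graph's full connectivity for architectural symmetry.

## The network

Per epoch, two branches run in parallel and interact at the region level:

1. **Multi-scale temporal encoder.** Three parallel valid (no-padding,
   stride-1) 1-D convolutions per channel with kernel sizes
   $\{100, 50, 25\}$ (0.4, 0.2, 0.1 s at 250 Hz; long-, medium- and
   short-range morphology), each followed by batch normalization and ReLU,
   then global average pooling over time, concatenation and an affine map to
   the shared width $D$.
2. **Projection** of each modality's node features to width $D$ (the
   temporal branch projects the multi-scale embeddings; the spectral branch
   the five band powers).
3. **Edge-conditioned graph convolution**: each scalar edge attribute (DFC
   or wPLI weight) is mapped by an MLP ($1 \to 64 \to D^2$, ReLU) to a full
   $D \times D$ kernel; messages are kernel-transformed neighbor features,
   mean-aggregated over the fully connected neighborhood, then ReLU and
   LayerNorm. Where a formulation differs between a ReLU-only and a
   ReLU+LayerNorm update, the normalized variant is implemented — it is the
   one that keeps deep edge-conditioned stacks trainable.
4. **Region attention pooling** into $R = 5$ anatomical groups (frontal
   {Fp1, Fp2, F3, F4, F7, F8}, central {C3, C4}, parietal {P3, P4},
   occipital {O1, O2}, temporal {T3, T4, T5, T6}; the assignment ships as a
   JSON config file, not code): a learnable score vector per region, softmax
   within the region, weighted sum.
5. **Bidirectional multi-head cross-modal attention** over the $R$ region
   positions ($H = 4$ heads, scale $1/\sqrt{d_h}$), temporal queries against
   spectral keys/values and vice versa.
6. **Gated fusion**: $g = \sigma(W_g [u; \tilde u])$, output
   $g \odot \tilde u + (1-g) \odot u$ — an elementwise convex blend of raw
   and attention-enhanced region features.
7. **Classifier**: both modalities' fused region features flattened to
   $2RD$, a two-layer network with ReLU and dropout (0.5, training only),
   sigmoid output.

Widths that the architecture leaves open ($D = 64$ by default, $H = 4$,
8 convolution channels per branch, edge-MLP hidden 64, classifier hidden
128) are engineering defaults, all configurable in `model_config()`.

**Batch normalization semantics.** Statistics are computed per sample over
(channels × time) during training — instance-style, so no information leaks
across the samples of a batch and training is exactly reproducible
regardless of batch composition — with running statistics (momentum 0.9)
used at inference.

**No deep-learning framework is used.** The forward pass and full analytic
reverse-mode gradients (through the convolution branches, batch/layer norms,
edge-kernel MLPs, attention and fusion) are implemented in R with
Rcpp/Armadillo kernels for the convolution and message-passing hot paths.
Every backward formula is checked against central finite differences in the
test suite (relative error ~1e-6 across all parameter groups, both BN
modes).

## Training and evaluation

Adam (learning rate 0.01, batch 32) on the focal loss
$-\alpha_t (1-p_t)^\gamma \log p_t$ with $\alpha = 0.25$, $\gamma = 2$ (the
standard defaults of the focal-loss formulation; the class imbalance of
spasm data is the motivation). The reference epoch budget is 150; the
synthetic benchmark in the tests uses 30. No early stopping, no learning
rate schedule, no re-sampling anywhere — the focal loss carries the
imbalance burden. Probabilities are thresholded at 0.5.

Cross-validation is always grouped at the patient level: a grouped
stratified k-fold (patients ordered by descending spasm count, ties broken
by id, dealt round-robin — so each fold approximates the global
spasm fraction) and leave-one-patient-out. A leakage audit at batch
assembly refuses any fold whose training and test patients intersect.

Metrics: accuracy, precision, recall, specificity, F1 from the confusion
counts (empty denominators yield 0 with a degeneracy flag), and AUC by the
rank-sum identity with average ranks for ties — exactly the pairwise
concordance probability, which the tests verify exhaustively on small
instances.

## Explainability

Attribution is gradient × input against the **pre-sigmoid logit** (the
probability's gradient vanishes when the output saturates; the logit's does
not). The temporal attribution is taken with respect to the standardized
input series, the spectral one with respect to the band-power features;
edge weights are held constant, since the question posed is about channel
contributions. Channel scores are means over the non-channel axis (the
spectral branch mirrors the temporal averaging), fused with a fixed
coefficient $\lambda = 0.5$ so both modalities weigh equally, and summed
within regions — aggregation conserves total evidence exactly. For display,
scores are min–max normalized per sample (the normalization is recorded in
the result object; raw scores are preserved), and rendered as an
interpolated scalp map on schematic 10–20 coordinates.

## The synthetic world

The generator exists so that every stage — preprocessing, graphs, training,
metrics, attribution — is testable without clinical data. It emulates the
statistical structure the detector relies on, not clinical realism:

* Background: per-channel $1/f^\beta$ Gaussian noise ($\beta = 1$) with a
  weak shared source (mixing weight 0.2) so baseline connectivity is
  non-trivial; channels are normalized to unit standard deviation.
* Events: on a designated channel subset only, a 2 Hz high-amplitude slow
  wave with a superimposed 20 Hz burst over a random 1–3 s Hann-tapered
  sub-interval, with amplitude `event_snr` (default 3) relative to the unit
  background. The default event subset is the fronto-central and
  anterior-temporal pairs {F3, F4, C3, C4, T3, T4} — the systems where
  spasm evidence concentrates clinically — chosen once; it also keeps the
  attribution-localization criterion's 1.5× enrichment bound geometrically
  satisfiable (the bound is impossible once the event set exceeds 10 of 16
  channels).
* Patient heterogeneity: a log-normal per-patient gain (σ = 0.2) and, with
  probability 0.3, one event channel swapped against a non-event channel.
  Note the gain is annihilated by the per-epoch z-score stage, so the
  heterogeneity that survives preprocessing is the channel jitter.

What a green synthetic benchmark establishes: that the implementation can
learn class-conditional spectral/connectivity structure confined to known
channels, generalize across patients under grouped splits, and attribute
its decisions back to the channels that actually carry the signal. What it
does not establish: performance on clinical EEG, robustness to artifacts,
or hypsarrhythmia-like nonstationarity — none of which the generator
models.

## Numerical choices and limitations

* Correlation and z-score stabilizers default to $10^{-8}$; BN/LN epsilons
  to $10^{-5}$. Degenerate windows yield near-zero correlations rather than
  errors; all-zero channels get floored log-powers with a warning.
* Initialization is Glorot-uniform throughout with zero biases and unit
  norm gains; training is bit-deterministic given the seed (initialization,
  shuffling and dropout all draw from one seeded stream; per-fold seeds are
  derived from the base seed).
* The separability-monotonicity property (held-out AUC non-decreasing in
  `event_snr`) is tested at a deliberately scaled-down size chosen so the
  AUC estimate has statistical power within the runtime budget; at very
  small scales the low-SNR AUC is dominated by sampling noise and the
  property is untestable.
* Known limitations: single binary output per epoch (no cross-epoch
  temporal model), no artifact/ICA handling, no alternative connectivity
  estimators (coherence, PLV, Granger), no graph sparsification. These are
  out of scope by design.
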