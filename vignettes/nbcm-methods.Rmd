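---
title: "Methods: contrast-normalized BCM learning of V1 receptive fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contrast-normalized BCM learning of V1 receptive fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbcm)
```

# The model

This package simulates how the receptive fields of primary-visual-cortex
(V1) simple cells could develop from visual experience under Hebbian
plasticity, and asks what divisive contrast normalization — a lateral
interaction believed to operate in V1 — adds to the population code.

## Retinal front end

Luminance images are log-transformed (the standard model of photoreceptor
light adaptation) and convolved with a difference-of-Gaussians (DoG) filter
modelling the center–surround organization of retinal ganglion cells (RGCs):

$$K(x, y) \;=\; G_{\sigma_c}(x, y) - \lambda\, G_{\sigma_s}(x, y),
\qquad \sigma_c = 0.75\ \mathrm{px},\ \ \sigma_s = 2.25\ \mathrm{px},$$

with $\lambda$ chosen so the *discrete* kernel sums exactly to zero (a
zero-DC, volume-balanced filter; balancing the sampled sums rather than the
analytic volumes avoids a residual DC term from truncation). The kernel is
truncated to a square of half-width $\lceil 4\sigma_s \rceil$ pixels, which
retains more than 99.99% of the surround Gaussian's volume. Convolution uses
"same"-size zero padding and a 10-pixel border is discarded (256×256 images
become 236×236 response maps). Finally, square patches of side $g$ (16 at
paper scale) are cut at uniformly random positions and each patch is
standardized to zero mean and unit standard deviation. These standardized
patches are the model RGC responses $d_i$; their sign carries the ON/OFF
channel distinction.

## BCM learning with a sliding threshold

A population of $J$ neurons shares the $g\times g$ RGC input. For each
presentation, neuron $j$ responds

$$c_j = s\!\Big(\sum_i m_{ij}\, d_i\Big), \qquad
s(r) = \begin{cases} k_1 \tanh r, & r > 0\\ k_2 \tanh r, & r \le 0
\end{cases}$$

with $k_1 = 25$, $k_2 = 1$ (a strongly asymmetric saturating output). The
weights and the per-neuron modification threshold $\theta_j$ evolve as

$$\delta m_{ij} = \eta\, c_j (c_j - \theta_j)\, d_i, \qquad
\delta \theta_j = \big(c_j^2 - \theta_j\big)/\tau,$$

so learning is Hebbian above threshold and anti-Hebbian below, and
$\theta_j$ is an exponential tracker of $\mathrm{E}[c_j^2]$ with time
constant $\tau = 1000$ presentations. The learning rate starts at
$\eta_0 = 10^{-5}$ and is cut by 0.1% once every 1000 iterations (a stepwise
schedule, not a continuous decay). Weights initialize uniformly on
$[-1, 1]$; thresholds initialize at 0, which keeps them in $[0, k_1^2]$
forever under the threshold dynamics.

## Divisive normalization (NBCM)

In NBCM mode each raw sigmoid output is divided by the pooled squared
activity of the whole population (Naka–Rushton-like, with semi-saturation
constant $\alpha$ and gain $\beta$):

$$c'_j = \frac{\beta\, c_j}{\alpha + \sum_i c_i^2}.$$

The pool uses the raw (pre-normalization) outputs of all $J$ neurons,
including $j$ itself, so the rule is non-recursive, the denominator is at
least $\alpha$, and $|c'_j| \le \beta k_1 / \alpha$. Two wiring questions the
equations leave open are settled as package defaults (both are
config-switchable):

* the normalized response $c'$ replaces $c$ in **both** the weight update and
  the threshold update (`norm_drives_threshold = TRUE`) — normalization is
  treated as the neuron's effective response;
* the sigmoid is **not** re-applied after normalization.

When $\alpha$ dominates the pool, one NBCM step equals one BCM step with
responses scaled by $\beta/\alpha$; the test suite asserts this limit to
1e-6.

## Receptive-field reconstruction and tuning

Learned weights act on DoG-filtered stimuli. The equivalent *stimulus-domain*
receptive field is the convolution of the weight array with the DoG kernel,
computed in the Fourier domain: weights are embedded (centered) in a
$(4g)^2$ zero array, transformed, multiplied by the transfer function of the
same discrete kernel, inverse-transformed, cropped back to $g\times g$, and
standardized. Using the FFT of the zero-padded *discrete* kernel (not the
analytic Gaussian transform) makes reconstruction exactly consistent with
the spatial filtering: a field's dot product with a raw patch equals the
weight vector's dot product with the DoG-filtered patch, which the tests
verify against a brute-force shift-and-add convolution oracle.

Tuning is read from the DC-centered amplitude spectrum of the zero-padded
field. The preferred frequency/orientation is the single strongest
coefficient over the non-DC half-plane restricted to radial frequencies in
$(0, 0.5]$ cycles/pixel; exact ties break toward the lower radial frequency,
then the lower angle. **Orientation convention**: the reported angle is the
direction of the spatial-frequency (modulation) vector, in degrees in
$(-90^\circ, 90^\circ]$; $0^\circ$ means modulation along the horizontal
axis, i.e. a vertically striped grating. Spatial-frequency bandwidth is the
octave separation of the outermost half-maximum crossings along the radial
line through the peak; orientation bandwidth is the angular extent of
half-maximum along the ring through the peak. Both use linear interpolation
between grid samples (the source equations do not specify a path or an
interpolation; the radial-line/ring convention is a documented choice), and
both carry a `censored` attribute when the profile never falls below
half-maximum inside the grid.

## Coding metrics

For a field set $F$ (rows standardized, norm $\sqrt{g^2-1} \approx g$) and
responses $R = F P^{\mathsf T}$ to $N$ log-transformed (not DoG-filtered)
evaluation patches:

* **lifetime sparseness** $S = 1 - \mathrm{E}[r]^2/\mathrm{E}[r^2]$ per
  neuron across stimuli, averaged over neurons. Responses are rectified to
  magnitudes first: on signed, near-zero-mean responses the statistic
  degenerates toward 1 regardless of response shape, and the magnitudes of
  the paper-scale values (~0.6) are only attainable on nonnegative inputs;
* **population sparseness**: the same statistic across neurons per stimulus
  (identically, lifetime sparseness of the transposed matrix);
* **dispersal** $D = \sum_j \sigma_j / \max_j \sigma_j \in [1, J]$; the
  report prints $D/J$ (the paper-scale table values are below 1, implying
  the normalized form) and returns the raw value alongside;
* **orthogonality**: one minus the mean absolute cosine similarity over
  unordered field pairs;
* **rank**: the number of singular values of $F$ above the absolute cutoff
  2.5 (meaningful because rows have norm $\approx g$);
* **coverage**: every sinusoid of the complete $g^2$-member real Fourier
  basis (odd–even pair per conjugate frequency class, unit norm) is encoded
  as $r = Fx$ and decoded with the tolerance-truncated pseudo-inverse.
  The decode is the orthogonal projection onto the retained right singular
  subspace, so $m_i = \lVert x - \hat x\rVert^2 \in [0, 1]$ and
  $R = 1 - \mathrm{E}[m_i]$ is exactly 1 for a complete invertible code.
  Defining $m_i$ as the squared residual of the unit-norm sinusoid (rather
  than a per-pixel mean) is what makes that normalization exact.

Evaluation patches are log-transformed but *not* DoG-filtered because the
reconstructed fields already absorb the DoG.

# The synthetic stimulus world

The photographs behind the original study are not deposited, so the package
generates its own: random-phase images with radial amplitude
$\propto f^{\text{slope}}$ (default slope $-1$, the classical 1/f structure
of natural scenes) and a smooth $\cos^2(2\varphi)$-lobed orientation gain
that places extra energy on the cardinal axes (natural scenes carry more
vertical/horizontal than oblique energy). Images are built as log-luminance
fields (default standard deviation 0.5, a realistic log contrast),
exponentiated, and offset by a tiny positive floor, so the retinal log
transform is exercised nontrivially and recovers approximately Gaussian 1/f
images.

The orientation gain is calibrated by root-finding on the actual discrete
grid so that the cardinal-to-oblique band-energy ratio (22.5° bands) equals
the requested bias exactly *on the annulus* $f \in [0.02, 0.5]$ cycles/pixel.
Calibrating on the full grid would chase a discretization artifact: the
lowest-frequency bins sit exactly on the axes with $\sim 1/f^2$ energy, and
the corner region beyond the Nyquist radius contains only oblique
frequencies. Generator and measurement (`orientation_energy_ratio()`) share
the band. The $\cos^2$ gain family saturates near a ratio of ~6; requesting
more is an error.

What the generator deliberately does **not** emulate: phase structure.
Random-phase 1/f images contain no edges, occlusions or elongated contours,
and their patch statistics are Gaussian. Consequences observed in this
scaled world, which a green test therefore does and does not establish:

* BCM still converges to redundant, spectrally clustered solutions and NBCM
  still yields the better-dispersed, higher-rank code — the *contrasts* are
  reproduced;
* but the learned orientation preferences need not align with the cardinal
  axes the way they do on real photographs (on Gaussian inputs BCM's
  selectivity is not pinned by kurtosis the way it is on natural scenes); at
  grid 8 the trained solutions prefer obliques. The rotation control
  therefore tests that preferences *follow* the image statistics under
  rotation, not that they sit at any particular absolute angle.

# Scaled-world and numerical choices

* **Acceptance world**: 8×8 patches, 32–64 neurons, 6 synthetic images of
  192×192 per seed, 1.5–2×10^5 presentations — everything else (DoG sigmas,
  k1, k2, τ, η schedule, α=1/β=2, tolerance 2.5) at paper-scale values.
  Chosen once for the 1-CPU/25-min test budget.
* **Two-pattern fixed point**: the classical analytic check uses a single
  linear-output neuron (`linear_output = TRUE`, provided exactly for this)
  and orthonormal patterns with probabilities $(p, 1-p)$. At the selective
  equilibrium $c = \theta = 1/p_k$ on the selected pattern. Two harness
  details matter: pattern signs are flipped so initial projections are
  non-negative (sign is a convention; a neuron whose projections start
  negative decays toward zero and escapes only on an impractically slow
  quadratic timescale), and $\eta = 5\times10^{-5}$ respects the stability
  bound $\eta\,\tau\,(1/p)^2 \lesssim 1$ (at $\eta = 5\times10^{-3}$ the
  dynamics demonstrably diverge).
* **Threshold tracking**: a single end-point $\theta$ fluctuates a few
  percent around $\mathrm{E}[c^2]$ (it is an EWMA with window $\sim\tau$),
  so the 1% tracking claim is tested on the time-average of $\theta$ over
  the final $20\tau$ against the empirical mean of $c^2$ on the matching
  window.
* **Normalization regimes**: with paper-scale $k_1 = 25$ and dozens of
  saturated neurons, the activity pool $\sum c^2$ is of order $10^4$, so
  $\alpha$ and $\beta$ of order 1 put NBCM deep in the suppressing regime:
  the effective drive $\eta\,c'(c'-\theta)$ is orders of magnitude below the
  BCM drive and the weights barely leave their initialization within the
  training budget. This is a real property of the literal update equations
  at this scale, worth knowing when interpreting the BCM-vs-NBCM contrasts:
  NBCM's advantage partly reflects the preserved heterogeneity of its
  initialization. For the regime phenotypes: the suppressing regime
  ($\alpha = 10^5 \gg \beta = 10$) is run with the learning rate compensated
  by the squared normalization gain, $\eta = 10^{-5}/s^2$ with
  $s = \beta/(\alpha + \mathrm{pool}_0)$ — a pure change of timescale, since
  in this limit NBCM *is* BCM with outputs scaled by $s$ — and converges to
  non-oriented, lowest-frequency fields (the Hebbian principal component of
  the DoG-filtered 1/f patches). The amplifying regime is realized with
  $\beta = 2\,\mathrm{pool}_0$, $\alpha = \beta/100$ at the standard
  $\eta$: normalization then amplifies, single steps are large, the weights
  never settle, and the learned patterns are white-noise-like. "Flat
  spectra" is measured on the weight patterns (reconstructed fields always
  carry the DoG envelope, whose exact DC null makes a literally flat field
  spectrum unreachable), with the flatness threshold fixed a priori at
  median spectral-energy excess kurtosis < 8 — iid-noise energies are
  approximately exponential (excess kurtosis 6), while structured solutions
  measure above 20.
* **Rotation control**: because the bias is symmetric between the two
  cardinal axes, the doubled-angle circular mean of preferred orientations
  cancels; the rotation shift is measured with the fourfold (90°-periodic)
  circular resultant, whose largest representable shift is 45°.
* **Degenerate inputs**: zero-variance patches are resampled (more than
  1000 consecutive failures is an error); a zero-variance reconstructed
  field or an all-zero spectrum is an error naming the neuron; an all-zero
  response row yields `NA` sparseness, reported as missing rather than
  propagated.
* **Determinism**: every stochastic entry point takes a seed and restores
  the caller's RNG state; training is bit-reproducible, and a run resumed
  from a checkpoint replays the identical presentation schedule
  (regenerated from the seed and sliced), reproducing the uninterrupted run
  bit for bit.

# Known limitations

* The compiled training loop processes one presentation at a time (as the
  update equations are defined); there is no minibatching.
* P- and M-cell center-size diversity, film calibration, color, and the
  ICA/PCA comparators are out of scope.
* Bandwidth estimates on tiny grids (g = 8) are coarse: the spectrum of an
  8×8 field is intrinsically smooth at scale 1/8 cycles/pixel, so
  orientation bandwidths below ~20° are not resolvable there.
* The NBCM-stays-near-initialization effect described above means
  paper-scale sparseness/dispersal *values* should not be expected from the
  scaled world; only the BCM-vs-NBCM directions are meaningful at this
  scale.
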