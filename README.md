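# nbcm

Simulation and analysis of V1 simple-cell receptive-field development under
the **BCM** (Bienenstock–Cooper–Munro) synaptic plasticity rule and its
contrast-normalized variant, **NBCM**, in which divisive normalization
couples an otherwise independent population of model cortical neurons.

## Who this is for

Computational neuroscientists studying unsupervised receptive-field
development and population coding: the package provides the full pipeline —
retinal preprocessing, Hebbian learning with a sliding modification
threshold, Fourier-domain receptive-field reconstruction and tuning
measurement, and a suite of population-coding quality metrics — needed to
ask whether a neurally plausible lateral interaction (contrast
normalization) turns a redundant Hebbian code into a sparse, dispersed,
heterogeneous one.

## The model

Images are log-transformed, convolved with a zero-DC difference-of-Gaussians
filter (σ_center = 0.75 px, σ_surround = 2.25 px) modelling retinal ganglion
cells, and cut into standardized patches *d*. Each of *J* neurons responds

    c_j = s( Σ_i m_ij d_i ),   s(r) = k1·tanh(r) for r > 0, k2·tanh(r) for r < 0

with k1 = 25, k2 = 1, and learns by the BCM rule with a sliding threshold:

    δm_ij = η c_j (c_j − θ_j) d_i        (Hebbian above θ, anti-Hebbian below)
    δθ_j  = (c_j² − θ_j) / τ             (θ tracks E[c²], τ = 1000)

with η = 1e-5 annealed by 0.1% per 1000 presentations. In NBCM mode the
response is first divisively normalized by the pooled squared population
activity,

    c'_j = β c_j / (α + Σ_i c_i²),

and c′ drives both updates. Learned weights are mapped back to
stimulus-domain receptive fields by convolution with the same DoG (computed
spectrally), and the resulting population code is scored by lifetime and
population sparseness (S = 1 − E[r]²/E[r²]), dispersal (Σ σ_j / max σ_j),
pairwise orthogonality, numerical rank at tolerance 2.5, and spectral
coverage R = 1 − E[m_i] from encoding/decoding a complete 2-D sinusoid
basis through the field matrix and its tolerance-truncated pseudo-inverse.

Because the photographs behind the original study are not deposited, the
package ships a synthetic-image module: random-phase 1/f images with a
calibrated excess of cardinal (vertical + horizontal) orientation energy,
plus rotated-ensemble controls, two-pattern analytic environments, and Gabor
fixtures with known ground-truth tuning.

## Worked example

Train matched BCM and NBCM populations on the same synthetic world and
compare their codes:

```r
library(nbcm)

spec <- synthetic_image_spec(n_images = 6, size = 192, orientation_bias = 2,
                             seed = 1)
images <- pink_noise_ensemble(spec)
patches <- retina_pipeline(images, grid_size = 8, n_patches = 10000, seed = 101)

reports <- list()
for (mode in c("bcm", "nbcm")) {
  cfg <- learning_config(n_neurons = 64, n_iterations = 2e5, mode = mode,
                         seed = 1)
  state <- train_network(patches, cfg, norm = norm_params(alpha = 1, beta = 2))
  fields <- reconstruct_fields(state, dog_params())
  eval_patches <- extract_patches(log_transform(images), grid_size = 8,
                                  n_patches = 1000, seed = 201)
  reports[[mode]] <- coding_report(fields, eval_patches)
}
print(reports$bcm)
print(reports$nbcm)
```

Output (exact, given the seeds above):

```
-- BCM --
Coding properties (64 fields, 1000 evaluation stimuli)
  mean reconstruction error     0.5469
  coverage R                    0.4531
  orthogonality                 0.8174
  rank                         29.0000
  lifetime sparseness           0.3664
  population sparseness         0.3454
  dispersal (/J)                0.6487
  dispersal (raw)              41.5141

-- NBCM (alpha = 1, beta = 2) --
Coding properties (64 fields, 1000 evaluation stimuli)
  mean reconstruction error     0.4062
  coverage R                    0.5938
  orthogonality                 0.8433
  rank                         38.0000
  lifetime sparseness           0.3395
  population sparseness         0.3400
  dispersal (/J)                0.7695
  dispersal (raw)              49.2479
```

Reading the numbers: the NBCM population decodes the complete sinusoid basis
with lower mean error (0.41 vs 0.55), is less internally redundant (higher
orthogonality), spans more of stimulus space (rank 38 vs 29 of a possible
64), and spreads response variance more evenly across neurons — the
qualitative signature of contrast normalization improving the population
code. Per-field tuning (preferred spatial frequency and orientation, octave
and angular bandwidths) comes from `tuning_table(fields)`.

An end-to-end command-line front end mirrors this flow
(`generate`, `train`, `analyze`, `compare`):

```sh
Rscript inst/cli/nbcm-cli.R train --out runs/bcm  --mode bcm  --seed 1 \
    --grid 8 --neurons 64 --iterations 200000
Rscript inst/cli/nbcm-cli.R train --out runs/nbcm --mode nbcm --seed 1 \
    --grid 8 --neurons 64 --iterations 200000
Rscript inst/cli/nbcm-cli.R analyze --state runs/bcm
Rscript inst/cli/nbcm-cli.R analyze --state runs/nbcm
Rscript inst/cli/nbcm-cli.R compare --a runs/bcm --b runs/nbcm
```

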