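# shapeprior

Shape-prior segmentation for the data-scarce regime: a toolkit that
supervises a U-Net not only with per-pixel classification but with the
**level-set representation** of the ground truth — its signed-distance
field and the curvature of the sharpened level set — so that the learned
features encode object geometry rather than raw intensity.

Who this is for: researchers in biological / medical image analysis who
want to train small 2D segmentation models on few annotated images, study
shape-prior losses, or reproduce the out-of-distribution circle benchmark
that isolates the effect of level-set supervision.

## The objective

Ground-truth masks $y_j$ are converted per class into signed Euclidean
distance fields $\phi_j$ (negative inside, zero on the 4-connected
boundary pixels, positive outside, clipped at the image diagonal). The
network carries two heads — softmax probabilities $p_j$ and a level-set
regression $\phi'_j$ — trained with

$$L = \lambda_1\,(L_{DICE} + L_{CE}) \;+\; \lambda_2\,\mathrm{mean}(\phi-\phi')^2
      \;+\; \lambda_3\,\mathrm{mean}\,\lvert K_{\hat\phi} - K_{\hat\phi'}\rvert ,$$

with $(\lambda_1,\lambda_2,\lambda_3) = (1, 0.1, 10^{-4})$. Here
$\hat\phi = \mathrm{sigmoid}(-1000\,\phi)$ sharpens the level set and $K$
is a mean-curvature expression of the sharpened field computed with
central differences:

$$K = \frac{(1+\hat\phi_a^2)\hat\phi_{bb} + (1+\hat\phi_b^2)\hat\phi_{aa}
- 2\hat\phi_a\hat\phi_b\hat\phi_{ab}}{2(1+\hat\phi_a^2+\hat\phi_b^2)^{1.5}+\varepsilon}.$$

A frozen auxiliary encoder (any provider honoring the 64×64 embedding
contract; a seeded synthetic mock ships with the package) can be fused
into the deepest decoder input by concatenation, addition, multiplication
or an attention gate. Evaluation uses the DICE coefficient (%) and the
average symmetric surface distance (ASD).

See the methods vignette (`vignettes/levelset-shape-priors.Rmd`) for the
full model description, parameter meanings and design notes.

## Worked example

```r
library(shapeprior)

# a label mask and its level-set representation
m <- matrix(0L, 8, 8); m[3:5, 3:6] <- 1L
phi <- labels_to_levelset(label_mask(m, num_classes = 2))
round(phi[3:5, 2:7, 2], 2)   # foreground channel: 0 on the boundary ring
#>      [,1] [,2] [,3] [,4] [,5] [,6]
#> [1,]    1    0    0    0    0    1
#> [2,]    1    0   -1   -1    0    1
#> [3,]    1    0    0    0    0    1

# the loss components for a perfect and an imperfect prediction
y <- array(0, c(8, 8, 2)); y[,,1] <- (m == 0); y[,,2] <- (m == 1)
total_loss(y, y, phi, phi)
#> loss: total 0 (seg 0 = dice 0 + ce 0, mse 0, curvature 0)

# the out-of-distribution circle study (train bright, test dim)
res <- run_ood_circle_experiment(seed = 1)
print(res)
#>                arm dice_mean   dice_sd  asd_mean     asd_sd   n
#>     with_curvature  99.11987 0.6312959 0.4187407 0.34534499 100
#>  without_curvature  99.42903 0.3665352 0.1694611 0.03958381 100
```

The experiment trains two identical U-Nets on brightness-1.0 circles —
one with the level-set + curvature supervision, one plain DICE+CE — and
evaluates both on half-brightness circles, printing a two-row table of
DICE and ASD (mean ± SD over the test set). In the run above the
supervised model holds 99.1% DICE and sub-pixel surface distance under
the halved test brightness. At this desk scale the plain baseline is
robust to the shift as well; the benchmark's value here is the
controlled setting itself (identical data, architecture and optimizer,
differing only in the level-set supervision). The run writes the same
table, the per-step loss curves and the resolved configs when `out_dir`
is given. A thin command-line interface wraps the same functions
(`inst/cli/shapeprior`: `synth-circles`, `train`, `eval`, `ood-circles`).

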