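# mfcnsr — multi-scale fusion CNNs for MR image super-resolution

`mfcnsr` is an R package for single-image super-resolution of structural
brain MR volumes with small multi-scale fusion convolutional networks
(MFCNs), built for researchers who want a fully inspectable, CPU-only,
dependency-light replication of the method — degradation model, network,
training loop, metrics and ablations — rather than a deep-learning
framework wrapper.

## The model

A low-resolution image is modelled as `L = D S H + e` (blur `S`,
decimation `D` by factor `f ∈ {2,3,4}`, noise `e`). Under the
pre-upsampling convention `L` is bicubically interpolated back to the
high-resolution grid, and a network learns the residual mapping from
aligned 33×33 patch pairs. The network stacks *multi-scale fusion units*

    x_{i+1} = ReLU(conv_main(x_i)) + Σ_j SP_j(x_i)

— a main convolution path (large kernels) fused by elementwise addition
with 1×1-convolution sub-paths (no ReLU before the addition) — followed by
a single-kernel reconstruction layer. The baseline (9/32 + 1/32,
3/64 + 1/64, recon 5/1; 24,897 parameters) and the published ablation
grammar are built in. Training is Euclidean-loss (`sum/(2B)`) SGD with
momentum; quality is measured by mask-restricted RMSE, SNR, PSNR
(`20·log10(255/RMSE)`) and windowed SSIM.

Everything runs on synthetic multi-tissue brain phantoms generated by the
package, so no data download is needed; the BrainWeb benchmark harness
(`brainweb_benchmark()`) accepts the real phantom if you fetch it.

## Worked example

```r
library(mfcnsr)

# 1. a cohort of labelled brain phantoms (three train, one held out)
cohort <- make_cohort(4, phantom_spec(), seed = 1)

# 2. degrade at f = 2 and extract aligned patch pairs
dspec <- degrade_spec(2)
sets <- lapply(cohort[1:3], function(v) {
  pairs <- degrade_volume(v, dspec)
  extract_patch_pairs(pairs[[ceiling(length(pairs) / 2)]], 600, seed = 1)
})
data <- patchset_bind(sets)
val_pairs <- degrade_volume(cohort[[4]], dspec)
val <- val_pairs[ceiling(length(val_pairs) / 2)]

# 3. train a reduced MFCN (9/8+1/8; 3/16+1/16; 5/1) at the stable rate
net <- build_network(reduced_baseline_spec(), seed = 7)
fit <- train(net, data, val,
             train_spec(lr = 1e-4, iterations = 1000, val_interval = 250))

# 4. compare against the bicubic baseline on the held-out slice
rec <- evaluate_methods(
  val[[1]]$hr,
  list(bicubic = val[[1]]$lr,
       mfcn = pmin(pmax(mfcn_forward(fit$params, val[[1]]$lr), 0), 1)),
  mask = val[[1]]$mask, scale_factor = 2
)
print(rec)
```

Output from this exact script (seeded, so reproducible):

```
<metrics_report> mask-weighted means:
  method scale n_slices  rmse   snr  psnr   ssim
 bicubic     2        1 14.94 17.82 24.64 0.8505
    mfcn     2        1 14.41 18.14 24.96 0.8570
```

The trained network beats bicubic interpolation by ~0.3 dB PSNR on the
held-out phantom after only 1000 iterations and 3 training subjects (the
longer paired runs in the test suite reach ~+0.5 dB): RMSE and PSNR are
on the 0–255 scale over the brain mask, and SSIM uses the standard 11×11
gaussian window. The ablation harness (`builtin_variants()`, `run_sweep()`,
`compare_convergence()`) reproduces the qualitative architecture
findings, including that the MFCN converges no slower than its plain
stacked-CNN counterpart under paired seeds.

A subcommand CLI covers the same pipeline end to end:

```sh
Rscript inst/cli/mfcnsr phantom --n 4 --out work/phantoms --seed 1
Rscript inst/cli/mfcnsr train --scale 2 --budget 1000 --out work/run --seed 1
Rscript inst/cli/mfcnsr ablate --scale 2 --budget 400 --out work/ablation
```

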