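# petrestore

Simulation, OSEM reconstruction and deep-learning restoration of PET lung
tumours, with a complete quantitative evaluation suite.

## The problem

PET quantification of lung tumours — typically via the standardised uptake
value, SUV = C / (D / W) with tissue concentration C (kBq/ml), injected dose
D (MBq) and body weight W (kg) — is biased by the partial volume effect and
destabilised by Poisson noise. Resolution (PSF) modelling inside OSEM
reconstruction sharpens small lesions but adds Gibbs-like edge overshoot
that inflates SUV_max: recovery coefficients RC = measured / true activity
exceed 1 at tumour edges while the median is under-recovered.

`petrestore` is for researchers studying these effects with fully synthetic
ground truth. It generates torso phantoms containing tumours with three
uptake patterns (uniform, split halves, hollow/necrotic), simulates analytic
PET raw data (attenuated parallel-beam projections, anisotropic Gaussian PSF,
scatter/randoms background, Poisson noise), reconstructs with PSF-modelled
OSEM (6 iterations x 21 subsets, no post-filter), and trains a 7-layer 3D CNN
(32 filters of 3x3x3, batch norm, dropout 0.3, Adam at 0.001, MSE) to map
reconstructed crops back to their ground-truth activity. Evaluation covers
RC_max / RC_median / RC_peak (1 cm^3 spherical VOI), 3D MSSIM over 7x7x7
windows, sphericity (36 pi V^2)^(1/3) / A, half-ratio analysis and
volume-binned cohort tables.

## Worked example

A reduced single-CPU run of the full pipeline (desk preset: 64x64x32 grid at
[2.09, 2.09, 2.03] mm, 45 tumours, 3M prompts, 20^3 crops, 24 epochs):

```r
library(petrestore)

cfg  <- experiment_config(1, "desk", seed = 7)
res  <- run_experiment(cfg)          # simulate, reconstruct, train, evaluate
rep  <- res$report                   # one row per held-out tumour
big  <- rep[rep$volume_ml >= 5, ]

mean(big$rc_max_recon)               # 2.25  <- PSF-OSEM Gibbs overshoot
mean(big$rc_max)                     # 1.29  <- CNN restoration, closer to 1
mean(big$rc_median_recon)            # 0.80
mean(big$rc_median)                  # 0.84
mean(rep$mssim_recon)                # 0.67
mean(rep$mssim)                      # 0.68
```

The run takes about ten minutes on one CPU.

On the held-out tumours larger than 5 ml the reconstruction's maximum
activity overshoots the truth (RC_max far above 1, the hallmark of
unfiltered PSF modelling), while the network's predictions bring RC_max much
closer to 1 and raise the structural similarity to the ground truth. The
trained model transfers without retraining to data simulated with PSFs drawn
from N(4.5, 0.2) mm (`experiment_config(2, ...)`) and with half / double
count levels (`experiment_config(3, ...)`).

Individual stages are available as plain functions — `make_torso_phantom()`,
`make_tumour()`, `assemble_ground_truth()`, `forward_project()`,
`poisson_sample()`, `osem_reconstruct()`, `train_cnn()`, `restore_crop()`,
`rc_metrics()`, `mssim()`, `sphericity()` — with NIfTI I/O
(`write_volume()` / `read_volume()`) for exchanging volumes. A thin CLI over
the same functions lives at `inst/cli/petrestore.R`.

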