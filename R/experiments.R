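#' Experiment configuration
#'
#' Bundles every knob of the simulate/reconstruct/train/evaluate pipeline.
#' Two presets: `"paper"` mirrors the full-scale study protocol (344 x 344 x
#' 127 grid, 2110 cases, 100M prompts, 500 epochs) and is intended for
#' cluster hardware; `"desk"` is a reduced protocol with the same structure
#' that runs on a single CPU (64 x 64 x 32 grid, tens of cases, millions of
#' counts, short training).
#'
#' @param experiment 1 (train/test, fixed PSF), 2 (apply the experiment-1
#'   model to PSFs drawn from N(4.5, 0.2) mm), or 3 (apply it to hollow >5 ml
#'   tumours simulated at half and double the prompt count).
#' @param preset `"desk"` or `"paper"`.
#' @param seed master seed; every stochastic stage derives its own seed from
#'   it.
#' @param ... named overrides of any preset field.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(experiment = 1L, preset = c("desk", "paper"),
                              seed = 1L, ...) {
  preset <- match.arg(preset)
  base <- if (preset == "desk") {
    list(grid_dim = c(64L, 64L, 32L), voxel_size = c(2.09, 2.09, 2.03),
         crop = 18L, n_angles = 84L,
         n_per_class = c(uniform = 40L, halves = 40L, hollow = 40L),
         total_prompts = 3e6, trues_fraction = 0.352,
         psf = psf_spec(4.5), psf_mode = "fixed",
         recon = recon_config(n_iterations = 6L, n_subsets = 21L, psf = psf_spec(4.5)),
         epochs = 16L, batch_size = 5L, learning_rate = 0.001,
         volume_range = c(0.5, 8), frac_large = 0.5, large_range = c(5, 8),
         activity_range = c(6, 35), halves_ratio_range = c(1.2, 3),
         elongation_range = c(0, 0.35),
         test_fraction = 0.2, val_fraction = 0.2, n_augment = 12L,
         augment_factors = c(0.5, 0.8),
         prompt_multipliers = c(0.5, 2), n_exp3 = 10L)
  } else {
    list(grid_dim = c(344L, 344L, 127L), voxel_size = c(2.09, 2.09, 2.03),
         crop = 50L, n_angles = 168L,
         n_per_class = c(uniform = 800L, halves = 721L, hollow = 589L),
         total_prompts = 1e8, trues_fraction = 0.352,
         psf = psf_spec(4.5), psf_mode = "fixed",
         recon = recon_config(n_iterations = 6L, n_subsets = 21L, psf = psf_spec(4.5)),
         epochs = 500L, batch_size = 50L, learning_rate = 0.001,
         volume_range = c(0.01, 200), frac_large = 0.35, large_range = c(5, 200),
         activity_range = c(6, 35), halves_ratio_range = c(1.2, 3),
         elongation_range = c(0, 0.6),
         test_fraction = 0.2, val_fraction = 0.2, n_augment = 247L,
         augment_factors = c(0.5, 0.8),
         prompt_multipliers = c(0.5, 2), n_exp3 = 10L)
  }
  over <- list(...)
  base[names(over)] <- over
  cfg <- c(list(experiment = as.integer(experiment), preset = preset,
                seed = as.integer(seed)), base)
  if (!cfg$experiment %in% 1:3) stop("experiment must be 1, 2 or 3")
  if (any(cfg$n_per_class < 0) || sum(cfg$n_per_class) < 1)
    stop("invalid dataset composition")
  if (cfg$n_angles %% cfg$recon$n_subsets != 0)
    stop("angle count must be divisible by the subset count")
  structure(cfg, class = "experiment_config")
}

#' Dataset composition bookkeeping
#'
#' @param cfg an [experiment_config()].
#' @return list: per-class counts, `total`, `n_test` (after the train/test
#'   split) and `n_train`.
#' @export
experiment_composition <- function(cfg) {
  total <- sum(cfg$n_per_class)
  n_test <- round(cfg$test_fraction * total)
  list(n_per_class = cfg$n_per_class, total = total,
       n_test = n_test, n_train = total - n_test)
}

## draw the per-case tumour parameters (deterministic given cfg$seed)
draw_case_specs <- function(cfg, patterns = NULL, volume_range = NULL) {
  if (is.null(patterns))
    patterns <- rep(names(cfg$n_per_class), cfg$n_per_class)
  n <- length(patterns)
  with_seed(derive_seed(cfg$seed, 1L), {
    vols <- numeric(n)
    for (i in seq_len(n)) {
      vols[i] <- if (!is.null(volume_range)) {
        runif(1, volume_range[1], volume_range[2])
      } else if (runif(1) < cfg$frac_large) {
        runif(1, cfg$large_range[1], cfg$large_range[2])
      } else {
        exp(runif(1, log(cfg$volume_range[1]), log(min(cfg$large_range[1],
                                                       cfg$volume_range[2]))))
      }
    }
    acts <- runif(n, cfg$activity_range[1], cfg$activity_range[2])
    ratios <- runif(n, cfg$halves_ratio_range[1], cfg$halves_ratio_range[2])
    elong <- runif(n, cfg$elongation_range[1], cfg$elongation_range[2])
    lapply(seq_len(n), function(i)
      tumour_spec(pattern = patterns[i], target_volume_ml = vols[i],
                  primary_activity = acts[i],
                  secondary_activity = if (patterns[i] == "halves")
                    acts[i] / ratios[i] else NULL,
                  elongation = elong[i],
                  seed = derive_seed(cfg$seed, 100L + i)))
  })
}

#' Simulate one complete case
#'
#' Ground-truth assembly, PSF blurring, attenuated forward projection,
#' count scaling with scatter/randoms background, Poisson sampling, OSEM
#' reconstruction with image-based PSF modelling, and cropping of the
#' ground-truth / reconstructed pair around the tumour.
#'
#' @param torso from [make_torso_phantom()].
#' @param geom a [sinogram_geometry()].
#' @param cfg an [experiment_config()].
#' @param spec the case's [tumour_spec()].
#' @param case_seed per-case seed (placement + noise).
#' @param psf simulation/reconstruction PSF (matched).
#' @param total_prompts prompt count for this case.
#' @return list of class `sim_case`: `gt_crop`, `recon_crop`, `mask_crop`,
#'   `region_crops`, `record`, `psf`, `total_prompts`, `background`,
#'   `volume_ml`, `pattern`.
#' @export
simulate_case <- function(torso, geom, cfg, spec, case_seed, psf = cfg$psf,
                          total_prompts = cfg$total_prompts) {
  tum <- make_tumour(spec, cfg$voxel_size)
  gt <- assemble_ground_truth(torso, tum, placement_seed = derive_seed(case_seed, 1L))
  blurred <- apply_image_psf(gt$activity, psf, cfg$voxel_size)
  trues <- forward_project(blurred, gt$attenuation, geom)
  acq <- acquisition_spec(total_prompts = total_prompts,
                          trues_fraction = cfg$trues_fraction, psf = psf)
  sc <- scale_and_contaminate(trues, acq)
  prompts <- poisson_sample(sc$expected, seed = derive_seed(case_seed, 2L))
  rcfg <- cfg$recon; rcfg$psf <- psf
  recon <- osem_reconstruct(prompts, mu = gt$attenuation, background = sc$background,
                            cfg = rcfg, geom = geom, calibration = sc$trues_scale)
  rec <- gt$record
  gt_crop <- crop_around_tumour(gt$activity, rec, cfg$crop)
  recon_crop <- crop_around_tumour(recon, rec, cfg$crop)
  mask_crop <- crop_around_tumour(rec$mask + 0, rec, cfg$crop) >= 0.5
  region_crops <- lapply(rec$region_masks, function(m)
    crop_around_tumour(m + 0, rec, cfg$crop) >= 0.5)
  structure(list(gt_crop = gt_crop, recon_crop = recon_crop,
                 mask_crop = mask_crop, region_crops = region_crops,
                 pattern = rec$pattern, volume_ml = rec$volume_ml,
                 sphericity = rec$sphericity, background = rec$background,
                 centroid = rec$centroid, psf = psf,
                 total_prompts = total_prompts, case_seed = case_seed),
            class = "sim_case")
}

#' Build a simulated dataset
#'
#' @param cfg an [experiment_config()].
#' @param patterns optional explicit pattern vector (defaults to the
#'   configured composition).
#' @param volume_range optional explicit volume sampling range.
#' @param prompts optional per-dataset prompt count override.
#' @param progress print progress.
#' @return list: `cases` (list of `sim_case`) and `manifest` (data.frame).
#' @export
build_dataset <- function(cfg, patterns = NULL, volume_range = NULL,
                          prompts = NULL, progress = FALSE) {
  torso <- make_torso_phantom(cfg$grid_dim, cfg$voxel_size)
  geom <- sinogram_geometry(cfg$grid_dim, cfg$voxel_size, cfg$n_angles)
  specs <- draw_case_specs(cfg, patterns, volume_range)
  psfs <- if (identical(cfg$psf_mode, "sampled")) {
    with_seed(derive_seed(cfg$seed, 2L),
              lapply(seq_along(specs), function(i) sample_psf_dataset2()))
  } else {
    rep(list(cfg$psf), length(specs))
  }
  cases <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    cases[[i]] <- simulate_case(torso, geom, cfg, specs[[i]],
                                case_seed = derive_seed(cfg$seed, 500L + i),
                                psf = psfs[[i]],
                                total_prompts = if (is.null(prompts))
                                  cfg$total_prompts else prompts)
    if (progress) message(sprintf("case %d/%d (%s, %.2f ml)", i, length(specs),
                                  cases[[i]]$pattern, cases[[i]]$volume_ml))
  }
  manifest <- do.call(rbind, lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    data.frame(id = i, pattern = cs$pattern, volume_ml = cs$volume_ml,
               sphericity = cs$sphericity, background = cs$background,
               fwhm_transaxial = cs$psf$fwhm_transaxial,
               fwhm_axial = cs$psf$fwhm_axial,
               total_prompts = cs$total_prompts, case_seed = cs$case_seed)
  }))
  list(cases = cases, manifest = manifest)
}

## per-case normalisation of the reconstructed crop; the ground-truth target
## shares the input's record so one inverse transform restores both scales
prepare_pair <- function(case) {
  nm <- minmax_normalize(case$recon_crop)
  list(x = nm$values,
       y = (case$gt_crop - nm$record$min) / (nm$record$max - nm$record$min),
       record = nm$record)
}

#' Normalise a list of cases into training pairs
#' @param cases list of `sim_case`.
#' @return list with `x`, `y` (lists of normalised crops) and `records`.
#' @export
prepare_training_pairs <- function(cases) {
  pairs <- lapply(cases, prepare_pair)
  list(x = lapply(pairs, `[[`, "x"), y = lapply(pairs, `[[`, "y"),
       records = lapply(pairs, `[[`, "record"))
}

#' Evaluate reconstructed and restored crops against the ground truth
#'
#' For every case the reconstructed crop is normalised, pushed through the
#' network, rescaled with its stored normalisation record, and both the
#' reconstruction and the prediction are scored inside the ground-truth
#' mask: RC max/median/peak, MSSIM, detectability, and the half-ratio for
#' split tumours.
#'
#' @param cases list of `sim_case`.
#' @param model trained `pet_cnn`.
#' @param voxel_size voxel edges in mm.
#' @return `MetricsReport` data.frame, one row per case.
#' @export
evaluate_cases <- function(cases, model, voxel_size) {
  rows <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    pred <- restore_crop(model, cs$recon_crop)
    rc_r <- rc_metrics(cs$recon_crop, cs$gt_crop, cs$mask_crop, voxel_size,
                       pattern = cs$pattern)
    rc_p <- rc_metrics(pred, cs$gt_crop, cs$mask_crop, voxel_size,
                       pattern = cs$pattern)
    ms_r <- mssim(cs$recon_crop, cs$gt_crop)
    ms_p <- mssim(pred, cs$gt_crop)
    hr <- if (cs$pattern == "halves")
      halves_ratio_analysis(pred, cs$gt_crop, cs$region_crops) else NULL
    data.frame(id = i, pattern = cs$pattern, volume_ml = cs$volume_ml,
               sphericity = cs$sphericity,
               rc_max = rc_p$rc_max, rc_median = rc_p$rc_median,
               rc_peak = rc_p$rc_peak,
               rc_max_recon = rc_r$rc_max, rc_median_recon = rc_r$rc_median,
               rc_peak_recon = rc_r$rc_peak,
               mssim = as.numeric(ms_p), mssim_recon = as.numeric(ms_r),
               detected = detect_tumour(pred, cs$mask_crop, cs$background),
               half_ratio_true = if (is.null(hr)) NA_real_ else hr$true_ratio,
               half_ratio_pred = if (is.null(hr)) NA_real_ else hr$predicted_ratio)
  })
  do.call(rbind, rows)
}

#' Run a full experiment
#'
#' Experiment 1 simulates the configured dataset with a fixed PSF, splits it
#' 80/20 into training and test cases (20% of the training cases held out
#' for validation), optionally augments the training set by shrinking larger
#' tumours, trains the restoration network and evaluates the held-out cases.
#' Experiments 2 and 3 never retrain: they apply a previously trained model
#' to data simulated with sampled PSFs (2) or with half/double prompt counts
#' on hollow >5 ml tumours (3).
#'
#' @param cfg an [experiment_config()].
#' @param model trained `pet_cnn` (required for experiments 2 and 3).
#' @param progress print progress.
#' @return list: `report` (MetricsReport), `summary` (binned RCs for
#'   prediction and reconstruction), `manifest`, plus for experiment 1
#'   `model`, `history` and `split`; experiment 3 returns one entry per
#'   prompt level.
#' @export
run_experiment <- function(cfg, model = NULL, progress = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (cfg$experiment == 1L) {
    ds <- build_dataset(cfg, progress = progress)
    n <- length(ds$cases)
    comp <- experiment_composition(cfg)
    idx <- with_seed(derive_seed(cfg$seed, 3L), sample.int(n))
    test_idx <- sort(idx[seq_len(comp$n_test)])
    train_idx <- sort(idx[-seq_len(comp$n_test)])
    n_val <- max(1L, round(cfg$val_fraction * length(train_idx)))
    val_idx <- train_idx[seq_len(n_val)]
    fit_idx <- setdiff(train_idx, val_idx)
    train_cases <- augment_by_scaling(ds$cases[fit_idx], cfg$n_augment,
                                      cfg$augment_factors,
                                      seed = derive_seed(cfg$seed, 4L))
    tr <- prepare_training_pairs(train_cases)
    va <- prepare_training_pairs(ds$cases[val_idx])
    model <- build_model(model_spec(), seed = derive_seed(cfg$seed, 5L))
    model <- train_cnn(model, tr$x, tr$y,
                       train_config(epochs = cfg$epochs, batch_size = cfg$batch_size,
                                    learning_rate = cfg$learning_rate,
                                    seed = derive_seed(cfg$seed, 6L)),
                       x_val = va$x, y_val = va$y, verbose = progress)
    report <- evaluate_cases(ds$cases[test_idx], model, cfg$voxel_size)
    list(model = model, history = model$history, report = report,
         summary = list(prediction = binned_rc_summary(report),
                        reconstruction = binned_rc_summary(
                          rename_recon_cols(report))),
         manifest = ds$manifest,
         split = list(train = fit_idx, val = val_idx, test = test_idx))
  } else if (cfg$experiment == 2L) {
    if (is.null(model)) stop("experiment 2 applies the model trained in experiment 1; pass it via `model`")
    cfg$psf_mode <- "sampled"
    ds <- build_dataset(cfg, progress = progress)
    report <- evaluate_cases(ds$cases, model, cfg$voxel_size)
    list(report = report,
         summary = list(prediction = binned_rc_summary(report),
                        reconstruction = binned_rc_summary(rename_recon_cols(report))),
         manifest = ds$manifest)
  } else {
    if (is.null(model)) stop("experiment 3 applies the model trained in experiment 1; pass it via `model`")
    patterns <- rep("hollow", cfg$n_exp3)
    out <- lapply(cfg$prompt_multipliers, function(mult) {
      ds <- build_dataset(cfg, patterns = patterns,
                          volume_range = cfg$large_range,
                          prompts = mult * cfg$total_prompts,
                          progress = progress)
      report <- evaluate_cases(ds$cases, model, cfg$voxel_size)
      list(prompt_multiplier = mult, report = report,
           summary = list(prediction = binned_rc_summary(report),
                          reconstruction = binned_rc_summary(rename_recon_cols(report))),
           manifest = ds$manifest)
    })
    names(out) <- paste0("x", cfg$prompt_multipliers)
    out
  }
}

## view the reconstruction columns of a MetricsReport under the RC names
rename_recon_cols <- function(report) {
  data.frame(volume_ml = report$volume_ml, rc_max = report$rc_max_recon,
             rc_median = report$rc_median_recon, rc_peak = report$rc_peak_recon)
}
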