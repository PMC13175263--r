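#' 3D CNN architecture specification
#'
#' Seven same-padded 3x3x3 convolutional layers: six hidden layers with 32
#' filters, ReLU activations and batch normalisation, dropout (rate 0.3)
#' after the first two batch-norm layers, and a final single-filter layer
#' with linear activation and no normalisation. Input and output share the
#' same single-channel spatial shape.
#'
#' @param n_layers number of convolutional layers.
#' @param filters filters per hidden layer.
#' @param dropout_rate dropout probability.
#' @param dropout_layers 1-based hidden layers followed by dropout.
#' @param bn_eps batch-norm stability epsilon.
#' @param bn_momentum running-statistics momentum (running = momentum *
#'   running + (1 - momentum) * batch).
#' @export
model_spec <- function(n_layers = 7L, filters = 32L, dropout_rate = 0.3,
                       dropout_layers = c(1L, 2L), bn_eps = 1e-3,
                       bn_momentum = 0.9) {
  stopifnot(n_layers >= 2, filters >= 1, dropout_rate >= 0, dropout_rate < 1)
  structure(list(n_layers = as.integer(n_layers), filters = as.integer(filters),
                 kernel = 3L, dropout_rate = dropout_rate,
                 dropout_layers = as.integer(dropout_layers),
                 bn_eps = bn_eps, bn_momentum = bn_momentum),
            class = "model_spec")
}

#' Build an untrained restoration network
#'
#' He-normal weight initialisation; unit batch-norm scale, zero shift.
#'
#' @param spec a [model_spec()].
#' @param seed RNG seed for the weight draw.
#' @return object of class `pet_cnn`: `spec` plus a `params` list (per layer
#'   `W`, `b`, and for hidden layers `gamma`, `beta`, `run_mean`, `run_var`).
#' @export
build_model <- function(spec = model_spec(), seed = 1L) {
  L <- spec$n_layers
  params <- with_seed(seed, lapply(seq_len(L), function(l) {
    cin <- if (l == 1) 1L else spec$filters
    cout <- if (l == L) 1L else spec$filters
    fan_in <- cin * 27
    p <- list(W = matrix(rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout),
              b = numeric(cout))
    if (l < L) {
      p$gamma <- rep(1, cout); p$beta <- numeric(cout)
      p$run_mean <- numeric(cout); p$run_var <- rep(1, cout)
    }
    p
  }))
  structure(list(spec = spec, params = params), class = "pet_cnn")
}

#' Per-layer trainable convolution weight counts
#'
#' Weights + biases of each convolution (batch-norm parameters excluded).
#' @param model a `pet_cnn`.
#' @export
count_conv_params <- function(model) {
  vapply(model$params, function(p) length(p$W) + length(p$b), numeric(1))
}

#' Min-max normalisation to \[0, 1\] with an invertible record
#'
#' @param volume numeric array with `max > min`.
#' @return list: `values` scaled to \[0, 1\] and `record` (class
#'   `normalization_record` holding `min` and `max`).
#' @export
minmax_normalize <- function(volume) {
  lo <- min(volume); hi <- max(volume)
  if (!(hi > lo)) stop("constant volume: min-max scaling is undefined")
  list(values = (volume - lo) / (hi - lo),
       record = structure(list(min = lo, max = hi), class = "normalization_record"))
}

#' Invert a min-max normalisation
#' @param volume scaled array.
#' @param record the `normalization_record` from [minmax_normalize()].
#' @export
minmax_denormalize <- function(volume, record) {
  if (!inherits(record, "normalization_record"))
    stop("record must be a normalization_record")
  volume * (record$max - record$min) + record$min
}

#' Training configuration
#'
#' @param epochs training epochs.
#' @param batch_size cases per Adam step.
#' @param learning_rate Adam step size (default 0.001).
#' @param seed seed governing shuffling, dropout and any weight draw.
#' @export
train_config <- function(epochs = 30L, batch_size = 10L, learning_rate = 0.001,
                         seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = 0.9, beta2 = 0.999,
                 adam_eps = 1e-8, seed = as.integer(seed)),
            class = "train_config")
}

## stack a list of equal-dim 3D crops into an (nvox x n) matrix
stack_crops <- function(crops) {
  dm <- dim(crops[[1]])
  m <- vapply(crops, function(cr) {
    if (!identical(dim(cr), dm)) stop("crop shapes differ")
    as.vector(cr)
  }, numeric(prod(dm)))
  structure(m, crop_dim = dm)
}

#' Train the restoration network
#'
#' Mini-batch Adam on the mean-squared error between normalised
#' reconstructed crops and normalised ground-truth crops. Inputs and targets
#' must already be scaled to \[0, 1\] (see [prepare_training_pairs()]).
#'
#' @param model a `pet_cnn` from [build_model()].
#' @param x list of normalised input crops (equal cubic dims).
#' @param y list of normalised target crops.
#' @param cfg a [train_config()].
#' @param x_val,y_val optional validation lists for per-epoch monitoring.
#' @param verbose print per-epoch losses.
#' @return the trained model, with a `history` data.frame attached
#'   (`epoch`, `train_loss`, `val_loss`).
#' @export
train_cnn <- function(model, x, y, cfg = train_config(), x_val = NULL,
                      y_val = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "pet_cnn"), length(x) == length(y), length(x) >= 1)
  xm <- stack_crops(x); ym <- stack_crops(y)
  if (!identical(dim(xm), dim(ym))) stop("input and target shapes differ")
  dims <- attr(xm, "crop_dim")
  spec <- model$spec
  params <- model$params
  adam <- lapply(params, function(p) lapply(p[intersect(names(p),
            c("W", "b", "gamma", "beta"))], function(q) list(m = q * 0, v = q * 0)))
  t_step <- 0L
  n <- ncol(xm)
  hist_rows <- vector("list", cfg$epochs)
  vxm <- if (!is.null(x_val)) stack_crops(x_val) else NULL
  vym <- if (!is.null(y_val)) stack_crops(y_val) else NULL

  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      ep_loss <- 0
      for (bt in batches) {
        t_step <- t_step + 1L
        drop_seed <- derive_seed(cfg$seed, 1000L * ep + t_step)
        step <- cnn_train_step_cpp(xm[, bt, drop = FALSE], ym[, bt, drop = FALSE],
                                   params, dims, spec$bn_eps, spec$dropout_rate,
                                   spec$dropout_layers, drop_seed)
        ep_loss <- ep_loss + step$loss * length(bt)
        for (l in seq_along(params)) {
          for (nm in names(adam[[l]])) {
            g <- step$grads[[l]][[nm]]
            st <- adam[[l]][[nm]]
            st$m <- cfg$beta1 * st$m + (1 - cfg$beta1) * g
            st$v <- cfg$beta2 * st$v + (1 - cfg$beta2) * g^2
            mhat <- st$m / (1 - cfg$beta1^t_step)
            vhat <- st$v / (1 - cfg$beta2^t_step)
            params[[l]][[nm]] <- params[[l]][[nm]] -
              cfg$learning_rate * mhat / (sqrt(vhat) + cfg$adam_eps)
            adam[[l]][[nm]] <- st
          }
          if (l < length(params)) {
            bs <- step$bn_stats[[l]]
            mom <- spec$bn_momentum
            params[[l]]$run_mean <- mom * params[[l]]$run_mean + (1 - mom) * bs$mean
            params[[l]]$run_var <- mom * params[[l]]$run_var + (1 - mom) * bs$var
          }
        }
      }
      train_loss <- ep_loss / n
      val_loss <- NA_real_
      if (!is.null(vxm)) {
        pred <- cnn_forward_cpp(vxm, params, dims, spec$bn_eps)
        val_loss <- mean((pred - vym)^2)
      }
      hist_rows[[ep]] <- data.frame(epoch = ep, train_loss = train_loss,
                                    val_loss = val_loss)
      if (verbose)
        message(sprintf("epoch %3d  train %.5f  val %s", ep, train_loss,
                        ifelse(is.na(val_loss), "-", sprintf("%.5f", val_loss))))
    }
  })
  model$params <- params
  model$history <- do.call(rbind, hist_rows)
  model
}

#' Forward pass on normalised crops
#'
#' @param model trained `pet_cnn`.
#' @param crop normalised 3D crop (or list of crops).
#' @param record `normalization_record` used to rescale the output back to
#'   kBq/ml; required.
#' @return restored crop(s) on the original activity scale.
#' @export
predict_cnn <- function(model, crop, record) {
  if (missing(record) || is.null(record))
    stop("a normalization_record is required to rescale the prediction")
  single <- !is.list(crop)
  crops <- if (single) list(crop) else crop
  xm <- stack_crops(crops)
  dims <- attr(xm, "crop_dim")
  out <- cnn_forward_cpp(xm, model$params, dims, model$spec$bn_eps)
  res <- lapply(seq_len(ncol(out)), function(i)
    minmax_denormalize(array(out[, i], dims), record))
  if (single) res[[1]] else res
}

#' One-step restoration of a reconstructed crop
#'
#' Normalises the crop, runs the network, and inverts the normalisation so
#' the result is in kBq/ml.
#'
#' @param model trained `pet_cnn`.
#' @param recon_crop reconstructed activity crop (kBq/ml).
#' @export
restore_crop <- function(model, recon_crop) {
  nm <- minmax_normalize(recon_crop)
  predict_cnn(model, nm$values, nm$record)
}

#' Scale-augment a training case
#'
#' Spatially rescales the ground-truth and reconstructed crops (trilinear)
#' and the mask (threshold 0.5) by `factor` about the crop centre, updating
#' the recorded volume by `factor^3`. Factors in (0, 1] shrink tumours,
#' creating additional small cases.
#'
#' @param case list with `gt_crop`, `recon_crop`, `mask_crop`, `volume_ml`.
#' @param factor scale factor in (0, 1].
#' @export
augment_case <- function(case, factor) {
  if (factor <= 0 || factor > 1) stop("scale factor must lie in (0, 1]")
  if (factor == 1) return(case)
  dm <- dim(case$gt_crop)
  case$gt_crop <- cpp_rescale3(case$gt_crop, dm, factor)
  case$recon_crop <- cpp_rescale3(case$recon_crop, dm, factor)
  case$mask_crop <- array(cpp_rescale3(case$mask_crop + 0, dm, factor) >= 0.5, dm)
  case$volume_ml <- case$volume_ml * factor^3
  case$augmented <- TRUE
  case$scale_factor <- factor
  case
}

#' Augment a dataset by shrinking larger tumours
#'
#' Draws `n_augment` cases from the larger half of the volume distribution
#' and rescales each by a factor uniform in `factor_range`, appending the
#' scaled copies to the dataset.
#'
#' @param cases list of training cases.
#' @param n_augment number of augmented copies to add.
#' @param factor_range scale-factor range, within (0, 1].
#' @param seed RNG seed.
#' @export
augment_by_scaling <- function(cases, n_augment, factor_range = c(0.5, 0.8),
                               seed = 1L) {
  if (any(factor_range <= 0) || any(factor_range > 1))
    stop("scale factors must lie in (0, 1]")
  if (n_augment == 0) return(cases)
  vols <- vapply(cases, function(cs) cs$volume_ml, numeric(1))
  big <- which(vols >= median(vols))
  with_seed(seed, {
    pick <- sample(big, n_augment, replace = n_augment > length(big))
    fac <- runif(n_augment, factor_range[1], factor_range[2])
  })
  c(cases, lapply(seq_len(n_augment), function(i)
    augment_case(cases[[pick[i]]], fac[i])))
}
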