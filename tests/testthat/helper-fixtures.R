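# Analytic voxelised shapes and small shared fixtures, built in code.

# centred sphere mask: n^3 grid, radius r (same units as voxel_size)
ball_mask <- function(n, r, voxel_size = c(1, 1, 1)) {
  cc <- (n + 1) / 2
  gx <- ((1:n) - cc) * voxel_size[1]
  gy <- ((1:n) - cc) * voxel_size[2]
  gz <- ((1:n) - cc) * voxel_size[3]
  sqrt(outer(outer(gx^2, gy^2, "+"), gz^2, "+")) <= r
}

ellipsoid_mask <- function(n, semi_axes, voxel_size = c(1, 1, 1)) {
  cc <- (n + 1) / 2
  gx <- ((1:n) - cc) * voxel_size[1] / semi_axes[1]
  gy <- ((1:n) - cc) * voxel_size[2] / semi_axes[2]
  gz <- ((1:n) - cc) * voxel_size[3] / semi_axes[3]
  outer(outer(gx^2, gy^2, "+"), gz^2, "+") <= 1
}

# uniform cylinder along z
cylinder_volume <- function(grid_dim, radius_vox, value = 1) {
  cc <- (grid_dim[1:2] + 1) / 2
  r2 <- outer(((1:grid_dim[1]) - cc[1])^2, ((1:grid_dim[2]) - cc[2])^2, "+")
  out <- array(0, grid_dim)
  for (z in seq_len(grid_dim[3])) out[, , z] <- (r2 <= radius_vox^2) * value
  out
}

# the shared desk-scale pipeline run used by the restoration and
# generalisation acceptance tests; computed once per session
pipeline_cache <- new.env(parent = emptyenv())

get_pipeline_results <- function() {
  if (!is.null(pipeline_cache$res)) return(pipeline_cache$res)
  cfg <- experiment_config(1, "desk", seed = 7)
  exp1 <- run_experiment(cfg)
  cfg2 <- experiment_config(2, "desk", seed = 8,
                            n_per_class = c(uniform = 4L, halves = 4L, hollow = 4L))
  exp2 <- run_experiment(cfg2, model = exp1$model)
  cfg3 <- experiment_config(3, "desk", seed = 9, n_exp3 = 8L)
  exp3 <- run_experiment(cfg3, model = exp1$model)
  pipeline_cache$res <- list(exp1 = exp1, exp2 = exp2, exp3 = exp3)
  pipeline_cache$res
}
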