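# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the whole suite runs quickly.

# Small, fast phantom for module tests.
small_phantom <- function(...) {
  phantom_config(grid_shape = c(16, 16, 10), ...)
}

# Noiseless, texture-free, jitter-free phantom: voxel TACs equal their
# region's analytic curve exactly and the four kinetic classes are pure.
noiseless_phantom <- function(grid_shape = c(16, 16, 10), bp_ad = 0.3, ...) {
  phantom_config(grid_shape = grid_shape, noise_scale = 0,
                 texture_amplitude = 0, bp_sd = 0, bp_ad = bp_ad, ...)
}

# Deterministic linearly separable feature table: two Gaussian clusters whose
# separation (10 SD) dwarfs the noise, so every leave-one-out fold stays
# separable.
separable_table <- function(n_ad = 19, n_hc = 21, n_features = 4, seed = 1,
                            shift = 10) {
  set.seed(seed)
  n <- n_ad + n_hc
  g <- c(rep("AD", n_ad), rep("HC", n_hc))
  m <- matrix(rnorm(n * n_features), n, n_features)
  m[g == "AD", 1] <- m[g == "AD", 1] + shift
  df <- data.frame(subject_id = sprintf("s%02d", 1:n), group = g)
  for (k in seq_len(n_features)) df[[paste0("f", k)]] <- m[, k]
  feature_table(df)
}

# Pure-noise feature table (no class signal).
noise_table <- function(n_ad = 19, n_hc = 21, n_features = 4, seed = 1) {
  separable_table(n_ad, n_hc, n_features, seed = seed, shift = 0)
}

# Build a dynamic_pet_image directly from a voxel -> TAC assignment.
image_from_tacs <- function(tac_matrix, assignment, schedule) {
  # tac_matrix: curves x frames; assignment: 3D array of curve indices (0 = empty)
  d <- dim(assignment)
  nf <- ncol(tac_matrix)
  data <- array(0, c(d, nf))
  flat <- matrix(data, ncol = nf)
  idx <- which(assignment != 0)
  flat[idx, ] <- tac_matrix[assignment[idx], , drop = FALSE]
  dynamic_pet_image(array(flat, c(d, nf)), schedule)
}
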