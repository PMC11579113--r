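# Programmatic fixtures: toy label volumes and small model configurations.

codes <- fs_label_codes()

# All-white-matter label grid with a ventricle block set by linear indices
# or by coordinate ranges.
white_with_ventricle <- function(dims, vent_index,
                                 vent_code = codes[["ventricle_left"]]) {
  lab <- array(codes[["white_matter"]], dims)
  lab[vent_index] <- vent_code
  label_volume(lab)
}

# 1 x 2 x 16 interior ventricle block in a white-matter cube: the block's
# face-neighbor count is 2*(1*2 + 2*16 + 16*1) = 100, so |AWM| = 100.
awm100_labels <- function() {
  dims <- c(20, 20, 20)
  lab <- array(codes[["white_matter"]], dims)
  lab[10, 10:11, 3:18] <- codes[["ventricle_left"]]
  label_volume(lab)
}

# Matching intensity volume: white-matter-like everywhere, CSF-dark inside
# the ventricle block (deterministic, no noise needed for the contracts).
awm100_volume <- function(labels) {
  v <- array(110, dim(labels$data))
  v[ventricle_mask(labels)] <- 30
  volume(v)
}

toy_model_config <- function(seed = 1, input_size = 8,
                             conv_filters = c(4, 6, 8, 8),
                             conv_kernel = 3, dense_width = 8,
                             dropout = 0.2, ...) {
  model_config(input_size = input_size, conv_filters = conv_filters,
               conv_kernel = conv_kernel, dense_width = dense_width,
               dropout = dropout, seed = seed, ...)
}

# A toy model guaranteed to have a non-degenerate output on `x` (some random
# inits die at the 1-voxel fourth block; those seeds are skipped).
live_toy_model <- function(seed = 1, x = NULL) {
  for (s in seed + 0:24) {
    m <- build_model(toy_model_config(seed = s))
    probe <- if (is.null(x)) array(1, c(8, 8, 8)) else x
    if (abs(predict_scalar(m, probe)) > 1e-8) return(m)
  }
  stop("no live toy model found")
}

# Single-voxel network (input 1^3, one channel per block) with hand-set
# center-tap weights, exact-identity batch norm, and no dropout: the whole
# network is a product of scalars with ReLU gates, so gradients can be
# derived by hand. `conv_w` gives the four center-tap weights, `conv_b` the
# biases; dense weights are both 1.
scalar_chain_model <- function(conv_w = c(1, 1, 1, 1),
                               conv_b = c(0, 0, 0, 0)) {
  cfg <- model_config(input_size = 1, conv_filters = c(1, 1, 1, 1),
                      conv_kernel = 6, dropout = 0, dense_width = 1, seed = 1)
  m <- build_model(cfg)
  # center tap of a 6^3 kernel with pad_lo = 2: (kd, kh, kw) = (2, 2, 2)
  center <- 2 + 6 * 2 + 36 * 2 + 1
  ci <- 0
  for (i in seq_along(m$layers)) {
    ly <- m$layers[[i]]
    if (ly$type == "conv") {
      ci <- ci + 1
      w <- matrix(0, nrow(ly$w), 1)
      w[center, 1] <- conv_w[ci]
      m$layers[[i]]$w <- w
      m$layers[[i]]$b <- conv_b[ci]
    } else if (ly$type == "bn") {
      # gamma / sqrt(rvar + 1e-5) == 1 exactly
      m$layers[[i]]$gamma <- 1
      m$layers[[i]]$rvar <- 1 - 1e-5
      m$layers[[i]]$rmean <- 0
      m$layers[[i]]$beta <- 0
    } else if (ly$type == "dense") {
      m$layers[[i]]$w <- matrix(1, nrow(ly$w), ncol(ly$w))
      m$layers[[i]]$b <- rep(0, length(ly$b))
    }
  }
  m
}

# Minimal hand-made subject for training tests (labels optional).
make_subject <- function(id, age, data) {
  structure(list(subject_id = id, age = age, volume = volume(data),
                 labels = NULL), class = "vb_subject")
}

# Cohort whose age is a linear function of total image intensity.
intensity_coded_cohort <- function(n, seed, dims = c(8, 8, 8)) {
  set.seed(seed)
  ages <- runif(n, 40, 90)
  lapply(seq_len(n), function(i) {
    base <- array(rnorm(prod(dims), sd = 0.05), dims)
    make_subject(sprintf("ic-%03d", i), ages[i], base + ages[i] / 50)
  })
}

desk_config <- function(seed, out_dir, ...) {
  desk_experiment_config(seed = seed, out_dir = out_dir, ...)
}
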