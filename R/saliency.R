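#' Configuration of the attribution methods
#'
#' @param ig_points Gauss-Legendre quadrature nodes for integrated gradients
#'   (default 50).
#' @param gshap_samples noise draws for gradient SHAP (default 5).
#' @param gshap_sigma standard deviation of the Gaussian input noise; if
#'   `NULL` (default) it is set per input to 0.1 times the input's intensity
#'   standard deviation.
#' @param seed integer seed for the stochastic methods.
#' @return an object of class `vb_saliency_config`.
#' @export
saliency_config <- function(ig_points = 50, gshap_samples = 5,
                            gshap_sigma = NULL, seed = 1) {
  if (ig_points < 1) stop("`ig_points` must be >= 1", call. = FALSE)
  if (gshap_samples < 1) stop("`gshap_samples` must be >= 1", call. = FALSE)
  if (!is.null(gshap_sigma) && gshap_sigma <= 0) {
    stop("`gshap_sigma` must be positive", call. = FALSE)
  }
  structure(list(ig_points = as.integer(ig_points),
                 gshap_samples = as.integer(gshap_samples),
                 gshap_sigma = gshap_sigma,
                 seed = as.integer(seed)),
            class = "vb_saliency_config")
}

new_attribution <- function(data, method) {
  structure(list(data = data, method = method), class = "vb_attribution")
}

#' @export
print.vb_attribution <- function(x, ...) {
  cat(sprintf("<vb_attribution> %s, %s voxels, range [%.3g, %.3g]\n",
              x$method, paste(dim(x$data), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

attr_input_grid <- function(x) {
  g <- as_grid(x)
  if (length(dim(g)) != 3L) stop("expected a single 3D volume", call. = FALSE)
  g
}

#' Gradient-based attribution methods
#'
#' `gradient_saliency()` (G) is the per-voxel partial derivative of the
#' model's scalar output with respect to the input. `input_x_gradient()`
#' (IXG) multiplies that gradient elementwise by the input itself.
#' `masked_gradient()` (MG) zeroes the gradient outside a brain mask, leaving
#' in-brain values untouched.
#'
#' @param model a model with [input_gradient()] support (e.g. `ba_model`).
#' @param x a `vb_volume` or 3D array.
#' @return a `vb_attribution` with the input's shape (signed values).
#' @export
gradient_saliency <- function(model, x) {
  g <- attr_input_grid(x)
  gr <- input_gradient(model, g)
  new_attribution(array(gr, dim(g)), "G")
}

#' @rdname gradient_saliency
#' @export
input_x_gradient <- function(model, x) {
  g <- attr_input_grid(x)
  gr <- array(input_gradient(model, g), dim(g))
  new_attribution(g * gr, "IXG")
}

#' @rdname gradient_saliency
#' @param mask logical 3D array of the input's shape (e.g. [brain_mask()]).
#' @export
masked_gradient <- function(model, x, mask) {
  g <- attr_input_grid(x)
  check_same_shape(g, mask, "volume and mask")
  gr <- array(input_gradient(model, g), dim(g))
  new_attribution(gr * (mask != 0), "MG")
}

#' Guided backpropagation and GradCAM
#'
#' `guided_backprop()` (GB) is a backward pass in which each ReLU, besides its
#' usual forward gating, also zeroes negative incoming backward signals.
#' `gradcam()` computes the gradient of the output with respect to the final
#' convolutional block's activations, weights each channel by its spatial
#' mean gradient, sums, applies ReLU, and upsamples the coarse map to input
#' shape by trilinear interpolation. `guided_gradcam()` (GGC) is the
#' elementwise product of the two.
#'
#' @inheritParams gradient_saliency
#' @return a `vb_attribution` with the input's shape.
#' @export
guided_backprop <- function(model, x) {
  g <- attr_input_grid(x)
  gr <- input_gradient(model, g, guided = TRUE)
  new_attribution(array(gr, dim(g)), "GB")
}

#' @rdname guided_backprop
#' @export
gradcam <- function(model, x) {
  stopifnot(inherits(model, "ba_model"))
  g <- attr_input_grid(x)
  xb <- as_input_batch(g, model$config$input_size)
  fw <- nn_forward(model, xb, training = FALSE, need_param_grads = FALSE)
  bw <- nn_backward(fw$net, fw$cache, 1, mode = "input",
                    stop_at = model$capture_layer)
  act <- fw$cache[[model$capture_layer]]$activation
  grad <- array(bw$gx, dim(act))
  d <- dim(act)
  C <- d[4]
  coarse <- array(0, d[1:3])
  for (c in seq_len(C)) {
    wc <- mean(grad[, , , c, 1])  # spatial mean of the channel gradient
    coarse <- coarse + wc * act[, , , c, 1]
  }
  coarse <- pmax(coarse, 0)
  new_attribution(upsample_trilinear(coarse, dim(g)), "GradCAM")
}

#' @rdname guided_backprop
#' @export
guided_gradcam <- function(model, x) {
  gb <- guided_backprop(model, x)
  gc <- gradcam(model, x)
  new_attribution(gb$data * gc$data, "GGC")
}

#' Integrated gradients
#'
#' Attribution of voxel i is `(x_i - baseline_i)` times the Gauss-Legendre
#' weighted average of the output gradient along the straight path from the
#' baseline to the input, using `config$ig_points` quadrature nodes on
#' `[0, 1]`. With enough nodes the attributions satisfy the completeness
#' identity: they sum to `f(x) - f(baseline)`.
#'
#' @inheritParams gradient_saliency
#' @param baseline reference volume (3D array or `vb_volume`); default
#'   all-zero.
#' @param config a [saliency_config()].
#' @param chunk_size interpolation points evaluated per forward/backward pass.
#' @return a `vb_attribution` with the input's shape.
#' @export
integrated_gradients <- function(model, x, baseline = NULL,
                                 config = saliency_config(),
                                 chunk_size = 10L) {
  g <- attr_input_grid(x)
  b <- if (is.null(baseline)) array(0, dim(g)) else attr_input_grid(baseline)
  check_same_shape(g, b, "input and baseline")
  gl <- pracma::gaussLegendre(config$ig_points, 0, 1)
  diff <- g - b
  avg_grad <- array(0, dim(g))
  for (s in seq(1L, config$ig_points, by = chunk_size)) {
    idx <- s:min(s + chunk_size - 1L, config$ig_points)
    xb <- array(0, c(dim(g), 1L, length(idx)))
    for (j in seq_along(idx)) xb[, , , 1L, j] <- b + gl$x[idx[j]] * diff
    gr <- input_gradient(model, xb)
    for (j in seq_along(idx)) {
      avg_grad <- avg_grad + gl$w[idx[j]] * array(gr[, , , 1L, j], dim(g))
    }
  }
  new_attribution(diff * avg_grad, "IG")
}

#' Gradient SHAP
#'
#' For each of `config$gshap_samples` draws the input is perturbed with
#' Gaussian noise, a baseline is drawn from the supplied baseline
#' distribution, and the gradient is evaluated at a uniformly drawn point of
#' the linear interpolation between baseline and noisy input. The attribution
#' is the sample mean of `(noisy input - baseline) x gradient`; deterministic
#' under `config$seed`.
#'
#' @inheritParams integrated_gradients
#' @param baselines list of baseline volumes (3D arrays or `vb_volume`), e.g.
#'   the unperturbed cohort; a single all-zero baseline if `NULL`.
#' @return a `vb_attribution` with the input's shape.
#' @export
gradient_shap <- function(model, x, baselines = NULL,
                          config = saliency_config()) {
  g <- attr_input_grid(x)
  if (is.null(baselines)) baselines <- list(array(0, dim(g)))
  bl <- lapply(baselines, attr_input_grid)
  for (b in bl) check_same_shape(g, b, "input and baseline")
  sigma <- config$gshap_sigma %||% (0.1 * max(sd(g), 1e-12))
  S <- config$gshap_samples
  draws <- with_seed(derive_seed(config$seed, "gshap"), {
    list(noise = array(rnorm(length(g) * S, sd = sigma), c(dim(g), S)),
         bidx = sample.int(length(bl), S, replace = TRUE),
         alpha = runif(S))
  })
  xb <- array(0, c(dim(g), 1L, S))
  diffs <- vector("list", S)
  for (s in seq_len(S)) {
    noisy <- g + draws$noise[, , , s]
    b <- bl[[draws$bidx[s]]]
    diffs[[s]] <- noisy - b
    xb[, , , 1L, s] <- b + draws$alpha[s] * diffs[[s]]
  }
  gr <- input_gradient(model, xb)
  acc <- array(0, dim(g))
  for (s in seq_len(S)) {
    acc <- acc + diffs[[s]] * array(gr[, , , 1L, s], dim(g))
  }
  new_attribution(acc / S, "GSHAP")
}

#' Normalize an attribution to a saliency probability density
#'
#' Saliency units are arbitrary, so absolute attribution values are
#' normalized to sum to 1 over the grid, giving a unitless saliency
#' probability density. The sign of individual attributions is deliberately
#' not preserved; this is the only place absolute values are taken.
#'
#' @param raw a `vb_attribution` (or 3D array), not identically zero.
#' @return a `vb_saliency`: list with `density` (non-negative 3D array
#'   summing to 1) and `method`.
#' @export
normalize_to_density <- function(raw) {
  method <- if (inherits(raw, "vb_attribution")) raw$method else "custom"
  g <- if (inherits(raw, "vb_attribution")) raw$data else as_grid(raw)
  a <- abs(g)
  tot <- sum(a)
  if (tot == 0) {
    stop("attribution is identically zero; density undefined", call. = FALSE)
  }
  structure(list(density = a / tot, method = method), class = "vb_saliency")
}

#' @export
print.vb_saliency <- function(x, ...) {
  cat(sprintf("<vb_saliency> %s, %s voxels, max density %.3g\n",
              x$method, paste(dim(x$density), collapse = "x"),
              max(x$density)))
  invisible(x)
}

#' Average saliency densities across a cohort
#'
#' Voxelwise mean of the densities, renormalized to sum to 1.
#'
#' @param maps non-empty list of `vb_saliency` with equal shapes.
#' @return a `vb_saliency`.
#' @export
cohort_average_map <- function(maps) {
  if (length(maps) == 0L) stop("need at least one map", call. = FALSE)
  acc <- NULL
  for (m in maps) {
    stopifnot(inherits(m, "vb_saliency"))
    if (is.null(acc)) acc <- m$density else {
      check_same_shape(acc, m$density, "saliency maps")
      acc <- acc + m$density
    }
  }
  avg <- acc / length(maps)
  structure(list(density = avg / sum(avg), method = maps[[1]]$method),
            class = "vb_saliency")
}

#' Fraction of saliency mass inside a mask
#'
#' @param map a `vb_saliency`.
#' @param mask logical 3D array (e.g. [brain_mask()]).
#' @return proportion in `[0, 1]`.
#' @export
inside_mass_fraction <- function(map, mask) {
  stopifnot(inherits(map, "vb_saliency"))
  check_same_shape(map$density, mask, "density and mask")
  sum(map$density[mask != 0])
}

#' Trilinear upsampling of a coarse 3D map
#'
#' Grid points are treated as cell centers (half-voxel alignment), the
#' convention used to bring a coarse GradCAM map back to input resolution.
#'
#' @param x 3D array.
#' @param out_dim target dimensions (length 3).
#' @return 3D array of dimension `out_dim`.
#' @export
upsample_trilinear <- function(x, out_dim) {
  d <- dim(x)
  out_dim <- as.integer(out_dim)
  if (all(d == out_dim)) return(x)
  # source coordinate of each target cell center, clamped to the grid
  src <- lapply(1:3, function(a) {
    s <- (seq_len(out_dim[a]) - 0.5) * d[a] / out_dim[a] + 0.5
    pmin(pmax(s, 1), d[a])
  })
  lo <- lapply(seq_along(src), function(a) {
    pmax(pmin(floor(src[[a]]), d[a] - 1L), 1L)
  })
  fr <- lapply(seq_along(src), function(a) src[[a]] - lo[[a]])
  out <- array(0, out_dim)
  i1 <- lo[[1]]; i2 <- pmin(i1 + 1L, d[1]); f1 <- fr[[1]]
  j1 <- lo[[2]]; j2 <- pmin(j1 + 1L, d[2]); f2 <- fr[[2]]
  k1 <- lo[[3]]; k2 <- pmin(k1 + 1L, d[3]); f3 <- fr[[3]]
  for (k in seq_len(out_dim[3])) {
    w3a <- 1 - f3[k]; w3b <- f3[k]
    sl <- matrix(x[, , k1[k]], d[1], d[2]) * w3a +
      matrix(x[, , k2[k]], d[1], d[2]) * w3b        # D x H plane blend
    a <- sl[i1, , drop = FALSE] * (1 - f1) + sl[i2, , drop = FALSE] * f1
    out[, , k] <- a[, j1, drop = FALSE] * rep(1 - f2, each = out_dim[1]) +
      a[, j2, drop = FALSE] * rep(f2, each = out_dim[1])
  }
  out
}

#' Compute one attribution method by tag
#'
#' Dispatch helper mapping the method tags `G`, `IXG`, `MG`, `GB`, `GGC`,
#' `IG`, `GSHAP` to their implementations.
#'
#' @param method method tag.
#' @param model the model.
#' @param x input volume.
#' @param mask brain mask (required for `MG`).
#' @param baselines baseline distribution for `GSHAP`.
#' @param config a [saliency_config()].
#' @return a `vb_attribution`.
#' @export
compute_attribution <- function(method, model, x, mask = NULL,
                                baselines = NULL,
                                config = saliency_config()) {
  switch(method,
         G = gradient_saliency(model, x),
         IXG = input_x_gradient(model, x),
         MG = {
           if (is.null(mask)) stop("MG requires a brain mask", call. = FALSE)
           masked_gradient(model, x, mask)
         },
         GB = guided_backprop(model, x),
         GGC = guided_gradcam(model, x),
         IG = integrated_gradients(model, x, config = config),
         GSHAP = gradient_shap(model, x, baselines = baselines,
                               config = config),
         stop("unknown method tag: ", method, call. = FALSE))
}
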