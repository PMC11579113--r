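# Independent oracles: a linear model for the attribution generics, naive
# loop-based re-implementations of the five similarity measures, and a
# central-finite-difference gradient.

# --- linear scalar model f(x) = sum(w * x) ---------------------------------

make_linear_model <- function(w) {
  structure(list(w = w), class = "test_linear_model")
}

predict_scalar.test_linear_model <- function(model, x, ...) {
  if (length(dim(x)) == 5L) {
    apply(x, 5, function(s) sum(model$w * array(s, dim(model$w))))
  } else {
    sum(model$w * x)
  }
}

input_gradient.test_linear_model <- function(model, x, guided = FALSE, ...) {
  d <- if (length(dim(x)) == 5L) dim(x) else c(dim(x), 1L, 1L)
  array(rep(as.vector(model$w), d[5]), d)
}

register_linear_model <- function() {
  registerS3method("predict_scalar", "test_linear_model",
                   predict_scalar.test_linear_model,
                   envir = asNamespace("ventbench"))
  registerS3method("input_gradient", "test_linear_model",
                   input_gradient.test_linear_model,
                   envir = asNamespace("ventbench"))
}
register_linear_model()

# --- central finite differences --------------------------------------------

fd_gradient <- function(model, x, idx, h = 1e-4) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (predict_scalar(model, xp) - predict_scalar(model, xm)) / (2 * h)
  }, numeric(1))
}

# --- brute-force similarity measures (naive loops, no shared code) ---------

o_dice <- function(a, b) {
  a <- as.vector(a) != 0
  b <- as.vector(b) != 0
  inter <- 0
  for (i in seq_along(a)) if (a[i] && b[i]) inter <- inter + 1
  if (sum(a) + sum(b) == 0) return(1)
  2 * inter / (sum(a) + sum(b))
}

o_hist_index <- function(v, bins) {
  lo <- min(v); hi <- max(v)
  if (lo == hi) return(rep(1L, length(v)))
  i <- as.integer(floor((v - lo) / (hi - lo) * bins)) + 1L
  ifelse(i > bins, bins, i)
}

o_nmi <- function(a, b, bins = 64) {
  ia <- o_hist_index(as.vector(a), bins)
  ib <- o_hist_index(as.vector(b), bins)
  n <- length(ia)
  joint <- matrix(0, bins, bins)
  for (i in seq_len(n)) joint[ia[i], ib[i]] <- joint[ia[i], ib[i]] + 1
  pj <- joint / n
  pa <- rowSums(pj); pb <- colSums(pj)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hj <- H(as.vector(pj))
  if (hj == 0) return(1)
  (H(pa) + H(pb)) / hj
}

o_nss <- function(s, f) {
  s <- as.vector(s); f <- as.vector(f) != 0
  m <- mean(s)
  sdev <- sqrt(sum((s - m)^2) / (length(s) - 1))
  if (sdev == 0) return(0)
  z <- (s - m) / sdev
  acc <- 0; k <- 0
  for (i in seq_along(s)) if (f[i]) { acc <- acc + z[i]; k <- k + 1 }
  acc / k
}

o_cc <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  ma <- mean(a); mb <- mean(b)
  cov_ab <- sum((a - ma) * (b - mb)) / (length(a) - 1)
  cov_ab / (sqrt(sum((a - ma)^2) / (length(a) - 1)) *
              sqrt(sum((b - mb)^2) / (length(b) - 1)))
}

o_sim <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  acc <- 0
  for (i in seq_along(a)) acc <- acc + min(a[i], b[i])
  acc
}

# random probability density on an 8^3 grid
random_density <- function(seed) {
  set.seed(seed)
  v <- abs(rnorm(8^3)) + 1e-9
  array(v / sum(v), c(8, 8, 8))
}
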