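#' Binarize a saliency density
#'
#' Matched-cardinality thresholding: the `k` voxels of highest density are
#' marked, with `k` typically the size of the ground-truth support. Ties are
#' broken deterministically by value (descending) then linear index
#' (ascending). A fixed-percentile threshold is available as an alternative.
#'
#' @param density 3D array (or `vb_saliency`).
#' @param k number of voxels to mark (matched cardinality).
#' @param percentile alternative: mark voxels at or above this percentile of
#'   the density values (used when `k` is `NULL`).
#' @return logical 3D array.
#' @export
binarize_saliency <- function(density, k = NULL, percentile = 95) {
  g <- as_grid(density)
  out <- array(FALSE, dim(g))
  if (!is.null(k)) {
    k <- min(as.integer(k), length(g))
    if (k > 0L) {
      ord <- order(-as.vector(g), seq_along(g))
      out[ord[seq_len(k)]] <- TRUE
    }
  } else {
    thr <- quantile(g, percentile / 100, names = FALSE, type = 7)
    out[g >= thr] <- TRUE
  }
  out
}

as_binary <- function(x) {
  if (inherits(x, "vb_ground_truth")) return(x$support)
  g <- as_grid(x)
  if (is.logical(g)) g else g != 0
}

as_density_grid <- function(x) {
  if (inherits(x, "vb_ground_truth")) return(x$density)
  as_grid(x)
}

#' Sorensen-Dice overlap of two binary maps
#'
#' `2|A intersect B| / (|A| + |B|)` on the binarized supports: 0 means no
#' overlap and 1 perfect overlap. Two empty maps are defined as perfectly
#' overlapping (1); exactly one empty map gives 0.
#'
#' @param a,b binary/logical 3D arrays (or objects binarizable to them:
#'   a `vb_ground_truth` contributes its support).
#' @return overlap in `[0, 1]`.
#' @export
dice <- function(a, b) {
  A <- as_binary(a)
  B <- as_binary(b)
  check_same_shape(A, B, "maps")
  na <- sum(A)
  nb <- sum(B)
  if (na + nb == 0L) return(1)
  2 * sum(A & B) / (na + nb)
}

#' Normalized mutual information of two maps
#'
#' `(H(A) + H(B)) / H(A, B)` from the joint histogram of the two maps'
#' values, the variant ranging from 1 (independent) to 2 (perfectly
#' correlated). Each map is binned into `bins` equal-width bins over its own
#' observed range. A constant map has zero marginal entropy and the index is
#' defined as 1 with a warning.
#'
#' @param a,b 3D arrays / `vb_saliency` / `vb_ground_truth` (density used).
#' @param bins histogram bins per map (>= 2), default 64.
#' @return value in `[1, 2]`.
#' @export
nmi <- function(a, b, bins = 64) {
  A <- as_density_grid(a)
  B <- as_density_grid(b)
  check_same_shape(A, B, "maps")
  if (bins < 2) stop("`bins` must be >= 2", call. = FALSE)
  ia <- bin_index(A, bins)
  ib <- bin_index(B, bins)
  joint <- tabulate(ia + bins * (ib - 1L), nbins = bins * bins)
  p <- joint / length(A)
  pa <- tabulate(ia, nbins = bins) / length(A)
  pb <- tabulate(ib, nbins = bins) / length(B)
  ha <- entropy_nats(pa)
  hb <- entropy_nats(pb)
  hab <- entropy_nats(p)
  if (ha == 0 || hb == 0 || hab == 0) {
    warning("degenerate single-bin marginal; NMI defined as 1")
    return(1)
  }
  (ha + hb) / hab
}

bin_index <- function(x, bins) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(1L, length(x)))
  i <- floor((as.vector(x) - r[1]) / (r[2] - r[1]) * bins) + 1L
  pmin(i, bins)
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized scanpath saliency
#'
#' The saliency grid is standardized to mean 0 and standard deviation 1, and
#' the standardized values are averaged over the fixation voxels, giving an
#' average z-score of the saliency at ground-truth locations. A zero-variance
#' saliency map yields 0 with a warning; an empty fixation map is rejected.
#' Unlike the other measures, NSS is not symmetric in its arguments.
#'
#' @param saliency 3D array or `vb_saliency`.
#' @param fixation binary/logical 3D array (or `vb_ground_truth` support)
#'   with at least one marked voxel.
#' @return signed value in z-units.
#' @export
nss <- function(saliency, fixation) {
  s <- as_density_grid(saliency)
  f <- as_binary(fixation)
  check_same_shape(s, f, "saliency and fixation maps")
  if (!any(f)) stop("fixation map has no marked voxels", call. = FALSE)
  sdev <- sd(as.vector(s))
  if (sdev == 0) {
    warning("zero-variance saliency map; NSS defined as 0")
    return(0)
  }
  z <- (s - mean(s)) / sdev
  mean(z[f])
}

#' Pearson correlation of two maps
#'
#' Covariance of the two maps divided by the product of their standard
#' deviations, computed over voxels. Constant maps are rejected (the
#' correlation is undefined), naming the offending argument.
#'
#' @param a,b 3D arrays / `vb_saliency` / `vb_ground_truth` (density used).
#' @return correlation in `[-1, 1]`.
#' @export
cc <- function(a, b) {
  A <- as_density_grid(a)
  B <- as_density_grid(b)
  check_same_shape(A, B, "maps")
  if (sd(as.vector(A)) == 0) stop("map `a` is constant; CC undefined", call. = FALSE)
  if (sd(as.vector(B)) == 0) stop("map `b` is constant; CC undefined", call. = FALSE)
  cor(as.vector(A), as.vector(B))
}

#' Histogram-intersection similarity of two densities
#'
#' Both maps must already be probability densities (each summing to 1 within
#' 1e-6); the similarity is the sum over voxels of the pairwise minima,
#' ranging from 0 (disjoint support) to 1 (identical densities).
#'
#' @param a,b densities (3D arrays / `vb_saliency` / `vb_ground_truth`).
#' @return overlap in `[0, 1]`.
#' @export
sim <- function(a, b) {
  A <- as_density_grid(a)
  B <- as_density_grid(b)
  check_same_shape(A, B, "maps")
  if (abs(sum(A) - 1) > 1e-6 || abs(sum(B) - 1) > 1e-6) {
    stop("`sim` requires normalized densities summing to 1", call. = FALSE)
  }
  sum(pmin(A, B))
}

#' Score one saliency map against the ground truth
#'
#' Computes all five similarity measures. Dice uses the ground-truth support
#' against the saliency binarized at matched cardinality (top `|support|`
#' voxels) by default; NSS uses the support as the fixation map; NMI, CC and
#' SIM compare against the ground-truth density.
#'
#' @param saliency a `vb_saliency`.
#' @param ground_truth a `vb_ground_truth`.
#' @param bins NMI histogram bins.
#' @param binarization `"matched"` (top-k, k = support size) or
#'   `"percentile"`.
#' @param percentile percentile when `binarization = "percentile"`.
#' @param method method tag for the report row (defaults to the map's own).
#' @return one-row data.frame: `method`, `dc`, `nmi`, `nss`, `cc`, `sim`.
#' @export
evaluate_method <- function(saliency, ground_truth, bins = 64,
                            binarization = c("matched", "percentile"),
                            percentile = 95, method = NULL) {
  stopifnot(inherits(saliency, "vb_saliency"),
            inherits(ground_truth, "vb_ground_truth"))
  binarization <- match.arg(binarization)
  sal_bin <- if (binarization == "matched") {
    binarize_saliency(saliency$density, k = sum(ground_truth$support))
  } else {
    binarize_saliency(saliency$density, k = NULL, percentile = percentile)
  }
  out <- data.frame(
    method = method %||% saliency$method,
    dc = dice(sal_bin, ground_truth$support),
    nmi = nmi(saliency$density, ground_truth$density, bins = bins),
    nss = nss(saliency$density, ground_truth$support),
    cc = cc(saliency$density, ground_truth$density),
    sim = sim(saliency$density, ground_truth$density),
    stringsAsFactors = FALSE)
  stopifnot(all(is.finite(unlist(out[-1]))))
  out
}

#' Percentage differences against the baseline method
#'
#' For each measure m and method, `100 * (m_method - m_baseline) /
#' |m_baseline|`. The baseline row is identically 0. A baseline measure of
#' exactly 0 leaves that column undefined (`NA`) rather than infinite.
#'
#' @param reports data.frame of [evaluate_method()] rows.
#' @param baseline_method method tag of the baseline (default `"MG"`).
#' @return data.frame of percentage differences, one row per method.
#' @export
percentage_table <- function(reports, baseline_method = "MG") {
  stopifnot(is.data.frame(reports), "method" %in% names(reports))
  if (!baseline_method %in% reports$method) {
    stop(sprintf("baseline method '%s' absent from reports", baseline_method),
         call. = FALSE)
  }
  measures <- intersect(c("dc", "nmi", "nss", "cc", "sim"), names(reports))
  base <- reports[reports$method == baseline_method, measures, drop = FALSE][1, ]
  out <- reports[, "method", drop = FALSE]
  for (m in measures) {
    bv <- base[[m]]
    out[[m]] <- if (bv == 0) NA_real_ else 100 * (reports[[m]] - bv) / abs(bv)
  }
  out[out$method == baseline_method, measures] <- 0
  out
}
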