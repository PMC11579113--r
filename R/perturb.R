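#' Age-to-dilation-coefficient mapping
#'
#' Subjects at or below the low CA percentile of the cohort receive
#' coefficient 0 (no ventricular change); subjects at or above the high
#' percentile receive 1 (maximum dilation); everyone between is assigned in
#' direct proportion to age, linearly between the two anchor ages. Percentile
#' anchors use the linear-interpolation empirical quantile (R type 7).
#'
#' @param low_percentile,high_percentile anchor percentiles, defaults 5 and 95.
#' @return an object of class `vb_dilation_spec`.
#' @export
dilation_spec <- function(low_percentile = 5, high_percentile = 95) {
  if (!(low_percentile >= 0 && low_percentile < high_percentile &&
        high_percentile <= 100)) {
    stop("need 0 <= low_percentile < high_percentile <= 100", call. = FALSE)
  }
  structure(list(low_percentile = low_percentile,
                 high_percentile = high_percentile),
            class = "vb_dilation_spec")
}

#' @rdname dilation_spec
#' @param age age (years); vectorized.
#' @param cohort_ages non-empty numeric vector of cohort ages defining the CA
#'   distribution.
#' @param spec a [dilation_spec()].
#' @return dilation coefficient(s) in `[0, 1]`.
#' @examples
#' dilation_coefficient(50, cohort_ages = 1:100)
#' @export
dilation_coefficient <- function(age, cohort_ages, spec = dilation_spec()) {
  if (length(cohort_ages) == 0L) {
    stop("`cohort_ages` must be non-empty", call. = FALSE)
  }
  a <- quantile(cohort_ages,
                probs = c(spec$low_percentile, spec$high_percentile) / 100,
                names = FALSE, type = 7)
  if (a[2] <= a[1]) {
    return(ifelse(age >= a[1], 1, 0))
  }
  pmin(1, pmax(0, (age - a[1]) / (a[2] - a[1])))
}

# The six face-neighbor offsets, as coordinate deltas.
face_offsets <- function() {
  rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
}

# Linear indices of in-bounds face neighbors for each index in `idx`
# (a list of 6 integer vectors aligned with idx; NA where out of bounds).
face_neighbors <- function(idx, dims) {
  co <- index_to_coord(idx, dims)
  offs <- face_offsets()
  lapply(seq_len(6), function(k) {
    nb <- sweep(co, 2, offs[k, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    out <- rep(NA_integer_, length(idx))
    out[ok] <- (nb[ok, 3] - 1L) * dims[1] * dims[2] +
      (nb[ok, 2] - 1L) * dims[1] + nb[ok, 1]
    out
  })
}

#' Ventricle edge voxels
#'
#' Returns the linear indices (sorted ascending) of ventricle voxels that have
#' at least one face (6-connected) neighbor outside the ventricle label set;
#' a neighbor beyond the grid boundary counts as outside.
#'
#' @param labels a `vb_labels`.
#' @return integer vector of linear voxel indices; empty (with a warning) if
#'   no voxel carries a ventricle label.
#' @export
find_edge_voxels <- function(labels) {
  stopifnot(inherits(labels, "vb_labels"))
  vm <- ventricle_mask(labels)
  idx <- which(vm)
  if (length(idx) == 0L) {
    warning("label volume contains no ventricle voxels")
    return(integer(0))
  }
  dims <- dim(vm)
  nbs <- face_neighbors(idx, dims)
  interior <- Reduce(`&`, lapply(nbs, function(nb) !is.na(nb) & vm[pmax(nb, 1L)]))
  sort(idx[!interior])
}

#' Partition the voxels adjacent to the ventricle edge
#'
#' Every non-ventricle face-neighbor of an edge voxel is assigned to the
#' adjacent-white-matter set (AWM) if it carries the white-matter label, and
#' to the adjacent-non-white-matter set (ANWM) otherwise.
#'
#' @param labels a `vb_labels`.
#' @param edges edge voxel indices from [find_edge_voxels()] on the same
#'   label volume.
#' @return a `vb_adjacency`: list with sorted integer index sets
#'   `edge_voxels`, `awm`, `anwm`.
#' @export
partition_adjacent <- function(labels, edges) {
  stopifnot(inherits(labels, "vb_labels"))
  if (length(edges) == 0L) {
    return(structure(list(edge_voxels = integer(0), awm = integer(0),
                          anwm = integer(0)), class = "vb_adjacency"))
  }
  vm <- ventricle_mask(labels)
  dims <- dim(vm)
  nbs <- unlist(face_neighbors(edges, dims))
  nbs <- unique(nbs[!is.na(nbs)])
  nbs <- nbs[!vm[nbs]]
  wm_code <- labels$label_codes[["white_matter"]]
  is_wm <- labels$data[nbs] == wm_code
  structure(list(edge_voxels = sort(as.integer(edges)),
                 awm = sort(nbs[is_wm]),
                 anwm = sort(nbs[!is_wm])),
            class = "vb_adjacency")
}

#' Dilate the lateral ventricles into adjacent white matter
#'
#' Exactly `round(coefficient * |AWM|)` adjacent-white-matter voxels (rounding
#' half away from zero), chosen uniformly without replacement under `seed`,
#' take the intensity and label of their nearest ventricle edge voxel
#' (Euclidean distance in voxel units; ties broken toward the smallest linear
#' index). Optionally, voxels that become the new ventricle boundary are then
#' redrawn from the empirical intensity distribution of the adjacent
#' non-white-matter set, keeping boundary statistics realistic; when that set
#' is empty the re-draw is a no-op. A coefficient of 0 is a strict no-op.
#'
#' @param vol a `vb_volume`.
#' @param labels the matching `vb_labels`.
#' @param coefficient dilation coefficient in `[0, 1]`.
#' @param seed integer seed for the voxel selection (and re-draw).
#' @param redraw_peripheral logical, default `TRUE`.
#' @return list with elements `volume`, `labels` (updated copies) and
#'   `replaced` (linear indices of the replaced AWM voxels).
#' @export
dilate_ventricles <- function(vol, labels, coefficient, seed,
                              redraw_peripheral = TRUE) {
  stopifnot(inherits(vol, "vb_volume"), inherits(labels, "vb_labels"))
  check_same_shape(vol, labels, "intensity and label volumes")
  if (!is.finite(coefficient) || coefficient < 0 || coefficient > 1) {
    stop("`coefficient` must lie in [0, 1]", call. = FALSE)
  }
  if (coefficient == 0) {
    return(list(volume = vol, labels = labels, replaced = integer(0)))
  }
  edges <- find_edge_voxels(labels)
  adj <- partition_adjacent(labels, edges)
  k <- as.integer(round_half_away(coefficient * length(adj$awm)))
  if (k == 0L) {
    return(list(volume = vol, labels = labels, replaced = integer(0)))
  }
  sel <- if (k == length(adj$awm)) adj$awm else {
    pick <- with_seed(derive_seed(seed, "awm-select"),
                      sample.int(length(adj$awm), k))
    adj$awm[sort(pick)]
  }

  # Nearest ventricle edge voxel per selected voxel (ties -> smallest index;
  # `edges` is sorted and which.min takes the first minimum).
  dims <- dim(vol$data)
  sc <- index_to_coord(sel, dims)
  ec <- index_to_coord(edges, dims)
  nearest <- vapply(seq_len(nrow(sc)), function(i) {
    d2 <- (ec[, 1] - sc[i, 1])^2 + (ec[, 2] - sc[i, 2])^2 +
      (ec[, 3] - sc[i, 3])^2
    edges[which.min(d2)]
  }, integer(1))

  new_data <- vol$data
  new_lab <- labels$data
  new_data[sel] <- vol$data[nearest]
  new_lab[sel] <- labels$data[nearest]
  new_labels <- label_volume(new_lab, label_codes = labels$label_codes,
                             spacing = labels$spacing)

  if (isTRUE(redraw_peripheral) && length(adj$anwm) > 0L) {
    new_edges <- find_edge_voxels(new_labels)
    newly_peripheral <- intersect(sel, new_edges)
    if (length(newly_peripheral) > 0L) {
      pool <- vol$data[adj$anwm]
      draw <- with_seed(derive_seed(seed, "peripheral-redraw"),
                        sample(pool, length(newly_peripheral), replace = TRUE))
      new_data[newly_peripheral] <- draw
    }
  }

  list(volume = volume(new_data, spacing = vol$spacing),
       labels = new_labels,
       replaced = sel)
}

#' Surrogate ground-truth map from perturbed/original pairs
#'
#' The cohort-average absolute difference between perturbed and unperturbed
#' volumes marks where the known age signal was injected. The map is
#' normalized to a probability density (sums to 1); the support is the set of
#' voxels with a strictly positive average difference.
#'
#' @param pairs non-empty list; each element a list/pair whose first entry is
#'   the perturbed `vb_volume` (or array) and second the original.
#' @return a `vb_ground_truth`: list with `density` (3D array summing to 1)
#'   and `support` (logical 3D array).
#' @export
synthesize_ground_truth <- function(pairs) {
  if (length(pairs) == 0L) stop("need at least one pair", call. = FALSE)
  acc <- NULL
  for (p in pairs) {
    pert <- as_grid(p[[1]])
    orig <- as_grid(p[[2]])
    check_same_shape(pert, orig, "perturbed and original volumes")
    d <- abs(pert - orig)
    if (is.null(acc)) acc <- d else {
      check_same_shape(acc, d, "pairs")
      acc <- acc + d
    }
  }
  m <- acc / length(pairs)
  tot <- sum(m)
  if (tot == 0) {
    stop("all perturbed volumes equal their originals; nothing to normalize",
         call. = FALSE)
  }
  structure(list(density = m / tot, support = m > 0),
            class = "vb_ground_truth")
}

#' @export
print.vb_ground_truth <- function(x, ...) {
  cat(sprintf("<vb_ground_truth> %s voxels, support %d\n",
              paste(dim(x$density), collapse = "x"), sum(x$support)))
  invisible(x)
}
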