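#' Parameters for the synthetic brain phantom
#'
#' The phantom is the benchmark's stand-in for FreeSurfer-processed
#' T1-weighted scans: two ellipsoidal lateral ventricles inside a white-matter
#' ellipsoid wrapped by a gray-matter shell, all against a dark background.
#' The only anatomy that changes with the latent age is the ventricle size
#' (semi-axes grow linearly with age), so the age signal a regressor can learn
#' coincides with the structure the perturbation module later dilates. An
#' optional cortical-thinning switch adds a second, weaker age effect and is
#' off by default.
#'
#' @param grid_size voxels per axis; must be a power of two and at least 16 so
#'   that four 2x pooling stages remain valid.
#' @param ventricle_base_radius base ventricle radius scale in voxels.
#' @param ventricle_age_slope radius growth in voxels per year (>= 0).
#' @param tissue_means named intensity means for `ventricle`, `white_matter`,
#'   `gray_matter`, `background`; T1w-like contrast requires the ventricle
#'   (CSF) mean below the white-matter mean.
#' @param tissue_sds named intensity standard deviations, same names.
#' @param age_range two-element numeric, minimum and maximum age in years.
#' @param cortical_thinning logical; if `TRUE` the gray shell thins with age.
#' @param label_codes role-to-code map, FreeSurfer aseg codes by default.
#' @return an object of class `vb_phantom_params`.
#' @examples
#' p <- phantom_params(grid_size = 16)
#' s <- generate_phantom(60, p, seed = 1)
#' sum(ventricle_mask(s$labels))
#' @export
phantom_params <- function(grid_size = 32,
                           ventricle_base_radius = 1.5,
                           ventricle_age_slope = 0.04,
                           tissue_means = c(ventricle = 30, white_matter = 110,
                                            gray_matter = 70, background = 0),
                           tissue_sds = c(ventricle = 5, white_matter = 6,
                                          gray_matter = 6, background = 2),
                           age_range = c(40, 90),
                           cortical_thinning = FALSE,
                           label_codes = fs_label_codes()) {
  if (grid_size < 16 || !is_power_of_two(grid_size)) {
    stop("`grid_size` must be a power of two >= 16", call. = FALSE)
  }
  roles <- c("ventricle", "white_matter", "gray_matter", "background")
  stopifnot(all(roles %in% names(tissue_means)),
            all(roles %in% names(tissue_sds)))
  if (anyDuplicated(tissue_means[roles])) {
    stop("`tissue_means` must be pairwise distinct", call. = FALSE)
  }
  if (tissue_means[["ventricle"]] >= tissue_means[["white_matter"]]) {
    stop("T1w-like contrast requires ventricle mean < white-matter mean",
         call. = FALSE)
  }
  if (ventricle_age_slope < 0) {
    stop("`ventricle_age_slope` must be >= 0", call. = FALSE)
  }
  if (length(age_range) != 2L || age_range[1] >= age_range[2]) {
    stop("`age_range` must be increasing [min, max]", call. = FALSE)
  }
  structure(list(grid_size = as.integer(grid_size),
                 ventricle_base_radius = ventricle_base_radius,
                 ventricle_age_slope = ventricle_age_slope,
                 tissue_means = tissue_means,
                 tissue_sds = tissue_sds,
                 age_range = as.double(age_range),
                 cortical_thinning = cortical_thinning,
                 label_codes = label_codes),
            class = "vb_phantom_params")
}

# Voxels inside an axis-aligned ellipsoid. cx/ax in voxel units.
ellipsoid_mask <- function(n, cx, ax) {
  ctr <- (n + 1) / 2
  g <- seq_len(n)
  dx <- (g - ctr - cx[1]) / ax[1]
  dy <- (g - ctr - cx[2]) / ax[2]
  dz <- (g - ctr - cx[3]) / ax[3]
  outer(outer(dx^2, dy^2, `+`), dz^2, `+`) <= 1
}

#' Generate one synthetic subject
#'
#' Builds the label geometry for the requested age, then draws intensities as
#' the tissue mean plus zero-mean Gaussian noise (clipped at zero). At a fixed
#' seed the ventricle voxel set grows monotonically with age because the
#' ellipsoid semi-axes are non-decreasing in age, so older phantoms' ventricle
#' masks contain younger ones'.
#'
#' @param age age in years; must lie within `params$age_range`.
#' @param params a [phantom_params()] object.
#' @param seed integer seed; the subject is a pure function of
#'   `(age, params, seed)`.
#' @param subject_id optional id string.
#' @return a `vb_subject`: list with `subject_id`, `age`, `volume`
#'   (`vb_volume`) and `labels` (`vb_labels`).
#' @export
generate_phantom <- function(age, params, seed, subject_id = NULL) {
  stopifnot(inherits(params, "vb_phantom_params"))
  rng <- params$age_range
  if (age < rng[1] || age > rng[2]) {
    stop(sprintf("age %.2f outside the phantom age range [%.2f, %.2f]",
                 age, rng[1], rng[2]), call. = FALSE)
  }
  n <- params$grid_size
  codes <- params$label_codes

  thin <- if (isTRUE(params$cortical_thinning)) {
    1 - 0.0008 * (age - rng[1])
  } else 1
  outer_ax <- c(0.40, 0.44, 0.40) * n * thin
  wm_ax <- c(0.33, 0.37, 0.33) * n
  r <- params$ventricle_base_radius + params$ventricle_age_slope * age
  vent_ax <- c(0.8, 1.6, 0.8) * r
  off <- 0.13 * n

  lab <- array(codes[["background"]], dim = c(n, n, n))
  lab[ellipsoid_mask(n, c(0, 0, 0), outer_ax)] <- codes[["gray_matter"]]
  lab[ellipsoid_mask(n, c(0, 0, 0), wm_ax)] <- codes[["white_matter"]]
  lab[ellipsoid_mask(n, c(-off, 0, 0), vent_ax)] <- codes[["ventricle_left"]]
  lab[ellipsoid_mask(n, c(+off, 0, 0), vent_ax)] <- codes[["ventricle_right"]]

  role_of <- c("background", "white_matter", "gray_matter",
               "ventricle", "ventricle")
  names(role_of) <- as.character(codes[c("background", "white_matter",
                                         "gray_matter", "ventricle_left",
                                         "ventricle_right")])
  roles <- role_of[as.character(lab)]
  mu <- params$tissue_means[roles]
  sdv <- params$tissue_sds[roles]
  noise <- with_seed(seed, rnorm(n^3))
  intens <- array(pmax(0, mu + noise * sdv), dim = c(n, n, n))

  labels <- label_volume(lab, label_codes = codes)
  vm <- ventricle_mask(labels)
  gm <- labels$data == codes[["gray_matter"]]
  wm <- labels$data == codes[["white_matter"]]
  if (!any(vm) || !any(gm) || !any(wm)) {
    stop("phantom geometry degenerate: a tissue class is empty", call. = FALSE)
  }

  structure(list(subject_id = subject_id %||% sprintf("sub-%08d", seed %% 1e8),
                 age = age,
                 volume = volume(intens),
                 labels = labels),
            class = "vb_subject")
}

#' @export
print.vb_subject <- function(x, ...) {
  cat(sprintf("<vb_subject> %s, age %.1f y, %s voxels\n", x$subject_id, x$age,
              paste(dim(x$volume$data), collapse = "x")))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Ages are sampled uniformly over the phantom age range; each subject's
#' anatomy and noise then derive from a per-subject sub-seed, so the cohort is
#' reproducible and insensitive to the order in which subjects are realized.
#'
#' @param n number of subjects (>= 0).
#' @param params a [phantom_params()] object.
#' @param seed integer seed.
#' @return list of `vb_subject` with unique ids.
#' @export
generate_cohort <- function(n, params, seed) {
  if (length(n) != 1L || is.na(n) || n < 0) {
    stop("`n` must be a non-negative count", call. = FALSE)
  }
  n <- as.integer(n)
  if (n == 0L) return(list())
  rng <- params$age_range
  ages <- with_seed(derive_seed(seed, "cohort-ages"), runif(n, rng[1], rng[2]))
  lapply(seq_len(n), function(i) {
    generate_phantom(ages[i], params,
                     seed = derive_seed(seed, paste0("subject-", i)),
                     subject_id = sprintf("sub-%04d", i))
  })
}

#' Split a cohort into disjoint subsets
#'
#' Subset sizes are `floor(n * fraction)` with the remainder assigned to the
#' first subset; membership is randomized under `seed` but each subset keeps
#' the cohort's original subject order.
#'
#' @param subjects list of subjects (any list).
#' @param fractions non-negative proportions summing to 1 (within 1e-9);
#'   names, if any, become subset names.
#' @param seed integer seed.
#' @return named list of disjoint sub-lists whose union is `subjects`.
#' @export
split_cohort <- function(subjects, fractions, seed) {
  frac_names <- names(fractions)
  fractions <- as.double(fractions)
  if (any(fractions < 0)) stop("`fractions` must be non-negative", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("`fractions` must sum to 1", call. = FALSE)
  }
  n <- length(subjects)
  sizes <- floor(n * fractions)
  sizes[1] <- sizes[1] + (n - sum(sizes))
  perm <- with_seed(derive_seed(seed, "split"), sample.int(max(n, 1L), n))
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  out <- lapply(seq_along(fractions), function(i) {
    if (sizes[i] == 0L) return(subjects[integer(0)])
    subjects[sort(perm[starts[i]:ends[i]])]
  })
  names(out) <- frac_names %||% paste0("subset", seq_along(fractions))
  out
}
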