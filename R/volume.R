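#' Intensity and label volume containers
#'
#' A `vb_volume` holds a cubic 3D scalar intensity grid with per-axis voxel
#' spacing in millimetres. A `vb_labels` holds a same-shaped integer grid of
#' tissue codes together with the mapping from anatomical roles to codes.
#' Default codes follow the FreeSurfer `aseg` convention for the structures
#' the benchmark uses (left/right lateral ventricle = 4/43).
#'
#' @param data 3D numeric array, equal extent on all three axes, finite values.
#' @param spacing numeric length-3 vector of voxel edge lengths in mm.
#' @return an object of class `vb_volume`.
#' @examples
#' v <- volume(array(rnorm(8), dim = c(2, 2, 2)))
#' dim(v$data)
#' @export
volume <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  if (length(unique(dim(data))) != 1L) {
    stop("volume grids must have equal extent on all three axes", call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("volume intensities must be finite", call. = FALSE)
  }
  spacing <- as.double(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be three positive voxel sizes (mm)", call. = FALSE)
  }
  structure(list(data = data, spacing = spacing), class = "vb_volume")
}

#' Default FreeSurfer-style label codes
#'
#' @return named integer vector mapping anatomical roles to label codes.
#' @export
fs_label_codes <- function() {
  c(background = 0L, white_matter = 2L, gray_matter = 3L,
    ventricle_left = 4L, ventricle_right = 43L)
}

#' @rdname volume
#' @param label_codes named integer vector mapping roles (`background`,
#'   `white_matter`, `gray_matter`, `ventricle_left`, `ventricle_right`)
#'   to integer codes.
#' @export
label_volume <- function(data, label_codes = fs_label_codes(),
                         spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  storage.mode(data) <- "integer"
  required <- c("background", "white_matter", "gray_matter",
                "ventricle_left", "ventricle_right")
  if (!all(required %in% names(label_codes))) {
    stop("`label_codes` must name: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  seen <- unique(as.vector(data))
  unknown <- setdiff(seen, as.integer(label_codes))
  if (length(unknown) > 0L) {
    stop("label grid contains codes absent from `label_codes`: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  spacing <- as.double(spacing)
  structure(list(data = data, label_codes = label_codes, spacing = spacing),
            class = "vb_labels")
}

#' @export
print.vb_volume <- function(x, ...) {
  cat(sprintf("<vb_volume> %s voxels, spacing %s mm, range [%.3g, %.3g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.vb_labels <- function(x, ...) {
  tab <- table(x$data)
  cat(sprintf("<vb_labels> %s voxels; codes: %s\n",
              paste(dim(x$data), collapse = "x"),
              paste(sprintf("%s=%s", names(tab), as.integer(tab)),
                    collapse = ", ")))
  invisible(x)
}

ventricle_codes <- function(labels) {
  as.integer(labels$label_codes[c("ventricle_left", "ventricle_right")])
}

#' Logical masks derived from a label volume
#'
#' `brain_mask()` marks every non-background voxel; it is the mask used by the
#' masked-gradient attribution method. `ventricle_mask()` marks lateral
#' ventricle voxels (both hemispheres).
#'
#' @param labels a `vb_labels` object.
#' @return logical 3D array of the label grid's shape.
#' @export
brain_mask <- function(labels) {
  stopifnot(inherits(labels, "vb_labels"))
  labels$data != labels$label_codes[["background"]]
}

#' @rdname brain_mask
#' @export
ventricle_mask <- function(labels) {
  stopifnot(inherits(labels, "vb_labels"))
  array(labels$data %in% ventricle_codes(labels), dim = dim(labels$data))
}

check_same_shape <- function(a, b, what = "grids") {
  da <- if (is.array(a)) dim(a) else dim(a$data)
  db <- if (is.array(b)) dim(b) else dim(b$data)
  if (!identical(as.integer(da), as.integer(db))) {
    stop(sprintf("%s must have identical shapes (%s vs %s)", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")),
         call. = FALSE)
  }
  invisible(TRUE)
}

as_grid <- function(x) {
  if (inherits(x, "vb_volume") || inherits(x, "vb_labels")) return(x$data)
  if (inherits(x, "vb_saliency")) return(x$density)
  if (is.array(x)) return(x)
  stop("expected a volume-like object or 3D array", call. = FALSE)
}
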