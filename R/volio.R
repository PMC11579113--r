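#' Read and write volumes as NIfTI-1
#'
#' Intensity volumes are written as float64 so that a write/read round trip
#' reproduces the grid bit-for-bit; label volumes are written as int32.
#' Gzipped files (`.nii.gz`) are handled transparently by the NIfTI backend.
#' Voxel spacing is carried in the NIfTI `pixdim` field (stored as float32 by
#' the standard, hence round-trips within about 1e-7 relative).
#'
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `read_volume()` returns a `vb_volume`; `read_labels()` a
#'   `vb_labels`; the writers return `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- read_nifti_checked(path)
  volume(array(as.double(img), dim = dim(img)[1:3]),
         spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname read_volume
#' @param label_codes role-to-code map for the labels being read.
#' @export
read_labels <- function(path, label_codes = fs_label_codes()) {
  img <- read_nifti_checked(path)
  label_volume(array(as.integer(round(as.double(img))), dim = dim(img)[1:3]),
               label_codes = label_codes,
               spacing = RNifti::pixdim(img)[1:3])
}

read_nifti_checked <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file does not exist: %s", path), call. = FALSE)
  }
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) {
                    stop(sprintf("cannot parse '%s' as NIfTI: %s",
                                 path, conditionMessage(e)), call. = FALSE)
                  })
  d <- dim(img)
  if (length(d) < 3L || any(d[-(1:3)] > 1L)) {
    stop(sprintf("'%s': header field `dim` describes a %dD image; expected 3D",
                 path, length(d)), call. = FALSE)
  }
  img
}

#' @rdname read_volume
#' @param x a `vb_volume` or `vb_labels`.
#' @export
write_volume <- function(x, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop(sprintf("parent directory does not exist: %s", dir), call. = FALSE)
  }
  is_labels <- inherits(x, "vb_labels")
  if (!is_labels && !inherits(x, "vb_volume")) {
    stop("`x` must be a vb_volume or vb_labels", call. = FALSE)
  }
  img <- RNifti::asNifti(x$data)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path,
                     datatype = if (is_labels) "int32" else "double")
  invisible(path)
}

#' Downsample a volume by an integer factor
#'
#' Intensity volumes are reduced by the mean of each `factor^3` block (this is
#' the 2x reduction used ahead of network training); label volumes take each
#' block's modal label, with ties broken toward the smallest label code so the
#' result is deterministic. Spacing is multiplied by the factor. The block
#' mean conserves the grid mean exactly, and the modal rule can never
#' introduce a label absent from the block.
#'
#' @param x a `vb_volume` or `vb_labels`.
#' @param factor integer that divides every axis length.
#' @param mode `"auto"` (by class), `"intensity"` (block mean) or `"label"`
#'   (block mode).
#' @return the reduced object of the same class.
#' @export
downsample <- function(x, factor, mode = c("auto", "intensity", "label")) {
  mode <- match.arg(mode)
  is_labels <- inherits(x, "vb_labels")
  if (mode == "auto") mode <- if (is_labels) "label" else "intensity"
  factor <- as.integer(factor)
  if (factor < 1L) stop("`factor` must be >= 1", call. = FALSE)
  d <- dim(x$data)
  if (any(d %% factor != 0L)) {
    stop(sprintf("factor %d does not divide grid extent %s", factor,
                 paste(d, collapse = "x")), call. = FALSE)
  }
  if (factor == 1L) return(x)
  m <- d %/% factor
  g <- seq_len(d[1])
  bx <- (g - 1L) %/% factor            # 0-based block coordinate per axis
  bid <- outer(outer(bx, bx * m[1], `+`), bx * m[1] * m[2], `+`) + 1L

  if (mode == "intensity") {
    sums <- rowsum(as.double(x$data), as.vector(bid))
    out <- array(sums / factor^3, dim = m)
    volume(out, spacing = x$spacing * factor)
  } else {
    codes <- sort(unique(as.vector(x$data)))
    counts <- table(factor(as.vector(bid), levels = seq_len(prod(m))),
                    factor(as.vector(x$data), levels = codes))
    pick <- codes[max.col(counts, ties.method = "first")]
    label_volume(array(as.integer(pick), dim = m),
                 label_codes = if (is_labels) x$label_codes else fs_label_codes(),
                 spacing = x$spacing * factor)
  }
}

#' Write and read a cohort table
#'
#' @param table data.frame with at least `subject_id`, `age`, `split`.
#' @param path CSV path.
#' @return the path (write) or the data.frame (read).
#' @export
write_cohort_table <- function(table, path) {
  stopifnot(all(c("subject_id", "age", "split") %in% names(table)))
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
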