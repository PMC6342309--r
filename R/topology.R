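#' Binary slice: thresholded low-attenuation map of one CT slice
#'
#' Encodes the binary-image convention used throughout the package:
#' 0 marks a low-attenuation lung pixel (attenuation strictly below the
#' threshold, inside the mask) and 1 marks everything else (normal lung
#' or outside the lung). The 0 set is the emphysema candidate set whose
#' topology is summarized by the Betti numbers.
#'
#' @param values integer matrix over \{0, 1\}.
#' @param threshold_hu the HU cutoff that produced it (`NA` if constructed
#'   directly).
#' @param n_lung_pixels count of inside-mask pixels (`NA` if unknown).
#' @return An object of class `binary_slice` with fields `values`,
#'   `threshold_hu`, `n_lung_pixels`, `n_low_pixels`.
#' @export
binary_slice <- function(values, threshold_hu = NA_real_,
                         n_lung_pixels = NA_integer_) {
  if (!is.matrix(values) || length(values) == 0L)
    stop_heqct("heqct_validation_error", "binary values must be a non-empty matrix")
  v <- matrix(as.integer(values != 0), nrow = nrow(values))
  structure(list(values = v,
                 threshold_hu = threshold_hu,
                 n_lung_pixels = as.integer(n_lung_pixels),
                 n_low_pixels = sum(v == 0L)),
            class = "binary_slice")
}

#' @export
print.binary_slice <- function(x, ...) {
  cat(sprintf("<binary_slice %d x %d, threshold %s HU, %d low / %s lung pixels>\n",
              nrow(x$values), ncol(x$values),
              format(x$threshold_hu), x$n_low_pixels,
              format(x$n_lung_pixels)))
  invisible(x)
}

#' Threshold a CT slice into a binary low-attenuation map
#'
#' A pixel becomes 0 (low attenuation) iff it lies inside the lung mask
#' AND its attenuation is strictly below `threshold_hu`; ties and all
#' other pixels become 1. The conventional emphysema thresholds are
#' -950, -910 and -880 HU, but any value is accepted.
#'
#' @param slice an [hu_slice()].
#' @param mask a [lung_mask()] of the same shape with at least one inside
#'   pixel.
#' @param threshold_hu numeric HU cutoff.
#' @return A [binary_slice()].
#' @export
binarize <- function(slice, mask, threshold_hu) {
  stopifnot(inherits(slice, "hu_slice"), inherits(mask, "lung_mask"))
  if (!identical(dim(slice$values), dim(mask$values)))
    stop_heqct("heqct_geometry_error", "slice and mask shapes differ")
  inside <- mask$values
  if (!any(inside))
    stop_heqct("heqct_degenerate_error", "mask has no lung pixels")
  low <- inside & (slice$values < threshold_hu)
  binary_slice(1L - (low * 1L), threshold_hu = threshold_hu,
               n_lung_pixels = sum(inside))
}

.as_binary_matrix <- function(b) {
  if (inherits(b, "binary_slice")) b$values
  else if (is.matrix(b)) matrix(as.integer(b != 0), nrow = nrow(b))
  else stop_heqct("heqct_validation_error", "expected a binary_slice or matrix")
}

#' Connected-component labels of a binary matrix
#'
#' Thin wrapper around the compiled union-find labeller. Labels the
#' pixels equal to `fg` under the given connectivity; other pixels get 0.
#'
#' @param m integer/logical matrix.
#' @param fg foreground value to label (0 or 1).
#' @param connectivity 4 or 8.
#' @return Integer matrix of labels 1..k (0 elsewhere).
#' @export
label_components <- function(m, fg = 0L, connectivity = 8L) {
  m <- .as_binary_matrix(m)
  .label_components(m, as.integer(fg), as.integer(connectivity))
}

#' Betti numbers of the low-attenuation set of a binary slice
#'
#' `b0` counts connected components of the 0 (low-attenuation) set;
#' `b1` counts its holes, i.e. connected components of the 1 set that do
#' not touch the grid border — the normal-lung islands completely
#' surrounded by low-attenuation tissue. Outside-lung pixels are 1 and
#' connect to the border, so they are never counted as holes; the mask is
#' not needed at topology time.
#'
#' The default dual connectivity pair (8 for the 0 set, 4 for the 1 set)
#' is the standard digital-topology pairing under which
#' `b0 - b1 == euler_characteristic()` holds identically; the swapped
#' pair (4, 8) is available for sensitivity analysis.
#'
#' @param b a [binary_slice()] or 0/1 matrix.
#' @param connectivity integer length-2 vector: connectivity of the
#'   0 (foreground) set then of the 1 (background) set; must be
#'   `c(8, 4)` or `c(4, 8)`.
#' @return List with integer fields `b0`, `b1`.
#' @export
betti_numbers <- function(b, connectivity = c(8L, 4L)) {
  m <- .as_binary_matrix(b)
  connectivity <- as.integer(connectivity)
  if (length(connectivity) != 2L ||
      !all(sort(connectivity) == c(4L, 8L)))
    stop_heqct("heqct_validation_error",
               "connectivity must be c(8, 4) or c(4, 8)")
  lab0 <- .label_components(m, 0L, connectivity[1])
  b0 <- max(lab0)
  lab1 <- .label_components(m, 1L, connectivity[2])
  if (max(lab1) == 0L) {
    b1 <- 0L
  } else {
    border <- unique(c(lab1[1, ], lab1[nrow(lab1), ],
                       lab1[, 1], lab1[, ncol(lab1)]))
    b1 <- length(setdiff(seq_len(max(lab1)), border))
  }
  list(b0 = as.integer(b0), b1 = as.integer(b1))
}

#' Euler characteristic of the low-attenuation set by cell counting
#'
#' Builds the cubical complex of the 0 set — each 0 pixel contributes a
#' closed unit square with its 4 vertices and 4 edges, shared cells
#' counted once — and returns chi = V - E + F. For the closed-square
#' complex two diagonal pixels share a vertex, so this chi corresponds to
#' 8-connectivity of the 0 set and satisfies `b0 - b1 == chi` under the
#' default connectivity pairing. Serves as an independent consistency
#' oracle for [betti_numbers()].
#'
#' @param b a [binary_slice()] or 0/1 matrix.
#' @return Integer Euler characteristic of the 0 set (0 for an empty set).
#' @export
euler_characteristic <- function(b) {
  m <- .as_binary_matrix(b)
  idx <- which(m == 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0L)
  nr1 <- nrow(m) + 1L  # vertex grid stride
  r <- idx[, 1]; c <- idx[, 2]
  # vertices of pixel (r, c): lattice points (r-1..r, c-1..c), id = row + col * nr1
  vid <- c((r - 1L) + (c - 1L) * nr1, r + (c - 1L) * nr1,
           (r - 1L) + c * nr1,        r + c * nr1)
  # horizontal edges keyed by left vertex, vertical edges by top vertex;
  # offset the two families so their ids never collide
  h <- c((r - 1L) + (c - 1L) * nr1, r + (c - 1L) * nr1)
  v <- c((r - 1L) + (c - 1L) * nr1, (r - 1L) + c * nr1)
  eid <- c(2L * h, 2L * v + 1L)
  V <- length(unique(vid))
  E <- length(unique(eid))
  as.integer(V - E + nrow(idx))
}

#' Export a binary slice as a PNG image (0 pixels black)
#'
#' @param b a [binary_slice()] or 0/1 matrix.
#' @param file output path.
#' @export
write_binary_png <- function(b, file) {
  if (!requireNamespace("png", quietly = TRUE))
    stop_heqct("heqct_format_error", "package 'png' is required for PNG export")
  png::writePNG(.as_binary_matrix(b), file)
  invisible(file)
}
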