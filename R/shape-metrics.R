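# Cell-shape descriptors computed from binary masks.

#' Shape factor of an object
#'
#' The shape factor is \eqn{4\pi A / P^2}: 1.0 for a perfect circle
#' (the isoperimetric maximum) and near 0 for a flattened or very
#' elongated object.
#'
#' @param area Object area (\eqn{\mu m^2} or px\eqn{^2}); must be positive.
#' @param perimeter Object perimeter (same length unit); must be positive.
#' @return Dimensionless shape factor, vectorized over inputs.
#' @examples
#' shape_factor(pi * 50^2, 2 * pi * 50)  # circle -> 1
#' shape_factor(4, 8)                    # unit square -> pi/4
#' @export
shape_factor <- function(area, perimeter) {
  if (any(!is.finite(area)) || any(!is.finite(perimeter)) ||
      any(area <= 0) || any(perimeter <= 0))
    stop("'area' and 'perimeter' must be positive and finite", call. = FALSE)
  4 * pi * area / perimeter^2
}

#' Elongation factor of an object
#'
#' The reciprocal of [shape_factor()]: 1.0 for a circle, larger for
#' elongated objects.
#'
#' @inheritParams shape_factor
#' @return Dimensionless elongation factor.
#' @export
elongation_factor <- function(area, perimeter) {
  1 / shape_factor(area, perimeter)
}

#' Crofton perimeter estimate of a binary mask
#'
#' Estimates the object perimeter from intercept counts along four line
#' directions (0, 45, 90, 135 degrees) via the Crofton formula
#' \eqn{P = \pi \, \mathrm{mean}_\theta[\mathrm{chords}(\theta) \cdot d(\theta)]},
#' where \eqn{d} is the line spacing (1 for axial, \eqn{1/\sqrt2} for
#' diagonal families). Counting boundary pixels instead would
#' systematically overestimate P and deflate the shape factor.
#'
#' @param mask Logical or 0/1 matrix (one or more foreground objects).
#' @return Perimeter in pixel units.
#' @export
crofton_perimeter <- function(mask) {
  m <- as_binary_matrix(mask)
  nr <- nrow(m); nc <- ncol(m)
  # pad so transitions at the image border are counted
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  c_h  <- sum(p[, -1] != p[, -ncol(p)])                       # along rows
  c_v  <- sum(p[-1, ] != p[-nrow(p), ])                       # along columns
  c_d1 <- sum(p[-1, -1] != p[-nrow(p), -ncol(p)])             # "\" diagonal
  c_d2 <- sum(p[-1, -ncol(p)] != p[-nrow(p), -1])             # "/" diagonal
  pi * mean(c(c_h / 2, c_v / 2, c_d1 / (2 * sqrt(2)), c_d2 / (2 * sqrt(2))))
}

#' Shape descriptors of a single-cell mask
#'
#' Computes area (pixel count), perimeter (Crofton estimate, see
#' [crofton_perimeter()]), shape factor \eqn{4\pi A/P^2} and elongation
#' factor \eqn{P^2/4\pi A} for a mask containing exactly one connected
#' (8-connectivity) foreground component.
#'
#' @param mask Logical or 0/1 matrix with a single connected object.
#' @param pixel_size Physical pixel size in \eqn{\mu}m/px (default 1, i.e.
#'   pixel units).
#' @return A one-row data frame with columns `area`, `perimeter`,
#'   `shape_factor`, `elongation_factor`.
#' @export
descriptors_from_mask <- function(mask, pixel_size = 1) {
  stopifnot_scalar(pixel_size)
  if (pixel_size <= 0) stop("'pixel_size' must be positive", call. = FALSE)
  m <- as_binary_matrix(mask)
  lab <- label_components8(m)
  ncomp <- max(lab)
  if (ncomp != 1L)
    stop(sprintf("mask must contain exactly one connected component, found %d",
                 ncomp), call. = FALSE)
  area <- sum(m) * pixel_size^2
  perim <- crofton_perimeter(m) * pixel_size
  data.frame(area = area, perimeter = perim,
             shape_factor = shape_factor(area, perim),
             elongation_factor = elongation_factor(area, perim))
}

#' Fraction of binucleated cells
#'
#' Assigns each nucleus to the cell whose mask contains the nucleus
#' centroid and reports the percentage of cells with two or more
#' assigned nuclei.
#'
#' @param cell_masks Integer-labelled matrix of cell masks (0 = background).
#' @param nuclei_masks Integer-labelled matrix of nucleus masks.
#' @return Percentage (0--100) of cells with >= 2 nuclei. Nuclei whose
#'   centroid falls outside every cell are counted unassigned with a
#'   warning.
#' @export
binucleation_fraction <- function(cell_masks, nuclei_masks) {
  if (!is.matrix(cell_masks) || !is.matrix(nuclei_masks) ||
      !all(dim(cell_masks) == dim(nuclei_masks)))
    stop("'cell_masks' and 'nuclei_masks' must be matrices of equal size",
         call. = FALSE)
  cells <- sort(unique(cell_masks[cell_masks > 0]))
  if (length(cells) == 0L) stop("no cells in 'cell_masks'", call. = FALSE)
  nuc_ids <- sort(unique(nuclei_masks[nuclei_masks > 0]))
  counts <- setNames(integer(length(cells)), cells)
  unassigned <- 0L
  nr <- nrow(nuclei_masks)
  for (nid in nuc_ids) {
    idx <- which(nuclei_masks == nid)
    r <- round(mean(((idx - 1L) %% nr) + 1L))
    cc <- round(mean(((idx - 1L) %/% nr) + 1L))
    owner <- cell_masks[r, cc]
    if (owner > 0) counts[as.character(owner)] <- counts[as.character(owner)] + 1L
    else unassigned <- unassigned + 1L
  }
  if (unassigned > 0L)
    warning(sprintf("%d nucleus centroid(s) fell outside every cell", unassigned))
  100 * sum(counts >= 2L) / length(cells)
}
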