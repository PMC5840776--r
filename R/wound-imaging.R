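# Wound-assay image processing: fluorescence well image -> cell mask ->
# wound region -> covered-area fraction.

#' Background-flatten and threshold a fluorescence image
#'
#' Removes slowly varying background by grayscale morphological opening
#' with a disc structuring element (a rolling-ball-style flatten filter)
#' and thresholds the residual with Otsu's method. The result is
#' invariant to uniform gain and to an added constant background: the
#' top-hat residual is normalized to \[0, 1\] before thresholding.
#'
#' @param image Nonnegative intensity matrix (or EBImage `Image`).
#' @param flatten_radius Radius of the flattening disc in pixels
#'   (default 50); must exceed the cell size for cells to survive the
#'   filter.
#' @return Logical cell mask. A constant image yields an empty mask with
#'   a warning.
#' @export
flatten_and_threshold <- function(image, flatten_radius = 50) {
  img <- as_intensity_matrix(image)
  if (flatten_radius <= 0) stop("'flatten_radius' must be positive", call. = FALSE)
  rng0 <- range(img)
  if (diff(rng0) <= .Machine$double.eps * max(1, rng0[2])) {
    warning("constant image; returning empty mask")
    return(matrix(FALSE, nrow(img), ncol(img)))
  }
  # normalize first: makes the result exactly invariant to uniform gain
  # and constant offset, and keeps grayscale morphology in [0, 1]
  img <- (img - rng0[1]) / diff(rng0)
  brush <- EBImage::makeBrush(2 * floor(flatten_radius) + 1, shape = "disc")
  bg <- EBImage::imageData(EBImage::opening(EBImage::Image(img), brush))
  tophat <- img - bg
  rng <- range(tophat)
  if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[2]))) {
    warning("image has no contrast after flattening; returning empty mask")
    return(matrix(FALSE, nrow(img), ncol(img)))
  }
  norm <- (tophat - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1), levels = 256)
  norm > thr
}

#' Wound region from the 0 h cell mask
#'
#' The wound (migration area) is the area free of cells at 0 h: the
#' cell mask is morphologically closed to bridge gaps between
#' neighbouring cells, and the largest connected (8-connectivity)
#' cell-free region of at least `min_area_frac` of the image is
#' returned. Cell-free regions touching the image border are ignored:
#' the exclusion zone is interior by construction, so border-touching
#' regions are background outside the monolayer, not the wound. The
#' selected component is dilated back by the closing radius (minus
#' actual cell pixels) to undo the erosion of the wound boundary that
#' closing causes.
#'
#' @param cell_mask_t0 Logical cell mask at 0 h.
#' @param closing_radius Radius (px) of the closing element (default 5).
#' @param min_area_frac Minimum wound area as a fraction of the image
#'   (default 0.01); below this the well is called a failed wound.
#' @return Logical wound mask.
#' @export
wound_mask_from_t0 <- function(cell_mask_t0, closing_radius = 5,
                               min_area_frac = 0.01) {
  m <- as_binary_matrix(cell_mask_t0, "cell_mask_t0")
  brush <- EBImage::makeBrush(2 * floor(closing_radius) + 1, shape = "disc")
  closed <- EBImage::imageData(EBImage::closing(EBImage::Image(m * 1), brush)) > 0.5
  lab <- label_components8(!closed)
  if (max(lab) == 0L)
    stop("no cell-free region: well did not form a defined wound area",
         call. = FALSE)
  sizes <- tabulate(lab[lab > 0L])
  # the wound is interior by construction; cell-free regions touching the
  # image border are background outside the monolayer, not the wound
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  sizes[intersect(border, seq_along(sizes))] <- 0L
  best <- which.max(sizes)
  if (sizes[best] < max(min_area_frac * length(m), 1))
    stop("largest cell-free region below minimum area: ",
         "well did not form a defined wound area", call. = FALSE)
  wound <- lab == best
  grown <- EBImage::imageData(EBImage::dilate(EBImage::Image(wound * 1), brush)) > 0.5
  grown & !m
}

#' Migration index of a well
#'
#' The percentage of the 0 h wound (migration) area covered by cell
#' pixels at 24 h.
#'
#' @param cell_mask_t24 Logical cell mask at 24 h.
#' @param wound_mask Logical wound mask from [wound_mask_from_t0()].
#' @return Percentage in \[0, 100\].
#' @export
migration_index <- function(cell_mask_t24, wound_mask) {
  m24 <- as_binary_matrix(cell_mask_t24, "cell_mask_t24")
  w <- as_binary_matrix(wound_mask, "wound_mask")
  if (!all(dim(m24) == dim(w)))
    stop("mask dimensions differ", call. = FALSE)
  if (!any(w)) stop("empty wound mask", call. = FALSE)
  100 * sum(m24 & w) / sum(w)
}

#' Score one well from its 0 h and 24 h images
#'
#' Convenience wrapper chaining [flatten_and_threshold()],
#' [wound_mask_from_t0()] and [migration_index()].
#'
#' @param img_t0,img_t24 Intensity images at 0 h and 24 h.
#' @param flatten_radius Passed to [flatten_and_threshold()].
#' @return List with `wound_area` (px), `covered_area` (px),
#'   `coverage_fraction` and `migration_index` (%).
#' @export
score_well <- function(img_t0, img_t24, flatten_radius = 50) {
  m0 <- flatten_and_threshold(img_t0, flatten_radius)
  m24 <- flatten_and_threshold(img_t24, flatten_radius)
  wound <- wound_mask_from_t0(m0)
  covered <- sum(m24 & wound)
  list(wound_area = sum(wound), covered_area = covered,
       coverage_fraction = covered / sum(wound),
       migration_index = migration_index(m24, wound))
}
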