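# Biosensor edge profiling: activity versus distance from the cell edge
# and versus local protrusion/retraction velocity.

# Signed Euclidean distance map: positive inside the mask, negative
# outside, in pixels; zero-crossing at the mask boundary.
signed_distmap <- function(mask) {
  m <- EBImage::Image(mask * 1)
  inside <- EBImage::imageData(EBImage::distmap(m))
  outside <- EBImage::imageData(EBImage::distmap(1 - m))
  inside - outside
}

edge_pixels <- function(mask) {
  er <- EBImage::imageData(
    EBImage::erode(EBImage::Image(mask * 1),
                   EBImage::makeBrush(3, shape = "box"))) > 0.5
  which(mask & !er)
}

#' Mean biosensor activity versus distance from the cell edge
#'
#' Computes the Euclidean distance transform inside the mask and bins
#' pixel activities by their distance to the nearest edge.
#'
#' @param ratio_image Biosensor ratio (activity) matrix.
#' @param mask Logical cell mask, same size.
#' @param bin_width Distance bin width in \eqn{\mu}m (default one
#'   pixel).
#' @param max_depth Maximum sampled distance from the edge in
#'   \eqn{\mu}m (default: the whole cell).
#' @param pixel_size Pixel size in \eqn{\mu}m/px (default 1).
#' @return Data frame with `distance` (bin centre, \eqn{\mu}m),
#'   `mean_activity`, `sem` and `n` per bin. Warns when the mask is
#'   thinner than one bin.
#' @export
distance_profile <- function(ratio_image, mask, bin_width = NULL,
                             max_depth = Inf, pixel_size = 1) {
  img <- ratio_image
  if (inherits(img, "Image")) img <- EBImage::imageData(img)
  if (!is.matrix(img) || !is.numeric(img) || any(!is.finite(img)))
    stop("'ratio_image' must be a finite numeric matrix", call. = FALSE)
  m <- as_binary_matrix(mask)
  if (!all(dim(img) == dim(m))) stop("image/mask dimensions differ", call. = FALSE)
  if (!any(m)) stop("empty mask", call. = FALSE)
  if (is.null(bin_width)) bin_width <- pixel_size
  if (bin_width <= 0) stop("'bin_width' must be positive", call. = FALSE)
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(m * 1))) * pixel_size
  sel <- m & d <= max_depth
  dd <- d[sel]; aa <- img[sel]
  if (max(dd) <= bin_width)
    warning("mask thinner than one distance bin; single-bin profile")
  bin <- pmax(1L, ceiling(dd / bin_width))
  n <- tabulate(bin)
  keep <- which(n > 0)
  means <- vapply(keep, function(b) mean(aa[bin == b]), numeric(1))
  sems <- vapply(keep, function(b) {
    v <- aa[bin == b]
    if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
  }, numeric(1))
  data.frame(distance = (keep - 0.5) * bin_width, mean_activity = means,
             sem = sems, n = n[keep])
}

#' Edge protrusion/retraction velocity between two masks
#'
#' For each edge pixel of `mask_t`, the signed distance to the boundary
#' of `mask_next` (positive when the edge moved outward = protrusion,
#' negative for retraction) divided by the frame interval. The
#' velocity field is the difference of the two signed distance maps, so
#' a static edge has velocity zero and swapping the masks flips every
#' sign.
#'
#' @param mask_t,mask_next Logical masks at consecutive frames.
#' @param dt Frame interval in minutes.
#' @param pixel_size Pixel size in \eqn{\mu}m/px.
#' @return List with `edge_idx` (linear indices of edge pixels of
#'   `mask_t`), `velocity` (\eqn{\mu}m/min at those pixels) and `field`
#'   (full signed-velocity matrix).
#' @export
edge_velocity <- function(mask_t, mask_next, dt, pixel_size = 1) {
  m0 <- as_binary_matrix(mask_t, "mask_t")
  m1 <- as_binary_matrix(mask_next, "mask_next")
  if (!all(dim(m0) == dim(m1))) stop("mask dimensions differ", call. = FALSE)
  if (!any(m0) || !any(m1)) stop("empty mask", call. = FALSE)
  stopifnot_scalar(dt); if (dt <= 0) stop("'dt' must be positive", call. = FALSE)
  field <- (signed_distmap(m1) - signed_distmap(m0)) * pixel_size / dt
  idx <- edge_pixels(m0)
  list(edge_idx = idx, velocity = field[idx], field = field)
}

#' Activity map over distance-from-edge and edge velocity
#'
#' For every frame pair, each pixel within `sample_depth` of the edge
#' contributes its activity at (its distance to the edge, the local
#' velocity of its nearest edge pixel). Bin means and counts form the
#' map; the per-category summary splits edges into protruding
#' (v > eps), retracting (v < -eps) and static (|v| <= eps).
#'
#' @param frames List of ratio (activity) matrices.
#' @param masks List of logical masks, same length and sizes.
#' @param dt Frame interval in minutes.
#' @param pixel_size Pixel size in \eqn{\mu}m/px.
#' @param sample_depth Sampling depth from the edge in \eqn{\mu}m
#'   (default 5).
#' @param distance_breaks,velocity_breaks Bin edges (\eqn{\mu}m and
#'   \eqn{\mu}m/min). Defaults: one-pixel distance bins to
#'   `sample_depth`; velocity bins of 0.5 \eqn{\mu}m/min spanning the
#'   observed range.
#' @param static_eps Half-width of the static velocity band
#'   (\eqn{\mu}m/min, default 0.2).
#' @return List of class `edge_sample_map`: `mean_activity` and
#'   `sample_counts` matrices (distance x velocity bins), the bin
#'   edges, `n_sampled` (total pixels sampled) and `categories` (mean
#'   activity and n for protruding / static / retracting edges).
#' @export
activity_velocity_map <- function(frames, masks, dt, pixel_size = 1,
                                  sample_depth = 5,
                                  distance_breaks = NULL,
                                  velocity_breaks = NULL,
                                  static_eps = 0.2) {
  if (length(frames) < 2 || length(frames) != length(masks))
    stop("need >= 2 frames with matching masks", call. = FALSE)
  nfr <- length(frames)
  samp_d <- samp_v <- samp_a <- vector("list", nfr - 1)
  for (t in seq_len(nfr - 1)) {
    m <- as_binary_matrix(masks[[t]])
    img <- frames[[t]]
    ev <- edge_velocity(m, masks[[t + 1]], dt, pixel_size)
    d <- EBImage::imageData(EBImage::distmap(EBImage::Image(m * 1))) * pixel_size
    sel <- which(m & d <= sample_depth)
    if (!length(sel)) next
    nr <- nrow(m)
    # nearest edge pixel by brute-force distance (images are small)
    er <- cbind(((ev$edge_idx - 1L) %% nr) + 1L, ((ev$edge_idx - 1L) %/% nr) + 1L)
    pr <- cbind(((sel - 1L) %% nr) + 1L, ((sel - 1L) %/% nr) + 1L)
    nearest <- vapply(seq_len(nrow(pr)), function(i) {
      which.min((er[, 1] - pr[i, 1])^2 + (er[, 2] - pr[i, 2])^2)
    }, integer(1))
    samp_d[[t]] <- d[sel]
    samp_v[[t]] <- ev$velocity[nearest]
    samp_a[[t]] <- img[sel]
  }
  dd <- unlist(samp_d); vv <- unlist(samp_v); aa <- unlist(samp_a)
  if (!length(dd)) {
    warning("no pixels within sample_depth of the edge")
    return(structure(list(mean_activity = matrix(NA_real_, 0, 0),
                          sample_counts = matrix(0L, 0, 0),
                          distance_breaks = numeric(0),
                          velocity_breaks = numeric(0), n_sampled = 0L,
                          categories = NULL), class = "edge_sample_map"))
  }
  if (is.null(distance_breaks))
    distance_breaks <- seq(0, sample_depth, by = pixel_size)
  if (is.null(velocity_breaks)) {
    vmax <- max(abs(vv), 0.5)
    velocity_breaks <- seq(-ceiling(vmax / 0.5) * 0.5,
                           ceiling(vmax / 0.5) * 0.5, by = 0.5)
  }
  di <- cut(dd, distance_breaks, include.lowest = TRUE, labels = FALSE)
  vi <- cut(vv, velocity_breaks, include.lowest = TRUE, labels = FALSE)
  ok <- !is.na(di) & !is.na(vi)
  nd <- length(distance_breaks) - 1L; nv <- length(velocity_breaks) - 1L
  counts <- matrix(0L, nd, nv)
  sums <- matrix(0, nd, nv)
  for (i in which(ok)) {
    counts[di[i], vi[i]] <- counts[di[i], vi[i]] + 1L
    sums[di[i], vi[i]] <- sums[di[i], vi[i]] + aa[i]
  }
  means <- ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_)
  cat_of <- function(sel) c(mean_activity = mean(aa[sel]), n = sum(sel))
  categories <- rbind(
    protruding = cat_of(ok & vv > static_eps),
    static = cat_of(ok & abs(vv) <= static_eps),
    retracting = cat_of(ok & vv < -static_eps))
  structure(list(mean_activity = means, sample_counts = counts,
                 distance_breaks = distance_breaks,
                 velocity_breaks = velocity_breaks,
                 n_sampled = sum(ok),
                 categories = as.data.frame(categories)),
            class = "edge_sample_map")
}
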