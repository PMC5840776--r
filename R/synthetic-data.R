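# Synthetic-data generators: every input the pipeline consumes, with known
# ground truth, so all stages are testable without raw microscopy.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot_scalar(seed)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a migration-screen well table with known hits
#'
#' Draws per-gene, per-replicate migration indices for a two-condition
#' (basal / HGF) exclusion-zone screen. Each gene's index is the control
#' mean times a known effect multiplier plus additive Gaussian plate
#' noise, clamped to \[0, 100\]. Hits are assigned round-robin to the four
#' phenotype categories; impaired and accelerated effects multiply both
#' conditions, HGF-only effects multiply only the HGF condition.
#' Viability fluorescence columns are drawn with no planted effects.
#'
#' @param n_genes Number of genes (>= 4).
#' @param hit_fraction Fraction of genes given a true effect (0--1).
#' @param plate_noise_sd Additive noise SD on the migration index
#'   (index percentage points; must be positive).
#' @param replicates Number of replicate screens (default 3).
#' @param seed RNG seed; the same seed reproduces the table exactly.
#' @param control_basal,control_hgf Control migration indices (%) in the
#'   two conditions. Defaults 55 (mid-range of a 50--60% control wound
#'   coverage) and 70 (HGF-stimulated).
#' @param effect_impaired,effect_accelerated Multipliers applied to
#'   affected genes (defaults 0.6 and 1.4).
#' @return List with `wells` (data frame: gene_id, replicate,
#'   migration_index_basal, migration_index_hgf, fluor_48h, fluor_72h)
#'   and `truth` (data frame: gene_id, true_effect_basal,
#'   true_effect_hgf, true_category).
#' @export
make_screen_table <- function(n_genes, hit_fraction = 0.25,
                              plate_noise_sd = 3, replicates = 3, seed = 1,
                              control_basal = 55, control_hgf = 70,
                              effect_impaired = 0.6,
                              effect_accelerated = 1.4) {
  if (n_genes < 4) stop("'n_genes' must be >= 4", call. = FALSE)
  if (hit_fraction < 0 || hit_fraction > 1)
    stop("'hit_fraction' must be in [0, 1]", call. = FALSE)
  if (plate_noise_sd <= 0) stop("'plate_noise_sd' must be positive", call. = FALSE)
  if (replicates < 1) stop("'replicates' must be >= 1", call. = FALSE)

  gene_id <- sprintf("g%04d", seq_len(n_genes))
  n_hits <- round(n_genes * hit_fraction)
  cats <- rep("none", n_genes)
  if (n_hits > 0) {
    cyc <- c("impaired", "accelerated", "hgf_impaired", "hgf_accelerated")
    idx <- with_seed(seed, sample.int(n_genes, n_hits))
    cats[idx] <- rep_len(cyc, n_hits)
  }
  eff_basal <- ifelse(cats == "impaired", effect_impaired,
               ifelse(cats == "accelerated", effect_accelerated, 1))
  eff_hgf <- ifelse(cats %in% c("impaired", "hgf_impaired"), effect_impaired,
             ifelse(cats %in% c("accelerated", "hgf_accelerated"),
                    effect_accelerated, 1))
  truth <- data.frame(gene_id = gene_id, true_effect_basal = eff_basal,
                      true_effect_hgf = eff_hgf, true_category = cats,
                      stringsAsFactors = FALSE)

  wells <- with_seed(seed + 1L, {
    g <- rep(seq_len(n_genes), each = replicates)
    n <- length(g)
    clamp <- function(x) pmin(pmax(x, 0), 100)
    f48 <- 1000 * exp(rnorm(n, 0, 0.05))
    data.frame(
      gene_id = gene_id[g],
      replicate = rep(seq_len(replicates), n_genes),
      migration_index_basal =
        clamp(control_basal * eff_basal[g] + rnorm(n, 0, plate_noise_sd)),
      migration_index_hgf =
        clamp(control_hgf * eff_hgf[g] + rnorm(n, 0, plate_noise_sd)),
      fluor_48h = f48,
      fluor_72h = f48 * (1.05 + rnorm(n, 0, 0.02)),
      stringsAsFactors = FALSE)
  })
  list(wells = wells, truth = truth)
}

#' Simulate a fluorescence image of an exclusion-zone wound
#'
#' Builds a dye-labelled well image: a confluent monolayer of bright
#' cell dots outside a circular cell-free wound. At `timepoint = "t0"`
#' the wound is empty; at `"t24"` cell dots are added inside the wound,
#' centred on uncovered pixels, until the covered fraction of the wound
#' is within 2% of `coverage_target`.
#'
#' @param coverage_target Fraction of the wound to cover at t24 (0--1).
#' @param dot_radius Cell dot radius in pixels (> 0).
#' @param seed RNG seed.
#' @param timepoint `"t0"` (wound empty) or `"t24"`.
#' @param dim Image dimensions in pixels.
#' @param wound_radius Wound radius in pixels.
#' @param n_cells Optional cap on the number of cell dots drawn.
#' @return List with `image` (intensity matrix), `wound_mask` (true
#'   wound region), `cell_mask` (true cell pixels), `seeded_fraction`
#'   (measured covered fraction of the wound) and `timepoint`.
#' @export
make_wound_scene <- function(coverage_target = 0.55, dot_radius = 3, seed = 1,
                             timepoint = c("t24", "t0"), dim = c(256, 256),
                             wound_radius = 80, n_cells = Inf) {
  timepoint <- match.arg(timepoint)
  if (dot_radius <= 0) stop("'dot_radius' must be positive", call. = FALSE)
  if (coverage_target < 0 || coverage_target > 1)
    stop("'coverage_target' must be in [0, 1]", call. = FALSE)
  cx <- (dim[1] + 1) / 2; cy <- (dim[2] + 1) / 2
  wound <- rasterize_ellipse(dim, cx, cy, wound_radius, wound_radius)
  cells <- matrix(FALSE, dim[1], dim[2])
  intens <- matrix(0, dim[1], dim[2])
  n_drawn <- 0L

  paint_dot <- function(px, py, bright) {
    x0 <- max(1L, floor(px - dot_radius)); x1 <- min(dim[1], ceiling(px + dot_radius))
    y0 <- max(1L, floor(py - dot_radius)); y1 <- min(dim[2], ceiling(py + dot_radius))
    xs <- x0:x1; ys <- y0:y1
    sub <- outer(xs - px, ys - py, function(a, b) a^2 + b^2) <= dot_radius^2
    cells[xs, ys] <<- cells[xs, ys] | sub
    intens[xs, ys] <<- pmax(intens[xs, ys], ifelse(sub, bright, 0))
    n_drawn <<- n_drawn + 1L
  }

  with_seed(seed, {
    # confluent but textured monolayer outside the wound: jittered grid
    # of touching dots, so a flatten filter larger than a cell still
    # sees cell-scale structure (as in dye-labelled well images)
    sp <- dot_radius * 2.0
    gx <- seq(1, dim[1], by = sp); gy <- seq(1, dim[2], by = sp)
    for (px in gx) for (py in gy) {
      if (n_drawn >= n_cells) break
      jx <- px + runif(1, -0.25, 0.25) * sp
      jy <- py + runif(1, -0.25, 0.25) * sp
      if ((jx - cx)^2 + (jy - cy)^2 <= (wound_radius + dot_radius)^2) next
      paint_dot(jx, jy, runif(1, 0.7, 1))
    }
    # dense ring of cells flush against the exclusion zone, emulating
    # the cell rim left by the stopper: keeps the wound edge defined
    ring_r <- wound_radius + dot_radius
    n_ring <- ceiling(2 * pi * ring_r / (1.5 * dot_radius))
    phis <- seq(0, 2 * pi, length.out = n_ring + 1)[-1] +
      runif(1, 0, 2 * pi / n_ring)
    for (phi in phis) {
      if (n_drawn >= n_cells) break
      paint_dot(cx + ring_r * cos(phi), cy + ring_r * sin(phi),
                runif(1, 0.7, 1))
    }
    if (timepoint == "t24" && coverage_target > 0) {
      wound_idx <- which(wound)
      nr <- dim[1]
      repeat {
        frac <- sum(cells[wound_idx]) / length(wound_idx)
        if (frac >= coverage_target - 0.02 &&
            (frac >= coverage_target || n_drawn >= n_cells)) break
        if (n_drawn >= n_cells) break
        open <- wound_idx[!cells[wound_idx]]
        if (!length(open)) break
        p <- open[sample.int(length(open), 1L)]
        paint_dot(((p - 1L) %% nr) + 1L, ((p - 1L) %/% nr) + 1L, runif(1, 0.7, 1))
      }
    }
    img <- pmax(intens, 0) + 0.05 + matrix(rnorm(prod(dim), 0, 0.01), dim[1], dim[2])
    list(image = pmax(img, 0), wound_mask = wound, cell_mask = cells,
         seeded_fraction = sum(cells & wound) / sum(wound),
         timepoint = timepoint)
  })
}

#' Rasterize a disc or ellipse mask with its analytic geometry
#'
#' Returns a centred pixel mask together with the closed-form area and
#' perimeter. The ellipse perimeter uses Ramanujan's approximation
#' \eqn{P \approx \pi[3(a+b) - \sqrt{(3a+b)(a+3b)}]}, accurate to better
#' than 0.01% for aspect ratios up to 5.
#'
#' @param shape `"disc"` or `"ellipse"`.
#' @param r Disc radius (px).
#' @param a,b Ellipse semi-axes (px).
#' @param dim Grid dimensions.
#' @return List with `mask`, `area`, `perimeter` (analytic, pixel units).
#' @export
make_masks <- function(shape = c("disc", "ellipse"), r = NULL, a = NULL,
                       b = NULL, dim = c(256, 256)) {
  shape <- match.arg(shape)
  if (shape == "disc") {
    if (is.null(r)) stop("'r' required for a disc", call. = FALSE)
    a <- b <- r
  }
  if (is.null(a) || is.null(b) || a <= 0 || b <= 0)
    stop("axis lengths must be positive", call. = FALSE)
  if (2 * a >= dim[1] || 2 * b >= dim[2])
    stop("shape does not fit on the grid", call. = FALSE)
  mask <- rasterize_ellipse(dim, (dim[1] + 1) / 2, (dim[2] + 1) / 2, a, b)
  perim <- if (a == b) 2 * pi * a
           else pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  list(mask = mask, area = pi * a * b, perimeter = perim)
}

#' Simulate a biosensor ratio movie with scripted edge motion
#'
#' Builds a movie of a roughly circular cell whose radius follows a
#' per-frame protrusion script, with biosensor activity inside the mask
#' set by a known function of distance to the cell edge (optionally also
#' of the polar angle) plus Gaussian noise.
#'
#' @param activity_profile Function of distance-to-edge in pixels (and
#'   optionally polar angle) returning activity.
#' @param protrusion_script Numeric vector of per-frame radius changes
#'   (px/frame, length `n_frames - 1`), or a matrix with one column per
#'   angular sector for sector-wise protrusion.
#' @param n_frames Number of frames (>= 2).
#' @param seed RNG seed.
#' @param dim Frame dimensions.
#' @param r0 Initial cell radius (px).
#' @param noise_sd Gaussian noise SD added inside the mask.
#' @return List with `frames` (list of ratio images), `masks` (list of
#'   logical masks), `velocity` (matrix, frames-1 x sectors, px/frame)
#'   and `radii` (matrix, frames x sectors).
#' @export
make_biosensor_movie <- function(activity_profile, protrusion_script,
                                 n_frames, seed = 1, dim = c(128, 128),
                                 r0 = 30, noise_sd = 0.05) {
  if (n_frames < 2) stop("'n_frames' must be >= 2", call. = FALSE)
  if (is.matrix(protrusion_script)) {
    if (nrow(protrusion_script) != n_frames - 1)
      stop("'protrusion_script' needs n_frames - 1 rows", call. = FALSE)
    script <- protrusion_script
  } else {
    if (length(protrusion_script) != n_frames - 1)
      stop("'protrusion_script' needs length n_frames - 1", call. = FALSE)
    script <- matrix(protrusion_script, ncol = 1)
  }
  k <- ncol(script)
  radii <- apply(rbind(rep(r0, k), script), 2, cumsum)
  if (any(radii <= 2) || any(radii >= min(dim) / 2 - 1))
    stop("protrusion script moves the cell edge off the grid", call. = FALSE)

  cx <- (dim[1] + 1) / 2; cy <- (dim[2] + 1) / 2
  x <- matrix(seq_len(dim[1]), dim[1], dim[2])
  y <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  rr <- sqrt((x - cx)^2 + (y - cy)^2)
  ang <- atan2(y - cy, x - cx)                       # (-pi, pi]
  sector <- pmin(k, 1L + floor((ang + pi) / (2 * pi) * k))
  takes_angle <- length(formals(activity_profile)) >= 2

  with_seed(seed, {
    frames <- masks <- vector("list", n_frames)
    for (t in seq_len(n_frames)) {
      m <- rr <= matrix(radii[t, sector], dim[1], dim[2])
      d <- EBImage::imageData(EBImage::distmap(m))   # distance to edge, px
      act <- if (takes_angle) activity_profile(d[m], ang[m])
             else activity_profile(d[m])
      img <- matrix(0, dim[1], dim[2])
      img[m] <- rep_len(act, sum(m)) + rnorm(sum(m), 0, noise_sd)
      frames[[t]] <- img
      masks[[t]] <- m
    }
    list(frames = frames, masks = masks, velocity = script, radii = radii)
  })
}
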