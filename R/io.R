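# Thin readers/writers for the pipeline's file interfaces: well-record
# and track CSVs, TIFF images/movies, fitted-model JSON and parameter
# sidecar YAML.

#' Write / read a well-record table
#'
#' Wells are stored as plain CSV with columns `gene_id`, `replicate`,
#' `migration_index_basal`, `migration_index_hgf`, `fluor_48h`,
#' `fluor_72h`.
#'
#' @param wells Well-record data frame.
#' @param path File path.
#' @return `read_wells_csv` returns the data frame; `write_wells_csv`
#'   returns `path` invisibly.
#' @export
write_wells_csv <- function(wells, path) {
  utils::write.csv(wells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_wells_csv
#' @export
read_wells_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read track tables
#'
#' Tracks are stored long-format (`track_id`, `frame`, `x`, `y`) with
#' the frame interval recorded in a `# dt=<minutes>` header comment.
#'
#' @param tracks List of [cell_track()] objects.
#' @param path File path.
#' @return `read_tracks_csv` returns a list of [cell_track()] objects;
#'   `write_tracks_csv` returns `path` invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  if (inherits(tracks, "cell_track")) tracks <- list(tracks)
  dt <- tracks[[1]]$dt
  df <- do.call(rbind, lapply(seq_along(tracks), function(i) {
    p <- tracks[[i]]$positions
    data.frame(track_id = i, frame = seq_len(nrow(p)), x = p[, 1], y = p[, 2])
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt=%g", dt), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @param dt Frame interval in minutes; if `NULL`, read from the
#'   `# dt=` header comment.
#' @export
read_tracks_csv <- function(path, dt = NULL) {
  first <- readLines(path, n = 1)
  if (is.null(dt)) {
    m <- regmatches(first, regexec("^#\\s*dt=([0-9.eE+-]+)", first))[[1]]
    if (length(m) < 2) stop("no dt header in ", path, call. = FALSE)
    dt <- as.numeric(m[2])
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  lapply(split(df, df$track_id), function(d) {
    d <- d[order(d$frame), ]
    cell_track(cbind(d$x, d$y), dt)
  })
}

#' Write / read images and movies as TIFF
#'
#' Single matrices are written as one-page TIFF, lists of matrices as
#' multi-page TIFF (one frame per page). Intensities are stored as
#' 32-bit floats, so values are preserved exactly.
#'
#' @param x Matrix, logical matrix, or list of matrices.
#' @param path File path.
#' @return `read_image_tiff` returns a matrix or list of matrices;
#'   `write_image_tiff` returns `path` invisibly.
#' @export
write_image_tiff <- function(x, path) {
  tomat <- function(m) { m <- m * 1; storage.mode(m) <- "double"; m }
  pages <- if (is.list(x)) lapply(x, tomat) else list(tomat(x))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  if (length(pages) == 1L) pages[[1]] else pages
}

#' Serialize a fitted model to JSON
#'
#' All model parameters plus transition matrix, log-likelihood and
#' convergence information, round-trippable via [read_fit_json()].
#'
#' @param fit A `prw_fit` object.
#' @param path File path.
#' @return `write_fit_json` returns `path` invisibly;
#'   `read_fit_json` returns a list of the stored fields with `params`
#'   rebuilt as a [model_params()] object.
#' @export
write_fit_json <- function(fit, path) {
  p <- fit$params
  obj <- list(
    n_states = fit$n_states,
    state1 = p$state1[c("mu_s", "sigma_s", "sigma_theta")],
    state2 = p$state2[c("mu_s", "sigma_s", "sigma_theta")],
    alpha = p$alpha, dwell = p$dwell,
    transition = fit$transition,
    log_likelihood = fit$log_likelihood,
    n_iterations = fit$n_iterations,
    converged = fit$converged)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$params <- model_params(
    do.call(state_params, as.list(obj$state1)),
    do.call(state_params, as.list(obj$state2)),
    alpha = obj$alpha, dwell = max(obj$dwell, 1))
  obj
}

#' Record generator parameters in a sidecar YAML file
#'
#' @param params Named list of parameters (seeds included).
#' @param path Path of the data file the sidecar describes; the sidecar
#'   is written next to it as `<path>.yaml`.
#' @return The sidecar path, invisibly.
#' @export
write_sidecar_yaml <- function(params, path) {
  sidecar <- paste0(path, ".yaml")
  yaml::write_yaml(params, sidecar)
  invisible(sidecar)
}
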