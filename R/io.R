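# File interfaces: multi-page TIFF movies and ROI label images, trial
# structure YAML, CSV tables, and JSON result serialization.

#' Write a movie as a multi-page TIFF
#'
#' Frames are scaled into `[0, 1]` by `scale` (default: the movie maximum,
#' rounded up) and written as 32-bit float pages; the scale is returned so
#' [read_movie_tiff()] can restore the original units.
#'
#' @param movie A [tmsi_movie()].
#' @param path Output file.
#' @param scale Fluorescence value mapped to 1.0.
#' @return Invisibly, the scale used.
#' @export
write_movie_tiff <- function(movie, path, scale = NULL) {
  stopifnot(inherits(movie, "tmsi_movie"))
  if (is.null(scale)) scale <- ceiling(max(movie$frames, 1))
  pages <- lapply(seq_len(dim(movie$frames)[1L]), function(i)
    pmin(pmax(movie$frames[i, , ] / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(scale)
}

#' Read a multi-page TIFF movie
#'
#' @param path TIFF file.
#' @param frame_rate,trial_markers,prestim_s Movie metadata (see
#'   [tmsi_movie()]).
#' @param scale Fluorescence value that 1.0 maps back to.
#' @return A [tmsi_movie()].
#' @export
read_movie_tiff <- function(path, frame_rate, trial_markers, prestim_s = 5,
                            scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  H <- nrow(pages[[1L]]); W <- ncol(pages[[1L]])
  frames <- array(0, dim = c(length(pages), H, W))
  for (i in seq_along(pages)) frames[i, , ] <- pages[[i]] * scale
  tmsi_movie(frames, frame_rate, trial_markers, prestim_s = prestim_s)
}

#' Write / read an ROI label image pair as TIFF
#'
#' ROI and neuropil label matrices are stored as two pages of integer
#' labels scaled by 1/255 (supports up to 255 ROIs).
#'
#' @param rois A [tmsi_rois()].
#' @param path Output file.
#' @export
write_rois_tiff <- function(rois, path) {
  stopifnot(inherits(rois, "tmsi_rois"))
  if (rois$n_roi > 255L) stop("write_rois_tiff: more than 255 ROIs")
  tiff::writeTIFF(list(rois$labels / 255, rois$neuropil / 255), path,
                  bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_rois_tiff
#' @export
read_rois_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 2L)
    stop("read_rois_tiff: expected 2 pages (labels, neuropil)")
  tmsi_rois(matrix(as.integer(round(pages[[1L]] * 255)), nrow(pages[[1L]])),
            matrix(as.integer(round(pages[[2L]] * 255)), nrow(pages[[2L]])))
}

#' Write / read trial structure as YAML
#'
#' @param movie_meta List with `frame_rate`, `prestim_s`, and
#'   `trial_markers` (data.frame start/condition).
#' @param path YAML file.
#' @export
write_trials_yaml <- function(movie_meta, path) {
  yaml::write_yaml(list(
    frame_rate = movie_meta$frame_rate,
    prestim_s = movie_meta$prestim_s,
    trials = lapply(seq_len(nrow(movie_meta$trial_markers)), function(i)
      list(start = movie_meta$trial_markers$start[i],
           condition = movie_meta$trial_markers$condition[i]))), path)
  invisible(path)
}

#' @rdname write_trials_yaml
#' @export
read_trials_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  list(frame_rate = y$frame_rate, prestim_s = y$prestim_s,
       trial_markers = data.frame(
         start = vapply(y$trials, function(t) as.integer(t$start), 1L),
         condition = vapply(y$trials, function(t) t$condition, "")))
}

#' Serialize a result list to JSON
#'
#' @param x List of results (test objects are flattened to statistic, df,
#'   p, method fields).
#' @param path Output file.
#' @export
write_results_json <- function(x, path) {
  flatten <- function(v) {
    if (inherits(v, "tmsi_test"))
      return(list(statistic = unname(v$statistic), p = v$p.value,
                  method = v$method, n1 = v$n1, n2 = v$n2))
    if (inherits(v, "tmsi_expfit"))
      return(list(a = v$a, b = v$b, adj_r2 = v$adj_r2,
                  ci_a = unname(v$ci["a", ]), ci_b = unname(v$ci["b", ]),
                  n = v$n, model = v$model))
    if (is.list(v)) return(lapply(v, flatten))
    v
  }
  jsonlite::write_json(flatten(x), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, force = TRUE)
  invisible(path)
}
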