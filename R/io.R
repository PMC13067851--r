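#' Read and write voltage movies
#'
#' Movies travel as multi-page 32-bit float TIFF stacks with a JSON metadata
#' sidecar (`<path>.json`) carrying `frame_interval_ms`, `spacing_um`,
#' `seed` and the affine value mapping (TIFF pages store the movie
#' normalized to \[0, 1\]; `value = v_offset + v_scale * stored`). An
#' R-native RDS container (`write_movie_rds`) round-trips the object
#' exactly. Reading refuses files whose sidecar lacks the required
#' attributes.
#'
#' @param movie a [voltage_movie()].
#' @param path TIFF file path.
#' @export
write_movie <- function(movie, path) {
  fr <- movie$frames
  lo <- min(fr); hi <- max(fr)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(fr)[3]), function(t) (fr[, , t] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(frame_interval_ms = movie$frame_interval_ms,
               spacing_um = movie$spacing_um,
               seed = if (is.null(movie$seed) || is.na(movie$seed)) NULL
                      else movie$seed,
               v_offset = lo, v_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("metadata sidecar missing: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  need <- c("frame_interval_ms", "spacing_um", "v_offset", "v_scale")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata attributes missing: ", paste(miss, collapse = ", "))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  fr <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  fr <- meta$v_offset + meta$v_scale * fr
  voltage_movie(fr, meta$frame_interval_ms, meta$spacing_um,
                seed = meta$seed %||% NA)
}

#' @rdname write_movie
#' @export
write_movie_rds <- function(movie, path) {
  stopifnot(inherits(movie, "voltage_movie"))
  movie$final_state <- NULL
  saveRDS(movie, path)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie_rds <- function(path) {
  mv <- readRDS(path)
  if (!inherits(mv, "voltage_movie")) stop("not a voltage_movie container")
  mv
}

#' Write phase-singularity tracks as a tab-separated table
#'
#' @param ps data.frame from [detect_ps()].
#' @param path output path.
#' @export
write_ps_table <- function(ps, path) {
  utils::write.table(ps[, c("frame", "row", "col", "charge")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a YAML protocol / rig configuration
#'
#' Thin wrapper over [yaml::read_yaml()] used by the command-line entry
#' points; returns the raw list.
#'
#' @param path YAML file.
#' @export
read_config_yaml <- function(path) yaml::read_yaml(path)
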