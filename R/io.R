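# Readers/writers for the external formats: DeepLabCut-dialect CSV tracks,
# an HDF5 neural container (traces, ragged events, centroids, timestamps),
# and JSON sidecars for metadata/ground truth.

#' Write a behavior track as DeepLabCut-dialect CSV
#'
#' Three header rows (scorer / bodyparts / coords) over a frame-index column
#' and x/y/likelihood triplets for the head, body and tail keypoints.
#' Simulated tracks are written with likelihood 1.
#'
#' @param track a `behavior_track`.
#' @param path output CSV path.
#' @param scorer scorer name for the header.
#' @return `path`, invisibly.
#' @export
write_dlc_csv <- function(track, path, scorer = "depthpop") {
  fr <- track$frames
  parts <- c("head", "body", "tail")
  header1 <- c("scorer", rep(scorer, 9))
  header2 <- c("bodyparts", rep(parts, each = 3))
  header3 <- c("coords", rep(c("x", "y", "likelihood"), 3))
  body <- cbind(seq_len(nrow(fr)) - 1L,
                fr$head_x, fr$head_y, 1,
                fr$body_x, fr$body_y, 1,
                fr$tail_x, fr$tail_y, 1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(header1, collapse = ","),
               paste(header2, collapse = ","),
               paste(header3, collapse = ",")), con)
  utils::write.table(body, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a DeepLabCut-dialect CSV track
#'
#' Parses the three-row header, takes the body-centre keypoint as the
#' canonical position, and linearly interpolates frames whose likelihood
#' falls below `min_likelihood` (tracking dropouts).
#'
#' @param path CSV path.
#' @param hz frame rate (Hz) used to build timestamps.
#' @param min_likelihood likelihood threshold below which a keypoint frame is
#'   replaced by linear interpolation.
#' @return a `behavior_track` (kind `"dlc"`).
#' @export
read_dlc_csv <- function(path, hz = 50, min_likelihood = 0.9) {
  hdr <- readLines(path, n = 3L)
  parts <- strsplit(hdr[2], ",")[[1]][-1]
  coords <- strsplit(hdr[3], ",")[[1]][-1]
  raw <- data.table::fread(path, skip = 3L, header = FALSE)
  dat <- as.data.frame(raw)[, -1, drop = FALSE]
  colnames(dat) <- paste(parts, coords, sep = "_")
  interp_low <- function(v, lik) {
    bad <- lik < min_likelihood
    if (any(bad) && !all(bad))
      v[bad] <- approx(which(!bad), v[!bad], xout = which(bad), rule = 2)$y
    v
  }
  out <- data.frame(t = (seq_len(nrow(dat)) - 1L) / hz)
  for (p in unique(parts)) {
    lik <- dat[[paste0(p, "_likelihood")]]
    out[[paste0(p, "_x")]] <- interp_low(dat[[paste0(p, "_x")]], lik)
    out[[paste0(p, "_y")]] <- interp_low(dat[[paste0(p, "_y")]], lik)
  }
  out$x <- out$body_x
  out$y <- out$body_y
  new_behavior_track("dlc", hz, out, list(source = path))
}

#' Write a neural session to an HDF5 container
#'
#' Datasets: `traces` (cells x frames), `timestamps`, `footprint_centroids`
#' (cells x 2), and the ragged per-cell event lists stored CSR-style as
#' `event_times` plus `event_offsets` (0-based starts per cell). Requires the
#' `rhdf5` package.
#'
#' @param session a `neural_session`.
#' @param path output `.h5` path (overwritten).
#' @return `path`, invisibly.
#' @export
write_neural_h5 <- function(session, path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stopf("writing HDF5 requires the rhdf5 package")
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(session$traces, path, "traces")
  rhdf5::h5write(session$timestamps, path, "timestamps")
  rhdf5::h5write(session$centroids, path, "footprint_centroids")
  lens <- vapply(session$events, length, integer(1))
  rhdf5::h5write(unlist(session$events) %||% numeric(0), path, "event_times")
  rhdf5::h5write(c(0L, cumsum(lens)), path, "event_offsets")
  rhdf5::h5write(session$id, path, "id")
  rhdf5::h5write(session$kind, path, "kind")
  rhdf5::h5write(session$imaging_hz, path, "imaging_hz")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a neural session from an HDF5 container
#'
#' @param path `.h5` path written by [write_neural_h5()].
#' @return a `neural_session`.
#' @export
read_neural_h5 <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stopf("reading HDF5 requires the rhdf5 package")
  traces <- rhdf5::h5read(path, "traces")
  ts <- as.numeric(rhdf5::h5read(path, "timestamps"))
  cents <- rhdf5::h5read(path, "footprint_centroids")
  et <- as.numeric(rhdf5::h5read(path, "event_times"))
  off <- as.integer(rhdf5::h5read(path, "event_offsets"))
  events <- lapply(seq_len(length(off) - 1L), function(i)
    if (off[i + 1] > off[i]) et[(off[i] + 1):off[i + 1]] else numeric(0))
  id <- as.character(rhdf5::h5read(path, "id"))
  kind <- as.character(rhdf5::h5read(path, "kind"))
  hz <- as.numeric(rhdf5::h5read(path, "imaging_hz"))
  rhdf5::h5closeAll()
  new_neural_session(id, kind, ts, traces, events, cents, hz)
}

#' Write trial metadata / ground truth as a JSON sidecar
#'
#' @param x a list or data.frame (e.g. a trial table or roster).
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_json_sidecar <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
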