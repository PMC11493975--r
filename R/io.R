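# File interchange: 16-bit multi-page TIFF for rasters (channel order
# N15, N14, S32), JSON sidecar for pixel geometry, TSV for run sets, CSV
# for tabular outputs.

MIMS_CHANNEL_ORDER <- c("N15", "N14", "S32")

#' Write a MIMS frame as 16-bit multi-page TIFF
#'
#' Channels are written as pages in the order 15N, 14N, 32S; a JSON sidecar
#' (`<path>.json`) records the pixel size, channel order and accumulation
#' count. Counts above 65535 are rejected (16-bit range).
#'
#' @param frame A [mims_frame()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mims_tiff <- function(frame, path) {
  stopifnot(inherits(frame, "mims_frame"))
  chans <- intersect(MIMS_CHANNEL_ORDER, names(frame$channels))
  pages <- lapply(chans, function(nm) {
    ch <- frame$channels[[nm]]
    if (max(ch) > 65535) stop("counts exceed 16-bit range in channel ", nm)
    ch / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  sidecar <- list(pixel_size_nm = frame$pixel_size_nm,
                  channel_order = chans,
                  n_frames_accumulated = frame$n_frames_accumulated)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a MIMS frame from TIFF + JSON sidecar
#'
#' @param path TIFF path written by [write_mims_tiff()].
#' @return A [mims_frame()].
#' @export
read_mims_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  chans <- lapply(pages, function(p) {
    m <- round(p * 65535)
    storage.mode(m) <- "integer"
    m
  })
  names(chans) <- meta$channel_order
  mims_frame(chans, pixel_size_nm = meta$pixel_size_nm,
             n_frames_accumulated = meta$n_frames_accumulated)
}

#' Write / read a label mask as 16-bit TIFF
#'
#' @param labels Integer label matrix (values <= 65535).
#' @param path TIFF path.
#' @return `path` invisibly; `read_label_tiff` returns the label matrix.
#' @export
write_label_tiff <- function(labels, path) {
  stopifnot(is.matrix(labels), all(labels >= 0), max(labels) <= 65535)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  m <- round(tiff::readTIFF(path) * 65535)
  storage.mode(m) <- "integer"
  m
}

#' Write network-inference runs as per-run TSVs
#'
#' One file per run (`run_001.tsv`, ...) with columns tf, target,
#' importance.
#'
#' @param runs A `run_set`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_run_tsvs <- function(runs, dir) {
  stopifnot(inherits(runs, "run_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(runs$runs))
    utils::write.table(runs$runs[[i]],
                       file.path(dir, sprintf("run_%03d.tsv", i)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read network-inference runs from a directory of TSVs
#'
#' @param dir Directory of TSV files with columns tf, target, importance.
#' @return A `run_set`.
#' @export
read_run_tsvs <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0L) stop("no .tsv files in ", dir)
  run_set(lapply(files, function(f)
    utils::read.table(f, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)))
}

#' Write a measurement or call table as CSV
#'
#' @param x Data frame (measurements, calls, screen results, ...).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
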