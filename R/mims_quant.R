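#' Construct a MIMS frame
#'
#' A MIMS frame holds one integer ion-count raster per isotope channel
#' (15N, 14N, 32S), the pixel size, and the number of accumulated frames.
#' All channels must share one shape and contain non-negative integer counts.
#'
#' @param channels Named list of integer matrices; names among
#'   `"N15"`, `"N14"`, `"S32"`.
#' @param pixel_size_nm Pixel edge length in nanometres.
#' @param n_frames_accumulated How many raw frames were summed into this one.
#' @return An object of class `mims_frame`.
#' @export
mims_frame <- function(channels, pixel_size_nm = 70,
                       n_frames_accumulated = 1L) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)))
  dims <- lapply(channels, dim)
  if (length(unique(vapply(dims, paste, collapse = "x", ""))) != 1L)
    stop("all channels must share one shape")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.matrix(ch) || any(ch < 0) || any(ch != round(ch)))
      stop("channel ", nm, " must be a matrix of non-negative integer counts")
    storage.mode(channels[[nm]]) <- "integer"
  }
  structure(list(channels = channels,
                 pixel_size_nm = pixel_size_nm,
                 n_frames_accumulated = as.integer(n_frames_accumulated)),
            class = "mims_frame")
}

#' @export
print.mims_frame <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("MIMS frame ", d[1], "x", d[2], " px, channels: ",
      paste(names(x$channels), collapse = ", "),
      ", ", x$n_frames_accumulated, " frame(s) accumulated\n", sep = "")
  invisible(x)
}

#' Accumulate MIMS frames by channel-wise summation
#'
#' Sums the ion counts of repeated frames of the same raster element-wise.
#' Summation (rather than averaging per-frame ratios) pools the Poisson
#' counts, so a ratio computed on the accumulated frame is the
#' statistically efficient pooled-count ratio.
#'
#' @param frames List of [mims_frame()] objects with identical shapes and
#'   channel sets.
#' @return A single accumulated `mims_frame`.
#' @export
accumulate_frames <- function(frames) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  if (length(frames) == 1L) return(frames[[1]])
  ref <- frames[[1]]
  for (fr in frames[-1]) {
    if (!inherits(fr, "mims_frame")) stop("all elements must be mims_frame")
    if (!identical(sort(names(fr$channels)), sort(names(ref$channels))))
      stop("channel sets differ across frames")
    if (!identical(dim(fr$channels[[1]]), dim(ref$channels[[1]])))
      stop("frame shapes differ")
  }
  out <- ref$channels
  for (fr in frames[-1])
    for (nm in names(out)) out[[nm]] <- out[[nm]] + fr$channels[[nm]]
  mims_frame(out, pixel_size_nm = ref$pixel_size_nm,
             n_frames_accumulated = sum(vapply(frames, function(f)
               f$n_frames_accumulated, integer(1))))
}

# 8-connected component labelling of a logical matrix, via a pixel
# adjacency graph (EBImage::bwlabel is 4-connected).
label_components_8 <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  idx <- which(fg)
  lab <- matrix(0L, nr, nc)
  if (length(idx) == 0L) return(lab)
  pos <- integer(nr * nc)
  pos[idx] <- seq_along(idx)
  r <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  edges <- NULL
  for (sh in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    r2 <- r + sh[1]; c2 <- cc + sh[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- fg[nb]
    if (any(keep))
      edges <- rbind(edges, cbind(pos[idx[ok][keep]], pos[nb[keep]]))
  }
  if (is.null(edges)) {
    memb <- seq_along(idx)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    memb <- igraph::components(g)$membership
  }
  lab[idx] <- as.integer(memb)
  # relabel 1..n in first-encounter order
  u <- unique(lab[idx])
  lab[idx] <- match(lab[idx], u)
  lab
}

#' Segment nuclei on the 14N channel
#'
#' Thresholds the 14N count raster with Otsu's method and labels
#' 8-connected components above a minimum area. The 14N channel is used
#' because its counts track total nitrogen (DNA density) regardless of
#' labelling state. Callers with externally defined regions of interest can
#' bypass segmentation and pass label matrices straight to
#' [measure_nuclei()].
#'
#' @param frame A [mims_frame()] with an `N14` channel.
#' @param min_area_px Minimum component area in pixels (default 50).
#' @param threshold Either `"otsu"` (default) or a numeric count cutoff.
#' @param channel `"N14"` (default) or `"total"` (sum of 15N and 14N
#'   counts). The total-nitrogen option is needed when nuclei retain label
#'   near saturation: a nucleus that is mostly 15N is dim on the 14N channel
#'   even though its total nitrogen density is high.
#' @return Integer label matrix (0 = background); an all-zero matrix for a
#'   blank image.
#' @export
segment_nuclei <- function(frame, min_area_px = 50, threshold = "otsu",
                           channel = c("N14", "total")) {
  channel <- match.arg(channel)
  stopifnot(inherits(frame, "mims_frame"),
            "N14" %in% names(frame$channels))
  img <- if (channel == "total" && "N15" %in% names(frame$channels))
    frame$channels$N14 + frame$channels$N15
  else frame$channels$N14
  mx <- max(img)
  if (mx == 0) return(matrix(0L, nrow(img), ncol(img)))
  cut <- if (identical(threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(img / mx), range = c(0, 1)) * mx
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L)
    threshold
  }
  lab <- label_components_8(img > cut)
  if (max(lab) > 0L) {
    areas <- tabulate(lab)
    drop <- which(areas < min_area_px)
    if (length(drop)) {
      lab[lab %in% drop] <- 0L
      u <- sort(unique(lab[lab > 0L]))
      lab[lab > 0L] <- match(lab[lab > 0L], u)
    }
  }
  lab
}

#' Build per-nucleus measurements from summed counts
#'
#' Derives the ratio quantities from summed nuclear ion counts:
#' `ratio = sum15/sum14`, `atom_fraction = sum15/(sum15 + sum14)`, and
#' `excess = atom_fraction - f_nat`. Excess may be slightly negative for
#' unlabelled nuclei due to counting noise and is reported as-is.
#'
#' @param label_id Identifiers.
#' @param sum15,sum14 Summed 15N and 14N counts (vectorised).
#' @param f_nat Natural 15N abundance.
#' @param area_px Nucleus areas in pixels.
#' @return Data frame with columns `label_id`, `area_px`, `sum15`, `sum14`,
#'   `ratio`, `atom_fraction`, `excess`.
#' @export
nucleus_measurement <- function(label_id, sum15, sum14,
                                f_nat = NATURAL_15N_ABUNDANCE,
                                area_px = NA_integer_) {
  stopifnot(is.numeric(sum15), is.numeric(sum14),
            all(sum15 >= 0), all(sum14 >= 0))
  if (any(sum14 == 0))
    stop("unmeasurable nucleus: sum14 = 0 (no 14N counts)")
  f <- sum15 / (sum15 + sum14)
  data.frame(label_id = label_id,
             area_px = area_px,
             sum15 = sum15,
             sum14 = sum14,
             ratio = sum15 / sum14,
             atom_fraction = f,
             excess = f - f_nat,
             stringsAsFactors = FALSE)
}

#' Measure one nucleus on a MIMS frame
#'
#' Sums the 15N and 14N counts over the mask and computes the count-sum
#' ratio (not the mean of per-pixel ratios, which is unstable at low 14N
#' counts).
#'
#' @param frame A [mims_frame()].
#' @param mask Logical matrix of the frame's shape, or an integer vector of
#'   pixel indices into the raster.
#' @param f_nat Natural 15N abundance.
#' @param label_id Identifier for the output row.
#' @return One-row measurement data frame (see [nucleus_measurement()]).
#' @export
measure_nucleus <- function(frame, mask, f_nat = NATURAL_15N_ABUNDANCE,
                            label_id = 1L) {
  stopifnot(inherits(frame, "mims_frame"),
            all(c("N15", "N14") %in% names(frame$channels)))
  px <- if (is.matrix(mask)) {
    stopifnot(identical(dim(mask), dim(frame$channels$N15)))
    which(mask)
  } else {
    stopifnot(is.numeric(mask), all(mask >= 1),
              all(mask <= length(frame$channels$N15)))
    as.integer(mask)
  }
  if (length(px) == 0L) stop("empty nucleus mask")
  nucleus_measurement(label_id = label_id,
                      sum15 = sum(frame$channels$N15[px]),
                      sum14 = sum(frame$channels$N14[px]),
                      f_nat = f_nat,
                      area_px = length(px))
}

#' Measure all labelled nuclei on a frame
#'
#' @param frame A [mims_frame()].
#' @param labels Integer label matrix (0 = background), e.g. from
#'   [segment_nuclei()] or the ground-truth masks of
#'   [synthesize_mims_frames()].
#' @param f_nat Natural 15N abundance.
#' @return Measurement data frame, one row per label.
#' @export
measure_nuclei <- function(frame, labels, f_nat = NATURAL_15N_ABUNDANCE) {
  stopifnot(is.matrix(labels),
            identical(dim(labels), dim(frame$channels[[1]])))
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0L)
    return(nucleus_measurement(integer(0), numeric(0), numeric(0),
                               f_nat)[0, ])
  do.call(rbind, lapply(ids, function(id)
    measure_nucleus(frame, which(labels == id), f_nat, label_id = id)))
}
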