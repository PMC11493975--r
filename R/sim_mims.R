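#' Configuration for MIMS raster synthesis
#'
#' Defaults follow the acquisition geometry the package models: 512 x 512
#' pixel frames, at least three frames per raster. Heterochromatin is
#' emulated as intra-nuclear hotspot patches in which the local DNA density
#' — and therefore the ion dose — is multiplied by `hotspot_factor` while
#' the isotope atom fraction is unchanged.
#'
#' @param raster_dim Frame dimensions in pixels.
#' @param n_frames Frames per raster (summed by [accumulate_frames()]).
#' @param dose_per_px Expected total ion counts per nucleus pixel per frame.
#' @param background_dose Expected counts per background pixel per frame.
#' @param radius_range Min/max nucleus radius in pixels.
#' @param hotspot_factor Dose multiplier inside heterochromatin patches.
#' @param hotspot_fraction Target fraction of nucleus area in patches.
#' @param f_nat Natural 15N abundance (background atom fraction).
#' @param fiducials Number of 32S fiducial marks to stamp (default 4).
#' @param pixel_size_nm Pixel size recorded in the frames.
#' @return A list of class `mims_sim_config`.
#' @export
mims_sim_config <- function(raster_dim = c(512, 512), n_frames = 3,
                            dose_per_px = 400, background_dose = 20,
                            radius_range = c(8, 14),
                            hotspot_factor = 2.0, hotspot_fraction = 0.15,
                            f_nat = NATURAL_15N_ABUNDANCE,
                            fiducials = 4, pixel_size_nm = 70) {
  stopifnot(length(raster_dim) == 2L, all(raster_dim >= 16),
            n_frames >= 1, dose_per_px > 0, background_dose >= 0,
            length(radius_range) == 2L, radius_range[1] >= 2,
            radius_range[2] >= radius_range[1],
            hotspot_factor >= 1, hotspot_fraction >= 0,
            hotspot_fraction < 1)
  structure(as.list(environment()), class = "mims_sim_config")
}

# Place non-overlapping disks by rejection sampling; error when the raster
# cannot hold them.
place_disks <- function(n, raster_dim, radius_range, max_tries = 5000) {
  centers <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      rad <- stats::runif(1, radius_range[1], radius_range[2])
      cx <- stats::runif(1, rad + 1, raster_dim[1] - rad)
      cy <- stats::runif(1, rad + 1, raster_dim[2] - rad)
      if (nrow(centers) == 0 ||
          all(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) >
              radii + rad + 2)) {
        centers <- rbind(centers, c(cx, cy))
        radii <- c(radii, rad)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("raster too small: could not place ", n,
           " non-overlapping nuclei")
  }
  list(centers = centers, radii = radii)
}

disk_pixels <- function(center, radius, raster_dim) {
  r0 <- max(1L, floor(center[1] - radius)); r1 <- min(raster_dim[1], ceiling(center[1] + radius))
  c0 <- max(1L, floor(center[2] - radius)); c1 <- min(raster_dim[2], ceiling(center[2] + radius))
  rr <- r0:r1; cc <- c0:c1
  grid <- expand.grid(r = rr, c = cc)
  d2 <- (grid$r - center[1])^2 + (grid$c - center[2])^2
  keep <- d2 <= radius^2
  (grid$c[keep] - 1L) * raster_dim[1] + grid$r[keep]
}

#' Synthesize MIMS frame stacks with ground truth
#'
#' Renders a cohort of cells as non-overlapping disk nuclei on a count
#' raster and draws Poisson ion counts per pixel and frame. For a nucleus
#' pixel with atom fraction `f = f_nat + true_excess` and local hotspot
#' factor `h` (`hotspot_factor` inside heterochromatin patches, 1
#' elsewhere), the expected per-frame counts are `dose * f * h` for 15N and
#' `dose * (1 - f) * h` for 14N. Background pixels carry `background_dose`
#' at natural abundance. The 32S channel carries square fiducial marks for
#' registration. The expected-count rasters are returned so tests can verify
#' that expectation is conserved before Poisson sampling.
#'
#' @param cells Data frame from [simulate_cohort()] (may have zero rows).
#' @param config A [mims_sim_config()].
#' @param seed Optional RNG seed; fixed seed gives identical stacks.
#' @return List with elements `frames` (list of [mims_frame()]), `masks`
#'   (integer label matrix; label i is cell i), `cells` (the input cohort
#'   with a `label` column), `expected` (per-frame expected-count rasters
#'   for N15/N14), and `fiducials` (centres of the 32S marks).
#' @export
synthesize_mims_frames <- function(cells, config = mims_sim_config(),
                                   seed = NULL) {
  stopifnot(inherits(config, "mims_sim_config"), is.data.frame(cells))
  maybe_with_seed(seed, {
    dm <- config$raster_dim
    n <- nrow(cells)
    masks <- matrix(0L, dm[1], dm[2])
    hot <- matrix(1, dm[1], dm[2])
    fvals <- matrix(config$f_nat, dm[1], dm[2])
    dose <- matrix(config$background_dose, dm[1], dm[2])

    if (n > 0) {
      disks <- place_disks(n, dm, config$radius_range)
      for (i in seq_len(n)) {
        px <- disk_pixels(disks$centers[i, ], disks$radii[i], dm)
        masks[px] <- i
        fvals[px] <- config$f_nat + cells$true_excess[i]
        dose[px] <- config$dose_per_px
        # heterochromatin patches: small disks until target area fraction
        target <- config$hotspot_fraction * length(px)
        hot_px <- integer(0)
        tries <- 0
        while (length(hot_px) < target && tries < 100) {
          ctr <- disks$centers[i, ] +
            stats::runif(2, -disks$radii[i] / 2, disks$radii[i] / 2)
          patch <- intersect(disk_pixels(ctr, 2.2, dm), px)
          hot_px <- union(hot_px, patch)
          tries <- tries + 1
        }
        hot[hot_px] <- config$hotspot_factor
      }
    }

    lam15 <- dose * fvals * hot
    lam14 <- dose * (1 - fvals) * hot

    # 32S fiducials: bright squares near the corners
    s32_base <- matrix(2, dm[1], dm[2])
    fid_centers <- NULL
    if (config$fiducials > 0) {
      marg <- max(8, round(min(dm) * 0.05))
      cand <- rbind(c(marg, marg), c(marg, dm[2] - marg),
                    c(dm[1] - marg, marg), c(dm[1] - marg, dm[2] - marg),
                    c(round(dm[1] / 2), round(dm[2] / 2)))
      fid_centers <- cand[seq_len(min(config$fiducials, nrow(cand))), ,
                          drop = FALSE]
      for (j in seq_len(nrow(fid_centers))) {
        rs <- pmax(1, fid_centers[j, 1] - 2):pmin(dm[1], fid_centers[j, 1] + 2)
        cs <- pmax(1, fid_centers[j, 2] - 2):pmin(dm[2], fid_centers[j, 2] + 2)
        s32_base[rs, cs] <- 500
      }
    }

    frames <- lapply(seq_len(config$n_frames), function(fr) {
      mims_frame(list(
        N15 = matrix(stats::rpois(length(lam15), lam15), dm[1], dm[2]),
        N14 = matrix(stats::rpois(length(lam14), lam14), dm[1], dm[2]),
        S32 = matrix(stats::rpois(length(s32_base), s32_base), dm[1], dm[2])),
        pixel_size_nm = config$pixel_size_nm,
        n_frames_accumulated = 1L)
    })

    cells_out <- cells
    if (n > 0) cells_out$label <- seq_len(n)
    list(frames = frames, masks = masks, cells = cells_out,
         expected = list(N15 = lam15, N14 = lam14),
         fiducials = fid_centers)
  })
}
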