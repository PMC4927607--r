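#' Displacement magnitude of a rigid shift
#'
#' Euclidean norm `sqrt(dx^2 + dy^2 + dz^2)` in mm.
#' @param shift A [rigid_shift()].
#' @export
displacement_magnitude <- function(shift) {
  stopifnot(inherits(shift, "rigid_shift"))
  sqrt(shift$dx^2 + shift$dy^2 + shift$dz^2)
}

#' Estimate a rigid translation between two volumes
#'
#' Translation-only registration: exhaustive normalised cross-correlation
#' over a translation grid (`step_mm` spacing within `+/- search_mm` per
#' axis), refined by a per-axis fine scan (step/5) around the grid peak
#' with a final parabolic polish. Returns the shift `d` such that
#' `moving(x) ~ reference(x - d)`, i.e. the content of `moving` is the
#' reference moved by `+d`.
#'
#' @param reference,moving Congruent `volume_image`s.
#' @param search_mm Half-width of the search window (mm).
#' @param step_mm Grid step (mm).
#' @param presmooth_vox Gaussian sigma (voxels) applied to both images
#'   before correlation; damps the interpolation bias of sub-voxel
#'   resampling on sharp images. 0 disables.
#' @return A [rigid_shift()] with attribute `"ncc"` (peak correlation).
#' @export
estimate_rigid_shift <- function(reference, moving, search_mm = 8,
                                 step_mm = 2, presmooth_vox = 1) {
  stopifnot(inherits(reference, "volume_image"),
            inherits(moving, "volume_image"),
            identical(dim(reference$values), dim(moving$values)),
            search_mm > 0, step_mm > 0)
  if (presmooth_vox > 0) {
    reference$values <- smooth_volume3(reference$values, presmooth_vox)
    moving$values <- smooth_volume3(moving$values, presmooth_vox)
  }
  if (sd(reference$values) == 0 || sd(moving$values) == 0) {
    warning("flat image: returning zero shift")
    out <- rigid_shift(0, 0, 0)
    attr(out, "ncc") <- NA_real_
    return(out)
  }
  grid <- seq(-search_mm, search_mm, by = step_mm)
  ng <- length(grid)
  ncc <- array(NA_real_, c(ng, ng, ng))
  d <- dim(moving$values)
  # correlate over a transversely cropped core (resampled edge voxels mix
  # with the zero padding); all slices are kept — in thin axial stacks the
  # edge slices carry most of the axial alignment information
  core <- array(TRUE, d)
  mx <- min(2, d[1] %/% 8)
  if (mx > 0) {
    core[c(seq_len(mx), d[1] - seq_len(mx) + 1), , ] <- FALSE
    core[, c(seq_len(mx), d[2] - seq_len(mx) + 1), ] <- FALSE
  }
  rv <- reference$values[core]
  score <- function(dx, dy, dz) {
    sh <- cpp_shift_volume(as.double(moving$values), d,
                           moving$voxel_pitch_mm, moving$slice_pitch_mm,
                           -dx, -dy, -dz)
    v <- suppressWarnings(stats::cor(rv, array(sh, d)[core]))
    if (is.na(v)) -Inf else v
  }
  for (iz in seq_len(ng)) for (iy in seq_len(ng)) for (ix in seq_len(ng))
    ncc[ix, iy, iz] <- score(grid[ix], grid[iy], grid[iz])
  best <- arrayInd(which.max(ncc), dim(ncc))
  fine <- c(grid[best[1]], grid[best[2]], grid[best[3]])
  fs <- step_mm / 5
  peak <- max(ncc)
  for (pass in 1:2) for (ax in 1:3) {
    cand <- fine[ax] + seq(-step_mm, step_mm, by = fs)
    vals <- vapply(cand, function(v) {
      dd <- fine; dd[ax] <- v; score(dd[1], dd[2], dd[3])
    }, numeric(1))
    j <- which.max(vals)
    fine[ax] <- cand[j]
    peak <- vals[j]
    if (j > 1 && j < length(cand)) {
      den <- vals[j - 1] - 2 * vals[j] + vals[j + 1]
      if (is.finite(den) && den < 0)
        fine[ax] <- cand[j] + 0.5 * fs * (vals[j - 1] - vals[j + 1]) / den
    }
  }
  out <- rigid_shift(fine[1], fine[2], fine[3])
  attr(out, "ncc") <- peak
  out
}

# separable Gaussian smoothing of a 3D array, sigma in voxels
smooth_volume3 <- function(a, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-half):half / sigma)^2)
  k <- k / sum(k)
  conv_dim <- function(a, dim) {
    a <- aperm(a, c(dim, setdiff(1:3, dim)))
    d <- dim(a)
    m <- matrix(a, nrow = d[1])
    m <- rbind(m[rep(1, half), , drop = FALSE], m,
               m[rep(d[1], half), , drop = FALSE])
    m <- apply(m, 2, function(v) as.numeric(stats::filter(v, k, sides = 2)))
    a <- array(m[(half + 1):(half + d[1]), ], d)
    aperm(a, order(c(dim, setdiff(1:3, dim))))
  }
  for (dm in 1:3) a <- conv_dim(a, dm)
  a
}

#' Frame-by-frame motion quality control
#'
#' Mirrors the motion QC procedure applied to the emission scan: a
#' counts-weighted sum of the frames inside the first `reference_window_s`
#' seconds is the reference; every other frame is registered to it and its
#' displacement magnitude reported. Motion inside the reference window
#' itself is undetectable by design. Frames with fewer than `min_counts`
#' total counts are skipped (too noisy to register) and reported as `NA`.
#'
#' @param frames List of `volume_image`s (count-proportional units).
#' @param schedule The matching `frame_schedule`.
#' @param reference_window_s Reference window length (default 60 s).
#' @param search_mm,step_mm Passed to [estimate_rigid_shift()].
#' @param min_counts Noise floor for registration (default 1e3).
#' @return A `motion_report`: per-frame table plus `average_mm` and
#'   `maximum_mm` over the registered frames.
#' @export
motion_qc_frames <- function(frames, schedule, reference_window_s = 60,
                             search_mm = 8, step_mm = 2, min_counts = 1e3) {
  stopifnot(length(frames) >= 2, length(frames) == nrow(schedule))
  if (max(schedule$start_s + schedule$duration_s) < reference_window_s)
    stop("schedule shorter than the reference window")
  in_ref <- schedule$start_s < reference_window_s
  if (!any(in_ref)) stop("no frames inside the reference window")
  totals <- vapply(frames, function(fr) sum(fr$values), numeric(1))
  ref <- frames[[which(in_ref)[1]]]
  ref$values <- Reduce(`+`, lapply(which(in_ref), function(i)
    frames[[i]]$values * totals[i])) / max(sum(totals[in_ref]), 1e-12)

  rows <- lapply(seq_along(frames), function(i) {
    if (in_ref[i])
      return(data.frame(frame = i, dx = NA, dy = NA, dz = NA,
                        magnitude_mm = NA, skipped = FALSE,
                        reference = TRUE))
    if (totals[i] < min_counts)
      return(data.frame(frame = i, dx = NA, dy = NA, dz = NA,
                        magnitude_mm = NA, skipped = TRUE,
                        reference = FALSE))
    sh <- estimate_rigid_shift(ref, frames[[i]], search_mm, step_mm)
    data.frame(frame = i, dx = sh$dx, dy = sh$dy, dz = sh$dz,
               magnitude_mm = displacement_magnitude(sh), skipped = FALSE,
               reference = FALSE)
  })
  tab <- do.call(rbind, rows)
  mags <- tab$magnitude_mm[!tab$reference & !tab$skipped]
  structure(list(table = tab,
                 average_mm = if (length(mags)) mean(mags) else NA_real_,
                 maximum_mm = if (length(mags)) max(mags) else NA_real_),
            class = "motion_report")
}

#' @export
print.motion_report <- function(x, ...) {
  cat(sprintf("<motion_report> average %.2f mm, maximum %.2f mm over %d frames\n",
              x$average_mm, x$maximum_mm, nrow(x$table)))
  invisible(x)
}

#' Write a motion report as CSV
#'
#' Per-frame displacements followed by summary rows (average over frames,
#' maximum over frames, and — when supplied — the transmission-emission
#' displacement).
#' @param report A `motion_report`.
#' @param path CSV path.
#' @param tx_shift Optional transmission-emission [rigid_shift()].
#' @export
write_motion_report <- function(report, path, tx_shift = NULL) {
  tab <- report$table
  tab$group <- "frame"
  extra <- data.frame(frame = NA, dx = NA, dy = NA, dz = NA,
                      magnitude_mm = c(report$average_mm,
                                       report$maximum_mm),
                      skipped = FALSE, reference = FALSE,
                      group = c("average_over_frames",
                                "maximum_over_frames"))
  if (!is.null(tx_shift))
    extra <- rbind(extra, data.frame(
      frame = NA, dx = tx_shift$dx, dy = tx_shift$dy, dz = tx_shift$dz,
      magnitude_mm = displacement_magnitude(tx_shift), skipped = FALSE,
      reference = FALSE, group = "transmission_emission"))
  write.csv(rbind(tab, extra), path, row.names = FALSE)
  invisible(path)
}
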