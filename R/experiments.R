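#' Experiment configuration
#'
#' Bundles everything a sweep needs: geometry, phantom, tracer, schedule,
#' input function, mismatch magnitude, margins, counts and seeds.
#' "Subjects" are seeds: each draws a \code{+/-10\%} jitter of the kinetic
#' parameters and a random in-plane mismatch direction at the configured
#' magnitude, so group results are not tied to one phantom realisation.
#'
#' @param tracer Tracer profile name (see [tracer_profile()]).
#' @param n_subjects Number of simulated subjects.
#' @param mismatch_mm Transmission-emission mismatch magnitude (mm).
#' @param margins ACF-margins in radial bins (default the studied ladder
#'   0, 2, 4, 6, 8, 10, 12, 14).
#' @param sss_mode `"sss3d"` or `"sss2d"` for the margin sweep.
#' @param counts_total Expected counts per subject scan.
#' @param scatter_fraction Simulated scatter fraction.
#' @param seed Base seed.
#' @param geometry A `scanner_geometry`.
#' @param nx Reconstruction matrix size.
#' @param settings A [recon_settings()].
#' @param phantom_args Extra arguments for [make_head_phantom()]
#'   (e.g. `axial_gradient`).
#' @param sss_args Extra arguments for [sss_estimate()].
#' @param schedule Frame schedule; defaults to the tracer's protocol.
#' @param n_outer Scatter-update outer loops for the reconstructions.
#' @export
experiment_config <- function(tracer = "verapamil_like", n_subjects = 2,
                              mismatch_mm = 5,
                              margins = c(0, 2, 4, 6, 8, 10, 12, 14),
                              sss_mode = "sss3d", counts_total = 2e7,
                              scatter_fraction = 0.35, seed = 1L,
                              geometry = desk_geometry(), nx = 64L,
                              settings = recon_settings(nx = nx),
                              phantom_args = list(), sss_args = list(),
                              schedule = NULL, n_outer = 1L) {
  stopifnot(all(margins >= 0), all(margins == round(margins)),
            n_subjects >= 1)
  if (is.null(schedule))
    schedule <- make_frame_schedule(
      if (tracer == "flumazenil_like") "flumazenil" else
        "verapamil_raclopride")
  structure(list(tracer = tracer, n_subjects = n_subjects,
                 mismatch_mm = mismatch_mm, margins = as.integer(margins),
                 sss_mode = sss_mode, counts_total = counts_total,
                 scatter_fraction = scatter_fraction,
                 seed = as.integer(seed), geometry = geometry,
                 nx = as.integer(nx), settings = settings,
                 phantom_args = phantom_args, sss_args = sss_args,
                 schedule = schedule, n_outer = as.integer(n_outer)),
            class = "experiment_config")
}

# jittered subject realisation: +/-10% log-uniform kinetic jitter, random
# in-plane mismatch direction
subject_acquisition <- function(config, subject, gradient = NULL) {
  seed_s <- config$seed + 1000L * subject
  tracer <- tracer_profile(config$tracer)
  tracer$regions <- withr::with_seed(seed_s, lapply(tracer$regions,
    function(rg) {
      for (nm in intersect(names(rg), c("K1", "k2", "k3", "k4")))
        rg[[nm]] <- rg[[nm]] * runif(1, 0.9, 1.1)
      rg
    }))
  theta <- withr::with_seed(seed_s + 1L, runif(1, 0, 2 * pi))
  mis <- rigid_shift(config$mismatch_mm * cos(theta),
                     config$mismatch_mm * sin(theta), 0)
  pargs <- config$phantom_args
  if (!is.null(gradient)) pargs$axial_gradient <- gradient
  spec_args <- pargs[names(pargs) %in% names(formals(phantom_spec))]
  mk_args <- pargs[names(pargs) %in% c("nx", "axial_gradient")]
  spec <- do.call(phantom_spec, spec_args)
  phant <- do.call(make_head_phantom,
                   c(list(spec, config$geometry, nx = config$nx), mk_args))
  acq <- simulate_acquisition(phant, tracer, config$schedule,
                              make_input_function(),
                              config$geometry, mismatch = mis,
                              scatter_fraction = config$scatter_fraction,
                              counts_total = config$counts_total,
                              seed = seed_s + 2L,
                              sss_args = config$sss_args)
  list(acq = acq, tracer = tracer, mismatch = mis, seed = seed_s)
}

# V_T per VOI from reconstructed frames
fit_vois <- function(frames, acq, min_label = 1L) {
  tacs <- voi_tacs(frames, acq$phantom$labels, acq$schedule)
  model <- acq$tracer$model
  out <- lapply(names(tacs), function(l) {
    ft <- fit_tac(tacs[[l]], model, acq$input)
    data.frame(label = as.integer(l),
               voi = acq$phantom$region_names[[l]],
               V_T = ft$V_T, converged = ft$converged)
  })
  do.call(rbind, out)
}

# summed image over frames `from` .. last (display/ratio window)
summed_image <- function(frames, from = 5L) {
  from <- min(from, length(frames))
  img <- frames[[from]]
  img$values <- Reduce(`+`, lapply(frames[from:length(frames)],
                                   function(v) v$values))
  img
}

# estimated over true scatter counts, pooled over the late frames
# (scale-invariant: insensitive to the arbitrary units of the SSS model)
scatter_count_ratio <- function(rec, acq, from = 5L) {
  nf <- length(acq$frames)
  frames <- min(from, nf):nf
  mvals <- rec$scatter_model$sino$values
  npix <- prod(dim(mvals)[1:2])
  est <- sum(vapply(frames, function(f) {
    s <- rec$tail_fits[[f]]$s
    sum(array(rep(s, each = npix), dim(mvals)) * mvals)
  }, numeric(1)))
  tru <- sum(vapply(frames, function(f)
    acq$frames[[f]]$expected_scatter, numeric(1)))
  if (tru == 0) return(NA_real_)
  est / tru
}

provenance_row <- function(config, subject, seed) {
  data.frame(config_hash = rlang::hash(unclass(config)),
             seed = seed, subject = subject,
             package_version = as.character(utils::packageVersion("acfmargin")))
}

#' ACF-margin sweep
#'
#' For each simulated subject, reconstructs every frame once per ACF-margin
#' (sharing the preliminary image, scatter shape and sensitivities across
#' margins, since the margin only enters the tail fit) and reports, per
#' subject and margin: the mean fitted-to-true scatter-scale ratio over the
#' late frames, per-VOI V_T, the V_T ratio against the 8-bin-margin
#' reference, and a summed-image (frames 5..last) activity ratio of the
#' no-margin to the 8-bin-margin reconstruction inside the artefact-prone
#' lower-brain VOI. Also detects the plateau: the smallest margin beyond
#' which the maximum |V_T change| between successive margins stays below
#' `plateau_tol`.
#'
#' @param config An [experiment_config()].
#' @param plateau_tol Relative V_T change defining the plateau (default
#'   0.02).
#' @return List of data frames: `vt` (per subject x margin x VOI),
#'   `tail` (per subject x margin), `ratio` (per subject), scalar
#'   `plateau_margin`, and `provenance`.
#' @export
run_margin_sweep <- function(config, plateau_tol = 0.02) {
  stopifnot(inherits(config, "experiment_config"))
  vt_rows <- list(); tail_rows <- list(); ratio_rows <- list()
  ref_margin <- if (8L %in% config$margins) 8L else
    config$margins[which.min(abs(config$margins - 8L))]
  for (s in seq_len(config$n_subjects)) {
    sub <- subject_acquisition(config, s)
    acq <- sub$acq
    shared <- prepare_recon_shared(acq, config$settings,
                                   mode = config$sss_mode,
                                   sss_args = config$sss_args)
    per_margin <- list()
    for (m in config$margins) {
      rec <- reconstruct_dynamic(acq,
                                 list(mode = config$sss_mode, margin = m,
                                      per_plane = TRUE),
                                 config$settings, shared = shared,
                                 sss_args = config$sss_args,
                                 n_outer = config$n_outer)
      per_margin[[as.character(m)]] <- rec
      tail_rows[[length(tail_rows) + 1]] <- data.frame(
        subject = s, margin = m,
        s_hat_ratio = scatter_count_ratio(rec, acq))
      vt <- fit_vois(rec$frames, acq)
      vt$subject <- s; vt$margin <- m
      vt_rows[[length(vt_rows) + 1]] <- vt
    }
    # summed-image ratio, no margin vs reference margin, lower-brain VOI
    lb <- which(acq$phantom$region_names == "lower_brain")
    if (length(lb) == 1) {
      lmask <- acq$phantom$labels$values ==
        as.integer(names(acq$phantom$region_names)[lb])
      s0 <- summed_image(per_margin[[as.character(config$margins[1])]]$frames)
      s8 <- summed_image(per_margin[[as.character(ref_margin)]]$frames)
      ratio_rows[[length(ratio_rows) + 1]] <- data.frame(
        subject = s,
        ratio_mean = mean(s0$values[lmask]) / mean(s8$values[lmask]),
        ref_margin = ref_margin)
    }
  }
  vt <- do.call(rbind, vt_rows)
  # V_T ratio against the reference margin, per subject x VOI
  ref <- vt[vt$margin == ref_margin, c("subject", "label", "V_T")]
  names(ref)[3] <- "V_T_ref"
  vt <- merge(vt, ref, by = c("subject", "label"), sort = FALSE)
  vt$vt_ratio_vs_ref <- vt$V_T / vt$V_T_ref
  vt <- vt[order(vt$subject, vt$margin, vt$label), ]

  plateau <- plateau_margin(vt, config$margins, plateau_tol)
  prov <- do.call(rbind, lapply(seq_len(config$n_subjects), function(s)
    provenance_row(config, s, config$seed + 1000L * s)))
  list(vt = vt, tail = do.call(rbind, tail_rows),
       ratio = if (length(ratio_rows)) do.call(rbind, ratio_rows) else NULL,
       plateau_margin = plateau, provenance = prov)
}

# smallest margin from which successive V_T changes stay below tol
plateau_margin <- function(vt, margins, tol) {
  margins <- sort(unique(margins))
  if (length(margins) < 2) return(margins[1])
  step_change <- vapply(seq_len(length(margins) - 1), function(i) {
    a <- vt[vt$margin == margins[i], ]
    b <- vt[vt$margin == margins[i + 1], ]
    mrg <- merge(a, b, by = c("subject", "label"))
    max(abs(mrg$V_T.y / mrg$V_T.x - 1))
  }, numeric(1))
  below <- rev(cumprod(rev(step_change < tol))) > 0
  if (!any(below)) return(margins[length(margins)])
  margins[which(below)[1]]
}

#' 2D versus 3D single scatter simulation
#'
#' Reconstructs each subject with both SSS modes at the reference 8-bin
#' (10-mm-equivalent) ACF-margin and reports per-VOI V_T and summed-image
#' activity for both, plus their 3D/2D ratios. An axial activity gradient
#' is applied by default, since 2D and 3D SSS coincide for axially uniform
#' objects.
#'
#' @param config An [experiment_config()]; its `sss_mode` is ignored.
#' @param margin ACF-margin used for both modes (default 8 bins).
#' @param axial_gradient Gradient strength for the phantom (default 0.5).
#' @return List with `vt` (per subject x VOI: V_T for both modes and the
#'   ratio), `activity` (summed-image VOI means and ratio) and
#'   `provenance`.
#' @export
run_sss_mode_comparison <- function(config, margin = 8L,
                                    axial_gradient = 0.5) {
  stopifnot(inherits(config, "experiment_config"))
  vt_rows <- list(); act_rows <- list()
  for (s in seq_len(config$n_subjects)) {
    sub <- subject_acquisition(config, s, gradient = axial_gradient)
    acq <- sub$acq
    recs <- lapply(c(sss3d = "sss3d", sss2d = "sss2d"), function(md) {
      shared <- prepare_recon_shared(acq, config$settings, mode = md,
                                     sss_args = config$sss_args)
      reconstruct_dynamic(acq, list(mode = md, margin = margin,
                                    per_plane = TRUE),
                          config$settings, shared = shared,
                          sss_args = config$sss_args,
                          n_outer = config$n_outer)
    })
    vt3 <- fit_vois(recs$sss3d$frames, acq)
    vt2 <- fit_vois(recs$sss2d$frames, acq)
    vt_rows[[s]] <- data.frame(subject = s, label = vt3$label,
                               voi = vt3$voi, V_T_3d = vt3$V_T,
                               V_T_2d = vt2$V_T,
                               vt_ratio_3d_2d = vt3$V_T / vt2$V_T)
    s3 <- summed_image(recs$sss3d$frames)
    s2 <- summed_image(recs$sss2d$frames)
    lv <- sort(unique(as.vector(acq$phantom$labels$values)))
    lv <- lv[lv > 0]
    act_rows[[s]] <- do.call(rbind, lapply(lv, function(l) {
      m <- acq$phantom$labels$values == l
      data.frame(subject = s, label = l,
                 voi = acq$phantom$region_names[[as.character(l)]],
                 act_3d = mean(s3$values[m]), act_2d = mean(s2$values[m]),
                 act_ratio_3d_2d = mean(s3$values[m]) / mean(s2$values[m]))
    }))
  }
  prov <- do.call(rbind, lapply(seq_len(config$n_subjects), function(s)
    provenance_row(config, s, config$seed + 1000L * s)))
  list(vt = do.call(rbind, vt_rows), activity = do.call(rbind, act_rows),
       provenance = prov)
}
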