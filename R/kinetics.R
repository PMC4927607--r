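#' Plasma-input compartment model time-activity curve
#'
#' Computes `C_model(t) = (1 - Vb) * C_tissue(t) + Vb * C_b(t)` on a 1-s
#' grid and averages it over each frame. The single-tissue (1T) impulse
#' response is `K1 exp(-k2 t)`; the reversible two-tissue (2T) response is
#' the standard bi-exponential in `(K1, k2, k3, k4)`. Convolution with the
#' plasma curve uses an exact-within-step exponential recursion (the input
#' is treated as piecewise linear), which is stable and free of FFT edge
#' artefacts at these problem sizes.
#'
#' @param params List with `K1`, `k2` (and `k3`, `k4` for 2T) in 1/min and
#'   `Vb` in `[0, 0.2]`.
#' @param model `"1t"` or `"2t"`.
#' @param input An [make_input_function()] object covering the schedule.
#' @param schedule A `frame_schedule`.
#' @return A `tac` data frame: `mid_min`, `dur_min`, `value` (kBq/ml).
#' @export
model_tac <- function(params, model = c("1t", "2t"), input, schedule) {
  model <- match.arg(model)
  fine <- model_curve(params, model, input)
  tac_from_curve(fine, input$t_s, schedule)
}

# continuous model curve on the input's time grid (kBq/ml)
model_curve <- function(params, model, input) {
  t_min <- input$t_s / 60
  dt <- diff(t_min[1:2])
  ct <- if (model == "1t") {
    params$K1 * conv_exp(params$k2, input$Cp, dt)
  } else {
    a <- two_tissue_amplitudes(params)
    a$A1 * conv_exp(a$alpha1, input$Cp, dt) +
      a$A2 * conv_exp(a$alpha2, input$Cp, dt)
  }
  (1 - params$Vb) * ct + params$Vb * input$Cb
}

# bi-exponential impulse-response decomposition of the reversible 2T model
two_tissue_amplitudes <- function(p) {
  s <- p$k2 + p$k3 + p$k4
  disc <- sqrt(max(s^2 - 4 * p$k2 * p$k4, 0))
  a1 <- (s - disc) / 2
  a2 <- (s + disc) / 2
  if (a2 - a1 < 1e-9) a2 <- a1 + 1e-9
  list(alpha1 = a1, alpha2 = a2,
       A1 = p$K1 * (p$k3 + p$k4 - a1) / (a2 - a1),
       A2 = p$K1 * (a2 - p$k3 - p$k4) / (a2 - a1))
}

# I(t) = int_0^t exp(-k (t - u)) f(u) du for piecewise-linear f on a
# uniform grid with step dt; exact within each step.
conv_exp <- function(k, f, dt) {
  n <- length(f)
  k <- max(k, 1e-10)
  E <- exp(-k * dt)
  c1 <- (1 - E) / k
  c2 <- (dt - c1) / k
  b <- diff(f) / dt
  inc <- f[-n] * c1 + b * c2
  # linear recurrence out[i+1] = E * out[i] + inc[i]
  c(0, as.numeric(stats::filter(inc, E, method = "recursive")))
}

tac_from_curve <- function(curve, t_s, schedule) {
  stopifnot(max(schedule$start_s + schedule$duration_s) <= max(t_s) + 1e-9)
  vals <- vapply(seq_len(nrow(schedule)), function(i) {
    a <- schedule$start_s[i]
    b <- a + schedule$duration_s[i]
    idx <- which(t_s >= a & t_s <= b)
    # trapezoid average over the frame
    sum(diff(t_s[idx]) * (curve[idx[-length(idx)]] + curve[idx[-1]]) / 2) /
      (t_s[idx[length(idx)]] - t_s[idx[1]])
  }, numeric(1))
  tac(mid_min = (schedule$start_s + schedule$duration_s / 2) / 60,
      dur_min = schedule$duration_s / 60, value = vals)
}

#' Construct a time-activity curve object
#' @param mid_min Frame mid-times (min), strictly increasing.
#' @param dur_min Frame durations (min).
#' @param value Activity concentrations (kBq/ml).
#' @param label Optional VOI label.
#' @export
tac <- function(mid_min, dur_min, value, label = NA) {
  stopifnot(all(diff(mid_min) > 0), all(dur_min > 0))
  out <- data.frame(mid_min = mid_min, dur_min = dur_min, value = value)
  attr(out, "label") <- label
  class(out) <- c("tac", "data.frame")
  out
}

#' Fit a compartment model to a TAC
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) with box bounds and a fixed-seed 3-start strategy; the
#' best converged start wins. The volume of distribution is computed from
#' the fitted rate constants: `V_T = K1/k2` (1T) or `K1/k2 (1 + k3/k4)`
#' (2T).
#'
#' @param tac_obj A `tac` with at least 6 frames.
#' @param model `"1t"` or `"2t"`.
#' @param input The plasma input used to generate the data.
#' @param weights `"frame_duration"` (default) or `"uniform"`.
#' @param init Optional named start values.
#' @param bounds Optional list with `lower`/`upper` named vectors.
#' @param n_starts Number of multi-starts (fixed seeds).
#' @param seed Base seed for start jitter.
#' @return A `kinetic_fit`: `params`, `V_T`, `wrss`, `cov`, `converged`.
#' @export
fit_tac <- function(tac_obj, model = c("1t", "2t"), input,
                    weights = c("frame_duration", "uniform"), init = NULL,
                    bounds = NULL, n_starts = 3, seed = 42L) {
  model <- match.arg(model)
  weights <- match.arg(weights)
  stopifnot(nrow(tac_obj) >= 6)
  pn <- if (model == "1t") c("K1", "k2", "Vb") else
    c("K1", "k2", "k3", "k4", "Vb")
  lower <- c(K1 = 1e-4, k2 = 1e-4, k3 = 1e-4, k4 = 1e-4, Vb = 0)[pn]
  upper <- c(K1 = 2, k2 = 2, k3 = 2, k4 = 2, Vb = 0.2)[pn]
  if (!is.null(bounds)) {
    lower[names(bounds$lower)] <- bounds$lower
    upper[names(bounds$upper)] <- bounds$upper
  }
  p0 <- c(K1 = 0.1, k2 = 0.1, k3 = 0.05, k4 = 0.05, Vb = 0.05)[pn]
  if (!is.null(init)) p0[names(init)] <- unlist(init)
  w <- if (weights == "frame_duration") tac_obj$dur_min else
    rep(1, nrow(tac_obj))
  sched <- frame_schedule(tac_obj$dur_min * 60)
  resid_fn <- function(par) {
    pl <- as.list(par)
    m <- model_tac(pl, model, input, sched)
    sqrt(w) * (tac_obj$value - m$value)
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- if (s == 1) p0 else withr::with_seed(
      as.integer(seed) + s,
      pmin(pmax(p0 * exp(runif(length(p0), -0.7, 0.7)), lower), upper))
    fit <- tryCatch(
      minpack.lm::nls.lm(start, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    return(structure(list(params = as.list(p0), V_T = NA_real_, wrss = NA,
                          cov = NULL, converged = FALSE),
                     class = "kinetic_fit"))
  par <- as.list(coef(best))
  vt <- if (model == "1t") par$K1 / par$k2 else
    par$K1 / par$k2 * (1 + par$k3 / par$k4)
  covm <- tryCatch({
    dof <- max(nrow(tac_obj) - length(pn), 1)
    solve(best$hessian) * best$deviance / dof
  }, error = function(e) NULL)
  structure(list(params = par, model = model, V_T = vt,
                 wrss = best$deviance, cov = covm,
                 converged = best$info %in% 1:4),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit:%s> V_T = %.4g (%s)\n", x$model, x$V_T,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  cat("  ", paste(sprintf("%s = %.4g", names(x$params),
                          unlist(x$params)), collapse = ", "), "\n")
  invisible(x)
}

#' Regional time-activity curves from dynamic frames
#'
#' Mean activity per label per frame.
#'
#' @param frames List of activity `volume_image`s, one per frame.
#' @param labels A label `volume_image` congruent with the frames.
#' @param schedule The `frame_schedule` (one row per frame).
#' @return Named list of `tac` objects, one per positive label.
#' @export
voi_tacs <- function(frames, labels, schedule) {
  stopifnot(length(frames) == nrow(schedule))
  lv <- sort(unique(as.vector(labels$values)))
  lv <- lv[lv > 0]
  if (length(lv) == 0) stop("no positive labels")
  masks <- lapply(lv, function(l) labels$values == l)
  names(masks) <- lv
  mids <- (schedule$start_s + schedule$duration_s / 2) / 60
  durs <- schedule$duration_s / 60
  out <- lapply(lv, function(l) {
    m <- masks[[as.character(l)]]
    if (!any(m)) stop(sprintf("label %s is empty", l))
    vals <- vapply(frames, function(fr) mean(fr$values[m]), numeric(1))
    tac(mids, durs, vals, label = l)
  })
  names(out) <- lv
  out
}
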