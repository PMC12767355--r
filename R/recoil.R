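# Laser-ablation recoil kinetics: instantaneous and peak recoil velocities
# from vertex-pair distance traces, optional exponential (Kelvin-Voigt)
# fits, and group comparison.

as_recoil_trace <- function(times_s, distances_um, orientation = "ML",
                            stage = "late") {
  stopifnot(length(times_s) == length(distances_um), length(times_s) >= 2L)
  if (any(diff(times_s) <= 0)) stop("times must be strictly increasing")
  if (any(distances_um <= 0)) stop("distances must be positive")
  structure(list(times_s = times_s, distances_um = distances_um,
                 edge_orientation_class = orientation, stage = stage),
            class = "recoil_trace")
}

#' Instantaneous recoil velocities
#'
#' Frame-to-frame velocities `v_i = (d_i - d_{i-1}) / (t_i - t_{i-1})` for
#' every consecutive pair of samples, the first interval running from the
#' pre-ablation frame.
#'
#' @param trace a `recoil_trace` (or list with `times_s`, `distances_um`).
#' @return numeric vector of velocities (um/s), one per interval.
#' @export
recoil_velocities <- function(trace) {
  t <- trace$times_s; d <- trace$distances_um
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  diff(d) / diff(t)
}

#' Peak recoil velocity with quality-control flag
#'
#' The maximum instantaneous velocity, used as the relative tension proxy.
#' Traces whose peak does not exceed the noise floor are flagged for
#' discard ("no measurable recoil"); the default floor is 0, and when
#' `pre_frames` velocities are supplied the floor is twice their SD.
#'
#' @param trace a `recoil_trace`.
#' @param noise_floor velocity floor (um/s).
#' @param pre_frames optional vector of pre-ablation distances used to
#'   estimate the measurement-noise velocity SD.
#' @return list `peak_velocity_um_per_s`, `discard` (logical), `velocities`.
#' @export
peak_recoil_velocity <- function(trace, noise_floor = 0, pre_frames = NULL) {
  v <- recoil_velocities(trace)
  if (!is.null(pre_frames) && length(pre_frames) >= 3L) {
    dt <- mean(diff(trace$times_s))
    noise_floor <- max(noise_floor, 2 * stats::sd(diff(pre_frames) / dt))
  }
  peak <- max(v)
  list(peak_velocity_um_per_s = peak, discard = peak <= noise_floor,
       velocities = v)
}

#' Fit the exponential recoil model
#'
#' Least-squares fit of `d(t) = d0 + A (1 - exp(-t / tau))` by profiling
#' tau (golden-section over log tau with the linear parameters solved
#' exactly at each tau), giving the initial recoil velocity `v0 = A / tau`
#' as a denoised tension proxy. Exact on noiseless traces.
#'
#' @param trace a `recoil_trace` with >= 4 post-ablation samples.
#' @return object of class `recoil_fit`: `d0, A_um, tau_s, v0_um_per_s`,
#'   `fitted`, `converged`.
#' @export
fit_exponential_recoil <- function(trace) {
  t <- trace$times_s; d <- trace$distances_um
  if (length(t) < 5L) stop("need >= 4 post-ablation samples to fit")
  sse_at <- function(log_tau) {
    basis <- 1 - exp(-t / exp(log_tau))
    fit <- stats::lm.fit(cbind(1, basis), d)
    sum(fit$residuals^2)
  }
  opt <- stats::optimize(sse_at, c(log(0.05), log(500)), tol = 1e-12)
  tau <- exp(opt$minimum)
  basis <- 1 - exp(-t / tau)
  fit <- stats::lm.fit(cbind(1, basis), d)
  d0 <- fit$coefficients[1]; A <- fit$coefficients[2]
  converged <- is.finite(A) && is.finite(tau) &&
    tau < 400 && A > -max(1e-6, 0.5 * abs(A))
  if (!converged) warning("exponential recoil fit did not converge cleanly")
  structure(list(d0 = unname(d0), A_um = unname(A), tau_s = tau,
                 v0_um_per_s = unname(A) / tau,
                 fitted = d0 + A * basis, converged = converged),
            class = "recoil_fit")
}

#' @export
print.recoil_fit <- function(x, ...) {
  cat(sprintf("<recoil fit: d0 %.3f um, A %.4f um, tau %.4f s, v0 %.4f um/s%s>\n",
              x$d0, x$A_um, x$tau_s, x$v0_um_per_s,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
coef.recoil_fit <- function(object, ...) {
  c(d0 = object$d0, A_um = object$A_um, tau_s = object$tau_s,
    v0_um_per_s = object$v0_um_per_s)
}

#' Compare peak recoil velocities between two groups
#'
#' Group means of peak velocity with Welch's unpaired t-test; traces flagged
#' for discard (no measurable recoil) are excluded and counted.
#'
#' @param traces_a,traces_b lists of `recoil_trace` objects.
#' @param noise_floor passed to [peak_recoil_velocity()].
#' @return list `mean_a`, `mean_b`, `n_a`, `n_b`, `n_discarded`,
#'   `t_statistic`, `p_value`.
#' @export
compare_recoil_groups <- function(traces_a, traces_b, noise_floor = 0) {
  peaks <- function(traces) {
    r <- lapply(traces, peak_recoil_velocity, noise_floor = noise_floor)
    keep <- !vapply(r, `[[`, logical(1), "discard")
    list(v = vapply(r[keep], `[[`, numeric(1), "peak_velocity_um_per_s"),
         n_disc = sum(!keep))
  }
  a <- peaks(traces_a); b <- peaks(traces_b)
  if (length(a$v) < 2L || length(b$v) < 2L)
    stop("need >= 2 retained traces per group")
  tt <- stats::t.test(a$v, b$v, var.equal = FALSE)
  list(mean_a = mean(a$v), mean_b = mean(b$v),
       n_a = length(a$v), n_b = length(b$v),
       n_discarded = a$n_disc + b$n_disc,
       t_statistic = unname(tt$statistic), p_value = tt$p.value)
}
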