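# Causal linear response from equilibrium correlations (fluctuation-
# dissipation theorem) and its one-sided Fourier transform.

.new_response_fn <- function(t, values, kBT, t_cut = NA_real_, label = "") {
  structure(list(t = t, values = values, kBT = kBT, t_cut = t_cut,
                 label = label), class = "response_fn")
}

#' Response function from a correlation function
#'
#' Applies the fluctuation-dissipation theorem
#' `J(t) = -(1/kBT) * theta(t) * dC/dt`: the causal linear response of the
#' observable to a conjugate force is the negative time derivative of the
#' equilibrium correlation function, divided by the thermal energy. The
#' derivative uses second-order central differences in the interior and
#' one-sided differences at the two ends; no smoothing is applied unless a
#' window is given.
#'
#' @param C A `corr_fn` on a uniform lag grid with at least 3 points.
#' @param kBT Thermal energy in the energy unit of the data. With
#'   separations in nm and stiffnesses expressed in kBT/nm^2 this is 1
#'   (the default); temperature enters only through this scale.
#' @param smooth Optional odd window length for a running-mean smoothing of
#'   `C` before differentiation (default: none).
#' @return A `response_fn` with fields `t` (ps, t >= 0), `values`
#'   (nm^2/(kBT ps) for separation coordinates), `kBT`, `t_cut` (NA until
#'   [apply_cutoff()] is used).
#' @export
response_from_correlation <- function(C, kBT = 1, smooth = NULL) {
  stopifnot(inherits(C, "corr_fn"))
  if (!is.numeric(kBT) || kBT <= 0) stop("kBT must be positive")
  n <- length(C$lags)
  if (n < 3L) stop("insufficient data: need at least 3 lags")
  v <- C$values
  if (!is.null(smooth)) {
    w <- as.integer(smooth)
    if (w < 1L || w %% 2L == 0L) stop("smoothing window must be odd")
    if (w > 1L)
      v <- stats::filter(v, rep(1 / w, w), sides = 2) |>
        (\(z) { z[is.na(z)] <- v[is.na(z)]; as.numeric(z) })()
  }
  dt <- C$dt
  d <- numeric(n)
  d[1L] <- (v[2L] - v[1L]) / dt
  d[n] <- (v[n] - v[n - 1L]) / dt
  if (n > 2L) d[2:(n - 1L)] <- (v[3:n] - v[1:(n - 2L)]) / (2 * dt)
  .new_response_fn(C$lags, -d / kBT, kBT,
                   label = paste(C$kind, paste(C$labels, collapse = "~")))
}

#' Truncate a response function beyond a cutoff time
#'
#' Values beyond `t_cut` are set to exactly zero; this suppresses the
#' long-lag noise tail of correlation-derived responses before Fourier
#' transformation. With `t_cut = "auto"` the cutoff is chosen adaptively:
#' the noise floor is estimated as the mean of `|J|` over the final 10% of
#' lags, and the signal end is the first time (searching the first 90% of
#' the lag range) at which the trailing running mean of `|J|` over a short
#' window (0.5% of the range, at least 5 samples) drops below that floor.
#' The cutoff is twice the signal-end time (safety margin); if no crossing
#' exists the full range is kept. Every lag of pure noise included beyond
#' the decay of the response inflates the variance of the Fourier
#' transform, so a tight cutoff matters when the lag range is much longer
#' than the relaxation time.
#'
#' @param J A `response_fn`.
#' @param t_cut Positive time in ps (at most the maximum lag), or `"auto"`.
#' @return The truncated `response_fn` with `t_cut` recorded.
#' @export
apply_cutoff <- function(J, t_cut = "auto") {
  stopifnot(inherits(J, "response_fn"))
  if (identical(t_cut, "auto")) t_cut <- auto_cutoff(J)
  if (!is.numeric(t_cut) || length(t_cut) != 1L || t_cut <= 0)
    stop("invalid cutoff: t_cut must be positive")
  tmax <- max(J$t)
  if (t_cut > tmax + 1e-12 * tmax)
    stop("invalid cutoff: t_cut exceeds the lag range (", tmax, " ps)")
  v <- J$values
  v[J$t > t_cut] <- 0
  .new_response_fn(J$t, v, J$kBT, t_cut, J$label)
}

#' Automatic cutoff selection for a noisy response function
#'
#' @param J A `response_fn`.
#' @return Cutoff time in ps.
#' @export
auto_cutoff <- function(J) {
  stopifnot(inherits(J, "response_fn"))
  n <- length(J$t)
  absj <- abs(J$values)
  tail_idx <- seq.int(max(1L, ceiling(0.9 * n)), n)
  floor_level <- mean(absj[tail_idx])
  w <- max(5L, round(0.005 * n))
  run <- stats::filter(absj, rep(1 / w, w), sides = 1)  # trailing mean
  search <- which(!is.na(run) & seq_len(n) <= floor(0.9 * n))
  hit <- search[run[search] < floor_level]
  if (!length(hit)) return(max(J$t))
  min(2 * J$t[hit[1L]], max(J$t))   # factor-2 safety margin
}

#' One-sided Fourier transform of a causal response function
#'
#' Computes `J~(omega) = integral_0^inf J(t) exp(+i omega t) dt` by
#' trapezoidal quadrature on the stored t grid (restricted to the cutoff).
#' Under this sign convention a single-exponential response `exp(-t/tau)`
#' maps to the elementary Debye form `tau/(1 - i omega tau)`, with
#' non-negative real and imaginary parts for positive amplitudes.
#'
#' @param J A `response_fn` (apply a cutoff first for noisy data).
#' @param omega Frequency grid in rad/ps; default is [omega_grid()] of `J`.
#' @return A `spectral_fn`: list with `omega` and complex `values`.
#' @export
fourier_response <- function(J, omega = NULL) {
  stopifnot(inherits(J, "response_fn"))
  if (is.null(omega)) omega <- omega_grid(J)
  if (!length(omega)) stop("invalid input: empty frequency grid")
  if (is.unsorted(omega, strictly = TRUE)) stop("omega grid must be strictly increasing")
  tmax <- if (is.finite(J$t_cut) && !is.na(J$t_cut)) J$t_cut else max(J$t)
  keep <- J$t <= tmax + 1e-12
  tt <- J$t[keep]; vv <- J$values[keep]
  nt <- length(tt)
  wts <- c(0.5, rep(1, nt - 2L), 0.5) * (tt[2L] - tt[1L])
  ph <- exp(1i * outer(omega, tt))          # n_omega x n_t
  vals <- as.vector(ph %*% (vv * wts))
  spectral_fn(omega, vals)
}

#' Construct a spectral function
#'
#' @param omega Strictly increasing frequency grid (rad/ps, omega >= 0).
#' @param values Complex values on the grid.
#' @return A `spectral_fn`.
#' @export
spectral_fn <- function(omega, values) {
  omega <- as.numeric(omega)
  values <- as.complex(values)
  if (length(omega) != length(values)) stop("grid/value length mismatch")
  if (any(!is.finite(omega)) || any(omega < 0)) stop("invalid omega grid")
  if (length(omega) > 1L && is.unsorted(omega, strictly = TRUE))
    stop("omega grid must be strictly increasing")
  if (any(!is.finite(Re(values)) | !is.finite(Im(values))))
    stop("non-finite spectral values")
  structure(list(omega = omega, values = values), class = "spectral_fn")
}

#' Default logarithmic frequency grid for a response function
#'
#' 200 log-spaced points spanning `[1e-4 * 2*pi / t_cut, pi / dt]` rad/ps:
#' four decades below the slowest resolvable relaxation up to the sampling
#' Nyquist frequency (the quadrature carries no information beyond it).
#'
#' @param J A `response_fn`, or `NULL` if `dt` and `t_cut` are given.
#' @param n Number of points.
#' @param omega_min,omega_max Optional explicit limits (rad/ps).
#' @return Numeric vector of frequencies.
#' @export
omega_grid <- function(J = NULL, n = 200L, omega_min = NULL, omega_max = NULL) {
  if (!is.null(J)) {
    dt <- J$t[2L] - J$t[1L]
    tc <- if (!is.na(J$t_cut)) J$t_cut else max(J$t)
  } else {
    dt <- 1; tc <- 100
  }
  if (is.null(omega_min)) omega_min <- 1e-4 * 2 * pi / tc
  if (is.null(omega_max)) omega_max <- pi / dt
  exp(seq(log(omega_min), log(omega_max), length.out = n))
}

#' Write spectral values as TSV (columns omega_rad_per_ps, re, im)
#' @param S A `spectral_fn`.
#' @param path Output path.
#' @export
write_spectrum <- function(S, path) {
  stopifnot(inherits(S, "spectral_fn"))
  utils::write.table(
    data.frame(omega_rad_per_ps = S$omega, re = Re(S$values), im = Im(S$values)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a response function as TSV (columns t_ps, value)
#' @param J A `response_fn`.
#' @param path Output path.
#' @export
write_response <- function(J, path) {
  stopifnot(inherits(J, "response_fn"))
  utils::write.table(data.frame(t_ps = J$t, value = J$values),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
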