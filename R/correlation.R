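# Equilibrium time-correlation estimation.

# raw lag sums S(l) = sum_t a[t] b[t+l], l = 0..n_lag, via zero-padded FFT
.lag_sums_fft <- function(a, b, n_lag) {
  L <- length(a)
  nf <- stats::nextn(2L * L, 2L)
  fa <- stats::fft(c(a, rep(0, nf - L)))
  fb <- stats::fft(c(b, rep(0, nf - L)))
  Re(stats::fft(Conj(fa) * fb, inverse = TRUE))[1:(n_lag + 1L)] / nf
}

.lag_sums_direct <- function(a, b, n_lag) {
  L <- length(a)
  vapply(0:n_lag, function(l) sum(a[1:(L - l)] * b[(1 + l):L]), numeric(1))
}

.new_corr_fn <- function(lags, values, kind, mean_subtracted, labels, dt,
                         asymmetry = NA_real_) {
  structure(list(lags = lags, values = values, kind = kind,
                 mean_subtracted = mean_subtracted, labels = labels,
                 dt = dt, asymmetry = asymmetry),
            class = "corr_fn")
}

#' Estimate an equilibrium time-correlation function
#'
#' Computes `C(tau) = <A(t) B(t+tau)>` with the unbiased-for-stationary
#' normalisation `1/(L - tau)` over the overlap, on the lag grid
#' `0, dt, ..., max_lag`. For a cross correlation (`A` not identical to `B`)
#' the two orderings `<A(0)B(tau)>` and `<B(0)A(tau)>` are averaged
#' (Onsager reciprocity guarantees their equality in equilibrium); their
#' maximum absolute difference is reported as the `asymmetry` diagnostic.
#'
#' @param A,B [ts_series()] objects on the same grid; `B` defaults to `A`
#'   (self correlation).
#' @param max_lag Maximum lag in ps; must be smaller than the series span.
#' @param subtract_mean Remove the sample means before correlating
#'   (default `TRUE`; use `FALSE` e.g. for raw unit-vector products).
#' @param kind Optional kind tag (`"self-sensor"`, `"self-effector"`,
#'   `"cross"`, ...); inferred as `"self"`/`"cross"` when missing.
#' @param method `"fft"` (zero-padded FFT, O(L log L)) or `"direct"`
#'   (explicit lag sums, retained as an independent reference path).
#' @param symmetrize Average the two orderings of a cross correlation
#'   (default `TRUE`); set `FALSE` to obtain the raw `<A(0)B(tau)>`
#'   ordering, e.g. for reciprocity diagnostics.
#' @return A `corr_fn` with fields `lags` (ps), `values`, `kind`,
#'   `mean_subtracted`, `labels`, `dt`, `asymmetry`.
#' @export
estimate_correlation <- function(A, B = A, max_lag,
                                 subtract_mean = TRUE,
                                 kind = NULL,
                                 method = c("fft", "direct"),
                                 symmetrize = TRUE) {
  stopifnot(inherits(A, "ts_series"), inherits(B, "ts_series"))
  method <- match.arg(method)
  if (abs(A$dt - B$dt) > 1e-12 * A$dt)
    stop("incompatible series: dt differs (", A$dt, " vs ", B$dt, ")")
  L <- length(A$values)
  if (L != length(B$values))
    stop("incompatible series: lengths differ (", L, " vs ",
         length(B$values), ")")
  n_lag <- as.integer(round(max_lag / A$dt))
  if (n_lag < 1L || n_lag >= L)
    stop("invalid lag: max_lag must lie in [dt, span) of the series")
  a <- A$values; b <- B$values
  if (subtract_mean) { a <- a - mean(a); b <- b - mean(b) }
  is_self <- identical(A$values, B$values)
  sums <- switch(method, fft = .lag_sums_fft, direct = .lag_sums_direct)
  norm <- L - 0:n_lag
  if (is_self) {
    vals <- sums(a, a, n_lag) / norm
    asym <- 0
  } else {
    ab <- sums(a, b, n_lag) / norm
    if (symmetrize) {
      ba <- sums(b, a, n_lag) / norm
      vals <- (ab + ba) / 2
      asym <- max(abs(ab - ba))
    } else {
      vals <- ab
      asym <- NA_real_
    }
  }
  if (is.null(kind)) kind <- if (is_self) "self" else "cross"
  .new_corr_fn((0:n_lag) * A$dt, vals, kind, subtract_mean,
               c(A$label, B$label), A$dt, asym)
}

# correlation of multi-component (matrix) observables: sum over columns of
# per-component correlations; used for unit-vector scalar-product kinetics
.correlate_components <- function(U, V, dt, n_lag, symmetrize) {
  L <- nrow(U)
  norm <- L - 0:n_lag
  vals <- numeric(n_lag + 1L)
  asym <- 0
  for (j in seq_len(ncol(U))) {
    uv <- .lag_sums_fft(U[, j], V[, j], n_lag) / norm
    if (symmetrize) {
      vu <- .lag_sums_fft(V[, j], U[, j], n_lag) / norm
      vals <- vals + (uv + vu) / 2
      asym <- max(asym, max(abs(uv - vu)))
    } else vals <- vals + uv
  }
  list(values = vals, asymmetry = asym)
}

#' @export
print.corr_fn <- function(x, ...) {
  cat(sprintf("<corr_fn> %s [%s ~ %s]: %d lags, dt = %g ps, C(0) = %.6g\n",
              x$kind, x$labels[1L], x$labels[2L], length(x$lags), x$dt,
              x$values[1L]))
  invisible(x)
}

#' Write a correlation function as TSV
#'
#' Columns: `lag_ps`, `value`, `kind`.
#' @param C A `corr_fn`.
#' @param path Output path.
#' @export
write_correlation <- function(C, path) {
  stopifnot(inherits(C, "corr_fn"))
  df <- data.frame(lag_ps = C$lags, value = C$values, kind = C$kind)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
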