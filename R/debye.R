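# Multi-Debye relaxation models: evaluation in both domains and
# simultaneous least-squares fitting to Re/Im of a spectral response.

#' Construct a multi-Debye relaxation model
#'
#' The model is `J~(omega) = sum_k a_k / (1 - i omega tau_k)` under the
#' `exp(+i omega t)` one-sided transform convention, equivalently
#' `J(t) = sum_k (a_k / tau_k) exp(-t / tau_k)` for `t >= 0`. Amplitudes are
#' real and unconstrained in sign (cross responses may need negative terms);
#' relaxation times are positive, stored sorted, and duplicate times are
#' merged by summing their amplitudes.
#'
#' @param a Amplitudes (units of `J~(0)`).
#' @param tau Relaxation times in ps; strictly positive.
#' @return A `debye_model`; empty models (`n = 0`) evaluate to zero.
#' @export
debye_model <- function(a = numeric(), tau = numeric()) {
  a <- as.numeric(a); tau <- as.numeric(tau)
  if (length(a) != length(tau)) stop("a and tau must have equal length")
  if (length(tau)) {
    if (any(!is.finite(a)) || any(!is.finite(tau)) || any(tau <= 0))
      stop("amplitudes must be finite and relaxation times positive")
    o <- order(tau)
    a <- a[o]; tau <- tau[o]
    # merge (near-)duplicate relaxation times
    if (length(tau) > 1L) {
      grp <- cumsum(c(TRUE, diff(tau) > 1e-9 * tau[-1L]))
      a <- as.numeric(tapply(a, grp, sum))
      tau <- as.numeric(tapply(tau, grp, function(z) z[1L]))
    }
  }
  structure(list(a = a, tau = tau, n = length(a)), class = "debye_model")
}

#' @export
print.debye_model <- function(x, ...) {
  cat(sprintf("<debye_model> %d components, J~(0) = %.6g\n", x$n, sum(x$a)))
  if (x$n) print(data.frame(a = x$a, tau_ps = x$tau))
  invisible(x)
}

#' Evaluate a Debye model in the frequency domain
#'
#' @param model A [debye_model()].
#' @param omega Frequencies in rad/ps.
#' @return Complex vector `sum_k a_k / (1 - i omega tau_k)`.
#' @export
debye_eval <- function(model, omega) {
  stopifnot(inherits(model, "debye_model"))
  if (!model$n) return(rep(0 + 0i, length(omega)))
  out <- rep(0 + 0i, length(omega))
  for (k in seq_len(model$n))
    out <- out + model$a[k] / (1 - 1i * omega * model$tau[k])
  out
}

#' Evaluate a Debye model in the time domain
#'
#' Exact inverse of [debye_eval()] under the module convention:
#' `J(t) = sum_k (a_k / tau_k) exp(-t / tau_k)`, defined for `t >= 0` only.
#'
#' @param model A [debye_model()].
#' @param t Times in ps, all non-negative.
#' @return A `response_fn` on the given grid (use `$values` for the numbers).
#' @export
debye_time <- function(model, t) {
  stopifnot(inherits(model, "debye_model"))
  if (any(t < 0)) stop("causality violation: negative time requested")
  v <- numeric(length(t))
  for (k in seq_len(model$n))
    v <- v + (model$a[k] / model$tau[k]) * exp(-t / model$tau[k])
  .new_response_fn(t, v, kBT = 1, t_cut = NA_real_, label = "debye")
}

# linear amplitude solve for fixed taus (variable projection inner step);
# a small ridge keeps near-collinear components (near-duplicate taus) from
# exploding into huge cancelling amplitude pairs
.debye_lstsq <- function(omega, y, tau, lambda = 0) {
  d <- 1 / (1 - 1i * outer(omega, tau))      # m x n complex basis
  M <- rbind(Re(d), Im(d))                   # 2m x n real design
  sv <- svd(M)
  pos <- sv$d > max(sv$d) * 1e-12
  dd <- sv$d[pos]
  a <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], y)) * dd / (dd^2 + lambda))
  a <- as.numeric(a)
  r <- y - M %*% a
  list(a = a, rss = sum(r * r))
}

#' Fit a multi-Debye model to a complex spectrum
#'
#' Simultaneous least squares on the real and imaginary parts:
#' minimises `sum_omega [Re residual^2 + Im residual^2]` on the stored
#' (typically log-spaced) grid with uniform weights. Uses variable
#' projection: for fixed relaxation times the amplitudes are solved
#' linearly (SVD least squares), and the times - constrained positive via
#' log-parameterisation - are refined by Nelder-Mead from multiple
#' log-spaced, seed-jittered initialisations. The best start by residual
#' norm is returned (ties broken by fewer above-floor components).
#'
#' @param spectrum A `spectral_fn` with at least `2 * n_components` points.
#' @param n_components Number of Debye terms (default 10).
#' @param seed Integer seed for the start jitter.
#' @param n_starts Number of multi-start initialisations (default 16; the
#'   first start is the unjittered log-spaced ladder).
#' @param tau_range Search range for relaxation times in ps; defaults to
#'   `[0.5/max(omega), 2/min(omega)]` (what the grid resolves). Times are
#'   softly confined to this range by a quadratic log-distance penalty.
#' @param ridge Relative ridge weight of the amplitude solve (scaled by
#'   `sum(y^2)`); regularises near-duplicate relaxation times.
#' @param select `"fixed"` fits exactly `n_components` terms; `"bic"` fits
#'   1 to `n_components` terms and returns the model minimising the
#'   Bayesian information criterion `m log(rss/m) + 2 n log(m)` (`m` =
#'   number of real data points). Parsimony selection keeps surplus
#'   components from chasing noise in the weakly constrained
#'   high-frequency tail.
#' @return A [debye_model()] with attributes `rss` (residual sum of
#'   squares), `resid_norm`, `contrib` (per-component `|a_k|`) and, for
#'   `select = "bic"`, `bic`.
#' @export
fit_debye <- function(spectrum, n_components = 10L, seed = 1L,
                      n_starts = 16L, tau_range = NULL, ridge = 1e-6,
                      select = c("fixed", "bic")) {
  stopifnot(inherits(spectrum, "spectral_fn"))
  select <- match.arg(select)
  n <- as.integer(n_components)
  if (n < 1L) stop("n_components must be >= 1")
  if (select == "bic") {
    m <- 2L * length(spectrum$omega)
    best <- NULL
    for (k in seq_len(n)) {
      f <- fit_debye(spectrum, n_components = k, seed = seed,
                     n_starts = n_starts, tau_range = tau_range,
                     ridge = ridge, select = "fixed")
      bic <- m * log(attr(f, "rss") / m) + (2 * k) * log(m)
      if (is.null(best) || bic < attr(best, "bic")) {
        attr(f, "bic") <- bic
        best <- f
      }
    }
    return(best)
  }
  m <- length(spectrum$omega)
  if (m < 2L * n)
    stop("under-determined fit: need at least ", 2L * n, " spectral points")
  if (any(!is.finite(Re(spectrum$values)) | !is.finite(Im(spectrum$values))))
    stop("non-finite spectrum rejected")
  omega <- spectrum$omega
  y <- c(Re(spectrum$values), Im(spectrum$values))
  if (is.null(tau_range)) {
    wpos <- omega[omega > 0]
    tau_range <- c(0.5 / max(wpos), 2 / min(wpos))
  }
  lambda <- ridge * sum(y * y)
  lrange <- log(tau_range)
  pscale <- 10 * max(sum(y * y), 1e-300)
  obj <- function(ltau) {
    tau <- exp(ltau)
    if (any(!is.finite(tau))) return(.Machine$double.xmax)
    pen <- pscale * sum(pmax(0, ltau - lrange[2L])^2 +
                          pmax(0, lrange[1L] - ltau)^2)
    .debye_lstsq(omega, y, tau, lambda)$rss + pen
  }
  base <- if (n == 1L) sqrt(prod(tau_range)) else
    exp(seq(log(tau_range[1L]), log(tau_range[2L]), length.out = n))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  best <- NULL
  for (s in seq_len(n_starts)) {
    tau0 <- if (s == 1L) base else base * exp(stats::rnorm(n, 0, 0.5))
    opt <- if (n == 1L) {
      o <- stats::optimize(obj, lrange + c(-2, 2), tol = 1e-12)
      list(par = o$minimum)
    } else {
      stats::optim(log(tau0), obj, method = "Nelder-Mead",
                   control = list(maxit = 400L * n, reltol = 1e-14))
    }
    sol <- .debye_lstsq(omega, y, exp(opt$par), lambda)
    floor_amp <- 1e-3 * sum(abs(sol$a))
    n_eff <- sum(abs(sol$a) > floor_amp)
    cand <- list(tau = exp(opt$par), a = sol$a, rss = sol$rss, n_eff = n_eff)
    if (is.null(best) || cand$rss < best$rss * (1 - 1e-12) ||
        (abs(cand$rss - best$rss) <= 1e-12 * max(best$rss, 1e-300) &&
         cand$n_eff < best$n_eff))
      best <- cand
  }
  model <- debye_model(best$a, best$tau)
  attr(model, "rss") <- best$rss
  attr(model, "resid_norm") <- sqrt(best$rss)
  attr(model, "contrib") <- abs(model$a)
  model
}

#' Longest relevant relaxation time of a Debye model
#'
#' The relaxation time of a multi-exponential response is defined as the
#' largest decay time among components whose amplitude magnitude exceeds a
#' floor (default `1e-3` of the total absolute amplitude), so that
#' numerically negligible terms introduced by over-parameterised fits do
#' not dominate.
#'
#' @param model A non-empty [debye_model()].
#' @param floor_frac Amplitude floor as a fraction of `sum(|a|)`.
#' @return `tau_max` in ps.
#' @export
relaxation_time <- function(model, floor_frac = 1e-3) {
  stopifnot(inherits(model, "debye_model"))
  if (!model$n) stop("degenerate model: no components")
  keep <- abs(model$a) > floor_frac * sum(abs(model$a))
  if (!any(keep)) stop("degenerate model: all amplitudes below floor")
  max(model$tau[keep])
}

#' Serialize a Debye model to JSON
#' @param model A [debye_model()].
#' @param path Output path.
#' @export
write_debye <- function(model, path) {
  stopifnot(inherits(model, "debye_model"))
  jsonlite::write_json(
    list(components = data.frame(a = model$a, tau_ps = model$tau),
         convention = "plus_i_omega_t"),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a Debye model from JSON
#' @param path Path written by [write_debye()].
#' @return A [debye_model()].
#' @export
read_debye <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$convention, "plus_i_omega_t"))
    stop("unknown spectral convention: ", x$convention)
  debye_model(x$components$a, x$components$tau_ps)
}
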