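# Overdamped harmonic (multivariate Ornstein-Uhlenbeck) benchmark networks
# with exact discretization and closed-form response/transmit oracles.

#' Define an overdamped harmonic network
#'
#' The coordinates obey `Gamma dX/dt = -K X + xi` with white thermal noise
#' `<xi(t) xi(t')^T> = 2 kBT Gamma delta(t - t')`. With stiffnesses in
#' kBT/nm^2 and frictions in kBT ps/nm^2, lengths are in nm and `kBT = 1`.
#'
#' @param K Symmetric positive-definite stiffness matrix (kBT/nm^2).
#' @param gamma Positive frictions (kBT ps/nm^2), one per coordinate
#'   (diagonal friction matrix).
#' @param kBT Thermal energy scale (default 1, reduced units).
#' @param labels Coordinate labels.
#' @return A `langevin_network`.
#' @export
langevin_network <- function(K, gamma, kBT = 1, labels = NULL) {
  K <- as.matrix(K)
  d <- nrow(K)
  if (ncol(K) != d) stop("K must be square")
  if (max(abs(K - t(K))) > 1e-10 * max(abs(K)))
    stop("K must be symmetric")
  K <- (K + t(K)) / 2
  gamma <- rep_len(as.numeric(gamma), d)
  if (any(gamma <= 0)) stop("frictions must be strictly positive")
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop("K not positive definite: offending eigenvalue ", format(min(ev)))
  if (is.null(labels)) labels <- paste0("x", seq_len(d))
  structure(list(K = K, gamma = gamma, kBT = kBT, labels = labels, d = d),
            class = "langevin_network")
}

# generalized eigenmodes: K v = lambda Gamma v with V' Gamma V = I, so that
# (K - i w Gamma)^{-1} = V diag(1/(lambda - i w)) V'
.network_modes <- function(net) {
  gi <- 1 / sqrt(net$gamma)
  M <- diag(gi, net$d) %*% net$K %*% diag(gi, net$d)
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  list(lambda = rev(e$values), V = diag(gi, net$d) %*% e$vectors[, net$d:1])
}

#' Simulate a stationary trajectory of the network
#'
#' Uses the exact discrete-time update of the multivariate
#' Ornstein-Uhlenbeck process: in the (generalized) eigenbasis of the
#' friction-weighted stiffness the dynamics decouple into independent
#' scalar AR(1) recursions with the matrix-exponential propagator
#' `exp(-lambda dt)` and the exact conditional variance, so the simulated
#' process has no time-step discretization bias. The initial state is drawn
#' from the stationary distribution.
#'
#' @param net A [langevin_network()].
#' @param dt Time step in ps.
#' @param n_steps Number of frames (>= 2).
#' @param seed Integer seed.
#' @return Named list of [ts_series()], one per coordinate.
#' @export
simulate_network <- function(net, dt, n_steps, seed = 1L) {
  stopifnot(inherits(net, "langevin_network"))
  if (dt <= 0) stop("dt must be positive")
  n_steps <- as.integer(n_steps)
  if (n_steps < 2L) stop("n_steps must be >= 2")
  md <- .network_modes(net)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  Y <- matrix(0, n_steps, net$d)
  for (k in seq_len(net$d)) {
    lam <- md$lambda[k]
    phi <- exp(-lam * dt)
    svar <- net$kBT / lam
    y0 <- stats::rnorm(1L, 0, sqrt(svar))
    inn <- stats::rnorm(n_steps - 1L, 0, sqrt(svar * (1 - phi^2)))
    Y[, k] <- c(y0, as.numeric(stats::filter(inn, phi, method = "recursive",
                                             init = y0)))
  }
  X <- Y %*% t(md$V)
  out <- lapply(seq_len(net$d),
                function(i) ts_series(X[, i], dt, net$labels[i]))
  names(out) <- net$labels
  out
}

#' Exact Debye representation of a pairwise response
#'
#' The frequency response `J~(omega) = (K - i omega Gamma)^{-1}` decomposes
#' over the network eigenmodes into an exact multi-Debye sum:
#' `J~_ij(omega) = sum_k a_k / (1 - i omega tau_k)` with
#' `a_k = v_ik v_jk / lambda_k` and `tau_k = 1/lambda_k`.
#'
#' @param net A [langevin_network()].
#' @param i,j Coordinate indices.
#' @return A [debye_model()].
#' @export
analytic_debye <- function(net, i, j) {
  stopifnot(inherits(net, "langevin_network"))
  md <- .network_modes(net)
  debye_model(md$V[i, ] * md$V[j, ] / md$lambda, 1 / md$lambda)
}

#' Exact frequency response of the network
#'
#' @param net A [langevin_network()].
#' @param omega Frequencies in rad/ps.
#' @param i,j Optional pair of coordinate indices; if given, a
#'   `spectral_fn` for that entry is returned, otherwise a complex array
#'   `d x d x n_omega` of the full `(K - i omega Gamma)^{-1}`.
#' @export
analytic_response <- function(net, omega, i = NULL, j = NULL) {
  stopifnot(inherits(net, "langevin_network"))
  if (!is.null(i) && !is.null(j))
    return(spectral_fn(omega, debye_eval(analytic_debye(net, i, j), omega)))
  md <- .network_modes(net)
  out <- array(0 + 0i, c(net$d, net$d, length(omega)))
  for (w in seq_along(omega)) {
    out[, , w] <- md$V %*% diag(1 / (md$lambda - 1i * omega[w]), net$d) %*%
      t(md$V)
  }
  out
}

#' Exact response triplet of a channel in the network
#'
#' @param net A [langevin_network()].
#' @param s,e Sensor and effector coordinate indices.
#' @return A [response_triplet()] of exact [debye_model()]s.
#' @export
analytic_triplet <- function(net, s = 1L, e = 2L) {
  if (s == e) stop("sensor and effector must differ")
  response_triplet(analytic_debye(net, s, s), analytic_debye(net, e, e),
                   analytic_debye(net, s, e),
                   label = paste0(net$labels[s], "->", net$labels[e]))
}

#' Exact transmit function of a channel in the network
#'
#' For a two-bead network with sensor anchor `k_s`, effector anchor `k_e`,
#' coupling `k_c` and frictions `gamma`, the closed form is
#' `T~_F^{s->e}(omega) = k_c / (k_s + k_c - i omega gamma_s)` (and with
#' `s` and `e` exchanged for the reverse direction).
#'
#' @param net A [langevin_network()].
#' @param s,e Sensor and effector coordinate indices.
#' @param direction `"s_to_e"` or `"e_to_s"`.
#' @param omega Frequencies in rad/ps.
#' @return A `transmit_spectrum` carrying exact Debye models.
#' @export
analytic_transmit <- function(net, s = 1L, e = 2L,
                              direction = c("s_to_e", "e_to_s"), omega) {
  direction <- match.arg(direction)
  force_transmit(analytic_triplet(net, s, e), direction, omega)
}

#' Rotational relaxation time from Stokes' law
#'
#' `tau_r = 1/(2 D_r)` with the rotational diffusion coefficient
#' `D_r = kB T / (8 pi eta R_h^3)` of a sphere of hydrodynamic radius `R_h`
#' in a medium of viscosity `eta`.
#'
#' @param viscosity Dynamic viscosity in Pa s.
#' @param radius_nm Hydrodynamic radius in nm.
#' @param temperature_K Temperature in K.
#' @return Relaxation time in seconds.
#' @export
stokes_rotation_time <- function(viscosity, radius_nm, temperature_K) {
  if (viscosity <= 0 || radius_nm <= 0 || temperature_K <= 0)
    stop("all inputs must be positive")
  kB <- 1.380649e-23
  Dr <- kB * temperature_K / (8 * pi * viscosity * (radius_nm * 1e-9)^3)
  1 / (2 * Dr)
}

#' Read a network from a JSON config (fields K, gamma, kBT, labels)
#' @param path Path to the config file.
#' @return A [langevin_network()].
#' @export
read_network <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  langevin_network(x$K, x$gamma,
                   kBT = if (is.null(x$kBT)) 1 else x$kBT,
                   labels = x$labels)
}

#' Two-bead benchmark network
#'
#' Two coordinates anchored with stiffness `k_s` (sensor) and `k_e`
#' (effector) and coupled with stiffness `k_c`:
#' `K = [[k_s + k_c, -k_c], [-k_c, k_e + k_c]]`.
#'
#' @param k_s,k_e,k_c Stiffnesses in kBT/nm^2.
#' @param gamma_s,gamma_e Frictions in kBT ps/nm^2.
#' @return A [langevin_network()] with labels `sensor`, `effector`.
#' @export
two_bead_network <- function(k_s = 1, k_e = 1, k_c = 1,
                             gamma_s = 1, gamma_e = 1) {
  langevin_network(matrix(c(k_s + k_c, -k_c, -k_c, k_e + k_c), 2L, 2L),
                   c(gamma_s, gamma_e), labels = c("sensor", "effector"))
}
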