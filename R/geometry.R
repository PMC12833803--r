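# Shift/splay/twist deformation modes of a two-helix bundle from
# per-frame terminal coordinates, with rigid-body motion removal.

.rownorm <- function(M) sqrt(rowSums(M * M))
.rowcross <- function(U, V) {
  cbind(U[, 2L] * V[, 3L] - U[, 3L] * V[, 2L],
        U[, 3L] * V[, 1L] - U[, 1L] * V[, 3L],
        U[, 1L] * V[, 2L] - U[, 2L] * V[, 1L])
}

#' Construct per-frame terminal coordinates of a two-helix bundle
#'
#' @param N1,N2,C1,C2 n-frame x 3 matrices of the two N-terminal and two
#'   C-terminal positions (nm).
#' @param dt Frame spacing in ps.
#' @return A `terminal_coords` object.
#' @export
terminal_coords <- function(N1, N2, C1, C2, dt) {
  mats <- list(N1 = N1, N2 = N2, C1 = C1, C2 = C2)
  n <- nrow(N1)
  for (nm in names(mats)) {
    m <- as.matrix(mats[[nm]])
    if (ncol(m) != 3L || nrow(m) != n) stop(nm, " must be n x 3")
    if (any(!is.finite(m))) stop("non-finite coordinate in ", nm)
    mats[[nm]] <- m
  }
  structure(c(mats, list(dt = dt, n = n)), class = "terminal_coords")
}

#' Read terminal coordinates from 13-column delimited text
#'
#' Columns: `time_ps`, then N1, N2, C1, C2 xyz in nm (12 coordinate
#' columns). Time must be strictly increasing and uniform.
#'
#' @param path Path to the file.
#' @return A [terminal_coords()] object.
#' @export
read_terminal_coordinates <- function(path) {
  series <- read_timeseries(path)
  if (length(series) != 12L)
    stop("expected 12 coordinate columns after the time column, got ",
         length(series))
  dt <- series[[1L]]$dt
  g <- function(i) cbind(series[[i]]$values, series[[i + 1L]]$values,
                         series[[i + 2L]]$values)
  terminal_coords(g(1L), g(4L), g(7L), g(10L), dt)
}

#' Decompose a bundle trajectory into shift, splay, and signed twist
#'
#' Per frame, with `n = N2 - N1`, `c = C2 - C1`, `a_i = C_i - N_i` and the
#' symmetrized bundle axis `a = (a_1 + a_2)/2`: the shift is the component
#' of the terminal separation parallel to the axis (`n_sh = |n . a_hat|`),
#' the splay its perpendicular complement, and the twist the signed angle
#' between the two splay unit vectors,
#' `phi = atan2((n_hat_sp x c_hat_sp) . a_hat, n_hat_sp . c_hat_sp)`
#' (positive = right-handed rotation about the axis). Frames whose splay
#' magnitude falls below 1e-9 nm have undefined twist and are flagged, not
#' interpolated.
#'
#' @param frames A [terminal_coords()] trajectory.
#' @return A `mode_trajectory`: data frame with columns `time_ps`, `n_sh`,
#'   `n_sp`, `c_sh`, `c_sp`, `phi`, plus attributes `nsp_hat`, `csp_hat`
#'   (splay unit vectors, for twist correlation functions), `dt` and
#'   `flagged` (indices of undefined-twist frames).
#' @export
decompose_modes <- function(frames) {
  stopifnot(inherits(frames, "terminal_coords"))
  a <- ((frames$C1 - frames$N1) + (frames$C2 - frames$N2)) / 2
  na <- .rownorm(a)
  if (any(na <= 1e-6))
    stop("degenerate bundle axis (|a| <= 1e-6 nm) at frame ",
         which(na <= 1e-6)[1L])
  ahat <- a / na
  dec <- function(v) {
    par <- rowSums(v * ahat)
    sp_vec <- v - par * ahat
    list(sh = abs(par), sp = .rownorm(sp_vec), sp_vec = sp_vec)
  }
  dn <- dec(frames$N2 - frames$N1)
  dc <- dec(frames$C2 - frames$C1)
  flagged <- which(dn$sp < 1e-9 | dc$sp < 1e-9)
  nhat <- dn$sp_vec / pmax(dn$sp, 1e-300)
  chat <- dc$sp_vec / pmax(dc$sp, 1e-300)
  phi <- atan2(rowSums(.rowcross(nhat, chat) * ahat), rowSums(nhat * chat))
  if (length(flagged)) {
    phi[flagged] <- NA_real_
    nhat[flagged, ] <- NA_real_
    chat[flagged, ] <- NA_real_
  }
  out <- data.frame(time_ps = (seq_len(frames$n) - 1L) * frames$dt,
                    n_sh = dn$sh, n_sp = dn$sp, c_sh = dc$sh, c_sp = dc$sp,
                    phi = phi)
  structure(out, class = c("mode_trajectory", "data.frame"),
            nsp_hat = nhat, csp_hat = chat, dt = frames$dt,
            flagged = flagged)
}

# Kabsch least-squares rotation R such that P %*% R best matches Q
# (rows = points); H = P^T Q, svd H = U D V^T, R = U diag(1,1,d) V^T with
# d = sign(det(U V^T)) enforcing a proper rotation
.kabsch <- function(P, Q) {
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Remove rigid-body translation and rotation from a bundle trajectory
#'
#' Each frame's four terminal points are translated to zero centroid and
#' rotated by the least-squares (Kabsch) superposition onto the reference
#' frame's centered points, leaving only internal deformation. Collinear
#' point sets cannot fix a rotation and are rejected.
#'
#' @param frames A [terminal_coords()] trajectory.
#' @param reference Reference frame index (default 1).
#' @return Aligned [terminal_coords()].
#' @export
remove_rigid_body <- function(frames, reference = 1L) {
  stopifnot(inherits(frames, "terminal_coords"))
  n <- frames$n
  reference <- as.integer(reference)
  if (reference < 1L || reference > n) stop("invalid reference frame")
  stack <- function(i) rbind(frames$N1[i, ], frames$N2[i, ],
                             frames$C1[i, ], frames$C2[i, ])
  Qr <- stack(reference)
  Qr <- sweep(Qr, 2L, colMeans(Qr))
  svr <- svd(Qr)
  if (svr$d[2L] < 1e-12 * max(svr$d[1L], 1))
    stop("unalignable frame: reference points are collinear")
  out <- list(N1 = frames$N1, N2 = frames$N2, C1 = frames$C1, C2 = frames$C2)
  for (i in seq_len(n)) {
    P <- stack(i)
    P <- sweep(P, 2L, colMeans(P))
    sv <- svd(P)
    if (sv$d[2L] < 1e-12 * max(sv$d[1L], 1))
      stop("unalignable frame: collinear point set at frame ", i)
    pre <- sum((P - Qr)^2)
    A <- P %*% .kabsch(P, Qr)
    if (sum((A - Qr)^2) > pre + 1e-9 * max(pre, 1))
      stop("superposition failed to reduce the residual at frame ", i)
    out$N1[i, ] <- A[1L, ]; out$N2[i, ] <- A[2L, ]
    out$C1[i, ] <- A[3L, ]; out$C2[i, ] <- A[4L, ]
  }
  terminal_coords(out$N1, out$N2, out$C1, out$C2, frames$dt)
}

#' Unwrapped cumulative twist (handedness) series
#'
#' Accumulates frame-to-frame signed twist increments wrapped to
#' `(-pi, pi]`; a sustained negative drift reports left-handed rotation of
#' the bundle about its long axis. Increments of exactly `pi` in magnitude
#' are directionally ambiguous and rejected.
#'
#' @param mode_traj A [decompose_modes()] result with no undefined-twist
#'   frames.
#' @return Numeric vector of cumulative twist (rad), starting at `phi[1]`.
#' @export
handedness_series <- function(mode_traj) {
  stopifnot(inherits(mode_traj, "mode_trajectory"))
  phi <- mode_traj$phi
  if (anyNA(phi))
    stop("undefined twist inside the analyzed span (frame ",
         which(is.na(phi))[1L], ")")
  d <- diff(phi)
  d <- d - 2 * pi * round(d / (2 * pi))   # wrap to (-pi, pi]
  amb <- which(abs(abs(d) - pi) < 1e-12)
  if (length(amb))
    stop("ambiguous twist increment of magnitude pi at frame ", amb[1L] + 1L)
  cumsum(c(phi[1L], d))
}

#' Extract a deformation-mode time series
#'
#' @param mode_traj A [decompose_modes()] result.
#' @param mode `"shift"` or `"splay"`.
#' @param end `"sensor"` (N-terminal) or `"effector"` (C-terminal).
#' @return A [ts_series()] suitable for [estimate_correlation()].
#' @export
mode_series <- function(mode_traj, mode = c("shift", "splay"),
                        end = c("sensor", "effector")) {
  stopifnot(inherits(mode_traj, "mode_trajectory"))
  mode <- match.arg(mode); end <- match.arg(end)
  col <- paste0(if (end == "sensor") "n_" else "c_",
                if (mode == "shift") "sh" else "sp")
  ts_series(mode_traj[[col]], attr(mode_traj, "dt"),
            paste(mode, end, sep = "-"))
}

#' Twist correlation functions of a bundle
#'
#' Twist kinetics are quantified through raw scalar products of the splay
#' unit vectors (no mean subtraction): the sensor/effector self
#' correlations `<u_hat(0) . u_hat(t)>` and the symmetrized cross
#' correlation `<n_hat_sp(0) . c_hat_sp(t)>`.
#'
#' @param mode_traj A [decompose_modes()] result with no flagged frames.
#' @param max_lag Maximum lag in ps.
#' @return List of `corr_fn`: `self_s`, `self_e`, `cross`.
#' @export
twist_correlations <- function(mode_traj, max_lag) {
  stopifnot(inherits(mode_traj, "mode_trajectory"))
  U <- attr(mode_traj, "nsp_hat")
  V <- attr(mode_traj, "csp_hat")
  if (anyNA(U) || anyNA(V))
    stop("undefined twist frames present; trim or re-extract the span")
  dt <- attr(mode_traj, "dt")
  n_lag <- as.integer(round(max_lag / dt))
  if (n_lag < 1L || n_lag >= nrow(U)) stop("invalid max_lag")
  lags <- (0:n_lag) * dt
  ss <- .correlate_components(U, U, dt, n_lag, symmetrize = FALSE)
  ee <- .correlate_components(V, V, dt, n_lag, symmetrize = FALSE)
  ce <- .correlate_components(U, V, dt, n_lag, symmetrize = TRUE)
  list(self_s = .new_corr_fn(lags, ss$values, "self-sensor", FALSE,
                             c("nsp_hat", "nsp_hat"), dt),
       self_e = .new_corr_fn(lags, ee$values, "self-effector", FALSE,
                             c("csp_hat", "csp_hat"), dt),
       cross = .new_corr_fn(lags, ce$values, "cross", FALSE,
                            c("nsp_hat", "csp_hat"), dt, ce$asymmetry))
}

#' Write a mode trajectory as TSV
#'
#' Columns: `time_ps`, `n_sh`, `n_sp`, `c_sh`, `c_sp`, `phi`,
#' `phi_unwrapped`.
#' @param mode_traj A [decompose_modes()] result.
#' @param path Output path.
#' @export
write_mode_trajectory <- function(mode_traj, path) {
  stopifnot(inherits(mode_traj, "mode_trajectory"))
  df <- as.data.frame(mode_traj)
  df$phi_unwrapped <- if (anyNA(df$phi)) NA_real_ else
    handedness_series(mode_traj)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
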