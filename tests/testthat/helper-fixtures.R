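# shared fixtures: simple rotations, OU generators independent of the
# package's simulator, and small geometry builders

rot_z <- function(angle) {
  matrix(c(cos(angle), sin(angle), 0,
           -sin(angle), cos(angle), 0,
           0, 0, 1), 3L, 3L)
}

rot_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  ca <- cos(angle); sa <- sin(angle)
  outer(a, a) * (1 - ca) + diag(3L) * ca +
    matrix(c(0, a[3L], -a[2L], -a[3L], 0, a[1L], a[2L], -a[1L], 0), 3L, 3L) * sa
}

# independent scalar OU generator (plain AR(1) recursion, not the package's
# eigen-decomposed multivariate path)
ou_series <- function(n, dt, k = 1, gamma = 1, kBT = 1, seed = 1) {
  set.seed(seed)
  phi <- exp(-k / gamma * dt)
  x <- numeric(n)
  x[1L] <- rnorm(1L, 0, sqrt(kBT / k))
  innov <- rnorm(n - 1L, 0, sqrt(kBT / k * (1 - phi^2)))
  for (i in 2:n) x[i] <- phi * x[i - 1L] + innov[i - 1L]
  ts_series(x, dt, "ou")
}

# straight two-helix bundle along z with prescribed terminal layout
straight_bundle <- function(n_frames = 1L, sep = 1, height = 5) {
  ones <- rep(1, n_frames)
  terminal_coords(
    N1 = cbind(0, 0, 0) [ones, , drop = FALSE],
    N2 = cbind(sep, 0, 0)[ones, , drop = FALSE],
    C1 = cbind(0, 0, height)[ones, , drop = FALSE],
    C2 = cbind(sep, 0, height)[ones, , drop = FALSE],
    dt = 1)
}

# apply a global rotation + translation to every frame of a bundle
transform_bundle <- function(frames, R = diag(3L), shift = c(0, 0, 0)) {
  tr <- function(M) sweep(M %*% t(R), 2L, -shift)
  terminal_coords(tr(frames$N1), tr(frames$N2), tr(frames$C1), tr(frames$C2),
                  frames$dt)
}

# bundle with exact twist schedule: helix separations placed symmetrically
# about the bundle axis so that a = (a1 + a2)/2 is exactly the z axis.
# N pair separated by u = sep * e_x, C pair by v = Rz(phi) u.
twist_bundle <- function(angles, sep = 1, height = 5, dt = 1) {
  n <- length(angles)
  u <- c(sep, 0, 0)
  v <- t(vapply(angles, function(a) c(rot_z(a) %*% u), numeric(3L)))
  top <- matrix(rep(c(0, 0, height), each = n), n, 3L)
  terminal_coords(N1 = matrix(rep(-u / 2, each = n), n, 3L),
                  N2 = matrix(rep(u / 2, each = n), n, 3L),
                  C1 = top - v / 2, C2 = top + v / 2, dt = dt)
}

rel_rms <- function(est, ref) sqrt(mean((est - ref)^2) / mean(ref^2))
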