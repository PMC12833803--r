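test_that("mode decomposition reproduces hand-computed values", {
  # bundle axis exactly along z; N separation along +x, C separation along
  # +y: splay 1 at both ends, zero shift, twist +pi/2 (right-handed)
  fr <- twist_bundle(pi / 2)
  m <- decompose_modes(fr)
  expect_equal(m$n_sh, 0)
  expect_equal(m$n_sp, 1)
  expect_equal(m$c_sh, 0)
  expect_equal(m$c_sp, 1)
  expect_equal(m$phi, pi / 2)

  # C separation along -y: left-handed quarter turn
  expect_equal(decompose_modes(twist_bundle(-pi / 2))$phi, -pi / 2)

  # pure shift: N2 displaced along the axis only
  fr3 <- terminal_coords(rbind(c(0, 0, 0)), rbind(c(1e-2, 0, 0.8)),
                         rbind(c(0, 0, 5)), rbind(c(1e-2, 0, 5)), dt = 1)
  m3 <- decompose_modes(fr3)
  expect_equal(m3$n_sh, 0.8, tolerance = 1e-12)
  expect_equal(m3$n_sp, 1e-2, tolerance = 1e-12)
  expect_equal(m3$phi, 0)

  # straight parallel bundle: zero shift/twist, splay = separation
  mb <- decompose_modes(straight_bundle(3L, sep = 1.2))
  expect_equal(mb$n_sp, rep(1.2, 3L))
  expect_equal(mb$phi, rep(0, 3L))
})

test_that("terminal separation parallel to the axis flags undefined twist", {
  fr <- terminal_coords(rbind(c(0, 0, 0)), rbind(c(0, 0, 1e-12)),
                        rbind(c(0, 0, 5)), rbind(c(1, 0, 5)), dt = 1)
  m <- decompose_modes(fr)
  expect_equal(attr(m, "flagged"), 1L)
  expect_true(is.na(m$phi[1L]))
  expect_error(handedness_series(m), "undefined twist")
  expect_error(twist_correlations(m, 1), "undefined twist")
})

test_that("decomposition is invariant under global rotation and translation", {
  set.seed(13)
  n <- 40L
  base <- straight_bundle(n, sep = 1, height = 5)
  jitter <- function(M) M + matrix(rnorm(length(M), 0, 0.05), ncol = 3L)
  fr <- terminal_coords(jitter(base$N1), jitter(base$N2),
                        jitter(base$C1), jitter(base$C2), dt = 1)
  m0 <- decompose_modes(fr)
  R <- rot_axis(c(1, 2, -1), 1.1)
  fr2 <- transform_bundle(fr, R, shift = c(3, -7, 0.5))
  m1 <- decompose_modes(fr2)
  for (col in c("n_sh", "n_sp", "c_sh", "c_sp", "phi"))
    expect_equal(m1[[col]], m0[[col]], tolerance = 1e-10)
})

test_that("helix relabelling leaves the twist unchanged, mirroring flips it", {
  fr <- twist_bundle(0.9)
  m <- decompose_modes(fr)
  # swapping helix labels negates both separation vectors: the angle from
  # one splay direction to the other is invariant
  swapped <- terminal_coords(fr$N2, fr$N1, fr$C2, fr$C1, dt = 1)
  ms <- decompose_modes(swapped)
  expect_equal(ms$phi, m$phi, tolerance = 1e-12)
  expect_equal(ms$n_sp, m$n_sp)
  # a mirror image (y -> -y) reverses the handedness
  mir <- function(M) M %*% diag(c(1, -1, 1))
  mm <- decompose_modes(terminal_coords(mir(fr$N1), mir(fr$N2),
                                        mir(fr$C1), mir(fr$C2), dt = 1))
  expect_equal(mm$phi, -m$phi, tolerance = 1e-12)
})

test_that("a prescribed twist schedule is recovered exactly", {
  angles <- c(0, 0.3, -0.8, 2.0, -2.9)
  m <- decompose_modes(twist_bundle(angles))
  expect_equal(m$phi, angles, tolerance = 1e-8)

  # unwrapped handedness reproduces a monotone left-handed drift even when
  # the wrapped twist jumps across the branch cut
  drift <- seq(0, -3 * pi, length.out = 25L)
  md <- decompose_modes(twist_bundle(drift))
  hs <- handedness_series(md)
  expect_equal(hs, drift, tolerance = 1e-8)
  expect_true(all(diff(hs) < 0))
})

test_that("rigid-body removal restores the reference pose", {
  n <- 30L
  base <- straight_bundle(n, sep = 1, height = 5)
  # apply a different random rotation + translation to every frame
  set.seed(21)
  fr <- base
  for (i in 2:n) {
    R <- rot_axis(rnorm(3L), runif(1, -pi, pi))
    sh <- rnorm(3L, 0, 4)
    for (f in c("N1", "N2", "C1", "C2"))
      fr[[f]][i, ] <- c(base[[f]][i, ] %*% t(R)) + sh
  }
  fr <- terminal_coords(fr$N1, fr$N2, fr$C1, fr$C2, dt = 1)
  al <- remove_rigid_body(fr, reference = 1L)
  ref <- sapply(c("N1", "N2", "C1", "C2"), function(f) al[[f]][1L, ])
  for (i in 2:n)
    for (f in c("N1", "N2", "C1", "C2"))
      expect_equal(al[[f]][i, ], unname(ref[, f]), tolerance = 1e-8,
                   ignore_attr = TRUE)
  # and the internal modes are untouched by alignment
  expect_equal(decompose_modes(al)$phi, decompose_modes(fr)$phi,
               tolerance = 1e-8)

  # collinear point sets cannot fix a rotation
  col <- terminal_coords(rbind(c(0, 0, 0)), rbind(c(0, 0, 1)),
                         rbind(c(0, 0, 2)), rbind(c(0, 0, 3)), dt = 1)
  expect_error(remove_rigid_body(col), "collinear")
})

test_that("twist correlations use raw unit-vector products", {
  # static frames: all self correlations are exactly 1 at every lag,
  # the cross correlation is cos(phi)
  n <- 12L
  phi0 <- 0.7
  tc <- twist_correlations(decompose_modes(twist_bundle(rep(phi0, n))),
                           max_lag = 4)
  expect_equal(tc$self_s$values, rep(1, 5L))
  expect_equal(tc$self_e$values, rep(1, 5L))
  expect_equal(tc$cross$values, rep(cos(phi0), 5L))
  expect_false(tc$cross$mean_subtracted)
})

test_that("mode trajectories and coordinate files round-trip as text", {
  set.seed(3)
  n <- 8L
  base <- straight_bundle(n)
  jit <- function(M) M + matrix(rnorm(length(M), 0, 0.02), ncol = 3L)
  fr <- terminal_coords(jit(base$N1), jit(base$N2), jit(base$C1), jit(base$C2),
                        dt = 0.5)
  m <- decompose_modes(fr)
  expect_s3_class(mode_series(m, "shift", "sensor"), "ts_series")
  expect_equal(mode_series(m, "splay", "effector")$values, m$c_sp)

  p <- withr::local_tempfile(fileext = ".tsv")
  write_mode_trajectory(m, p)
  back <- utils::read.delim(p)
  expect_equal(back$phi, m$phi, tolerance = 1e-12)

  # 13-column coordinate reader reconstructs the trajectory
  p2 <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame((seq_len(n) - 1L) * 0.5, fr$N1, fr$N2, fr$C1, fr$C2)
  names(df) <- c("time_ps", paste0(rep(c("n1", "n2", "c1", "c2"), each = 3L),
                                   c("x", "y", "z")))
  utils::write.table(format(df, digits = 17), p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  fr2 <- read_terminal_coordinates(p2)
  expect_equal(fr2$N2, fr$N2, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(decompose_modes(fr2)$phi, m$phi, tolerance = 1e-12)
})
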