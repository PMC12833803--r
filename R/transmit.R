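# Force/displacement transmit functions, viscoelastic moduli and the
# rectification factor, computed from fitted response triplets.

#' Bundle the three fitted responses of a transmission channel
#'
#' A channel between a sensor coordinate `s` and an effector coordinate `e`
#' is characterised by two self responses and a single cross response
#' (Onsager reciprocity). All three are analytic multi-Debye
#' representations sharing the `exp(+i omega t)` convention.
#'
#' @param self_s,self_e,cross [debye_model()]s for the sensor-side self,
#'   effector-side self and cross response.
#' @param label Free-text mode label (e.g. "shift").
#' @return A `response_triplet`.
#' @export
response_triplet <- function(self_s, self_e, cross, label = "") {
  for (m in list(self_s, self_e, cross))
    if (!inherits(m, "debye_model")) stop("all members must be debye_model")
  if (abs(sum(self_s$a)) < 1e-300 || abs(sum(self_e$a)) < 1e-300)
    stop("zero-frequency self response must be nonzero on both sides")
  structure(list(self_s = self_s, self_e = self_e, cross = cross,
                 label = label), class = "response_triplet")
}

.new_transmit <- function(omega, values, direction, kind, num, den) {
  structure(list(omega = omega, values = values, direction = direction,
                 kind = kind, num = num, den = den),
            class = "transmit_spectrum")
}

.transmit_ratio <- function(num, den, omega, direction, kind) {
  nv <- debye_eval(num, omega)
  dv <- debye_eval(den, omega)
  scale <- max(abs(dv))
  bad <- which(abs(dv) < 1e-12 * max(scale, 1e-300))
  if (length(bad))
    stop("singular self-response: |denominator| below threshold at omega = ",
         format(omega[bad[1L]]))
  .new_transmit(omega, nv / dv, direction, kind, num, den)
}

#' Force transmit function of a channel
#'
#' The fraction of a frequency-dependent force applied at one site that
#' arrives at the other site when the remote site is held stationary:
#' `T~_F^{s->e}(omega) = J~_cross / J~_self^e` (and with the opposite self
#' response for the reverse direction).
#'
#' @param triplet A [response_triplet()].
#' @param direction `"s_to_e"` or `"e_to_s"`.
#' @param omega Frequency grid in rad/ps.
#' @return A `transmit_spectrum` carrying the complex values and the
#'   numerator/denominator Debye models (needed by
#'   [kernel_from_spectrum()]).
#' @export
force_transmit <- function(triplet, direction = c("s_to_e", "e_to_s"),
                           omega) {
  stopifnot(inherits(triplet, "response_triplet"))
  direction <- match.arg(direction)
  den <- if (direction == "s_to_e") triplet$self_e else triplet$self_s
  .transmit_ratio(triplet$cross, den, omega, direction, "force")
}

#' Displacement transmit function of a channel
#'
#' The ratio of the displacement induced at the remote site to the imposed
#' displacement when the remote site is force free:
#' `T~_X^{s->e} = J~_cross / J~_self^s`. Algebraically the force and inverse
#' displacement transmit functions coincide:
#' `T~_X^{s->e} = T~_F^{e->s}` exactly.
#'
#' @inheritParams force_transmit
#' @return A `transmit_spectrum`.
#' @export
displacement_transmit <- function(triplet, direction = c("s_to_e", "e_to_s"),
                                  omega) {
  stopifnot(inherits(triplet, "response_triplet"))
  direction <- match.arg(direction)
  den <- if (direction == "s_to_e") triplet$self_s else triplet$self_e
  .transmit_ratio(triplet$cross, den, omega, direction, "displacement")
}

#' Viscoelastic moduli of a channel
#'
#' Inverts the 2x2 response matrix
#' `[[J~_self^s, J~_cross], [J~_cross, J~_self^e]]` at every frequency to
#' obtain the moduli matrix `G~`; at `omega = 0` this is the stiffness
#' matrix of the channel.
#'
#' @param triplet A [response_triplet()].
#' @param omega Frequency grid in rad/ps.
#' @return A `moduli_set`: list with `omega`, `G_self_s`, `G_self_e`,
#'   `G_cross` (complex vectors).
#' @export
moduli <- function(triplet, omega) {
  stopifnot(inherits(triplet, "response_triplet"))
  Js <- debye_eval(triplet$self_s, omega)
  Je <- debye_eval(triplet$self_e, omega)
  Jc <- debye_eval(triplet$cross, omega)
  det <- Js * Je - Jc^2
  scale <- max(abs(Js), abs(Je), abs(Jc))^2
  bad <- which(abs(det) < 1e-12 * max(scale, 1e-300))
  if (length(bad))
    stop("ill-conditioned responses: response matrix singular at omega = ",
         format(omega[bad[1L]]))
  structure(list(omega = omega, G_self_s = Je / det, G_self_e = Js / det,
                 G_cross = -Jc / det),
            class = "moduli_set")
}

#' Rectification factor of a channel
#'
#' The ratio of the sensor-to-effector and effector-to-sensor step-force
#' transmission plateaus,
#' `gamma = T~_F^{s->e}(0) / T~_F^{e->s}(0) = J~_self^s(0) / J~_self^e(0)`,
#' taken analytically from the Debye amplitude sums. `gamma != 1` signals
#' directional asymmetry of the channel; by construction
#' `gamma(s->e) * gamma(e->s) = 1`.
#'
#' @param triplet A [response_triplet()].
#' @param direction Reference direction of the ratio.
#' @return Scalar `gamma`.
#' @export
rectification_factor <- function(triplet, direction = c("s_to_e", "e_to_s")) {
  stopifnot(inherits(triplet, "response_triplet"))
  direction <- match.arg(direction)
  s0 <- sum(triplet$self_s$a)
  e0 <- sum(triplet$self_e$a)
  if (direction == "s_to_e") {
    if (abs(e0) < 1e-300) stop("degenerate effector response")
    s0 / e0
  } else {
    if (abs(s0) < 1e-300) stop("degenerate sensor response")
    e0 / s0
  }
}

#' @export
print.transmit_spectrum <- function(x, ...) {
  cat(sprintf("<transmit_spectrum> %s %s: %d frequencies, |T~(omega_min)| = %.4g\n",
              x$kind, x$direction, length(x$omega), Mod(x$values[1L])))
  invisible(x)
}

#' Write a transmit spectrum as TSV
#'
#' Columns: `omega_rad_per_ps`, `re`, `im`, `modulus`.
#' @param T A `transmit_spectrum`.
#' @param path Output path.
#' @export
write_transmit <- function(T, path) {
  stopifnot(inherits(T, "transmit_spectrum"))
  utils::write.table(
    data.frame(omega_rad_per_ps = T$omega, re = Re(T$values),
               im = Im(T$values), modulus = Mod(T$values)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
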