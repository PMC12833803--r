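# Pearson coupling between deformation modes with block-averaged errors.

#' Pearson correlation coefficient of two series
#'
#' `R = <dx dy> / sqrt(<dx^2><dy^2>)` with `d` the deviation from the time
#' average.
#'
#' @param x,y [ts_series()] objects or numeric vectors of equal length
#'   (at least 3 frames).
#' @return Scalar in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  xv <- if (inherits(x, "ts_series")) x$values else as.numeric(x)
  yv <- if (inherits(y, "ts_series")) y$values else as.numeric(y)
  if (length(xv) != length(yv)) stop("series lengths differ")
  if (length(xv) < 3L) stop("need at least 3 frames")
  if (stats::var(xv) == 0 || stats::var(yv) == 0)
    stop("constant series: Pearson coefficient undefined")
  stats::cor(xv, yv)
}

#' Mode-coupling matrix with block-averaged standard errors
#'
#' Computes pairwise Pearson coefficients between the given series (full
#' length), and standard errors as the standard deviation of per-block
#' estimates divided by `sqrt(n_blocks)`, with the series cut into
#' contiguous equal-length blocks. With a second list `y` a rectangular
#' cross matrix (e.g. sensor-end vs effector-end modes) is returned; with
#' one list the matrix is square and symmetric with unit diagonal. Blocks
#' in which either series is constant are excluded with a warning.
#'
#' @param x Named list of [ts_series()] (or numeric vectors).
#' @param y Optional second named list for cross-end pairings.
#' @param n_blocks Number of blocks for the error estimate (default 3).
#' @return A `coupling_matrix`: list with `R`, `SE`, `n_blocks`.
#' @export
coupling_matrix <- function(x, y = NULL, n_blocks = 3L) {
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 2L) stop("n_blocks must be >= 2")
  as_vec <- function(s) if (inherits(s, "ts_series")) s$values else as.numeric(s)
  X <- lapply(x, as_vec)
  Y <- if (is.null(y)) X else lapply(y, as_vec)
  L <- unique(c(vapply(X, length, integer(1)), vapply(Y, length, integer(1))))
  if (length(L) != 1L) stop("all series must have equal length")
  bl <- L %/% n_blocks
  if (bl < 3L) stop("too few frames for ", n_blocks, " blocks")
  blocks <- lapply(seq_len(n_blocks),
                   function(b) ((b - 1L) * bl + 1L):(b * bl))
  R <- matrix(NA_real_, length(X), length(Y),
              dimnames = list(names(x), names(if (is.null(y)) x else y)))
  SE <- R
  for (i in seq_along(X)) for (j in seq_along(Y)) {
    R[i, j] <- stats::cor(X[[i]], Y[[j]])
    rb <- vapply(blocks, function(idx) {
      xi <- X[[i]][idx]; yj <- Y[[j]][idx]
      if (stats::var(xi) == 0 || stats::var(yj) == 0) NA_real_
      else stats::cor(xi, yj)
    }, numeric(1))
    if (anyNA(rb)) {
      warning("block with zero variance excluded for pair (",
              names(x)[i], ", ", names(if (is.null(y)) x else y)[j], ")")
      rb <- rb[!is.na(rb)]
    }
    SE[i, j] <- if (length(rb) > 1L) stats::sd(rb) / sqrt(length(rb)) else NA_real_
  }
  structure(list(R = R, SE = SE, n_blocks = n_blocks, cross = !is.null(y)),
            class = "coupling_matrix")
}

#' @export
print.coupling_matrix <- function(x, ...) {
  cat(sprintf("<coupling_matrix> %s, %d blocks\n",
              if (x$cross) "cross-end" else "same-end", x$n_blocks))
  fm <- matrix(sprintf("%.3f +/- %.3f", x$R, x$SE), nrow(x$R),
               dimnames = dimnames(x$R))
  print(fm, quote = FALSE)
  invisible(x)
}

#' Write a coupling matrix as TSV (cells "value +/- se")
#' @param cm A `coupling_matrix`.
#' @param path Output path.
#' @export
write_coupling <- function(cm, path) {
  stopifnot(inherits(cm, "coupling_matrix"))
  fm <- matrix(sprintf("%.6g +/- %.3g", cm$R, cm$SE), nrow(cm$R),
               dimnames = dimnames(cm$R))
  utils::write.table(fm, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
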