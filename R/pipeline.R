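# End-to-end analysis pipeline: series -> correlations -> FDT responses ->
# cutoff -> Fourier -> Debye fits -> transmit functions -> kernels ->
# time-domain signal responses -> rectification, plus a results bundle.

#' Default analysis configuration
#'
#' @param input Input description, one of:
#'   `list(network = <langevin_network or path>, dt = , n_steps = )` to
#'   simulate a benchmark network; `list(timeseries = <path>, sensor = ,
#'   effector = )` to read two columns of a delimited time-series file;
#'   `list(coordinates = <path>, mode = "shift"|"splay"|"twist")` to extract
#'   a deformation mode from 13-column terminal coordinates.
#' @param kBT Thermal energy scale (default 1, reduced units).
#' @param max_lag_ps Maximum correlation lag; default one tenth of the span.
#' @param t_cut Response cutoff in ps or `"auto"`.
#' @param n_debye Maximum Debye components per response fit; the component
#'   count is selected by BIC up to this bound (see [fit_debye()]).
#' @param n_omega,omega_min,omega_max Frequency-grid specification.
#' @param seed Master seed; stage seeds are small fixed offsets of it.
#' @param n_blocks Blocks for coupling/uncertainty estimates.
#' @param out_dir Optional directory for the results bundle (JSON summary +
#'   per-stage TSV tables).
#' @param align Remove rigid-body motion before twist extraction.
#' @return A named list, the `AnalysisConfig`.
#' @export
pipeline_config <- function(input, kBT = 1, max_lag_ps = NULL,
                            t_cut = "auto", n_debye = 10L, n_omega = 200L,
                            omega_min = NULL, omega_max = NULL, seed = 1L,
                            n_blocks = 3L, out_dir = NULL, align = TRUE) {
  list(input = input, kBT = kBT, max_lag_ps = max_lag_ps, t_cut = t_cut,
       n_debye = n_debye, n_omega = n_omega, omega_min = omega_min,
       omega_max = omega_max, seed = seed, n_blocks = n_blocks,
       out_dir = out_dir, align = align)
}

.pl_validate <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config$input)) stop("validation: config$input missing")
  inp <- config$input
  for (f in c("timeseries", "coordinates"))
    if (!is.null(inp[[f]]) && !file.exists(inp[[f]]))
      stop("validation: input path not found: ", inp[[f]])
  if (!is.null(inp$network) && is.character(inp$network) &&
      !file.exists(inp$network))
    stop("validation: network config not found: ", inp$network)
  if (!is.null(config$kBT) && config$kBT <= 0)
    stop("validation: kBT must be positive")
  defaults <- pipeline_config(inp)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  config
}

.pl_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.pl_correlations <- function(config) {
  inp <- config$input
  if (!is.null(inp$network)) {
    net <- if (is.character(inp$network)) read_network(inp$network) else inp$network
    series <- simulate_network(net, inp$dt, inp$n_steps,
                               seed = config$seed)
    s <- series[[1L]]; e <- series[[2L]]
  } else if (!is.null(inp$timeseries)) {
    series <- read_timeseries(inp$timeseries)
    s <- series[[inp$sensor]]; e <- series[[inp$effector]]
  } else if (!is.null(inp$coordinates)) {
    frames <- read_terminal_coordinates(inp$coordinates)
    if (identical(inp$mode, "twist")) {
      if (isTRUE(config$align)) frames <- remove_rigid_body(frames)
      mt <- decompose_modes(frames)
      ml <- if (is.null(config$max_lag_ps))
        (nrow(mt) - 1L) * attr(mt, "dt") / 10 else config$max_lag_ps
      return(list(corr = twist_correlations(mt, ml), modes = mt))
    }
    mt <- decompose_modes(frames)
    s <- mode_series(mt, inp$mode, "sensor")
    e <- mode_series(mt, inp$mode, "effector")
  } else stop("validation: no usable input block")
  ml <- if (is.null(config$max_lag_ps))
    (length(s$values) - 1L) * s$dt / 10 else config$max_lag_ps
  list(corr = list(
    self_s = estimate_correlation(s, max_lag = ml, kind = "self-sensor"),
    self_e = estimate_correlation(e, max_lag = ml, kind = "self-effector"),
    cross = estimate_correlation(s, e, max_lag = ml, kind = "cross")))
}

#' Run the full transmit-function pipeline
#'
#' Chains all analysis stages on a configured input: obtain the
#' sensor/effector series, estimate the three correlation functions, apply
#' the fluctuation-dissipation theorem, truncate at the noise cutoff,
#' Fourier transform, fit multi-Debye models, form the response triplet,
#' compute both transmit directions, build time-domain kernels, evaluate
#' step-response plateaus, and report the rectification factor. All
#' randomness derives from `config$seed`, so reruns with the same
#' configuration are bit-identical.
#'
#' @param config An [pipeline_config()] list or path to a JSON file with
#'   the same fields.
#' @return A results bundle (list) with elements `gamma` (zero-frequency),
#'   `gamma_plateau` (step-response ratio), `tau_max` (per response, ps),
#'   `plateau` (per direction), `transmit` (per direction data frames),
#'   `t_cut`, `fits`, `seeds` and the echoed `config`. If
#'   `config$out_dir` is set the bundle is also written to disk
#'   (`results.json` + TSV tables).
#' @export
run_pipeline <- function(config) {
  config <- .pl_stage("validate", .pl_validate(config))
  acq <- .pl_stage("acquire", .pl_correlations(config))
  corr <- acq$corr
  resp <- .pl_stage("respond", lapply(corr, response_from_correlation,
                                      kBT = config$kBT))
  resp <- .pl_stage("cutoff", lapply(resp, apply_cutoff,
                                     t_cut = config$t_cut))
  t_cuts <- vapply(resp, `[[`, numeric(1), "t_cut")
  grid <- .pl_stage("grid", omega_grid(
    resp$cross, n = config$n_omega,
    omega_min = config$omega_min, omega_max = config$omega_max))
  spectra <- .pl_stage("fourier", lapply(resp, fourier_response, omega = grid))
  seeds <- config$seed + c(self_s = 101L, self_e = 211L, cross = 307L)
  fits <- .pl_stage("fitdebye", lapply(names(spectra), function(nm)
    fit_debye(spectra[[nm]], n_components = config$n_debye,
              seed = seeds[[nm]], select = "bic")))
  names(fits) <- names(spectra)
  triplet <- .pl_stage("triplet", response_triplet(
    fits$self_s, fits$self_e, fits$cross,
    label = if (!is.null(config$input$mode)) config$input$mode else "custom"))
  tf <- .pl_stage("transmit", list(
    s_to_e = force_transmit(triplet, "s_to_e", grid),
    e_to_s = force_transmit(triplet, "e_to_s", grid)))
  kern <- .pl_stage("kernel", lapply(tf, kernel_from_spectrum))
  stp <- .pl_stage("convolve", lapply(kern, step_response, amplitude = 1))
  plateau <- vapply(stp, attr, numeric(1), "plateau")
  res <- list(
    gamma = rectification_factor(triplet),
    gamma_plateau = plateau[["s_to_e"]] / plateau[["e_to_s"]],
    tau_max = vapply(fits, relaxation_time, numeric(1)),
    plateau = plateau,
    t_cut = t_cuts,
    transmit = lapply(tf, function(T)
      data.frame(omega_rad_per_ps = T$omega, re = Re(T$values),
                 im = Im(T$values), modulus = Mod(T$values))),
    fits = fits,
    kernels = kern,
    corr = corr,
    seeds = c(master = config$seed, seeds),
    config = config[setdiff(names(config), "input")]
  )
  if (!is.null(config$out_dir)) .pl_write(res, tf, stp, config$out_dir)
  res
}

.pl_write <- function(res, tf, stp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in names(tf))
    write_transmit(tf[[d]], file.path(dir, paste0("transmit_", d, ".tsv")))
  for (d in names(stp))
    write_signal(stp[[d]], file.path(dir, paste0("step_", d, ".tsv")))
  for (nm in names(res$fits))
    write_debye(res$fits[[nm]], file.path(dir, paste0("debye_", nm, ".json")))
  for (nm in names(res$corr))
    write_correlation(res$corr[[nm]], file.path(dir, paste0("corr_", nm, ".tsv")))
  jsonlite::write_json(
    list(gamma = res$gamma, gamma_plateau = res$gamma_plateau,
         tau_max_ps = as.list(res$tau_max), plateau = as.list(res$plateau),
         t_cut_ps = as.list(res$t_cut), seeds = as.list(res$seeds)),
    file.path(dir, "results.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
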