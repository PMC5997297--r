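#' Configure the microchannel chemoattractant diffusion model
#'
#' Models gradient formation along a microchannel as the 2D unsteady diffusion
#' equation dC/dt = D (Cxx + Cyy) on the channel rectangle, with a constant
#' concentration on the source edge, a concentration-proportional outflux
#' (Robin condition) on the sink edge, and no-flux PDMS walls. Solved by
#' explicit finite differences on a regular grid.
#'
#' The diffusion coefficient is supplied in cm^2/s and converted internally to
#' um^2/s (0.5e-4 cm^2/s = 5e3 um^2/s). The Robin coefficient k is a
#' mass-transfer coefficient in um/s (outflux = k * C at the sink edge); the
#' default k = D/L_res with L_res = 1000 um makes the sink behave as an
#' effectively well-mixed large reservoir.
#'
#' @param channel_length channel length, um (default 850).
#' @param channel_width channel width, um (default 10).
#' @param D diffusion coefficient, cm^2/s (default 0.5e-4).
#' @param source_concentration fixed concentration at the source edge, a.u.
#' @param sink_outflux_coefficient Robin k, um/s; NULL for the default
#'   D_um/1000.
#' @param initial_concentration scalar or nx-by-ny matrix of starting
#'   concentrations (default 0 everywhere).
#' @param grid_spacing node spacing, um (default 5; same in x and y).
#' @param time_step time step in seconds; NULL picks 50% of the explicit
#'   stability bound dx^2/(4 D).
#' @param total_time_h simulated time span, hours.
#' @param source_bc "dirichlet" (fixed source) or "noflux" (closed edge).
#' @param sink_bc "robin", "dirichlet0" (perfect sink) or "noflux".
#' @return object of class `diffusion_config`.
#' @export
diffusion_config <- function(channel_length = 850, channel_width = 10,
                             D = 0.5e-4, source_concentration = 1,
                             sink_outflux_coefficient = NULL,
                             initial_concentration = 0,
                             grid_spacing = 5, time_step = NULL,
                             total_time_h = 24,
                             source_bc = c("dirichlet", "noflux"),
                             sink_bc = c("robin", "dirichlet0", "noflux")) {
  source_bc <- match.arg(source_bc)
  sink_bc <- match.arg(sink_bc)
  for (v in list(channel_length, channel_width, D, grid_spacing, total_time_h))
    if (!is.numeric(v) || v <= 0)
      stop("diffusion_config: lengths, D, grid_spacing and total_time_h must ",
           "be strictly positive", call. = FALSE)
  D_um <- D * 1e8  # cm^2/s -> um^2/s
  bound <- grid_spacing^2 / (4 * D_um)
  if (is.null(time_step)) time_step <- 0.5 * bound
  if (time_step > bound * (1 + 1e-12))
    stop(sprintf(paste0("diffusion_config: explicit stability bound violated: ",
                        "need D*dt/dx^2 <= 1/4, i.e. dt <= %.6g s (got %.6g s)"),
                 bound, time_step), call. = FALSE)
  if (is.null(sink_outflux_coefficient))
    sink_outflux_coefficient <- D_um / 1000
  structure(list(channel_length = channel_length,
                 channel_width = channel_width,
                 D = D, D_um = D_um,
                 source_concentration = source_concentration,
                 sink_outflux_coefficient = sink_outflux_coefficient,
                 initial_concentration = initial_concentration,
                 grid_spacing = grid_spacing, time_step = time_step,
                 total_time_h = total_time_h,
                 source_bc = source_bc, sink_bc = sink_bc),
            class = "diffusion_config")
}

#' Solve the chemoattractant diffusion problem
#'
#' Explicit finite-difference integration of the configured problem; the field
#' is recorded at the requested snapshot times. The solution obeys the maximum
#' principle (values stay in [0, source_concentration] for the default
#' zero-initial source/sink problem).
#'
#' @param config a [diffusion_config()].
#' @param snapshot_times_h times (hours) at which to store the field; all must
#'   lie within [0, total_time_h].
#' @return object of class `gradient_field`: list with x_um, y_um, times_h,
#'   conc (nx x ny x n_snapshots array) and the config.
#' @export
solve_diffusion <- function(config, snapshot_times_h = c(6, 24)) {
  stopifnot(inherits(config, "diffusion_config"))
  if (any(snapshot_times_h < 0) || any(snapshot_times_h > config$total_time_h))
    stop("solve_diffusion: snapshot times outside the simulated range",
         call. = FALSE)
  dx <- config$grid_spacing
  nx <- round(config$channel_length / dx) + 1L
  ny <- max(2L, round(config$channel_width / dx) + 1L)
  C0 <- config$initial_concentration
  if (is.matrix(C0)) {
    stopifnot(nrow(C0) == nx, ncol(C0) == ny)
  } else C0 <- matrix(C0, nx, ny)
  dt <- config$time_step
  r <- config$D_um * dt / dx^2
  ord <- order(snapshot_times_h)
  steps <- as.integer(round(snapshot_times_h[ord] * 3600 / dt))
  src_code <- if (config$source_bc == "dirichlet") 0L else 1L
  snk_code <- switch(config$sink_bc, robin = 0L, dirichlet0 = 1L, noflux = 2L)
  arr <- diffusion_run_cpp(C0, r, dx,
                           config$sink_outflux_coefficient / config$D_um,
                           config$source_concentration, src_code, snk_code,
                           steps)
  # restore requested order
  arr <- arr[, , order(ord), drop = FALSE]
  structure(list(x_um = (seq_len(nx) - 1) * dx, y_um = (seq_len(ny) - 1) * dx,
                 times_h = snapshot_times_h, conc = arr, config = config),
            class = "gradient_field")
}

# Width-averaged concentration profile along x at the stored time t_h
width_averaged_profile <- function(field, t_h) {
  i <- match(TRUE, abs(field$times_h - t_h) < 1e-9)
  if (is.na(i))
    stop("requested time not among stored snapshots", call. = FALSE)
  rowMeans(field$conc[, , i])
}

#' Normalize a fluorescence/concentration profile to [0, 1]
#'
#' Rescales a profile so its minimum maps to 0 and its maximum to 1:
#' (I(x) - I_min) / (I_max - I_min). Affine-invariant and order-preserving.
#'
#' @param profile numeric vector with at least two distinct values.
#' @return numeric vector in [0, 1].
#' @export
relative_fluorescence <- function(profile) {
  if (length(profile) < 2)
    stop("relative_fluorescence: profile needs >= 2 values", call. = FALSE)
  lo <- min(profile); hi <- max(profile)
  if (hi == lo)
    stop("relative_fluorescence: degenerate (constant) profile", call. = FALSE)
  (profile - lo) / (hi - lo)
}

#' Gradient steepness and temporal stability
#'
#' Steepness is the mean absolute x-slope (central differences) of the
#' width-averaged concentration profile at a stored snapshot time.
#' `stability_report` returns the relative change |s(t1) - s(t2)| / s(t1).
#'
#' @param field a `gradient_field` from [solve_diffusion()].
#' @param t_h,t1_h,t2_h snapshot times (hours) stored in the field.
#' @return steepness in concentration units per um; or the relative change.
#' @export
gradient_steepness <- function(field, t_h) {
  p <- width_averaged_profile(field, t_h)
  dx <- field$config$grid_spacing
  n <- length(p)
  slopes <- (p[3:n] - p[1:(n - 2)]) / (2 * dx)
  mean(abs(slopes))
}

#' @rdname gradient_steepness
#' @export
stability_report <- function(field, t1_h, t2_h) {
  s1 <- gradient_steepness(field, t1_h)
  s2 <- gradient_steepness(field, t2_h)
  abs(s1 - s2) / s1
}

# Total solute mass with trapezoidal weights (exact conservation under the
# mirror-ghost no-flux discretization, up to float rounding)
total_mass <- function(field, t_h) {
  i <- match(TRUE, abs(field$times_h - t_h) < 1e-9)
  m <- field$conc[, , i]
  wx <- rep(1, nrow(m)); wx[c(1, nrow(m))] <- 0.5
  wy <- rep(1, ncol(m)); wy[c(1, ncol(m))] <- 0.5
  dx <- field$config$grid_spacing
  sum((wx %o% wy) * m) * dx^2
}

# Closed-form steady 1D profile for the source-Dirichlet / sink-Robin problem:
# C(x) = C0 (1 - x / (L + D/k)); for k -> Inf this is the linear 1-to-0 line.
steady_robin_profile <- function(x_um, L, C0, D_um, k) {
  if (!is.finite(k)) return(C0 * (1 - x_um / L))
  C0 * (1 - x_um / (L + D_um / k))
}

#' Microchip geometry worked example
#'
#' Computes the volume of one microchannel from its printed dimensions and
#' compares it against the reservoir volume, returning the order-of-magnitude
#' difference that justifies treating the source reservoir as a constant-
#' concentration boundary.
#'
#' @param width_um,height_um,length_um channel dimensions (default 10 x 20 x
#'   850 um).
#' @param reservoir_volume_mm3 reservoir volume, mm^3 (default 200, a 6 mm
#'   biopsy-punch reservoir).
#' @return list with channel_volume_mm3, reservoir_volume_mm3 and
#'   orders_of_magnitude (log10 of the ratio).
#' @export
microchip_geometry <- function(width_um = 10, height_um = 20, length_um = 850,
                               reservoir_volume_mm3 = 200) {
  channel_mm3 <- width_um * height_um * length_um * 1e-9
  list(channel_volume_mm3 = channel_mm3,
       reservoir_volume_mm3 = reservoir_volume_mm3,
       orders_of_magnitude = log10(reservoir_volume_mm3 / channel_mm3))
}
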