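#' Default parameters of the MAPK/ERK relaxation-oscillator model
#'
#' The pathway model is a six-variable ODE system with the feedback topology
#' of the EGF-driven MAPK cascade: receptor activation (`u`), a bistable
#' SOS/RAS module with fast positive feedback (`s`), a slow negative feedback
#' in which active ERK phosphorylates and inactivates SOS (`q`, recovery time
#' of tens of minutes), and the three-tier RAF (`r`) / MEK (`m`) / ERK (`e`)
#' cascade shaping a ~30 min all-or-nothing ERK activity pulse. The
#' parameters below are calibrated so that the relaxation time is
#' `tau = 51.5 min`, the single-pulse integrated response is
#' `R_max = 2.65e9 molecule*s`, the dose response is near-digital (no
#' response at 3 pg/ml EGF, full response from 10 pg/ml up), and constant
#' EGF in an intermediate dose window yields sustained ERK oscillations.
#'
#' Rates are per minute; `ERK_tot` is molecules per cell; `K_egf` is in
#' pg/ml; remaining parameters are dimensionless fractions. Parameters whose
#' value is proportional to the abundance of a protein or implicit enzyme
#' (total ERK, kinase activation rates, the ERK->SOS feedback rate, and all
#' pseudo-first-order deactivation/dephosphorylation rates) carry
#' `cell_variable = TRUE` and are the ones resampled per cell by
#' [sample_population()].
#'
#' @param nf1_strength_scale Dimensionless multiplier on the ERK->SOS
#'   negative-feedback rate `c_q` (default 1 = nominal strength).
#' @return A tibble of class `mapk_params` with columns `name`, `value`,
#'   `unit`, `cell_variable`, plus attribute `nf1_strength_scale`.
#' @export
mapk_params <- function(nf1_strength_scale = 1) {
  stopifnot(nf1_strength_scale > 0)
  def <- tibble::tribble(
    ~name,      ~value,   ~unit,            ~cell_variable,
    "ERK_tot",  2.183e6,  "molecule",       TRUE,  # total ERK per cell
    "K_egf",    20,       "pg/ml",          FALSE, # receptor half-saturation
    "h_egf",    4,        "",               FALSE, # receptor cooperativity
    "a_u",      4.0,      "1/min",          TRUE,  # receptor activation
    "d_u",      1.0,      "1/min",          TRUE,  # receptor deactivation
    "b_u",      0.40,     "1/min",          TRUE,  # receptor -> SOS/RAS drive
    "b_s",      1.5,      "1/min",          TRUE,  # RAS->SOS positive feedback
    "K_s",      0.60,     "fraction",       FALSE, # PF half-saturation
    "d_s",      0.25,     "1/min",          TRUE,  # RAS-GTP hydrolysis
    "c_q",      0.13,     "1/min",          TRUE,  # ERK->SOS neg. feedback
    "d_q",      0.041,    "1/min",          TRUE,  # SOS recovery (slow)
    "K_q",      0.20,     "fraction",       FALSE, # feedback inhibition scale
    "h_q",      6,        "",               FALSE, # feedback Hill exponent
    "c_r",      1.0,      "1/min",          TRUE,  # RAS -> RAF activation
    "d_r",      0.30,     "1/min",          TRUE,  # RAF dephosphorylation
    "c_m",      1.0,      "1/min",          TRUE,  # RAF -> MEK activation
    "d_m",      0.30,     "1/min",          TRUE,  # MEK dephosphorylation
    "c_e",      1.5,      "1/min",          TRUE,  # MEK -> ERK activation
    "K_m",      0.50,     "fraction",       FALSE, # ERK activation threshold
    "d_e",      0.30,     "1/min",          TRUE   # ERK dephosphorylation
  )
  if (any(def$value < 0)) stop("Model parameters must be non-negative.", call. = FALSE)
  structure(def,
    nf1_strength_scale = nf1_strength_scale,
    class = c("mapk_params", class(def))
  )
}

params_vector <- function(params) {
  stopifnot(inherits(params, "mapk_params"))
  v <- stats::setNames(params$value, params$name)
  if (any(v < 0) || anyNA(v)) stop("Model parameters must be non-negative.", call. = FALSE)
  v
}

#' EGF pulse-train stimulation protocol
#'
#' @param sequence Binary string, e.g. `"1011"`: pulse slot `i` starts at
#'   `t = (i - 1) * T_min` minutes; a `'1'` delivers a square EGF pulse.
#' @param T_min Base repeating time between slots, minutes.
#' @param pulse_duration Pulse length in minutes (default 5; must be < `T_min`).
#' @param dose_on EGF concentration of a `'1'` pulse, pg/ml (default 100).
#' @param doses Optional per-slot dose vector overriding
#'   `sequence * dose_on` (used for amplitude scans).
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(sequence, T_min, pulse_duration = 5, dose_on = 100,
                          doses = NULL) {
  bits <- seq_to_bits(sequence)
  stopifnot(T_min > 0, pulse_duration > 0, pulse_duration < T_min, dose_on >= 0)
  doses <- doses %||% (bits * dose_on)
  stopifnot(length(doses) == length(bits), all(doses >= 0))
  structure(
    list(
      sequence = sequence, bits = bits, L = length(bits), T_min = T_min,
      pulse_duration = pulse_duration, doses = doses
    ),
    class = "protocol_spec"
  )
}

# EGF(t) as a step function: segment start times and doses over [0, t_end].
protocol_segments <- function(protocol, t_end) {
  starts <- 0
  doses <- 0
  for (i in seq_len(protocol$L)) {
    t0 <- (i - 1) * protocol$T_min
    if (t0 >= t_end || protocol$doses[i] <= 0) next
    starts <- c(starts, t0, t0 + protocol$pulse_duration)
    doses <- c(doses, protocol$doses[i], 0)
  }
  keep <- !duplicated(starts, fromLast = TRUE)
  ord <- order(starts[keep])
  list(start = starts[keep][ord], dose = doses[keep][ord])
}

mapk_rhs <- function(t, y, parms) {
  with(as.list(c(y, parms)), {
    drive <- egf^h_egf / (K_egf^h_egf + egf^h_egf)
    g <- 1 / (1 + (q / K_q)^h_q) # NF1 inhibition of SOS/RAS activation
    du <- a_u * drive * (1 - u) - d_u * u
    ds <- (b_u * u + b_s * s^2 / (K_s^2 + s^2)) * g * (1 - s) - d_s * s
    dq <- c_q * nf1 * e * (1 - q) - d_q * q
    dr <- c_r * s * (1 - r) - d_r * r
    dm <- c_m * r * (1 - m) - d_m * m
    de <- c_e * m^2 / (K_m^2 + m^2) * (1 - e) - d_e * e
    list(c(du, ds, dq, dr, dm, de))
  })
}

#' Simulate the MAPK model under an EGF protocol
#'
#' Deterministic integration from the resting state (pre-equilibrated at
#' EGF = 0), piecewise over the constant-EGF segments of the protocol with
#' an adaptive solver ([deSolve::lsoda], rtol 1e-8).
#'
#' @param params A [mapk_params()] table.
#' @param protocol A [protocol_spec()], or a single dose (pg/ml) for
#'   constant-EGF stimulation.
#' @param t_end_min Simulation horizon in minutes (default `L * T_min + 30`).
#' @param dt_out_s Output grid spacing in seconds (default 1).
#' @param equilibrate_h Pre-equilibration time at EGF = 0, hours (default 48).
#' @return A tibble of class `mapk_trajectory` with columns `time_s` and
#'   `ERKpp` (molecules/cell); the full fractional state is kept in columns
#'   `u`, `s`, `q`, `r`, `m`, `e`.
#' @export
simulate_mapk <- function(params, protocol, t_end_min = NULL, dt_out_s = 1,
                          equilibrate_h = 48) {
  p <- params_vector(params)
  p["nf1"] <- attr(params, "nf1_strength_scale") %||% 1
  if (is.numeric(protocol) && length(protocol) == 1L) {
    stopifnot(!is.null(t_end_min))
    segs <- list(start = 0, dose = protocol)
  } else {
    stopifnot(inherits(protocol, "protocol_spec"))
    t_end_min <- t_end_min %||% (protocol$L * protocol$T_min + 30)
    segs <- protocol_segments(protocol, t_end_min)
  }
  y0 <- c(u = 0, s = 0, q = 0, r = 0, m = 0, e = 0)
  # pre-equilibrate at EGF = 0 until the relative drift is negligible
  eq <- deSolve::lsoda(
    y0, c(0, equilibrate_h * 60), mapk_rhs,
    parms = c(p, egf = 0), rtol = 1e-8, atol = 1e-12
  )
  y0 <- eq[nrow(eq), -1]
  drift <- max(abs(eq[nrow(eq), -1] - eq[1, -1])) / equilibrate_h
  if (drift > 1e-8) {
    warning("Initial state not fully equilibrated (drift ", signif(drift, 2), " per hour).")
  }
  dt_min <- dt_out_s / 60
  bounds <- c(segs$start, t_end_min)
  out <- NULL
  y <- y0
  for (i in seq_along(segs$start)) {
    t0 <- bounds[i]
    t1 <- bounds[i + 1]
    if (t1 <= t0) next
    times <- unique(c(seq(t0, t1, by = dt_min), t1))
    seg <- deSolve::lsoda(
      y, times, mapk_rhs,
      parms = c(p, egf = segs$dose[i]), rtol = 1e-8, atol = 1e-12
    )
    if (attr(seg, "istate")[1] < 0) {
      stop("ODE integration failed on segment starting at t = ", t0, " min.", call. = FALSE)
    }
    y <- seg[nrow(seg), -1]
    keep <- if (is.null(out)) seq_len(nrow(seg)) else -1L # drop repeated boundary row
    out <- rbind(out, seg[keep, , drop = FALSE])
  }
  traj <- tibble::as_tibble(as.data.frame(out))
  names(traj)[1] <- "time_min"
  traj <- dplyr::mutate(traj,
    time_s = .data$time_min * 60,
    ERKpp = pmax(.data$e, 0) * p[["ERK_tot"]]
  )
  traj <- dplyr::select(
    traj, "time_s", "ERKpp",
    dplyr::all_of(c("u", "s", "q", "r", "m", "e"))
  )
  class(traj) <- c("mapk_trajectory", class(traj))
  traj
}

trapz_xy <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Integrated ERK responses per pulse window
#'
#' `R_i` is the time integral of ERK_pp over the window of pulse `i`,
#' `[(i-1)*T, i*T]` (pulse `i` is applied at `t = (i-1)*T`), in
#' molecule-seconds, by the trapezoidal rule on the trajectory grid.
#'
#' @param traj A [simulate_mapk()] trajectory.
#' @param T_min Window length in minutes.
#' @param L Number of windows.
#' @return Numeric vector `R_1 ... R_L` (molecule*s).
#' @export
integrated_response <- function(traj, T_min, L) {
  stopifnot(T_min > 0, L >= 1)
  t <- traj$time_s
  if (max(t) < L * T_min * 60 - 1e-6) {
    stop("Trajectory must cover [0, L*T].", call. = FALSE)
  }
  vapply(seq_len(L), function(i) {
    lo <- (i - 1) * T_min * 60
    hi <- i * T_min * 60
    sel <- t >= lo - 1e-9 & t <= hi + 1e-9
    trapz_xy(t[sel], traj$ERKpp[sel])
  }, numeric(1))
}

#' Reference single-pulse response R_max
#'
#' Integrated ERK response to one isolated 5-min pulse at `dose` pg/ml,
#' integrated over a window long enough to capture the whole ERK pulse.
#'
#' @param params A [mapk_params()] table.
#' @param dose EGF dose, pg/ml (default 100).
#' @param dt_out_s Output grid spacing, seconds.
#' @return `R_max` in molecule*s.
#' @export
single_pulse_response <- function(params, dose = 100, dt_out_s = 1) {
  prot <- protocol_spec("1", T_min = 90, dose_on = dose)
  traj <- simulate_mapk(params, prot, t_end_min = 90, dt_out_s = dt_out_s)
  integrated_response(traj, T_min = 90, L = 1)
}

#' Near-digital amplitude response to a single pulse
#'
#' @inheritParams single_pulse_response
#' @param doses EGF doses to scan, pg/ml.
#' @return A tibble with columns `dose`, `R_1`, `R_rel` (relative to the
#'   100 pg/ml response).
#' @export
amplitude_response <- function(params, doses = c(0, 3, 10, 30, 100), dt_out_s = 6) {
  R_max <- single_pulse_response(params, dose = 100, dt_out_s = dt_out_s)
  tibble::tibble(
    dose = doses,
    R_1 = vapply(doses, function(d) {
      if (d == 0) return(0)
      single_pulse_response(params, dose = d, dt_out_s = dt_out_s)
    }, numeric(1)),
    R_rel = .data$R_1 / R_max
  )
}

two_pulse_ratio <- function(params, T_min, dt_out_s = 6) {
  prot <- protocol_spec("11", T_min = T_min)
  traj <- simulate_mapk(params, prot, t_end_min = 2 * T_min, dt_out_s = dt_out_s)
  R <- integrated_response(traj, T_min, 2)
  R[2] / R[1]
}

#' Relaxation time of the pathway
#'
#' The minimal inter-pulse interval after which a second full ERK response is
#' possible: the `T` at which the second of two 5-min 100 pg/ml pulses
#' elicits half the response of the first, `R_2(T)/R_1(T) = 0.5`, found by
#' bisection over `T` in `bracket` to 0.1 min.
#'
#' @param params A [mapk_params()] table.
#' @param bracket Search interval for `T`, minutes (default `c(30, 90)`).
#' @param tol Bisection tolerance in minutes (default 0.1).
#' @param dt_out_s Trajectory output grid, seconds.
#' @return `tau` in minutes.
#' @export
measure_relaxation_time <- function(params, bracket = c(30, 90), tol = 0.1,
                                    dt_out_s = 6) {
  f <- function(T_min) two_pulse_ratio(params, T_min, dt_out_s = dt_out_s) - 0.5
  flo <- f(bracket[1])
  fhi <- f(bracket[2])
  if (flo * fhi > 0) {
    stop("R_2/R_1 - 0.5 does not change sign on the bracket; ",
      "model appears miscalibrated.",
      call. = FALSE
    )
  }
  stats::uniroot(f, bracket,
    f.lower = flo, f.upper = fhi, tol = tol
  )$root
}

#' Does the model oscillate under constant EGF?
#'
#' Detects sustained ERK_pp oscillations under constant stimulation by
#' counting upward threshold crossings in the second half of a long run.
#'
#' @param params A [mapk_params()] table.
#' @param dose Constant EGF dose, pg/ml.
#' @param t_end_min Horizon, minutes (default 1200).
#' @param threshold Crossing threshold as a fraction of `ERK_tot` (default 0.2).
#' @return TRUE if at least three full ERK pulses occur in the second half.
#' @export
oscillates <- function(params, dose, t_end_min = 1200, threshold = 0.2) {
  traj <- simulate_mapk(params, dose, t_end_min = t_end_min, dt_out_s = 30)
  half <- traj$time_s > t_end_min * 30 # second half (s = min*60/2)
  x <- traj$e[half] > threshold
  crossings <- sum(diff(x) == 1)
  crossings >= 3
}

#' Scan the strength of the ERK->SOS negative feedback
#'
#' Re-measures the relaxation time and the presence of constant-EGF
#' oscillations while scaling the ERK->SOS feedback rate. Weakening the
#' feedback shortens `tau`; below a critical strength the system no longer
#' converts constant EGF into pulse trains, and `tau` may become undefined
#' (reported as `NA`).
#'
#' @param params A [mapk_params()] table.
#' @param scale_grid Multipliers in (0, 1] applied to the feedback rate.
#' @param doses Constant EGF doses probed for oscillations; `oscillates` is
#'   TRUE if any of them yields sustained pulses (the oscillatory dose window
#'   shifts as the feedback weakens).
#' @return A tibble with columns `scale`, `tau_min`, `oscillates`.
#' @export
scan_feedback_strength <- function(params, scale_grid = c(1, 0.5, 0.25, 0.1),
                                   doses = c(5, 10, 30)) {
  purrr::map_dfr(scale_grid, function(sc) {
    p_sc <- mapk_params(nf1_strength_scale = sc)
    p_sc$value <- params$value # preserve caller's base values
    # T below the ~30 min ERK pulse duration would let window 2 integrate the
    # tail of pulse 1, so tau is only measurable on [30, 90]; outside -> NA
    tau <- tryCatch(
      measure_relaxation_time(p_sc, bracket = c(30, 90)),
      error = function(e) NA_real_
    )
    tibble::tibble(
      scale = sc, tau_min = tau,
      oscillates = any(vapply(doses, function(d) oscillates(p_sc, d), logical(1)))
    )
  })
}

#' Write / read a trajectory as TSV
#'
#' @param traj A [simulate_mapk()] trajectory.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(
    data.frame(time_s = traj$time_s, ERKpp_molecules = traj$ERKpp),
    path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Write / read a model parameter table as CSV
#'
#' Layout: columns `name`, `value`, `unit`, `cell_variable` (yes/no).
#'
#' @param params A [mapk_params()] table.
#' @param path File path.
#' @return `path` invisibly ([write_params()]); a `mapk_params` table
#'   ([read_params()]).
#' @export
write_params <- function(params, path) {
  out <- data.frame(
    name = params$name, value = params$value, unit = params$unit,
    cell_variable = ifelse(params$cell_variable, "yes", "no")
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "value", "unit", "cell_variable") %in% names(df)))
  out <- mapk_params()
  stopifnot(setequal(df$name, out$name))
  df <- df[match(out$name, df$name), ]
  out$value <- as.numeric(df$value)
  out$unit <- df$unit
  out$cell_variable <- df$cell_variable %in% c("yes", "TRUE", "true")
  out
}
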