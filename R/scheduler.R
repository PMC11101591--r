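# The global simulation loop: periodic BMU activation (targeted), stepping
# of all concurrently active BMUs, background mineralisation of quiescent
# bone, and output recording. Time advances in daily steps; one calendar
# year is 365.25 days for all rate conversions.

DAYS_PER_YEAR <- 365.25

#' BMU activation schedule
#'
#' Total number of remodelling events over a simulation and their
#' periodicity: `N = floor(Ac_f * T * A_RVE)` events, evenly spaced with
#' period `T_rep = 1 / (Ac_f * A_RVE)` (converted to days); the n-th BMU
#' activates at `n * T_rep`.
#'
#' @param Ac_f Activation frequency, BMU/mm^2/year.
#' @param A_RVE Total RVE area, mm^2 (the fixed lattice area).
#' @param T_years Total simulated time, years.
#' @return List with `N` (count) and `T_rep_days` (`Inf` when `Ac_f = 0`).
#' @export
activation_schedule <- function(Ac_f, A_RVE, T_years) {
  stopifnot(Ac_f >= 0, A_RVE > 0, T_years > 0)
  if (Ac_f == 0) return(list(N = 0L, T_rep_days = Inf))
  list(
    N = as.integer(floor(Ac_f * T_years * A_RVE)),
    T_rep_days = DAYS_PER_YEAR / (Ac_f * A_RVE)
  )
}

#' Simulation configuration
#'
#' Collects every input of a simulation run: geometry source (built-in
#' generator parameters, or a file), remodelling parameters, mineralisation
#' law inputs, free parameters Ac.f and Tsec, total time, step and
#' recording stride, and the master seed. Defaults describe physiological
#' remodelling (Ac.f = 4 BMU/mm^2/year, Tsec = 4 years, complete refilling)
#' on a 1 mm^2 synthetic RVE at 2 µm resolution.
#'
#' @param Ac_f Activation frequency, BMU/mm^2/year.
#' @param Tsec Secondary mineralisation time, years.
#' @param T_years Total simulated time, years.
#' @param u_f Underfilling coefficient.
#' @param width_px,height_px,lambda,target_f_Bm,thickness_range Geometry
#'   generator inputs (see [generate_trabecular_geometry()]).
#' @param geometry_file Optional path to a binary raster (PNG/TIFF,
#'   nonzero = bone) used instead of the generator; `lambda` still applies.
#' @param alpha0 Initial uniform ash fraction of bone (default 0.70).
#' @param dt Time step, days (default 1).
#' @param record_every Recording stride, days (default 7).
#' @param seed Master seed (integer); drives geometry and all dynamics.
#' @param activate_at_zero If `TRUE`, the first BMU activates at t = 0
#'   rather than at t = T_rep.
#' @param mineralise_in_active Passed to [sim_state()].
#' @param bin_width BMDD histogram bin width, wt% (default 0.25).
#' @param track_pixels Optional integer vector of linear pixel indices
#'   whose ash fraction is recorded at every recording step.
#' @param ... Overrides for [remodelling_params()] fields (e.g. `FP`,
#'   `R_On_mean`, `R_On_sd`, `Rs_P`, `Rv_P`, `Mlt`, `search_radius`) or
#'   [calibrate_mineralisation_law()] inputs (`alpha_primary`, `ca_cap`,
#'   `completion`, `T_prim`).
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(Ac_f = 4, Tsec = 4, T_years = 5, u_f = 0,
                              width_px = 500, height_px = 500, lambda = 2,
                              target_f_Bm = 0.42,
                              thickness_range = c(200, 400),
                              geometry_file = NULL,
                              alpha0 = 0.70, dt = 1, record_every = 7,
                              seed = 1L, activate_at_zero = FALSE,
                              mineralise_in_active = FALSE,
                              bin_width = 0.25, track_pixels = NULL, ...) {
  stopifnot(dt > 0, T_years > 0, record_every >= 1)
  extra <- list(...)
  law_fields <- intersect(names(extra),
                          c("alpha_primary", "ca_cap", "completion", "T_prim"))
  par_fields <- setdiff(names(extra), law_fields)
  ok <- par_fields %in% c("Rs_P", "Rv_P", "FP", "Mlt", "R_On_mean",
                          "R_On_sd", "search_radius")
  if (!all(ok))
    stop("unknown configuration field(s): ",
         paste(par_fields[!ok], collapse = ", "))
  cfg <- list(
    Ac_f = Ac_f, Tsec = Tsec, T_years = T_years, u_f = u_f,
    width_px = width_px, height_px = height_px, lambda = lambda,
    target_f_Bm = target_f_Bm, thickness_range = thickness_range,
    geometry_file = geometry_file, alpha0 = alpha0, dt = dt,
    record_every = record_every, seed = as.integer(seed),
    activate_at_zero = activate_at_zero,
    mineralise_in_active = mineralise_in_active,
    bin_width = bin_width, track_pixels = track_pixels,
    params_extra = extra[par_fields], law_extra = extra[law_fields]
  )
  class(cfg) <- "sim_config"
  cfg
}

config_params <- function(config) {
  do.call(remodelling_params,
          c(list(Ac_f = config$Ac_f, u_f = config$u_f),
            config$params_extra))
}

config_law <- function(config) {
  do.call(calibrate_mineralisation_law,
          c(list(Tsec = config$Tsec), config$law_extra))
}

config_geometry <- function(config) {
  if (!is.null(config$geometry_file)) {
    read_geometry_image(config$geometry_file, config$lambda)
  } else {
    generate_trabecular_geometry(
      config$width_px, config$height_px, config$lambda,
      target_f_Bm = config$target_f_Bm,
      thickness_range = config$thickness_range,
      seed = config$seed, validate = FALSE
    )
  }
}

# Summary quantities of the current state, computed from the clocks.
state_summary <- function(st) {
  bone <- st$label == 1L
  n_bone <- sum(bone)
  f_bm <- n_bone / st$Nb_RVE
  if (n_bone) {
    a <- law_alpha(st$law, st$t - st$t_start[bone])
    a[is.na(a)] <- 0  # paused osteoid inside active BMUs
    rho_app <- sum(density_from_ash(a, st$constants)) / st$Nb_RVE
    ca_mean <- mean(ca_from_ash(a, st$constants))
  } else {
    rho_app <- 0
    ca_mean <- NA_real_
  }
  c(f_Bm = f_bm, f_Ma = 1 - f_bm, rho_app = rho_app, ca_mean = ca_mean)
}

# Core daily loop. Mutates `st`; returns the recorded series and events.
run_dynamics <- function(st, config) {
  sched <- activation_schedule(config$Ac_f, st$A_RVE, config$T_years)
  days_total <- round(config$T_years * DAYS_PER_YEAR)
  dt <- config$dt
  n_steps <- ceiling(days_total / dt)
  rec_days <- if (config$record_every <= days_total)
    unique(c(0, seq(config$record_every, days_total,
                    by = config$record_every), days_total))
  else c(0, days_total)
  rec <- matrix(NA_real_, length(rec_days), 5,
                dimnames = list(NULL, c("day", "f_Bm", "f_Ma",
                                        "rho_app", "ca_mean")))
  track <- !is.null(config$track_pixels)
  if (track)
    tracked <- matrix(NA_real_, length(rec_days),
                      length(config$track_pixels))
  track_alpha <- function() {
    idx <- config$track_pixels
    a <- law_alpha(st$law, st$t - st$t_start[idx])
    a[st$label[idx] == 1L & is.na(a)] <- 0
    a
  }
  ri <- 1L
  rec[ri, ] <- c(0, state_summary(st))
  if (track) tracked[ri, ] <- track_alpha()
  ri <- ri + 1L
  next_n <- if (config$activate_at_zero) 0L else 1L

  for (k in seq_len(n_steps)) {
    t_day <- min(k * dt, days_total)
    st$t <- t_day
    # 1) activation(s) whose scheduled time has been reached
    while (next_n <= sched$N && next_n * sched$T_rep_days <= t_day + 1e-9) {
      b <- activate_bmu(st)
      if (is.null(b)) break
      next_n <- next_n + 1L
    }
    if (st$halted) {
      warning(sprintf(
        "simulation halted at day %g: bone perimeter exhausted", t_day))
      break
    }
    # 2) advance active BMUs in activation order
    if (length(st$active))
      for (b in st$active) step_bmu(st, b, dt)
    # 3) background mineralisation is implicit: every released clock reads
    #    tau_m = t - t_start, capped at the freeze clock inside law_alpha
    # 4) recording
    if (ri <= length(rec_days) && t_day >= rec_days[ri] - 1e-9) {
      rec[ri, ] <- c(t_day, state_summary(st))
      if (track) tracked[ri, ] <- track_alpha()
      ri <- ri + 1L
    }
  }
  series <- as.data.frame(rec[seq_len(ri - 1L), , drop = FALSE])
  ev <- lapply(st$bmus, function(b) {
    data.frame(n = b$n, t_act = b$t_act, row = b$pS[1], col = b$pS[2],
               R_On = b$R_On, phase = b$phase, t_done = b$t_done,
               resorbed_px = length(b$resorbed_idx),
               formed_px = length(b$formed_idx))
  })
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(n = integer(0), t_act = numeric(0), row = integer(0),
               col = integer(0), R_On = numeric(0), phase = character(0),
               t_done = numeric(0), resorbed_px = integer(0),
               formed_px = integer(0))
  list(series = series, events = events,
       tracked = if (track) tracked else NULL)
}

#' Run a remodelling simulation
#'
#' Executes the full daily loop: geometry synthesis (or a supplied initial
#' state), BMU activation at the scheduled times, concurrent BMU
#' progression, background mineralisation, and recording. Deterministic
#' given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param init_state Optional [sim_state] to continue from (e.g. a saved
#'   physiological warm-up); it is copied, not modified. When supplied, the
#'   geometry step is skipped and remodelling parameters/law come from
#'   `config`.
#' @param dynamics_seed Optional integer overriding the dynamics RNG seed
#'   (used by [run_replicates()] to vary replicates on a shared geometry).
#' @return Object of class `sim_result`: `series` (data.frame of day,
#'   f_Bm, f_Ma, rho_app, ca_mean), `events` (BMU log), `bmdd` (final
#'   [compute_bmdd()] summary), `alpha` (final ash-fraction matrix),
#'   `grid` (final [label_grid]), `state` (final [sim_state] for
#'   chaining), `tracked`, `config`, `halted`.
#' @export
run_simulation <- function(config, init_state = NULL, dynamics_seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  law <- config_law(config)
  params <- config_params(config)
  if (is.null(init_state)) {
    grid <- config_geometry(config)
    st <- sim_state(grid, law, params, alpha0 = config$alpha0,
                    mineralise_in_active = config$mineralise_in_active)
  } else {
    st <- clone_state(init_state)
    st$law <- law
    st$params <- params
    # rebase clocks to the new run's t = 0; osteoid still paused in BMUs
    # left incomplete at hand-over starts mineralising after Mlt
    pending <- st$label == 1L & is.na(st$t_start)
    st$t_start[pending] <- st$t + params$Mlt
    st$t_start <- st$t_start - st$t
    st$t <- 0
    st$bmus <- list()
    st$active <- list()
    st$n_act <- 0L
    st$kern_fft <- NULL
    st$kern_radius_px <- NA_real_
  }
  if (is.null(dynamics_seed))
    dynamics_seed <- (config$seed + 1L) %% .Machine$integer.max
  set.seed(as.integer(dynamics_seed))
  dyn <- run_dynamics(st, config)
  alpha <- state_alpha(st)
  grid_final <- label_grid(st$label, st$lambda)
  res <- list(
    series = dyn$series, events = dyn$events,
    bmdd = if (any(st$label == 1L))
      compute_bmdd(alpha, grid_final, bin_width = config$bin_width)
    else NULL,
    alpha = alpha, grid = grid_final, state = st,
    tracked = dyn$tracked, config = config, halted = st$halted
  )
  class(res) <- "sim_result"
  res
}

#' @export
print.sim_result <- function(x, ...) {
  fin <- x$series[nrow(x$series), ]
  cat(sprintf(
    "<sim_result> T = %g y, %d BMU(s); final f_Bm = %.3f, rho_app = %.3f g/cm^3, Ca_MEAN = %.2f wt%%\n",
    x$config$T_years, nrow(x$events), fin$f_Bm, fin$rho_app, fin$ca_mean
  ))
  invisible(x)
}

# Deep copy of a sim_state (matrices are copied by value in R; BMU lists
# are dropped on purpose -- chaining assumes completed remodelling).
clone_state <- function(st) {
  new <- new.env(parent = emptyenv())
  for (nm in c("label", "lambda", "nr", "nc", "Nb_RVE", "A_RVE", "law",
               "params", "constants", "mineralise_in_active", "t_start",
               "owner", "t", "n_act", "halted"))
    assign(nm, get(nm, st), new)
  new$bmus <- list()
  new$active <- list()
  new$kern_fft <- NULL
  new$kern_radius_px <- NA_real_
  class(new) <- c("sim_state", "environment")
  new
}

#' Run replicated simulations on a shared initial geometry
#'
#' Generates (or loads) the initial geometry once, then runs `n_reps`
#' simulations with distinct dynamics sub-seeds derived from the master
#' seed. Reported as per-quantity mean and standard deviation across
#' replicates.
#'
#' @param config A [simulation_config()].
#' @param n_reps Number of replicates (>= 1).
#' @param init_state Optional shared starting [sim_state] (overrides the
#'   geometry step; used for scenario chains).
#' @return Object of class `sim_replicates`: `runs` (list of
#'   `sim_result`), `summary` (data.frame of final Ca_MEAN, Ca_PEAK,
#'   Ca_WIDTH, skewness, f_Bm, rho_app with mean and sd), `config`,
#'   `n_reps`.
#' @export
run_replicates <- function(config, n_reps = 5, init_state = NULL) {
  stopifnot(inherits(config, "sim_config"), n_reps >= 1)
  if (is.null(init_state)) {
    grid <- config_geometry(config)
    law <- config_law(config)
    params <- config_params(config)
    init_state <- sim_state(grid, law, params, alpha0 = config$alpha0,
                            mineralise_in_active = config$mineralise_in_active)
  }
  runs <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    runs[[r]] <- run_simulation(
      config, init_state = init_state,
      dynamics_seed = (config$seed + r) %% .Machine$integer.max
    )
  }
  fin <- do.call(rbind, lapply(runs, function(x) {
    s <- x$series[nrow(x$series), ]
    data.frame(
      Ca_MEAN = x$bmdd$Ca_MEAN, Ca_PEAK = x$bmdd$Ca_PEAK,
      Ca_WIDTH = x$bmdd$Ca_WIDTH, skewness = x$bmdd$skewness,
      f_Bm = s$f_Bm, rho_app = s$rho_app
    )
  }))
  summary <- data.frame(
    quantity = names(fin),
    mean = vapply(fin, mean, numeric(1)),
    sd = if (n_reps > 1) vapply(fin, stats::sd, numeric(1)) else
      rep(0, ncol(fin)),
    row.names = NULL
  )
  structure(list(runs = runs, finals = fin, summary = summary,
                 config = config, n_reps = n_reps),
            class = "sim_replicates")
}

#' @export
print.sim_replicates <- function(x, ...) {
  cat(sprintf("<sim_replicates> %d replicate(s)\n", x$n_reps))
  print(x$summary)
  invisible(x)
}
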