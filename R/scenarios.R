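# Preset experiment configurations: physiological control, the two
# postmenopausal (type I) osteoporosis hypotheses (longer formation period;
# higher activation frequency), the two senile (type II) hypotheses
# (underfilling; no filling / uncoupling), and the alternative
# histomorphometric parameter set (Ac.f = 18 BMU/mm^2/year with 40 µm
# hemiosteons). Pathological scenarios start from the state reached after
# a physiological warm-up, so differences are attributable to the scenario.

#' Scenario presets
#'
#' @return Named list of parameter overrides per preset: `control`
#'   (Ac.f = 4 BMU/mm^2/year, Tsec = 4 y, u_f = 0), `high_FP`
#'   (FP = 475 d), `high_Acf` (Ac.f = 8), `underfilling` (u_f = 0.5),
#'   `no_filling` (u_f = 1), `parfitt` (Ac.f = 18, R_On ~ N(40, 1) µm).
#' @export
scenario_presets <- function() {
  list(
    control      = list(Ac_f = 4, Tsec = 4, u_f = 0),
    high_FP      = list(FP = 475),
    high_Acf     = list(Ac_f = 8),
    underfilling = list(u_f = 0.5),
    no_filling   = list(u_f = 1),
    # sigma scaled with the radius (2.5 * 40/100 = 1 um)
    parfitt      = list(Ac_f = 18, R_On_mean = 40, R_On_sd = 1)
  )
}

#' Build a scenario configuration
#'
#' Applies a preset's overrides to a base configuration. The returned
#' config describes the pathology (or control) phase only; use
#' [run_scenarios()] for the full warm-up + pathology chain.
#'
#' @param name Preset name (see [scenario_presets()]).
#' @param base_config A [simulation_config()].
#' @return A `sim_config`.
#' @export
build_scenario <- function(name, base_config) {
  presets <- scenario_presets()
  if (!name %in% names(presets))
    stop("unknown preset: ", name, " (known: ",
         paste(names(presets), collapse = ", "), ")")
  ov <- presets[[name]]
  cfg <- base_config
  for (nm in names(ov)) {
    if (nm %in% c("Ac_f", "Tsec", "u_f")) cfg[[nm]] <- ov[[nm]]
    else cfg$params_extra[[nm]] <- ov[[nm]]
  }
  cfg
}

#' Run the osteoporosis scenario chain
#'
#' Performs a physiological warm-up (control parameters) on the base
#' geometry, then continues each requested scenario from the saved warm-up
#' state. The warm-up state can be cached to disk and is reused across
#' scenarios.
#'
#' @param base_config A [simulation_config()]; its geometry, seed and
#'   control parameters drive the warm-up.
#' @param scenarios Character vector of preset names (the control is always
#'   included as the comparison baseline).
#' @param warmup_years Duration of the physiological warm-up (default 5).
#' @param scenario_years Duration of each pathology phase (default 3).
#' @param n_reps Replicates per scenario (distinct dynamics sub-seeds).
#' @param cache_dir Optional directory; the warm-up state is serialised
#'   there (`warmup_state.rds`) and reused on repeated calls with the same
#'   configuration seed.
#' @return List with `results` (named list of `sim_replicates`),
#'   `comparison` (the [compare_scenarios()] table) and `warmup`
#'   (the warm-up `sim_result`).
#' @export
run_scenarios <- function(base_config,
                          scenarios = c("high_FP", "high_Acf",
                                        "underfilling", "no_filling"),
                          warmup_years = 5, scenario_years = 3,
                          n_reps = 3, cache_dir = NULL) {
  ctrl_cfg <- build_scenario("control", base_config)
  warm_cfg <- ctrl_cfg
  warm_cfg$T_years <- warmup_years

  warm <- NULL
  cache_file <- NULL
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    cache_file <- file.path(cache_dir,
                            sprintf("warmup_seed%d.rds", warm_cfg$seed))
    if (file.exists(cache_file)) warm <- readRDS(cache_file)
  }
  if (is.null(warm)) {
    warm <- run_simulation(warm_cfg)
    if (!is.null(cache_file)) saveRDS(warm, cache_file)
  }

  names_all <- unique(c("control", scenarios))
  results <- list()
  for (nm in names_all) {
    cfg <- build_scenario(nm, base_config)
    cfg$T_years <- scenario_years
    results[[nm]] <- run_replicates(cfg, n_reps = n_reps,
                                    init_state = warm$state)
  }
  list(results = results,
       comparison = compare_scenarios(results, control = "control"),
       warmup = warm)
}

#' Sweep activation frequency and secondary mineralisation time
#'
#' Runs replicated simulations for every (Ac.f, Tsec) pair on the grid and
#' tabulates the final BMDD descriptors and apparent density — the
#' simulated analogue of the Ca_MEAN / Ca_PEAK / rho_app versus Ac.f
#' curves per mineralisation kinetics.
#'
#' @param Ac_f_values,Tsec_values Numeric grids (non-empty).
#' @param base_config A [simulation_config()].
#' @param n_reps Replicates per grid point.
#' @return Data.frame with one row per (Ac.f, Tsec) pair: mean and sd of
#'   Ca_MEAN, Ca_PEAK, rho_app and f_Bm across replicates.
#' @export
run_sweep <- function(Ac_f_values, Tsec_values, base_config, n_reps = 5) {
  stopifnot(length(Ac_f_values) >= 1, length(Tsec_values) >= 1)
  rows <- list()
  for (ts in Tsec_values) for (af in Ac_f_values) {
    cfg <- base_config
    cfg$Ac_f <- af
    cfg$Tsec <- ts
    reps <- run_replicates(cfg, n_reps = n_reps)
    f <- reps$finals
    rows[[length(rows) + 1L]] <- data.frame(
      Ac_f = af, Tsec = ts,
      Ca_MEAN = mean(f$Ca_MEAN), Ca_MEAN_sd = stats::sd(f$Ca_MEAN),
      Ca_PEAK = mean(f$Ca_PEAK), Ca_PEAK_sd = stats::sd(f$Ca_PEAK),
      rho_app = mean(f$rho_app), rho_app_sd = stats::sd(f$rho_app),
      f_Bm = mean(f$f_Bm), f_Bm_sd = stats::sd(f$f_Bm)
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
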