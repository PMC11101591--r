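# The BMU (basic multicellular unit) state machine. A BMU is activated on
# the bone perimeter at the surface region with the highest mean ash
# fraction (targeted remodelling), resorbs a hemiosteonal cavity radially
# at constant speed, rests through a quiescent reversal phase, then refills
# the cavity radially inwards from the cement line, stopping early when the
# underfilling radius u_f * R_On is reached. Formation writes only into the
# BMU's own resorbed set (cement-line containment).

#' Remodelling parameters
#'
#' Timing periods, hemiosteon radius distribution, underfilling and the
#' targeted-search radius. Defaults are the standard histomorphometric
#' values: Rs.P = 21 d, Rv.P = 10 d, FP = 91 d, Mlt = 10 d, hemiosteon
#' radius N(100, 2.5) µm.
#'
#' @param Ac_f Activation frequency, BMU/mm^2/year.
#' @param Rs_P,Rv_P,FP,Mlt Resorption, reversal, formation periods and
#'   mineralisation lag time, days.
#' @param R_On_mean,R_On_sd Hemiosteon radius distribution, µm. The radius
#'   is sampled once per BMU from a normal truncated at 3 sd and at zero.
#' @param u_f Underfilling coefficient in \[0, 1\]: 0 = complete refilling,
#'   1 = no filling (uncoupling).
#' @param search_radius Radius (µm) of the disc over which the mean ash
#'   fraction is evaluated around each perimeter point during targeted
#'   activation; defaults to `R_On_mean`.
#' @return A named list of class `remodelling_params`.
#' @export
remodelling_params <- function(Ac_f = 4, Rs_P = 21, Rv_P = 10, FP = 91,
                               Mlt = 10, R_On_mean = 100, R_On_sd = 2.5,
                               u_f = 0, search_radius = NULL) {
  stopifnot(Ac_f >= 0, Rs_P > 0, Rv_P >= 0, FP > 0, Mlt >= 0,
            R_On_mean > 0, R_On_sd >= 0, u_f >= 0, u_f <= 1)
  if (is.null(search_radius)) search_radius <- R_On_mean
  structure(list(Ac_f = Ac_f, Rs_P = Rs_P, Rv_P = Rv_P, FP = FP, Mlt = Mlt,
                 R_On_mean = R_On_mean, R_On_sd = R_On_sd, u_f = u_f,
                 search_radius = search_radius),
            class = "remodelling_params")
}

#' Create a simulation state
#'
#' Bundles the geometry, mineralisation law, remodelling parameters and the
#' per-pixel state (labels, mineralisation clocks) into a mutable
#' environment that the stepping functions update in place. Bone pixels are
#' initialised at ash fraction `alpha0` with the consistent clock
#' `M^-1(alpha0)`, so pre-existing bone keeps mineralising towards the cap.
#'
#' @param grid A [label_grid].
#' @param law A `mineralisation_law`.
#' @param params A [remodelling_params] list.
#' @param alpha0 Initial ash fraction of all bone pixels (default 0.70).
#' @param constants A [material_constants] list.
#' @param mineralise_in_active If `FALSE` (default), pixels formed by a BMU
#'   keep their mineralisation clock paused until that BMU completes.
#' @return An environment of class `sim_state`.
#' @export
sim_state <- function(grid, law, params, alpha0 = 0.70,
                      constants = material_constants(),
                      mineralise_in_active = FALSE) {
  stopifnot(inherits(grid, "label_grid"),
            inherits(law, "mineralisation_law"),
            inherits(params, "remodelling_params"))
  if (alpha0 < 0 || alpha0 >= law$c_max)
    stop("alpha0 must lie in [0, c_max)")
  st <- new.env(parent = emptyenv())
  st$label <- grid$labels
  st$lambda <- grid$lambda
  st$nr <- nrow(grid$labels)
  st$nc <- ncol(grid$labels)
  st$Nb_RVE <- grid$Nb_RVE
  st$A_RVE <- grid$A_RVE
  st$law <- law
  st$params <- params
  st$constants <- constants
  st$mineralise_in_active <- mineralise_in_active
  # Per-pixel mineralisation is tracked by the day its clock started:
  # tau_m(p, t) = t - t_start(p). NA on marrow and on osteoid whose clock
  # is paused inside an active BMU (released at BMU completion).
  tau0 <- inverse_law(law, alpha0)
  st$t_start <- matrix(NA_real_, st$nr, st$nc)
  st$t_start[st$label == 1L] <- -tau0
  st$owner <- matrix(0L, st$nr, st$nc)
  st$t <- 0
  st$bmus <- list()      # all BMUs ever activated
  st$active <- list()    # currently active BMUs, in activation order
  st$n_act <- 0L
  st$halted <- FALSE
  st$kern_radius_px <- NA_real_
  st$kern_fft <- NULL
  class(st) <- c("sim_state", "environment")
  st
}

#' Current ash-fraction field of a simulation state
#'
#' Bone pixels whose mineralisation clock is paused inside an active BMU
#' (unmineralised osteoid) report ash fraction 0; marrow is `NA`.
#'
#' @param state A [sim_state].
#' @return Matrix of ash fractions (`NA` on marrow).
#' @export
state_alpha <- function(state) {
  a <- law_alpha(state$law, state$t - state$t_start)
  a[state$label == 1L & is.na(state$t_start)] <- 0
  a
}

#' Current mineralisation clocks of a simulation state
#'
#' @param state A [sim_state].
#' @return Matrix of clock values tau_m in days (`NA` on marrow and on
#'   osteoid whose clock has not been released yet).
#' @export
state_tau_m <- function(state) state$t - state$t_start

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf(
    "<sim_state> %d x %d px @ %g um, t = %g d, f_Bm = %.3f, %d BMU(s) active, %d activated\n",
    x$nr, x$nc, x$lambda, x$t, sum(x$label) / x$Nb_RVE,
    length(x$active), x$n_act
  ))
  invisible(x)
}

# Perimeter mean ash fraction via periodic disc convolution: returns the
# mean alpha over bone pixels within the search disc of each perimeter
# point (full disc intersected with bone).
perimeter_search_means <- function(state, perim_idx) {
  r_px <- state$params$search_radius / state$lambda
  if (is.null(state$kern_fft) || !identical(state$kern_radius_px, r_px)) {
    state$kern_fft <- disc_kernel_fft(r_px, state$nr, state$nc)
    state$kern_radius_px <- r_px
  }
  az <- state_alpha(state)
  az[is.na(az)] <- 0
  bone <- matrix(as.numeric(state$label), state$nr, state$nc)
  s <- circ_convolve(az, state$kern_fft)
  n <- circ_convolve(bone, state$kern_fft)
  s[perim_idx] / pmax(n[perim_idx], 1)
}

#' Activate a new BMU by targeted remodelling
#'
#' Computes the mean ash fraction within the search disc of every perimeter
#' point, seeds the BMU at the point with the highest mean (ties broken
#' uniformly at random), samples the hemiosteon radius, and registers the
#' BMU as active in the resorption phase with local clock zero.
#'
#' @param state A [sim_state]; modified in place.
#' @return The new BMU (an environment), invisibly `NULL` when the
#'   perimeter is empty (the caller must halt the simulation).
#' @export
activate_bmu <- function(state) {
  perim <- extract_perimeter(state$label)
  if (length(perim) == 0L) {
    state$halted <- TRUE
    return(invisible(NULL))
  }
  means <- perimeter_search_means(state, perim)
  mx <- max(means)
  ties <- which(means >= mx - 1e-9)
  pick <- perim[ties[sample.int(length(ties), 1L)]]
  p <- state$params
  R_On <- if (p$R_On_sd == 0) p$R_On_mean else {
    repeat {
      r <- stats::rnorm(1, p$R_On_mean, p$R_On_sd)
      if (r > 0 && abs(r - p$R_On_mean) <= 3 * p$R_On_sd) break
    }
    r
  }

  rc <- arrayInd(pick, c(state$nr, state$nc))
  pr <- rc[1]; pc <- rc[2]
  R_px <- ceiling(R_On / state$lambda)
  rows <- max(1L, pr - R_px):min(state$nr, pr + R_px)
  cols <- max(1L, pc - R_px):min(state$nc, pc + R_px)
  d <- sqrt(outer((rows - pr)^2, (cols - pc)^2, "+")) * state$lambda
  keep <- which(d <= R_On)
  idx <- as.integer(outer(rows, (cols - 1L) * state$nr, "+"))[keep]
  dist <- d[keep]
  o <- order(dist)

  b <- new.env(parent = emptyenv())
  b$n <- state$n_act + 1L
  b$pS <- c(row = pr, col = pc)
  b$pS_idx <- pick
  b$R_On <- R_On
  b$tau_b <- 0
  b$phase <- "RESORPTION"
  b$tau1 <- p$Rs_P
  b$tau2 <- p$Rs_P + p$Rv_P
  b$tau3 <- p$Rs_P + p$Rv_P + p$FP
  b$u_f <- p$u_f
  b$cand_idx <- idx[o]
  b$cand_dist <- dist[o]
  b$res_ptr <- 1L
  b$resorbed_idx <- integer(0)
  b$resorbed_dist <- numeric(0)
  b$form_ptr <- 0L
  b$formed_idx <- integer(0)
  b$t_act <- state$t
  b$t_done <- NA_real_
  class(b) <- c("bmu", "environment")

  state$n_act <- b$n
  state$bmus[[b$n]] <- b
  state$active[[length(state$active) + 1L]] <- b
  b
}

# Remove bone pixels of `b` newly inside the resorption radius.
.resorb_to_radius <- function(state, b, r_Rs) {
  hi <- findInterval(r_Rs + 1e-9, b$cand_dist)
  if (hi >= b$res_ptr) {
    rng <- b$res_ptr:hi
    ii <- b$cand_idx[rng]
    is_bone <- state$label[ii] == 1L
    if (any(is_bone)) {
      ii <- ii[is_bone]
      state$label[ii] <- 0L
      state$t_start[ii] <- NA_real_
      state$owner[ii] <- 0L
      b$resorbed_idx <- c(b$resorbed_idx, ii)
      b$resorbed_dist <- c(b$resorbed_dist, b$cand_dist[rng][is_bone])
    }
    b$res_ptr <- hi + 1L
  }
  invisible(NULL)
}

# Lay down new bone on the BMU's own resorbed pixels with distance >= r_F
# that are still marrow. New bone is unmineralised osteoid; mineralisation
# starts Mlt days after the clock is released (at formation, or at BMU
# completion when clocks pause inside active BMUs).
.form_to_radius <- function(state, b, r_F) {
  if (b$form_ptr < 1L) return(invisible(NULL))
  lo <- findInterval(r_F - 1e-9, b$resorbed_dist) + 1L
  if (lo <= b$form_ptr) {
    ii <- b$resorbed_idx[lo:b$form_ptr]
    mar <- state$label[ii] == 0L
    if (any(mar)) {
      ii <- ii[mar]
      state$label[ii] <- 1L
      state$owner[ii] <- b$n
      state$t_start[ii] <- if (state$mineralise_in_active)
        state$t + state$params$Mlt else NA_real_
      b$formed_idx <- c(b$formed_idx, ii)
    }
    b$form_ptr <- lo - 1L
  }
  invisible(NULL)
}

.complete_bmu <- function(state, b) {
  b$phase <- "DONE"
  b$t_done <- state$t
  if (!state$mineralise_in_active && length(b$formed_idx)) {
    ii <- b$formed_idx
    mine <- state$owner[ii] == b$n & state$label[ii] == 1L
    state$t_start[ii[mine]] <- b$t_done + state$params$Mlt
  }
  state$active <- Filter(function(x) !identical(x, b), state$active)
  invisible(NULL)
}

#' Advance one BMU by one time step
#'
#' Advances the BMU's local clock by `dt` days and applies the action of
#' its current phase: radial resorption (bone pixels within the growing
#' resorption radius become marrow), quiescent reversal (no change), or
#' radial formation (marrow pixels of the BMU's resorbed set between the
#' shrinking formation radius and the cement line become unmineralised
#' bone). Formation ends at the formation period or as soon as the
#' formation radius drops below `u_f * R_On`, whichever comes first.
#'
#' @param state A [sim_state]; modified in place.
#' @param bmu A BMU environment from [activate_bmu()].
#' @param dt Time step, days.
#' @return The BMU, invisibly.
#' @export
step_bmu <- function(state, bmu, dt = 1) {
  if (bmu$phase == "DONE") return(invisible(bmu))
  p <- state$params
  bmu$tau_b <- bmu$tau_b + dt
  if (bmu$phase == "RESORPTION") {
    r_Rs <- bmu$R_On * min(bmu$tau_b, bmu$tau1) / p$Rs_P
    .resorb_to_radius(state, bmu, r_Rs)
    if (bmu$tau_b >= bmu$tau1 - 1e-9) bmu$phase <- "REVERSAL"
  }
  if (bmu$phase == "REVERSAL") {
    # quiescent: the remodelling region keeps radius R_On, nothing changes
    if (bmu$tau_b >= bmu$tau2 - 1e-9) {
      bmu$phase <- "FORMATION"
      bmu$form_ptr <- length(bmu$resorbed_idx)
    }
  }
  if (bmu$phase == "FORMATION" && bmu$tau_b > bmu$tau2) {
    r_F <- bmu$R_On * (1 - (min(bmu$tau_b, bmu$tau3) - bmu$tau2) / p$FP)
    if (r_F < bmu$u_f * bmu$R_On - 1e-9) {
      .complete_bmu(state, bmu)      # partial refill: ends immediately
    } else {
      .form_to_radius(state, bmu, r_F)
      if (bmu$tau_b >= bmu$tau3 - 1e-9) .complete_bmu(state, bmu)
    }
  }
  invisible(bmu)
}

#' @rdname step_bmu
#' @export
resorption_step <- function(state, bmu, dt = 1) {
  if (bmu$phase != "RESORPTION") stop("BMU is not in the resorption phase")
  step_bmu(state, bmu, dt)
}

#' @rdname step_bmu
#' @export
reversal_step <- function(state, bmu, dt = 1) {
  if (bmu$phase != "REVERSAL") stop("BMU is not in the reversal phase")
  step_bmu(state, bmu, dt)
}

#' @rdname step_bmu
#' @export
formation_step <- function(state, bmu, dt = 1) {
  if (bmu$phase != "FORMATION") stop("BMU is not in the formation phase")
  step_bmu(state, bmu, dt)
}

#' @export
print.bmu <- function(x, ...) {
  cat(sprintf(
    "<bmu #%d> seed (%d, %d), R_On = %.1f um, phase %s, tau_b = %g d, resorbed %d px, formed %d px\n",
    x$n, x$pS[1], x$pS[2], x$R_On, x$phase, x$tau_b,
    length(x$resorbed_idx), length(x$formed_idx)
  ))
  invisible(x)
}
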