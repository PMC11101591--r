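# The mineralisation law: a double-exponential rise of the ash fraction
# with the pixel's mineralisation clock tau_m (days),
#   M(tau) = c1 (1 - exp(-tau/t1)) + (c_max - c1)(1 - exp(-tau/t2)),
# where the fast first exponential is the primary mineralisation phase
# (plateau c1) and the slow second exponential the secondary phase towards
# the calcium cap c_max. Calibration fixes c1 at the primary-phase ash
# plateau, c_max at the ~30 wt% Ca cap, t1 so that primary mineralisation
# is practically complete within ~10 days, and t2 so that M reaches the
# stated completion of c_max at the secondary mineralisation time Tsec.

#' Calibrate the double-exponential mineralisation law
#'
#' @param Tsec Total secondary mineralisation time, years.
#' @param alpha_primary Ash-fraction plateau of primary mineralisation
#'   (default 0.45).
#' @param ca_cap Maximum calcium content, wt% (default 30); sets
#'   `c_max = ca_cap / (100 * ca_per_mineral)`.
#' @param completion Fraction of a plateau counted as "complete" (default
#'   0.95): t1 is set so the first exponential reaches
#'   `completion * c1` at `T_prim`, and t2 so that `M(Tsec)` equals
#'   `completion * c_max`.
#' @param T_prim Duration of primary mineralisation, days (default 10).
#' @param constants A [material_constants] list.
#' @return Object of class `mineralisation_law`: `c1`, `c_max`, `t1`, `t2`
#'   (days), `Tsec` (years), `Tsec_days`, and `tau_freeze` — the clock value
#'   at which a pixel is considered fully mineralised
#'   (`M(tau_freeze) = 0.999 c_max`) and is frozen.
#' @export
calibrate_mineralisation_law <- function(Tsec,
                                         alpha_primary = 0.45,
                                         ca_cap = 30,
                                         completion = 0.95,
                                         T_prim = 10,
                                         constants = material_constants()) {
  stopifnot(Tsec > 0, completion > 0, completion < 1, T_prim > 0)
  Tsec_days <- Tsec * 365.25
  if (Tsec_days <= T_prim)
    stop("infeasible calibration: Tsec must exceed the primary phase")
  c_max <- (ca_cap / 100) / constants$ca_per_mineral
  c1 <- alpha_primary
  if (!(c1 > 0 && c1 < c_max && c_max < 1))
    stop("infeasible calibration: need 0 < c1 < c_max < 1")
  t1 <- T_prim / log(1 / (1 - completion))
  # M(Tsec_days) = completion * c_max, solved for t2.
  target <- completion * c_max
  f <- function(t2) {
    c1 * (1 - exp(-Tsec_days / t1)) +
      (c_max - c1) * (1 - exp(-Tsec_days / t2)) - target
  }
  if (f(1e-6) < 0)
    stop("infeasible calibration: completion target unreachable at Tsec")
  t2 <- stats::uniroot(f, c(1e-6, 1e7), tol = 1e-10)$root
  law <- structure(
    list(c1 = c1, c_max = c_max, t1 = t1, t2 = t2,
         Tsec = Tsec, Tsec_days = Tsec_days,
         completion = completion, T_prim = T_prim),
    class = "mineralisation_law"
  )
  law$tau_freeze <- inverse_law(law, 0.999 * c_max)
  law
}

#' @export
print.mineralisation_law <- function(x, ...) {
  cat(sprintf(
    "<mineralisation_law> c1 = %.3f, c_max = %.4f, t1 = %.2f d, t2 = %.1f d, Tsec = %g y\n",
    x$c1, x$c_max, x$t1, x$t2, x$Tsec
  ))
  invisible(x)
}

#' Evaluate the mineralisation law
#'
#' @param law A `mineralisation_law`.
#' @param tau_m Mineralisation clock value(s), days; must be >= 0.
#' @return Ash fraction(s) `M(tau_m)`, strictly increasing in `tau_m`, with
#'   `M(0) = 0` and supremum `c_max`.
#' @export
evaluate_law <- function(law, tau_m) {
  stopifnot(inherits(law, "mineralisation_law"))
  if (any(tau_m < 0, na.rm = TRUE)) stop("tau_m must be non-negative")
  law$c1 * (1 - exp(-tau_m / law$t1)) +
    (law$c_max - law$c1) * (1 - exp(-tau_m / law$t2))
}

# Fast internal path: clamps negative clocks (lag not elapsed) to zero and
# caps at the freeze clock; accepts NA (marrow).
law_alpha <- function(law, tau_m) {
  tau <- pmin(pmax(tau_m, 0), law$tau_freeze)
  law$c1 * (1 - exp(-tau / law$t1)) +
    (law$c_max - law$c1) * (1 - exp(-tau / law$t2))
}

#' Invert the mineralisation law
#'
#' Numerical inverse of `M` by bisection (tolerance 1e-10 on alpha). Used
#' to assign a consistent clock to bone initialised at a given ash fraction
#' so that it keeps mineralising towards the cap.
#'
#' @param law A `mineralisation_law`.
#' @param alpha Ash fraction(s) in \[0, c_max).
#' @return Clock value(s) tau with `M(tau) = alpha`.
#' @export
inverse_law <- function(law, alpha) {
  stopifnot(inherits(law, "mineralisation_law"))
  if (any(alpha < 0 | alpha >= law$c_max))
    stop("alpha must lie in [0, c_max)")
  vapply(alpha, function(a) {
    if (a == 0) return(0)
    lo <- 0
    hi <- law$t2
    while (evaluate_law(law, hi) < a) hi <- hi * 2
    while (hi - lo > 1e-8) {
      mid <- (lo + hi) / 2
      if (evaluate_law(law, mid) < a) lo <- mid else hi <- mid
    }
    mid <- (lo + hi) / 2
    # refine on alpha scale
    for (i in 1:60) {
      if (abs(evaluate_law(law, mid) - a) < 1e-12) break
      if (evaluate_law(law, mid) < a) lo <- mid else hi <- mid
      mid <- (lo + hi) / 2
    }
    mid
  }, numeric(1))
}

#' Advance mineralisation clocks
#'
#' Advances the clock of every bone pixel that is mineralising (not inside
#' an active BMU, not yet frozen) by `dt` days and returns the updated
#' clocks together with the implied ash-fraction field. Pixels whose clock
#' is still negative (mineralisation lag not elapsed) advance their clock
#' but keep ash fraction 0; pixels at or beyond the freeze clock are capped
#' and no longer change.
#'
#' @param tau_m Matrix of mineralisation clocks (days; `NA` on marrow).
#' @param law A `mineralisation_law`.
#' @param active Optional logical matrix marking pixels inside active BMUs
#'   (their clocks are untouched this call).
#' @param dt Time step, days (> 0).
#' @return List with updated `tau_m` and the `alpha` matrix.
#' @export
advance_mineralisation <- function(tau_m, law, active = NULL, dt = 1) {
  stopifnot(dt > 0)
  adv <- !is.na(tau_m)
  if (!is.null(active)) adv <- adv & !active
  tau_m[adv] <- pmin(tau_m[adv] + dt, law$tau_freeze)
  list(tau_m = tau_m, alpha = law_alpha(law, tau_m))
}
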