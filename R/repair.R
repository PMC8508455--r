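#' Repair model parameters
#'
#' The DSB repair framework tracks the remaining DSB yield N0(t) under an
#' induction term active during irradiation and a sum of pathway repair
#' potentials:
#' `dN0/dt = alpha(L) dD/dt - V_NHEJ - V_HR - V_SSA - V_microSSA - V_AltNHEJ`.
#' The pathway potentials are pluggable; the built-in default is
#' first-order kinetics `V_p = k_p f_p (N0 - N_ir)` with a fast
#' (NHEJ-like, half-life ~0.3 h) and slow (HR/SSA-like, ~4 h) component,
#' standing in for the full 29-equation pathway system the framework can
#' host. Irreparable DSBs (`N_ir`) never enter any potential, so
#' N0(t) -> N_ir at long times.
#'
#' @param alpha DSB induction per Gy per cell at the LET of interest.
#' @param dose absorbed dose, Gy.
#' @param dose_rate `NULL` for an instantaneous dose at t = 0, or a
#'   function of time (h) returning dD/dt in Gy/h.
#' @param irradiation_end_h end of the protracted irradiation, h (needed
#'   with `dose_rate`).
#' @param N_ir irreparable yield (count); see [irreparable_yield()].
#' @param pathways data frame with columns `name`, `fraction`
#'   (summing to 1) and `half_life_h`.
#' @param k_on_foci,k_off_foci gamma-H2AX focus formation and decay rates,
#'   1/h.
#' @param foci_floor residual focus level below which decay stops.
#' @return a `repair_params`.
#' @export
repair_params <- function(alpha = 25.9, dose = 1, dose_rate = NULL,
                          irradiation_end_h = 0, N_ir = 0,
                          pathways = default_pathways(),
                          k_on_foci = 8, k_off_foci = 0.4,
                          foci_floor = 0) {
  k <- log(2) / pathways$half_life_h
  if (any(k < 0) || any(pathways$fraction < 0))
    stop("pathway rates and fractions must be >= 0")
  if (abs(sum(pathways$fraction) - 1) > 1e-8)
    stop("pathway fractions must sum to 1")
  if (k_on_foci < 0 || k_off_foci < 0) stop("foci rates must be >= 0")
  structure(list(alpha = alpha, dose = dose, dose_rate = dose_rate,
                 irradiation_end_h = irradiation_end_h, N_ir = N_ir,
                 pathways = transform(pathways, k = k),
                 k_on_foci = k_on_foci, k_off_foci = k_off_foci,
                 foci_floor = foci_floor),
            class = "repair_params")
}

#' Default repair pathway table
#'
#' Fast NHEJ-dominated component plus slow homology-mediated components;
#' fractions and half-lives are configurable surrogates.
#'
#' @return data frame `name`, `fraction`, `half_life_h`.
#' @export
default_pathways <- function() {
  data.frame(
    name = c("NHEJ", "HR", "SSA", "micro-SSA", "Alt-NHEJ"),
    fraction = c(0.75, 0.12, 0.06, 0.03, 0.04),
    half_life_h = c(0.3, 4, 4, 8, 8))
}

#' Irreparable DSB yield from a damage tally
#'
#' With this damage scheme the irreparable yield is
#' `N_DSB+ + 2 x N_DSB++`: complex DSB clusters resist repair, and a
#' DSB++ cluster holds two DSBs.
#'
#' @param tally a `damage_tally`.
#' @return irreparable count.
#' @export
irreparable_yield <- function(tally) {
  unname(tally$counts[["DSB+"]] + 2 * tally$counts[["DSB++"]])
}

#' Solve the repair kinetics
#'
#' Integrates the repair balance with `deSolve`, tracking N0, the
#' per-pathway repaired totals and the gamma-H2AX focus yield
#' `dF/dt = k_on N0 - k_off max(F - F_floor, 0)`.
#' With the default instantaneous dose the initial condition is
#' `N0(0) = alpha * dose` and no induction term remains for t > 0.
#'
#' @param params a [repair_params()].
#' @param t_end_h end time, hours.
#' @param dt_h output resolution, hours.
#' @return a `repair_state` data frame: `t_h`, `N0`, one `rep_<pathway>`
#'   column per pathway, `repaired`, `foci`.
#' @export
solve_repair <- function(params, t_end_h = 25, dt_h = 0.05) {
  stopifnot(inherits(params, "repair_params"))
  pw <- params$pathways
  np <- nrow(pw)
  instant <- is.null(params$dose_rate)
  N0_0 <- if (instant) params$alpha * params$dose else 0
  y0 <- c(N0 = N0_0, setNames(rep(0, np), paste0("rep_", pw$name)), F = 0)
  deriv <- function(t, y, p) {
    N0 <- y[1]
    reparable <- max(N0 - params$N_ir, 0)
    V <- pw$k * pw$fraction * reparable
    induction <- if (instant || t > params$irradiation_end_h) 0 else
      params$alpha * params$dose_rate(t)
    dF <- params$k_on_foci * N0 -
      params$k_off_foci * max(y[np + 2] - params$foci_floor, 0)
    list(c(induction - sum(V), V, dF))
  }
  times <- seq(0, t_end_h, by = dt_h)
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-9, atol = 1e-9)
  out <- as.data.frame(sol)
  names(out)[1] <- "t_h"
  names(out)[ncol(out)] <- "foci"
  out$repaired <- rowSums(out[, paste0("rep_", pw$name), drop = FALSE])
  class(out) <- c("repair_state", "data.frame")
  out
}

#' Scaled gamma-H2AX focus curve
#'
#' Foci are assumed to mark DSBs 1:1 at baseline; the curve returned is
#' the focus yield versus time, peak-normalised ("scaled") by default.
#'
#' @param state a [solve_repair()] result.
#' @param normalize divide by the peak value.
#' @return data frame `t_h`, `foci` (scaled when `normalize`).
#' @export
gamma_h2ax_curve <- function(state, normalize = TRUE) {
  f <- state$foci
  if (normalize && max(f) > 0) f <- f / max(f)
  data.frame(t_h = state$t_h, foci = f)
}

#' DSB induction per dose from a tally
#'
#' @param tally a `damage_tally`.
#' @param dose_Gy absorbed dose, Gy (> 0).
#' @param genome_gbp optional genome size in Gbp; when given, the yield is
#'   additionally normalised per Gbp.
#' @return induction in Gy^-1 per cell (or Gy^-1 Gbp^-1).
#' @export
alpha_from_tally <- function(tally, dose_Gy, genome_gbp = NULL) {
  if (dose_Gy <= 0) stop("dose must be > 0")
  n_dsb <- nrow(tally$dsb_positions)
  a <- n_dsb / dose_Gy
  if (!is.null(genome_gbp)) a <- a / genome_gbp
  a
}
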