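# Human ventricular myocyte electrophysiology: ten Tusscher-Panfilov 2006
# formulation with optional fibrotic ionic remodeling. The ODE right-hand
# side and integrators live in src/tt06.cpp; this file is the user surface.

.variants <- c("epicardial", "endocardial", "mid-myocardial")

.variant_code <- function(variant) {
  i <- match(variant, .variants)
  if (is.na(i))
    stop("unknown cell variant '", variant, "'; supported: ",
         paste(.variants, collapse = ", "), call. = FALSE)
  i - 1L
}

#' Maximal conductances and permeabilities of the ventricular cell model
#'
#' Returns the parameter set of the ten Tusscher-Panfilov 2006 human
#' ventricular myocyte model for one transmural variant. The variant
#' determines the transient-outward (`G_to`) and slow delayed-rectifier
#' (`G_Ks`) conductances and the kinetics of the `s` inactivation gate.
#'
#' @param variant cell variant: `"epicardial"` (default), `"endocardial"`
#'   or `"mid-myocardial"`.
#' @return an object of class `cell_params`: a named list of maximal
#'   conductances/permeabilities (nS/pF except where the model defines
#'   otherwise), the membrane capacitance per unit area `Cm` (uF/cm^2),
#'   and the variant tag.
#' @export
#' @examples
#' p <- cell_params()
#' p$G_Na
cell_params <- function(variant = "epicardial") {
  code <- .variant_code(variant)
  p <- list(
    G_Na  = 14.838,
    G_K1  = 5.405,
    G_to  = c(0.294, 0.073, 0.294)[code + 1L],
    G_Kr  = 0.153,
    G_Ks  = c(0.392, 0.392, 0.098)[code + 1L],
    G_CaL = 3.98e-5,
    k_NaCa = 1000,
    P_NaK = 2.724,
    G_pCa = 0.1238,
    G_pK  = 0.0146,
    G_bNa = 2.9e-4,
    G_bCa = 5.92e-4,
    Cm = 0.185,
    variant = variant,
    variant_code = code
  )
  structure(p, class = "cell_params")
}

.state_names <- c("Vm", "m", "h", "j", "xr1", "xr2", "xs", "r", "s",
                  "d", "f", "f2", "fCass", "Rbar", "Cai", "CaSS", "CaSR",
                  "Nai", "Ki")

#' Resting initial state of the ventricular cell model
#'
#' Published resting initial conditions of the ten Tusscher-Panfilov 2006
#' model (a fixed point of the unstimulated ODEs to well under 0.5 mV of
#' membrane-potential drift per second). Deterministic: repeated calls
#' return identical states.
#'
#' @inheritParams cell_params
#' @return named numeric vector of length 19 (class `cell_state`):
#'   membrane potential `Vm` (mV), 12 gating variables in `[0,1]`, the
#'   ryanodine-receptor adaptation variable `Rbar`, and intracellular ion
#'   concentrations (mM).
#' @export
init_cell_state <- function(variant = "epicardial") {
  .variant_code(variant)  # validates
  s <- c(Vm = -86.2, m = 0, h = 0.75, j = 0.75, xr1 = 0, xr2 = 1, xs = 0,
         r = 0, s = 1, d = 0, f = 1, f2 = 1, fCass = 1, Rbar = 1,
         Cai = 7e-5, CaSS = 7e-5, CaSR = 1.3, Nai = 7.67, Ki = 138.3)
  structure(s, class = c("cell_state", "numeric"))
}

.check_state <- function(state) {
  if (length(state) != 19L)
    stop("cell state must have 19 entries", call. = FALSE)
  if (any(!is.finite(state)))
    stop("non-finite entries in cell state", call. = FALSE)
  invisible(state)
}

#' Transmembrane currents and SR fluxes at a given state
#'
#' Evaluates every membrane current of the model plus the sarcoplasmic-
#' reticulum calcium fluxes. The reported total ionic current `I_ion` is
#' the sum of the twelve membrane currents by construction.
#'
#' @param state a `cell_state` vector (see [init_cell_state()]).
#' @param params a `cell_params` object.
#' @return named numeric vector: the twelve membrane currents (pA/pF), the
#'   SR fluxes `I_rel`, `I_up`, `I_leak`, `I_xfer` (mM/ms) and the total
#'   `I_ion` (pA/pF).
#' @export
ionic_currents <- function(state, params = cell_params()) {
  .check_state(state)
  .tt06_currents_cpp(as.numeric(state), unclass(params))
}

#' Advance a single cell by one (or more) time steps
#'
#' Rush-Larsen exponential update for the gating variables (a contraction
#' toward the voltage-dependent steady state, hence gates remain in
#' `[0,1]` for any valid `dt`) and forward-Euler update for the membrane
#' potential and ion concentrations.
#'
#' @inheritParams ionic_currents
#' @param dt time step, ms; must satisfy `0 < dt <= 0.05`.
#' @param i_stim external stimulus current density, pA/pF; negative values
#'   depolarize.
#' @param n_steps number of steps to take (default 1).
#' @return the advanced `cell_state`.
#' @export
step_cell <- function(state, params = cell_params(), dt = 0.02, i_stim = 0,
                      n_steps = 1L) {
  .check_state(state)
  if (!is.finite(dt) || dt <= 0 || dt > 0.05)
    stop("dt must be in (0, 0.05] ms, got ", dt, call. = FALSE)
  out <- .tt06_step_cpp(as.numeric(state), unclass(params), dt, i_stim,
                        as.integer(n_steps))
  if (!all(is.finite(out)) || out[1] < -105 || out[1] > 65)
    stop("cell state left invariant bounds (instability): Vm = ", out[1],
         call. = FALSE)
  names(out) <- .state_names
  structure(out, class = c("cell_state", "numeric"))
}

#' Fibrotic ionic remodeling factors
#'
#' Multipliers applied to remodeled (fibrotic-region) myocytes: 50%
#' reduction of the inward-rectifier current I_K1, 50% reduction of the
#' L-type calcium current I_CaL, 40% reduction of the fast sodium current
#' I_Na, and a 30% reduction of local tissue conductivity.
#'
#' @param scale_K1,scale_CaL,scale_Na dimensionless conductance
#'   multipliers in `(0, 1]`.
#' @param conductivity_factor dimensionless multiplier on the local
#'   diffusion coefficient at fibrotic nodes, in `(0, 1]`.
#' @return an object of class `fibrosis_remodeling`.
#' @export
fibrosis_remodeling <- function(scale_K1 = 0.5, scale_CaL = 0.5,
                                scale_Na = 0.6, conductivity_factor = 0.7) {
  v <- c(scale_K1 = scale_K1, scale_CaL = scale_CaL, scale_Na = scale_Na,
         conductivity_factor = conductivity_factor)
  if (any(!is.finite(v)) || any(v <= 0) || any(v > 1))
    stop("all remodeling factors must lie in (0, 1]", call. = FALSE)
  structure(as.list(v), class = "fibrosis_remodeling")
}

#' Apply fibrotic remodeling to a cell parameter set
#'
#' Scales `G_K1`, `G_CaL` and `G_Na` by the remodeling factors, leaving
#' all other parameters untouched. The input is not mutated.
#'
#' @param params a `cell_params` object.
#' @param remodeling a [fibrosis_remodeling()] object.
#' @return a new `cell_params` object.
#' @export
apply_fibrosis_remodeling <- function(params,
                                      remodeling = fibrosis_remodeling()) {
  stopifnot(inherits(remodeling, "fibrosis_remodeling"))
  out <- params
  out$G_K1  <- params$G_K1  * remodeling$scale_K1
  out$G_CaL <- params$G_CaL * remodeling$scale_CaL
  out$G_Na  <- params$G_Na  * remodeling$scale_Na
  out
}

#' Pace a single cell and summarise the last beat
#'
#' Applies periodic stimuli (default -52 pA/pF for 1 ms, a twice-threshold
#' convention) at a fixed cycle length and records membrane potential and
#' cytosolic calcium.
#'
#' @param params a `cell_params` object.
#' @param cycle_length pacing cycle length, ms.
#' @param n_beats number of beats (>= 1).
#' @param dt integration step, ms.
#' @param stim_amplitude stimulus current, pA/pF (negative depolarizes).
#' @param stim_duration stimulus duration, ms.
#' @param sample_interval_ms recording cadence, ms.
#' @return an object of class `paced_trace`: full `time_ms`, `vm`, `cai`
#'   traces, the last-beat slice, and summary scalars `apd90_ms`,
#'   `dvdt_max` (mV/ms) and `ca_amplitude` (mM) computed on the last beat.
#' @export
pace_single_cell <- function(params = cell_params(), cycle_length = 600,
                             n_beats = 10L, dt = 0.02,
                             stim_amplitude = -52, stim_duration = 1,
                             sample_interval_ms = 0.1) {
  if (cycle_length <= 0) stop("cycle_length must be > 0", call. = FALSE)
  if (n_beats < 1) stop("n_beats must be >= 1", call. = FALSE)
  if (dt <= 0 || dt > 0.05) stop("dt must be in (0, 0.05] ms", call. = FALSE)
  st <- init_cell_state(params$variant)
  tr <- .tt06_pace_cpp(as.numeric(st), unclass(params), cycle_length,
                       as.integer(n_beats), dt, stim_amplitude,
                       stim_duration, sample_interval_ms)
  t0 <- (n_beats - 1) * cycle_length
  sel <- tr$time_ms >= t0
  tl <- tr$time_ms[sel] - t0
  vl <- tr$vm[sel]
  cl <- tr$cai[sel]

  dvdt <- diff(vl) / diff(tl)
  dvdt_max <- max(dvdt)
  i_act <- which.max(dvdt)
  t_act <- tl[i_act]
  rest <- vl[1]
  i_peak <- which.max(vl)
  peak <- vl[i_peak]
  v90 <- peak - 0.9 * (peak - rest)
  after <- which(seq_along(vl) > i_peak & vl <= v90)
  apd90 <- if (length(after)) tl[after[1]] - t_act else NA_real_

  structure(list(
    time_ms = tr$time_ms, vm = tr$vm, cai = tr$cai,
    last_beat = list(time_ms = tl, vm = vl, cai = cl),
    apd90_ms = apd90, dvdt_max = dvdt_max,
    ca_amplitude = max(cl) - min(cl),
    peak_vm = peak, resting_vm = rest,
    cycle_length = cycle_length, n_beats = n_beats, dt = dt,
    sample_interval_ms = sample_interval_ms,
    params = params), class = "paced_trace")
}

#' @export
print.paced_trace <- function(x, ...) {
  cat("Paced single-cell trace (", x$params$variant, ")\n", sep = "")
  cat(sprintf("  %d beats at CL %g ms, dt %g ms\n", x$n_beats,
              x$cycle_length, x$dt))
  cat(sprintf("  last beat: APD90 = %.1f ms, dV/dt_max = %.1f mV/ms, ",
              x$apd90_ms, x$dvdt_max))
  cat(sprintf("Ca amplitude = %.4g mM\n", x$ca_amplitude))
  invisible(x)
}
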