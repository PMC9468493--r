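# Li-Rinzel / Nadkarni-Jung kinetics: cytosolic calcium (c_cs, uM), the
# IP3-receptor recovery variable (q, dimensionless in [0,1]) and IP3 (p, uM)
# exchange calcium between cytosol and ER through the IP3 receptor, SERCA,
# and a ligand-independent leak.

# Flat layout shared with the compiled stepping kernel.
.lr_par_order <- c("vs", "C0", "v2", "ks", "a2", "d1", "d2", "d5",
                   "v1", "c1", "tau", "p0", "vp", "kp")

# Parameters free (inferred) in the Bayesian inversion: the extensive rate
# constants of the calcium fluxes and of IP3 production/degradation.
.lr_free_default <- c("vs", "v1", "v2", "tau", "vp", "ks")

#' Kinetic parameters of the intracellular calcium model
#'
#' Constructs the parameter set of the Li-Rinzel-type astrocyte calcium
#' model. Defaults are the previously validated literature values used as
#' prior means in the Bayesian inversion.
#'
#' @param vs Maximal SERCA pump rate, uM/s.
#' @param C0 Total free calcium concentration in the cell, uM.
#' @param v2 ER leak rate constant, 1/s.
#' @param ks SERCA half-activation constant, uM.
#' @param a2 IP3-receptor inactivation rate coefficient, 1/(uM s).
#' @param d1,d2,d5 IP3-receptor dissociation constants, uM.
#' @param v1 Maximal IP3-receptor channel rate, 1/s.
#' @param c1 ER-to-cytosol volume ratio (dimensionless, in (0, 1)).
#' @param tau IP3 lifetime, s.
#' @param p0 Baseline IP3 concentration, uM.
#' @param vp Maximal IP3 production rate, uM/s.
#' @param kp IP3 production half-activation constant, uM.
#' @param free Character vector naming the parameters treated as free in
#'   the model inversion. Defaults to the extensive rate constants
#'   \code{c("vs", "v1", "v2", "tau", "vp", "ks")}.
#'
#' @return A named numeric vector of class \code{"kinetic_params"} with a
#'   \code{"free"} attribute.
#' @examples
#' p <- kinetic_params()
#' er_calcium(0.1, p)
#' @export
kinetic_params <- function(vs = 0.9, C0 = 2, v2 = 0.11, ks = 0.1, a2 = 0.2,
                           d1 = 0.13, d2 = 1.049, d5 = 0.08234, v1 = 6,
                           c1 = 0.185, tau = 7.14, p0 = 0.16, vp = 0.13,
                           kp = 1.1, free = .lr_free_default) {
  p <- c(vs = vs, C0 = C0, v2 = v2, ks = ks, a2 = a2, d1 = d1, d2 = d2,
         d5 = d5, v1 = v1, c1 = c1, tau = tau, p0 = p0, vp = vp, kp = kp)
  if (any(!is.finite(p)) || any(p <= 0))
    stop("all kinetic parameters must be finite and strictly positive")
  if (p[["c1"]] >= 1)
    stop("c1 (ER/cytosol volume ratio) must lie in (0, 1)")
  free <- match.arg(free, names(p), several.ok = TRUE)
  structure(p, free = free, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Li-Rinzel kinetic parameters (free in inversion: ",
      paste(attr(x, "free"), collapse = ", "), ")\n", sep = "")
  print(unclass(x))
  invisible(x)
}

.lr_flat <- function(params) unname(unclass(params)[.lr_par_order])

#' Hidden kinetic state
#'
#' The state triple evolved by the kinetic model: cytosolic calcium,
#' IP3-receptor recovery variable, and IP3 concentration.
#'
#' @param c_cs Cytosolic calcium concentration, uM (non-negative).
#' @param q IP3-receptor recovery variable, dimensionless in \[0, 1\].
#' @param p IP3 concentration, uM (non-negative).
#' @return Named numeric vector of class \code{"kinetic_state"}.
#' @export
kinetic_state <- function(c_cs, q, p) {
  s <- c(c_cs = c_cs, q = q, p = p)
  if (any(!is.finite(s))) stop("kinetic state must be finite")
  if (c_cs < 0 || p < 0) stop("c_cs and p must be non-negative")
  if (q < 0 || q > 1) stop("q must lie in [0, 1]")
  structure(s, class = "kinetic_state")
}

.as_state <- function(x) {
  if (inherits(x, "kinetic_state")) return(unname(unclass(x)))
  x <- unname(as.numeric(x))
  if (length(x) != 3L) stop("a kinetic state has exactly 3 components")
  x
}

#' ER calcium from the conservation relationship
#'
#' Total cell calcium is conserved, so the ER concentration is determined
#' by the cytosolic one: \code{C_ER = (C0 * (1 + c1) - C_CS) / c1}.
#'
#' @param c_cs Cytosolic calcium, uM; must not exceed \code{C0 * (1 + c1)}.
#' @param params A [kinetic_params()] object.
#' @return ER calcium concentration, uM (vectorised over \code{c_cs}).
#' @export
er_calcium <- function(c_cs, params = kinetic_params()) {
  cmax <- params[["C0"]] * (1 + params[["c1"]])
  if (any(c_cs < 0) || any(c_cs > cmax * (1 + 1e-9)))
    stop("c_cs outside [0, C0*(1+c1)]: ER calcium would be negative")
  (cmax - c_cs) / params[["c1"]]
}

#' Calcium fluxes between ER and cytosol
#'
#' IP3-receptor channel flux (\code{j_c}), SERCA pump flux (\code{j_s}),
#' and ligand-independent ER leak (\code{j_l}), all in uM/s.
#'
#' @param state A [kinetic_state()] (or numeric triple c_cs, q, p).
#' @param params A [kinetic_params()] object.
#' @return List with components \code{j_c}, \code{j_s}, \code{j_l}.
#' @export
compute_fluxes <- function(state, params = kinetic_params()) {
  s <- .as_state(state)
  c_cs <- s[1]; q <- s[2]; p <- s[3]
  cer <- er_calcium(c_cs, params)
  j_c <- params[["v1"]] * (p / (p + params[["d1"]]))^3 *
    (c_cs / (c_cs + params[["d5"]]))^3 * q^3 * (cer - c_cs)
  j_s <- params[["vs"]] * c_cs^2 / (c_cs^2 + params[["ks"]]^2)
  j_l <- params[["v2"]] * (cer - c_cs)
  list(j_c = j_c, j_s = j_s, j_l = j_l)
}

#' Time derivative of the kinetic state
#'
#' Right-hand side of the kinetic ODEs: the calcium balance
#' \code{j_c - j_s + j_l}, the receptor recovery kinetics, and
#' calcium-dependent IP3 production with first-order decay.
#'
#' @inheritParams compute_fluxes
#' @return Numeric triple \code{(dc_cs/dt, dq/dt, dp/dt)} in
#'   (uM/s, 1/s, uM/s).
#' @export
state_derivative <- function(state, params = kinetic_params()) {
  s <- .as_state(state)
  # guard the conservation domain before handing off to the kernel
  er_calcium(s[1], params)
  d <- lr_deriv_cpp(s, .lr_flat(params))
  names(d) <- c("c_cs", "q", "p")
  d
}

.check_grid <- function(frame_dt, micro_dt) {
  if (micro_dt <= 0) stop("micro_dt must be positive")
  if (frame_dt < 0) stop("frame_dt must be non-negative")
  if (frame_dt == 0) return(0L)
  nsub <- frame_dt / micro_dt
  if (abs(nsub - round(nsub)) > 1e-8)
    stop("frame_dt must be an integer multiple of micro_dt")
  as.integer(round(nsub))
}

#' Advance the kinetic state by one acquisition frame
#'
#' Integrates the deterministic dynamics over one frame interval using
#' explicit Euler sub-steps on the microtime grid (default: ten 0.1 s
#' sub-steps per 1 s frame). After each sub-step the state is safeguarded
#' into its physical domain (c_cs within the conservation bounds, q in
#' \[0, 1\], p positive); the number of safeguard activations is returned
#' in the \code{"clamps"} attribute.
#'
#' @param state A [kinetic_state()] (or numeric triple).
#' @param params A [kinetic_params()] object.
#' @param frame_dt Frame interval, s; must be an integer multiple of
#'   \code{micro_dt}. \code{frame_dt = 0} returns the input unchanged.
#' @param micro_dt Integration sub-step, s.
#' @return The advanced state (numeric triple, class
#'   \code{"kinetic_state"}) with attribute \code{"clamps"}.
#' @export
evolve_step <- function(state, params = kinetic_params(), frame_dt = 1,
                        micro_dt = 0.1) {
  s <- .as_state(state)
  .check_grid(frame_dt, micro_dt)
  res <- lr_evolve_cpp(s, .lr_flat(params), frame_dt, micro_dt)
  out <- res$state
  if (any(!is.finite(out))) stop("state became non-finite during integration")
  names(out) <- c("c_cs", "q", "p")
  structure(out, clamps = res$clamps, class = "kinetic_state")
}

#' Simulate the kinetic model on the acquisition grid
#'
#' Repeated [evolve_step()] over \code{t = 0, frame_dt, 2*frame_dt, ...,
#' duration}; the first row is the initial state.
#'
#' @param state0 Initial [kinetic_state()].
#' @param params A [kinetic_params()] object.
#' @param duration Total simulated time, s (> 0).
#' @param frame_dt Frame interval, s.
#' @param micro_dt Integration sub-step, s.
#' @return A data frame with columns \code{time}, \code{c_cs}, \code{q},
#'   \code{p} and attribute \code{"clamps"} (total safeguard count).
#' @examples
#' traj <- simulate_kinetics(kinetic_state(0.1, 0.5, 0.5), duration = 30)
#' range(traj$c_cs)
#' @export
simulate_kinetics <- function(state0, params = kinetic_params(), duration,
                              frame_dt = 1, micro_dt = 0.1) {
  if (duration <= 0) stop("duration must be positive")
  s0 <- .as_state(state0)
  .check_grid(frame_dt, micro_dt)
  n_frames <- as.integer(floor(duration / frame_dt + 1e-9)) + 1L
  res <- lr_simulate_cpp(s0, .lr_flat(params), n_frames, frame_dt, micro_dt)
  st <- res$states
  if (any(!is.finite(st))) stop("state became non-finite during integration")
  out <- data.frame(time = (seq_len(n_frames) - 1) * frame_dt,
                    c_cs = st[, 1], q = st[, 2], p = st[, 3])
  attr(out, "clamps") <- res$clamps
  out
}
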