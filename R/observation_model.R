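# Saturating indicator observation model: GCaMP-type calcium indicators
# bind calcium with a hyperbolic (one-site) saturation curve, so recorded
# fluorescence is an affine function of the bound fraction.

#' Observation-model parameters
#'
#' Parameters of the saturating fluorescence observation function
#' \code{g(c) = kappa_f * c / (c + k_d) + d_f}. \code{kappa_f} and
#' \code{d_f} are the per-recording gain and background; \code{k_d} is the
#' indicator dissociation constant, fixed at 0.167 uM (167 nM) for GCaMP6m.
#'
#' @param kappa_f Fluorescence scale (gain), arbitrary fluorescence units;
#'   strictly positive.
#' @param d_f Fluorescence offset (background), arbitrary units.
#' @param k_d Indicator dissociation constant, uM; strictly positive.
#' @return Named list of class \code{"observation_params"}.
#' @examples
#' obs <- observation_params(kappa_f = 2, d_f = 1)
#' observe(obs$k_d, obs)  # half-saturation: kappa_f/2 + d_f
#' @export
observation_params <- function(kappa_f = 1, d_f = 0, k_d = 0.167) {
  if (!is.finite(k_d) || k_d <= 0) stop("k_d must be finite and positive")
  if (!is.finite(kappa_f) || kappa_f <= 0)
    stop("kappa_f must be finite and positive")
  if (!is.finite(d_f)) stop("d_f must be finite")
  structure(list(kappa_f = kappa_f, d_f = d_f, k_d = k_d),
            class = "observation_params")
}

#' Map cytosolic calcium to indicator fluorescence
#'
#' @param c_cs Cytosolic calcium concentration(s), uM; non-negative.
#' @param obs An [observation_params()] object.
#' @return Fluorescence in arbitrary units; strictly increasing in
#'   \code{c_cs}, ranging from \code{d_f} (at 0) towards the plateau
#'   \code{kappa_f + d_f}.
#' @export
observe <- function(c_cs, obs = observation_params()) {
  if (any(!is.finite(c_cs)) || any(c_cs < 0))
    stop("c_cs must be finite and non-negative")
  obs$kappa_f * c_cs / (c_cs + obs$k_d) + obs$d_f
}

#' Predict a fluorescence trace from a calcium time course
#'
#' Elementwise application of [observe()]; fluorescence is treated as an
#' instantaneous function of calcium (no indicator decay term).
#'
#' @param c_cs_series Numeric vector of cytosolic calcium values, uM.
#' @param obs An [observation_params()] object.
#' @return Fluorescence vector of the same length.
#' @export
predict_trace <- function(c_cs_series, obs = observation_params()) {
  if (length(c_cs_series) == 0L) return(numeric(0))
  observe(c_cs_series, obs)
}

#' Invert the observation function
#'
#' Recovers calcium from fluorescence strictly inside the observable range
#' \code{(d_f, kappa_f + d_f)}.
#'
#' @param y Fluorescence value(s), arbitrary units.
#' @param obs An [observation_params()] object.
#' @return Cytosolic calcium, uM.
#' @export
invert_observation <- function(y, obs = observation_params()) {
  if (any(y <= obs$d_f) || any(y >= obs$kappa_f + obs$d_f))
    stop("fluorescence outside the open observable range")
  obs$k_d * (y - obs$d_f) / (obs$kappa_f + obs$d_f - y)
}
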