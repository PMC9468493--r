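# Priors for the model inversion. Initial states carry dimensional Gaussian
# priors; the free kinetic parameters are inferred on a log scale: the
# physical value is prior_mean * exp(xi), with xi Gaussian with mean 0 and
# the stated dimensionless variance. This enforces positivity.

#' Default priors for the model inversion
#'
#' Gaussian priors on the initial hidden state (identity scale) and on the
#' six free kinetic parameters (exponential transform: the inversion
#' parameter is the dimensionless exponent, prior mean 0, variance 2; the
#' physical prior mean equals the parameter's literature value).
#'
#' @return A data frame of class \code{"prior_spec"} with columns
#'   \code{name}, \code{mean} (physical units), \code{variance},
#'   \code{transform} (\code{"identity"} or \code{"exp"}; for \code{"exp"}
#'   the variance applies to the exponent), and \code{block}
#'   (\code{"state0"} or \code{"kinetic"}).
#' @examples
#' default_priors()
#' @export
default_priors <- function() {
  spec <- data.frame(
    name = c("c_cs0", "q0", "p0",
             "vs", "v1", "v2", "tau", "vp", "ks"),
    mean = c(0.1, 0.5, 0.5,
             0.9, 6, 0.11, 7.14, 0.13, 0.1),
    variance = c(0.05, 0.2, 0.2,
                 2, 2, 2, 2, 2, 2),
    transform = c(rep("identity", 3), rep("exp", 6)),
    block = c(rep("state0", 3), rep("kinetic", 6)),
    stringsAsFactors = FALSE
  )
  class(spec) <- c("prior_spec", "data.frame")
  spec
}

#' Map an inversion-scale parameter to its physical value
#'
#' For exponentially transformed parameters the inversion works with a
#' dimensionless exponent \code{xi}; the physical value is
#' \code{prior_mean * exp(xi)}.
#'
#' @param xi Exponent(s) on the inversion scale (dimensionless).
#' @param prior_mean Physical prior mean (strictly positive).
#' @return Physical parameter value(s); strictly positive.
#' @examples
#' to_physical(log(2), 0.11)  # doubled ER leak rate
#' @export
to_physical <- function(xi, prior_mean) {
  if (any(!is.finite(xi))) stop("xi must be finite")
  if (any(prior_mean <= 0)) stop("prior_mean must be positive")
  prior_mean * exp(xi)
}

.check_priors <- function(priors) {
  need <- c("name", "mean", "variance", "transform", "block")
  if (!all(need %in% names(priors))) stop("malformed prior specification")
  if (any(priors$variance <= 0)) stop("prior variances must be positive")
  ref <- default_priors()
  if (!all(ref$name %in% priors$name))
    stop("priors must cover the initial state and all six free parameters")
  invisible(priors)
}
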