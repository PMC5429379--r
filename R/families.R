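#' Covariance parameterisations for parsimonious Gaussian mixtures
#'
#' Each mixture component covariance is factored as
#' \deqn{\Sigma_g = \lambda_g D_g A_g D_g^T,}{Sigma_g = lambda_g D_g A_g D_g',}
#' where \eqn{\lambda_g} is the volume, \eqn{A_g} a diagonal shape matrix with
#' \eqn{\det(A_g) = 1}, and \eqn{D_g} an orthogonal orientation matrix. A
#' family name such as \code{"VEV"} states, position by position, whether
#' volume, shape and orientation are Equal across components, Varying, or
#' (for shape/orientation) constrained to the Identity -- spherical shape or
#' axis-aligned orientation. The ten families below are the complete set for
#' three-dimensional data.
#'
#' @return A data frame with one row per family and columns \code{name},
#'   \code{volume}, \code{shape} and \code{orientation}.
#' @examples
#' gmm_families()
#' @export
gmm_families <- function() {
  data.frame(
    name = c("EII", "VII", "EEI", "VEI", "EVI",
             "VVI", "EEE", "EEV", "VEV", "VVV"),
    volume = c("equal", "varying", "equal", "varying", "equal",
               "varying", "equal", "equal", "varying", "varying"),
    shape = c("spherical", "spherical", "equal", "equal", "varying",
              "varying", "equal", "equal", "equal", "varying"),
    orientation = c("axis-aligned", "axis-aligned", "axis-aligned",
                    "axis-aligned", "axis-aligned", "axis-aligned",
                    "equal", "varying", "varying", "varying"),
    stringsAsFactors = FALSE
  )
}

#' Free-parameter count of a Gaussian mixture family
#'
#' Counts parameters from the volume/shape/orientation decomposition:
#' \code{d*k} means, \code{k - 1} mixing weights, 1 or \code{k} volumes,
#' 0 / \code{d - 1} / \code{k*(d - 1)} shape parameters (spherical / equal /
#' varying) and 0 / \code{d*(d-1)/2} / \code{k*d*(d-1)/2} orientation
#' parameters (axis-aligned / equal / varying).
#'
#' @param family One of the ten family names, e.g. \code{"VEV"}.
#' @param k Number of mixture components.
#' @param d Data dimension (default 3, the pleasure--arousal--dominance
#'   space).
#' @return Integer parameter count.
#' @examples
#' gmm_nparams("VVV", k = 1) # 9
#' gmm_nparams("VEV", k = 5) # 41
#' @export
gmm_nparams <- function(family, k, d = 3) {
  fam <- .family_row(family)
  stopifnot(k >= 1, d >= 1)
  n_mean <- d * k
  n_weight <- k - 1
  n_volume <- if (fam$volume == "equal") 1L else k
  n_shape <- switch(fam$shape,
    spherical = 0L,
    equal = d - 1L,
    varying = k * (d - 1L)
  )
  n_orient <- switch(fam$orientation,
    `axis-aligned` = 0L,
    equal = d * (d - 1L) / 2L,
    varying = k * d * (d - 1L) / 2L
  )
  as.integer(n_mean + n_weight + n_volume + n_shape + n_orient)
}

.family_row <- function(family) {
  fams <- gmm_families()
  i <- match(family, fams$name)
  if (is.na(i)) {
    stop("unknown covariance family: ", family, call. = FALSE)
  }
  fams[i, ]
}
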