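#' Polar grid of radial-basis neurons for egocentric coding
#'
#' The "where" stream is modeled as a population of polar neurons, each tuned
#' to one egocentric coordinate (radial distance, bearing) of a landmark
#' relative to the agent. The default network has 36 azimuth divisions (10
#' degree resolution) times 10 radial divisions = 360 neurons. A neuron's
#' activation for a target at `(r, theta)` is the product of two Gaussians in
#' the squared radial and (circularly wrapped) angular differences, with
#' variances `sigma_r_sq` and `sigma_theta_sq` used directly in the exponent
#' denominators.
#'
#' @param n_azimuth number of azimuth divisions (default 36).
#' @param n_radial number of radial divisions (default 10).
#' @param r_max maximum encoded radius in map units (default 10).
#' @param sigma_r_sq radial variance, map units squared (default 0.06).
#' @param sigma_theta_sq angular variance, radians squared (default 0.002).
#' @return An object of class `polar_grid` with per-neuron centers
#'   `(r, theta)` stored in `$centers`.
#' @export
polar_grid <- function(n_azimuth = 36, n_radial = 10, r_max = 10,
                       sigma_r_sq = 0.06, sigma_theta_sq = 0.002) {
  stopifnot(n_azimuth >= 1, n_radial >= 1, r_max > 0,
            sigma_r_sq > 0, sigma_theta_sq > 0)
  theta_c <- 2 * pi * (seq_len(n_azimuth) - 1) / n_azimuth   # [0, 2pi)
  r_c <- r_max * seq_len(n_radial) / n_radial                # (0, r_max]
  centers <- expand.grid(r = r_c, theta = theta_c, KEEP.OUT.ATTRS = FALSE)
  structure(
    list(n_azimuth = n_azimuth, n_radial = n_radial, r_max = r_max,
         sigma_r_sq = sigma_r_sq, sigma_theta_sq = sigma_theta_sq,
         centers = centers),
    class = "polar_grid"
  )
}

# circular difference wrapped to [-pi, pi]
wrap_angle <- function(a) {
  ((a + pi) %% (2 * pi)) - pi
}

#' Encode an egocentric target as a population activation field
#'
#' @param grid a [polar_grid()].
#' @param r radial distance of the target, `0 <= r <= r_max`.
#' @param theta bearing of the target in radians.
#' @return Numeric vector of per-neuron activations in `[0, 1]`, one per
#'   neuron, with the grid attached as an attribute.
#' @examples
#' g <- polar_grid()
#' f <- encode_egocentric(g, r = 5, theta = pi / 4)
#' decode_position(g, f)
#' @export
encode_egocentric <- function(grid, r, theta) {
  stopifnot(inherits(grid, "polar_grid"))
  if (!is.finite(r) || r < 0 || r > grid$r_max) {
    stop("target radius ", r, " outside encodable range [0, ", grid$r_max, "]")
  }
  dth <- wrap_angle(grid$centers$theta - theta)
  dr <- grid$centers$r - r
  act <- exp(-dth^2 / grid$sigma_theta_sq) * exp(-dr^2 / grid$sigma_r_sq)
  structure(act, grid = grid, class = "activation_field")
}

#' Decode the perceived egocentric coordinates from an activation field
#'
#' Activation-weighted average of the neuron centers; the angular mean is
#' computed circularly (vector averaging), so decoding is seam-safe at
#' 0 / 2pi. For targets within half a radial bin of the covered radial band
#' the round-trip error is at most half a grid bin in each coordinate.
#'
#' @param grid a [polar_grid()].
#' @param field activation vector from [encode_egocentric()] (or any
#'   non-negative per-neuron weights).
#' @return Named numeric vector `c(r =, theta =)` with `theta` in `[0, 2pi)`.
#' @export
decode_position <- function(grid, field) {
  stopifnot(inherits(grid, "polar_grid"))
  w <- as.numeric(field)
  if (length(w) != nrow(grid$centers)) {
    stop("activation field length ", length(w), " does not match the grid (",
         nrow(grid$centers), " neurons)")
  }
  if (any(w < 0)) stop("activations must be non-negative")
  s <- sum(w)
  if (s == 0) stop("no active neurons: all-zero activation field")
  r_hat <- sum(w * grid$centers$r) / s
  theta_hat <- atan2(sum(w * sin(grid$centers$theta)),
                     sum(w * cos(grid$centers$theta))) %% (2 * pi)
  c(r = r_hat, theta = theta_hat)
}
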