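# The three encoding models mapping a mixture onto a (noisy) percept.

#' Three-category response of the sum-threshold model
#'
#' The simplest encoder: a microbe-like responder sums the +/-1 values of
#' the mixture components and emits one of three percepts. Sums above +2
#' read "yum", below -2 "yuck", and anything from -2 to +2 (inclusive)
#' "meh". The response is deterministic; discrimination of two mixtures
#' reduces to comparing categories.
#'
#' @param mixture_sum Integer sum(s) of the +/-1 component values
#'   (vectorized).
#' @return Character vector of `"yum"`, `"meh"`, `"yuck"`.
#' @examples
#' microbe_category(c(-4, 0, 2, 4))
#' @export
microbe_category <- function(mixture_sum) {
  stopifnot(is.numeric(mixture_sum))
  ifelse(mixture_sum > 2, "yum", ifelse(mixture_sum < -2, "yuck", "meh"))
}

#' Linear color mixing
#'
#' The noiseless percept of a light mixture is the coordinate-wise sum of
#' its component RGB vectors (no renormalization): cone excitations add.
#'
#' @param components Matrix with one component vector per row (3
#'   columns), or a single length-3 vector.
#' @return Numeric length-3 mixture vector.
#' @export
color_mixture_vector <- function(components) {
  if (is.null(dim(components))) components <- matrix(components, nrow = 1)
  if (nrow(components) == 0L) {
    .odorspace_error("empty mixture", "odorspace_invalid_mixture")
  }
  stopifnot(ncol(components) == 3)
  colSums(components)
}

#' Ring-code mixture angle
#'
#' Maps a mixture of unit vectors on the circle to the angle of their
#' vector sum; normalizing to unit length discards intensity, emulating
#' the removal of intensity cues in the discrimination task.
#'
#' @param components Numeric vector of component angles in radians.
#' @param tol Degenerate-mixture threshold on the sum-vector norm.
#' @return Angle in `[0, 2*pi)`.
#' @export
ring_mixture_angle <- function(components, tol = 1e-12) {
  if (length(components) == 0L) {
    .odorspace_error("empty mixture", "odorspace_invalid_mixture")
  }
  sx <- sum(cos(components)); sy <- sum(sin(components))
  if (sqrt(sx^2 + sy^2) <= tol) {
    .odorspace_error("degenerate ring mixture: sum vector has near-zero norm",
                     "odorspace_degenerate_mixture")
  }
  atan2(sy, sx) %% (2 * pi)
}

#' Perceptual noise
#'
#' `perturb_ring()` adds zero-mean Gaussian noise to an angle (result
#' reduced mod 2*pi); `perturb_color()` adds independent zero-mean
#' Gaussian noise to each RGB coordinate, with no clipping to the unit
#' cube (the decision rule uses distances only).
#'
#' @param angle Numeric vector of angles in radians.
#' @param sigma_ring,sigma_rgb Noise standard deviation.
#' @return Noisy angle(s) / vector(s), same shape as the input.
#' @export
perturb_ring <- function(angle, sigma_ring) {
  stopifnot(sigma_ring >= 0)
  (angle + stats::rnorm(length(angle), 0, sigma_ring)) %% (2 * pi)
}

#' @rdname perturb_ring
#' @param vector Length-3 RGB vector or matrix with one vector per row.
#' @export
perturb_color <- function(vector, sigma_rgb) {
  stopifnot(sigma_rgb >= 0)
  vector + stats::rnorm(length(vector), 0, sigma_rgb)
}

#' Perceptual noise configuration
#'
#' Bundles the per-model noise parameters: the angular noise SD of the
#' ring code (default 0.4 rad), the RGB coordinate noise SD (calibrated
#' from the just-noticeable difference if not supplied), and the JND
#' itself (default 0.01 in the unit cube). The sum-threshold model is
#' noiseless.
#'
#' @param sigma_ring Ring angular noise SD in radians.
#' @param sigma_rgb RGB coordinate noise SD; if `NULL`, calibrated by
#'   [calibrate_color_noise()] when first needed.
#' @param jnd Just-noticeable Euclidean separation in the RGB cube.
#' @return A `noise_config` object.
#' @export
noise_config <- function(sigma_ring = 0.4, sigma_rgb = NULL, jnd = 0.01) {
  stopifnot(sigma_ring > 0, jnd > 0, is.null(sigma_rgb) || sigma_rgb > 0)
  structure(list(sigma_ring = sigma_ring, sigma_rgb = sigma_rgb, jnd = jnd),
            class = "noise_config")
}

#' @export
print.noise_config <- function(x, ...) {
  cat("<noise_config> sigma_ring =", x$sigma_ring, "rad; jnd =", x$jnd,
      "; sigma_rgb =", if (is.null(x$sigma_rgb)) "(uncalibrated)" else x$sigma_rgb, "\n")
  invisible(x)
}

.ensure_sigma_rgb <- function(noise) {
  if (is.null(noise$sigma_rgb)) {
    noise$sigma_rgb <- calibrate_color_noise(jnd = noise$jnd)
  }
  noise
}

# Vectorized single-trial odd-man-out on 3-D Gaussian percepts:
# duplicates at v (n x 3), single at w (n x 3), noise sd sigma.
# Returns logical vector: closest pair is the duplicate pair.
.omo_color_correct <- function(v, w, sigma, Z = NULL) {
  n <- nrow(v)
  if (is.null(Z)) Z <- matrix(stats::rnorm(9 * n), nrow = n)
  A <- v + sigma * Z[, 1:3, drop = FALSE]
  B <- v + sigma * Z[, 4:6, drop = FALSE]
  S <- w + sigma * Z[, 7:9, drop = FALSE]
  dab <- rowSums((A - B)^2)
  das <- rowSums((A - S)^2)
  dbs <- rowSums((B - S)^2)
  .break_ties(dab, das, dbs)
}

# Circular analogue: duplicates at angle a, single at angle b.
.omo_ring_correct <- function(a, b, sigma, Z = NULL) {
  n <- length(a)
  if (is.null(Z)) Z <- matrix(stats::rnorm(3 * n), nrow = n)
  A <- a + sigma * Z[, 1]
  B <- a + sigma * Z[, 2]
  S <- b + sigma * Z[, 3]
  dab <- .circ_dist(A, B)
  das <- .circ_dist(A, S)
  dbs <- .circ_dist(B, S)
  .break_ties(dab, das, dbs)
}

.circ_dist <- function(x, y) {
  d <- abs(x - y) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

.break_ties <- function(dab, das, dbs) {
  # correct iff the duplicate pair is strictly closest; exact ties
  # (measure-zero under continuous noise) resolved uniformly at random
  correct <- dab < das & dab < dbs
  tie <- (dab == das & dab <= dbs) | (dab == dbs & dab <= das)
  if (any(tie)) {
    k <- sum(tie)
    three_way <- tie & (das == dbs & dab == das)
    correct[tie] <- stats::runif(k) < ifelse(three_way[tie], 1 / 3, 1 / 2)
  }
  correct
}

#' Calibrate RGB noise to the just-noticeable difference
#'
#' Finds the coordinate noise SD at which two stimuli separated by a
#' Euclidean distance of `jnd` are "just discriminable". Under the
#' default protocol that means single-trial odd-man-out probability
#' correct 0.5 (chance is 1/3); the alternative `"majority26"` protocol
#' instead targets the single-trial accuracy at which a 14-of-26
#' majority is reached half the time. The root is found by bisection on
#' sigma with common random numbers, Monte-Carlo `n_mc` trials per
#' evaluation.
#'
#' @param jnd Just-noticeable Euclidean separation (default 0.01).
#' @param protocol `"single_trial"` (default) or `"majority26"`.
#' @param n_mc Monte-Carlo trials per bisection evaluation (>= 1e5).
#' @param tol Required closeness of the achieved probability to target.
#' @return Calibrated `sigma_rgb`, with attributes `p_achieved`, `n_mc`,
#'   and `target`.
#' @export
calibrate_color_noise <- function(jnd = 0.01, protocol = c("single_trial", "majority26"),
                                  n_mc = 1e5, tol = 0.005) {
  stopifnot(jnd > 0, n_mc >= 1e4)
  protocol <- match.arg(protocol)
  target <- switch(protocol,
    single_trial = 0.5,
    majority26 = {
      # single-trial p at which P(Binom(26, p) >= 14) = 0.5
      stats::uniroot(function(p) stats::pbinom(13, 26, p, lower.tail = FALSE) - 0.5,
                     c(1 / 3, 1))$root
    })
  Z <- matrix(stats::rnorm(9 * n_mc), nrow = n_mc)
  v <- matrix(0, n_mc, 3)
  w <- cbind(rep(jnd, n_mc), 0, 0)
  p_at <- function(sigma) mean(.omo_color_correct(v, w, sigma, Z = Z))
  lo <- jnd / 100; hi <- jnd * 10
  if (p_at(hi) > target || p_at(lo) < target) {
    .odorspace_error("calibration bracket failure", "odorspace_calibration_error")
  }
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (p_at(mid) > target) lo <- mid else hi <- mid
  }
  sigma <- (lo + hi) / 2
  p_hat <- p_at(sigma)
  if (abs(p_hat - target) > tol) {
    .odorspace_error(sprintf(
      "calibration did not converge: p = %.4f at sigma = %.3g (target %.4f, n_mc = %g)",
      p_hat, sigma, target, n_mc), "odorspace_calibration_error")
  }
  structure(sigma, p_achieved = p_hat, n_mc = n_mc, target = target)
}
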