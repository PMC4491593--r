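# Sphere-packing counts, coloring lower bounds, grid and ring
# capacities — the combinatorial half of the critique, in exact integer
# arithmetic.

#' Hamming-ball volume in mixture space
#'
#' Number of N-subsets of C primaries within replacement distance R of a
#' fixed N-subset: `sum_{r=0}^{R} C(N, r) * C(C - N, r)` (choose r
#' components to remove and r outside components to add).
#'
#' @param C Total primaries.
#' @param N Mixture size.
#' @param R Replacement radius.
#' @return Exact [bigint][as_bigint].
#' @export
hamming_ball_volume <- function(C, N, R) {
  stopifnot(R >= 0, N >= 1, C >= N)
  vol <- as_bigint(0)
  for (r in 0:R) {
    vol <- big_add(vol, big_mul(big_choose(N, r), big_choose(C - N, r)))
  }
  vol
}

#' Sphere-packing count of discriminable mixtures
#'
#' The criticized extrapolation: with C primaries, N per mixture, and a
#' critical unshared distance D, the number of packable regions is
#' estimated as the total number of mixtures divided by the volume of a
#' ball of radius D/2,
#' `S = floor( C(C, N) / sum_{R=0}^{D/2} C(N, R) C(C-N, R) )`.
#' All arithmetic is exact. For odd D the upper summation limit D/2 is
#' non-integral; the exact counts at radii `(D-1)/2` and `(D+1)/2` are
#' both reported and, under the default `odd_method = "geometric_mean"`,
#' their geometric mean is reported as the interpolated count `S_interp`
#' (log-linear interpolation, which reproduces the printed ~9e11 at
#' C=128, N=30, D=15). D = 1 needs no ball division: every mixture is its
#' own region and `S = C(C, N)`.
#'
#' @param C Total primaries.
#' @param N Mixture size, `1 <= N <= C`.
#' @param D Critical unshared distance, `1 <= D <= 2N`.
#' @param odd_method For odd D > 1: `"geometric_mean"` (default),
#'   `"floor"` (radius `(D-1)/2`), or `"ceiling"` (radius `(D+1)/2`).
#' @return A `sphere_count` object: list with `C`, `N`, `D`, `S` (exact
#'   [bigint][as_bigint]; for odd D > 1 the selected variant rounded from
#'   the interpolation), `S_floor`/`S_ceil` (exact bigints bracketing odd
#'   D), `S_interp` (double), and `log10_S`.
#' @examples
#' sphere_count(128, 30, 15)
#' @export
sphere_count <- function(C, N, D, odd_method = c("geometric_mean", "floor", "ceiling")) {
  odd_method <- match.arg(odd_method)
  stopifnot(C >= 1, N >= 1, N <= C, D >= 1, D <= 2 * N,
            C == floor(C), N == floor(N), D == floor(D))
  total <- big_choose(C, N)
  count_at <- function(R) big_divmod(total, hamming_ball_volume(C, N, R))$q
  if (D == 1) {
    S <- total
    out <- list(S = S, S_floor = S, S_ceil = S, S_interp = as.double(S))
  } else if (D %% 2 == 0) {
    S <- count_at(D / 2)
    out <- list(S = S, S_floor = S, S_ceil = S, S_interp = as.double(S))
  } else {
    s_lo <- count_at((D + 1) / 2)   # larger radius -> smaller count
    s_hi <- count_at((D - 1) / 2)
    interp <- 10^((big_log10(s_lo) + big_log10(s_hi)) / 2)
    S <- switch(odd_method,
                geometric_mean = as_bigint(sprintf("%.0f", round(interp))),
                floor = s_hi,
                ceiling = s_lo)
    out <- list(S = S, S_floor = s_hi, S_ceil = s_lo,
                S_interp = switch(odd_method,
                                  geometric_mean = interp,
                                  floor = as.double(s_hi),
                                  ceiling = as.double(s_lo)))
  }
  structure(c(list(C = C, N = N, D = D, odd_method = odd_method), out,
              list(log10_S = log10(out$S_interp))),
            class = "sphere_count")
}

#' @export
print.sphere_count <- function(x, ...) {
  cat("<sphere_count> C =", x$C, " N =", x$N, " D =", x$D, "\n")
  if (x$D %% 2 == 1 && x$D > 1) {
    cat("  exact counts at radii", (x$D - 1) / 2, "and", (x$D + 1) / 2, ":",
        format(x$S_floor), "/", format(x$S_ceil), "\n")
    cat("  interpolated S =", format(x$S_interp, digits = 4),
        " (log10 =", format(x$log10_S, digits = 4), ")\n")
  } else {
    cat("  S =", format(x$S), " (log10 =", format(x$log10_S, digits = 4), ")\n")
  }
  invisible(x)
}

#' Sphere-coloring lower bound on the number of percepts
#'
#' If two mixtures at the critical distance need only differ in percept a
#' fraction `q` of the time, an equal-frequency labeling of the packed
#' spheres satisfies the criterion with just `k = ceiling(1 / (1 - q))`
#' percept labels (e.g. q = 0.5: alternate two labels; q = 0.9: ten
#' labels). The count of packed spheres therefore does not bound the
#' number of percepts.
#'
#' @param q Required fraction of differing neighbors, `0 < q < 1`.
#' @return Minimal number of percept labels (integer).
#' @examples
#' min_percepts_for_criterion(c(0.5, 0.9, 0.9999))
#' @export
min_percepts_for_criterion <- function(q) {
  if (any(q <= 0 | q >= 1)) {
    .odorspace_error("q must lie strictly between 0 and 1", "odorspace_domain_error")
  }
  x <- 1 / (1 - q)
  # guard against floating-point representation of q pushing an integral
  # 1/(1-q) just above its true value
  as.integer(ceiling(x - 1e-9 * pmax(1, x)))
}

#' Grid count of discriminable percepts
#'
#' Number of just-noticeably-different stimuli on an axis-aligned grid of
#' step `jnd` in a unit hypercube: `floor(1/jnd)^dims`.
#'
#' @param jnd Grid step (just-noticeable difference).
#' @param dims Number of dimensions.
#' @return Exact count as a double.
#' @examples
#' grid_percept_count(0.01, 3)  # 1e6
#' @export
grid_percept_count <- function(jnd, dims) {
  stopifnot(jnd > 0, jnd <= 1, dims >= 1, dims == floor(dims))
  floor(1 / jnd + 1e-9)^dims
}

# P(correct) of a single ring odd-man-out trial at angular separation
# delta, noise sd sigma; common random numbers Z (n x 3).
.ring_trial_p <- function(delta, sigma, Z) {
  mean(.omo_ring_correct(rep(0, nrow(Z)), rep(delta, nrow(Z)), sigma, Z = Z))
}

#' Ring-code capacity
#'
#' How many equally spaced vectors fit around the unit circle such that
#' each is discriminable from its neighbors at the `criterion` level of
#' single-trial odd-man-out accuracy, given angular noise `sigma_ring`?
#' The separation `delta` at which accuracy equals the criterion is
#' located by bisection (Monte-Carlo with common random numbers,
#' `n_mc` trials per evaluation); the capacity is `floor(2*pi / delta)`.
#'
#' @param sigma_ring Angular noise SD in radians (default 0.4).
#' @param criterion Single-trial accuracy defining "just discriminable"
#'   (default 0.5; chance is 1/3).
#' @param n_mc Monte-Carlo trials per bisection evaluation (default 1e5).
#' @return Integer capacity, with attribute `delta50` (the separation at
#'   criterion).
#' @examples
#' \donttest{
#' set.seed(1)
#' ring_capacity(0.4)  # 10
#' }
#' @export
ring_capacity <- function(sigma_ring = 0.4, criterion = 0.5, n_mc = 1e5) {
  stopifnot(sigma_ring > 0, criterion > 1 / 3, criterion < 1, n_mc >= 1e4)
  Z <- matrix(stats::rnorm(3 * n_mc), nrow = n_mc)
  lo <- 0; hi <- pi
  if (.ring_trial_p(hi, sigma_ring, Z) < criterion) {
    # even opposite points are not discriminable at this criterion
    return(structure(2L, delta50 = pi))
  }
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (.ring_trial_p(mid, sigma_ring, Z) < criterion) lo <- mid else hi <- mid
  }
  delta50 <- (lo + hi) / 2
  structure(as.integer(floor(2 * pi / delta50 + 1e-9)), delta50 = delta50)
}

#' Order of magnitude of a subset count
#'
#' `log10 C(C, N)` rounded to the nearest integer, computed from the
#' exact big-integer binomial coefficient.
#'
#' @param C Total primaries.
#' @param N Mixture size.
#' @return Integer power of ten.
#' @examples
#' log10_subset_count(128, 60)  # 37
#' @export
log10_subset_count <- function(C, N) {
  as.integer(round(big_log10(big_choose(C, N))))
}

#' Critical mixture size in the color model
#'
#' Searches for the smallest mixture size N at which 30...N-light
#' mixtures differing by a single component (overlap O = N - 1,
#' component norm 1/N, fresh random directions) drop to 50% class
#' discriminability — the mixture size needed before the critical
#' distance exceeds one component. Monotone in N, located by bisection
#' over `n_range`.
#'
#' @param jnd Just-noticeable difference used to calibrate the RGB noise.
#' @param noise Optional pre-calibrated [noise_config()].
#' @param n_replicates Replicate designs per evaluation (default 200).
#' @param n_pairs,n_trials Class design (defaults 20 and 26).
#' @param n_range Search bracket for N (default c(30, 120)).
#' @param seed Optional integer seed.
#' @return Integer critical mixture size, with attribute `fractions`
#'   (the mean discriminability measured at each probed N).
#' @export
critical_mixture_size_color <- function(jnd = 0.01, noise = NULL,
                                        n_replicates = 200, n_pairs = 20,
                                        n_trials = 26, n_range = c(30, 120),
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(noise)) noise <- noise_config(jnd = jnd)
  noise <- .ensure_sigma_rgb(noise)
  probe <- function(N) {
    fr <- vapply(seq_len(n_replicates), function(r) {
      .replicate_fractions_noisy("color", N, N - 1, C = NA, n_pairs, n_trials,
                                 noise, fresh_vectors = TRUE)
    }, numeric(1))
    mean(fr)
  }
  lo <- n_range[1]; hi <- n_range[2]
  probed <- c()
  f_lo <- probe(lo); probed[as.character(lo)] <- f_lo
  f_hi <- probe(hi); probed[as.character(hi)] <- f_hi
  if (f_lo <= 0.5 || f_hi > 0.5) {
    .odorspace_error(sprintf(
      "search bracket exhausted: fraction %.3f at N=%d, %.3f at N=%d",
      f_lo, lo, f_hi, hi), "odorspace_estimation_error")
  }
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    f <- probe(mid)
    probed[as.character(mid)] <- f
    if (f > 0.5) lo <- mid else hi <- mid
  }
  structure(as.integer(hi), fractions = probed)
}

#' Replacement-distance neighbor count
#'
#' Number of N-subsets of C primaries at exactly one replacement from a
#' given subset: `N * (C - N)`. For C = 128, N = 30 this is 2940, so the
#' "at least 2C" nearest-neighbor bound holds a fortiori.
#'
#' @param C Total primaries.
#' @param N Mixture size.
#' @return Integer neighbor count.
#' @export
one_replacement_neighbors <- function(C, N) {
  stopifnot(C >= N, N >= 1)
  as.integer(N * (C - N))
}
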