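# Odd-man-out test engine, class-level discriminability, psychometric
# curves over replicate designs, and critical-distance extraction.

# Noiseless percepts (v_a, v_b) of a mixture pair under a model.
.pair_percepts <- function(model, pair, primaries = NULL) {
  if (!is.null(pair$vectors)) {
    stopifnot(model == "color")
    return(list(a = colSums(pair$vectors[pair$components_a, , drop = FALSE]),
                b = colSums(pair$vectors[pair$components_b, , drop = FALSE])))
  }
  stopifnot(inherits(primaries, "primary_set"), primaries$model_kind == model)
  switch(model,
    microbe = list(a = sum(primaries$values[pair$components_a]),
                   b = sum(primaries$values[pair$components_b])),
    color = list(a = color_mixture_vector(primaries$values[pair$components_a, , drop = FALSE]),
                 b = color_mixture_vector(primaries$values[pair$components_b, , drop = FALSE])),
    ring = list(a = ring_mixture_angle(primaries$values[pair$components_a]),
                b = ring_mixture_angle(primaries$values[pair$components_b]))
  )
}

#' Run a single odd-man-out trial
#'
#' Three vials are presented: two contain one mixture of the pair and
#' the third (the target, position randomized) contains the other. Each
#' percept is corrupted by the model's noise, the two samples with the
#' smallest distance (Euclidean for color, circular arc for the ring
#' code) are declared identical, and the remaining sample is chosen as
#' the odd one. The trial is correct when the chosen sample is the
#' target. Which mixture of the pair plays target is re-randomized per
#' trial.
#'
#' @param model `"color"` or `"ring"` (the sum-threshold model is
#'   deterministic and has no trials; see [pair_discriminability()]).
#' @param pair A [mixture_pair][make_mixture_pair].
#' @param noise A [noise_config()].
#' @param primaries The [primary_set][draw_primaries], unless the pair
#'   embeds its own vectors.
#' @return A `trial_record`: list with the three noisy samples `x` (in
#'   presentation order), `odd_position`, `chosen_position`, `correct`.
#' @export
odd_man_out_trial <- function(model, pair, noise, primaries = NULL) {
  if (model == "microbe") {
    .odorspace_error("the sum-threshold model is deterministic; use pair_discriminability()",
                     "odorspace_protocol_error")
  }
  stopifnot(model %in% c("color", "ring"), inherits(noise, "noise_config"))
  pp <- .pair_percepts(model, pair, primaries)
  target_is_a <- stats::runif(1) < 0.5
  dup <- if (target_is_a) pp$b else pp$a
  tgt <- if (target_is_a) pp$a else pp$b
  if (model == "color") {
    noise <- .ensure_sigma_rgb(noise)
    s <- noise$sigma_rgb
    samples <- list(perturb_color(dup, s), perturb_color(dup, s), perturb_color(tgt, s))
    dist_fun <- function(x, y) sqrt(sum((x - y)^2))
  } else {
    s <- noise$sigma_ring
    samples <- list(perturb_ring(dup, s), perturb_ring(dup, s), perturb_ring(tgt, s))
    dist_fun <- function(x, y) .circ_dist(x, y)
  }
  ord <- sample.int(3)                 # sample i is presented at position ord[i]
  x <- samples[order(ord)]
  odd_position <- ord[3]
  d12 <- dist_fun(x[[1]], x[[2]])
  d13 <- dist_fun(x[[1]], x[[3]])
  d23 <- dist_fun(x[[2]], x[[3]])
  d <- c(d12, d13, d23)
  closest <- which(d == min(d))
  if (length(closest) > 1L) closest <- sample(closest, 1L)
  chosen <- c(3L, 2L, 1L)[closest]     # sample outside the closest pair
  structure(list(x = x, odd_position = odd_position, chosen_position = chosen,
                 correct = chosen == odd_position),
            class = "trial_record")
}

#' Discriminability of one mixture pair
#'
#' For the noisy models, the pair is presented in `n_trials` independent
#' odd-man-out trials (default 26, one per simulated subject, all with
#' the same noise level) and declared discriminable when more than half
#' the trials are correct (14 or more of 26). For the deterministic
#' sum-threshold model the pair is discriminable exactly when the two
#' response categories differ.
#'
#' @inheritParams odd_man_out_trial
#' @param model `"microbe"`, `"color"`, or `"ring"`.
#' @param n_trials Number of odd-man-out trials (default 26).
#' @return A `pair_result`: list with `n_trials`, `n_correct` (`NA` for
#'   the deterministic model), and `discriminable`.
#' @export
pair_discriminability <- function(model, pair, noise = noise_config(),
                                  n_trials = 26, primaries = NULL) {
  if (model == "microbe") {
    pp <- .pair_percepts(model, pair, primaries)
    disc <- microbe_category(pp$a) != microbe_category(pp$b)
    return(structure(list(n_trials = 0L, n_correct = NA_integer_,
                          discriminable = disc), class = "pair_result"))
  }
  stopifnot(n_trials >= 1)
  pp <- .pair_percepts(model, pair, primaries)
  crit <- floor(n_trials / 2) + 1L
  target_is_a <- stats::runif(n_trials) < 0.5
  if (model == "color") {
    noise <- .ensure_sigma_rgb(noise)
    v <- rbind(pp$a, pp$b)[1L + target_is_a, , drop = FALSE]  # duplicates
    w <- rbind(pp$a, pp$b)[2L - target_is_a, , drop = FALSE]  # target
    correct <- .omo_color_correct(v, w, noise$sigma_rgb)
  } else {
    a <- ifelse(target_is_a, pp$b, pp$a)
    b <- ifelse(target_is_a, pp$a, pp$b)
    correct <- .omo_ring_correct(a, b, noise$sigma_ring)
  }
  n_correct <- sum(correct)
  structure(list(n_trials = as.integer(n_trials), n_correct = as.integer(n_correct),
                 discriminable = n_correct >= crit), class = "pair_result")
}

#' Fraction of discriminable pairs in a class
#'
#' @param class_pairs List of pairs from [make_class()].
#' @inheritParams pair_discriminability
#' @return Fraction in `[0, 1]`.
#' @export
class_fraction <- function(model, class_pairs, noise = noise_config(),
                           n_trials = 26, primaries = NULL) {
  mean(vapply(class_pairs, function(p) {
    pair_discriminability(model, p, noise, n_trials, primaries)$discriminable
  }, logical(1)))
}

# ---- vectorized curve engines -------------------------------------------

# One replicate of the sum-threshold model: fresh +/-1 primaries, then for
# each overlap class the class fraction of category-discriminable pairs.
.replicate_fractions_microbe <- function(N, overlaps, C, n_pairs) {
  p <- sample(c(-1, 1), C, replace = TRUE)
  vapply(overlaps, function(O) {
    m <- 2 * N - O
    idx <- vapply(seq_len(n_pairs), function(i) sample.int(C, m), integer(m))
    vals <- matrix(p[idx], nrow = m)
    s1 <- colSums(vals[seq_len(N), , drop = FALSE])
    s2 <- colSums(vals[(N - O + 1):m, , drop = FALSE])
    mean(microbe_category(s1) != microbe_category(s2))
  }, numeric(1))
}

# Noiseless percepts of the n_pairs pairs in one (N, O) class; returns a
# list(va, vb) of n_pairs x k matrices (k = 3 for color, 1 for ring).
.class_percepts <- function(model, N, O, C, n_pairs, primaries, fresh_vectors) {
  m <- 2 * N - O
  if (fresh_vectors) {
    va <- matrix(0, n_pairs, 3); vb <- matrix(0, n_pairs, 3)
    for (j in seq_len(n_pairs)) {
      pr <- fresh_random_pair_color(N, O)
      va[j, ] <- colSums(pr$vectors[pr$components_a, , drop = FALSE])
      vb[j, ] <- colSums(pr$vectors[pr$components_b, , drop = FALSE])
    }
    return(list(va = va, vb = vb))
  }
  idx <- vapply(seq_len(n_pairs), function(i) sample.int(C, m), integer(m))
  if (model == "color") {
    va <- matrix(0, n_pairs, 3); vb <- matrix(0, n_pairs, 3)
    for (j in seq_len(n_pairs)) {
      va[j, ] <- colSums(primaries$values[idx[seq_len(N), j], , drop = FALSE])
      vb[j, ] <- colSums(primaries$values[idx[(N - O + 1):m, j], , drop = FALSE])
    }
    list(va = va, vb = vb)
  } else {
    ang <- matrix(primaries$values[idx], nrow = m)
    a1 <- atan2(colSums(sin(ang[seq_len(N), , drop = FALSE])),
                colSums(cos(ang[seq_len(N), , drop = FALSE]))) %% (2 * pi)
    a2 <- atan2(colSums(sin(ang[(N - O + 1):m, , drop = FALSE])),
                colSums(cos(ang[(N - O + 1):m, , drop = FALSE]))) %% (2 * pi)
    list(va = matrix(a1, ncol = 1), vb = matrix(a2, ncol = 1))
  }
}

# One replicate of a noisy model: class fractions for every overlap.
.replicate_fractions_noisy <- function(model, N, overlaps, C, n_pairs, n_trials,
                                       noise, fresh_vectors) {
  if (!fresh_vectors) {
    primaries <- draw_primaries(model, C, norm = 1 / N)
  } else {
    primaries <- NULL
  }
  crit <- floor(n_trials / 2) + 1L
  vapply(overlaps, function(O) {
    pp <- .class_percepts(model, N, O, C, n_pairs, primaries, fresh_vectors)
    K <- n_pairs * n_trials
    pair_id <- rep(seq_len(n_pairs), each = n_trials)
    target_is_a <- stats::runif(K) < 0.5
    if (model == "color") {
      va <- pp$va[pair_id, , drop = FALSE]
      vb <- pp$vb[pair_id, , drop = FALSE]
      v <- ifelse(matrix(target_is_a, K, 3), vb, va)   # duplicates
      w <- ifelse(matrix(target_is_a, K, 3), va, vb)   # target
      correct <- .omo_color_correct(v, w, noise$sigma_rgb)
    } else {
      aa <- pp$va[pair_id, 1]; bb <- pp$vb[pair_id, 1]
      dup <- ifelse(target_is_a, bb, aa)
      tgt <- ifelse(target_is_a, aa, bb)
      correct <- .omo_ring_correct(dup, tgt, noise$sigma_ring)
    }
    n_correct <- rowSums(matrix(correct, nrow = n_pairs, byrow = TRUE))
    mean(n_correct >= crit)
  }, numeric(1))
}

#' Discriminability-versus-overlap curve
#'
#' Runs the full mixture-discrimination protocol: per replicate, a fresh
#' random primary set is drawn and, for every overlap class, `n_pairs`
#' mixture pairs are generated and tested (26 odd-man-out trials each for
#' the noisy models; a single deterministic category comparison for the
#' sum-threshold model). The curve reports the mean and SD over
#' replicates of the per-class fraction of discriminable pairs.
#'
#' @param model `"microbe"`, `"color"`, or `"ring"`.
#' @param N Mixture size (default 30).
#' @param overlaps Overlap grid; defaults to
#'   `c(0, 5, 10, 15, 20, 25, 28, 29, 30)` scaled to N = 30.
#' @param C Size of the primary pool (default 128).
#' @param n_pairs Pairs per class (default 20).
#' @param n_trials Odd-man-out trials per pair (default 26).
#' @param n_replicates Replicate designs (default 1000).
#' @param noise A [noise_config()]; `sigma_rgb` is calibrated from the
#'   JND if missing.
#' @param fresh_vectors Color model only: draw each pair's components
#'   fresh from all directions (norm 1/N) instead of from the `C`-primary
#'   pool, emulating an unbounded-dimensional stimulus space.
#' @param seed Optional integer seed; replicate substream seeds are
#'   derived from it so each replicate is independently reproducible.
#' @return A `discrimination_curve` object: data frame `curve` with
#'   columns `O`, `mean_fraction`, `sd_fraction`, plus the run metadata.
#' @examples
#' \donttest{
#' cv <- discrimination_curve("microbe", n_replicates = 50, seed = 1)
#' critical_distance(cv)
#' }
#' @export
discrimination_curve <- function(model, N = 30,
                                 overlaps = NULL,
                                 C = 128, n_pairs = 20, n_trials = 26,
                                 n_replicates = 1000,
                                 noise = noise_config(),
                                 fresh_vectors = FALSE, seed = NULL) {
  stopifnot(model %in% .MODEL_KINDS, N >= 1, n_replicates >= 1)
  if (fresh_vectors && model != "color") {
    .odorspace_error("fresh_vectors applies to the color model only",
                     "odorspace_config_error")
  }
  if (is.null(overlaps)) {
    overlaps <- unique(pmin(N, c(0, 5, 10, 15, 20, 25, N - 2, N - 1, N)))
    overlaps <- sort(overlaps[overlaps >= 0])
  }
  feasible <- fresh_vectors | (2 * N - overlaps <= C)
  if (!all(feasible)) {
    warning("skipping infeasible overlap classes: O = ",
            paste(overlaps[!feasible], collapse = ", "))
    overlaps <- overlaps[feasible]
  }
  if (length(overlaps) == 0L) {
    .odorspace_error("no feasible overlap class", "odorspace_infeasible")
  }
  if (model == "color") noise <- .ensure_sigma_rgb(noise)
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  fr <- matrix(0, n_replicates, length(overlaps))
  for (r in seq_len(n_replicates)) {
    set.seed(rep_seeds[r])
    fr[r, ] <- if (model == "microbe") {
      .replicate_fractions_microbe(N, overlaps, C, n_pairs)
    } else {
      .replicate_fractions_noisy(model, N, overlaps, C, n_pairs, n_trials,
                                 noise, fresh_vectors)
    }
  }
  structure(list(
    model = model, N = as.integer(N), C = as.integer(C),
    n_pairs = as.integer(n_pairs), n_trials = as.integer(n_trials),
    n_replicates = as.integer(n_replicates),
    fresh_vectors = fresh_vectors, noise = noise, seed = seed,
    curve = data.frame(O = overlaps,
                       mean_fraction = colMeans(fr),
                       sd_fraction = apply(fr, 2, stats::sd))
  ), class = "discrimination_curve")
}

#' @export
print.discrimination_curve <- function(x, ...) {
  cat("<discrimination_curve> model =", x$model, " N =", x$N,
      if (x$fresh_vectors) "(fresh vectors)",
      " replicates =", x$n_replicates, "\n")
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.discrimination_curve <- function(x, ...) {
  cbind(model = x$model, N = x$N, x$curve,
        n_replicates = x$n_replicates,
        seed = if (is.null(x$seed)) NA_integer_ else x$seed)
}

#' @export
plot.discrimination_curve <- function(x, level = 0.5, overlay = NULL, ...) {
  graphics::plot(x$curve$O, x$curve$mean_fraction, type = "b", pch = 16,
                 ylim = c(0, 1), xlab = "shared components O",
                 ylab = "fraction of discriminable pairs",
                 main = paste0(x$model, " model, N = ", x$N), ...)
  has_bar <- x$curve$sd_fraction > 0
  if (any(has_bar)) {
    graphics::arrows(x$curve$O[has_bar],
                     pmax(0, (x$curve$mean_fraction - x$curve$sd_fraction)[has_bar]),
                     x$curve$O[has_bar],
                     pmin(1, (x$curve$mean_fraction + x$curve$sd_fraction)[has_bar]),
                     angle = 90, code = 3, length = 0.03)
  }
  graphics::abline(h = level, lty = 2)
  if (!is.null(overlay)) {
    graphics::points(overlay$O, overlay$fraction, pch = 1, col = "red")
  }
  invisible(x)
}

#' Critical distance at the 50% crossing
#'
#' The critical distance D is the number of unshared components at which
#' half the mixture pairs in a class are discriminable: the mean curve is
#' linearly interpolated between the adjacent overlap grid points around
#' the crossing, giving the crossing overlap `O_star`, and
#' `D = N - O_star`. If the mean never falls below `level` for any
#' `O <= N - 1`, a single unshared component already suffices and D = 1.
#'
#' @param curve A [discrimination_curve()].
#' @param level Crossing level (default 0.5).
#' @return A `critical_distance` object: list with `D` (real),
#'   `D_int` (rounded for reporting), `O_star`, `level`.
#' @export
critical_distance <- function(curve, level = 0.5) {
  stopifnot(inherits(curve, "discrimination_curve"), level > 0, level < 1)
  df <- curve$curve[order(curve$curve$O), ]
  N <- curve$N
  below_last <- df$O < N
  if (all(df$mean_fraction[below_last] >= level)) {
    return(structure(list(D = 1, D_int = 1L, O_star = as.numeric(N - 1),
                          level = level), class = "critical_distance"))
  }
  if (df$mean_fraction[1] < level) {
    .odorspace_error("curve lies entirely below the criterion level",
                     "odorspace_no_critical_distance")
  }
  i <- which(df$mean_fraction >= level & c(df$mean_fraction[-1], Inf) < level)[1]
  o_star <- df$O[i] + (df$mean_fraction[i] - level) /
    (df$mean_fraction[i] - df$mean_fraction[i + 1]) * (df$O[i + 1] - df$O[i])
  structure(list(D = N - o_star, D_int = as.integer(round(N - o_star)),
                 O_star = o_star, level = level),
            class = "critical_distance")
}

#' @export
print.critical_distance <- function(x, ...) {
  cat("<critical_distance> D =", format(x$D, digits = 4),
      "(reported", x$D_int, "), crossing overlap O* =",
      format(x$O_star, digits = 4), "at level", x$level, "\n")
  invisible(x)
}

#' Export a discrimination curve as CSV
#'
#' @param curve A [discrimination_curve()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
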