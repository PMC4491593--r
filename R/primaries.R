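# Synthetic stimulus designs: random primary sets and overlap-controlled
# mixture pairs.

.MODEL_KINDS <- c("microbe", "color", "ring")

.odorspace_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "odorspace_error")))
}

#' Draw a random set of primary stimuli
#'
#' Generates the pool of `C` primary stimuli for one of the three
#' encoding models:
#' * `"microbe"`: each primary is an attractant (+1) or repellent (-1)
#'   with probability 1/2;
#' * `"color"`: each primary is an RGB vector with coordinates drawn
#'   uniformly on \[0,1\] and then rescaled to Euclidean norm `norm`
#'   (default 1/30, the equal-parts intensity for 30-light mixtures);
#' * `"ring"`: each primary is a unit vector at an angle drawn uniformly
#'   on \[0, 2*pi).
#'
#' Uses R's global random number generator; seed with [set.seed()] for
#' reproducibility.
#'
#' @param model_kind One of `"microbe"`, `"color"`, `"ring"`.
#' @param C Number of primaries (default 128).
#' @param norm Euclidean norm of each color primary; ignored for the
#'   other models. Defaults to 1/30.
#' @return A `primary_set` object: list with `model_kind`, `C`, and
#'   `values` (a numeric vector of +/-1, a `C x 3` matrix, or a vector of
#'   angles in radians).
#' @examples
#' set.seed(1)
#' p <- draw_primaries("microbe", C = 128)
#' table(p$values)
#' @export
draw_primaries <- function(model_kind, C = 128, norm = 1 / 30) {
  if (length(model_kind) != 1L || !model_kind %in% .MODEL_KINDS) {
    .odorspace_error(paste0("unknown model_kind: ", paste(model_kind, collapse = ",")),
                     "odorspace_config_error")
  }
  stopifnot(C >= 1, C == floor(C))
  values <- switch(model_kind,
    microbe = sample(c(-1, 1), C, replace = TRUE),
    color = {
      v <- matrix(stats::runif(3 * C), nrow = C, ncol = 3,
                  dimnames = list(NULL, c("R", "G", "B")))
      v / sqrt(rowSums(v^2)) * norm
    },
    ring = stats::runif(C, 0, 2 * pi)
  )
  structure(list(model_kind = model_kind, C = as.integer(C), values = values),
            class = "primary_set")
}

#' @export
print.primary_set <- function(x, ...) {
  cat("<primary_set> model =", x$model_kind, " C =", x$C, "\n")
  invisible(x)
}

.new_mixture_pair <- function(a, b, N, O, vectors = NULL) {
  structure(list(components_a = a, components_b = b,
                 N = as.integer(N), O = as.integer(O),
                 D_pair = as.integer(N - O), vectors = vectors),
            class = "mixture_pair")
}

#' @export
print.mixture_pair <- function(x, ...) {
  cat("<mixture_pair> N =", x$N, " O =", x$O, " unshared per mixture =", x$D_pair,
      if (!is.null(x$vectors)) " (embedded vectors)", "\n")
  invisible(x)
}

#' Create one overlap-controlled mixture pair
#'
#' Draws `2N - O` distinct primary indices uniformly without replacement;
#' the first `N` form mixture a and the last `N` form mixture b, so the
#' middle block of `O` indices is shared by construction and the overlap
#' is exactly `O`.
#'
#' @param primaries A [primary_set][draw_primaries] (only its `C` is
#'   used here).
#' @param N Mixture size.
#' @param O Number of shared components, `0 <= O <= N`.
#' @return A `mixture_pair` object with integer index sets
#'   `components_a`, `components_b`.
#' @export
make_mixture_pair <- function(primaries, N, O) {
  stopifnot(inherits(primaries, "primary_set"))
  .check_class_spec(N, O, primaries$C)
  m <- 2 * N - O
  idx <- sample.int(primaries$C, m)
  .new_mixture_pair(idx[seq_len(N)], idx[(N - O + 1):m], N, O)
}

.check_class_spec <- function(N, O, C, n_pairs = 1L) {
  stopifnot(N >= 1, O >= 0, O <= N, n_pairs >= 1)
  if (2 * N - O > C) {
    .odorspace_error(sprintf("infeasible design: 2N - O = %d exceeds C = %d",
                             2 * N - O, C), "odorspace_infeasible")
  }
  invisible(TRUE)
}

#' Create a class of mixture pairs
#'
#' A mixture class is the set of pairs sharing one `(N, O)` combination;
#' the experimental design uses 20 pairs per class.
#'
#' @inheritParams make_mixture_pair
#' @param n_pairs Number of independent pairs (default 20).
#' @return List of [mixture_pair][make_mixture_pair] objects.
#' @export
make_class <- function(primaries, N, O, n_pairs = 20) {
  .check_class_spec(N, O, primaries$C, n_pairs)
  lapply(seq_len(n_pairs), function(i) make_mixture_pair(primaries, N, O))
}

#' Mixture pair with freshly drawn color vectors
#'
#' Emulates an unbounded-dimensional primary space: instead of drawing
#' from a fixed pool of `C` primaries, every pair gets `2N - O` freshly
#' drawn random color vectors of norm `norm` (default 1/N), with a shared
#' block of exactly `O` vectors.
#'
#' @param N Mixture size.
#' @param O Shared components, `0 <= O <= N`.
#' @param norm Euclidean norm of each component vector (default `1/N`).
#' @return A `mixture_pair` whose `vectors` field holds the
#'   `(2N - O) x 3` matrix of embedded component vectors;
#'   `components_a`/`components_b` index rows of that matrix.
#' @export
fresh_random_pair_color <- function(N, O, norm = 1 / N) {
  stopifnot(N >= 1, O >= 0, O <= N)
  m <- 2 * N - O
  v <- matrix(stats::runif(3 * m), nrow = m, ncol = 3)
  v <- v / sqrt(rowSums(v^2)) * norm
  .new_mixture_pair(seq_len(N), (N - O + 1):m, N, O, vectors = v)
}

#' Export / import a mixture design as JSON
#'
#' Serializes a primary set together with a list of mixture pairs for
#' reproducibility audits, and reads it back.
#'
#' @param primaries A [primary_set][draw_primaries].
#' @param pairs List of [mixture_pair][make_mixture_pair] objects.
#' @param path File path for the JSON document.
#' @return `design_to_json()` returns `path` invisibly;
#'   `design_from_json()` returns `list(primaries, pairs)`.
#' @export
design_to_json <- function(primaries, pairs, path) {
  doc <- list(
    model_kind = primaries$model_kind,
    C = primaries$C,
    values = primaries$values,
    pairs = lapply(pairs, function(p) {
      list(components_a = p$components_a, components_b = p$components_b,
           N = p$N, O = p$O)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname design_to_json
#' @export
design_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  values <- doc$values
  if (doc$model_kind == "color") {
    values <- do.call(rbind, lapply(values, unlist))
    colnames(values) <- c("R", "G", "B")
  }
  primaries <- structure(list(model_kind = doc$model_kind, C = as.integer(doc$C),
                              values = values), class = "primary_set")
  pairs <- lapply(doc$pairs, function(p) {
    .new_mixture_pair(as.integer(unlist(p$components_a)),
                      as.integer(unlist(p$components_b)), p$N, p$O)
  })
  list(primaries = primaries, pairs = pairs)
}
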