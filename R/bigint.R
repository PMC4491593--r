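# Exact non-negative integer arithmetic on base-1e7 limb vectors.
#
# The capacity estimates divide binomial coefficients far beyond 2^53
# (e.g. C(128,30) ~ 1.5e29), so doubles cannot carry the combinatorics
# exactly. Limbs are stored little-endian as integer-valued doubles in
# [0, 1e7); products of two limbs (< 1e14) and short convolution sums
# stay below 2^53, so all operations are exact.

.BIG_BASE <- 1e7
.BIG_DIGITS <- 7L

#' Create a big integer
#'
#' Constructs an exact arbitrary-precision non-negative integer, either
#' from an integer-valued double below 2^53 or from a decimal string.
#'
#' @param x A single non-negative integer-valued number, or a string of
#'   decimal digits.
#' @return An object of class `bigint`.
#' @examples
#' as_bigint(12345)
#' as_bigint("123456789012345678901234567890")
#' @export
as_bigint <- function(x) {
  if (inherits(x, "bigint")) return(x)
  if (is.character(x)) {
    s <- gsub("\\s", "", x)
    if (!grepl("^[0-9]+$", s)) stop("not a decimal digit string: ", x)
    s <- sub("^0+(?=[0-9])", "", s, perl = TRUE)
    n <- nchar(s)
    starts <- seq(n, 1, by = -.BIG_DIGITS)
    limbs <- vapply(starts, function(e) {
      b <- max(1L, e - .BIG_DIGITS + 1L)
      as.numeric(substr(s, b, e))
    }, numeric(1))
    return(.big_trim(limbs))
  }
  stopifnot(is.numeric(x), length(x) == 1L, x >= 0, x == floor(x), x < 2^53)
  limbs <- numeric(0)
  x <- as.numeric(x)
  repeat {
    limbs <- c(limbs, x %% .BIG_BASE)
    x <- (x - x %% .BIG_BASE) / .BIG_BASE
    if (x == 0) break
  }
  .big_trim(limbs)
}

.big_trim <- function(limbs) {
  while (length(limbs) > 1L && limbs[length(limbs)] == 0) limbs <- limbs[-length(limbs)]
  structure(list(limbs = limbs), class = "bigint")
}

.big_carry <- function(limbs) {
  # propagate carries; limbs may temporarily exceed the base but not 2^53
  i <- 1L
  while (i <= length(limbs)) {
    if (limbs[i] >= .BIG_BASE) {
      carry <- floor(limbs[i] / .BIG_BASE)
      limbs[i] <- limbs[i] - carry * .BIG_BASE
      if (i == length(limbs)) limbs <- c(limbs, 0)
      limbs[i + 1L] <- limbs[i + 1L] + carry
    }
    i <- i + 1L
  }
  .big_trim(limbs)
}

#' @export
print.bigint <- function(x, ...) {
  cat("<bigint> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.bigint <- function(x, ...) {
  l <- rev(x$limbs)
  paste0(l[1], paste(sprintf("%07d", l[-1]), collapse = ""))
}

#' @export
as.character.bigint <- function(x, ...) format(x)

#' @export
as.double.bigint <- function(x, ...) sum(x$limbs * .BIG_BASE^(seq_along(x$limbs) - 1))

big_cmp <- function(a, b) {
  la <- length(a$limbs); lb <- length(b$limbs)
  if (la != lb) return(sign(la - lb))
  for (i in la:1) {
    if (a$limbs[i] != b$limbs[i]) return(sign(a$limbs[i] - b$limbs[i]))
  }
  0L
}

big_add <- function(a, b) {
  n <- max(length(a$limbs), length(b$limbs))
  la <- c(a$limbs, numeric(n - length(a$limbs)))
  lb <- c(b$limbs, numeric(n - length(b$limbs)))
  .big_carry(la + lb)
}

big_sub <- function(a, b) {
  # requires a >= b
  if (big_cmp(a, b) < 0) stop("bigint subtraction would be negative")
  n <- length(a$limbs)
  la <- a$limbs
  lb <- c(b$limbs, numeric(n - length(b$limbs)))
  r <- la - lb
  for (i in seq_len(n)) {
    if (r[i] < 0) {
      r[i] <- r[i] + .BIG_BASE
      r[i + 1L] <- r[i + 1L] - 1
    }
  }
  .big_trim(r)
}

big_mul <- function(a, b) {
  la <- a$limbs; lb <- b$limbs
  out <- numeric(length(la) + length(lb))
  for (i in seq_along(la)) {
    if (la[i] == 0) next
    seg <- la[i] * lb
    idx <- (i - 1L) + seq_along(lb)
    out[idx] <- out[idx] + seg
    # keep partial sums well below 2^53
    big <- which(out[idx] >= 2^52)
    for (j in big) {
      k <- idx[j]
      carry <- floor(out[k] / .BIG_BASE)
      out[k] <- out[k] - carry * .BIG_BASE
      out[k + 1L] <- out[k + 1L] + carry
    }
  }
  .big_carry(out)
}

big_mul_small <- function(a, m) {
  # m a non-negative integer-valued double with m < 2^53 / 1e7
  stopifnot(m >= 0, m == floor(m), m < 2^53 / .BIG_BASE)
  if (m == 0) return(as_bigint(0))
  .big_carry(a$limbs * m)
}

big_divmod_small <- function(a, d) {
  # exact quotient and remainder for divisor d < 2^53 / 1e7
  stopifnot(d >= 1, d == floor(d), d < 2^53 / .BIG_BASE)
  q <- numeric(length(a$limbs))
  rem <- 0
  for (i in length(a$limbs):1) {
    cur <- rem * .BIG_BASE + a$limbs[i]
    q[i] <- floor(cur / d)
    rem <- cur - q[i] * d
  }
  list(q = .big_trim(q), r = rem)
}

big_divmod <- function(a, b) {
  # schoolbook long division; quotient limb found by binary search so
  # every comparison is exact
  if (length(b$limbs) == 1L) {
    if (b$limbs[1] == 0) stop("division by zero")
    dm <- big_divmod_small(a, b$limbs[1])
    return(list(q = dm$q, r = as_bigint(dm$r)))
  }
  if (big_cmp(a, b) < 0) return(list(q = as_bigint(0), r = a))
  qlimbs <- numeric(length(a$limbs))
  rem <- as_bigint(0)
  for (i in length(a$limbs):1) {
    rem <- .big_trim(c(a$limbs[i], if (!(length(rem$limbs) == 1L && rem$limbs[1] == 0)) rem$limbs))
    lo <- 0; hi <- .BIG_BASE - 1
    while (lo < hi) { # largest d with d*b <= rem
      mid <- ceiling((lo + hi) / 2)
      if (big_cmp(big_mul_small(b, mid), rem) <= 0) lo <- mid else hi <- mid - 1
    }
    qlimbs[i] <- lo
    if (lo > 0) rem <- big_sub(rem, big_mul_small(b, lo))
  }
  list(q = .big_trim(qlimbs), r = rem)
}

#' Exact binomial coefficient
#'
#' Computes `choose(n, k)` in exact arbitrary-precision arithmetic via the
#' multiplicative recurrence; every intermediate division is exact.
#'
#' @param n,k Non-negative integers with `k <= n`.
#' @return A [bigint][as_bigint] equal to the binomial coefficient.
#' @examples
#' format(big_choose(128, 30))
#' @export
big_choose <- function(n, k) {
  stopifnot(n >= 0, k >= 0, k <= n, n == floor(n), k == floor(k))
  k <- min(k, n - k)
  res <- as_bigint(1)
  if (k == 0) return(res)
  for (i in seq_len(k)) {
    res <- big_mul_small(res, n - k + i)
    dm <- big_divmod_small(res, i)
    stopifnot(dm$r == 0)
    res <- dm$q
  }
  res
}

#' Base-10 logarithm of a big integer
#'
#' @param x A [bigint][as_bigint] (or number coercible to one); must be
#'   positive.
#' @return `log10(x)` as a double, accurate to ~1e-12 relative.
#' @export
big_log10 <- function(x) {
  x <- as_bigint(x)
  l <- x$limbs
  if (length(l) == 1L && l[1] == 0) stop("log10 of zero")
  top <- l[max(1L, length(l) - 2L):length(l)]
  head_val <- sum(top * .BIG_BASE^(seq_along(top) - 1))
  log10(head_val) + (length(l) - length(top)) * .BIG_DIGITS
}
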