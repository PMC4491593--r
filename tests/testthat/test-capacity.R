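test_that("Hamming-ball volume matches brute-force subset enumeration", {
  for (C in c(6, 8, 10, 12)) {
    for (N in 1:min(4, C - 1)) {
      for (R in 0:min(N, C - N)) {
        expect_identical(
          as.double(hamming_ball_volume(C, N, R)),
          oracle_ball_volume_bruteforce(C, N, R),
          info = sprintf("C=%d N=%d R=%d", C, N, R))
      }
    }
  }
})

test_that("sphere_count reproduces the worked examples exactly", {
  # tiny case by hand: 15 two-subsets of 6, ball of radius 1 holds 9
  expect_identical(as.double(sphere_count(6, 2, 2)$S), 1)

  # D = 1: every mixture its own region
  s1 <- sphere_count(128, 30, 1)
  expect_identical(format(s1$S), format(big_choose(128, 30)))
  expect_gt(s1$log10_S, 27)

  # odd D = 15: exact brackets at radii 7 and 8 and their geometric mean;
  # oracle via floating-point lchoose arithmetic
  s15 <- sphere_count(128, 30, 15)
  ball_log <- function(R) log(sum(exp(lchoose(30, 0:R) + lchoose(98, 0:R))))
  s7 <- exp(lchoose(128, 30) - ball_log(7))
  s8 <- exp(lchoose(128, 30) - ball_log(8))
  expect_equal(as.double(s15$S_floor), floor(s7), tolerance = 1e-10)
  expect_equal(as.double(s15$S_ceil), floor(s8), tolerance = 1e-10)
  expect_equal(s15$S_interp, sqrt(floor(s7) * floor(s8)), tolerance = 1e-9)
  # the printed headline value, within a factor 1.5
  expect_lt(abs(log10(s15$S_interp) - log10(9e11)), log10(1.5))

  # floor / ceiling variants expose the brackets
  expect_identical(format(sphere_count(128, 30, 15, "floor")$S), format(s15$S_floor))
  expect_identical(format(sphere_count(128, 30, 15, "ceiling")$S), format(s15$S_ceil))

  expect_error(sphere_count(128, 30, 0))
  expect_error(sphere_count(10, 12, 2))
})

test_that("sphere_count is non-increasing in D and anchored at C(C,N) for D = 1", {
  for (C in c(5, 10, 15, 20)) {
    for (N in unique(c(1, C %/% 3, C %/% 2))) {
      if (N < 1) next
      vals <- vapply(1:(2 * N), function(D) sphere_count(C, N, D)$S_interp, numeric(1))
      expect_true(all(diff(vals) <= 1e-9), info = sprintf("C=%d N=%d", C, N))
      expect_identical(vals[1], as.double(big_choose(C, N)))
    }
  }
})

test_that("the coloring bound is exact at the quoted criteria and monotone in q", {
  expect_identical(min_percepts_for_criterion(0.5), 2L)
  expect_identical(min_percepts_for_criterion(0.9), 10L)
  expect_identical(min_percepts_for_criterion(0.9999), 10000L)
  qs <- sort(runif(50, 0.01, 0.999))
  ks <- min_percepts_for_criterion(qs)
  expect_true(all(diff(ks) >= 0))
  expect_error(min_percepts_for_criterion(0), class = "odorspace_domain_error")
  expect_error(min_percepts_for_criterion(1), class = "odorspace_domain_error")
})

test_that("grid percept counts are exact", {
  expect_identical(grid_percept_count(0.01, 3), 1e6)
  expect_identical(grid_percept_count(0.5, 3), 8)
  expect_identical(grid_percept_count(0.01, 1), 100)
})

test_that("subset-count orders of magnitude are exact", {
  expect_identical(log10_subset_count(128, 60), 37L)
  expect_identical(log10_subset_count(6, 2), 1L)
  expect_identical(log10_subset_count(17, 17), 0L)
})

test_that("ring capacity is 10 at sigma 0.4 and scales inversely with sigma", {
  set.seed(61)
  cap4 <- ring_capacity(0.4, n_mc = 1e5)
  expect_identical(as.integer(cap4), 10L)
  # independent oracle: the separation at criterion on a line
  d50 <- attr(cap4, "delta50")
  p_at_d50 <- oracle_line_omo_p(d50, 0.4)
  expect_equal(p_at_d50, 0.5, tolerance = 0.01 / 0.5)

  cap2 <- ring_capacity(0.2, n_mc = 1e5)
  expect_lte(abs(as.integer(cap2) - 2L * as.integer(cap4)), 1L)

  # overwhelming noise wraps the circle
  expect_lte(as.integer(ring_capacity(pi, n_mc = 2e4)), 2L)
})

test_that("every mixture has far more one-replacement neighbors than 2C", {
  expect_identical(one_replacement_neighbors(128, 30), 2940L)
  expect_gte(one_replacement_neighbors(128, 30), 256L)
})

test_that("the critical color mixture size lands near 60 and behaves at N = 30", {
  # reduced replicates (40 per probe) keep this test fast; the acceptance
  # band 50..75 is wide relative to the Monte-Carlo error
  set.seed(62)
  noise <- noise_config(sigma_rgb = calibrate_color_noise(n_mc = 1e5))
  n30 <- mean(vapply(1:40, function(i) {
    odorspace:::.replicate_fractions_noisy("color", 30, 29, NA, 20, 26, noise, TRUE)
  }, numeric(1)))
  expect_gt(n30, 0.5)  # 30-light mixtures still above the criterion

  ncrit <- critical_mixture_size_color(noise = noise, n_replicates = 40, seed = 63)
  expect_gte(as.integer(ncrit), 50L)
  expect_lte(as.integer(ncrit), 75L)
})
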