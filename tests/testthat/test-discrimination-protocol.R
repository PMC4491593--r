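test_that("single odd-man-out trials behave at the chance floor and noiseless limits", {
  set.seed(21)
  p <- draw_primaries("ring", C = 128)
  identical_pair <- make_mixture_pair(p, 30, 30)
  noise <- noise_config(sigma_ring = 0.4, sigma_rgb = 0.005)

  # identical mixtures: correct with probability 1/3
  correct <- vapply(1:1e4, function(i) {
    odd_man_out_trial("ring", identical_pair, noise, p)$correct
  }, logical(1))
  expect_equal(mean(correct), 1 / 3, tolerance = 0.015 / (1 / 3))

  # noise -> 0 with distinct mixtures: always correct
  tiny <- noise_config(sigma_ring = 1e-12, sigma_rgb = 1e-12)
  distinct <- make_mixture_pair(p, 30, 0)
  correct0 <- vapply(1:200, function(i) {
    odd_man_out_trial("ring", distinct, tiny, p)$correct
  }, logical(1))
  expect_true(all(correct0))

  expect_error(odd_man_out_trial("microbe", identical_pair, noise, p),
               class = "odorspace_protocol_error")
})

test_that("ring mixtures half a circle apart are essentially always discriminated", {
  set.seed(22)
  n <- 1e4
  correct <- odorspace:::.omo_ring_correct(rep(0, n), rep(pi, n), 0.4)
  # reference value 0.99737 from an independent 1e7-trial simulation of
  # the three-sample circular decision rule
  expect_gt(mean(correct), 0.995)
  expect_equal(mean(correct), 0.99737, tolerance = 0.004 / 0.99737)
})

test_that("pair_discriminability implements the deterministic and the 14-of-26 criteria", {
  # sum-threshold pairs judged purely on categories
  p <- structure(list(model_kind = "microbe", C = 8L,
                      values = c(1, 1, 1, 1, -1, -1, -1, -1)),
                 class = "primary_set")
  yum_vs_yuck <- structure(list(components_a = 1:4, components_b = 5:8,
                                N = 4L, O = 0L, D_pair = 4L, vectors = NULL),
                           class = "mixture_pair")
  expect_true(pair_discriminability("microbe", yum_vs_yuck, primaries = p)$discriminable)
  # sums 0 and 2 are both "meh"
  meh_pair <- structure(list(components_a = c(1, 2, 5, 6), components_b = c(1, 2, 3, 5),
                             N = 4L, O = 3L, D_pair = 1L, vectors = NULL),
                        class = "mixture_pair")
  expect_false(pair_discriminability("microbe", meh_pair, primaries = p)$discriminable)

  # identical noisy pairs are "discriminable" only by binomial luck:
  # P(Binom(26, 1/3) >= 14), computed independently
  set.seed(23)
  pc <- draw_primaries("color", C = 64)
  same <- make_mixture_pair(pc, 30, 30)
  noise <- noise_config(sigma_rgb = 0.005)
  hits <- vapply(1:3000, function(i) {
    pair_discriminability("color", same, noise, primaries = pc)$discriminable
  }, logical(1))
  p_lucky <- pbinom(13, 26, 1 / 3, lower.tail = FALSE)  # = 0.02475
  expect_equal(mean(hits), p_lucky,
               tolerance = (3 * sqrt(p_lucky * (1 - p_lucky) / 3000)) / p_lucky)
})

test_that("class_fraction reproduces the analytic O=0 collision probability", {
  set.seed(24)
  p_disjoint <- oracle_microbe_fraction(0)
  expect_equal(p_disjoint, 0.6566, tolerance = 1e-4)
  fr <- vapply(1:300, function(i) {
    prim <- draw_primaries("microbe", 128)
    class_fraction("microbe", make_class(prim, 30, 0), primaries = prim)
  }, numeric(1))
  expect_equal(mean(fr), p_disjoint, tolerance = 0.02 / p_disjoint)
  # fully-overlapping classes are never discriminable for the microbe
  prim <- draw_primaries("microbe", 128)
  expect_identical(class_fraction("microbe", make_class(prim, 30, 30), primaries = prim), 0)
})

test_that("vectorized curve engine agrees with the scalar per-pair protocol", {
  # same analytic target, two independent code paths
  set.seed(25)
  scalar <- mean(vapply(1:150, function(i) {
    prim <- draw_primaries("ring", 128)
    class_fraction("ring", make_class(prim, 30, 25), noise_config(), primaries = prim)
  }, numeric(1)))
  cv <- discrimination_curve("ring", overlaps = 25, n_replicates = 150, seed = 77)
  engine <- cv$curve$mean_fraction
  se <- cv$curve$sd_fraction / sqrt(150)
  expect_lt(abs(scalar - engine), 5 * se + 0.02)
})

test_that("microbe curve tracks the exact analytic curve and crosses at O* ~ 15.26", {
  cv <- discrimination_curve("microbe", overlaps = c(0, 5, 10, 14, 15, 16, 17, 20, 30),
                             n_replicates = 400, seed = 31)
  exact <- vapply(cv$curve$O, oracle_microbe_fraction, numeric(1))
  se <- cv$curve$sd_fraction / sqrt(400)
  expect_true(all(abs(cv$curve$mean_fraction - exact) < 4 * se + 0.005))
  cd <- critical_distance(cv)
  expect_equal(cd$O_star, oracle_microbe_crossing(), tolerance = 1 / oracle_microbe_crossing())
  expect_equal(cd$D_int, 15, tolerance = 1 / 15)  # integer within +/-1
})

test_that("mean discriminability is non-increasing in overlap for every model", {
  noise <- noise_config(sigma_rgb = calibrate_color_noise(n_mc = 5e4))
  for (model in c("microbe", "ring", "color")) {
    cv <- discrimination_curve(model, overlaps = c(0, 10, 20, 28, 30),
                               n_replicates = 120, noise = noise,
                               seed = 40 + match(model, c("microbe", "ring", "color")))
    mf <- cv$curve$mean_fraction
    tol <- 2 * cv$curve$sd_fraction / sqrt(120)
    expect_true(all(diff(mf) <= tol[-1] + tol[-length(tol)]),
                info = model)
  }
})

test_that("lower ring noise dominates higher ring noise pointwise", {
  curves <- lapply(c(0.3, 0.4, 0.5), function(s) {
    discrimination_curve("ring", overlaps = c(0, 10, 20, 25, 28),
                         n_replicates = 150, noise = noise_config(sigma_ring = s),
                         seed = 50)$curve$mean_fraction
  })
  se_slack <- 0.03  # ~2 SE at 150 replicates
  expect_true(all(curves[[1]] >= curves[[2]] - se_slack))
  expect_true(all(curves[[2]] >= curves[[3]] - se_slack))
})

test_that("critical_distance interpolates, floors at D = 1, and rejects flat-low curves", {
  fake <- function(O, mf, N = 30) {
    structure(list(model = "ring", N = N, curve = data.frame(
      O = O, mean_fraction = mf, sd_fraction = 0)), class = "discrimination_curve")
  }
  # synthetic step: 1.0 below O = 10, 0.0 from 10 on -> O* = 9.5, D = 20.5
  step <- fake(0:30, c(rep(1, 10), rep(0, 21)))
  cd <- critical_distance(step)
  expect_equal(cd$O_star, 9.5)
  expect_equal(cd$D, 20.5)
  # curve above level everywhere up to N-1 -> D = 1
  high <- fake(c(0, 10, 20, 29, 30), c(1, 1, 0.95, 0.9, 0.02))
  expect_equal(critical_distance(high)$D, 1)
  # entirely below level -> error
  low <- fake(c(0, 10, 30), c(0.3, 0.2, 0))
  expect_error(critical_distance(low), class = "odorspace_no_critical_distance")
})

test_that("curves are reproducible from the seed and infeasible overlaps are skipped", {
  c1 <- discrimination_curve("microbe", overlaps = c(0, 15, 30), n_replicates = 20, seed = 5)
  c2 <- discrimination_curve("microbe", overlaps = c(0, 15, 30), n_replicates = 20, seed = 5)
  expect_identical(c1$curve, c2$curve)
  c3 <- discrimination_curve("microbe", overlaps = c(0, 15, 30), n_replicates = 20, seed = 6)
  expect_false(identical(c1$curve, c3$curve))

  expect_warning(
    cv <- discrimination_curve("microbe", N = 70, overlaps = c(0, 40, 69),
                               n_replicates = 5, seed = 1),
    "infeasible")
  expect_identical(cv$curve$O, c(40, 69))
})
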