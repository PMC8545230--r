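test_that("search_space validates bounds and dimensions", {
  sp <- search_space(3, c(-1, 0, 2), c(1, 5, 3))
  expect_equal(sp$dims, 3L)
  expect_error(search_space(0, 0, 1), "positive integer")
  expect_error(search_space(2, 1, 1), "strictly below")
  expect_error(search_space(2, c(0, 2), c(1, 1)), "strictly below")
})

test_that("initial population is uniform within bounds with zero velocities", {
  sp <- search_space(2, 0, 1)
  pop <- init_population(sp, 5, seed = 11)
  expect_equal(dim(pop$positions), c(5L, 2L))
  expect_true(all(pop$positions >= 0 & pop$positions <= 1))
  expect_true(all(pop$velocities == 0))
  expect_true(all(is.na(pop$fitness)))

  # law-of-large-numbers check: per-dimension mean within 3 standard errors
  sp2 <- search_space(4, -5, 5)
  pop2 <- init_population(sp2, 100, seed = 3)
  se <- (10 / sqrt(12)) / sqrt(100)
  expect_true(all(abs(colMeans(pop2$positions)) < 3 * se))

  expect_error(init_population(sp, 4), "at least 5")
})

test_that("evaluation fills fitness, counts calls, and rejects bad objectives", {
  sp <- search_space(2, -5, 5)
  pop <- init_population(sp, 10, seed = 1)
  pop$positions[1, ] <- c(0, 0)
  pop$positions[2, ] <- c(1, 2)
  pop <- evaluate_population(pop, get_objective("sphere"))
  expect_identical(pop$fitness[1], 0)
  expect_identical(pop$fitness[2], 5)
  expect_identical(evaluation_count(pop), 10L)
  pop <- evaluate_population(pop, get_objective("sphere"))
  expect_identical(evaluation_count(pop), 20L)

  expect_error(evaluate_population(pop, function(x) NaN), "agent 1")
  expect_error(evaluate_population(pop, function(x) if (x[1] > 0) 1 else Inf),
               "non-finite")
})

test_that("roles follow sorted fitness with index tie-breaks and a full partition", {
  sp <- search_space(2, 0, 1)
  pop <- init_population(sp, 5, seed = 2)
  pop$fitness <- c(3, 1, 2, 5, 4)
  roles <- assign_roles(pop)
  expect_identical(roles$hickory, 2L)
  expect_identical(roles$acorn, c(3L, 1L, 5L))
  expect_identical(roles$normal, 4L)
  expect_setequal(c(roles$n2_split, roles$n3_split), roles$normal)
  expect_length(intersect(roles$n2_split, roles$n3_split), 0)

  pop$fitness <- rep(1, 5)
  expect_identical(assign_roles(pop)$hickory, 1L)  # tie -> lowest index

  pop10 <- init_population(sp, 10, seed = 2)
  pop10 <- evaluate_population(pop10, get_objective("sphere"))
  r10 <- assign_roles(pop10)
  expect_identical(length(r10$n2_split) + length(r10$n3_split), 6L)

  pop$fitness <- rep(NA_real_, 5)
  expect_error(assign_roles(pop), "not been evaluated")
})

test_that("Levy scale factor matches its closed form", {
  expect_identical(levy_sigma(1.0), 1)
  beta <- 1.5
  direct <- ((gamma(1 + beta) * sin(pi * beta / 2)) /
             (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  expect_equal(levy_sigma(1.5), direct, tolerance = 1e-15)
  expect_error(levy_sigma(2.5), "\\(0, 2\\]")
  expect_error(levy_sigma(0), "\\(0, 2\\]")
})

test_that("Levy samples have the stated form and heavy tails", {
  set.seed(1)
  v <- levy_sample(1.5, 3)
  expect_length(v, 3)
  expect_true(all(is.finite(v)))

  # forced draws: 0.01 * 0.5 * sigma / 0.5^(1/1.5)
  forced <- levy_sample(1.5, 1, r_a = 0.5, r_b = 0.5)
  expect_equal(forced, 0.01 * 0.5 * levy_sigma(1.5) / 0.5^(2 / 3), tolerance = 1e-12)
  expect_equal(round(forced, 6), 0.005529)

  set.seed(7)
  draws <- abs(replicate(10000, levy_sample(1.5, 1)))
  expect_lt(stats::median(draws), stats::quantile(draws, 0.99) / 10)
})

test_that("seasonal constant is the acorn-to-hickory distance", {
  sp <- search_space(2, -10, 10)
  pop <- init_population(sp, 6, seed = 5)
  pop$fitness <- 1:6
  roles <- assign_roles(pop)
  # acorns on top of the hickory
  for (k in roles$acorn) pop$positions[k, ] <- pop$positions[roles$hickory, ]
  expect_equal(seasonal_constant(pop, roles), c(0, 0, 0))
  # a 3-4-5 triangle
  pop$positions[roles$hickory, ] <- c(0, 0)
  pop$positions[roles$acorn[1], ] <- c(3, 4)
  expect_equal(seasonal_constant(pop, roles)[1], 5)
  # translation invariance
  before <- seasonal_constant(pop, roles)
  pop$positions <- pop$positions + 7.5
  expect_equal(seasonal_constant(pop, roles), before)
})

test_that("seasonal threshold decays from 1e-6 to 1e-6/365^2.5", {
  expect_equal(seasonal_minimum(0, 100), 1e-6)
  expect_equal(seasonal_minimum(100, 100), 1e-6 / 365^2.5, tolerance = 1e-15)
  vals <- sapply(1:50, seasonal_minimum, t_m = 50)
  expect_true(all(diff(vals) < 0))
  expect_error(seasonal_minimum(1, 0), "positive")
})

test_that("the run harness is deterministic with non-increasing curves", {
  sp <- search_space(4, -5, 5)
  for (alg in registered_algorithms()) {
    p <- switch(alg,
      ss = ss_params(n = 8, t_m = 15), assoa = assoa_params(n = 8, t_m = 15),
      gwo = gwo_params(n = 8, t_m = 15), ga = ga_params(n = 8, t_m = 15))
    r1 <- run_optimizer(alg, sp, "sphere", p, seed = 42)
    r2 <- run_optimizer(alg, sp, "sphere", p, seed = 42)
    expect_identical(r1, r2)
    expect_true(all(diff(r1$curve) <= 0))
    expect_identical(r1$best_fitness, r1$curve[length(r1$curve)])
  }
  expect_error(run_optimizer("simulated-annealing", sp, "sphere"), "registered")
})

test_that("every step keeps positions inside the bounds", {
  sp <- search_space(3, -2, 2)
  for (alg in registered_algorithms()) {
    p <- switch(alg,
      ss = ss_params(n = 10, t_m = 10), assoa = assoa_params(n = 10, t_m = 10),
      gwo = gwo_params(n = 10, t_m = 10), ga = ga_params(n = 10, t_m = 10))
    r <- run_optimizer(alg, sp, "rastrigin", p, seed = 5)
    expect_true(all(r$best_position >= -2 & r$best_position <= 2))
  }
})

test_that("results serialize to a curve CSV and a JSON summary", {
  sp <- search_space(2, -1, 1)
  r <- run_optimizer("ss", sp, "sphere", ss_params(n = 6, t_m = 5), seed = 3)
  curve_csv <- withr::local_tempfile(fileext = ".csv")
  summary_json <- withr::local_tempfile(fileext = ".json")
  write_result(r, curve_csv, summary_json)
  curve <- utils::read.csv(curve_csv)
  expect_equal(curve$best_fitness, r$curve)
  js <- jsonlite::read_json(summary_json, simplifyVector = TRUE)
  expect_equal(js$seed, 3)
  expect_equal(js$best_fitness, r$best_fitness)
})
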