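make_eval_pop <- function(n = 10, d = 3, seed = 1, lower = -5, upper = 5) {
  sp <- search_space(d, lower, upper)
  pop <- init_population(sp, n, seed = seed)
  pop <- evaluate_population(pop, get_objective("sphere"))
  list(space = sp, pop = pop)
}

test_that("glide_move implements the gliding displacement", {
  expect_equal(glide_move(c(1, 2), c(1, 2), 0.7, 1.9), c(1, 2))      # fixed point
  expect_equal(glide_move(c(0, 0), c(1, 1), 1, 1.9), c(1.9, 1.9))
  base <- glide_move(c(0, 0), c(1, 2), 0.5, 1.9)
  twice <- glide_move(c(0, 0), c(1, 2), 1.0, 1.9)
  expect_equal(twice, 2 * base)                                       # linear in d_g
  expect_error(glide_move(c(0, 0), c(1, 2, 3), 1, 1.9), "equal length")
})

test_that("predator probability gates the random-location branch", {
  env <- make_eval_pop(seed = 4)
  set.seed(9)
  roles <- assign_roles(env$pop)

  # P_dp ~ 0: every draw R >= P_dp, no random relocation fires
  p_lo <- ss_params(n = 10, t_m = 50, P_dp = 1e-12)
  stepped <- ss_step(env$pop, roles, p_lo, env$space, get_objective("sphere"), t = 1)
  tr <- attr(stepped, "trace")
  expect_false(any(tr[!is.na(tr)] == "random-location"))

  # P_dp ~ 1: every moved agent relocates uniformly within bounds
  set.seed(9)
  roles <- assign_roles(env$pop)
  p_hi <- ss_params(n = 10, t_m = 50, P_dp = 1 - 1e-12)
  stepped <- ss_step(env$pop, roles, p_hi, env$space, get_objective("sphere"), t = 1)
  tr <- attr(stepped, "trace")
  expect_true(all(tr[!is.na(tr)] == "random-location"))
  expect_true(all(stepped$positions >= -5 & stepped$positions <= 5))
})

test_that("forced seasonal trigger relocates normals by scaled Levy flights", {
  env <- make_eval_pop(n = 40, d = 2, seed = 6, lower = 0, upper = 1)
  pop <- env$pop
  set.seed(2)
  roles <- assign_roles(pop)
  # collapse the elite so S_c = 0 < S_min always triggers; P_dp tiny so the
  # pre-relocation moves are glides
  for (k in c(roles$acorn, roles$hickory)) pop$positions[k, ] <- 0.5
  pop <- evaluate_population(pop, get_objective("sphere"))
  p <- ss_params(n = 40, t_m = 100, P_dp = 1e-12)
  stepped <- ss_step(pop, roles, p, env$space, get_objective("sphere"), t = 1)
  tr <- attr(stepped, "trace")
  expect_true(all(tr[roles$normal] == "relocation-SS"))
  normals <- stepped$positions[roles$normal, ]
  expect_true(all(normals >= 0 & normals <= 1))
  # Levy steps are 0.01-scaled: the bulk of relocated coordinates sit near the
  # lower bound, with occasional heavy-tail excursions
  expect_lt(stats::median(normals), 0.05)
})

test_that("ASSOA relocation follows its closed form with a zero-denominator guard", {
  expect_equal(relocate_assoa(c(2, 2), c(2, 2), 0.7), c(2, 2))  # fixed point
  expect_equal(relocate_assoa(1, 2, 0.5), -6)                   # hand arithmetic
  expect_equal(relocate_assoa(c(1, 3), c(2, 5), 0), c(2, 5))    # r = 0
  expect_true(all(is.finite(relocate_assoa(c(0, 0), c(1, -1), 0.3))))
  expect_error(relocate_assoa(c(1, 2), 1, 0.5), "equal length")
})

test_that("the p gate selects between basic glides and advanced cases", {
  env <- make_eval_pop(n = 12, seed = 8)
  obj <- get_objective("sphere")

  run_one <- function(params) {
    set.seed(31)
    roles <- assign_roles(env$pop)
    stepped <- assoa_step(env$pop, roles, params, env$space, obj, t = 1)
    attr(stepped, "trace")
  }

  tr <- run_one(assoa_params(n = 12, t_m = 50, p_fixed = 1))
  expect_true(all(tr[!is.na(tr)] %in% c("case1", "case2", "case3", "random-location")))

  tr <- run_one(assoa_params(n = 12, t_m = 50, p_fixed = 0, a_fixed = 1))
  expect_true(all(tr[!is.na(tr)] == "case4"))

  tr <- run_one(assoa_params(n = 12, t_m = 50, p_fixed = 0, a_fixed = 0, d_fixed = 1))
  expect_true(all(tr[!is.na(tr)] == "case5"))

  tr <- run_one(assoa_params(n = 12, t_m = 50, p_fixed = 0, a_fixed = 0, d_fixed = 0))
  expect_true(all(tr[!is.na(tr)] == "case6"))
})

test_that("each moved agent gets exactly one trace entry per iteration", {
  env <- make_eval_pop(n = 15, seed = 10)
  set.seed(3)
  roles <- assign_roles(env$pop)
  stepped <- assoa_step(env$pop, roles, assoa_params(n = 15, t_m = 20),
                        env$space, get_objective("sphere"), t = 1)
  tr <- attr(stepped, "trace")
  expect_length(tr, 15)
  moved <- c(roles$acorn, roles$normal)
  # hickory never moves; on the advanced branch acorns do not move either
  expect_true(is.na(tr[roles$hickory]))
  expect_true(all(!is.na(tr[roles$normal])))
})

test_that("with the p branch pinned high, ASSOA reproduces SS bit-identically", {
  sp <- search_space(6, -4, 4)
  r_ss <- run_optimizer("ss", sp, "rastrigin", ss_params(n = 10, t_m = 25), seed = 17)
  r_as <- run_optimizer("assoa", sp, "rastrigin",
                        assoa_params(n = 10, t_m = 25, p_fixed = 1), seed = 17)
  expect_identical(r_ss$curve, r_as$curve)
  expect_identical(r_ss$best_position, r_as$best_position)
})

test_that("ASSOA does not trail SS on the planted selection task", {
  # paired seeds over 10 planted realizations (D = 10, harness defaults);
  # the advanced moves earn their keep on the rugged selection landscape
  cmp <- compare_algorithms("fs", c("assoa", "ss"), M = 10, seed = 1)
  means <- cmp$summary$mean_fitness
  names(means) <- cmp$summary$algorithm
  expect_lte(means[["assoa"]], means[["ss"]])
})
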