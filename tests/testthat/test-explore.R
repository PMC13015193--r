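test_that("perturbation adds clipped Gaussian noise of the requested scale", {
  v <- rep(0.5, 4)
  set.seed(14)
  expect_equal(perturb(v, 1e-12), v, tolerance = 1e-9)
  draws <- t(replicate(10000, perturb(v, 0.02)))
  expect_true(all(draws >= 0 & draws <= 1))
  expect_equal(unname(apply(draws, 2, sd)), rep(0.02, 4), tolerance = 0.05)
  expect_equal(unname(colMeans(draws)), rep(0.5, 4), tolerance = 0.002)
  # clipping keeps boundary vectors inside the unit box
  expect_true(all(perturb(rep(0, 50), 0.5) >= 0))
  expect_true(all(perturb(rep(1, 50), 0.5) <= 1))
})

fake_archive <- function(amp, spd) {
  tibble::tibble(id = seq_along(amp), amplitude = amp, max_speed = spd,
                 valid = TRUE, params = replicate(length(amp), runif(5),
                                                  simplify = FALSE))
}

test_that("nearest_valid equals exhaustive search and breaks ties by id", {
  set.seed(15)
  arch <- fake_archive(runif(200, 0, 110), runif(200, 0, 400))
  for (i in 1:500) {
    goal <- c(runif(1, -10, 120), runif(1, -20, 420))
    d <- ((arch$amplitude - goal[1]) / 110)^2 +
      ((arch$max_speed - goal[2]) / 300)^2
    expect_equal(nearest_valid(arch, goal)$id, which.min(d))
  }
  # exact hit returns that entry; exact tie prefers the lower id
  expect_equal(nearest_valid(arch, c(arch$amplitude[7], arch$max_speed[7]))$id, 7)
  tie <- fake_archive(c(10, 30), c(100, 100))
  expect_equal(nearest_valid(tie, c(20, 100))$id, 1)
})

test_that("grid metrics count occupied cells and mean density", {
  g <- behavior_grid()
  empty <- fake_archive(numeric(0), numeric(0))
  expect_equal(grid_metrics(empty, g)$area, 0)
  one <- fake_archive(12, 50)
  expect_equal(grid_metrics(one, g)$area, 1)
  expect_equal(grid_metrics(one, g)$density, 1)
  two_same <- fake_archive(c(12, 13), c(50, 55))
  expect_equal(grid_metrics(two_same, g)$area, 1)
  expect_equal(grid_metrics(two_same, g)$density, 2)
  two_diff <- fake_archive(c(12, 40), c(50, 200))
  expect_equal(grid_metrics(two_diff, g)$area, 2)
  expect_equal(grid_metrics(two_diff, g)$density, 1)
})

test_that("extend goals land in the one-cell dilation ring", {
  g <- behavior_grid()
  arch <- fake_archive(22, 105)   # occupies cell (4, 10)
  set.seed(16)
  for (i in 1:50) {
    goal <- sample_goal(arch, g, "extend")
    cgx <- unname(floor(goal[1] / g$cell_amplitude))
    cgy <- unname(floor(goal[2] / g$cell_speed))
    expect_lte(max(abs(c(cgx - 4, cgy - 10))), 1)
    expect_false(cgx == 4 && cgy == 10)
  }
})

test_that("fill targets interior holes and falls back to extend without holes", {
  g <- behavior_grid()
  # 3x3 occupied block with the center cell empty: a genuine hole
  amp <- g$cell_amplitude * (c(0, 1, 2, 0, 2, 0, 1, 2) + 0.5)
  spd <- g$cell_speed * (c(0, 0, 0, 1, 1, 2, 2, 2) + 0.5)
  holey <- fake_archive(amp, spd)
  set.seed(17)
  for (i in 1:20) {
    goal <- sample_goal(holey, g, "fill")
    expect_equal(unname(floor(goal[1] / g$cell_amplitude)), 1)
    expect_equal(unname(floor(goal[2] / g$cell_speed)), 1)
  }
  # fully dense rectangle: no holes, fill degrades to the extend ring
  amp2 <- g$cell_amplitude * (rep(0:2, 3) + 0.5)
  spd2 <- g$cell_speed * (rep(0:2, each = 3) + 0.5)
  dense <- fake_archive(amp2, spd2)
  for (i in 1:20) {
    goal <- sample_goal(dense, g, "fill")
    cgx <- unname(floor(goal[1] / g$cell_amplitude))
    cgy <- unname(floor(goal[2] / g$cell_speed))
    expect_false(cgx >= 0 && cgx <= 2 && cgy >= 0 && cgy <= 2)
  }
})

test_that("goal sampling is deterministic under a fixed seed", {
  arch <- fake_archive(c(20, 45), c(80, 160))
  set.seed(18)
  a <- replicate(10, sample_goal(arch, strategy = "extend"))
  set.seed(18)
  b <- replicate(10, sample_goal(arch, strategy = "extend"))
  expect_identical(a, b)
  expect_error(sample_goal(fake_archive(numeric(0), numeric(0))), "empty")
})

surrogate_seeds <- function() {
  ev <- surrogate_evaluator()
  vec <- c(0.3, 0.4, runif(48))
  m <- ev(vec)
  dplyr::bind_cols(
    tibble::tibble(id = 1L, parent = NA_integer_, provenance = "seed"),
    m, tibble::tibble(params = list(vec)))
}

test_that("the exploration loop stores only valid movements and grows the domain monotonically", {
  set.seed(19)
  seeds <- surrogate_seeds()
  res <- run_gep(seeds, surrogate_evaluator(),
                 gep_config(n_extend_rounds = 40, n_fill_rounds = 10))
  expect_true(all(res$archive$valid))
  expect_true(all(res$archive$amplitude >= 10 & res$archive$amplitude <= 110))
  expect_true(all(res$archive$duration <= 2))
  expect_true(all(diff(res$history$area) >= 0))
  expect_gt(nrow(res$archive), nrow(seeds))
  expect_gt(max(res$history$area), 1)
  # extend rounds precede fill rounds
  expect_equal(res$history$strategy,
               c(rep("extend", 40), rep("fill", 10)))
})

test_that("the exploration loop replays identically under a fixed seed", {
  seeds <- local({ set.seed(20); surrogate_seeds() })
  set.seed(21)
  a <- run_gep(seeds, surrogate_evaluator(),
               gep_config(n_extend_rounds = 15, n_fill_rounds = 5))
  set.seed(21)
  b <- run_gep(seeds, surrogate_evaluator(),
               gep_config(n_extend_rounds = 15, n_fill_rounds = 5))
  expect_identical(a$archive$params, b$archive$params)
  expect_identical(a$history, b$history)
})

test_that("the CMA-ES core minimizes a separable quadratic within bounds", {
  set.seed(22)
  sphere <- function(x) sum((x - 0.3)^2)
  r <- triphasim:::cmaes_minimize(sphere, runif(8), 0.1, max_evals = 2000)
  expect_lt(r$best$value, 1e-6)
  expect_true(all(r$best$x >= 0 & r$best$x <= 1))
})

test_that("the seeder honors its published defaults and repairs bounds", {
  cfg <- seeder_config()
  expect_equal(cfg$sigma0, 0.005)
  expect_equal(cfg$targets[[1]][1], 30)
  # candidates are repaired onto [0, 1] before the objective ever sees them
  seen_bad <- FALSE
  fn <- function(x) {
    if (any(x < 0 | x > 1)) seen_bad <<- TRUE
    sum(x^2)
  }
  set.seed(23)
  triphasim:::cmaes_minimize(fn, rep(0.01, 5), 0.5, max_evals = 300)
  expect_false(seen_bad)
})

test_that("seed_search harvests every valid movement it encounters", {
  # surrogate runner: vector's first two coordinates set amplitude and
  # speed of a synthetic minimum-jerk trace
  topo <- build_topology("iaOnly14")
  runner <- function(v) {
    amp <- 120 * v[1]
    dur <- max(0.35, 1.2 - v[2])
    synth_trace(amplitude = amp, duration = dur)
  }
  set.seed(24)
  seeds <- seed_search(topo,
                       seeder_config(budget = 400, n_probe = 60,
                                     restarts = 1, n_target = 3),
                       runner = runner)
  expect_gte(nrow(seeds), 1)
  expect_true(all(seeds$valid))
  expect_true(all(seeds$provenance == "seed"))
  expect_true(all(vapply(seeds$params, length, 1L) == 14))
})
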