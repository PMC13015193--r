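#' Behavior-domain grid
#'
#' Regular grid over the (amplitude, maximal speed) behavior space used
#' to measure the behavior-domain area (number of cells containing at
#' least one valid movement) and mean density (valid movements per
#' occupied cell).
#'
#' @param cell_amplitude cell width (degrees).
#' @param cell_speed cell height (deg/s).
#' @export
behavior_grid <- function(cell_amplitude = 5, cell_speed = 10) {
  stopifnot(cell_amplitude > 0, cell_speed > 0)
  structure(list(cell_amplitude = cell_amplitude, cell_speed = cell_speed),
            class = "behavior_grid")
}

grid_cells <- function(archive, grid) {
  if (nrow(archive) == 0) {
    return(tibble::tibble(cx = integer(0), cy = integer(0),
                          count = integer(0)))
  }
  dplyr::count(
    tibble::tibble(cx = floor(archive$amplitude / grid$cell_amplitude),
                   cy = floor(archive$max_speed / grid$cell_speed)),
    .data$cx, .data$cy, name = "count"
  )
}

#' Behavior-domain area and density
#'
#' @param archive an archive tibble (needs `amplitude` and `max_speed`).
#' @param grid a [behavior_grid()].
#' @return A list: `area` (occupied cells), `density` (valid movements
#'   per occupied cell; 0 for an empty archive), `cells` (occupancy
#'   tibble `cx`, `cy`, `count`, cell indices = floor(value/cell size)).
#' @export
grid_metrics <- function(archive, grid = behavior_grid()) {
  cells <- grid_cells(archive, grid)
  area <- nrow(cells)
  list(area = area,
       density = if (area > 0) nrow(archive) / area else 0,
       cells = cells)
}

neighbor_offsets <- expand.grid(dx = -1:1, dy = -1:1)
neighbor_offsets <- neighbor_offsets[!(neighbor_offsets$dx == 0 &
                                         neighbor_offsets$dy == 0), ]
ortho_offsets <- data.frame(dx = c(-1, 1, 0, 0), dy = c(0, 0, -1, 1))

# Empty cells of the one-cell dilation ring (8-neighborhood) around the
# occupied region — the extend frontier.
frontier_cells <- function(cells) {
  if (nrow(cells) == 0) {
    return(tibble::tibble(cx = integer(0), cy = integer(0)))
  }
  occ <- paste(cells$cx, cells$cy)
  cand <- dplyr::distinct(tibble::tibble(
    cx = rep(cells$cx, each = nrow(neighbor_offsets)) + neighbor_offsets$dx,
    cy = rep(cells$cy, each = nrow(neighbor_offsets)) + neighbor_offsets$dy
  ))
  cand[!(paste(cand$cx, cand$cy) %in% occ), , drop = FALSE]
}

# Hole cells: empty cells with occupied cells on at least two of their
# four orthogonal sides (a solid rectangle of occupied cells has none,
# so fill falls back to extend there).
hole_cells <- function(cells) {
  cand <- frontier_cells(cells)
  if (nrow(cand) == 0) return(cand)
  occ <- paste(cells$cx, cells$cy)
  n_occ <- vapply(seq_len(nrow(cand)), function(i) {
    sum(paste(cand$cx[i] + ortho_offsets$dx,
              cand$cy[i] + ortho_offsets$dy) %in% occ)
  }, integer(1))
  cand[n_occ >= 2, , drop = FALSE]
}

#' Sample a self-generated goal in behavior space
#'
#' `extend` draws a uniform point inside an empty cell of the one-cell
#' dilation ring around the occupied region (pushing the domain
#' outwards); `fill` draws inside an empty cell having at least two
#' occupied neighbors (plugging holes), falling back to `extend` when no
#' such hole exists.
#'
#' @param archive non-empty archive tibble.
#' @param grid a [behavior_grid()].
#' @param strategy `"extend"` or `"fill"`.
#' @return `c(amplitude, speed)` goal point.
#' @export
sample_goal <- function(archive, grid = behavior_grid(),
                        strategy = c("extend", "fill")) {
  strategy <- match.arg(strategy)
  if (nrow(archive) == 0) stop("archive is empty", call. = FALSE)
  cells <- grid_cells(archive, grid)
  cand <- if (strategy == "fill") hole_cells(cells) else
    frontier_cells(cells)
  if (nrow(cand) == 0) cand <- frontier_cells(cells)
  pick <- cand[sample.int(nrow(cand), 1), ]
  c(amplitude = (pick$cx + runif(1)) * grid$cell_amplitude,
    speed = (pick$cy + runif(1)) * grid$cell_speed)
}

#' Nearest archived movement to a behavior goal
#'
#' Euclidean distance in the scaled behavior space
#' (`amplitude / amplitude_scale`, `speed / speed_scale`); ties are
#' broken deterministically by the lowest entry id.
#'
#' @param archive non-empty archive tibble with `id`, `amplitude`,
#'   `max_speed`.
#' @param goal `c(amplitude, speed)`.
#' @param amplitude_scale,speed_scale normalization constants (the
#'   amplitude validity ceiling and a typical fast-movement speed).
#' @return The nearest archive row (one-row tibble).
#' @export
nearest_valid <- function(archive, goal, amplitude_scale = 110,
                          speed_scale = 300) {
  stopifnot(nrow(archive) > 0)
  d <- ((archive$amplitude - goal[1]) / amplitude_scale)^2 +
    ((archive$max_speed - goal[2]) / speed_scale)^2
  ord <- order(d, archive$id)
  archive[ord[1], ]
}

#' Randomly perturb a command vector
#'
#' Adds independent zero-mean Gaussian noise (sd `sigma_explore`) to each
#' normalized coordinate and clips to `[0, 1]` — the random policy of the
#' goal exploration process.
#'
#' @param vector numeric command vector in `[0, 1]`.
#' @param sigma_explore per-coordinate noise sd, > 0.
#' @return Perturbed numeric vector in `[0, 1]`.
#' @export
perturb <- function(vector, sigma_explore = 0.02) {
  stopifnot(sigma_explore > 0)
  pmin(pmax(vector + rnorm(length(vector), 0, sigma_explore), 0), 1)
}

#' Seeder configuration (bounded CMA-ES)
#'
#' @param targets list of `c(amplitude, duration)` movement templates
#'   (degrees, s) whose tracking costs the seeder minimizes in turn; the
#'   defaults pair a relaxed slow target with a fast one so the harvested
#'   seeds span the speed axis of the behavior space.
#' @param sigma0 initial global step size of the evolution strategy
#'   (0.005 on the normalized `[0, 1]` scale).
#' @param budget total simulation budget (trials) across probes and
#'   restarts of all targets.
#' @param n_probe random probe trials (per target) used to pick the
#'   initial mean of the evolution strategy (the best-scoring probe).
#' @param restarts restarts from the probe-best mean per target; each
#'   restart raises the initial step size twentyfold (capped at 0.3), so
#'   the first restart honors `sigma0` and later ones escape flat
#'   plateaus.
#' @param n_target per-target quota: a target's search stops early once
#'   this many harvested seeds are relevant to it (peak speed at least
#'   half the target template's peak speed `1.875 A / D`), so finding
#'   easy slow movements cannot cut short the search for fast ones.
#' @export
seeder_config <- function(targets = list(c(30, 1), c(45, 0.6)),
                          sigma0 = 0.005, budget = 12000, n_probe = 400,
                          restarts = 3, n_target = 6) {
  stopifnot(sigma0 > 0, budget > n_probe * length(targets), restarts >= 1,
            n_probe >= 0, length(targets) >= 1)
  structure(list(targets = targets,
                 sigma0 = sigma0, budget = budget, n_probe = n_probe,
                 restarts = restarts, n_target = n_target),
            class = "seeder_config")
}

# Compact (mu/mu_w, lambda)-CMA-ES with cumulative step-size adaptation
# and rank-one + rank-mu covariance update; candidates are repaired onto
# [lower, upper] before evaluation.  `fn` is called once per candidate.
cmaes_minimize <- function(fn, x0, sigma0, lower = 0, upper = 1,
                           max_evals = 1000, stop_fn = NULL,
                           lambda = NULL) {
  n <- length(x0)
  if (is.null(lambda)) lambda <- 4 + floor(3 * log(n))
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  xmean <- x0
  sigma <- sigma0
  C <- diag(n); B <- diag(n); D <- rep(1, n)
  ps <- pc <- rep(0, n)
  eigen_due <- 0
  evals <- 0
  best <- list(x = x0, value = Inf)

  while (evals < max_evals) {
    if (evals >= eigen_due) {
      C <- (C + t(C)) / 2
      eig <- eigen(C, symmetric = TRUE)
      D <- sqrt(pmax(eig$values, 1e-20))
      B <- eig$vectors
      eigen_due <- evals + lambda / (c1 + cmu) / n / 10
    }
    arz <- matrix(rnorm(n * lambda), n, lambda)
    ary <- B %*% (D * arz)
    arx <- xmean + sigma * ary
    arx_rep <- pmin(pmax(arx, lower), upper)
    fit <- numeric(lambda)
    for (k in seq_len(lambda)) {
      fit[k] <- fn(arx_rep[, k])
      evals <- evals + 1
      if (!is.null(stop_fn) && stop_fn()) {
        return(list(best = best, evals = evals, sigma = sigma))
      }
    }
    idx <- order(fit)
    if (fit[idx[1]] < best$value) {
      best <- list(x = arx_rep[, idx[1]], value = fit[idx[1]])
    }
    sel <- idx[seq_len(mu)]
    # recombination on the repaired points
    xold <- xmean
    xmean <- drop(arx_rep[, sel, drop = FALSE] %*% w)
    yw <- (xmean - xold) / sigma
    Cinv_yw <- B %*% ((t(B) %*% yw) / D)
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * Cinv_yw
    hsig <- sqrt(sum(ps^2)) /
      sqrt(1 - (1 - cs)^(2 * evals / lambda)) / chiN < 1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * yw
    artmp <- (arx_rep[, sel, drop = FALSE] - xold) / sigma
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %*% t(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * artmp %*% (w * t(artmp))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    if (!is.finite(sigma) || sigma > 1) sigma <- 1
  }
  list(best = best, evals = evals, sigma = sigma)
}

new_archive <- function() {
  tibble::tibble(
    id = integer(0), parent = integer(0), provenance = character(0),
    amplitude = numeric(0), max_speed = numeric(0), duration = numeric(0),
    mse = numeric(0), penalty_prep = numeric(0), penalty_main = numeric(0),
    cost = numeric(0), valid = logical(0), reasons = character(0),
    triphasic = logical(0),
    ag1_time = numeric(0), ag1_amp = numeric(0), ant_time = numeric(0),
    ant_amp = numeric(0), ag2_time = numeric(0), ag2_amp = numeric(0),
    params = list()
  )
}

archive_row <- function(id, parent, provenance, metrics, params) {
  dplyr::bind_cols(
    tibble::tibble(id = id, parent = parent, provenance = provenance),
    metrics,
    tibble::tibble(params = list(as.numeric(params)))
  )
}

#' Default trial evaluator
#'
#' Builds the closure mapping a normalized command vector to its
#' one-row [evaluate_movement()] metrics, running the full closed-loop
#' simulation.  [run_gep()] and [seed_search()] accept any function with
#' this signature, which is how tests substitute cheap surrogates.
#'
#' @inheritParams run_trial
#' @return `function(vector) -> one-row metrics tibble`.
#' @export
trial_evaluator <- function(topology, plant = default_plant(),
                            sim = sim_config(), ranges = command_ranges(),
                            go_include_alpha = FALSE) {
  function(vector) {
    evaluate_movement(run_trial(vector, topology, plant, sim,
                                ranges = ranges,
                                go_include_alpha = go_include_alpha))
  }
}

#' Harvest seed movements with a bounded evolution strategy
#'
#' Runs CMA-ES (initial step size `sigma0`, exploration limits `[0, 1]`
#' on every normalized parameter) to minimize the tracking-plus-penalty
#' cost toward a minimum-jerk target template.  Every valid movement
#' encountered during the optimization — not only the optimum — is
#' harvested as a seed.  Returns an empty archive when the budget yields
#' no valid movement (the caller decides whether to retry).
#'
#' @param topology a [build_topology()] object.
#' @param seeder a [seeder_config()].
#' @param plant,sim,ranges passed to [run_trial()].
#' @param evaluator optional replacement for [trial_evaluator()]
#'   (used by tests); the CMA cost still needs traces, so a custom
#'   `runner` mapping vector -> trace can be supplied too.
#' @param runner optional `function(vector) -> trace`.
#' @return An archive tibble of seeds (provenance `"seed"`).
#' @export
seed_search <- function(topology, seeder = seeder_config(),
                        plant = default_plant(), sim = sim_config(),
                        ranges = command_ranges(),
                        evaluator = NULL, runner = NULL) {
  stopifnot(seeder$budget > 0)
  if (is.null(runner)) {
    runner <- function(vector) run_trial(vector, topology, plant, sim,
                                         ranges = ranges)
  }
  if (is.null(evaluator)) evaluator <- function(trace) evaluate_movement(trace)

  archive <- new_archive()
  harvest <- function(vec, trace) {
    m <- evaluator(trace)
    if (isTRUE(m$valid)) {
      archive <<- dplyr::bind_rows(
        archive,
        archive_row(nrow(archive) + 1L, NA_integer_, "seed", m, vec))
    }
    m
  }
  n <- topology$n_params
  n_targets <- length(seeder$targets)
  per_target <- ceiling(seeder$budget / n_targets)
  for (ti in seq_len(n_targets)) {
    tgt <- seeder$targets[[ti]]
    # a harvested seed is relevant to this target when its peak speed
    # reaches at least half the target template's (1.875 A / D)
    speed_floor <- 0.5 * 1.875 * tgt[1] / tgt[2]
    n_relevant <- 0L
    cma_cost <- function(vec) {
      trace <- runner(vec)
      if (isTRUE(attr(trace, "failed"))) return(1e6)
      n_before <- nrow(archive)
      m <- harvest(vec, trace)
      if (nrow(archive) > n_before &&
          isTRUE(m$max_speed >= speed_floor)) {
        n_relevant <<- n_relevant + 1L
      }
      sel <- trace$time >= 2
      desired <- trace$angle[1] + minjerk_template(tgt[1], tgt[2], 5,
                                                   trace$time)
      mean((trace$angle[sel] - desired[sel])^2) +
        m$penalty_prep + m$penalty_main
    }
    done <- function() n_relevant >= seeder$n_target
    # random probe: evaluate candidates, keep the best few (distinct
    # basins) as starting means for the restarts
    probe_x <- matrix(runif(n * max(1, seeder$n_probe)), nrow = n)
    probe_v <- rep(Inf, ncol(probe_x))
    for (i in seq_len(seeder$n_probe)) {
      if (done()) break
      probe_v[i] <- cma_cost(probe_x[, i])
    }
    top <- order(probe_v)
    per_restart <- ceiling((per_target - seeder$n_probe) / seeder$restarts)
    for (r in seq_len(seeder$restarts)) {
      if (done()) break
      # restarts escalate the step size twentyfold (capped) and double
      # the population (IPOP), each starting from a different top probe
      # candidate — the usual remedies when the search stalls on the
      # no-movement plateau or a poor starting basin
      sigma_r <- min(seeder$sigma0 * 20^(r - 1), 0.3)
      lambda_r <- (4 + floor(3 * log(n))) * 2^(max(0, r - 2))
      x0_r <- probe_x[, top[min(r, sum(is.finite(probe_v)))]]
      cmaes_minimize(cma_cost, x0_r, sigma_r, 0, 1,
                     max_evals = per_restart,
                     stop_fn = done, lambda = lambda_r)
    }
  }
  archive
}

#' Goal-exploration (rGEP) configuration
#'
#' @param n_extend_rounds,n_fill_rounds rounds of the two goal
#'   strategies (extend first, then fill).
#' @param max_goals_per_round cap on goals per round; the actual number
#'   scales with the length of the current domain boundary.
#' @param min_goals_per_round floor on goals per round.
#' @param sigma_explore per-coordinate perturbation sd on the normalized
#'   scale.
#' @export
gep_config <- function(n_extend_rounds = 300, n_fill_rounds = 50,
                       max_goals_per_round = 25, min_goals_per_round = 4,
                       sigma_explore = 0.02) {
  stopifnot(n_extend_rounds >= 0, n_fill_rounds >= 0, sigma_explore > 0)
  structure(list(n_extend_rounds = n_extend_rounds,
                 n_fill_rounds = n_fill_rounds,
                 max_goals_per_round = max_goals_per_round,
                 min_goals_per_round = min_goals_per_round,
                 sigma_explore = sigma_explore),
            class = "gep_config")
}

#' Run the random Goal Exploration Process
#'
#' Starting from seed movements, repeatedly: sample a goal on the
#' periphery of (extend) or inside (fill) the known behavior domain,
#' retrieve the archived movement nearest to the goal, replay its
#' parameters with added Gaussian noise, simulate, score, and store the
#' result if and only if it is a valid movement.  The number of goals
#' per round scales with the current boundary length (capped), so runs
#' per round grow with the domain.
#'
#' @param seeds archive tibble of valid seed movements (from
#'   [seed_search()] or a previous run).
#' @param evaluator `function(vector) -> metrics row`
#'   (see [trial_evaluator()]).
#' @param gep a [gep_config()].
#' @param grid a [behavior_grid()].
#' @return A `gep_result` list: `archive` (valid movements only, with
#'   `params` list-column), `history` (one row per round: `round`,
#'   `strategy`, `runs`, `n_valid`, `area`, `density`), `grid`, `config`.
#' @export
run_gep <- function(seeds, evaluator, gep = gep_config(),
                    grid = behavior_grid()) {
  stopifnot(nrow(seeds) >= 1, all(seeds$valid))
  archive <- seeds
  archive$id <- seq_len(nrow(archive))
  runs <- 0L
  history <- NULL
  strategies <- c(rep("extend", gep$n_extend_rounds),
                  rep("fill", gep$n_fill_rounds))
  for (round_i in seq_along(strategies)) {
    strategy <- strategies[round_i]
    ring <- frontier_cells(grid_cells(archive, grid))
    n_goals <- max(gep$min_goals_per_round,
                   min(gep$max_goals_per_round, nrow(ring)))
    for (g in seq_len(n_goals)) {
      goal <- sample_goal(archive, grid, strategy)
      parent <- nearest_valid(archive, goal)
      cand <- perturb(parent$params[[1]], gep$sigma_explore)
      metrics <- evaluator(cand)
      runs <- runs + 1L
      if (isTRUE(metrics$valid)) {
        archive <- dplyr::bind_rows(
          archive,
          archive_row(nrow(archive) + 1L, parent$id, strategy, metrics, cand))
      }
    }
    gm <- grid_metrics(archive, grid)
    history <- dplyr::bind_rows(
      history,
      tibble::tibble(round = round_i, strategy = strategy, runs = runs,
                     n_valid = nrow(archive), area = gm$area,
                     density = gm$density))
  }
  structure(list(archive = archive, history = history, grid = grid,
                 config = gep),
            class = "gep_result")
}

#' @export
print.gep_result <- function(x, ...) {
  gm <- grid_metrics(x$archive, x$grid)
  cat(sprintf(
    "<gep_result> %d valid movements, behavior-domain area %d cells, density %.2f\n",
    nrow(x$archive), gm$area, gm$density))
  invisible(x)
}
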