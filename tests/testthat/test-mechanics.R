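test_that("muscle length-angle map interpolates the published endpoint lengths", {
  expect_equal(muscle_length_of_angle(0, biceps), 0.34)
  expect_equal(muscle_length_of_angle(120, biceps), 0.25)
  expect_equal(muscle_length_of_angle(60, biceps), 0.295)
  expect_equal(muscle_length_of_angle(0, triceps), 0.275)
  expect_equal(muscle_length_of_angle(120, triceps), 0.345)
  expect_error(muscle_length_of_angle(-5, biceps), "angle")
  expect_error(muscle_length_of_angle(130, biceps), "angle")
})

test_that("stimulus-tension sigmoid anchors: rest silence, midpoint, saturation", {
  expect_equal(stimulus_tension(-60, biceps), 0)
  expect_equal(stimulus_tension(-60, triceps), 0)
  expect_equal(stimulus_tension(-20, biceps), 400 / 2 - 4.5)
  expect_equal(stimulus_tension(1e4, biceps), 400 - 4.5)
  expect_equal(stimulus_tension(1e4, triceps), 300 - 4)
  # monotone non-decreasing
  v <- seq(-80, 20, by = 0.5)
  expect_true(all(diff(stimulus_tension(v, biceps)) >= 0))
})

test_that("length-tension bell reproduces the tabulated working-range fractions", {
  expect_equal(length_tension(biceps$lt_resting_length, biceps), 1)
  expect_equal(length_tension(biceps$lt_resting_length + biceps$lt_width,
                              biceps), 0)
  expect_equal(length_tension(0.05, biceps), 0)  # far outside, clamped
  # biceps spans about 10-90% over 25-34 cm, triceps 90-100% over
  # 27.5-34.5 cm
  expect_lt(abs(length_tension(0.25, biceps) - 0.10), 0.04)
  expect_lt(abs(length_tension(0.34, biceps) - 0.90), 0.02)
  expect_gt(length_tension(0.275, triceps), 0.88)
  expect_gt(length_tension(0.345, triceps), 0.95)
})

test_that("a muscle at rest holds zero tension through hill_step", {
  st <- muscle_state(length = biceps$slack_length)
  for (i in 1:100) st <- hill_step(st, biceps$slack_length, 1e-3, biceps)
  expect_equal(st$tension, 0)
})

test_that("isometric tension converges to the closed-form fixed point", {
  # hold the muscle at a fixed length with constant membrane potential;
  # the linear ODE's steady state is (Kpe*dx + A) / (1 + Kpe/Kse)
  L <- 0.34
  v_m <- -20
  st <- muscle_state(length = L, membrane_potential = v_m)
  for (i in 1:3000) st <- hill_step(st, L, 1e-3, biceps)
  A <- muscle_activation(v_m, L, biceps)
  dx <- max(0, L - biceps$slack_length)
  kpe <- biceps$parallel_stiffness_Kpe
  kse <- biceps$serial_stiffness_Kse
  T_star <- (kpe * dx + A) / (1 + kpe / kse)
  expect_lt(abs(st$tension - T_star) / T_star, 1e-3)
})

test_that("ramp stretch tension follows the analytic linear-ODE solution", {
  # passive ramp from the slack length at speed v: with a = (Kse/B)*B*v,
  # b = (Kse/B)*Kpe*v, lambda = (Kse/B)*(1+Kpe/Kse), and T(0) = 0,
  # T(t) = (b/l) t + (a/l - b/l^2) (1 - exp(-l t))
  m <- biceps
  v <- 0.02
  dt <- 1e-4
  n <- 2000
  st <- muscle_state(length = m$slack_length)
  for (i in seq_len(n)) {
    st <- hill_step(st, m$slack_length + v * i * dt, dt, m)
  }
  k <- m$serial_stiffness_Kse / m$damping_B
  a <- k * m$damping_B * v
  b <- k * m$parallel_stiffness_Kpe * v
  l <- k * (1 + m$parallel_stiffness_Kpe / m$serial_stiffness_Kse)
  t_end <- n * dt
  T_exact <- (b / l) * t_end + (a / l - b / l^2) * (1 - exp(-l * t_end))
  expect_lt(abs(st$tension - T_exact) / T_exact, 1e-3)
})

test_that("tension never goes negative under arbitrary bounded length drives", {
  set.seed(1)
  for (rep in 1:5) {
    st <- muscle_state(length = 0.30)
    lens <- 0.30 + cumsum(rnorm(300, 0, 0.002))
    lens <- pmin(pmax(lens, 0.2), 0.4)
    for (L in lens) {
      st <- hill_step(st, L, 1e-3, biceps)
      expect_gte(st$tension, 0)
    }
  }
})

test_that("joint statics: zero or balanced tensions leave the angle unchanged", {
  plant <- default_plant()
  j <- joint_state(30, 0, plant$joint$inertia)
  f0 <- muscle_state(length = 0.3, tension = 0)
  j2 <- joint_step(j, f0, f0, 1e-3, moment_arm(biceps), moment_arm(triceps))
  expect_equal(j2$angle, 30)
  # torque balance: r_f * T_f = r_e * T_e
  r_f <- moment_arm(biceps); r_e <- moment_arm(triceps)
  tf <- muscle_state(length = 0.3, tension = 10)
  te <- muscle_state(length = 0.3, tension = 10 * r_f / r_e)
  j3 <- joint_step(j, tf, te, 1e-3, r_f, r_e)
  expect_equal(j3$angle, 30, tolerance = 1e-12)
})

test_that("constant net flexor torque matches undamped constant-acceleration kinematics", {
  plant <- default_plant()
  I <- plant$joint$inertia
  r_f <- moment_arm(biceps)
  tf <- muscle_state(length = 0.3, tension = 20)
  t0 <- muscle_state(length = 0.3, tension = 0)
  j <- joint_state(0, 0, I)
  dt <- 1e-4
  n <- 2000
  prev <- 0
  for (i in seq_len(n)) {
    j <- joint_step(j, tf, t0, dt, r_f, moment_arm(triceps), b_joint = 0)
    expect_gte(j$angle, prev)   # strictly non-decreasing toward the stop
    prev <- j$angle
  }
  alpha <- r_f * 20 / I * 180 / pi          # deg/s^2
  theta_exact <- 0.5 * alpha * (n * dt)^2
  expect_lt(abs(j$angle - theta_exact) / theta_exact, 1e-3)
})

test_that("hard stops clip the angle and zero the velocity", {
  plant <- default_plant()
  j <- joint_state(119.9, 500, plant$joint$inertia)
  tf <- muscle_state(length = 0.3, tension = 100)
  t0 <- muscle_state(length = 0.3, tension = 0)
  for (i in 1:50) {
    j <- joint_step(j, tf, t0, 1e-3, moment_arm(biceps), moment_arm(triceps))
  }
  expect_equal(j$angle, 120)
  expect_lte(j$angular_velocity, 0 + 1e-12)
})

test_that("forearm+hand inertia from the segment table is positive and fixed", {
  plant <- default_plant()
  expect_gt(plant$joint$inertia, 0)
  expect_equal(plant$joint$inertia,
               limb_inertia(plant$segments$forearm, plant$segments$hand))
  expect_equal(plant$segments$forearm$mass, 0.802)
  expect_equal(plant$segments$hand$mass, 0.966)
})

test_that("zero-activation plant is stationary at any starting angle", {
  topo <- build_topology("full50")
  for (a0 in c(0, 30, 60, 90, 120)) {
    tr <- run_trial(baseline_vector(topo), topo,
                    sim = sim_config(initial_angle = a0))
    expect_lt(max(abs(tr$angle - a0)), 1e-6)
  }
})
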