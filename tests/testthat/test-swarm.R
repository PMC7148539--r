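open_dom <- function(ext = c(250, 80, 80))
  domain_spec(lapply(ext, function(e) c(0, e)))

test_that("zero-variance agents are displaced by exactly v * dt", {
  f <- uniform_field(c(10, 0, 0))
  dom <- open_dom()
  sw <- new_swarm(20, c(5, 40, 40), variance_rate = 0)
  sw2 <- step_swarm(sw, f, dom, dt = 0.1)
  expect_equal(sw2$positions[, 1], rep(6, 20))
  expect_equal(sw2$positions[, 2], rep(40, 20))
  expect_equal(sw2$positions[, 3], rep(40, 20))
  expect_equal(sw2$time, 0.1)
})

test_that("pure-diffusion displacements have the Brownian variance", {
  # v = 0, sigma^2 = 2.5 mm^2/s per axis, T = 10 s: per-axis displacement
  # variance should be 25 mm^2 within 4 standard errors (SE = s2*sqrt(2/(N-1)))
  f <- uniform_field(c(0, 0, 0), ext = c(4000, 4000, 4000))
  dom <- domain_spec(lapply(1:3, function(i) c(0, 4000)),
                     face_bc = stats::setNames(
                       rep("project", 6),
                       c("x_min", "x_max", "y_min", "y_max", "z_min", "z_max")))
  n <- 10000L
  set.seed(2024)
  sw <- new_swarm(n, c(2000, 2000, 2000), variance_rate = 2.5)
  for (s in 1:100) sw <- step_swarm(sw, f, dom, dt = 0.1)
  target <- 2.5 * 10
  se <- target * sqrt(2 / (n - 1))
  for (j in 1:3) {
    disp <- sw$positions[, j] - 2000
    expect_lt(abs(var(disp) - target), 4 * se)
    expect_lt(abs(mean(disp)), 4 * sqrt(target / n))
  }
})

test_that("boundary handling clamps at project faces and flags exits", {
  dom <- open_dom(c(100, 80, 80))
  pos <- rbind(c(50, 40, -2),    # below project bottom -> clamp z to 0
               c(120, 40, 40),   # past downstream exit -> exited
               c(-5, 40, 40),    # past upstream exit -> exited
               c(50, 90, 40),    # past project side wall -> clamp y to 80
               c(50, 40, 40))    # inside -> untouched
  bc <- apply_boundaries(pos, dom)
  expect_equal(bc$positions[1, ], c(50, 40, 0))
  expect_equal(bc$positions[4, ], c(50, 80, 40))
  expect_equal(bc$positions[5, ], c(50, 40, 40))
  expect_equal(bc$exited, c(FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(bc$exit_face[2], "x_max")
  expect_equal(bc$exit_face[3], "x_min")
})

test_that("exit dominates projection when both faces are violated", {
  dom <- open_dom(c(100, 80, 80))
  # simultaneously past the project bottom and the downstream exit face
  bc <- apply_boundaries(rbind(c(130, 40, -10)), dom)
  expect_true(bc$exited[1])
  expect_equal(bc$exit_face[1], "x_max")
  # and with only project faces violated, the clamp is the nearest point
  bc2 <- apply_boundaries(rbind(c(50, 95, -10)), dom)
  expect_false(bc2$exited[1])
  expect_equal(bc2$positions[1, ], c(50, 80, 0))
})

test_that("fixed seed gives bit-identical runs; zero-diffusion ignores seed", {
  f <- uniform_field(c(10, 0, 0))
  dom <- open_dom()
  cfg <- sim_config(release_point = c(5, 40, 40), n_agents = 200,
                    variance_rate = 2.5, dt = 0.1, t_end = 10,
                    record_interval = 0.5)
  zn <- zone("goal", x_interval = c(100, 240))
  a <- simulate_swarm(cfg, f, dom, list(zn), seed = 12)
  b <- simulate_swarm(cfg, f, dom, list(zn), seed = 12)
  expect_identical(a$positions, b$positions)
  expect_identical(a$arrivals, b$arrivals)
  expect_identical(a$occupancy, b$occupancy)

  cfg0 <- sim_config(release_point = c(5, 40, 40), n_agents = 50,
                     variance_rate = 0, dt = 0.1, t_end = 10)
  r1 <- simulate_swarm(cfg0, f, dom, list(zn), seed = 1)
  r2 <- simulate_swarm(cfg0, f, dom, list(zn), seed = 999)
  expect_identical(r1$positions, r2$positions)
  expect_identical(r1$arrivals, r2$arrivals)
})

test_that("agents are conserved and contained at every step", {
  f <- uniform_field(c(25, 0, 0), ext = c(120, 80, 80))
  dom <- open_dom(c(120, 80, 80))
  n <- 400L
  set.seed(31)
  sw <- new_swarm(n, c(5, 40, 5), variance_rate = 10)
  for (s in 1:60) {
    sw <- step_swarm(sw, f, dom, dt = 0.1)
    expect_equal(sum(sw$active) + sum(!is.na(sw$exit_time)), n)
    act <- sw$positions[sw$active, , drop = FALSE]
    if (nrow(act) > 0) {
      expect_true(all(act[, 1] >= 0 & act[, 1] <= 120))
      expect_true(all(act[, 2] >= 0 & act[, 2] <= 80))
      expect_true(all(act[, 3] >= 0 & act[, 3] <= 80))
    }
    # exit_time set iff inactive
    expect_true(all(is.na(sw$exit_time) == sw$active))
  }
  expect_gt(sum(!is.na(sw$exit_time)), 0)  # plug flow must flush some agents
})

test_that("deterministic transit: uniform flow gives exact arrival times", {
  f <- uniform_field(c(10, 0, 0))
  dom <- open_dom()
  cfg <- sim_config(release_point = c(0, 40, 40), n_agents = 100,
                    variance_rate = 0, dt = 0.1, t_end = 60)
  zn <- zone("goal", x_interval = c(100, 240))
  res <- simulate_swarm(cfg, f, dom, list(zn), seed = 4)
  at <- first_arrival_times(res, "goal")
  expect_length(at, 100)
  expect_true(all(at == 10))
  st <- moment_stats(at)
  expect_equal(st$std, 0)
  expect_equal(st$mean, 10)
  expect_equal(res$termination, "all_done")
})

test_that("a zone upstream of a pure-drift release records no arrivals", {
  f <- uniform_field(c(10, 0, 0))
  dom <- open_dom()
  cfg <- sim_config(release_point = c(100, 40, 40), n_agents = 20,
                    variance_rate = 0, dt = 0.1, t_end = 5)
  zn <- zone("upstream", x_interval = c(10, 50))
  res <- simulate_swarm(cfg, f, dom, list(zn), seed = 1)
  expect_length(first_arrival_times(res, "upstream"), 0)
})

test_that("a single zero-variance agent follows forward-Euler advection", {
  dom <- open_dom(c(100, 100, 100))
  axes <- list(seq(0, 100, 25), seq(0, 100, 25), seq(0, 100, 25))
  af <- affine_field(axes, list(c(5, 0.1, 0, 0), c(0, 0, 0, 0),
                                c(2, 0, 0, 0)))
  cfg <- sim_config(release_point = c(10, 50, 10), n_agents = 1,
                    variance_rate = 0, dt = 0.2, t_end = 4,
                    record_interval = 0.2)
  res <- simulate_swarm(cfg, af$field, dom, zones = list(), seed = 1,
                        track = 1)
  # oracle: explicit Euler of dx/dt = v(x)
  p <- c(10, 50, 10)
  euler <- matrix(NA_real_, 21, 3)
  euler[1, ] <- p
  for (s in 1:20) {
    v <- c(af$f[[1]](p), af$f[[2]](p), af$f[[3]](p))
    p <- p + v * 0.2
    euler[s + 1, ] <- p
  }
  expect_equal(res$trajectories[, , 1], euler, tolerance = 1e-12)
})

test_that("first-passage times follow the inverse-Gaussian law", {
  # constant drift u = 10 mm/s, sigma^2 = 2.5 mm^2/s, barrier at L = 100 mm:
  # IG with mean L/u = 10 s and shape L^2/sigma^2 = 4000
  f <- uniform_field(c(10, 0, 0), ext = c(400, 400, 400))
  dom <- domain_spec(lapply(1:3, function(i) c(0, 400)),
                     face_bc = stats::setNames(
                       rep("project", 6),
                       c("x_min", "x_max", "y_min", "y_max", "z_min", "z_max")))
  n <- 4000L
  cfg <- sim_config(release_point = c(50, 200, 200), n_agents = n,
                    variance_rate = 2.5, dt = 0.01, t_end = 20,
                    record_interval = 1)
  zn <- zone("barrier", x_interval = c(150, 390))
  res <- simulate_swarm(cfg, f, dom, list(zn), seed = 60)
  at <- first_arrival_times(res, "barrier")
  expect_length(at, n)

  mu <- 10; lambda <- 100^2 / 2.5
  sd_ig <- sqrt(mu^3 / lambda)
  expect_lt(abs(mean(at) - mu), 3 * sd_ig / sqrt(n))
  # crossings are observed at step resolution, which misses within-step
  # excursions past the barrier; the closed form for discretely monitored
  # crossing shifts the barrier by zeta(1/2)/sqrt(2*pi) * sigma * sqrt(dt)
  # (continuity correction), giving the corrected IG oracle
  L_eff <- 100 + 0.5826 * sqrt(2.5) * sqrt(0.01)
  ks <- suppressWarnings(
    stats::ks.test(at, function(q) pinvgauss(q, L_eff / 10, L_eff^2 / 2.5)))
  expect_gt(ks$p.value, 0.01)
})

test_that("release point must lie inside the domain", {
  f <- uniform_field()
  dom <- open_dom()
  cfg <- sim_config(release_point = c(-5, 40, 40), n_agents = 10,
                    t_end = 1)
  expect_error(simulate_swarm(cfg, f, dom), class = "zoodrift_invalid_argument")
})

test_that("sim_config validates its invariants", {
  expect_error(sim_config(c(0, 0, 0), dt = 0), class = "zoodrift_invalid_argument")
  expect_error(sim_config(c(0, 0, 0), n_agents = 0),
               class = "zoodrift_invalid_argument")
  expect_error(sim_config(c(0, 0, 0), variance_rate = -1),
               class = "zoodrift_invalid_argument")
  expect_error(sim_config(c(0, 0, 0), dt = 0.1, record_interval = 0.25),
               class = "zoodrift_invalid_argument")
})
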