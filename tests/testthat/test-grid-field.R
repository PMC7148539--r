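test_that("field construction enforces grid invariants", {
  ax <- list(0:2, 0:2, 0:2)
  ok <- grid_velocity_field(ax, list(array(1, c(3, 3, 3)),
                                     array(0, c(3, 3, 3)),
                                     array(0, c(3, 3, 3))))
  expect_s3_class(ok, "grid_field")
  expect_equal(ok$ndim, 3L)

  expect_error(grid_velocity_field(list(c(0, 1, 1), 0:2, 0:2),
                                   list(array(0, c(3, 3, 3)),
                                        array(0, c(3, 3, 3)),
                                        array(0, c(3, 3, 3)))),
               class = "zoodrift_invalid_field")
  expect_error(grid_velocity_field(ax, list(array(0, c(3, 3, 2)),
                                            array(0, c(3, 3, 3)),
                                            array(0, c(3, 3, 3)))),
               class = "zoodrift_invalid_field")
  expect_error(grid_velocity_field(list(0, 0:2, 0:2),
                                   list(array(0, c(1, 3, 3)),
                                        array(0, c(1, 3, 3)),
                                        array(0, c(1, 3, 3)))),
               class = "zoodrift_invalid_field")
})

test_that("interpolation reproduces node values and constant fields exactly", {
  set.seed(11)
  axes <- list(c(0, 1, 3, 7), c(-2, 0, 5), c(0, 4))
  comps <- lapply(1:3, function(k) array(rnorm(24), dim = c(4, 3, 2)))
  f <- grid_velocity_field(axes, comps)
  nodes <- as.matrix(expand.grid(axes))
  v <- interpolate_velocity(f, nodes)
  for (k in 1:3)
    expect_equal(unname(v[, k]), as.vector(comps[[k]]), tolerance = 1e-14)

  cf <- uniform_field(c(10, 0, 0))
  expect_equal(unname(interpolate_velocity(cf, c(123.4, 17, 9.99))),
               c(10, 0, 0))
})

test_that("interpolation is exact for affine velocity fields", {
  axes <- list(c(0, 2, 5, 10), c(0, 3, 8), c(0, 1, 4))
  af <- affine_field(axes, list(c(1, 0.5, -0.2, 2),
                                c(-3, 0, 1, 0.1),
                                c(0.7, -1, 0.3, 0)))
  set.seed(42)
  pts <- cbind(runif(50, 0, 10), runif(50, 0, 8), runif(50, 0, 4))
  v <- interpolate_velocity(af$field, pts)
  for (k in 1:3) {
    want <- apply(pts, 1, af$f[[k]])
    expect_equal(unname(v[, k]), want, tolerance = 1e-12)
  }
})

test_that("interpolation matches a brute-force oracle on random grids", {
  set.seed(99)
  for (rep in 1:100) {
    ndim <- sample(2:3, 1)
    axes <- random_axes(ndim)
    shape <- lengths(axes)
    comps <- lapply(seq_len(ndim), function(k) array(rnorm(prod(shape)), shape))
    f <- grid_velocity_field(axes, comps)
    lo <- vapply(axes, min, 0); hi <- vapply(axes, max, 0)
    p <- lo + runif(ndim) * (hi - lo)
    got <- interpolate_velocity(f, p)
    want <- oracle_interp(axes, comps, p)
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
})

test_that("out-of-box queries are clamped to the boundary value", {
  axes <- list(c(0, 10), c(0, 10), c(0, 10))
  af <- affine_field(axes, list(c(0, 1, 0, 0), c(0, 0, 0, 0), c(0, 0, 0, 0)))
  # query far outside: value equals the clamped boundary point's value
  expect_equal(unname(interpolate_velocity(af$field, c(50, 5, 5))[1]), 10)
  expect_equal(unname(interpolate_velocity(af$field, c(-50, 5, 5))[1]), 0)
})

test_that("dimension mismatches and bad queries raise classed errors", {
  f <- uniform_field()
  expect_error(interpolate_velocity(f, c(1, 2)), class = "zoodrift_dimension")
  expect_error(interpolate_velocity(f, c(1, NA, 3)), class = "zoodrift_numeric")
  expect_error(interpolate_velocity(list(), c(1, 2, 3)),
               class = "zoodrift_invalid_field")
})

test_that("time-varying fields interpolate linearly between snapshots", {
  axes <- list(0:1 * 10, 0:1 * 10, 0:1 * 10)
  snap <- function(u) list(array(u, c(2, 2, 2)), array(0, c(2, 2, 2)),
                           array(0, c(2, 2, 2)))
  f <- grid_velocity_field(axes, list(snap(0), snap(10)), time_points = c(0, 2))
  p <- c(5, 5, 5)
  expect_equal(unname(interpolate_velocity(f, p, time = 1)[1]), 5)
  expect_equal(unname(interpolate_velocity(f, p, time = 0.5)[1]), 2.5)
  # constant extrapolation outside the snapshot range
  expect_equal(unname(interpolate_velocity(f, p, time = -3)[1]), 0)
  expect_equal(unname(interpolate_velocity(f, p, time = 99)[1]), 10)
  expect_error(interpolate_velocity(f, p), class = "zoodrift_invalid_argument")
})

test_that("tiling: identity, constant fields, and periodic extension", {
  f <- uniform_field(c(3, -1, 0.5), ext = c(10, 10, 10))
  expect_equal(tile_flow(f, 1, 1), f)

  t32 <- tile_flow(f, 3, 2)
  expect_equal(range(t32$axes$x), c(0, 30))
  expect_equal(range(t32$axes$y), c(0, 20))
  expect_equal(unname(interpolate_velocity(t32, c(27, 13, 4))),
               c(3, -1, 0.5))

  # one full sine period in x: tiled field repeats exactly at x + L
  x <- seq(0, 2 * pi, length.out = 9)
  axes <- list(x, c(0, 1), c(0, 1))
  u <- array(rep(sin(x), times = 4), dim = c(9, 2, 2))
  zero <- array(0, dim = c(9, 2, 2))
  f2 <- grid_velocity_field(axes, list(u, zero, zero))
  t2 <- tile_flow(f2, 2, 1)
  for (i in seq_along(x)) {
    for (yz in list(c(0, 0), c(1, 1))) {
      a <- interpolate_velocity(t2, c(x[i], yz[1], yz[2]))
      b <- interpolate_velocity(t2, c(x[i] + 2 * pi, yz[1], yz[2]))
      expect_equal(a, b, tolerance = 1e-12)
    }
  }

  # interpolated (off-node) periodicity too
  set.seed(5)
  for (q in runif(10, 0, 2 * pi)) {
    a <- interpolate_velocity(t2, c(q, 0.5, 0.5))
    b <- interpolate_velocity(t2, c(q + 2 * pi, 0.5, 0.5))
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("tiling rejects bad counts and aperiodic fields", {
  f <- uniform_field()
  expect_error(tile_flow(f, 0, 1), class = "zoodrift_invalid_argument")
  x <- c(0, 1, 2)
  u <- array(rep(c(0, 1, 5), times = 4), dim = c(3, 2, 2))  # ends differ
  zero <- array(0, dim = c(3, 2, 2))
  f2 <- grid_velocity_field(list(x, c(0, 1), c(0, 1)), list(u, zero, zero))
  expect_error(tile_flow(f2, 2, 1), class = "zoodrift_periodicity")
  expect_s3_class(tile_flow(f2, 2, 1, check = FALSE), "grid_field")
})

test_that("parabolic channel profile has no-slip ends and the stated vertex", {
  dom <- domain_spec(list(c(0, 320), c(0, 80), c(0, 80)))
  f <- parabolic_channel_field(44.4, 80, dom)
  u_at <- function(z) unname(interpolate_velocity(f, c(160, 40, z))[1])
  expect_equal(u_at(40), 44.4)           # vertex at mid-height
  expect_equal(u_at(0), 0)               # no-slip bottom
  expect_equal(u_at(80), 0)              # no-slip top
  expect_equal(u_at(20), 0.75 * 44.4)    # quarter height: 4 * 1/4 * 3/4
  expect_error(parabolic_channel_field(44.4, -1, dom),
               class = "zoodrift_invalid_argument")
  expect_error(parabolic_channel_field(-1, 80, dom),
               class = "zoodrift_invalid_argument")
})

test_that("domain_spec validates bounds and face tags", {
  expect_error(domain_spec(list(c(1, 0), c(0, 1), c(0, 1))),
               class = "zoodrift_invalid_argument")
  d <- domain_spec(list(c(0, 1), c(0, 1), c(0, 1)))
  expect_equal(unname(d$face_bc[c("x_min", "x_max")]), c("exit", "exit"))
  expect_equal(unname(d$face_bc["z_max"]), "project")
  expect_error(domain_spec(list(c(0, 1), c(0, 1), c(0, 1)),
                           face_bc = c(x_min = "banana")),
               class = "zoodrift_invalid_argument")
})
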