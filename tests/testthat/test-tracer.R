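test_that("a uniform field carries the particle on a horizontal line to the East", {
  f <- uniform_field(0.01)
  tr <- trace_particle(f, particle(5), c(-200, 12))
  expect_equal(tr$status, "EXITED")
  expect_equal(tr$exit_port, "E")
  expect_lt(max(abs(tr$path$y - 12)), 1e-9)
  expect_equal(utils::tail(tr$path$x, 1), f$geom$extent)
})

test_that("release from rest follows the closed-form drag relaxation", {
  U <- 0.01
  f <- uniform_field(U)
  p <- particle(10)  # tau ~ 2.9e-6 s
  tau <- relaxation_time(p)
  tr <- trace_particle(f, p, c(-200, 0),
                       controls = trace_controls(release = "rest"))
  ## position integral of v(t) = U (1 - exp(-t/tau)), in um
  xa <- -200 + (U * (tr$path$t - tau * (1 - exp(-tr$path$t / tau)))) * 1e6
  expect_equal(tr$path$x, xa, tolerance = 1e-9)
  ## released at fluid velocity there is no transient at all
  tr2 <- trace_particle(f, p, c(-200, 0))
  expect_equal(tr2$path$x, -200 + U * 1e6 * tr2$path$t, tolerance = 1e-12)
})

test_that("small particles follow streamlines through the junction", {
  skip_if_not_installed("deSolve")
  f <- solve_flow(std_geom(), case1_rates(), n_across = 40)
  seed <- c(-250, 10)
  tr <- trace_particle(f, particle(1), seed)
  expect_equal(tr$status, "EXITED")
  ## independent streamline integration of dx/dt = u(x) with lsoda
  rhs <- function(t, y, parms) {
    ## hold the streamline once it leaves through a port
    if (point_region(f$geom, y[1], y[2]) == "outside") return(list(c(0, 0)))
    uv <- sample_velocity(f, y[1], y[2])
    list(c(uv[1], uv[2]) * 1e6)   # um/s
  }
  tmax <- utils::tail(tr$path$t, 1)
  sl <- deSolve::lsoda(seed, seq(0, tmax, length.out = 200), rhs, NULL,
                       rtol = 1e-9, atol = 1e-9)
  ## compare the lateral coordinate where both cross the exit port plane
  exit_x_tr <- approx(tr$path$y, tr$path$x, xout = 248)$y
  exit_x_sl <- approx(sl[, 3], sl[, 2], xout = 248)$y
  expect_lt(abs(exit_x_tr - exit_x_sl), 0.002 * 100)
})

test_that("Poiseuille transport preserves the lateral position", {
  f <- poiseuille_field(40)
  for (y0 in c(-30, 0, 25)) {
    tr <- trace_particle(f, particle(2), c(-250, y0))
    expect_equal(tr$exit_port, "E")
    expect_lt(abs(utils::tail(tr$path$y, 1) - y0), 0.005 * 100)
  }
})

test_that("finite particle size excludes trajectories from the wall zone", {
  f <- solve_flow(std_geom(), case1_rates(), n_across = 40)
  p <- particle(12)
  trs <- trace_release(f, p, "W", 10)
  for (tr in trs) {
    d <- wall_distance(f$geom, tr$path$x, tr$path$y)
    expect_gte(min(d), p$diameter / 2 - 1e-6)
    if (tr$status == "FROZEN")
      expect_equal(d[length(d)], p$diameter / 2, tolerance = 1e-6)
  }
})

test_that("the particle-density default is immaterial at these Stokes numbers", {
  f <- solve_flow(std_geom(), case1_rates(), n_across = 24)
  t1 <- trace_particle(f, particle(10, density = 1050), c(-250, 10))
  t2 <- trace_particle(f, particle(10, density = 2000), c(-250, 10))
  expect_equal(utils::tail(t1$path$y, 1), utils::tail(t2$path$y, 1),
               tolerance = 1e-4)
})

test_that("tracing is deterministic and mirror covariant", {
  f <- solve_flow(std_geom(), case1_rates(), n_across = 24)
  a <- trace_particle(f, particle(5), c(-250, 7))
  b <- trace_particle(f, particle(5), c(-250, 7))
  expect_identical(a$path, b$path)
  ## mirror the case about y = 0 (swap N and S rates) and the seed
  fm <- solve_flow(std_geom(), port_rates(1, 0.3, 0.4, -1.7), n_across = 24)
  m <- trace_particle(fm, particle(5), c(-250, -7))
  expect_equal(m$path$x, a$path$x, tolerance = 1e-9)
  expect_equal(m$path$y, -a$path$y, tolerance = 1e-9)
})

test_that("inlet seeding spans the eroded port uniformly", {
  g <- std_geom()
  s <- seed_inlet(g, "W", 10, particle(10))
  expect_equal(nrow(s), 10)
  expect_equal(range(s[, "y"]), c(-45, 45))
  expect_equal(diff(s[, "y"]), rep(10, 9))
  expect_equal(s[, "y"], -rev(s[, "y"]))      # symmetric about the midline
  expect_true(all(s[, "x"] == -g$extent))
  expect_equal(seed_inlet(g, "N", 1, particle(4))[1, ], c(x = 0, y = 250))
  expect_error(seed_inlet(g, "W", 10, particle(120)), "span")
  expect_error(seed_inlet(g, "Z", 10), "port")
})

test_that("a release returns one trajectory per seed, in order", {
  f <- solve_flow(std_geom(), case1_rates(), n_across = 24)
  trs <- trace_release(f, particle(8), "W", 10)
  expect_length(trs, 10)
  seeds <- t(vapply(trs, function(t) unname(t$seed), numeric(2)))
  expect_equal(seeds, unname(seed_inlet(f$geom, "W", 10, particle(8))))
  ## the only outlet in this flow case is N
  ex <- vapply(trs, function(t) t$status, "")
  expect_true(all(vapply(trs[ex == "EXITED"], function(t) t$exit_port, "") == "N"))
})

test_that("seeds outside the eroded domain are rejected", {
  f <- poiseuille_field(24)
  expect_error(trace_particle(f, particle(10), c(-250, 47)), "eroded")
  expect_error(trace_particle(f, particle(10), c(0, 300)), "eroded")
})

test_that("trajectories serialize to annotated CSV", {
  f <- uniform_field()
  tr <- trace_particle(f, particle(5), c(-200, 0))
  tmp <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, tmp)
  lines <- readLines(tmp)
  expect_match(lines[1], "Dp_um=5")
  df <- utils::read.csv(tmp, comment.char = "#")
  expect_equal(names(df), c("t_s", "x_um", "y_um"))
  expect_equal(nrow(df), nrow(tr$path))
})
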