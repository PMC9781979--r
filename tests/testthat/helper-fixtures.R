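## Shared small fixtures. Flow solves cache their factorization per grid
## resolution, so repeated solve_flow() calls at the same n_across are cheap
## after the first.

std_geom <- function() cross_geometry(100)

poiseuille_field <- function(n = 40) {
  solve_flow(std_geom(), port_rates(1, 0, -1, 0), n_across = n)
}

case1_rates <- function() port_rates(1, -1.7, 0.4, 0.3)

## a synthetic uniform flow field (u = u0 m/s, v = 0) on the cross geometry,
## bypassing the solver; for tracer unit tests with a known exact solution
uniform_field <- function(u0 = 0.01, geom = std_geom(), n = 20) {
  h <- geom$width / n
  N <- round(2 * geom$extent / h)
  coords <- (0:N) * h - geom$extent
  U <- matrix(u0, N + 1, N + 1)
  structure(list(geom = geom, rates = port_rates(1, 0, -1, 0),
                 fluid = fluid_properties(), n_across = n, h = h,
                 x_nodes = coords, y_nodes = coords,
                 U = U, V = U * 0, mac = NULL, cs_key = NA, mask = NULL),
            class = "flow_field")
}

## straight synthetic trajectory along y = y0 from the West port to the East
## port, unevenly sampled in time
straight_traj <- function(y0 = 5, geom = std_geom(), npts = 57) {
  s <- seq(0, 1, length.out = npts)^1.3
  x <- -geom$extent + s * 2 * geom$extent
  structure(list(path = data.frame(t = s * 0.05, x = x, y = rep(y0, npts)),
                 status = "EXITED", exit_port = "E",
                 seed = c(x0 = -geom$extent, y0 = y0),
                 particle = particle(5), tau = 1e-6),
            class = "trajectory")
}
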