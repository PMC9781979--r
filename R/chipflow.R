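## Monolithic whole-chip simulation: rasterize the full channel network
## onto one masked grid, solve Stokes flow over it, and trace particles
## end to end. This is the reference route against which unit-wise
## composition is checked; it shares the validated discretization and
## tracer with the single-intersection path but involves no decomposition.

#' Solve the full-chip laminar velocity field monolithically
#'
#' Rasterizes every channel segment of an equal-width orthogonal chip onto
#' a single uniform MAC grid, prescribes parabolic profiles at the boundary
#' terminals, and solves one Stokes system over the whole domain.
#'
#' @param chip A [chip_graph()] (all edges must share one width, and node
#'   coordinates must fall on the grid implied by `width / n_across`).
#' @param fluid A [fluid_properties()].
#' @param n_across Cells across the channel width.
#' @return An object of class `chip_flow_field` with node-centered
#'   velocities (m/s), wall segments, terminal port segments and grid
#'   metadata, traceable with [trace_particle_chip()].
#' @export
solve_chip_flow_full <- function(chip, fluid = fluid_properties(),
                                 n_across = 24) {
  w <- unique(chip$edges$width)
  if (length(w) > 1) stop("monolithic solve requires a single channel width")
  h <- w / n_across
  ids <- chip$nodes$id
  npos <- function(id) c(chip$nodes$x[ids == id], chip$nodes$y[ids == id])
  ## grid bounding box aligned to h
  xs <- range(chip$nodes$x); ys <- range(chip$nodes$y)
  gx0 <- xs[1] - w / 2; gy0 <- ys[1] - w / 2
  snap <- function(v) round(v / h)
  Nx <- snap(xs[2] + w / 2 - gx0); Ny <- snap(ys[2] + w / 2 - gy0)
  mask <- matrix(FALSE, Nx, Ny)
  cellc <- function(i) gx0 + (i - 0.5) * h
  ## rasterize each edge as a rectangle of half-width w/2 about its centerline
  xc <- gx0 + (seq_len(Nx) - 0.5) * h
  yc <- gy0 + (seq_len(Ny) - 0.5) * h
  for (k in seq_len(nrow(chip$edges))) {
    a <- npos(chip$edges$from[k]); b <- npos(chip$edges$to[k])
    lo <- pmin(a, b) - c(w / 2, w / 2) * (abs(a - b) < 1e-9)
    hi <- pmax(a, b) + c(w / 2, w / 2) * (abs(a - b) < 1e-9)
    ## along the channel the rectangle runs terminal-to-terminal
    sel_x <- xc > lo[1] & xc < hi[1]
    sel_y <- yc > lo[2] & yc < hi[2]
    mask[sel_x, sel_y] <- TRUE
  }
  ## terminal port faces
  port_faces <- list(); port_labels <- character(0)
  ports_mat <- NULL
  for (i in seq_len(nrow(chip$boundary))) {
    nd <- chip$boundary$node[i]
    k <- which(chip$edges$from == nd | chip$edges$to == nd)[1]
    othr <- setdiff(c(chip$edges$from[k], chip$edges$to[k]), nd)
    d <- npos(othr) - npos(nd); d <- d / sqrt(sum(d^2))   # into the chip
    P <- npos(nd)
    if (abs(d[1]) > 0.5) {              # horizontal channel, u-port
      I <- snap(P[1] - gx0)
      jr <- snap(P[2] - w / 2 - gy0) + seq_len(n_across)
      port_faces[[length(port_faces) + 1]] <-
        list(axis = "u", idx = cbind(I + 1L, jr), inflow_sign = sign(d[1]))
      seg <- c(P[1], P[2] - w / 2, P[1], P[2] + w / 2)
    } else {                            # vertical channel, v-port
      J <- snap(P[2] - gy0)
      ir <- snap(P[1] - w / 2 - gx0) + seq_len(n_across)
      port_faces[[length(port_faces) + 1]] <-
        list(axis = "v", idx = cbind(ir, J + 1L), inflow_sign = sign(d[2]))
      seg <- c(P[1] - w / 2, P[2], P[1] + w / 2, P[2])
    }
    port_labels <- c(port_labels, nd)
    ports_mat <- rbind(ports_mat, c(seg, -d))   # outward normal
  }
  sys <- .stokes_system(mask, port_faces)
  prof <- .port_profile(n_across, 1)
  fv <- numeric(sys$nfv); off <- 0L
  for (i in seq_len(nrow(chip$boundary))) {
    fv[off + seq_len(n_across)] <- port_faces[[i]]$inflow_sign * prof *
      chip$boundary$rate[i]
    off <- off + n_across
  }
  mac <- .stokes_apply(sys, fv)
  nodes <- .mac_to_nodes(sys, mac)
  ## wall segments: boundary faces between fluid and non-fluid, minus ports
  walls <- .mask_wall_segments(mask, gx0, gy0, h, port_faces)
  structure(list(chip = chip, h = h, gx0 = gx0, gy0 = gy0,
                 x_nodes = gx0 + (0:Nx) * h, y_nodes = gy0 + (0:Ny) * h,
                 U = nodes$U * 0.01, V = nodes$V * 0.01,
                 mask = mask, walls = walls,
                 ports = ports_mat, port_labels = port_labels,
                 width = w, n_across = n_across, fluid = fluid),
            class = "chip_flow_field")
}

## unit-length wall faces of a mask (um), excluding prescribed port faces
.mask_wall_segments <- function(mask, gx0, gy0, h, port_faces) {
  Nx <- nrow(mask); Ny <- ncol(mask)
  pad <- matrix(FALSE, Nx + 2, Ny + 2); pad[2:(Nx + 1), 2:(Ny + 1)] <- mask
  segs <- list()
  up <- matrix(FALSE, Nx + 1, Ny); vp <- matrix(FALSE, Nx, Ny + 1)
  for (pf in port_faces)
    if (pf$axis == "u") up[pf$idx] <- TRUE else vp[pf$idx] <- TRUE
  ## vertical faces (walls where exactly one of the two x-neighbours is fluid)
  for (I in 0:Nx) for (j in 1:Ny) {
    lf <- pad[I + 1, j + 1]; rf <- pad[I + 2, j + 1]
    if (xor(lf, rf) && !up[I + 1, j])
      segs[[length(segs) + 1]] <- c(gx0 + I * h, gy0 + (j - 1) * h,
                                    gx0 + I * h, gy0 + j * h)
  }
  for (i in 1:Nx) for (J in 0:Ny) {
    bf <- pad[i + 1, J + 1]; tf <- pad[i + 1, J + 2]
    if (xor(bf, tf) && !vp[i, J + 1])
      segs[[length(segs) + 1]] <- c(gx0 + (i - 1) * h, gy0 + J * h,
                                    gx0 + i * h, gy0 + J * h)
  }
  do.call(rbind, segs)
}

#' Trace a particle through a monolithic chip flow field
#'
#' Same drag model, integrator and freeze rule as [trace_particle()], on
#' the whole-chip grid; the trace ends when the particle crosses a terminal
#' port plane.
#'
#' @param field A [solve_chip_flow_full()] result.
#' @param p A [particle()].
#' @param seed Release position (x, y) in um.
#' @param fluid A [fluid_properties()].
#' @param controls A [trace_controls()].
#' @return A `trajectory` whose `exit_port` is the terminal node id.
#' @export
trace_particle_chip <- function(field, p, seed, fluid = fluid_properties(),
                                controls = trace_controls()) {
  q <- abs(field$chip$boundary$rate)
  qmin <- min(q[q > 1e-12])
  L <- (diff(range(field$x_nodes)) + diff(range(field$y_nodes))) * 1e-6
  max_time <- if (is.null(controls$max_time)) 50 * L / (qmin * 0.01)
              else controls$max_time
  res <- trace_particle_cpp(field$U, field$V, field$x_nodes[1],
                            field$y_nodes[1], field$h,
                            field$walls, field$ports,
                            seed[1], seed[2], p$diameter, p$density,
                            fluid$viscosity, controls$step_frac, max_time,
                            max(q) * 0.01, identical(controls$release, "rest"))
  status <- c("EXITED", "FROZEN", "MAX_TIME")[res$status + 1]
  structure(list(path = data.frame(t = res$t, x = res$x, y = res$y),
                 status = status,
                 exit_port = if (res$exit_port > 0)
                   field$port_labels[res$exit_port] else NA_character_,
                 seed = c(x0 = seed[1], y0 = seed[2]),
                 particle = p, tau = res$tau),
            class = "trajectory")
}
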