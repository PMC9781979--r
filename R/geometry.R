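#' @useDynLib crossflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

PORTS <- c("W", "N", "E", "S")

#' Four-port cross-junction geometry
#'
#' Builds the "+"-shaped planar domain of a critical intersection: a central
#' junction square of side `width` with four rectangular arms of length
#' `arm_length` meeting at right angles. Coordinates are junction-centered
#' (micrometres), x increasing eastward and y northward, so the junction
#' square spans `[-width/2, width/2]^2` and, e.g., the West port segment lies
#' at `x = -(width/2 + arm_length)`.
#'
#' @param width Common channel width W in micrometres. Generated cases use
#'   50--200 um.
#' @param arm_length Arm length in micrometres. The default `2 * width` is
#'   long enough for the port flow to be fully developed at the creeping-flow
#'   Reynolds numbers of these devices (entry length much smaller than W)
#'   while keeping grids desk-sized.
#' @return An object of class `cross_geometry` with the junction half-width,
#'   domain extent, the eight wall segments and the four port segments.
#' @examples
#' g <- cross_geometry(100)
#' g$extent   # 250 um from the junction center to each port
#' @export
cross_geometry <- function(width, arm_length = 2 * width) {
  if (!is.numeric(width) || length(width) != 1 || width <= 0)
    stop("width must be a positive scalar (micrometres)")
  if (!is.numeric(arm_length) || length(arm_length) != 1 || arm_length <= 0)
    stop("arm_length must be a positive scalar (micrometres)")
  a <- width / 2
  b <- a + arm_length
  ## eight wall segments (x1, y1, x2, y2), walking each arm's two sides
  walls <- rbind(
    c(-b,  a, -a,  a), c(-a,  a, -a,  b),   # W arm top wall, N arm west wall
    c( a,  b,  a,  a), c( a,  a,  b,  a),   # N arm east wall, E arm top wall
    c( b, -a,  a, -a), c( a, -a,  a, -b),   # E arm bottom, S arm east wall
    c(-a, -b, -a, -a), c(-a, -a, -b, -a))   # S arm west wall, W arm bottom
  ## port segments (x1, y1, x2, y2) and outward unit normals
  ports <- list(
    W = list(seg = c(-b, -a, -b, a), normal = c(-1, 0)),
    N = list(seg = c(-a,  b,  a, b), normal = c(0, 1)),
    E = list(seg = c( b, -a,  b, a), normal = c(1, 0)),
    S = list(seg = c(-a, -b,  a, -b), normal = c(0, -1)))
  structure(list(width = width, arm_length = arm_length,
                 half = a, extent = b, walls = walls, ports = ports),
            class = "cross_geometry")
}

#' @export
print.cross_geometry <- function(x, ...) {
  cat("Cross-junction geometry\n")
  cat(sprintf("  width W     : %g um\n", x$width))
  cat(sprintf("  arm length  : %g um\n", x$arm_length))
  cat(sprintf("  extent      : [-%g, %g] um in x and y\n", x$extent, x$extent))
  invisible(x)
}

#' Locate a point within the cross domain
#'
#' Partitions the domain into the junction square and the four arms. Points
#' with `|x| <= W/2` and `|y| <= W/2` belong to the junction (boundary ties go
#' to the square); points outside the fluid domain return `"outside"`.
#'
#' @param geom A [cross_geometry()].
#' @param x,y Coordinates in micrometres (vectorized).
#' @return Character vector with values `"junction"`, `"W"`, `"N"`, `"E"`,
#'   `"S"` or `"outside"`.
#' @export
point_region <- function(geom, x, y) {
  a <- geom$half; b <- geom$extent
  out <- rep("outside", length(x))
  out[abs(x) <= a & abs(y) <= a] <- "junction"
  out[x < -a & x >= -b & abs(y) <= a] <- "W"
  out[x >  a & x <=  b & abs(y) <= a] <- "E"
  out[y >  a & y <=  b & abs(x) <= a] <- "N"
  out[y < -a & y >= -b & abs(x) <= a] <- "S"
  out
}

#' Distance to the nearest channel wall
#'
#' Euclidean distance from a point to the nearest of the eight wall segments
#' (port openings are not walls). Used by the tracer for finite-size particle
#' contact.
#'
#' @inheritParams point_region
#' @return Numeric vector of distances in micrometres.
#' @export
wall_distance <- function(geom, x, y) {
  vapply(seq_along(x), function(i) wall_distance_cpp(geom$walls, x[i], y[i]),
         numeric(1))
}

#' Signed port rates of a cross junction
#'
#' Mean velocities (cm/s) at the four ports, positive into the junction. The
#' West port is inlet-only by convention; equal channel widths make mass
#' conservation equivalent to the four rates summing to zero.
#'
#' @param qW,qN,qE,qS Signed mean port velocities in cm/s (positive = inflow).
#' @param tol Conservation tolerance (cm/s).
#' @return An object of class `port_rates`.
#' @examples
#' port_rates(qW = 1, qN = -1.4, qE = 0.4, qS = 0)
#' @export
port_rates <- function(qW, qN, qE, qS, tol = 1e-9) {
  q <- c(W = qW, N = qN, E = qE, S = qS)
  if (any(!is.finite(q))) stop("port rates must be finite")
  if (qW < 0) stop("invalid case: the West port is inlet-only (qW >= 0)")
  if (abs(sum(q)) > tol * max(1, max(abs(q))))
    stop("port rates violate mass conservation (must sum to zero)")
  if (!any(q[c("N", "E", "S")] < 0))
    stop("invalid case: no outlet (all of qN, qE, qS are inflows)")
  structure(list(qW = qW, qN = qN, qE = qE, qS = qS,
                 n_outlets = sum(q[c("N", "E", "S")] < 0)),
            class = "port_rates")
}

#' @export
print.port_rates <- function(x, ...) {
  cat(sprintf("Port rates (cm/s, + into junction): W %+0.4g  N %+0.4g  E %+0.4g  S %+0.4g (%d outlet%s)\n",
              x$qW, x$qN, x$qE, x$qS, x$n_outlets, if (x$n_outlets > 1) "s" else ""))
  invisible(x)
}

#' Enumerate the seven fluid-behavior cases
#'
#' With the West port inlet-only, the fluid behavior at a cross junction is
#' fixed by which of the North, East and South ports are outlets: of the
#' `2^3 = 8` sign patterns the all-inflow one is impossible, leaving exactly
#' seven cases. Case 1 is the pattern with East and South flowing in and
#' North flowing out; the remaining six ids follow the ascending binary order
#' of the (N, E, S) outflow flags.
#'
#' @return A data.frame with columns `case_id`, `N_out`, `E_out`, `S_out`,
#'   `inlets`, `outlets`.
#' @export
flow_case_table <- function() {
  pat <- expand.grid(S_out = c(FALSE, TRUE), E_out = c(FALSE, TRUE),
                     N_out = c(FALSE, TRUE))[, 3:1]
  pat <- pat[rowSums(pat) > 0, ]                       # at least one outlet
  key <- pat$N_out * 4 + pat$E_out * 2 + pat$S_out
  pat <- pat[order(key), ]
  key <- sort(key)
  ## case 1 anchored at (N out, E in, S in) = binary 100; others by binary order
  ids <- integer(7)
  ids[key == 4] <- 1L
  ids[key != 4] <- 1L + seq_len(6)
  pat$case_id <- ids
  pat <- pat[order(pat$case_id), c("case_id", "N_out", "E_out", "S_out")]
  pat$inlets <- apply(pat, 1, function(r)
    paste(c("W", c("N", "E", "S")[!as.logical(r[2:4])]), collapse = ""))
  pat$outlets <- apply(pat, 1, function(r)
    paste(c("N", "E", "S")[as.logical(r[2:4])], collapse = ""))
  rownames(pat) <- NULL
  pat
}

#' Classify the fluid behavior of a set of port rates
#'
#' Maps the outflow sign pattern of (qN, qE, qS) to one of the seven case ids
#' of [flow_case_table()]. The classification only depends on signs, so it is
#' invariant to rescaling all rates by a positive constant.
#'
#' @param rates A [port_rates()].
#' @return A list with `case_id`, `inlet_set` and `outlet_set`.
#' @examples
#' classify_flow_case(port_rates(1, -1.7, 0.4, 0.3))$case_id  # 1
#' @export
classify_flow_case <- function(rates) {
  stopifnot(inherits(rates, "port_rates"))
  tab <- flow_case_table()
  row <- tab[tab$N_out == (rates$qN < 0) & tab$E_out == (rates$qE < 0) &
             tab$S_out == (rates$qS < 0), ]
  list(case_id = row$case_id,
       inlet_set = strsplit(row$inlets, "")[[1]],
       outlet_set = strsplit(row$outlets, "")[[1]])
}

#' Classify the particle behavior of a traced trajectory
#'
#' The particle case is the (entry port, exit port) pair: entry is the port
#' segment holding the first trajectory point, exit the port holding the last
#' point, or `"FROZEN"` when the particle stuck to a wall. A given particle
#' case can arise under several fluid cases.
#'
#' @param traj A `trajectory` from [trace_particle()].
#' @param geom The [cross_geometry()] the trajectory was traced in.
#' @return A list with `entry_port` and `exit_port`.
#' @export
classify_particle_case <- function(traj, geom) {
  p1 <- traj$path[1, ]
  on_port <- vapply(PORTS, function(p) {
    s <- geom$ports[[p]]$seg; n <- geom$ports[[p]]$normal
    along <- abs((p1$x - s[1]) * n[1] + (p1$y - s[2]) * n[2])
    lat_lo <- min(s[c(1, 3)]) - 1e-6 <= p1$x && p1$x <= max(s[c(1, 3)]) + 1e-6
    lat_hi <- min(s[c(2, 4)]) - 1e-6 <= p1$y && p1$y <= max(s[c(2, 4)]) + 1e-6
    along < 1e-6 && lat_lo && lat_hi
  }, logical(1))
  if (!any(on_port)) stop("trajectory does not start on a port segment")
  entry <- PORTS[which(on_port)[1]]
  exit <- if (traj$status == "FROZEN") "FROZEN" else traj$exit_port
  list(entry_port = entry, exit_port = exit)
}

#' Serialize a geometry to JSON
#'
#' @param geom A [cross_geometry()].
#' @return A JSON string `{"width_um": w, "arm_length_um": a}`.
#' @export
geometry_to_json <- function(geom) {
  jsonlite::toJSON(list(width_um = geom$width, arm_length_um = geom$arm_length),
                   auto_unbox = TRUE)
}

#' @rdname geometry_to_json
#' @param json JSON string produced by [geometry_to_json()].
#' @export
geometry_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  cross_geometry(x$width_um, x$arm_length_um)
}
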