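#' Sample a random intersection case
#'
#' Draws one randomized cross-junction case from the study ranges: channel
#' width uniform on 50--200 um, particle diameter uniform on 1--20 um, outlet
#' count uniform on {1, 2, 3} with the outlet ports drawn uniformly among
#' {N, E, S}; inflow rates (West and any non-outlet port) uniform on 0--2
#' cm/s; all but one outflow rate uniform on 0--2 cm/s; and the remaining
#' outlet closed by mass conservation (total inflow minus the other
#' outflows). Draws whose closure is negative or exceeds 2 cm/s are rejected
#' and resampled, so every emitted case satisfies the range constraints and
#' conserves mass exactly.
#'
#' Uses the current R RNG state; seed it for reproducibility.
#'
#' @param arm_ratio Arm length as a multiple of the width.
#' @param max_reject Rejection-loop bound.
#' @return An object of class `intersection_case`: `geometry`, `rates`,
#'   `particle`.
#' @examples
#' set.seed(7); sample_case()
#' @export
sample_case <- function(arm_ratio = 2, max_reject = 1e6) {
  width <- stats::runif(1, 50, 200)
  dp <- stats::runif(1, 1, 20)   # always < width over these ranges
  for (i in seq_len(max_reject)) {
    n_out <- sample(1:3, 1)
    outlets <- sample(c("N", "E", "S"), n_out)
    inlets_other <- setdiff(c("N", "E", "S"), outlets)
    q <- c(W = stats::runif(1, 0, 2), N = 0, E = 0, S = 0)
    for (p in inlets_other) q[p] <- stats::runif(1, 0, 2)
    if (n_out > 1)
      for (p in outlets[seq_len(n_out - 1)]) q[p] <- -stats::runif(1, 0, 2)
    last <- outlets[n_out]
    closure <- sum(q)               # total inflow minus assigned outflows
    if (closure > 0 && closure <= 2) {
      q[last] <- -closure
      return(structure(list(geometry = cross_geometry(width, arm_ratio * width),
                            rates = port_rates(q[["W"]], q[["N"]], q[["E"]], q[["S"]]),
                            particle = particle(dp)),
                       class = "intersection_case"))
    }
  }
  stop("rejection sampling failed after ", max_reject, " draws")
}

#' @export
print.intersection_case <- function(x, ...) {
  cat(sprintf("Intersection case: W = %.4g um, Dp = %.4g um\n",
              x$geometry$width, x$particle$diameter))
  print(x$rates)
  invisible(x)
}

## Resample a polyline to n points at equal arc-length fractions
## (both endpoints included).
.resample_polyline <- function(pts, n = 10) {
  if (nrow(pts) == 1) return(pts[rep(1, n), , drop = FALSE])
  d <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  s <- c(0, cumsum(d))
  L <- s[length(s)]
  if (L == 0) return(pts[rep(1, n), , drop = FALSE])
  ## drop zero-length duplicates for interpolation
  keep <- c(TRUE, d > 0)
  sx <- s[keep]
  target <- seq(0, L, length.out = n)
  cbind(stats::approx(sx, pts[keep, 1], xout = target)$y,
        stats::approx(sx, pts[keep, 2], xout = target)$y)
}

#' Split a trajectory into entrance, middle and exit segments
#'
#' Splits an exited trajectory at its two crossings of the junction-square
#' boundary into the entrance (entry arm), middle (junction square) and exit
#' (exit arm) parts, each resampled to exactly 10 points at equal arc-length
#' fractions including both endpoints -- the 30 points / 60 coordinates a
#' training record stores. The crossing points are interpolated onto the
#' square boundary so consecutive segments share their junction endpoint.
#'
#' @param traj A `trajectory` with status `EXITED` whose entry and exit ports
#'   differ.
#' @param geom The governing [cross_geometry()].
#' @return An object of class `segmented_trajectory`: matrices `entrance`,
#'   `middle`, `exit`, each 10 x 2 (um).
#' @export
segment_trajectory <- function(traj, geom) {
  if (traj$status != "EXITED")
    stop("only exited trajectories can be segmented (status ", traj$status, ")")
  pc <- classify_particle_case(traj, geom)
  if (pc$entry_port == pc$exit_port) stop("entry and exit ports must differ")
  P <- as.matrix(traj$path[, c("x", "y")])
  a <- geom$half
  inside <- abs(P[, 1]) <= a & abs(P[, 2]) <= a
  if (!any(inside)) stop("trajectory never enters the junction square")
  k1 <- which(inside)[1]
  k2 <- max(which(inside))
  cross_pt <- function(p1, p2, port) {
    ## crossing of segment p1-p2 with the square face toward `port`
    if (port %in% c("W", "E")) {
      xf <- if (port == "W") -a else a
      f <- (xf - p1[1]) / (p2[1] - p1[1])
    } else {
      yf <- if (port == "S") -a else a
      f <- (yf - p1[2]) / (p2[2] - p1[2])
    }
    f <- min(max(f, 0), 1)
    p1 + f * (p2 - p1)
  }
  c1 <- if (k1 == 1) P[1, ] else cross_pt(P[k1 - 1, ], P[k1, ], pc$entry_port)
  c2 <- if (k2 == nrow(P)) P[k2, ] else cross_pt(P[k2, ], P[k2 + 1, ], pc$exit_port)
  entrance <- rbind(P[seq_len(max(k1 - 1, 1)), , drop = FALSE], c1)
  middle <- rbind(c1, P[seq(k1, k2), , drop = FALSE], c2)
  exit <- rbind(c2, P[seq(min(k2 + 1, nrow(P)), nrow(P)), , drop = FALSE])
  structure(list(entrance = .resample_polyline(entrance, 10),
                 middle = .resample_polyline(middle, 10),
                 exit = .resample_polyline(exit, 10),
                 entry_port = pc$entry_port, exit_port = pc$exit_port),
            class = "segmented_trajectory")
}

#' @export
print.segmented_trajectory <- function(x, ...) {
  cat(sprintf("Segmented trajectory: %s -> %s, 3 x 10 points\n",
              x$entry_port, x$exit_port))
  invisible(x)
}

## flatten a segmented trajectory to the 60-coordinate target vector
.segments_to_targets <- function(seg) {
  as.numeric(t(rbind(seg$entrance, seg$middle, seg$exit)))
}

#' Generate a trajectory training dataset
#'
#' Reproduces the randomized data-generation protocol at configurable scale:
#' for each case, draw an intersection with [sample_case()], solve the flow
#' once, release `seeds_per_case` particles from every inlet port, trace
#' them, split each exited trajectory with [segment_trajectory()], and emit
#' one record of 7 features `(Dp, W, x0, y0, qW, qN, qE)` and 60 target
#' coordinates per trajectory. Frozen and timed-out trajectories are
#' excluded from the records (their exit segment is undefined); their counts
#' are reported so the exclusion is visible. Generation is reproducible from
#' the master seed, which fans out to one sub-seed per case.
#'
#' @param n_cases Number of random intersection cases.
#' @param seeds_per_case Particles per release at each inlet (default 10).
#' @param seed Master RNG seed.
#' @param n_across Flow-solver cells across the channel width (default 24
#'   for generation-scale work; raise for refinement studies).
#' @param arm_ratio Arm length over width.
#' @param controls A [trace_controls()].
#' @param fluid A [fluid_properties()].
#' @return A data.frame with columns `feat_1..feat_7`, `tgt_1..tgt_60` and
#'   provenance columns `case_seed`, `entry_port`, `exit_port`, `flow_case`.
#'   Attributes `n_frozen`, `n_max_time`, `n_traced` report exclusions.
#' @export
build_dataset <- function(n_cases, seeds_per_case = 10, seed = 1,
                          n_across = 24, arm_ratio = 2,
                          controls = trace_controls(),
                          fluid = fluid_properties()) {
  stopifnot(n_cases >= 1)
  set.seed(seed)
  case_seeds <- sample.int(.Machine$integer.max - 1L, n_cases)
  rows <- vector("list", n_cases)
  n_frozen <- n_max_time <- n_traced <- 0L
  for (ci in seq_len(n_cases)) {
    set.seed(case_seeds[ci])
    cs <- sample_case(arm_ratio = arm_ratio)
    fc <- classify_flow_case(cs$rates)
    field <- solve_flow(cs$geometry, cs$rates, fluid, n_across = n_across)
    q <- c(W = cs$rates$qW, N = cs$rates$qN, E = cs$rates$qE, S = cs$rates$qS)
    recs <- list()
    for (port in fc$inlet_set) {
      if (q[[port]] <= 0) next   # a zero-rate port releases no particles
      trs <- trace_release(field, cs$particle, port, seeds_per_case, fluid, controls)
      for (tr in trs) {
        n_traced <- n_traced + 1L
        if (tr$status == "FROZEN") { n_frozen <- n_frozen + 1L; next }
        if (tr$status == "MAX_TIME") { n_max_time <- n_max_time + 1L; next }
        seg <- segment_trajectory(tr, cs$geometry)
        recs[[length(recs) + 1L]] <- c(
          cs$particle$diameter, cs$geometry$width, tr$seed[1], tr$seed[2],
          cs$rates$qW, cs$rates$qN, cs$rates$qE,
          .segments_to_targets(seg),
          case_seeds[ci], match(seg$entry_port, PORTS),
          match(seg$exit_port, PORTS), fc$case_id)
      }
    }
    if (length(recs)) rows[[ci]] <- do.call(rbind, recs)
  }
  M <- do.call(rbind, rows)
  ds <- as.data.frame(M)
  names(ds) <- c(paste0("feat_", 1:7), paste0("tgt_", 1:60),
                 "case_seed", "entry_port", "exit_port", "flow_case")
  ds$entry_port <- PORTS[ds$entry_port]
  ds$exit_port <- PORTS[ds$exit_port]
  stopifnot(ncol(ds) == 7 + 60 + 4)
  attr(ds, "n_frozen") <- n_frozen
  attr(ds, "n_max_time") <- n_max_time
  attr(ds, "n_traced") <- n_traced
  attr(ds, "master_seed") <- seed
  ds
}

#' Feature and target scaler with the fixed sampling ranges
#'
#' Min-max scaling anchored at the sampling ranges of the study rather than
#' the realized data, so any two datasets share the same scale: Dp on
#' [1, 20] um, width on [50, 200] um, rates on [-2, 2] cm/s, and every
#' coordinate (seed positions and the 60 targets) by the maximum domain
#' half-extent at W = 200 um (500 um for arm length 2W), mapped to [0, 1].
#'
#' @param arm_ratio Arm length over width (sets the coordinate half-extent).
#' @return An object of class `range_scaler`.
#' @export
range_scaler <- function(arm_ratio = 2) {
  ext <- 200 * (0.5 + arm_ratio)   # um, half-extent at the widest channel
  structure(list(
    feat_lo = c(1, 50, -ext, -ext, -2, -2, -2),
    feat_hi = c(20, 200, ext, ext, 2, 2, 2),
    coord_lo = -ext, coord_hi = ext, arm_ratio = arm_ratio),
    class = "range_scaler")
}

#' @rdname range_scaler
#' @param scaler A `range_scaler`.
#' @param X Feature matrix (n x 7) in raw units.
#' @export
normalize_features <- function(scaler, X) {
  X <- rbind(X)
  sweep(sweep(X, 2, scaler$feat_lo, "-"), 2,
        scaler$feat_hi - scaler$feat_lo, "/")
}

#' @rdname range_scaler
#' @param Y Target matrix (n x 60) in um (or normalized, for the inverse).
#' @export
normalize_targets <- function(scaler, Y) {
  (Y - scaler$coord_lo) / (scaler$coord_hi - scaler$coord_lo)
}

#' @rdname range_scaler
#' @export
denormalize_targets <- function(scaler, Y) {
  Y * (scaler$coord_hi - scaler$coord_lo) + scaler$coord_lo
}

#' @rdname range_scaler
#' @export
denormalize_features <- function(scaler, X) {
  X <- rbind(X)
  sweep(sweep(X, 2, scaler$feat_hi - scaler$feat_lo, "*"), 2,
        scaler$feat_lo, "+")
}

#' Normalize a dataset with the fixed-range scaler
#'
#' @param ds A [build_dataset()] data.frame.
#' @param scaler A [range_scaler()]; defaults to the ranges implied by the
#'   dataset's arm ratio.
#' @return A list with `data` (features and targets scaled to [0, 1],
#'   provenance columns untouched) and `scaler`. The mapping is affine and
#'   exactly invertible.
#' @export
normalize_records <- function(ds, scaler = range_scaler()) {
  if (nrow(ds) == 0) stop("empty dataset")
  fcols <- paste0("feat_", 1:7); tcols <- paste0("tgt_", 1:60)
  out <- ds
  out[fcols] <- normalize_features(scaler, as.matrix(ds[fcols]))
  out[tcols] <- normalize_targets(scaler, as.matrix(ds[tcols]))
  list(data = out, scaler = scaler)
}

#' Case-level train/test split
#'
#' Splits at the intersection-case level (all trajectories of a case stay on
#' the same side, preventing leakage between nearly identical records),
#' stratified by fluid-behavior case id.
#'
#' @param ds Dataset from [build_dataset()] (normalized or not).
#' @param train_frac Fraction of cases assigned to training (default 0.7).
#' @param seed RNG seed for the split.
#' @return A list with integer row indices `train` and `test`.
#' @export
split_dataset <- function(ds, train_frac = 0.7, seed = 1) {
  stopifnot(train_frac > 0, train_frac < 1)
  set.seed(seed)
  cases <- unique(ds[, c("case_seed", "flow_case")])
  train_cases <- unlist(lapply(split(cases$case_seed, cases$flow_case), function(cs) {
    cs <- cs[sample.int(length(cs))]
    cs[seq_len(max(1, round(train_frac * length(cs))))]
  }))
  idx <- which(ds$case_seed %in% train_cases)
  list(train = idx, test = setdiff(seq_len(nrow(ds)), idx))
}

#' Scaler JSON sidecar
#'
#' @param scaler A [range_scaler()].
#' @param path Output JSON path.
#' @export
write_scaler_json <- function(scaler, path) {
  jsonlite::write_json(unclass(scaler), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scaler_json
#' @export
read_scaler_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  structure(x, class = "range_scaler")
}
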