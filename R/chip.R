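## Chip-level modeling: a planar orthogonal channel network is decomposed
## into straight channels and cross intersections; segment flow rates follow
## the electrical-circuit analogy (hydraulic resistance R = 12 mu L / W^3
## per unit depth, the planar Poiseuille law), and whole-chip particle paths
## are pieced from straight-line transport plus per-intersection
## predictions (surrogate or physics oracle).

#' Chip channel network
#'
#' @param nodes data.frame with columns `id`, `x`, `y` (um).
#' @param edges data.frame with columns `id`, `from`, `to`, `width` (um).
#'   Edges must be axis-aligned (orthogonal layout).
#' @param boundary data.frame with columns `node`, `rate`: prescribed mean
#'   velocity (cm/s) at terminal nodes, positive into the chip. Boundary
#'   fluxes must conserve mass globally.
#' @return An object of class `chip_graph`.
#' @export
chip_graph <- function(nodes, edges, boundary) {
  stopifnot(all(c("id", "x", "y") %in% names(nodes)),
            all(c("id", "from", "to", "width") %in% names(edges)),
            all(c("node", "rate") %in% names(boundary)))
  nodes$id <- as.character(nodes$id)
  edges$from <- as.character(edges$from); edges$to <- as.character(edges$to)
  edges$id <- as.character(edges$id)
  boundary$node <- as.character(boundary$node)
  pos <- function(id) unlist(nodes[nodes$id == id, c("x", "y")])
  for (k in seq_len(nrow(edges))) {
    d <- pos(edges$to[k]) - pos(edges$from[k])
    if (all(abs(d) > 1e-9) || all(abs(d) < 1e-9))
      stop("edge ", edges$id[k], " is not axis-aligned")
  }
  deg <- table(c(edges$from, edges$to))
  if (any(deg > 4)) stop("node degree > 4 is not supported")
  if (any(edges$width <= 0)) stop("edge widths must be positive")
  if (any(edges$width < 50 | edges$width > 200))
    warning("edge widths outside the 50-200 um study range")
  ## global conservation of boundary fluxes (rate * width)
  fl <- vapply(seq_len(nrow(boundary)), function(i) {
    w <- edges$width[edges$from == boundary$node[i] | edges$to == boundary$node[i]][1]
    boundary$rate[i] * w
  }, 1)
  if (abs(sum(fl)) > 1e-6 * max(abs(fl)))
    stop("boundary rates do not conserve mass globally")
  term <- names(deg)[deg == 1]
  if (!all(boundary$node %in% term))
    stop("boundary conditions must sit on terminal (degree-1) nodes")
  structure(list(nodes = nodes, edges = edges, boundary = boundary,
                 degree = deg), class = "chip_graph")
}

#' @export
print.chip_graph <- function(x, ...) {
  cat(sprintf("Chip graph: %d nodes, %d channel segments, %d boundary terminals\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$boundary)))
  if (!is.null(x$edges$mean_velocity))
    cat("  segment flow rates solved (resistor-network analogy)\n")
  invisible(x)
}

#' Read / write a chip description in JSON
#'
#' Layout: `{"nodes":[{id,x_um,y_um}], "edges":[{id,from,to,width_um}],
#' "boundary":[{node,mean_velocity_cmps}]}`. Edge lengths derive from node
#' positions.
#'
#' @param path JSON file path.
#' @return A [chip_graph()].
#' @export
read_chip_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  chip_graph(nodes = data.frame(id = x$nodes$id, x = x$nodes$x_um, y = x$nodes$y_um),
             edges = data.frame(id = x$edges$id, from = x$edges$from,
                                to = x$edges$to, width = x$edges$width_um),
             boundary = data.frame(node = x$boundary$node,
                                   rate = x$boundary$mean_velocity_cmps))
}

#' @rdname read_chip_json
#' @param chip A [chip_graph()].
#' @export
write_chip_json <- function(chip, path) {
  jsonlite::write_json(list(
    nodes = data.frame(id = chip$nodes$id, x_um = chip$nodes$x,
                       y_um = chip$nodes$y),
    edges = data.frame(id = chip$edges$id, from = chip$edges$from,
                       to = chip$edges$to, width_um = chip$edges$width),
    boundary = data.frame(node = chip$boundary$node,
                          mean_velocity_cmps = chip$boundary$rate)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.edge_length <- function(chip, k) {
  a <- chip$nodes[chip$nodes$id == chip$edges$from[k], c("x", "y")]
  b <- chip$nodes[chip$nodes$id == chip$edges$to[k], c("x", "y")]
  sqrt(sum((b - a)^2))
}

#' Decompose a chip into straight channels and intersections
#'
#' Every maximal run of collinear segments joined at degree-2 nodes is one
#' STRAIGHT unit; every internal node of degree 3 or 4 is an INTERSECTION
#' unit (degree-3 junctions are crosses with one closed arm).
#'
#' @param chip A [chip_graph()].
#' @return A list with data.frame `units` (unit id, kind, member ids) and
#'   counts `n_straight`, `n_intersections`.
#' @examples
#' decompose_chip(h_chip_fixture())$n_intersections  # 2
#' @export
decompose_chip <- function(chip) {
  deg <- chip$degree
  ends <- names(deg)[deg != 2]
  visited <- character(0)
  straights <- list()
  dirn <- function(a, b) {
    d <- c(chip$nodes$x[chip$nodes$id == b] - chip$nodes$x[chip$nodes$id == a],
           chip$nodes$y[chip$nodes$id == b] - chip$nodes$y[chip$nodes$id == a])
    d / sqrt(sum(d^2))
  }
  for (k in seq_len(nrow(chip$edges))) {
    eid <- chip$edges$id[k]
    if (eid %in% visited) next
    ## walk both ways through degree-2 nodes
    chain <- eid
    for (endcol in c("from", "to")) {
      nd <- chip$edges[[endcol]][k]
      prev <- eid
      while (deg[[nd]] == 2) {
        nxt <- chip$edges$id[(chip$edges$from == nd | chip$edges$to == nd) &
                               chip$edges$id != prev]
        d1 <- dirn(chip$edges$from[chip$edges$id == prev], chip$edges$to[chip$edges$id == prev])
        d2 <- dirn(chip$edges$from[chip$edges$id == nxt], chip$edges$to[chip$edges$id == nxt])
        if (max(abs(abs(d1) - abs(d2))) > 1e-9)
          stop("bent straight unit at node ", nd, " (non-collinear segments)")
        chain <- union(chain, nxt)
        nd2 <- setdiff(c(chip$edges$from[chip$edges$id == nxt],
                         chip$edges$to[chip$edges$id == nxt]), nd)
        prev <- nxt; nd <- nd2
      }
    }
    visited <- c(visited, chain)
    straights[[length(straights) + 1]] <- chain
  }
  inter <- names(deg)[deg >= 3]
  units <- rbind(
    data.frame(unit = paste0("S", seq_along(straights)), kind = "STRAIGHT",
               members = vapply(straights, paste, "", collapse = "+")),
    if (length(inter))
      data.frame(unit = paste0("X", seq_along(inter)), kind = "INTERSECTION",
                 members = inter))
  list(units = units, n_straight = length(straights),
       n_intersections = length(inter))
}

#' Solve segment flow rates by the resistor-network analogy
#'
#' Each channel segment behaves like a resistor with hydraulic resistance
#' `R = 12 mu L / W^3` per unit depth (planar Poiseuille); node pressures
#' solve the Kirchhoff current law with the prescribed terminal fluxes as
#' sources, and segment volumetric rates follow from `Q = dP / R`.
#'
#' @param chip A [chip_graph()].
#' @param fluid A [fluid_properties()].
#' @return The chip with `edges$Q` (m^2/s per unit depth, positive from
#'   `from` to `to`), `edges$mean_velocity` (cm/s) and `nodes$pressure`
#'   (Pa) added.
#' @export
solve_flow_network <- function(chip, fluid = fluid_properties()) {
  nn <- nrow(chip$nodes); ids <- chip$nodes$id
  L <- matrix(0, nn, nn); b <- numeric(nn)
  R <- numeric(nrow(chip$edges))
  for (k in seq_len(nrow(chip$edges))) {
    len <- .edge_length(chip, k) * 1e-6
    w <- chip$edges$width[k] * 1e-6
    R[k] <- 12 * fluid$viscosity * len / w^3
    i <- match(chip$edges$from[k], ids); j <- match(chip$edges$to[k], ids)
    L[i, i] <- L[i, i] + 1 / R[k]; L[j, j] <- L[j, j] + 1 / R[k]
    L[i, j] <- L[i, j] - 1 / R[k]; L[j, i] <- L[j, i] - 1 / R[k]
  }
  for (i in seq_len(nrow(chip$boundary))) {
    k <- which(chip$edges$from == chip$boundary$node[i] |
                 chip$edges$to == chip$boundary$node[i])[1]
    b[match(chip$boundary$node[i], ids)] <-
      chip$boundary$rate[i] * 0.01 * chip$edges$width[k] * 1e-6
  }
  src <- b
  ## pressure gauge at node 1
  L[1, ] <- 0; L[1, 1] <- 1; b[1] <- 0
  p <- solve(L, b)
  chip$nodes$pressure <- p
  chip$edges$Q <- (p[match(chip$edges$from, ids)] - p[match(chip$edges$to, ids)]) / R
  chip$edges$mean_velocity <- chip$edges$Q / (chip$edges$width * 1e-6) / 0.01
  ## Kirchhoff residual (flow imbalance + source) at every node
  res <- vapply(seq_len(nn), function(i) {
    sum(chip$edges$Q[chip$edges$to == ids[i]]) -
      sum(chip$edges$Q[chip$edges$from == ids[i]]) + src[i]
  }, 1)
  attr(chip, "kirchhoff_residual") <- max(abs(res)) / max(abs(chip$edges$Q))
  chip
}

#' Straight-channel particle transport
#'
#' In a straight channel a particle keeps its lateral position: the exit
#' lateral fraction equals the entry fraction (`xi` measured from the left
#' wall when facing the flow direction). Exposed for clarity; composition
#' uses it implicitly.
#'
#' @param xi Lateral fraction in [0, 1].
#' @param unit Ignored (any straight unit).
#' @return `xi`, unchanged.
#' @export
transport_straight <- function(xi, unit = NULL) {
  stopifnot(all(xi >= 0 & xi <= 1))
  xi
}

.perp <- function(d) c(-d[2], d[1])

#' Physics-oracle intersection predictor
#'
#' Returns a predictor with the same interface as the surrogate (7 features
#' in, a segmented trajectory out) that solves the local cross-junction flow
#' and traces the particle instead of running the network. Used as the
#' reference route in composition checks; swapping it for a trained
#' surrogate changes accuracy, not the composition contract.
#'
#' @param n_across Flow-solver resolution.
#' @param arm_ratio Arm length over width of the local cross model.
#' @param fluid A [fluid_properties()].
#' @return A function `(features) -> segmented_trajectory`.
#' @export
physics_predictor <- function(n_across = 24, arm_ratio = 2,
                              fluid = fluid_properties()) {
  force(n_across); force(arm_ratio); force(fluid)
  function(features) {
    dp <- features[1]; w <- features[2]
    qW <- features[5]; qN <- features[6]; qE <- features[7]
    qS <- -(qW + qN + qE)
    geom <- cross_geometry(w, arm_ratio * w)
    field <- solve_flow(geom, port_rates(qW, qN, qE, qS), fluid, n_across)
    tr <- trace_particle(field, particle(dp), features[3:4], fluid)
    if (tr$status != "EXITED")
      return(structure(list(entrance = NULL, middle = NULL, exit = NULL,
                            entry_port = "W", exit_port = tr$status),
                       class = "segmented_trajectory"))
    segment_trajectory(tr, geom)
  }
}

#' Surrogate intersection predictor
#'
#' Wraps a trained [dense_chain][build_network()] into the per-intersection
#' predictor interface used by [compose_trajectory()].
#'
#' @param model A trained `dense_chain`.
#' @return A function `(features) -> segmented_trajectory`.
#' @export
surrogate_predictor <- function(model) {
  force(model)
  function(features) predict_trajectory(model, features)
}

#' Compose a whole-chip particle trajectory from unit predictions
#'
#' Alternates straight-line transport (lateral position preserved) with
#' per-intersection predictions. At each intersection the particle's
#' arrival arm is relabeled as the local West port, the local port rates are
#' read off the solved resistor network (closed arms of T-junctions get rate
#' 0), the local 7-feature vector is built, and the predictor (surrogate or
#' physics oracle) supplies the 30-point local trajectory whose exit arm and
#' exit position carry the particle onward. Terminates at a terminal node
#' or on a FROZEN prediction.
#'
#' @param chip A [solve_flow_network()] result.
#' @param predictor A [physics_predictor()] or [surrogate_predictor()].
#' @param p A [particle()].
#' @param entry Terminal node id with inflow.
#' @param xi0 Entry lateral fraction in [0, 1], measured from the left wall
#'   facing the flow.
#' @param arm_ratio Arm ratio of the local intersection model.
#' @param max_units Safety bound on traversed units.
#' @return An object of class `chip_path`: `path` (data.frame `x`, `y`,
#'   `unit`), `status` (`"EXITED"` or `"FROZEN"`), `exit_node`, `exit_xi`,
#'   `max_gap` (largest inter-piece gap, um).
#' @export
compose_trajectory <- function(chip, predictor, p, entry, xi0,
                               arm_ratio = 2, max_units = 100) {
  if (is.null(chip$edges$mean_velocity))
    stop("solve the flow network first (solve_flow_network)")
  stopifnot(entry %in% chip$boundary$node)
  if (chip$boundary$rate[chip$boundary$node == entry] <= 0)
    stop("entry terminal must be an inflow terminal")
  stopifnot(xi0 >= 0, xi0 <= 1)
  ids <- chip$nodes$id
  npos <- function(id) c(chip$nodes$x[ids == id], chip$nodes$y[ids == id])
  edges_at <- function(nd) which(chip$edges$from == nd | chip$edges$to == nd)

  k <- edges_at(entry)
  nd <- entry
  other <- function(k, nd) setdiff(c(chip$edges$from[k], chip$edges$to[k]), nd)
  d <- npos(other(k, nd)) - npos(nd); d <- d / sqrt(sum(d^2))
  w <- chip$edges$width[k]
  if (p$diameter >= w) stop("particle does not fit in the entry channel")
  ly <- w / 2 - xi0 * w                     # signed offset along perp(d)
  ## clamp to the admissible (eroded) span
  ly <- min(max(ly, -(w - p$diameter) / 2), (w - p$diameter) / 2)

  pts <- list(); unit_tags <- character(0); max_gap <- 0
  add_pts <- function(M, tag) {
    pts[[length(pts) + 1]] <<- M
    unit_tags <<- c(unit_tags, rep(tag, nrow(M)))
  }
  status <- "EXITED"; exit_node <- NA_character_
  cur <- npos(nd) + ly * .perp(d)

  for (it in seq_len(max_units)) {
    nxt <- other(k, nd)
    ext <- chip$edges$width[k] / 2 + arm_ratio * chip$edges$width[k]
    if (chip$degree[[nxt]] == 1) {
      ## straight run to a terminal
      endp <- npos(nxt) + ly * .perp(d)
      add_pts(rbind(cur, endp), chip$edges$id[k])
      exit_node <- nxt
      break
    }
    ## straight run to the local West port line of the next intersection
    port_in <- npos(nxt) - ext * d + ly * .perp(d)
    add_pts(rbind(cur, port_in), chip$edges$id[k])

    ## local cross frame: arrival direction = local +x (east); West = arrival arm
    perp <- .perp(d)
    wloc <- chip$edges$width[k]
    inc <- edges_at(nxt)
    if (any(abs(chip$edges$width[inc] - wloc) > 1e-9))
      stop("intersection ", nxt, " has unequal arm widths")
    labs <- c("E", "N", "W", "S")
    dirs <- list(d, perp, -d, -perp)
    q <- c(E = 0, N = 0, W = 0, S = 0)
    edge_of <- c(E = NA, N = NA, W = NA, S = NA)
    for (ke in inc) {
      dv <- npos(other(ke, nxt)) - npos(nxt); dv <- dv / sqrt(sum(dv^2))
      lab <- labs[vapply(dirs, function(dd) sum(abs(dd - dv)) < 1e-9, TRUE)]
      into <- if (chip$edges$to[ke] == nxt) chip$edges$mean_velocity[ke]
              else -chip$edges$mean_velocity[ke]
      q[lab] <- into
      edge_of[lab] <- ke
    }
    feats <- c(p$diameter, wloc, -ext, ly, q[["W"]], q[["N"]], q[["E"]])
    seg <- predictor(feats)
    if (seg$exit_port %in% c("FROZEN", "MAX_TIME")) { status <- "FROZEN"; break }
    ## map the 30 local points into chip coordinates
    Rot <- cbind(d, perp)
    loc <- rbind(seg$entrance, seg$middle, seg$exit)
    chipp <- sweep(loc %*% t(Rot), 2, npos(nxt), "+")
    max_gap <- max(max_gap, sqrt(sum((chipp[1, ] - port_in)^2)))
    add_pts(chipp, paste0("X:", nxt))
    ## continue along the predicted exit arm
    lab <- seg$exit_port
    if (lab == "W") stop("predicted exit through the arrival arm")
    if (is.na(edge_of[lab]))
      stop("predicted exit arm ", lab, " has no channel at node ", nxt)
    if (q[lab] >= 0)
      stop("predicted exit arm ", lab, " carries inflow in the network solution")
    d_new <- dirs[[match(lab, labs)]]
    P_exit <- chipp[30, ]
    ly <- sum((P_exit - npos(nxt)) * .perp(d_new))
    cur <- P_exit
    nd <- nxt; k <- edge_of[lab]; d <- d_new
  }
  w_exit <- chip$edges$width[k]
  path <- data.frame(x = do.call(rbind, pts)[, 1], y = do.call(rbind, pts)[, 2],
                     unit = unit_tags)
  structure(list(path = path, status = status, exit_node = exit_node,
                 exit_xi = (w_exit / 2 - ly) / w_exit, max_gap = max_gap),
            class = "chip_path")
}

#' @export
print.chip_path <- function(x, ...) {
  cat(sprintf("Composed chip path: %d points, status %s%s, exit xi %.3f, max gap %.3g um\n",
              nrow(x$path), x$status,
              if (!is.na(x$exit_node)) paste0(" at ", x$exit_node) else "",
              x$exit_xi, x$max_gap))
  invisible(x)
}
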