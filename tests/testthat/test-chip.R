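test_that("the H-chip decomposes into seven straights and two intersections", {
  d <- decompose_chip(h_chip_fixture())
  expect_equal(d$n_straight, 7)
  expect_equal(d$n_intersections, 2)
  expect_setequal(d$units$kind, c("STRAIGHT", "INTERSECTION"))
})

test_that("degenerate chips decompose as expected", {
  one <- chip_graph(
    nodes = data.frame(id = c("A", "B"), x = c(0, 400), y = 0),
    edges = data.frame(id = "e", from = "A", to = "B", width = 100),
    boundary = data.frame(node = c("A", "B"), rate = c(1, -1)))
  d <- decompose_chip(one)
  expect_equal(d$n_straight, 1); expect_equal(d$n_intersections, 0)

  plus <- chip_graph(
    nodes = data.frame(id = c("W", "N", "E", "S", "C"),
                       x = c(-300, 0, 300, 0, 0), y = c(0, 300, 0, -300, 0)),
    edges = data.frame(id = paste0("e", 1:4), from = c("W", "N", "E", "S"),
                       to = "C", width = 100),
    boundary = data.frame(node = c("W", "N", "E", "S"),
                          rate = c(1, -1.7, 0.4, 0.3)))
  dp <- decompose_chip(plus)
  expect_equal(dp$n_straight, 4); expect_equal(dp$n_intersections, 1)
  ## degree-2 nodes merge into one straight unit
  chainy <- chip_graph(
    nodes = data.frame(id = c("A", "M", "B"), x = c(0, 200, 500), y = 0),
    edges = data.frame(id = c("e1", "e2"), from = c("A", "M"),
                       to = c("M", "B"), width = 100),
    boundary = data.frame(node = c("A", "B"), rate = c(1, -1)))
  dc <- decompose_chip(chainy)
  expect_equal(dc$n_straight, 1)
})

test_that("chip validation catches malformed networks", {
  expect_error(chip_graph(
    nodes = data.frame(id = c("A", "B"), x = c(0, 100), y = c(0, 50)),
    edges = data.frame(id = "e", from = "A", to = "B", width = 100),
    boundary = data.frame(node = c("A", "B"), rate = c(1, -1))),
    "axis-aligned")
  expect_error(chip_graph(
    nodes = data.frame(id = c("A", "B"), x = c(0, 400), y = 0),
    edges = data.frame(id = "e", from = "A", to = "B", width = 100),
    boundary = data.frame(node = c("A", "B"), rate = c(1, -0.5))),
    "conserve")
})

test_that("the resistor analogy gives series, symmetric and parallel laws", {
  ## series: same Q in both segments
  ser <- chip_graph(
    nodes = data.frame(id = c("A", "M", "B"), x = c(0, 300, 700), y = 0),
    edges = data.frame(id = c("e1", "e2"), from = c("A", "M"),
                       to = c("M", "B"), width = 100),
    boundary = data.frame(node = c("A", "B"), rate = c(1, -1)))
  s <- solve_flow_network(ser)
  expect_equal(s$edges$Q[1], s$edges$Q[2], tolerance = 1e-12)
  expect_equal(s$edges$mean_velocity[1], 1, tolerance = 1e-12)
  expect_lt(attr(s, "kirchhoff_residual"), 1e-10)

  ## symmetric H with equal inlets: the crossbar carries no flow
  hsym <- chip_graph(
    nodes = data.frame(id = c("N1", "S1", "N2", "S2", "J1", "J2"),
                       x = c(0, 0, 300, 300, 0, 300),
                       y = c(200, -200, 200, -200, 0, 0)),
    edges = data.frame(id = paste0("e", 1:5),
                       from = c("N1", "J1", "N2", "J2", "J1"),
                       to = c("J1", "S1", "J2", "S2", "J2"),
                       width = 100),
    boundary = data.frame(node = c("N1", "S1", "N2", "S2"),
                          rate = c(1, -1, 1, -1)))
  hs <- solve_flow_network(hsym)
  expect_lt(abs(hs$edges$Q[5]), 1e-15)

  ## parallel branches of equal length, widths 100 vs 200:
  ## R ~ 1/W^3 so the flow split is 1 : 8
  par <- chip_graph(
    nodes = data.frame(id = c("A", "J1", "J2", "B"),
                       x = c(0, 200, 600, 800), y = 0),
    edges = data.frame(id = paste0("e", 1:4),
                       from = c("A", "J1", "J1", "J2"),
                       to = c("J1", "J2", "J2", "B"),
                       width = c(100, 100, 200, 100)),
    boundary = data.frame(node = c("A", "B"), rate = c(1, -1)))
  ps <- solve_flow_network(par)
  expect_equal(ps$edges$Q[3] / ps$edges$Q[2], 8, tolerance = 1e-9)
  ## equal widths split equally
  pe <- par; pe$edges$width <- 100
  pe2 <- solve_flow_network(chip_graph(pe$nodes, pe$edges, pe$boundary))
  expect_equal(pe2$edges$Q[3], pe2$edges$Q[2], tolerance = 1e-12)
})

test_that("straight transport is the identity and composes to itself", {
  expect_equal(transport_straight(0.5), 0.5)
  expect_equal(transport_straight(0.1), 0.1)
  xi <- 0.37
  for (k in 1:5) xi <- transport_straight(xi)
  expect_equal(xi, 0.37)
  expect_error(transport_straight(1.2))
})

test_that("a single straight chip composes to a straight line at xi", {
  one <- chip_graph(
    nodes = data.frame(id = c("A", "B"), x = c(0, 600), y = 0),
    edges = data.frame(id = "e", from = "A", to = "B", width = 100),
    boundary = data.frame(node = c("A", "B"), rate = c(1, -1)))
  one <- solve_flow_network(one)
  cp <- compose_trajectory(one, physics_predictor(), particle(10), "A", 0.3)
  expect_equal(cp$status, "EXITED")
  expect_equal(cp$exit_node, "B")
  expect_equal(cp$exit_xi, 0.3)
  ## facing +x flow, xi = 0.3 sits 0.3 W from the left (+y) wall
  expect_true(all(abs(cp$path$y - 20) < 1e-9))
})

test_that("a plus chip with one intersection equals the direct prediction", {
  plus <- chip_graph(
    nodes = data.frame(id = c("W", "N", "E", "S", "C"),
                       x = c(-300, 0, 300, 0, 0), y = c(0, 300, 0, -300, 0)),
    edges = data.frame(id = paste0("e", 1:4), from = c("W", "N", "E", "S"),
                       to = "C", width = 100),
    boundary = data.frame(node = c("W", "N", "E", "S"),
                          rate = c(1, -1.7, 0.4, 0.3)))
  plus <- solve_flow_network(plus)
  pred <- physics_predictor(n_across = 24)
  xi0 <- 0.45
  cp <- compose_trajectory(plus, pred, particle(8), "W", xi0)
  expect_equal(cp$status, "EXITED")
  expect_equal(cp$exit_node, "N")
  ## direct single-intersection prediction, re-embedded at the node C = origin
  y0 <- 50 - xi0 * 100
  seg <- pred(c(8, 100, -250, y0, 1, -1.7, 0.4))
  direct <- rbind(seg$entrance, seg$middle, seg$exit)
  comp <- as.matrix(cp$path[cp$path$unit == "X:C", c("x", "y")])
  expect_equal(unname(comp), unname(direct), tolerance = 1e-9)
  expect_lt(cp$max_gap, 0.02 * 100)
})

test_that("composition rejects exits that contradict the network solution", {
  plus <- chip_graph(
    nodes = data.frame(id = c("W", "N", "E", "S", "C"),
                       x = c(-300, 0, 300, 0, 0), y = c(0, 300, 0, -300, 0)),
    edges = data.frame(id = paste0("e", 1:4), from = c("W", "N", "E", "S"),
                       to = "C", width = 100),
    boundary = data.frame(node = c("W", "N", "E", "S"),
                          rate = c(1, -1.7, 0.4, 0.3)))
  plus <- solve_flow_network(plus)
  ## a predictor that always claims an East exit (East is an inlet here)
  liar <- function(features) {
    structure(list(entrance = matrix(0, 10, 2), middle = matrix(0, 10, 2),
                   exit = matrix(rep(c(250, 0), each = 10), 10),
                   entry_port = "W", exit_port = "E"),
              class = "segmented_trajectory")
  }
  expect_error(compose_trajectory(plus, liar, particle(8), "W", 0.5),
               "inflow")
})

test_that("chip JSON round-trips", {
  chip <- h_chip_fixture()
  tmp <- tempfile(fileext = ".json")
  write_chip_json(chip, tmp)
  chip2 <- read_chip_json(tmp)
  expect_equal(chip2$nodes$x, chip$nodes$x)
  expect_equal(chip2$edges$width, chip$edges$width)
  expect_equal(chip2$boundary$rate, chip$boundary$rate)
})

test_that("fixtures write the expected files and parameters", {
  fc <- fixture_cases()
  expect_equal(fc$width_um[fc$id == "A"], 190.34)
  expect_equal(fc$dp_um[fc$id == "A"], 13)
  expect_equal(fc$dp_um[fc$id == "I"], 11)
  expect_equal(fc$width_um[fc$id == "I"], 72.94)
  ## pinned default rates conserve mass
  expect_equal(fc$qW + fc$qN + fc$qE + fc$qS, rep(0, 9))
  dir <- tempfile()
  paths <- make_fixtures(dir)
  expect_true(all(file.exists(file.path(dir, c("h_chip.json",
                                               "intersection_cases.json")))))
  chip <- read_chip_json(file.path(dir, "h_chip.json"))
  expect_equal(decompose_chip(chip)$n_intersections, 2)
})
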