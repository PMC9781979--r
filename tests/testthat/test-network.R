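test_that("the chain maps 7 inputs to 60 outputs through 27-input blocks", {
  m <- build_network(network_spec(), seed = 1)
  ## block input widths: 7, 27 (= 7 + 20), 27
  expect_equal(vapply(m$blocks, function(b) nrow(b$W[[1]]), 1), c(7, 27, 27))
  ## six weight matrices per block: into 5 hidden layers plus the output
  expect_equal(vapply(m$blocks, function(b) length(b$W), 1), rep(6, 3))
  expect_true(all(vapply(m$blocks, function(b) ncol(b$W[[2]]), 1) == 400))
  expect_equal(vapply(m$blocks, function(b) ncol(b$W[[6]]), 1), rep(20, 3))
  Y <- predict_chain(m, matrix(runif(7), 1))
  expect_equal(dim(Y), c(1, 60))
  Y5 <- predict_chain(m, matrix(runif(35), 5))
  expect_equal(dim(Y5), c(5, 60))
  expect_error(network_spec("swish"), "unknown activation")
})

test_that("initialization is seeded and parameter counts are deterministic", {
  a <- build_network(network_spec(), seed = 7)
  b <- build_network(network_spec(), seed = 7)
  c <- build_network(network_spec(), seed = 8)
  expect_identical(a$blocks, b$blocks)
  expect_false(identical(a$blocks, c$blocks))
  ## 3 blocks x (in*400 + 3*400^2 + ... ) computed independently
  count_block <- function(nin) {
    sizes <- c(nin, rep(400, 5), 20)
    sum(sizes[-length(sizes)] * sizes[-1]) + sum(sizes[-1])
  }
  expect_equal(n_parameters(a), count_block(7) + 2 * count_block(27))
})

test_that("pooled R-squared matches hand-computed references", {
  expect_equal(r_squared(cbind(c(0, 1, 2)), cbind(c(0, 1, 2))), 1)
  truth <- cbind(c(0, 1, 2))
  expect_equal(r_squared(cbind(rep(mean(truth), 3)), truth), 0)
  expect_equal(r_squared(cbind(c(0, 1, 1)), truth), 0.5)
  expect_error(r_squared(cbind(c(1, 1)), cbind(c(1, 1))), "variance")
  expect_error(r_squared(cbind(1), cbind(1)))
})

test_that("training memorizes a duplicated dataset and is reproducible", {
  ## tiny architecture keeps this a seconds-scale check
  ds <- build_dataset(n_cases = 3, seed = 21)
  ds <- ds[rep(seq_len(nrow(ds)), length.out = 160), ]
  ds$case_seed <- rep(1:8, each = 20)   # synthetic case ids for the split
  ds$flow_case <- ds$case_seed %% 2     # keep flow case constant per case id
  nd <- normalize_records(ds)
  spec <- network_spec("leaky_relu", hidden_units = 128, hidden_layers = 3)
  cfg <- train_config(epochs = 2000, batch = 64, lr = 3e-3, seed = 2)
  m1 <- train_network(build_network(spec, 2), nd, cfg)
  expect_gt(m1$r2_test, 0.98)   # duplicated records: memorization limit
  expect_lt(utils::tail(m1$history$loss, 1), 2e-4)
  m2 <- train_network(build_network(spec, 2), nd, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$blocks, m2$blocks)
  ## loss history is monotone-ish: end far below start
  expect_lt(utils::tail(m1$history$loss, 1), m1$history$loss[1] / 100)
})

test_that("prediction de-normalizes, warns on extrapolation, and is stable", {
  ds <- build_dataset(n_cases = 3, seed = 21)
  ds <- ds[rep(seq_len(nrow(ds)), length.out = 160), ]
  ds$case_seed <- rep(1:8, each = 20)
  ds$flow_case <- ds$case_seed %% 2
  nd <- normalize_records(ds)
  spec <- network_spec("leaky_relu", hidden_units = 128, hidden_layers = 3)
  m <- train_network(build_network(spec, 2), nd,
                     train_config(epochs = 2000, batch = 64, lr = 3e-3, seed = 2))
  feats <- as.numeric(ds[1, paste0("feat_", 1:7)])
  s1 <- predict_trajectory(m, feats)
  s2 <- predict_trajectory(m, feats)
  expect_identical(s1$entrance, s2$entrance)
  expect_equal(dim(rbind(s1$entrance, s1$middle, s1$exit)), c(30, 2))
  ## on a memorized record the prediction tracks the targets (RMS over the
  ## 30 points, in um)
  truth <- matrix(as.numeric(ds[1, paste0("tgt_", 1:60)]), ncol = 2, byrow = TRUE)
  err <- rbind(s1$entrance, s1$middle, s1$exit) - truth
  expect_lt(sqrt(mean(err^2)), 0.05 * 500)
  expect_warning(predict_trajectory(m, c(25, feats[2:7])), "extrapolat")
  expect_error(predict_trajectory(build_network(spec, 1), feats), "scaler")
})

test_that("the activation study runs all arms under matched conditions", {
  ds <- build_dataset(n_cases = 4, seed = 33)
  ds <- ds[rep(seq_len(nrow(ds)), length.out = 200), ]
  ds$case_seed <- rep(1:10, each = 20)
  ds$flow_case <- ds$case_seed %% 2
  nd <- normalize_records(ds)
  cfg <- train_config(epochs = 40, batch = 64, seed = 3)
  tab <- activation_study(nd, config = cfg, hidden_units = 32,
                          hidden_layers = 2)
  expect_equal(tab$activation, c("leaky_relu", "relu", "sigmoid", "tanh"))
  expect_true(all(c("final_loss", "r2_train", "r2_test") %in% names(tab)))
  expect_true(all(tab$final_loss >= 0))
  expect_true(all(tab$r2_test <= 1))
  expect_error(activation_study(nd, activations = "swish", config = cfg),
               "unknown activation")
  ## identical seeds and activation give identical results
  tab2 <- activation_study(nd, activations = "tanh", config = cfg,
                           hidden_units = 32, hidden_layers = 2)
  expect_equal(tab2$r2_test, tab$r2_test[tab$activation == "tanh"])
})

test_that("model checkpoints round-trip through disk", {
  m <- build_network(network_spec(hidden_units = 16, hidden_layers = 1), 5)
  tmp <- tempfile(fileext = ".rds")
  write_model(m, tmp)
  m2 <- read_model(tmp)
  expect_equal(m2$blocks, m$blocks)
  X <- matrix(runif(14), 2)
  expect_identical(predict_chain(m, X), predict_chain(m2, X))
})
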