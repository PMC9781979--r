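.ACTIVATIONS <- c(leaky_relu = 0L, relu = 1L, sigmoid = 2L, tanh = 3L)

#' Chained dense-network specification
#'
#' The surrogate is a chain of three fully connected blocks. Block 1 maps
#' the 7 case features to the 20 entrance-segment coordinates; block 2 takes
#' the 7 features concatenated with block 1's 20 outputs (27 inputs) and
#' predicts the 20 middle-segment coordinates; block 3 likewise takes 27
#' inputs (features + middle segment) and predicts the 20 exit-segment
#' coordinates, for 60 outputs in total. Each block has five hidden fully
#' connected layers of `hidden_units` units (default 400) with the chosen
#' activation; input and output layers are linear.
#'
#' @param activation Hidden activation: `"leaky_relu"` (default), `"relu"`,
#'   `"sigmoid"` or `"tanh"`.
#' @param hidden_units Width of each hidden layer (default 400).
#' @param hidden_layers Number of hidden layers per block (default 5).
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(activation = "leaky_relu", hidden_units = 400,
                         hidden_layers = 5) {
  if (!activation %in% names(.ACTIVATIONS))
    stop("unknown activation: ", activation)
  structure(list(activation = activation, hidden_units = hidden_units,
                 hidden_layers = hidden_layers,
                 block_inputs = c(7L, 27L, 27L), block_output = 20L),
            class = "network_spec")
}

.block_sizes <- function(spec, k) {
  c(spec$block_inputs[k], rep(spec$hidden_units, spec$hidden_layers),
    spec$block_output)
}

#' Build a chained dense network with seeded initialization
#'
#' Weights are He-initialized for the ReLU family and Xavier-initialized for
#' sigmoid/tanh; biases start at zero. Two builds with the same seed are
#' identical.
#'
#' @param spec A [network_spec()].
#' @param seed RNG seed for the initialization.
#' @return An object of class `dense_chain`.
#' @export
build_network <- function(spec = network_spec(), seed = 1) {
  stopifnot(inherits(spec, "network_spec"))
  set.seed(seed)
  he <- spec$activation %in% c("leaky_relu", "relu")
  blocks <- lapply(1:3, function(k) {
    sizes <- .block_sizes(spec, k)
    W <- list(); b <- list()
    for (l in seq_len(length(sizes) - 1)) {
      sd <- if (he) sqrt(2 / sizes[l]) else sqrt(1 / sizes[l])
      W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], sd = sd),
                       sizes[l], sizes[l + 1])
      b[[l]] <- numeric(sizes[l + 1])
    }
    list(W = W, b = b)
  })
  structure(list(spec = spec, blocks = blocks, scaler = NULL,
                 history = NULL, seed = seed), class = "dense_chain")
}

#' Number of trainable parameters
#' @param model A `dense_chain`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$blocks, function(b)
    sum(vapply(b$W, length, 1)) + sum(vapply(b$b, length, 1)), 1))
}

#' @export
print.dense_chain <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Chained dense network: 3 blocks (%s), inputs 7/27/27 -> 20 each (60 total)\n",
              s$activation))
  cat(sprintf("  %d hidden layers x %d units per block; %s parameters%s\n",
              s$hidden_layers, s$hidden_units,
              format(n_parameters(x), big.mark = ","),
              if (!is.null(x$history)) " (trained)" else ""))
  invisible(x)
}

#' Forward pass of the chain
#'
#' @param model A `dense_chain`.
#' @param X n x 7 matrix of normalized features.
#' @param chained If `TRUE` (inference) each downstream block receives the
#'   previous block's prediction; if `FALSE` (teacher forcing) it receives
#'   the ground-truth segment from `Y`.
#' @param Y n x 60 matrix of normalized targets, required when
#'   `chained = FALSE`.
#' @return n x 60 matrix of normalized predicted coordinates.
#' @export
predict_chain <- function(model, X, chained = TRUE, Y = NULL) {
  X <- rbind(X)
  stopifnot(ncol(X) == 7)
  if (!chained && is.null(Y)) stop("teacher forcing requires Y")
  if (is.null(Y)) Y <- matrix(0, nrow(X), 60)
  forward_chain_cpp(X, model$blocks, .ACTIVATIONS[[model$spec$activation]],
                    chained, rbind(Y))
}

#' Training configuration
#'
#' Minibatch Adam on the summed mean-squared error of the three blocks in
#' normalized coordinates. The split, initialization and batch order are
#' all fixed by `seed`, so identical configurations give identical
#' histories.
#'
#' @param epochs Training epochs (default 200 at desk scale).
#' @param batch Minibatch size.
#' @param lr Initial Adam learning rate.
#' @param train_frac Fraction of cases in the training split (default 0.7).
#' @param seed Seed controlling split and batch order.
#' @param chain_mode How downstream blocks are fed during training:
#'   `"chained"` (default: predictions, with gradients flowing through the
#'   whole chain -- this matches the inference-time regime the model is
#'   evaluated in), `"teacher"` (ground-truth upstream segments
#'   throughout), or `"curriculum"` (teacher-forced warmup for the first
#'   40% of epochs, then chained fine-tuning).
#' @param lr_schedule `"cosine"` (default: cosine anneal from `lr` to
#'   `lr / 100`) or `"step"` (decay by 0.3 at 70% and 90% of the budget).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 200, batch = 256, lr = 1e-3,
                         train_frac = 0.7, seed = 1,
                         chain_mode = c("chained", "teacher", "curriculum"),
                         lr_schedule = c("cosine", "step")) {
  stopifnot(epochs >= 1, train_frac > 0, train_frac < 1)
  structure(list(epochs = as.integer(epochs), batch = as.integer(batch),
                 lr = lr, train_frac = train_frac, seed = as.integer(seed),
                 chain_mode = match.arg(chain_mode),
                 lr_schedule = match.arg(lr_schedule)),
            class = "train_config")
}

#' Pooled coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` pooled over all output dimensions of the
#' evaluation set, with per-dimension means in `SS_tot`. This is the
#' accuracy-rate metric of the surrogate; a per-dimension mean predictor
#' scores exactly 0 and perfect predictions score 1.
#'
#' @param pred,truth Matrices of equal shape with at least 2 rows.
#' @return Scalar R-squared.
#' @examples
#' r_squared(cbind(c(0, 1, 1)), cbind(c(0, 1, 2)))  # 0.5
#' @export
r_squared <- function(pred, truth) {
  pred <- rbind(pred); truth <- rbind(truth)
  stopifnot(all(dim(pred) == dim(truth)), nrow(truth) >= 2)
  ss_tot <- sum(sweep(truth, 2, colMeans(truth))^2)
  if (ss_tot == 0) stop("zero total variance in truth")
  1 - sum((pred - truth)^2) / ss_tot
}

## per-dimension-averaged R^2 (secondary report; dims with zero variance
## are dropped)
.r_squared_per_dim <- function(pred, truth) {
  v <- apply(truth, 2, stats::var)
  keep <- v > 0
  mean(vapply(which(keep), function(j)
    1 - sum((pred[, j] - truth[, j])^2) / sum((truth[, j] - mean(truth[, j]))^2),
    1))
}

#' Train the chained surrogate
#'
#' Splits the dataset 70/30 at the case level (stratified by fluid case),
#' then minimizes the summed MSE of the three block outputs with minibatch
#' Adam, feeding downstream blocks per `chain_mode`. Reported R-squared
#' values use predicted chaining (inference mode), the metric that matters
#' for deployment.
#'
#' @param model A [build_network()] result.
#' @param dataset A normalized dataset from [normalize_records()].
#' @param config A [train_config()].
#' @return The trained `dense_chain` with `history` (per-epoch loss),
#'   `r2_train`, `r2_test`, `split`, and the scaler attached.
#' @export
train_network <- function(model, dataset, config = train_config()) {
  stopifnot(inherits(model, "dense_chain"))
  ds <- dataset$data
  if (is.null(ds)) stop("dataset must come from normalize_records()")
  if (nrow(ds) < 100) stop("need at least 100 records for a meaningful split")
  X <- as.matrix(ds[paste0("feat_", 1:7)])
  Y <- as.matrix(ds[paste0("tgt_", 1:60)])
  sp <- split_dataset(ds, config$train_frac, config$seed)
  if (!length(sp$train) || !length(sp$test)) stop("empty split")
  Xtr <- X[sp$train, , drop = FALSE]; Ytr <- Y[sp$train, , drop = FALSE]
  set.seed(config$seed + 1L)
  perms <- vapply(seq_len(config$epochs),
                  function(e) sample.int(nrow(Xtr)) - 1L,
                  integer(nrow(Xtr)))
  ep <- seq_len(config$epochs)
  lr_epoch <- if (identical(config$lr_schedule, "cosine")) {
    config$lr * pmax(0.5 * (1 + cos(pi * (ep - 1) / max(config$epochs - 1, 1))), 0.01)
  } else {
    config$lr * ifelse(ep > 0.9 * config$epochs, 0.09,
                       ifelse(ep > 0.7 * config$epochs, 0.3, 1))
  }
  teacher_epoch <- switch(config$chain_mode,
    teacher = rep(1L, config$epochs),
    chained = rep(0L, config$epochs),
    curriculum = as.integer(ep <= 0.4 * config$epochs))
  fit <- train_chain_cpp(X = Xtr, Y = Ytr, blocks_init = model$blocks,
                         act = .ACTIVATIONS[[model$spec$activation]],
                         batch = config$batch, lr_epoch = lr_epoch,
                         teacher_epoch = teacher_epoch, perms = perms)
  model$blocks <- lapply(fit$blocks, function(b) list(W = b$W, b = lapply(b$b, as.numeric)))
  model$history <- data.frame(epoch = seq_len(config$epochs),
                              loss = as.numeric(fit$loss))
  model$scaler <- dataset$scaler
  Ptr <- predict_chain(model, Xtr)
  Pte <- predict_chain(model, X[sp$test, , drop = FALSE])
  model$r2_train <- r_squared(Ptr, Ytr)
  model$r2_test <- r_squared(Pte, Y[sp$test, , drop = FALSE])
  model$r2_train_per_dim <- .r_squared_per_dim(Ptr, Ytr)
  model$r2_test_per_dim <- .r_squared_per_dim(Pte, Y[sp$test, , drop = FALSE])
  model$split <- sp
  model$config <- config
  model
}

#' Predict a segmented trajectory from case features
#'
#' Runs the chain in inference mode (each block fed the previous block's
#' prediction), de-normalizes, and returns the three 10-point segments in
#' junction-centered micrometres. Millisecond-scale; no flow solve involved.
#'
#' @param model A trained `dense_chain`.
#' @param features Numeric length-7: `(Dp_um, width_um, x0_um, y0_um,
#'   qW, qN, qE)` in raw units (um, cm/s).
#' @param scaler A [range_scaler()]; defaults to the one stored in the model.
#' @return A `segmented_trajectory` (exit port inferred from the final
#'   predicted point's nearest port arm).
#' @export
predict_trajectory <- function(model, features, scaler = model$scaler) {
  if (is.null(scaler)) stop("no scaler: train the model or pass one explicitly")
  stopifnot(length(features) == 7)
  Xn <- normalize_features(scaler, matrix(features, 1))
  if (any(Xn < -1e-9 | Xn > 1 + 1e-9))
    warning("features outside the sampled training ranges; extrapolating")
  Yn <- predict_chain(model, Xn)
  Y <- denormalize_targets(scaler, Yn)
  pts <- matrix(Y, ncol = 2, byrow = TRUE)
  seg <- list(entrance = pts[1:10, ], middle = pts[11:20, ], exit = pts[21:30, ])
  ## infer the exit arm from the final point
  last <- pts[30, ]
  width <- features[2]
  geom <- cross_geometry(width, scaler$arm_ratio * width)
  reg <- point_region(geom, last[1], last[2])
  seg$exit_port <- if (reg %in% PORTS) reg else
    c("W", "E", "S", "N")[which.max(c(-last[1], last[1], -last[2], last[2]))]
  seg$entry_port <- point_region(geom, pts[1, 1], pts[1, 2])
  structure(seg, class = "segmented_trajectory")
}

#' Compare hidden activations at matched budget
#'
#' Trains the same architecture on the same dataset, split and seeds once
#' per activation and tabulates final loss and train/test R-squared -- the
#' activation benchmark for choosing the deployment surrogate. With adequate
#' data the test ordering is Leaky ReLU >= ReLU >= Tanh >= Sigmoid.
#'
#' @param dataset A normalized dataset from [normalize_records()].
#' @param activations Character vector of activations to compare.
#' @param config A [train_config()] shared by every arm.
#' @param hidden_units,hidden_layers Architecture knobs shared by every arm.
#' @param verbose Print a line per arm.
#' @return A data.frame with one row per activation: `final_loss`,
#'   `r2_train`, `r2_test`.
#' @export
activation_study <- function(dataset,
                             activations = c("leaky_relu", "relu", "sigmoid", "tanh"),
                             config = train_config(),
                             hidden_units = 400, hidden_layers = 5,
                             verbose = FALSE) {
  bad <- setdiff(activations, names(.ACTIVATIONS))
  if (length(bad)) stop("unknown activation: ", paste(bad, collapse = ", "))
  rows <- lapply(activations, function(a) {
    m <- build_network(network_spec(a, hidden_units, hidden_layers),
                       seed = config$seed)
    m <- train_network(m, dataset, config)
    if (verbose)
      message(sprintf("%-10s loss %.3e  train R2 %.4f  test R2 %.4f",
                      a, utils::tail(m$history$loss, 1), m$r2_train, m$r2_test))
    data.frame(activation = a, final_loss = utils::tail(m$history$loss, 1),
               r2_train = m$r2_train, r2_test = m$r2_test)
  })
  do.call(rbind, rows)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a list (architecture spec, weight arrays, scaler,
#' training history) in RDS form.
#'
#' @param model A `dense_chain`.
#' @param path Checkpoint path.
#' @export
write_model <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  structure(readRDS(path), class = "dense_chain")
}
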