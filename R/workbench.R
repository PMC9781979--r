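## Pipeline entry points behind the command-line tool (inst/cli/crossflow.R).
## Each run writes its artifact plus a JSON manifest (config, master seed,
## package version) so any output is reproducible from its manifest. The
## master seed fans out to fixed-offset sub-seeds: sampler = seed,
## split/batching = seed + 1 (inside train_network), so stages are
## independently reproducible.

.manifest <- function(path, config) {
  jsonlite::write_json(c(config, list(
    package = "crossflow",
    version = as.character(utils::packageVersion("crossflow")))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Generate a dataset and write it to CSV
#'
#' Runs sample -> solve -> trace -> segment, writes the records CSV, the
#' scaler JSON sidecar and a manifest, and logs the frozen/timed-out
#' trajectory counts.
#'
#' @param n_cases,seeds_per_case,seed,n_across As [build_dataset()].
#' @param out Output CSV path (sidecars get `.scaler.json` and
#'   `.manifest.json` suffixes).
#' @param quiet Suppress the log line.
#' @return The dataset, invisibly.
#' @export
run_generate <- function(n_cases, seeds_per_case = 10, seed = 1,
                         n_across = 24, out = "dataset.csv", quiet = FALSE) {
  ds <- build_dataset(n_cases, seeds_per_case, seed, n_across)
  utils::write.csv(ds, out, row.names = FALSE)
  write_scaler_json(range_scaler(), paste0(out, ".scaler.json"))
  .manifest(paste0(out, ".manifest.json"),
            list(command = "generate", n_cases = n_cases,
                 seeds_per_case = seeds_per_case, seed = seed,
                 n_across = n_across,
                 n_records = nrow(ds),
                 n_frozen = attr(ds, "n_frozen"),
                 n_max_time = attr(ds, "n_max_time")))
  if (!quiet)
    message(sprintf("generated %d records from %d cases (%d frozen, %d timed out)",
                    nrow(ds), n_cases, attr(ds, "n_frozen"), attr(ds, "n_max_time")))
  invisible(ds)
}

#' Read a dataset CSV written by [run_generate()]
#' @param path CSV path.
#' @return The records data.frame.
#' @export
read_dataset_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Train a surrogate from a dataset CSV and checkpoint it
#'
#' @param data Dataset CSV path (from [run_generate()]).
#' @param activation Hidden activation.
#' @param epochs,batch,lr,seed Training knobs; see [train_config()].
#' @param out Checkpoint path; metrics CSV and manifest written alongside.
#' @param quiet Suppress the log line.
#' @return The trained model, invisibly.
#' @export
run_train <- function(data, activation = "leaky_relu", epochs = 200,
                      batch = 256, lr = 1e-3, seed = 1,
                      out = "model.rds", quiet = FALSE) {
  ds <- read_dataset_csv(data)
  nd <- normalize_records(ds)
  cfg <- train_config(epochs = epochs, batch = batch, lr = lr, seed = seed)
  model <- build_network(network_spec(activation), seed = seed)
  model <- train_network(model, nd, cfg)
  write_model(model, out)
  utils::write.csv(model$history, paste0(out, ".metrics.csv"), row.names = FALSE)
  .manifest(paste0(out, ".manifest.json"),
            list(command = "train", data = data, activation = activation,
                 epochs = epochs, batch = batch, lr = lr, seed = seed,
                 r2_train = model$r2_train, r2_test = model$r2_test))
  if (!quiet)
    message(sprintf("trained %s: train R2 %.4f, test R2 %.4f",
                    activation, model$r2_train, model$r2_test))
  invisible(model)
}

#' Evaluate a checkpoint on a dataset CSV
#'
#' @param model Checkpoint path or `dense_chain`.
#' @param data Dataset CSV path.
#' @return A list with pooled `r2` and `r2_per_dim` over the whole file.
#' @export
run_evaluate <- function(model, data) {
  if (is.character(model)) model <- read_model(model)
  ds <- read_dataset_csv(data)
  nd <- normalize_records(ds)
  X <- as.matrix(nd$data[paste0("feat_", 1:7)])
  Y <- as.matrix(nd$data[paste0("tgt_", 1:60)])
  P <- predict_chain(model, X)
  list(r2 = r_squared(P, Y), r2_per_dim = .r_squared_per_dim(P, Y),
       n = nrow(X))
}

#' Predict one trajectory from raw features
#'
#' @param model Checkpoint path or `dense_chain`.
#' @param features Length-7 numeric `(Dp, W, x0, y0, qW, qN, qE)`.
#' @return A `segmented_trajectory`.
#' @export
run_predict <- function(model, features) {
  if (is.character(model)) model <- read_model(model)
  predict_trajectory(model, features)
}

#' Compose a whole-chip path and write it to CSV
#'
#' @param chip Chip JSON path or [chip_graph()].
#' @param model Checkpoint path, `dense_chain`, or `NULL` to use the
#'   physics oracle at intersections.
#' @param entry Entry terminal node id.
#' @param xi Entry lateral fraction.
#' @param dp Particle diameter, um.
#' @param out Optional CSV path for the composed path (with unit column).
#' @return The `chip_path`, invisibly.
#' @export
run_compose <- function(chip, model = NULL, entry, xi = 0.5, dp = 10,
                        out = NULL) {
  if (is.character(chip)) chip <- read_chip_json(chip)
  chip <- solve_flow_network(chip)
  pred <- if (is.null(model)) physics_predictor()
          else surrogate_predictor(if (is.character(model)) read_model(model) else model)
  cp <- compose_trajectory(chip, pred, particle(dp), entry, xi)
  if (!is.null(out)) utils::write.csv(cp$path, out, row.names = FALSE)
  invisible(cp)
}
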