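#' Pipeline run configuration
#'
#' @param seed Master seed driving generation, splitting, and training.
#' @param n_per_class Synthetic segment counts per class.
#' @param model `"rnn"` or `"ert"`.
#' @param layer_sizes RNN architecture (input width is fixed by the data;
#'   hidden/output defaults 100, 80, 4).
#' @param learning_rate,epochs,scale RNN training hyperparameters.
#' @param train_fraction Train share of the shuffled split.
#' @param out_dir Optional directory for artifacts (features CSV, model
#'   JSON, report JSON).
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1, n_per_class = c(400, 400, 400, 400),
                       model = c("rnn", "ert"),
                       layer_sizes = NULL, learning_rate = 0.2,
                       epochs = 300, scale = 0.9, train_fraction = 0.9,
                       out_dir = NULL) {
  model <- match.arg(model)
  structure(list(seed = seed, n_per_class = n_per_class, model = model,
                 layer_sizes = layer_sizes, learning_rate = learning_rate,
                 epochs = epochs, scale = scale,
                 train_fraction = train_fraction, out_dir = out_dir),
            class = "run_config")
}

#' Run the full pipeline: simulate, featurize, train, evaluate
#'
#' Generates a seeded synthetic dataset, extracts and normalizes features
#' (normalizer fitted on the training split only), trains the requested
#' classifier, and evaluates it on the held-out split. With `out_dir` set,
#' the feature table, trained model, and report are written to disk.
#'
#' @param config A [run_config()].
#' @param segments Optional pre-built list of [eeg_segment()] (skips the
#'   synthetic stage, e.g. for EDF-imported data).
#' @param verbose Log stage progress.
#' @return List with `report` (an `evaluation_report`), `model`,
#'   `features`, `normalizer`, `split`, and `config`.
#' @export
run_pipeline <- function(config = run_config(), segments = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message("[eegrnn] ", ...)

  if (is.null(segments)) {
    say("simulate: ", paste(config$n_per_class, collapse = "/"),
        " segments, seed ", config$seed)
    segments <- generate_dataset(
      synthetic_config(config$n_per_class, seed = config$seed))
  }
  say("featurize: ", length(segments), " segments")
  feats <- featurize_segments(segments)

  if (config$model == "ert") {
    say("train: extremely randomized trees")
    fit <- train_baseline("ert", feats, config$train_fraction,
                          seed = config$seed)
    out <- list(report = fit$report, model = fit$model, features = feats,
                normalizer = NULL, split = fit$split, config = config)
  } else {
    split <- split_train_test(nrow(feats), config$train_fraction,
                              seed = config$seed)
    fc <- feature_columns(feats)
    norm <- fit_normalizer(feats[split$train, ])
    Xtr <- apply_normalizer(norm, as.matrix(feats[split$train, fc]))
    Xte <- apply_normalizer(norm, as.matrix(feats[split$test, fc]))
    arch <- config$layer_sizes %||% c(ncol(Xtr), 100, 80, 4)
    say("train: random neural network ", paste(arch, collapse = "-"),
        ", lr ", config$learning_rate, ", ", config$epochs, " epochs")
    net <- train_rnn(Xtr, feats$label[split$train], layer_sizes = arch,
                     learning_rate = config$learning_rate,
                     epochs = config$epochs, scale = config$scale,
                     seed = config$seed)
    say("evaluate: ", length(split$test), " held-out segments")
    pred <- predict(net, Xte)
    report <- evaluation_metrics(confusion(feats$label[split$test],
                                           pred$label))
    report$metadata <- list(model = "rnn", seed = config$seed,
                            architecture = arch,
                            learning_rate = config$learning_rate,
                            epochs = config$epochs,
                            train_fraction = config$train_fraction)
    out <- list(report = report, model = net, features = feats,
                normalizer = norm, split = split, config = config)
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(feats, file.path(config$out_dir, "features.csv"),
              row.names = FALSE)
    report_to_json(out$report, file.path(config$out_dir, "report.json"))
    if (config$model == "rnn")
      save_rnn(out$model, file.path(config$out_dir, "model.json"),
               normalizer = out$normalizer)
    say("artifacts written to ", config$out_dir)
  }
  out
}

#' K-fold cross-validated evaluation
#'
#' Refits the normalizer and the model inside every fold (no leakage) and
#' pools the held-out predictions into a single confusion matrix.
#'
#' @param features Feature data frame with a `label` column.
#' @param k Number of folds.
#' @param seed Integer seed for fold assignment and training.
#' @param model `"rnn"` or `"ert"`.
#' @param stratify Stratify folds by label (default `FALSE`).
#' @param ... Passed to [train_rnn()] (e.g. `layer_sizes`, `epochs`) or to
#'   [ranger::ranger()]-backed training.
#' @return An `evaluation_report` over the pooled predictions.
#' @export
cross_validate <- function(features, k = 10, seed = 1,
                           model = c("rnn", "ert"), stratify = FALSE, ...) {
  model <- match.arg(model)
  n <- nrow(features)
  folds <- kfold(n, k, seed = seed,
                 stratify_labels = if (stratify) features$label else NULL)
  fc <- feature_columns(features)
  y_true <- integer(0); y_pred <- integer(0)
  for (f in seq_len(k)) {
    test <- folds[[f]]; train <- setdiff(seq_len(n), test)
    if (model == "rnn") {
      norm <- fit_normalizer(features[train, ])
      Xtr <- apply_normalizer(norm, as.matrix(features[train, fc]))
      Xte <- apply_normalizer(norm, as.matrix(features[test, fc]))
      net <- train_rnn(Xtr, features$label[train], seed = seed, ...)
      pred <- predict(net, Xte)$label
    } else {
      df <- data.frame(label = factor(features$label, levels = 0:3),
                       features[, fc, drop = FALSE])
      fit <- ranger::ranger(label ~ ., data = df[train, ], num.trees = 300,
                            splitrule = "extratrees", num.random.splits = 1,
                            replace = FALSE, sample.fraction = 1, seed = seed)
      pred <- as.integer(as.character(predict(fit, df[test, ])$predictions))
    }
    y_true <- c(y_true, features$label[test])
    y_pred <- c(y_pred, pred)
  }
  report <- evaluation_metrics(confusion(y_true, y_pred))
  report$metadata <- list(model = model, k = k, seed = seed,
                          stratified = stratify)
  report
}
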