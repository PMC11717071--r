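# polynomial rolling hash of a string; cheap content fingerprint for run
# manifests (stays below 2^31 so double arithmetic is exact)
.fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 21661
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Assemble a run configuration
#'
#' @param data either `list(synthetic = list(...))` with arguments for
#'   [synthetic_spec()], or `list(path = "spectra.csv")`.
#' @param preprocess list of preprocessing steps for [preprocess_chain()]
#'   (default mean centering, the study's choice).
#' @param selection list with `method` in
#'   `c("CU", "CARS", "UVE", "none")` and optional `cars`/`uve` parameter
#'   lists.
#' @param model list with `type` in `c("bilstm_attention", "bilstm",
#'   "lstm")`, optional `config` (arguments for [net_config()]), and
#'   optional `tune = list(n_whales, max_iterations)` to run the whale
#'   search instead of a fixed config.
#' @param split list with `ratio` (default 0.7), `seed`, `stratify`.
#' @param val_fraction fraction of the training set held out as the
#'   validation set for tuning/monitoring (default 0.2).
#' @param seed master seed for every stage.
#' @param output_dir directory for run artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(data = list(synthetic = list()),
                       preprocess = list("MC"),
                       selection = list(method = "CU"),
                       model = list(type = "bilstm_attention"),
                       split = list(ratio = 0.7, stratify = TRUE),
                       val_fraction = 0.2,
                       seed = 1L,
                       output_dir = tempfile("specalib_run_")) {
  if (sum(!is.null(data$synthetic), !is.null(data$path)) != 1)
    stop("config must name exactly one data source (synthetic or path)")
  structure(list(data = data, preprocess = preprocess,
                 selection = selection, model = model, split = split,
                 val_fraction = val_fraction, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose top-level keys match [run_config()]
#'   arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Execute the full calibration pipeline
#'
#' Stages, in order: load or generate the dataset; split into
#' calibration/validation/prediction sets; fit the preprocessing chain on
#' the calibration spectra and apply it everywhere; run the configured
#' wavelength selection; train (or whale-tune, then train) the configured
#' model; evaluate. Every artifact lands in `cfg$output_dir`:
#' `manifest.json` (config hash + seeds), `selected_wavelengths.txt`,
#' `metrics.json`, `model.json` (checkpoint), `history.csv` (per-epoch
#' losses) and, when tuning, `tuning_audit.csv`.
#'
#' @param cfg a [run_config()] (or a YAML path accepted by
#'   [read_run_config()]).
#' @return List with `dataset`, `split` indices, fitted `chain`,
#'   `selected` band indices, fitted `model`, `metrics` and
#'   `artifact_dir`; invisibly also written to disk.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$output_dir, "run.log")
  logline <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = log_path, append = TRUE)
  }
  started <- Sys.time()

  # --- data ---
  ds <- if (!is.null(cfg$data$synthetic)) {
    sp <- do.call(synthetic_spec,
                  c(cfg$data$synthetic,
                    if (is.null(cfg$data$synthetic$seed))
                      list(seed = cfg$seed)))
    generate_synthetic(sp)
  } else read_spectra(cfg$data$path)
  logline("data: ", nrow(ds$reflectance), " spectra x ",
          ncol(ds$reflectance), " bands")

  # --- split ---
  ratio <- cfg$split$ratio %||% 0.7
  strat <- cfg$split$stratify %||% TRUE
  sp <- split_spectra(ds, ratio, seed = cfg$seed, stratify = strat)
  train_ds <- sp$train; test_ds <- sp$test
  # validation carved from the training set
  vspl <- split_spectra(train_ds, 1 - cfg$val_fraction,
                        seed = cfg$seed + 1L, stratify = strat)
  fit_ds <- vspl$train; val_ds <- vspl$test
  logline("split: ", nrow(fit_ds$reflectance), " train / ",
          nrow(val_ds$reflectance), " val / ",
          nrow(test_ds$reflectance), " test (seed ", cfg$seed, ")")

  # --- preprocess (fitted on the full calibration set) ---
  chain <- fit_chain(preprocess_chain(cfg$preprocess),
                     train_ds$reflectance)
  Xfit <- apply_chain(chain, fit_ds$reflectance)
  Xval <- apply_chain(chain, val_ds$reflectance)
  Xtrain <- apply_chain(chain, train_ds$reflectance)
  Xtest <- apply_chain(chain, test_ds$reflectance)

  # --- wavelength selection ---
  method <- toupper(cfg$selection$method %||% "CU")
  sel <- switch(method,
    NONE = seq_len(ncol(Xtrain)),
    CARS = do.call(cars_select,
                   c(list(X = Xtrain, y = train_ds$analyte,
                          seed = cfg$seed),
                     cfg$selection$cars))$selected,
    UVE = do.call(uve_select,
                  c(list(X = Xtrain, y = train_ds$analyte,
                         seed = cfg$seed),
                    cfg$selection$uve))$selected,
    CU = cu_cascade(Xtrain, train_ds$analyte,
                    c(list(seed = cfg$seed), cfg$selection$cars),
                    c(list(seed = cfg$seed), cfg$selection$uve))$selected,
    stop("unknown selection method: ", method))
  logline("selection (", method, "): ", length(sel), " bands")
  writeLines(format(ds$wavelengths[sel], digits = 8, trim = TRUE),
             file.path(cfg$output_dir, "selected_wavelengths.txt"))

  # --- model ---
  type <- cfg$model$type %||% "bilstm_attention"
  tuning <- NULL
  if (!is.null(cfg$model$tune)) {
    tuning <- tune_network(Xfit[, sel, drop = FALSE], fit_ds$analyte,
                           Xval[, sel, drop = FALSE], val_ds$analyte,
                           n_whales = cfg$model$tune$n_whales %||% 6L,
                           max_iterations =
                             cfg$model$tune$max_iterations %||% 5L,
                           seed = cfg$seed, model_type = type)
    net_cfg <- tuning$config
    write.table(tuning$audit,
                file.path(cfg$output_dir, "tuning_audit.csv"),
                sep = ",", row.names = FALSE, quote = FALSE)
    logline("tuning: best validation MSE ",
            format(tuning$best_fitness, digits = 5))
  } else {
    net_cfg <- do.call(net_config,
                       c(cfg$model$config,
                         if (is.null(cfg$model$config$seed))
                           list(seed = cfg$seed)))
  }
  model <- bilstm_attention(Xfit[, sel, drop = FALSE], fit_ds$analyte,
                            net_cfg, model_type = type,
                            x_val = Xval[, sel, drop = FALSE],
                            y_val = val_ds$analyte)
  save_model(model, file.path(cfg$output_dir, "model.json"))
  write.table(model$history, file.path(cfg$output_dir, "history.csv"),
              sep = ",", row.names = FALSE, quote = FALSE)

  # --- evaluation ---
  metrics <- metrics_report(
    type,
    train_ds$analyte, predict(model, Xtrain[, sel, drop = FALSE]),
    test_ds$analyte, predict(model, Xtest[, sel, drop = FALSE]))
  jsonlite::write_json(as.data.frame(metrics),
                       file.path(cfg$output_dir, "metrics.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "rows")
  logline("metrics: RP2 ", format(metrics$RP2, digits = 5),
          ", RMSEP ", format(metrics$RMSEP, digits = 5))

  manifest <- list(
    config = unclass(cfg),
    config_hash = .fnv1a(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                                          digits = NA)),
    seed = cfg$seed,
    n_selected = length(sel),
    started = format(started), finished = format(Sys.time()))
  jsonlite::write_json(manifest, file.path(cfg$output_dir,
                                           "manifest.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)

  invisible(list(dataset = ds, train = train_ds, test = test_ds,
                 chain = chain, selected = sel, model = model,
                 tuning = tuning, metrics = metrics,
                 artifact_dir = cfg$output_dir))
}
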