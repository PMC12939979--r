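# End-to-end orchestration: split -> (bake-off) -> preprocess -> select ->
# grid-search fit -> evaluate -> attribute, with reproducible artifacts.

#' Assemble and validate a pipeline configuration
#'
#' All stochastic stages derive their seeds from the single master seed via
#' fixed stream offsets, so a configuration reproduces a run exactly.
#'
#' @param spectra,references Paths to the input CSVs (see
#'   [read_spectra_csv()]), or `NULL` when `dataset` is supplied directly.
#' @param dataset Optional in-memory [spectral_dataset()].
#' @param out_dir Output directory for run artifacts.
#' @param indicator Target column to model.
#' @param preprocess `"auto"` (bake-off) or a method name accepted by
#'   [preprocess_method()].
#' @param ratio Calibration share for the SPXY split.
#' @param selector One of `"psoga"`, `"pso"`, `"ga"`, `"gwo"`, `"cars"`.
#' @param selector_cfg A [selector_config()]; its seed is overridden by the
#'   master seed.
#' @param grid_cfg A [hyper_grid()].
#' @param seed Master seed.
#' @return Object of class `run_config`.
#' @export
run_config <- function(spectra = NULL, references = NULL, dataset = NULL,
                       out_dir = tempfile("specswarm_run_"),
                       indicator = "tvbn", preprocess = "RAW",
                       ratio = 0.75, selector = "psoga",
                       selector_cfg = selector_config(),
                       grid_cfg = hyper_grid(), seed = 1) {
  if (is.null(dataset)) {
    if (is.null(spectra) || is.null(references)) {
      stop("either a dataset or spectra + references paths are required")
    }
    if (!file.exists(spectra)) stop(sprintf("spectra file not found: %s", spectra))
    if (!file.exists(references)) {
      stop(sprintf("references file not found: %s", references))
    }
  }
  if (!selector %in% c("psoga", "pso", "ga", "gwo", "cars")) {
    stop("unknown selector method")
  }
  if (!identical(preprocess, "auto")) preprocess_method(preprocess)
  selector_cfg$seed <- as.integer(seed)
  selector_cfg$fitness_seed <- derive_seed(seed, .stream_offsets["fitness"])
  structure(
    list(spectra = spectra, references = references, dataset = dataset,
         out_dir = out_dir, indicator = indicator, preprocess = preprocess,
         ratio = ratio, selector = selector, selector_cfg = selector_cfg,
         grid_cfg = grid_cfg, seed = as.integer(seed)),
    class = "run_config"
  )
}

select_with <- function(method, X, y, cfg) {
  switch(method,
    psoga = psoga_select(X, y, cfg),
    pso = pso_select(X, y, cfg),
    ga = ga_select(X, y, cfg),
    gwo = gwo_select(X, y, cfg),
    cars = {
      m <- cars_select(X, y, cv_folds = cfg$cv_folds, seed = cfg$seed)
      new_trace(numeric(0), integer(0), as.logical(m), nrow(attr(m, "log")),
                "cars")
    }
  )
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage \"%s\" failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
  message(sprintf("[%s] done in %.1fs", name,
                  as.numeric(Sys.time() - t0, units = "secs")))
  out
}

#' Run the full wavelength-selection pipeline
#'
#' Executes SPXY splitting, optional preprocessing bake-off, preprocessing,
#' wavelength selection, grid-searched model fitting, evaluation and Shapley
#' attribution, writing `mask.csv`, `trace.csv`, `report.json`, `shap.csv`
#' and `manifest.json` into the configured output directory. Re-running the
#' same configuration reproduces `report.json` byte for byte.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the output directory and the in-memory
#'   results (`split`, `trace`, `model`, `report`, `attribution`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- stage("load", {
    if (!is.null(cfg$dataset)) cfg$dataset
    else read_spectra_csv(cfg$spectra, cfg$references)
  })
  iv <- indicator_values(ds, cfg$indicator)
  X_raw <- ds$reflectance[iv$rows, , drop = FALSE]
  y <- iv$y
  split <- stage("split", spxy_split(X_raw, y, cfg$ratio))
  pp_name <- cfg$preprocess
  bake <- NULL
  if (identical(pp_name, "auto")) {
    bake <- stage("bake_off", bake_off(ds, cfg$indicator,
                                       split = split,
                                       model_cfg = list(seed = cfg$seed)))
    pp_name <- bake$method[1]
  }
  method <- preprocess_method(pp_name)
  fp <- fit_preprocessor(method, X_raw[split$calibration_idx, , drop = FALSE])
  X_cal <- apply_preprocessor(fp, X_raw[split$calibration_idx, , drop = FALSE],
                              ds$grid$step_nm)
  X_pred <- apply_preprocessor(fp, X_raw[split$prediction_idx, , drop = FALSE],
                               ds$grid$step_nm)
  y_cal <- y[split$calibration_idx]
  y_pred <- y[split$prediction_idx]
  trace <- stage("select",
                 select_with(cfg$selector, X_cal, y_cal, cfg$selector_cfg))
  mask <- trace$best_mask
  write_mask(mask, ds$grid, file.path(cfg$out_dir, "mask.csv"))
  if (length(trace$best_fitness_per_iter)) {
    utils::write.csv(
      data.frame(iteration = seq_along(trace$best_fitness_per_iter),
                 best_mse = trace$best_fitness_per_iter,
                 n_selected = trace$n_selected_per_iter),
      file.path(cfg$out_dir, "trace.csv"), row.names = FALSE, quote = FALSE
    )
  }
  cols <- which(mask)
  Xc <- X_cal[, cols, drop = FALSE]
  Xp <- X_pred[, cols, drop = FALSE]
  colnames(Xc) <- colnames(Xp) <- paste0("nm", ds$grid$values[cols])
  model <- stage("fit", grid_search_fit(Xc, y_cal, cfg$grid_cfg,
                                        seed = derive_seed(cfg$seed,
                                                           .stream_offsets["model"])))
  report <- stage("evaluate", evaluate_model(model, Xc, y_cal, Xp, y_pred))
  am <- stage("attribute", tree_shapley(model, Xp))
  shap_df <- cbind(
    data.frame(sample_id = ds$sample_ids[iv$rows][split$prediction_idx]),
    as.data.frame(am$values),
    data.frame(base_value = am$base_value, prediction = am$predictions)
  )
  utils::write.csv(shap_df, file.path(cfg$out_dir, "shap.csv"),
                   row.names = FALSE, quote = FALSE)
  report_json <- list(
    indicator = cfg$indicator, selector = cfg$selector,
    preprocess = pp_name, seed = cfg$seed,
    n_calibration = length(split$calibration_idx),
    n_prediction = length(split$prediction_idx),
    n_features = report$n_features,
    best_params = report$best_params,
    R2c = report$r2_cal, RMSEC = report$rmse_cal,
    R2p = report$r2_pred, RMSEP = report$rmse_pred, RPD = report$rpd
  )
  jsonlite::write_json(report_json, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("specswarm")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed, selector = cfg$selector, preprocess = pp_name,
    indicator = cfg$indicator, ratio = cfg$ratio,
    selector_cfg = cfg$selector_cfg[setdiff(names(cfg$selector_cfg), NULL)],
    evaluations = trace$evaluations
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(out_dir = cfg$out_dir, split = split, bake_off = bake,
                 trace = trace, model = model, report = report,
                 attribution = am))
}

#' Compare wavelength selectors on one shared split
#'
#' Runs each requested selector on the same calibration data, fits and
#' evaluates a grid-searched model per selected mask, and returns one
#' report row per method together with the per-iteration best-fitness
#' convergence curves. CARS appears in the table but is excluded from the
#' curves: its variable-screening mechanism is not evolutionary, so it has
#' no comparable fitness trajectory (a note is logged when it is
#' requested).
#'
#' @param cfg A [run_config()] (its `selector` field is ignored).
#' @param methods Character vector of at least two selector names.
#' @return List with `table` (a `data.frame`: method, R2c, RMSEC, R2p,
#'   RMSEP, RPD, n_selected) and `curves` (long `data.frame`: method,
#'   iteration, best_mse, n_selected; evolutionary methods only).
#' @export
compare_selectors <- function(cfg, methods = c("psoga", "pso", "ga")) {
  stopifnot(inherits(cfg, "run_config"))
  if (length(methods) < 2 && !identical(methods, "psoga")) {
    # a single method is allowed for smoke runs; warn otherwise
  }
  ds <- if (!is.null(cfg$dataset)) cfg$dataset else {
    read_spectra_csv(cfg$spectra, cfg$references)
  }
  iv <- indicator_values(ds, cfg$indicator)
  X_raw <- ds$reflectance[iv$rows, , drop = FALSE]
  y <- iv$y
  split <- spxy_split(X_raw, y, cfg$ratio)
  method_pp <- preprocess_method(
    if (identical(cfg$preprocess, "auto")) "RAW" else cfg$preprocess)
  fp <- fit_preprocessor(method_pp,
                         X_raw[split$calibration_idx, , drop = FALSE])
  X_cal <- apply_preprocessor(fp, X_raw[split$calibration_idx, , drop = FALSE],
                              ds$grid$step_nm)
  X_pred <- apply_preprocessor(fp, X_raw[split$prediction_idx, , drop = FALSE],
                               ds$grid$step_nm)
  y_cal <- y[split$calibration_idx]
  y_pred <- y[split$prediction_idx]
  rows <- list(); curves <- list()
  for (m in methods) {
    trace <- select_with(m, X_cal, y_cal, cfg$selector_cfg)
    cols <- which(trace$best_mask)
    Xc <- X_cal[, cols, drop = FALSE]
    Xp <- X_pred[, cols, drop = FALSE]
    colnames(Xc) <- colnames(Xp) <- paste0("nm", ds$grid$values[cols])
    model <- grid_search_fit(Xc, y_cal, cfg$grid_cfg,
                             seed = derive_seed(cfg$seed,
                                                .stream_offsets["model"]))
    rep_ <- evaluate_model(model, Xc, y_cal, Xp, y_pred)
    rows[[m]] <- data.frame(
      method = m, R2c = rep_$r2_cal, RMSEC = rep_$rmse_cal,
      R2p = rep_$r2_pred, RMSEP = rep_$rmse_pred, RPD = rep_$rpd,
      n_selected = length(cols), stringsAsFactors = FALSE
    )
    if (m == "cars") {
      message("cars: excluded from convergence curves (non-evolutionary)")
    } else {
      curves[[m]] <- data.frame(
        method = m,
        iteration = seq_along(trace$best_fitness_per_iter),
        best_mse = trace$best_fitness_per_iter,
        n_selected = trace$n_selected_per_iter
      )
    }
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       curves = do.call(rbind, c(curves, list(make.row.names = FALSE))))
}
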