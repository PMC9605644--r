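#' Write a run configuration to a YAML file
#'
#' Sections mirror the module names (`io`, `engine`, `preprocess`, `gabor`,
#' `gema`, `controller`, `synthetic`, `pump`). [load_run_config()] reads the
#' same layout; omitted keys fall back to the package defaults, so a config
#' file only needs the keys it changes.
#'
#' @param config A [run_config()].
#' @param path Output path, or `""` to print to the console.
#' @return `path`, invisibly.
#' @export
save_run_config <- function(config, path = "") {
  p <- config$params
  lst <- list(
    io = list(input_dir = config$input_dir, output_dir = config$output_dir,
              gold_dir = config$gold_dir, eval_block = config$eval_block,
              log_level = config$log_level),
    engine = list(engine = config$engine, mode = config$mode,
                  online = config$online, poll_interval = config$poll_interval,
                  gradient_threshold = config$gradient_threshold),
    preprocess = list(clahe_clip_limit = config$preprocess$clahe_clip_limit,
                      clahe_tile_grid = config$preprocess$clahe_tile_grid,
                      gaussian_sigma = config$preprocess$gaussian_sigma),
    gabor = list(f = config$gabor$f, size = config$gabor$size,
                 thetas = config$gabor$thetas, gamma = config$gabor$gamma,
                 eta = config$gabor$eta, combine = config$gabor$combine),
    gema = list(adaptive_block_size = p$adaptive_block_size,
                adaptive_method = p$adaptive_method, cv_source = p$cv_source,
                closing_size = p$closing_se$size,
                closing_shape = p$closing_se$shape,
                dilation_size = p$dilation_se$size,
                dilation_shape = p$dilation_se$shape),
    controller = list(refit_tolerance = config$refit_tolerance,
                      min_refit_window = config$min_refit_window),
    synthetic = unclass(config$synthetic),
    pump = list(min_percent = config$pump_min_percent,
                max_percent = config$pump_max_percent)
  )
  drop_null <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, drop_null)
      x[!vapply(x, is.null, logical(1))]
    } else x
  }
  txt <- yaml::as.yaml(drop_null(lst))
  if (identical(path, "")) cat(txt) else writeLines(txt, path)
  invisible(path)
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file in the layout written by [save_run_config()].
#' @return A [run_config()].
#' @export
load_run_config <- function(path) {
  y <- tryCatch(yaml::read_yaml(path), error = function(e) {
    abort_gema(sprintf("Cannot parse config '%s': %s", path, conditionMessage(e)),
               "gemaseg_config_error")
  })
  pick <- function(section, key, default) {
    v <- y[[section]][[key]]
    if (is.null(v)) default else v
  }
  d <- run_config() # defaults
  syn_defaults <- synthetic_config()
  syn_args <- y$synthetic %||% list()
  syn_args <- syn_args[names(syn_args) %in% names(formals(synthetic_config))]
  synthetic <- do.call(synthetic_config, utils::modifyList(
    list(kind = syn_defaults$kind), syn_args))
  run_config(
    input_dir = pick("io", "input_dir", NULL),
    output_dir = pick("io", "output_dir", NULL),
    gold_dir = pick("io", "gold_dir", NULL),
    eval_block = pick("io", "eval_block", d$eval_block),
    log_level = pick("io", "log_level", d$log_level),
    engine = pick("engine", "engine", d$engine),
    mode = pick("engine", "mode", d$mode),
    online = pick("engine", "online", d$online),
    poll_interval = pick("engine", "poll_interval", d$poll_interval),
    gradient_threshold = pick("engine", "gradient_threshold",
                              d$gradient_threshold),
    preprocess = preprocess_config(
      clahe_clip_limit = pick("preprocess", "clahe_clip_limit",
                              d$preprocess$clahe_clip_limit),
      clahe_tile_grid = pick("preprocess", "clahe_tile_grid",
                             d$preprocess$clahe_tile_grid),
      gaussian_sigma = pick("preprocess", "gaussian_sigma",
                            d$preprocess$gaussian_sigma)),
    gabor = gabor_bank_config(
      f = pick("gabor", "f", d$gabor$f),
      size = pick("gabor", "size", d$gabor$size),
      thetas = pick("gabor", "thetas", d$gabor$thetas),
      gamma = pick("gabor", "gamma", d$gabor$gamma),
      eta = pick("gabor", "eta", d$gabor$eta),
      combine = pick("gabor", "combine", d$gabor$combine)),
    params = gema_params(
      adaptive_block_size = pick("gema", "adaptive_block_size",
                                 d$params$adaptive_block_size),
      adaptive_method = pick("gema", "adaptive_method",
                             d$params$adaptive_method),
      cv_source = pick("gema", "cv_source", d$params$cv_source),
      closing_se = struct_element(pick("gema", "closing_size", 5L),
                                  pick("gema", "closing_shape", "square")),
      dilation_se = struct_element(pick("gema", "dilation_size", 3L),
                                   pick("gema", "dilation_shape", "square"))),
    refit_tolerance = pick("controller", "refit_tolerance", d$refit_tolerance),
    min_refit_window = pick("controller", "min_refit_window",
                            d$min_refit_window),
    synthetic = synthetic,
    pump_min_percent = pick("pump", "min_percent", NULL),
    pump_max_percent = pick("pump", "max_percent", NULL)
  )
}
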