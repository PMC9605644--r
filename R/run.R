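#' Run configuration
#'
#' Bundles every tunable of a batch or online segmentation run: paths,
#' engine selection, biological mode, and the per-module parameter objects.
#'
#' @param input_dir Directory of input frames (PNG/JPEG/TIFF), processed in
#'   natural filename order.
#' @param output_dir Directory for masks, `trace.csv` and reports.
#' @param engine `"gema"` (adaptive Gabor engine) or `"gradient"`
#'   (morphological-gradient baseline).
#' @param mode `"growth"` or `"apoptosis"`; direction of the threshold
#'   schedule.
#' @param online Poll `input_dir` for new files instead of a single batch.
#' @param poll_interval Polling period in seconds (> 0) for online runs.
#' @param preprocess A [preprocess_config()].
#' @param gabor A [gabor_bank_config()].
#' @param params A [gema_params()].
#' @param refit_tolerance,min_refit_window Controller settings, see
#'   [controller()].
#' @param gradient_threshold Fixed threshold of the baseline engine
#'   (default 25).
#' @param synthetic A [synthetic_config()] used by [run_generate()].
#' @param gold_dir Optional directory of gold-standard masks (`{0, 255}`
#'   PNGs named like the frames, or `frame_*` replaced by `mask_*`).
#' @param eval_block Evaluate every `eval_block`-th frame against the gold
#'   standard (default 100, matching gold standards annotated every 100th
#'   image; use 1 to evaluate every frame).
#' @param pump_min_percent,pump_max_percent Optional percent-cells bounds:
#'   crossing them emits an advisory `would-pump: ON/OFF` log line (no
#'   hardware is driven).
#' @param log_level `"info"` or `"quiet"`.
#' @return A list of class `gema_run_config`.
#' @export
run_config <- function(input_dir = NULL, output_dir = NULL,
                       engine = c("gema", "gradient"),
                       mode = c("growth", "apoptosis"),
                       online = FALSE, poll_interval = 5,
                       preprocess = preprocess_config(),
                       gabor = gabor_bank_config(),
                       params = gema_params(),
                       refit_tolerance = 0.05, min_refit_window = 5L,
                       gradient_threshold = 25,
                       synthetic = synthetic_config(),
                       gold_dir = NULL, eval_block = 100L,
                       pump_min_percent = NULL, pump_max_percent = NULL,
                       log_level = c("info", "quiet")) {
  engine <- match.arg(engine)
  mode <- match.arg(mode)
  log_level <- match.arg(log_level)
  if (online && poll_interval <= 0) {
    abort_gema("poll_interval must be > 0 for online runs.", "gemaseg_config_error")
  }
  structure(
    list(input_dir = input_dir, output_dir = output_dir, engine = engine,
         mode = mode, online = online, poll_interval = poll_interval,
         preprocess = preprocess, gabor = gabor, params = params,
         refit_tolerance = refit_tolerance,
         min_refit_window = as.integer(min_refit_window),
         gradient_threshold = gradient_threshold, synthetic = synthetic,
         gold_dir = gold_dir, eval_block = as.integer(eval_block),
         pump_min_percent = pump_min_percent,
         pump_max_percent = pump_max_percent, log_level = log_level),
    class = "gema_run_config"
  )
}

run_log <- function(config, fmt, ...) {
  if (config$log_level != "quiet") message(sprintf(fmt, ...))
}

list_frame_files <- function(dir) {
  pat <- paste0("\\.(", paste(supported_image_ext, collapse = "|"), ")$")
  files <- list.files(dir, pattern = pat, ignore.case = TRUE)
  files <- files[!grepl("^mask_", files)] # skip ground-truth masks in fixtures
  natural_sort(files)
}

new_engine_state <- function(config) {
  list(
    controller = controller(mode = config$mode,
                            refit_tolerance = config$refit_tolerance,
                            min_refit_window = config$min_refit_window),
    bank = build_gabor_bank(config$gabor),
    last_pump = NA
  )
}

# process one frame through the configured engine; returns row + mask + state
process_frame <- function(config, es, path, index) {
  frame <- read_frame(path, index = index)
  if (config$engine == "gema") {
    res <- segment_gema(frame, es$controller, preprocess = config$preprocess,
                        bank = es$bank, params = config$params,
                        combine = config$gabor$combine)
    es$controller <- res$state
    mask <- res$mask
    row <- res$row
  } else {
    gray <- to_grayscale(frame)
    pre <- preprocess_frame(gray, config$preprocess)
    mask <- segment_gradient(frame, preprocess = config$preprocess,
                             threshold = config$gradient_threshold)
    row <- gema_trace(frame = index, filename = frame$source_name,
                      cv = coefficient_of_variation(pre),
                      threshold = as.integer(config$gradient_threshold),
                      percent_cells = percent_cells(mask))
  }
  es <- emit_pump_advice(config, es, row$percent_cells)
  list(row = row, mask = mask, state = es)
}

# advisory only: report when percent_cells crosses the configured bounds
emit_pump_advice <- function(config, es, pct) {
  lo <- config$pump_min_percent; hi <- config$pump_max_percent
  if (is.null(lo) && is.null(hi)) return(es)
  on <- (!is.null(hi) && pct >= hi)
  off <- (!is.null(lo) && pct <= lo)
  decision <- if (on) TRUE else if (off) FALSE else es$last_pump
  if (!identical(decision, es$last_pump) && !is.na(decision)) {
    run_log(config, "would-pump: %s (percent_cells = %.2f)",
            if (decision) "ON" else "OFF", pct)
  }
  es$last_pump <- decision
  es
}

mask_filename <- function(frame_filename) {
  paste0(tools::file_path_sans_ext(frame_filename), "_mask.png")
}

#' Offline batch segmentation of an image directory
#'
#' Processes every readable frame of `input_dir` in natural filename order
#' through the selected engine, writes the `{0, 255}` mask PNGs under
#' `output_dir/masks`, the per-frame trace to `output_dir/trace.csv`, and,
#' when `gold_dir` is configured, an every-`eval_block`-th-frame evaluation
#' report to `output_dir/evaluation.csv`. Unreadable frames are logged and
#' skipped.
#'
#' @param config A [run_config()] with `input_dir` and `output_dir` set.
#' @return A list with `trace` (a [gema_trace()]) and `evaluation` (a
#'   tibble or `NULL`), invisibly.
#' @export
run_offline <- function(config) {
  files <- list_frame_files(config$input_dir)
  if (length(files) == 0) {
    abort_gema(sprintf("No readable images found in '%s'.", config$input_dir),
               "gemaseg_startup_error")
  }
  mask_dir <- file.path(config$output_dir, "masks")
  dir.create(mask_dir, recursive = TRUE, showWarnings = FALSE)
  es <- new_engine_state(config)
  rows <- list()
  masks <- list()
  kept <- character(0)
  for (i in seq_along(files)) {
    path <- file.path(config$input_dir, files[i])
    res <- tryCatch(
      process_frame(config, es, path, index = i - 1L),
      gemaseg_error = function(e) {
        warning(sprintf("Skipping frame '%s': %s", files[i], conditionMessage(e)),
                call. = FALSE)
        NULL
      }
    )
    if (is.null(res)) next
    es <- res$state
    rows[[length(rows) + 1L]] <- res$row
    masks[[length(masks) + 1L]] <- res$mask
    kept <- c(kept, files[i])
    write_mask_png(res$mask, file.path(mask_dir, mask_filename(files[i])))
  }
  trace <- as_gema_trace(dplyr::bind_rows(rows))
  write_trace(trace, file.path(config$output_dir, "trace.csv"))
  evaluation <- NULL
  if (!is.null(config$gold_dir)) {
    evaluation <- evaluate_against_gold(config, kept, masks, trace$frame)
    if (!is.null(evaluation)) {
      write_evaluation(evaluation, file.path(config$output_dir, "evaluation.csv"))
    }
  }
  run_log(config, "Processed %d/%d frame(s) with engine '%s'.",
          nrow(trace), length(files), config$engine)
  invisible(list(trace = trace, evaluation = evaluation))
}

evaluate_against_gold <- function(config, filenames, masks, frames) {
  gold <- purrr::map(filenames, function(f) {
    for (cand in c(f, sub("frame", "mask", f),
                   paste0(tools::file_path_sans_ext(f), ".png"))) {
      p <- file.path(config$gold_dir, cand)
      if (file.exists(p)) return(read_mask_png(p))
    }
    NULL
  })
  have <- !purrr::map_lgl(gold, is.null)
  if (!any(have)) {
    warning("No gold masks matched the processed frames; skipping evaluation.",
            call. = FALSE)
    return(NULL)
  }
  evaluate_masks(masks[have], gold[have], frames = frames[have],
                 block = config$eval_block)
}

#' Online (polling) segmentation of a watched directory
#'
#' Polls `input_dir` every `poll_interval` seconds and processes files that
#' are new and size-stable (a file whose size changed between two polls is
#' still being written and is deferred). The trace CSV is appended after
#' every frame, so a killed run loses at most the in-flight frame; on
#' restart the existing trace is consulted, already-processed frames are
#' not reprocessed, and the controller state is rebuilt by replaying the
#' recorded CV series. The run terminates when a file named `STOP` appears
#' in `input_dir` (or after `max_polls` polls).
#'
#' @param config A [run_config()].
#' @param max_polls Stop after this many polls (default `Inf`; useful for
#'   tests and bounded sessions).
#' @return The final [gema_trace()], invisibly.
#' @export
run_online <- function(config, max_polls = Inf) {
  if (!dir.exists(config$input_dir)) {
    abort_gema(sprintf("Input directory '%s' does not exist.", config$input_dir),
               "gemaseg_startup_error")
  }
  mask_dir <- file.path(config$output_dir, "masks")
  dir.create(mask_dir, recursive = TRUE, showWarnings = FALSE)
  trace_path <- file.path(config$output_dir, "trace.csv")
  es <- new_engine_state(config)
  trace <- gema_trace()
  if (file.exists(trace_path)) {
    trace <- read_trace(trace_path)
    if (config$engine == "gema") {
      for (i in seq_len(nrow(trace))) {
        es$controller <- update_controller(es$controller, trace$frame[i],
                                           trace$cv[i])
      }
    }
    run_log(config, "Resuming: %d frame(s) already in the trace.", nrow(trace))
  }
  processed <- trace$filename
  prev_sizes <- NULL
  polls <- 0
  repeat {
    polls <- polls + 1
    if (file.exists(file.path(config$input_dir, "STOP"))) break
    files <- list_frame_files(config$input_dir)
    sizes <- file.size(file.path(config$input_dir, files))
    names(sizes) <- files
    stable <- if (is.null(prev_sizes)) {
      files
    } else {
      files[!is.na(sizes) &
              (files %in% names(prev_sizes)) &
              sizes == prev_sizes[files]]
    }
    prev_sizes <- sizes
    todo <- setdiff(stable, processed)
    for (f in todo) {
      idx <- if (nrow(trace) == 0) 0L else max(trace$frame) + 1L
      res <- tryCatch(
        process_frame(config, es, file.path(config$input_dir, f), index = idx),
        gemaseg_error = function(e) {
          warning(sprintf("Skipping frame '%s': %s", f, conditionMessage(e)),
                  call. = FALSE)
          NULL
        }
      )
      processed <- c(processed, f)
      if (is.null(res)) next
      es <- res$state
      trace <- as_gema_trace(dplyr::bind_rows(trace, res$row))
      write_mask_png(res$mask, file.path(mask_dir, mask_filename(f)))
      write_trace(trace, trace_path) # crash-safe append-equivalent rewrite
    }
    if (polls >= max_polls) break
    if (length(todo) == 0) Sys.sleep(config$poll_interval)
  }
  invisible(trace)
}

#' Generate a synthetic fixture directory
#'
#' Runs the synthetic generator with `config$synthetic` and writes frames,
#' ground-truth masks and the manifest to `output_dir`.
#'
#' @param config A [run_config()] with `output_dir` set.
#' @return The sequence from [generate_sequence()], invisibly.
#' @export
run_generate <- function(config) {
  seq <- generate_sequence(config$synthetic)
  write_sequence(seq, config$output_dir)
  run_log(config, "Wrote %d synthetic frame(s) to '%s'.",
          length(seq$frames), config$output_dir)
  invisible(seq)
}

#' Evaluate previously written masks against a gold directory
#'
#' Pairs the mask PNGs under `output_dir/masks` with gold masks in
#' `gold_dir` by filename, evaluates every `eval_block`-th frame and
#' writes `output_dir/evaluation.csv`.
#'
#' @param config A [run_config()] with `output_dir` and `gold_dir` set.
#' @return The evaluation tibble, invisibly.
#' @export
run_evaluate <- function(config) {
  mask_dir <- file.path(config$output_dir, "masks")
  files <- natural_sort(list.files(mask_dir, pattern = "\\.png$"))
  if (length(files) == 0) {
    abort_gema(sprintf("No mask PNGs found under '%s'.", mask_dir),
               "gemaseg_startup_error")
  }
  masks <- purrr::map(files, ~read_mask_png(file.path(mask_dir, .x)))
  sources <- sub("_mask\\.png$", ".png", files)
  evaluation <- evaluate_against_gold(config, sources, masks,
                                      frames = seq_along(files) - 1L)
  if (is.null(evaluation)) {
    abort_gema("No gold masks matched the predicted masks.",
               "gemaseg_startup_error")
  }
  write_evaluation(evaluation, file.path(config$output_dir, "evaluation.csv"))
  invisible(evaluation)
}
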