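#' Default end-to-end run configuration
#'
#' Collects the per-stage settings of the full pipeline (simulate,
#' preprocess, train, predict, evaluate) in one auditable list. The
#' defaults describe the package's scaled-down synthetic study: 60 training
#' phantoms (with a validation split), 20 held-out evaluation phantoms,
#' 64 x 64 planes at 2.73 mm, a reduced U-Net (8 base channels, depth 3)
#' trained for 20 epochs with mini-batches of 16 at learning rate 0.001.
#'
#' @param seed global integer seed; every random stage derives its own seed
#'   from it.
#' @param out_dir directory for artifacts (created if missing).
#' @param n_train,n_eval phantom counts for the training pool (split into
#'   train/validation by `val_fraction`) and the held-out evaluation set.
#' @param crop_xy,target_xy_spacing preprocessing geometry.
#' @param base_channels,depth network size.
#' @param epochs,batch_size,learning_rate,val_fraction training settings.
#' @param augment a [warp_params()].
#' @param ranges a [phantom_ranges()].
#' @param margin_mm,exclusion_mm ground-truth label rules.
#' @param threshold,min_volume_ml evaluation thresholds.
#' @param write_cases write each simulated case as NIfTI + JSON under
#'   `out_dir/cases/`.
#' @param verbose print per-epoch training progress.
#' @return nested configuration list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, out_dir = file.path(tempdir(), "autobsuv_run"),
                               n_train = 60L, n_eval = 20L,
                               crop_xy = 64L, target_xy_spacing = 2.73,
                               base_channels = 8L, depth = 3L,
                               epochs = 20L, batch_size = 16L,
                               learning_rate = 0.001, val_fraction = 0.2,
                               augment = warp_params(),
                               ranges = phantom_ranges(),
                               margin_mm = 8, exclusion_mm = 15,
                               threshold = 0.5, min_volume_ml = 1.0,
                               write_cases = FALSE, verbose = FALSE) {
  structure(list(
    seed = as.integer(seed) %% 1000000000L, out_dir = out_dir,
    phantom = list(n_train = as.integer(n_train), n_eval = as.integer(n_eval),
                   ranges = ranges, margin_mm = margin_mm,
                   exclusion_mm = exclusion_mm),
    preprocess = preprocess_config(target_xy_spacing, crop_xy),
    model = unet_config(base_channels, depth),
    train = train_config(learning_rate = learning_rate,
                         batch_size = batch_size, epochs = epochs,
                         augment = augment, seed = 0L,
                         val_fraction = val_fraction),
    eval = list(threshold = threshold, min_volume_ml = min_volume_ml),
    write_cases = isTRUE(write_cases), verbose = isTRUE(verbose)),
    class = "run_config")
}

# 32-bit polynomial rolling hash over a character string, for stamping
# artifacts (exact doubles: intermediate values stay below 2^53)
rolling_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_stamp <- function(config) {
  drop_fn <- function(x) {
    if (is.list(x)) lapply(x, drop_fn) else x
  }
  js <- jsonlite::toJSON(drop_fn(unclass(config)), auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  rolling_hash(as.character(js))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full simulate-train-evaluate pipeline
#'
#' Executes, in order: phantom simulation, preprocessing, network training
#' with BSUV-metric model selection, study-level prediction on the held-out
#' evaluation phantoms, and evaluation. All artifacts (per-epoch history,
#' per-case records, the summary table and a `run.json` stamp with the
#' seed and a configuration hash) are written under `config$out_dir`.
#' Re-running with the same configuration reproduces the outputs
#' bit-for-bit under single-threaded execution.
#'
#' @param config a `run_config` from [default_run_config()], a nested list
#'   with the same shape, or a path to a YAML file holding one.
#' @return (invisibly) list with `summary`, `records`, `history`, `net`,
#'   and the output paths.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configurations requires the 'yaml' package")
    user <- yaml::read_yaml(config)
    config <- do.call(default_run_config, user)
  }
  if (!inherits(config, "run_config"))
    config <- do.call(default_run_config, config)
  seed <- config$seed
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  ph <- config$phantom
  message("[simulate] generating ", ph$n_train, " training and ", ph$n_eval,
          " evaluation phantoms (seed ", seed, ")")
  train_cases <- with_stage("simulate", make_dataset(
    ph$n_train, base_seed = seed, spec_ranges = ph$ranges,
    margin_mm = ph$margin_mm, exclusion_mm = ph$exclusion_mm))
  eval_cases <- with_stage("simulate", make_dataset(
    ph$n_eval, base_seed = seed + 463L, spec_ranges = ph$ranges,
    margin_mm = ph$margin_mm, exclusion_mm = ph$exclusion_mm))
  if (config$write_cases) {
    with_stage("simulate", {
      for (cs in train_cases)
        write_phantom_case(cs, file.path(out_dir, "cases", "train", cs$case_id))
      for (cs in eval_cases)
        write_phantom_case(cs, file.path(out_dir, "cases", "eval", cs$case_id))
    })
  }

  message("[preprocess] building ", config$preprocess$crop_xy, "x",
          config$preprocess$crop_xy, " slice stacks")
  stacks <- with_stage("preprocess", lapply(train_cases, function(cs)
    build_slice_stack(cs$ct, cs$pet, cs$label, config$preprocess)))
  n_val <- max(1L, round(config$train$val_fraction * length(stacks)))
  val_idx <- seq(length(stacks) - n_val + 1L, length(stacks))
  message("[train] ", length(stacks) - n_val, " training / ", n_val,
          " validation cases, ", config$train$epochs, " epochs")
  net <- with_stage("train", build_unet(config$model, seed = seed + 104729L))
  tcfg <- config$train
  tcfg$seed <- seed + 15485863L
  fit <- with_stage("train", train_unet(net, stacks[-val_idx],
                                        stacks[val_idx], tcfg,
                                        verbose = config$verbose))

  message("[evaluate] ", length(eval_cases), " held-out phantoms")
  records <- with_stage("evaluate", evaluate_cases(
    fit$net, eval_cases, config$preprocess,
    threshold = config$eval$threshold,
    min_volume_ml = config$eval$min_volume_ml))
  summ <- summarize_eval(records)

  paths <- list(history = file.path(out_dir, "history.csv"),
                records = file.path(out_dir, "records.csv"),
                summary = file.path(out_dir, "summary.csv"),
                model = file.path(out_dir, "model.rds"),
                run = file.path(out_dir, "run.json"))
  write.csv(fit$history, paths$history, row.names = FALSE)
  write.csv(records, paths$records, row.names = FALSE)
  sum_df <- data.frame(n = summ$n, n_failed = summ$n_failed,
                       mean_pct = summ$mean_pct, sd_pct = summ$sd_pct,
                       ci95_lo_pct = summ$ci95_pct[1],
                       ci95_hi_pct = summ$ci95_pct[2],
                       min_pct = summ$range_pct[1],
                       max_pct = summ$range_pct[2],
                       dice_mean = summ$dice_mean,
                       best_epoch = fit$best_epoch,
                       best_val_score = fit$best_score, seed = seed)
  write.csv(sum_df, paths$summary, row.names = FALSE)
  save_unet(fit$net, paths$model)
  jsonlite::write_json(list(seed = seed, config_hash = config_stamp(config),
                            n_train = ph$n_train, n_eval = ph$n_eval,
                            best_epoch = fit$best_epoch,
                            best_val_score = fit$best_score),
                       paths$run, auto_unbox = TRUE, digits = NA)
  message(sprintf("[done] dBSUV mean %.2f%%, 95%% interval [%.2f, %.2f]%%, %d/%d failed",
                  summ$mean_pct, summ$ci95_pct[1], summ$ci95_pct[2],
                  summ$n_failed, summ$n))
  invisible(list(summary = summ, records = records, history = fit$history,
                 net = fit$net, best_epoch = fit$best_epoch,
                 best_score = fit$best_score, paths = paths))
}
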