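#' Predict a study-level probability map
#'
#' Runs the network plane by plane over a preprocessed slice stack (in
#' inference mode, so predictions are deterministic and independent of
#' batching) and reassembles the outputs into the study volume.
#'
#' @param net a trained `unet`.
#' @param stack a [build_slice_stack()] output preprocessed with the same
#'   configuration used in training.
#' @param batch_size planes per forward pass.
#' @return object of class `probability_map`: `values` array in `[0, 1]`
#'   on the preprocessed grid, plus `spacing` and `origin`.
#' @export
predict_study <- function(net, stack, batch_size = 16L) {
  stopifnot(inherits(net, "unet"), inherits(stack, "slice_stack"))
  prob <- predict_tensor(net, stack$ct, stack$pet, batch_size)
  structure(list(values = prob, spacing = stack$spacing,
                 origin = stack$origin), class = "probability_map")
}

#' Threshold a probability map into a blood-pool ROI
#'
#' Voxels with probability strictly greater than `threshold` form the ROI.
#' If the ROI volume falls below `min_volume_ml` the delineation is deemed
#' unusable (`failed = TRUE`, a result state rather than an error) and no
#' BSUV is reported; otherwise the BSUV is the ROI average of the PET.
#'
#' @param pmap a `probability_map` (or 3-D array in `[0, 1]`).
#' @param pet PET volume in SUV on the same grid: 3-D array (e.g.
#'   `stack$pet_raw`) or [volume_grid()].
#' @param threshold probability cut (default 0.5; strict `>`).
#' @param min_volume_ml failure criterion (default 1 ml).
#' @param spacing voxel spacing in mm; taken from `pmap` when available.
#' @return object of class `roi_result`: `mask`, `volume_ml`, `bsuv`,
#'   `failed`, `threshold_used`, `min_volume_ml`.
#' @export
extract_roi <- function(pmap, pet, threshold = 0.5, min_volume_ml = 1.0,
                        spacing = NULL) {
  vals <- if (inherits(pmap, "probability_map")) pmap$values else pmap
  if (is.null(spacing)) {
    if (!inherits(pmap, "probability_map"))
      stop("spacing must be supplied when pmap is a bare array")
    spacing <- pmap$spacing
  }
  pet_vals <- if (inherits(pet, "volume_grid")) pet$values else pet
  if (!all(dim(vals) == dim(pet_vals)))
    stop("probability map and PET grids do not match")
  mask <- vals > threshold
  volume_ml <- sum(mask) * voxel_volume_ml(spacing)
  failed <- volume_ml < min_volume_ml
  bsuv <- if (!failed && any(mask)) mean(pet_vals[mask]) else NA_real_
  structure(list(mask = array(as.integer(mask), dim(mask)),
                 volume_ml = volume_ml, bsuv = bsuv, failed = failed,
                 threshold_used = threshold, min_volume_ml = min_volume_ml),
            class = "roi_result")
}

#' Relative BSUV deviation between automatic and manual determination
#'
#' `(bsuv_cnn - bsuv_man) / bsuv_man`: the fractional deviation of the
#' automatically derived blood SUV from the reference value.
#'
#' @param bsuv_cnn automatically derived blood SUV.
#' @param bsuv_man reference (manual / ground-truth) blood SUV, `> 0`.
#' @return signed fraction.
#' @export
delta_bsuv <- function(bsuv_cnn, bsuv_man) {
  if (any(bsuv_man <= 0)) stop("bsuv_man must be > 0")
  (bsuv_cnn - bsuv_man) / bsuv_man
}

#' Dice overlap coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`. Two empty masks are defined to agree
#' perfectly (Dice 1), so degenerate cases do not poison summaries.
#'
#' @param a,b binary arrays on the same grid (or `lumen_label`s /
#'   `roi_result`s).
#' @return value in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  am <- if (is.list(a)) a$mask else a
  bm <- if (is.list(b)) b$mask else b
  if (!all(dim(am) == dim(bm))) stop("mask grids do not match")
  am <- am > 0; bm <- bm > 0
  sa <- sum(am); sb <- sum(bm)
  if (sa + sb == 0) return(1)
  2 * sum(am & bm) / (sa + sb)
}

#' Standardized uptake ratio
#'
#' Tumor SUV divided by blood SUV. (No uptake-time normalization is
#' applied; the inputs are used as given.)
#'
#' @param tumor_suv tumor SUV.
#' @param bsuv blood SUV, `> 0`.
#' @return the ratio.
#' @export
compute_sur <- function(tumor_suv, bsuv) {
  if (any(bsuv <= 0)) stop("bsuv must be > 0")
  tumor_suv / bsuv
}

#' Evaluate a trained network on phantom cases
#'
#' For every case the paired volumes are preprocessed, the probability map
#' is predicted, the automatic ROI is extracted (0.5 threshold, 1 ml
#' failure criterion) and compared against the ground-truth label: both
#' BSUVs are ROI averages of the un-normalized PET on the preprocessed
#' grid.
#'
#' @param net a trained `unet`.
#' @param cases list of cases as produced by [make_dataset()].
#' @param cfg a [preprocess_config()].
#' @param threshold,min_volume_ml see [extract_roi()].
#' @return data.frame with one row per case: `case_id`, `bsuv_man`,
#'   `bsuv_cnn`, `delta_bsuv` (fraction), `dice`, `volume_ml`, `failed`,
#'   `true_bsuv`.
#' @export
evaluate_cases <- function(net, cases, cfg = preprocess_config(),
                           threshold = 0.5, min_volume_ml = 1.0) {
  rows <- lapply(cases, function(cs) {
    stack <- build_slice_stack(cs$ct, cs$pet, cs$label, cfg)
    pmap <- predict_study(net, stack)
    roi <- extract_roi(pmap, stack$pet_raw, threshold, min_volume_ml,
                       spacing = stack$spacing)
    man_mask <- stack$label > 0
    bsuv_man <- if (any(man_mask)) mean(stack$pet_raw[man_mask]) else NA_real_
    failed <- roi$failed || is.na(bsuv_man)
    dv <- if (!failed) delta_bsuv(roi$bsuv, bsuv_man) else NA_real_
    data.frame(case_id = cs$case_id, bsuv_man = bsuv_man, bsuv_cnn = roi$bsuv,
               delta_bsuv = dv, dice = dice_coefficient(roi$mask, stack$label),
               volume_ml = roi$volume_ml, failed = failed,
               true_bsuv = cs$truth$true_bsuv,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarize evaluation records
#'
#' Reports the distribution of relative BSUV deviations over the non-failed
#' cases in percent: mean, SD, empirical 95% interval (2.5th/97.5th
#' percentiles) and total range, plus the failure count and a Dice summary.
#'
#' @param records data.frame from [evaluate_cases()] (needs columns
#'   `delta_bsuv`, `failed`, optionally `dice`).
#' @return object of class `eval_summary`: `n`, `n_failed`, `mean_pct`,
#'   `sd_pct` (`NA` for fewer than two values), `ci95_pct`, `range_pct`,
#'   `dice_mean`, `dice_range`.
#' @export
summarize_eval <- function(records) {
  failed <- records$failed
  ok <- records$delta_bsuv[!failed & !is.na(records$delta_bsuv)] * 100
  s <- list(n = nrow(records), n_failed = sum(failed))
  if (length(ok) >= 1) {
    s$mean_pct <- mean(ok)
    s$sd_pct <- if (length(ok) >= 2) sd(ok) else NA_real_
    s$ci95_pct <- unname(quantile(ok, c(0.025, 0.975)))
    s$range_pct <- range(ok)
  } else {
    s$mean_pct <- s$sd_pct <- NA_real_
    s$ci95_pct <- s$range_pct <- c(NA_real_, NA_real_)
  }
  if (!is.null(records$dice)) {
    s$dice_mean <- mean(records$dice[!failed])
    s$dice_range <- if (any(!failed)) range(records$dice[!failed])
                    else c(NA_real_, NA_real_)
  }
  structure(s, class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("evaluation: n = %d, failed (<%s ml) = %d\n", x$n, "1", x$n_failed))
  if (!is.na(x$mean_pct)) {
    cat(sprintf("  dBSUV: mean %.2f%%, SD %s, 95%% interval [%.2f, %.2f]%%, range [%.2f, %.2f]%%\n",
                x$mean_pct,
                ifelse(is.na(x$sd_pct), "NA", sprintf("%.2f%%", x$sd_pct)),
                x$ci95_pct[1], x$ci95_pct[2], x$range_pct[1], x$range_pct[2]))
  }
  if (!is.null(x$dice_mean))
    cat(sprintf("  Dice: mean %.3f, range [%.3f, %.3f]\n", x$dice_mean,
                x$dice_range[1], x$dice_range[2]))
  invisible(x)
}
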