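#' Non-rigid warp augmentation parameters
#'
#' Random smooth displacement fields used to augment training planes: a
#' coarse grid of i.i.d. Gaussian displacements is bilinearly upsampled to
#' the plane resolution and applied identically to CT, PET and label
#' (nearest neighbour for the label).
#'
#' @param control_grid_spacing spacing of the displacement control grid,
#'   voxels.
#' @param displacement_sigma SD of the control-point displacements, voxels
#'   (`>= 0`; 0 yields the identity transform).
#' @param probability fraction of training samples augmented.
#' @return object of class `warp_params`.
#' @export
warp_params <- function(control_grid_spacing = 8L, displacement_sigma = 1.5,
                        probability = 0.5) {
  if (displacement_sigma < 0) stop("displacement_sigma must be >= 0")
  if (control_grid_spacing < 1) stop("control_grid_spacing must be >= 1")
  if (probability < 0 || probability > 1) stop("probability must be in [0, 1]")
  structure(list(control_grid_spacing = as.integer(control_grid_spacing),
                 displacement_sigma = displacement_sigma,
                 probability = probability), class = "warp_params")
}

#' Training configuration
#'
#' @param learning_rate RMSprop learning rate (default 0.001).
#' @param batch_size planes per mini-batch (default 64).
#' @param epochs training epochs (default 250; scaled-down profiles are
#'   legitimate for small synthetic studies).
#' @param augment a [warp_params()].
#' @param seed integer seed controlling shuffling, augmentation and any
#'   weight initialization performed by the caller.
#' @param val_fraction fraction of cases held out for validation when the
#'   caller asks [run_pipeline()] to split automatically.
#' @param rmsprop_rho,rmsprop_eps RMSprop smoothing constant and epsilon.
#' @param threshold probability threshold used inside the monitoring
#'   metric.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 64L,
                         epochs = 250L, augment = warp_params(), seed = 1L,
                         val_fraction = 0.2, rmsprop_rho = 0.9,
                         rmsprop_eps = 1e-8, threshold = 0.5) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (epochs < 1) stop("epochs must be >= 1")
  if (!inherits(augment, "warp_params")) stop("augment must be warp_params")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), augment = augment,
                 seed = as.integer(seed), val_fraction = val_fraction,
                 rmsprop_rho = rmsprop_rho, rmsprop_eps = rmsprop_eps,
                 threshold = threshold), class = "train_config")
}

#' Logistic (binary cross-entropy) loss
#'
#' Mean binary cross-entropy between predicted probabilities and binary
#' labels, over all voxels. Probabilities are clipped to `[eps, 1 - eps]`
#' so the loss stays finite.
#'
#' @param prob array of probabilities in `(0, 1)`.
#' @param label binary array of the same shape.
#' @param eps clipping constant.
#' @return non-negative scalar.
#' @export
logistic_loss <- function(prob, label, eps = 1e-7) {
  if (length(prob) != length(label)) stop("shape mismatch between prob and label")
  p <- pmin(pmax(as.numeric(prob), eps), 1 - eps)
  l <- as.numeric(label)
  -mean(l * log(p) + (1 - l) * log(1 - p))
}

# per-plane ROI mean of `pet` over `mask`; NA when the mask is empty
plane_roi_mean <- function(pet_plane, mask_plane) {
  if (!any(mask_plane)) return(NA_real_)
  mean(pet_plane[mask_plane])
}

#' Mean plane-wise BSUV error (training monitor metric)
#'
#' For each image plane `i`, the blood-SUV averages over the reference
#' label (`BSUV_man`) and over the thresholded network prediction
#' (`BSUV_cnn`) are computed on the un-normalized PET. If exactly one of
#' the two delineations is missing on a plane, the mean of that quantity
#' over the other planes of the same batch is substituted; if both are
#' missing (or no substitute exists in the batch) the plane is skipped.
#' The absolute relative differences `|BSUV_cnn - BSUV_man| / BSUV_man`
#' are averaged within and then over the batches.
#'
#' @param prob probability array `[H, W, N]` (or `[H, W, 1, N]`).
#' @param label binary array `[H, W, N]`.
#' @param pet_raw PET array `[H, W, N]` in SUV units.
#' @param threshold probability threshold defining the predicted ROI.
#' @param batch_size planes per batch (batches are consecutive groups).
#' @return the score (`>= 0`), or `NA_real_` if every plane was skipped.
#' @export
bsuv_monitor_metric <- function(prob, label, pet_raw, threshold = 0.5,
                                batch_size = 64L) {
  if (length(dim(prob)) == 4L) prob <- array(prob, dim(prob)[c(1, 2, 4)])
  n <- dim(prob)[3]
  stopifnot(dim(label)[3] == n, dim(pet_raw)[3] == n)
  batches <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  batch_scores <- numeric(0)
  for (bi in batches) {
    cnn <- man <- rep(NA_real_, length(bi))
    for (j in seq_along(bi)) {
      k <- bi[j]
      cnn[j] <- plane_roi_mean(pet_raw[, , k], prob[, , k] > threshold)
      man[j] <- plane_roi_mean(pet_raw[, , k], label[, , k] > 0)
    }
    cnn_mean <- if (any(!is.na(cnn))) mean(cnn, na.rm = TRUE) else NA_real_
    man_mean <- if (any(!is.na(man))) mean(man, na.rm = TRUE) else NA_real_
    diffs <- numeric(0)
    for (j in seq_along(bi)) {
      c_j <- cnn[j]; m_j <- man[j]
      if (is.na(c_j) && is.na(m_j)) next  # both missing: skip the plane
      if (is.na(c_j)) c_j <- cnn_mean
      if (is.na(m_j)) m_j <- man_mean
      if (is.na(c_j) || is.na(m_j)) next  # no batch substitute available
      diffs <- c(diffs, abs((c_j - m_j) / m_j))
    }
    if (length(diffs)) batch_scores <- c(batch_scores, mean(diffs))
  }
  if (!length(batch_scores)) return(NA_real_)
  mean(batch_scores)
}

# bilinearly upsample a coarse control grid to H x W (borders clamped)
upsample_field <- function(coarse, H, W, spacing) {
  vol <- array(coarse, c(dim(coarse), 1L))
  out <- cpp_resample3d(vol, c(spacing, spacing, 1), c(0, 0, 0),
                        c(H, W, 1L), c(1, 1, 1), c(0, 0, 0), 0L)
  matrix(out, H, W)
}

#' Apply a random non-rigid warp to a training sample
#'
#' Draws one smooth displacement field (from the current RNG state) and
#' applies it to all image channels (bilinear, results clipped to `[0, 1]`)
#' and to the label (nearest neighbour), preserving the pairing between
#' channels and label.
#'
#' @param ct,pet 2-D normalized planes (values in `[0, 1]`).
#' @param label 2-D binary plane (or `NULL`).
#' @param params a [warp_params()].
#' @return list with warped `ct`, `pet`, `label`.
#' @export
elastic_warp <- function(ct, pet, label = NULL, params = warp_params()) {
  H <- nrow(ct); W <- ncol(ct)
  s <- params$control_grid_spacing
  nch <- floor((H - 1) / s) + 2L
  ncw <- floor((W - 1) / s) + 2L
  if (params$displacement_sigma > 0) {
    cdx <- matrix(rnorm(nch * ncw, sd = params$displacement_sigma), nch, ncw)
    cdy <- matrix(rnorm(nch * ncw, sd = params$displacement_sigma), nch, ncw)
  } else {
    cdx <- cdy <- matrix(0, nch, ncw)
  }
  dxf <- upsample_field(cdx, H, W, s)
  dyf <- upsample_field(cdy, H, W, s)
  img <- array(c(ct, pet), c(H, W, 2L))
  wimg <- cpp_warp2d(img, dxf, dyf, 0L)
  wimg[wimg < 0] <- 0
  wimg[wimg > 1] <- 1
  wlab <- NULL
  if (!is.null(label)) {
    wl <- cpp_warp2d(array(label + 0, c(H, W, 1L)), dxf, dyf, 1L)
    wlab <- matrix(as.integer(wl > 0.5), H, W)
  }
  list(ct = wimg[, , 1], pet = wimg[, , 2], label = wlab)
}

# Flatten a list of labeled slice stacks into training tensors.
stacks_to_tensors <- function(stacks) {
  stopifnot(length(stacks) >= 1)
  if (inherits(stacks, "slice_stack")) stacks <- list(stacks)
  H <- dim(stacks[[1]]$ct)[1]; W <- dim(stacks[[1]]$ct)[2]
  n <- sum(vapply(stacks, stack_planes, integer(1)))
  ct <- array(0, c(H, W, n)); pet <- array(0, c(H, W, n))
  pet_raw <- array(0, c(H, W, n)); y <- array(0L, c(H, W, n))
  case_of <- integer(n)
  at <- 0L
  for (ci in seq_along(stacks)) {
    st <- stacks[[ci]]
    if (is.null(st$label)) stop("training stacks must carry labels")
    k <- stack_planes(st)
    idx <- at + seq_len(k)
    ct[, , idx] <- st$ct
    pet[, , idx] <- st$pet
    pet_raw[, , idx] <- st$pet_raw
    y[, , idx] <- st$label
    case_of[idx] <- ci
    at <- at + k
  }
  list(ct = ct, pet = pet, pet_raw = pet_raw, y = y, case_of = case_of,
       H = H, W = W, n = n)
}

rmsprop_update <- function(params, grads, state, lr, rho, eps) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state[[nm]] <- if (is.null(state[[nm]])) (1 - rho) * g * g
                   else rho * state[[nm]] + (1 - rho) * g * g
    params[[nm]] <- params[[nm]] - lr * g / (sqrt(state[[nm]]) + eps)
  }
  list(params = params, state = state)
}

# validation-set probabilities in inference mode, plane-batched
predict_tensor <- function(net, ct, pet, batch_size = 16L) {
  n <- dim(ct)[3]
  H <- dim(ct)[1]; W <- dim(ct)[2]
  prob <- array(0, c(H, W, n))
  for (bi in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    x <- array(0, c(H, W, 2L, length(bi)))
    x[, , 1L, ] <- ct[, , bi]
    x[, , 2L, ] <- pet[, , bi]
    prob[, , bi] <- unet_forward(net, x, training = FALSE)$prob[, , 1L, ]
  }
  prob
}

#' Train the U-Net with logistic loss and BSUV-error model selection
#'
#' Optimizes the network with RMSprop on shuffled, warp-augmented training
#' planes under logistic loss. After every epoch the mean plane-wise
#' BSUV-error metric ([bsuv_monitor_metric()]) is evaluated on the
#' validation stacks (inference mode, un-augmented) and the model with the
#' lowest validation score is retained as the final network. The whole
#' procedure is a pure function of the inputs and `cfg$seed`.
#'
#' @param net an initialized `unet` (see [build_unet()]).
#' @param train_stacks list of labeled [build_slice_stack()] outputs.
#' @param val_stacks list of labeled stacks for validation.
#' @param cfg a [train_config()].
#' @param verbose print one line per epoch.
#' @return list with `net` (the best model, including its frozen batch-norm
#'   statistics), `history` (data.frame: epoch, train_loss, val_score),
#'   `best_epoch` and `best_score`.
#' @export
train_unet <- function(net, train_stacks, val_stacks, cfg = train_config(),
                       verbose = FALSE) {
  stopifnot(inherits(net, "unet"), inherits(cfg, "train_config"))
  tr <- stacks_to_tensors(train_stacks)
  va <- stacks_to_tensors(val_stacks)
  if (tr$n < 1) stop("empty training stack")
  with_local_seed(cfg$seed, {
    opt_state <- list()
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_score = numeric(0))
    best_score <- Inf
    best <- list(params = net$params, bn = net$bn)
    best_epoch <- NA_integer_
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample(tr$n)
      losses <- numeric(0)
      for (bi in split(perm, ceiling(seq_along(perm) / cfg$batch_size))) {
        nb <- length(bi)
        x <- array(0, c(tr$H, tr$W, 2L, nb))
        y <- array(0, c(tr$H, tr$W, 1L, nb))
        for (j in seq_len(nb)) {
          k <- bi[j]
          ctp <- tr$ct[, , k]; petp <- tr$pet[, , k]; lab <- tr$y[, , k]
          if (cfg$augment$displacement_sigma > 0 &&
              runif(1) < cfg$augment$probability) {
            wp <- elastic_warp(ctp, petp, lab, cfg$augment)
            ctp <- wp$ct; petp <- wp$pet; lab <- wp$label
          }
          x[, , 1L, j] <- ctp
          x[, , 2L, j] <- petp
          y[, , 1L, j] <- lab
        }
        fw <- unet_forward(net, x, training = TRUE)
        net$bn <- fw$bn
        losses <- c(losses, logistic_loss(fw$prob, y))
        dlogits <- (fw$prob - y) / length(y)
        grads <- unet_backward(net, fw$cache, dlogits)
        upd <- rmsprop_update(net$params, grads, opt_state,
                              cfg$learning_rate, cfg$rmsprop_rho,
                              cfg$rmsprop_eps)
        net$params <- upd$params
        opt_state <- upd$state
      }
      vprob <- predict_tensor(net, va$ct, va$pet, cfg$batch_size)
      score <- bsuv_monitor_metric(vprob, va$y, va$pet_raw,
                                   threshold = cfg$threshold,
                                   batch_size = cfg$batch_size)
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = mean(losses),
                                           val_score = score))
      if (verbose)
        message(sprintf("epoch %3d  loss %.5f  val BSUV score %s", epoch,
                        mean(losses),
                        ifelse(is.na(score), "NA", sprintf("%.5f", score))))
      if (!is.na(score) && score < best_score) {
        best_score <- score
        best <- list(params = net$params, bn = net$bn)
        best_epoch <- epoch
      }
    }
    if (is.infinite(best_score)) {  # no epoch produced a usable score
      best <- list(params = net$params, bn = net$bn)
      best_epoch <- cfg$epochs
      best_score <- NA_real_
    }
    net$params <- best$params
    net$bn <- best$bn
    list(net = net, history = history, best_epoch = best_epoch,
         best_score = best_score)
  })
}
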