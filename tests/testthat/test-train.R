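test_that("logistic loss reproduces its closed forms", {
  lab <- array(c(1, 0, 1, 0), c(2, 2, 1, 1))
  expect_lt(logistic_loss(lab, lab), 1e-5)                   # perfect prediction
  half <- array(0.5, dim(lab))
  expect_equal(logistic_loss(half, lab), log(2))             # ln 2 per voxel
  expect_equal(logistic_loss(array(0.9, c(1, 1, 1, 1)),
                             array(1, c(1, 1, 1, 1))), -log(0.9))
  expect_gte(logistic_loss(half, lab), 0)
  expect_error(logistic_loss(half, lab[, 1, , ]), "mismatch")
})

# build a tiny (H, W, N) triple with prescribed per-plane ROI means
metric_fixture <- function(man_vals, cnn_vals) {
  n <- length(man_vals)
  pet <- array(0, c(4, 4, n)); lab <- array(0L, c(4, 4, n)); prob <- array(0, c(4, 4, n))
  for (k in seq_len(n)) {
    if (!is.na(man_vals[k])) { pet[1, 1, k] <- man_vals[k]; lab[1, 1, k] <- 1L }
    if (!is.na(cnn_vals[k])) { pet[3, 3, k] <- cnn_vals[k]; prob[3, 3, k] <- 0.9 }
  }
  list(prob = prob, lab = lab, pet = pet)
}

test_that("BSUV monitor metric averages absolute relative differences", {
  fx <- metric_fixture(c(1.0, 1.0), c(1.02, 0.96))
  expect_equal(bsuv_monitor_metric(fx$prob, fx$lab, fx$pet, batch_size = 2),
               0.03)
  # identical delineations score zero
  lab <- array(0L, c(4, 4, 2)); lab[2, 2, ] <- 1L
  pet <- array(runif(32) + 1, c(4, 4, 2))
  expect_equal(bsuv_monitor_metric(lab + 0, lab, pet, batch_size = 2), 0)
})

test_that("missing delineations fall back to batch means exactly as specified", {
  # image 2 has no predicted voxels: its BSUV_CNN is the mean over images 1, 3
  fx <- metric_fixture(c(2.0, 2.0, 2.0), c(2.1, NA, 1.9))
  got <- bsuv_monitor_metric(fx$prob, fx$lab, fx$pet, batch_size = 3)
  cnn2 <- mean(c(2.1, 1.9))
  oracle <- mean(c(abs(2.1 - 2) / 2, abs(cnn2 - 2) / 2, abs(1.9 - 2) / 2))
  expect_equal(got, oracle)
  # both missing: the plane is skipped
  fx2 <- metric_fixture(c(2.0, NA), c(2.1, NA))
  expect_equal(bsuv_monitor_metric(fx2$prob, fx2$lab, fx2$pet, batch_size = 2),
               0.05)
  # everything missing: score undefined, reported as missing
  fx3 <- metric_fixture(c(NA, NA), c(NA, NA))
  expect_true(is.na(bsuv_monitor_metric(fx3$prob, fx3$lab, fx3$pet,
                                        batch_size = 2)))
})

test_that("monitor metric against an independent brute-force recomputation", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 7
    prob <- array(runif(16 * n), c(4, 4, n))
    lab <- array(rbinom(16 * n, 1, 0.4), c(4, 4, n))
    pet <- array(runif(16 * n, 0.5, 3), c(4, 4, n))
    got <- bsuv_monitor_metric(prob, lab, pet, threshold = 0.5, batch_size = 3)
    # brute force, written independently of the implementation
    scores <- c()
    for (b in split(1:n, ceiling((1:n) / 3))) {
      cnn <- sapply(b, function(k) if (any(prob[, , k] > 0.5))
        mean(pet[, , k][prob[, , k] > 0.5]) else NA)
      man <- sapply(b, function(k) if (any(lab[, , k] > 0))
        mean(pet[, , k][lab[, , k] > 0]) else NA)
      ds <- c()
      for (j in seq_along(b)) {
        cj <- ifelse(is.na(cnn[j]), mean(cnn, na.rm = TRUE), cnn[j])
        mj <- ifelse(is.na(man[j]), mean(man, na.rm = TRUE), man[j])
        if (is.na(cnn[j]) && is.na(man[j])) next
        if (is.nan(cj) || is.nan(mj)) next
        ds <- c(ds, abs(cj - mj) / mj)
      }
      if (length(ds)) scores <- c(scores, mean(ds))
    }
    expect_equal(got, mean(scores))
  }
})

test_that("metric equals mean |dBSUV| when no delineation is missing", {
  cs <- make_dataset(1, base_seed = 44)[[1]]
  st <- build_slice_stack(cs$ct, cs$pet, cs$label, preprocess_config(crop_xy = 64))
  labeled <- which(apply(st$label, 3, sum) > 0)
  lab <- st$label[, , labeled, drop = FALSE]
  pet <- st$pet_raw[, , labeled, drop = FALSE]
  # synthetic "prediction": the label dilated by a one-voxel shift
  prob <- array(0, dim(lab))
  prob[-1, , ] <- 0.9 * lab[-dim(lab)[1], , ]
  score <- bsuv_monitor_metric(prob, lab, pet, batch_size = dim(lab)[3])
  per_plane <- sapply(seq_len(dim(lab)[3]), function(k)
    abs(delta_bsuv(mean(pet[, , k][prob[, , k] > 0.5]),
                   mean(pet[, , k][lab[, , k] > 0]))))
  expect_equal(score, mean(per_plane))
})

test_that("elastic warp is identity at sigma 0 and shares one field across channels", {
  plane <- matrix(runif(32 * 32), 32, 32)
  lab <- matrix(rbinom(32 * 32, 1, 0.1), 32, 32)
  out <- elastic_warp(plane, plane, lab, warp_params(displacement_sigma = 0))
  expect_equal(out$ct, plane, tolerance = 1e-12)
  expect_equal(out$pet, plane, tolerance = 1e-12)
  expect_identical(out$label, lab)
  # identical fiducial pattern in both channels stays identical under warping
  set.seed(21)
  fid <- matrix(0, 32, 32); fid[seq(4, 28, 8), ] <- 1; fid[, seq(4, 28, 8)] <- 1
  w <- elastic_warp(fid, fid, NULL, warp_params(displacement_sigma = 2))
  expect_identical(w$ct, w$pet)
  # reproducible under identical RNG state
  set.seed(33); w1 <- elastic_warp(plane, plane, lab, warp_params())
  set.seed(33); w2 <- elastic_warp(plane, plane, lab, warp_params())
  expect_identical(w1, w2)
})

test_that("warping perturbs but never destroys labels (empirical bounds, sigma <= 2)", {
  # bounds frozen from 100 seeded warps of a phantom case: the case-level
  # label count fluctuates by ~7% (sigma 1) to ~15% (sigma 2) on average
  cs <- make_dataset(1, base_seed = 13)[[1]]
  st <- build_slice_stack(cs$ct, cs$pet, cs$label, preprocess_config(crop_xy = 64))
  planes <- which(apply(st$label, 3, sum) > 0)
  n0 <- sum(st$label[, , planes])
  for (sg in c(1, 2)) {
    set.seed(100)
    params <- warp_params(displacement_sigma = sg)
    changes <- replicate(50, {
      tot <- 0
      for (k in planes)
        tot <- tot + sum(elastic_warp(st$ct[, , k], st$pet[, , k],
                                      st$label[, , k], params)$label)
      abs(tot - n0) / n0
    })
    expect_lt(mean(changes), 0.20)
    expect_lt(max(changes), 0.60)
    expect_gt(min(replicate(5, {
      tot <- 0
      for (k in planes)
        tot <- tot + sum(elastic_warp(st$ct[, , k], st$pet[, , k],
                                      st$label[, , k], params)$label)
      tot
    })), 0)  # labels never vanish
  }
})

test_that("training improves the validation BSUV score and selects the best model", {
  cases <- make_dataset(16, base_seed = 1)
  stacks <- lapply(cases, function(cs)
    build_slice_stack(cs$ct, cs$pet, cs$label, preprocess_config(crop_xy = 64)))
  cfg <- train_config(epochs = 6, batch_size = 16, seed = 5)
  net <- build_unet(unet_config(8L, 3L), seed = 11)
  fit <- train_unet(net, stacks[1:12], stacks[13:16], cfg)
  hist <- fit$history
  expect_identical(nrow(hist), 6L)
  expect_true(all(diff(hist$train_loss) < 0))  # loss decreases monotonically here
  scores <- hist$val_score[!is.na(hist$val_score)]
  expect_gte(length(scores), 2)
  expect_lt(min(scores), scores[1])  # training improves on the first score
  expect_equal(fit$best_score, min(hist$val_score, na.rm = TRUE))
  expect_identical(fit$best_epoch, hist$epoch[which.min(hist$val_score)])
})

test_that("training is reproducible and honours the one-epoch contract", {
  cases <- make_dataset(3, base_seed = 3)
  stacks <- lapply(cases, function(cs)
    build_slice_stack(cs$ct, cs$pet, cs$label, preprocess_config(crop_xy = 32)))
  cfg <- train_config(epochs = 2, batch_size = 8, seed = 5,
                      augment = warp_params(probability = 0.3))
  net <- build_unet(unet_config(2L, 2L), seed = 2)
  fit <- train_unet(net, stacks[1:2], stacks[3], cfg)
  fit2 <- train_unet(net, stacks[1:2], stacks[3], cfg)
  expect_identical(fit2$history, fit$history)
  expect_identical(fit2$net$params, fit$net$params)

  fit1 <- train_unet(net, stacks[1:2], stacks[3],
                     train_config(epochs = 1, batch_size = 8, seed = 5))
  expect_identical(fit1$best_epoch, 1L)
  expect_identical(nrow(fit1$history), 1L)
  expect_error(train_unet(net, list(), stacks[3], cfg))
})
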