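#' U-Net architecture configuration
#'
#' Describes the 2-D, two-input-channel U-Net used to map a paired CT/PET
#' transaxial plane to a per-voxel probability of aortic-lumen-core
#' membership. Each resolution level applies two blocks of 3x3 zero-padded
#' convolution + batch normalization + ReLU; 2x2 max-pooling (stride 2)
#' halves the resolution and doubles the channel count on the way down, and
#' a 3x3 transposed convolution (stride 2) doubles the resolution and halves
#' the channel count on the way up, with encoder features concatenated back
#' in via skip connections. A final 1x1 convolution with sigmoid output
#' yields the probability map.
#'
#' @param base_channels feature channels produced by the first convolution
#'   (default 32; the channel count doubles at each of the `depth`
#'   downsampling steps, e.g. 32-64-128 with a 256-channel bottleneck).
#' @param depth number of downsampling/upsampling operations (default 3).
#'   Input planes must have side lengths divisible by `2^depth`.
#' @param in_channels number of input channels (2: CT and PET).
#' @param foreground_prior expected fraction of foreground (lumen-core)
#'   voxels, used to initialize the final-layer bias at its logit. The
#'   lumen core occupies well under 1% of a whole-body plane, and biasing
#'   the output toward that prior keeps early training from spending its
#'   gradient budget suppressing background, which matters at short
#'   training schedules.
#' @return an object of class `unet_config`.
#' @export
unet_config <- function(base_channels = 32L, depth = 3L, in_channels = 2L,
                        foreground_prior = 0.01) {
  base_channels <- as.integer(base_channels)
  depth <- as.integer(depth)
  in_channels <- as.integer(in_channels)
  if (is.na(base_channels) || base_channels < 1L)
    stop("base_channels must be >= 1")
  if (is.na(depth) || depth < 1L)
    stop("depth must be >= 1")
  if (in_channels < 1L) stop("in_channels must be >= 1")
  if (foreground_prior <= 0 || foreground_prior >= 1)
    stop("foreground_prior must be in (0, 1)")
  structure(list(base_channels = base_channels, depth = depth,
                 in_channels = in_channels, foreground_prior = foreground_prior),
            class = "unet_config")
}

# channel width at encoder level l (1-based)
unet_channels <- function(cfg, l) cfg$base_channels * 2L^(l - 1L)

unet_param_names <- function(cfg) {
  nms <- character(0)
  for (l in seq_len(cfg$depth)) nms <- c(nms, paste0("enc", l, "_c", 1:2))
  nms <- c(nms, "bot_c1", "bot_c2")
  for (l in seq_len(cfg$depth)) nms <- c(nms, paste0("dec", l, "_c", 1:2))
  nms
}

#' Build and initialize a U-Net
#'
#' Allocates all convolution, transposed-convolution and batch-normalization
#' parameters for the architecture described by a [unet_config()]. Weights
#' use He-normal initialization; biases start at zero, batch-norm scale at
#' one. Batch-norm statistics are tracked as running averages during
#' training and frozen at inference so predictions are reproducible.
#'
#' @param cfg a [unet_config()].
#' @param seed optional integer; when given, initialization is performed
#'   under this seed without disturbing the caller's RNG state.
#' @return an object of class `unet` holding parameters, running statistics
#'   and the configuration.
#' @export
build_unet <- function(cfg, seed = NULL) {
  if (!inherits(cfg, "unet_config")) stop("cfg must be a unet_config")
  build <- function() {
    params <- list()
    bn <- list()
    he <- function(k, ci, co) {
      array(rnorm(k * k * ci * co, sd = sqrt(2 / (k * k * ci))),
            dim = c(k, k, ci, co))
    }
    add_conv_bn <- function(name, k, ci, co) {
      params[[paste0(name, "_w")]] <<- he(k, ci, co)
      params[[paste0(name, "_b")]] <<- numeric(co)
      params[[paste0(name, "_g")]] <<- rep(1, co)
      params[[paste0(name, "_be")]] <<- numeric(co)
      bn[[paste0(name, "_rm")]] <<- numeric(co)
      bn[[paste0(name, "_rv")]] <<- rep(1, co)
    }
    for (l in seq_len(cfg$depth)) {
      ci <- if (l == 1L) cfg$in_channels else unet_channels(cfg, l - 1L)
      cl <- unet_channels(cfg, l)
      add_conv_bn(paste0("enc", l, "_c1"), 3L, ci, cl)
      add_conv_bn(paste0("enc", l, "_c2"), 3L, cl, cl)
    }
    cb <- cfg$base_channels * 2L^cfg$depth
    add_conv_bn("bot_c1", 3L, unet_channels(cfg, cfg$depth), cb)
    add_conv_bn("bot_c2", 3L, cb, cb)
    for (l in seq_len(cfg$depth)) {
      cl <- unet_channels(cfg, l)
      cin_up <- if (l == cfg$depth) cb else unet_channels(cfg, l + 1L)
      # transposed conv stored as the adjoint stride-2 conv weight [3,3,co,ci]
      params[[paste0("dec", l, "_up_w")]] <-
        array(rnorm(9 * cl * cin_up, sd = sqrt(2 / (9 * cin_up))),
              dim = c(3L, 3L, cl, cin_up))
      params[[paste0("dec", l, "_up_b")]] <- numeric(cl)
      add_conv_bn(paste0("dec", l, "_c1"), 3L, 2L * cl, cl)
      add_conv_bn(paste0("dec", l, "_c2"), 3L, cl, cl)
    }
    c1 <- unet_channels(cfg, 1L)
    params$out_w <- array(rnorm(c1, sd = sqrt(2 / c1)), dim = c(1L, 1L, c1, 1L))
    params$out_b <- log(cfg$foreground_prior / (1 - cfg$foreground_prior))
    list(params = params, bn = bn)
  }
  pb <- if (is.null(seed)) build() else with_local_seed(seed, build())
  structure(list(cfg = cfg, params = pb$params, bn = pb$bn,
                 hyper = list(bn_momentum = 0.1, bn_eps = 1e-5)),
            class = "unet")
}

#' Number of trainable parameters of a U-Net
#' @param net an object of class `unet`.
#' @return integer count of trainable scalars (convolution weights and
#'   biases, batch-norm scales and shifts; running statistics excluded).
#' @export
count_params <- function(net) {
  stopifnot(inherits(net, "unet"))
  sum(vapply(net$params, length, integer(1)))
}

bind_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

#' Forward pass of the U-Net
#'
#' Maps a batch of preprocessed 2-channel planes to per-voxel lumen
#' membership probabilities. In inference mode (`training = FALSE`)
#' batch-norm uses frozen running statistics, so outputs are deterministic
#' and independent of batch composition.
#'
#' @param net an object of class `unet`.
#' @param x numeric array `[H, W, in_channels, N]` with values in `[0, 1]`.
#' @param training logical; when `TRUE`, batch statistics are used and a
#'   cache for backpropagation plus updated running statistics are returned.
#' @return list with `prob` (array `[H, W, 1, N]`, values strictly inside
#'   (0,1)), `logits`, and when training also `cache` and `bn` (updated
#'   running statistics).
#' @export
unet_forward <- function(net, x, training = FALSE) {
  stopifnot(inherits(net, "unet"))
  cfg <- net$cfg
  d <- dim(x)
  if (length(d) != 4L) stop("x must be a 4-D array [H, W, C, N]")
  if (d[3] != cfg$in_channels)
    stop("wrong channel count: expected ", cfg$in_channels, ", got ", d[3])
  if (d[1] %% 2L^cfg$depth != 0L || d[2] %% 2L^cfg$depth != 0L)
    stop("input side lengths must be divisible by 2^depth")
  cache <- list()
  bnup <- net$bn
  block <- function(name, a_in) {
    w <- net$params[[paste0(name, "_w")]]
    pad <- (dim(w)[1] - 1L) %/% 2L
    z <- cpp_conv_fw(a_in, w, net$params[[paste0(name, "_b")]], pad)
    bn <- cpp_bn_fw(z, net$params[[paste0(name, "_g")]],
                    net$params[[paste0(name, "_be")]],
                    bnup[[paste0(name, "_rm")]], bnup[[paste0(name, "_rv")]],
                    net$hyper$bn_momentum, net$hyper$bn_eps, training)
    a <- bn$y
    a[a < 0] <- 0
    if (training) {
      cache[[name]] <<- list(x = a_in, z = z, mean = bn$mean,
                             invstd = bn$invstd, h = bn$y)
      bnup[[paste0(name, "_rm")]] <<- bn$rmean
      bnup[[paste0(name, "_rv")]] <<- bn$rvar
    }
    a
  }
  skips <- vector("list", cfg$depth)
  a <- x
  for (l in seq_len(cfg$depth)) {
    a <- block(paste0("enc", l, "_c1"), a)
    a <- block(paste0("enc", l, "_c2"), a)
    skips[[l]] <- a
    mp <- cpp_maxpool_fw(a)
    if (training)
      cache[[paste0("pool", l)]] <- list(idx = mp$idx, H = dim(a)[1],
                                         W = dim(a)[2])
    a <- mp$y
  }
  a <- block("bot_c1", a)
  a <- block("bot_c2", a)
  for (l in rev(seq_len(cfg$depth))) {
    up_nm <- paste0("dec", l, "_up")
    if (training) cache[[up_nm]] <- list(x = a)
    a <- cpp_convt_fw(a, net$params[[paste0(up_nm, "_w")]],
                      net$params[[paste0(up_nm, "_b")]])
    skip <- skips[[l]]
    if (training)
      cache[[paste0("cat", l)]] <- list(skip_channels = dim(skip)[3])
    a <- bind_channels(skip, a)
    a <- block(paste0("dec", l, "_c1"), a)
    a <- block(paste0("dec", l, "_c2"), a)
  }
  if (training) cache$out <- list(x = a)
  logits <- cpp_conv_fw(a, net$params$out_w, net$params$out_b, 0L)
  prob <- plogis(logits)
  out <- list(prob = prob, logits = logits)
  if (training) {
    out$cache <- cache
    out$bn <- bnup
  }
  out
}

# Backpropagate d(loss)/d(logits) through the network; returns a flat named
# list of gradients matching net$params.
unet_backward <- function(net, cache, dlogits) {
  cfg <- net$cfg
  grads <- list()
  block_bw <- function(name, da) {
    cc <- cache[[name]]
    dh <- da
    dh[cc$h <= 0] <- 0
    bnb <- cpp_bn_bw(dh, cc$z, net$params[[paste0(name, "_g")]],
                     cc$mean, cc$invstd)
    grads[[paste0(name, "_g")]] <<- bnb$dgamma
    grads[[paste0(name, "_be")]] <<- bnb$dbeta
    w <- net$params[[paste0(name, "_w")]]
    pad <- (dim(w)[1] - 1L) %/% 2L
    cb <- cpp_conv_bw(cc$x, w, bnb$dx, pad)
    grads[[paste0(name, "_w")]] <<- cb$dw
    grads[[paste0(name, "_b")]] <<- cb$db
    cb$dx
  }
  cb <- cpp_conv_bw(cache$out$x, net$params$out_w, dlogits, 0L)
  grads$out_w <- cb$dw
  grads$out_b <- cb$db
  da <- cb$dx
  dskips <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth)) {
    da <- block_bw(paste0("dec", l, "_c2"), da)
    da <- block_bw(paste0("dec", l, "_c1"), da)
    csk <- cache[[paste0("cat", l)]]$skip_channels
    dskips[[l]] <- da[, , seq_len(csk), , drop = FALSE]
    dup <- da[, , csk + seq_len(dim(da)[3] - csk), , drop = FALSE]
    up_nm <- paste0("dec", l, "_up")
    ct <- cpp_convt_bw(cache[[up_nm]]$x, net$params[[paste0(up_nm, "_w")]], dup)
    grads[[paste0(up_nm, "_w")]] <- ct$dw
    grads[[paste0(up_nm, "_b")]] <- ct$db
    da <- ct$dx
  }
  da <- block_bw("bot_c2", da)
  da <- block_bw("bot_c1", da)
  for (l in rev(seq_len(cfg$depth))) {
    pc <- cache[[paste0("pool", l)]]
    da <- cpp_maxpool_bw(da, pc$idx, pc$H, pc$W)
    da <- da + dskips[[l]]
    da <- block_bw(paste0("enc", l, "_c2"), da)
    da <- block_bw(paste0("enc", l, "_c1"), da)
  }
  grads
}

#' Predict probability planes in inference mode
#'
#' @param net a trained `unet`.
#' @param x array `[H, W, in_channels, N]`.
#' @return array `[H, W, 1, N]` of probabilities.
#' @export
unet_predict <- function(net, x) {
  unet_forward(net, x, training = FALSE)$prob
}

#' @export
print.unet <- function(x, ...) {
  cat("2-D U-Net:", x$cfg$in_channels, "input channels,",
      x$cfg$base_channels, "base channels, depth", x$cfg$depth, "\n")
  cat("trainable parameters:", count_params(x), "\n")
  invisible(x)
}

#' Save / load a U-Net
#'
#' Weights and running statistics are serialized with `saveRDS`; the
#' architecture configuration is additionally written alongside as JSON so
#' checkpoints are self-describing.
#'
#' @param net a `unet`.
#' @param path file path for the checkpoint (an `.rds` file; a `.json`
#'   sidecar with the architecture is written next to it).
#' @return `save_unet` returns `path` invisibly; `load_unet` returns the
#'   restored `unet`.
#' @export
save_unet <- function(net, path) {
  stopifnot(inherits(net, "unet"))
  saveRDS(net, path)
  jsonlite::write_json(unclass(net$cfg), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "unet")) stop("not a unet checkpoint: ", path)
  net
}
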