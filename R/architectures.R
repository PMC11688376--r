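# ResNet50 encoder and the four segmentation decoders.
#
# Reference decoder configurations (fixed; the trainable-parameter totals of
# the four networks are pinned by tests):
#   * unet      -- encoder-decoder with skip connections, decoder channels
#                  (256, 128, 64, 32, 16), two 3x3 conv+BN+ReLU per block,
#                  3x3 two-channel head.
#   * unetpp    -- nested dense-skip decoder over the same channel widths,
#                  3x3 two-channel head.
#   * deeplabv3 -- output stride 16 (layer4 dilated), ASPP at 256 channels
#                  with atrous rates (12, 24, 36) plus image pooling, 3x3
#                  conv + BN + ReLU, 1x1 two-channel head, bilinear x16
#                  upsampling.
#   * resunet   -- as unet but with residual decoder blocks (1x1 projection
#                  shortcut with bias across each block) and a 1x1 head.
# The two-channel background/foreground head is reduced to a single-channel
# probability map by a channel softmax, so every network maps
# (H, W, 3, N) -> (H, W, 1, N) with values in [0, 1].

SAC_ARCHS <- c("unet", "unetpp", "deeplabv3", "resunet")

bottleneck <- function(b, prefix, input, mid, out_ch, stride = 1L, dil = 1L) {
  in_ch <- node_ch(b, input)
  c1 <- add_conv(b, paste0(prefix, ".conv1"), input, mid, 1L)
  b1 <- add_bn(b, paste0(prefix, ".bn1"), c1)
  r1 <- add_relu(b, paste0(prefix, ".relu1"), b1)
  c2 <- add_conv(b, paste0(prefix, ".conv2"), r1, mid, 3L, stride = stride, dil = dil)
  b2 <- add_bn(b, paste0(prefix, ".bn2"), c2)
  r2 <- add_relu(b, paste0(prefix, ".relu2"), b2)
  c3 <- add_conv(b, paste0(prefix, ".conv3"), r2, out_ch, 1L)
  b3 <- add_bn(b, paste0(prefix, ".bn3"), c3)
  sc <- input
  if (in_ch != out_ch || stride != 1L) {
    dc <- add_conv(b, paste0(prefix, ".down.conv"), input, out_ch, 1L, stride = stride)
    sc <- add_bn(b, paste0(prefix, ".down.bn"), dc)
  }
  ad <- add_add(b, paste0(prefix, ".sum"), c(b3, sc))
  add_relu(b, paste0(prefix, ".out"), ad)
}

resnet_layer <- function(b, prefix, input, n_blocks, mid, out_ch, stride, dil = 1L) {
  x <- bottleneck(b, paste0(prefix, ".b1"), input, mid, out_ch, stride = stride, dil = dil)
  for (i in seq_len(n_blocks - 1L))
    x <- bottleneck(b, paste0(prefix, ".b", i + 1L), x, mid, out_ch, dil = dil)
  x
}

# returns the five skip features c1 (/2, 64ch) .. c5 (/32 or /16, 2048ch)
resnet50_encoder <- function(b, dilate_layer4 = FALSE) {
  cv <- add_conv(b, "stem.conv", "input", 64L, 7L, stride = 2L, pad = 3L)
  bn <- add_bn(b, "stem.bn", cv)
  c1 <- add_relu(b, "stem.relu", bn)
  mp <- add_maxpool(b, "stem.pool", c1)
  c2 <- resnet_layer(b, "layer1", mp, 3L, 64L, 256L, stride = 1L)
  c3 <- resnet_layer(b, "layer2", c2, 4L, 128L, 512L, stride = 2L)
  c4 <- resnet_layer(b, "layer3", c3, 6L, 256L, 1024L, stride = 2L)
  c5 <- if (dilate_layer4)
    resnet_layer(b, "layer4", c4, 3L, 512L, 2048L, stride = 1L, dil = 2L)
  else
    resnet_layer(b, "layer4", c4, 3L, 512L, 2048L, stride = 2L)
  list(c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5)
}

decoder_block <- function(b, prefix, input, skip, out_ch, residual = FALSE) {
  up <- add_up2(b, paste0(prefix, ".up"), input)
  xc <- if (is.null(skip)) up
        else add_concat(b, paste0(prefix, ".cat"), c(up, skip))
  c1 <- add_conv(b, paste0(prefix, ".conv1"), xc, out_ch, 3L)
  b1 <- add_bn(b, paste0(prefix, ".bn1"), c1)
  r1 <- add_relu(b, paste0(prefix, ".relu1"), b1)
  c2 <- add_conv(b, paste0(prefix, ".conv2"), r1, out_ch, 3L)
  b2 <- add_bn(b, paste0(prefix, ".bn2"), c2)
  if (residual) {
    sc <- add_conv(b, paste0(prefix, ".short"), xc, out_ch, 1L, bias = TRUE)
    ad <- add_add(b, paste0(prefix, ".sum"), c(b2, sc))
    add_relu(b, paste0(prefix, ".out"), ad)
  } else {
    add_relu(b, paste0(prefix, ".out"), b2)
  }
}

build_unet_like <- function(b, out_channels, residual) {
  f <- resnet50_encoder(b)
  ch <- c(256L, 128L, 64L, 32L, 16L)
  skips <- list(f$c4, f$c3, f$c2, f$c1, NULL)
  x <- f$c5
  for (i in seq_along(ch)) {
    x <- decoder_block(b, paste0("dec", i), x, skips[[i]], ch[i], residual = residual)
  }
  hd <- add_conv(b, "head.conv", x, out_channels, if (residual) 1L else 3L, bias = TRUE)
  add_head_prob(b, "head.prob", hd)
}

build_unetpp <- function(b, out_channels) {
  f <- resnet50_encoder(b)
  enc <- list(f$c5, f$c4, f$c3, f$c2, f$c1)  # 2048, 1024, 512, 256, 64
  OC <- c(256L, 128L, 64L, 32L)
  SC <- c(1024L, 512L, 256L, 64L)
  X <- list()  # X[[paste(d, l)]]
  for (l in 0:3) {
    for (d in seq(l, 0)) {
      nm <- sprintf("x_%d_%d", d, l)
      input <- if (d == 0L) {
        if (l == 0L) enc[[1L]] else X[[sprintf("x_0_%d", l - 1L)]]
      } else if (l - 1L >= d) {
        X[[sprintf("x_%d_%d", d, l - 1L)]]
      } else {
        enc[[d + 1L]]
      }
      skips <- character(0)
      if (l >= d + 1L)
        skips <- vapply((d + 1L):l, function(dd) X[[sprintf("x_%d_%d", dd, l)]], "")
      skips <- c(skips, enc[[l + 2L]])
      out_ch <- if (d == 0L) OC[l + 1L] else SC[l + 1L]
      up <- add_up2(b, paste0(nm, ".up"), input)
      xc <- add_concat(b, paste0(nm, ".cat"), c(up, skips))
      c1 <- add_conv(b, paste0(nm, ".conv1"), xc, out_ch, 3L)
      b1 <- add_bn(b, paste0(nm, ".bn1"), c1)
      r1 <- add_relu(b, paste0(nm, ".relu1"), b1)
      c2 <- add_conv(b, paste0(nm, ".conv2"), r1, out_ch, 3L)
      b2 <- add_bn(b, paste0(nm, ".bn2"), c2)
      X[[nm]] <- add_relu(b, paste0(nm, ".out"), b2)
    }
  }
  x <- decoder_block(b, "x_0_4", X[["x_0_3"]], NULL, 16L)
  hd <- add_conv(b, "head.conv", x, out_channels, 3L, bias = TRUE)
  add_head_prob(b, "head.prob", hd)
}

build_deeplabv3 <- function(b, out_channels) {
  f <- resnet50_encoder(b, dilate_layer4 = TRUE)
  rates <- c(12L, 24L, 36L)
  br <- character(0)
  br[1] <- conv_bn_relu(b, "aspp.b0", f$c5, 256L, 1L)
  for (i in seq_along(rates))
    br[i + 1] <- conv_bn_relu(b, paste0("aspp.r", rates[i]), f$c5, 256L, 3L,
                              dil = rates[i])
  gp <- add_gap(b, "aspp.pool", f$c5)
  pc <- conv_bn_relu(b, "aspp.poolconv", gp, 256L, 1L)
  br[5] <- add_broadcast(b, "aspp.poolup", pc, like = f$c5)
  cat_ <- add_concat(b, "aspp.cat", br)
  pr <- conv_bn_relu(b, "aspp.project", cat_, 256L, 1L)
  c3 <- conv_bn_relu(b, "head.conv3", pr, 256L, 3L)
  hd <- add_conv(b, "head.conv", c3, out_channels, 1L, bias = TRUE)
  up <- add_bilinear(b, "head.up", hd, scale = 16)
  add_head_prob(b, "head.prob", up)
}

#' Build a segmentation network
#'
#' Constructs one of the four encoder-decoder segmentation architectures
#' with a ResNet50 encoder (randomly initialized, He scheme) and a fixed
#' reference decoder configuration. Every network maps a 3-channel image
#' batch to a single-channel probability map of the same spatial size; the
#' two output logits (background/foreground) are reduced by channel softmax.
#'
#' @param arch One of `"unet"`, `"unetpp"`, `"deeplabv3"`, `"resunet"`.
#' @param out_channels Output logit channels (2, the reference head; 1 gives
#'   a plain sigmoid head with correspondingly fewer parameters).
#' @param seed Integer seed for weight initialization; the same seed gives
#'   bit-identical initial parameters.
#' @return An object of class `"sac_model"`: the layer graph, parameter
#'   list, and batch-norm buffers.
#' @export
#' @examples
#' m <- build_model("resunet", seed = 1)
#' count_trainable_params(m)
build_model <- function(arch = SAC_ARCHS, out_channels = 2L, seed = 1L) {
  arch <- match.arg(arch)
  b <- new_builder()
  b$nodes[["input"]] <- list(op = "input", inputs = character(0), ch = 3L)
  output <- local_seed(seed, switch(arch,
    unet = build_unet_like(b, out_channels, residual = FALSE),
    resunet = build_unet_like(b, out_channels, residual = TRUE),
    unetpp = build_unetpp(b, out_channels),
    deeplabv3 = build_deeplabv3(b, out_channels)
  ))
  nodes <- b$nodes
  nodes[["input"]] <- NULL
  structure(list(arch = arch, in_channels = 3L, out_channels = out_channels,
                 nodes = nodes, params = b$params, buffers = b$buffers,
                 output = output),
            class = "sac_model")
}

#' Count trainable parameters
#'
#' Sum of the element counts of every trainable tensor of the network
#' (convolution kernels and biases, batch-norm scales and shifts; running
#' statistics are buffers, not parameters). The count depends only on the
#' architecture, not on input size or initialization seed.
#'
#' @param model A [build_model()] result.
#' @return Integer-valued numeric count.
#' @export
count_trainable_params <- function(model) {
  stopifnot(inherits(model, "sac_model"))
  sum(vapply(model$params, length, 0))
}

#' @export
print.sac_model <- function(x, ...) {
  cat(sprintf("<sac_model> %s: ResNet50 encoder, %d nodes, %s trainable parameters\n",
              x$arch, length(x$nodes),
              format(count_trainable_params(x), big.mark = ",")))
  invisible(x)
}

#' One-row architecture summary
#'
#' @param arch Architecture name, see [build_model()].
#' @return Tibble with the architecture and its trainable-parameter count.
#' @export
model_info <- function(arch = SAC_ARCHS) {
  arch <- match.arg(arch)
  m <- build_model(arch)
  tibble::tibble(arch = arch, encoder = "resnet50",
                 trainable_params = count_trainable_params(m))
}

#' Run a network on one image
#'
#' @param model A [build_model()] result (possibly trained).
#' @param image A grayscale matrix in `[0, 1]` (replicated to the encoder's
#'   3 input channels) or an (H, W, 3) array. Spatial dimensions must be
#'   divisible by 32.
#' @param threshold Binarization threshold in (0, 1); probabilities greater
#'   than or equal to the threshold become foreground.
#' @return For [predict_prob()] the probability matrix; for [predict_mask()]
#'   a 0/1 integer mask.
#' @export
predict_prob <- function(model, image) {
  stopifnot(inherits(model, "sac_model"))
  x <- image_to_input(image)
  fwd <- forward_net(model, x, training = FALSE)
  fwd$out[, , 1L, 1L]
}

#' @rdname predict_prob
#' @export
predict_mask <- function(model, image, threshold = 0.5) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    abort("threshold must lie in (0, 1)")
  p <- predict_prob(model, image)
  matrix(as.integer(p >= threshold), nrow(p), ncol(p))
}

image_to_input <- function(image) {
  if (is.matrix(image)) image <- array(rep(image, 3L), c(dim(image), 3L))
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L)
    abort("image must be a matrix or (H, W, 3) array")
  if (d[1L] %% 32L != 0L || d[2L] %% 32L != 0L)
    abort("image dimensions must be divisible by 32")
  array(image, c(d[1L], d[2L], 3L, 1L))
}
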