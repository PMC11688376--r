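# rotate a matrix about its center by `angle` degrees (inverse mapping);
# bilinear for images, nearest for masks, fill 0, same output size
rotate_about_center <- function(m, angle, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  H <- nrow(m); W <- ncol(m)
  th <- angle * pi / 180
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  r <- matrix(seq_len(H) - cr, H, W)
  c <- matrix(seq_len(W) - cc, H, W, byrow = TRUE)
  # source coordinates (rotate backwards)
  sr <- cos(th) * r + sin(th) * c + cr
  sc <- -sin(th) * r + cos(th) * c + cc
  if (interp == "nearest") {
    ri <- round(sr); ci <- round(sc)
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    out <- matrix(0, H, W)
    out[ok] <- m[cbind(ri[ok], ci[ok])]
    return(out)
  }
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  pick <- function(ri, ci) {
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    v <- matrix(0, H, W)
    v[ok] <- m[cbind(ri[ok], ci[ok])]
    v
  }
  pick(r0, c0) * (1 - fr) * (1 - fc) + pick(r0 + 1, c0) * fr * (1 - fc) +
    pick(r0, c0 + 1) * (1 - fr) * fc + pick(r0 + 1, c0 + 1) * fr * fc
}

flip_h <- function(m) m[, ncol(m):1, drop = FALSE]
flip_v <- function(m) m[nrow(m):1, , drop = FALSE]

#' Augment a paired image/mask training set fourfold
#'
#' Each original pair yields itself, one 45-degree rotation, one horizontal
#' flip and one vertical flip, so `n` pairs become exactly `4n`. The
#' identical geometric transform is applied to image and mask; rotation uses
#' bilinear interpolation for the image and nearest-neighbor for the mask
#' (keeping masks strictly binary), with zero fill and unchanged size.
#'
#' @param images,masks Lists of paired matrices of equal length.
#' @param angle Rotation angle in degrees (default 45).
#' @return A list with `images` and `masks` lists of length `4n`, ordered
#'   original, rotated, h-flipped, v-flipped per input pair, and an `origin`
#'   tibble recording provenance.
#' @export
augment_training_set <- function(images, masks, angle = 45) {
  if (!is.list(images) || !is.list(masks) || length(images) != length(masks))
    abort("images and masks must be paired lists of equal length")
  if (length(images) == 0L) abort("empty training set")
  ok <- purrr::map2_lgl(images, masks, function(i, m) all(dim(i) == dim(m)))
  if (!all(ok)) abort("image/mask dimension mismatch in pairs")
  out_i <- vector("list", 4L * length(images))
  out_m <- vector("list", 4L * length(masks))
  for (i in seq_along(images)) {
    j <- 4L * (i - 1L)
    img <- images[[i]]; msk <- as_binary_mask(masks[[i]])
    out_i[[j + 1L]] <- img
    out_m[[j + 1L]] <- msk
    out_i[[j + 2L]] <- rotate_about_center(img, angle, "bilinear")
    out_m[[j + 2L]] <- rotate_about_center(msk, angle, "nearest")
    out_i[[j + 3L]] <- flip_h(img)
    out_m[[j + 3L]] <- flip_h(msk)
    out_i[[j + 4L]] <- flip_v(img)
    out_m[[j + 4L]] <- flip_v(msk)
  }
  origin <- tibble::tibble(
    pair = rep(seq_along(images), each = 4L),
    transform = rep(c("original", "rot45", "hflip", "vflip"), length(images))
  )
  list(images = out_i, masks = out_m, origin = origin)
}

#' Stratified k-fold assignment
#'
#' Partitions `n` items into `k` folds of size `floor(n/k)` or
#' `ceiling(n/k)`, stratified by a class label: items are shuffled within
#' class and dealt round-robin with a fold cursor carried across classes, so
#' every fold's class counts stay within one item of the global fractions.
#'
#' @param n Number of items (or a data frame, in which case `nrow` is used).
#' @param k Number of folds (default 5).
#' @param labels Optional class labels of length `n` for stratification.
#' @param seed Integer seed; assignment is reproducible.
#' @return An object of class `"fold_split"` with `assignments` (tibble of
#'   `item`, `label`, `fold`) and `k`. Use [fold_iteration()] to get the
#'   train/test indices of one CV iteration.
#' @export
#' @examples
#' fs <- make_folds(500, k = 5, seed = 1)
#' table(fs$assignments$fold)
make_folds <- function(n, k = 5L, labels = NULL, seed = 1L) {
  if (is.data.frame(n)) n <- nrow(n)
  n <- as.integer(n); k <- as.integer(k)
  if (n < k) abort("need at least k items for k folds")
  if (is.null(labels)) labels <- rep("all", n)
  if (length(labels) != n) abort("labels must have length n")
  fold <- integer(n)
  cursor <- 0L
  local_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- (cursor + seq_along(idx) - 1L) %% k + 1L
      cursor <- cursor + length(idx)
    }
  })
  structure(list(
    assignments = tibble::tibble(item = seq_len(n), label = labels, fold = fold),
    k = k), class = "fold_split")
}

#' @rdname make_folds
#' @param fs A `fold_split` object.
#' @param i Iteration number in `1..k`; fold `i` is the held-out set.
#' @export
fold_iteration <- function(fs, i) {
  stopifnot(inherits(fs, "fold_split"), i >= 1L, i <= fs$k)
  test <- fs$assignments$item[fs$assignments$fold == i]
  list(train = setdiff(fs$assignments$item, test), test = test)
}

#' @export
print.fold_split <- function(x, ...) {
  cat(sprintf("<fold_split> %d items in %d folds\n", nrow(x$assignments), x$k))
  print(table(fold = x$assignments$fold, label = x$assignments$label))
  invisible(x)
}

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam, learning rate 1e-4,
#' batch size 2, with early stopping on validation Dice (patience 5,
#' best-checkpoint restore).
#'
#' @param loss `"dl"` (Dice), `"jl"` (Jaccard) or `"bcel"` (binary
#'   cross-entropy).
#' @param lr Learning rate.
#' @param batch_size Mini-batch size.
#' @param max_epochs Epoch cap.
#' @param patience Early-stop patience, in epochs without a new best
#'   validation Dice (ignored when no validation set is supplied).
#' @param stop_dice Optional training-Dice target: once an epoch's mean
#'   training Dice reaches it, training stops (a compute saver for
#'   already-separable data; `NULL` disables).
#' @param seed Integer seed for shuffling.
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(loss = c("dl", "jl", "bcel"), lr = 1e-4,
                         batch_size = 2L, max_epochs = 10L, patience = 5L,
                         stop_dice = NULL, seed = 1L) {
  loss <- match.arg(loss)
  if (lr <= 0) abort("lr must be positive")
  if (batch_size < 1L) abort("batch_size must be at least 1")
  structure(list(loss = loss, lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), stop_dice = stop_dice,
                 seed = as.integer(seed)),
            class = "train_config")
}

hard_dice <- function(p, y, threshold = 0.5) {
  pb <- p >= threshold
  s <- 2 * sum(pb * y)
  den <- sum(pb) + sum(y)
  if (den == 0) 1 else s / den
}

#' Train a segmentation network
#'
#' Desk-scale training loop: mini-batch Adam on the chosen loss, per-epoch
#' training loss and hard Dice, optional validation metrics with early
#' stopping (patience epochs without a new best validation Dice; the best
#' checkpoint is restored). Shuffling is seeded, so a fixed configuration
#' reproduces its history exactly.
#'
#' @param model A [build_model()] network.
#' @param images,masks Paired lists: grayscale matrices in `[0, 1]` and
#'   binary masks (spatial dimensions divisible by 32).
#' @param config A [train_config()].
#' @param val_images,val_masks Optional validation pairs.
#' @param verbose Print one line per epoch.
#' @return A list of class `"sac_training"`: `model` (best weights),
#'   `history` (tibble epoch/train_loss/train_dice/val_loss/val_dice).
#' @export
train <- function(model, images, masks, config = train_config(),
                  val_images = NULL, val_masks = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "sac_model"), inherits(config, "train_config"))
  if (!is.list(images) || length(images) == 0L) abort("empty training data")
  if (length(images) != length(masks)) abort("images and masks must be paired")
  n <- length(images)
  has_val <- !is.null(val_images)

  params <- model$params
  state <- adam_state(params)
  hist <- vector("list", config$max_epochs)
  best <- list(dice = -Inf, params = params, buffers = model$buffers)
  stale <- 0L

  order_seq <- local_seed(config$seed,
                          lapply(seq_len(config$max_epochs), function(e) sample(n)))

  for (epoch in seq_len(config$max_epochs)) {
    ord <- order_seq[[epoch]]
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0; ep_dice <- 0; n_seen <- 0L
    for (bi in batches) {
      x <- abind4(lapply(images[bi], image_to_input))
      y <- abind4(lapply(masks[bi], function(m)
        array(as_binary_mask(m), c(dim(m), 1L, 1L))))
      model$params <- params
      fwd <- forward_net(model, x, training = TRUE)
      model$buffers <- fwd$buffers
      lg <- loss_and_grad(config$loss, fwd$out, y)
      grads <- backward_net(model, fwd, lg$grad)
      upd <- adam_step(params, grads, state, lr = config$lr)
      params <- upd$params
      state <- upd$state
      nb <- length(bi)
      ep_loss <- ep_loss + lg$loss * nb
      ep_dice <- ep_dice + sum(vapply(seq_len(nb), function(j)
        hard_dice(fwd$out[, , 1L, j], y[, , 1L, j]), 0))
      n_seen <- n_seen + nb
    }
    model$params <- params
    row <- tibble::tibble(epoch = epoch, train_loss = ep_loss / n_seen,
                          train_dice = ep_dice / n_seen,
                          val_loss = NA_real_, val_dice = NA_real_)
    if (has_val) {
      vstats <- vapply(seq_along(val_images), function(j) {
        x <- image_to_input(val_images[[j]])
        y <- array(as_binary_mask(val_masks[[j]]),
                   c(dim(val_masks[[j]]), 1L, 1L))
        fwd <- forward_net(model, x, training = FALSE)
        c(loss_and_grad(config$loss, fwd$out, y)$loss,
          hard_dice(fwd$out[, , 1L, 1L], y[, , 1L, 1L]))
      }, numeric(2))
      row$val_loss <- mean(vstats[1L, ])
      row$val_dice <- mean(vstats[2L, ])
      if (row$val_dice > best$dice) {
        best <- list(dice = row$val_dice, params = params, buffers = model$buffers)
        stale <- 0L
      } else stale <- stale + 1L
    }
    hist[[epoch]] <- row
    if (verbose)
      message(sprintf("epoch %d: loss %.4f dice %.4f%s", epoch, row$train_loss,
                      row$train_dice,
                      if (has_val) sprintf(" | val %.4f/%.4f", row$val_loss,
                                           row$val_dice) else ""))
    if (has_val && stale >= config$patience) break
    if (!is.null(config$stop_dice) && row$train_dice >= config$stop_dice) break
    gc(FALSE)
  }
  if (has_val) {
    model$params <- best$params
    model$buffers <- best$buffers
  }
  structure(list(model = model, history = dplyr::bind_rows(hist),
                 config = config),
            class = "sac_training")
}

abind4 <- function(pieces) {
  d <- dim(pieces[[1L]])
  out <- array(0, c(d[1L], d[2L], d[3L], length(pieces)))
  for (i in seq_along(pieces)) out[, , , i] <- pieces[[i]]
  out
}

#' @export
print.sac_training <- function(x, ...) {
  cat(sprintf("<sac_training> %s, %d epochs (loss %s)\n", x$model$arch,
              nrow(x$history), x$config$loss))
  print(x$history)
  invisible(x)
}

#' @export
tidy.sac_training <- function(x, ...) x$history

#' Learning-curve plot
#'
#' @param object A [train()] result.
#' @param ... Unused.
#' @return A ggplot of loss and Dice per epoch.
#' @export
autoplot.sac_training <- function(object, ...) {
  h <- tidyr_longer(object$history)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~.data$metric, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "epoch", y = NULL, color = NULL)
}

# narrow reshape helper (keeps tidyr out of Imports)
tidyr_longer <- function(h) {
  long <- list(
    tibble::tibble(epoch = h$epoch, metric = "loss", series = "train",
                   value = h$train_loss),
    tibble::tibble(epoch = h$epoch, metric = "dice", series = "train",
                   value = h$train_dice),
    tibble::tibble(epoch = h$epoch, metric = "loss", series = "validation",
                   value = h$val_loss),
    tibble::tibble(epoch = h$epoch, metric = "dice", series = "validation",
                   value = h$val_dice)
  )
  out <- dplyr::bind_rows(long)
  out[!is.na(out$value), ]
}
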