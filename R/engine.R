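# Minimal reverse-mode layer-graph engine for the segmentation models.
#
# Feature maps are numeric arrays dim (H, W, C, N). Convolution runs through
# im2col (Rcpp) + BLAS GEMM; every op has a hand-written gradient. The graph
# is a named list of nodes in topological order; parameters live in
# model$params (named list of arrays), batch-norm running statistics in
# model$buffers. Parameter tensors are exactly the trainable quantities, so
# count_trainable_params() is a sum over this list.

new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$params <- list()
  env$buffers <- list()
  env
}

add_node <- function(b, name, op, inputs, ch, ...) {
  if (!is.null(b$nodes[[name]])) abort(paste0("duplicate node ", name))
  b$nodes[[name]] <- c(list(op = op, inputs = inputs, ch = ch), list(...))
  name
}

node_ch <- function(b, name) b$nodes[[name]]$ch

# weights stored (k*k*in_ch) x out_ch so convolution is one GEMM col %*% W
he_init <- function(n_out, fan_in) {
  matrix(rnorm(n_out * fan_in, sd = sqrt(2 / fan_in)), fan_in, n_out)
}

add_conv <- function(b, name, input, out_ch, k, stride = 1L, pad = NULL,
                     dil = 1L, bias = FALSE) {
  in_ch <- node_ch(b, input)
  if (is.null(pad)) pad <- dil * (k - 1L) %/% 2L
  b$params[[paste0(name, ".W")]] <- he_init(out_ch, k * k * in_ch)
  if (bias) b$params[[paste0(name, ".b")]] <- numeric(out_ch)
  add_node(b, name, "conv", input, out_ch, k = as.integer(k),
           stride = as.integer(stride), pad = as.integer(pad),
           dil = as.integer(dil), bias = bias, in_ch = in_ch)
}

add_bn <- function(b, name, input) {
  ch <- node_ch(b, input)
  b$params[[paste0(name, ".gamma")]] <- rep(1, ch)
  b$params[[paste0(name, ".beta")]] <- numeric(ch)
  b$buffers[[paste0(name, ".mean")]] <- numeric(ch)
  b$buffers[[paste0(name, ".var")]] <- rep(1, ch)
  add_node(b, name, "bn", input, ch)
}

add_relu <- function(b, name, input) add_node(b, name, "relu", input, node_ch(b, input))
add_add <- function(b, name, inputs) add_node(b, name, "add", inputs, node_ch(b, inputs[1L]))
add_concat <- function(b, name, inputs) {
  add_node(b, name, "concat", inputs, sum(vapply(inputs, function(i) node_ch(b, i), 0)))
}
add_maxpool <- function(b, name, input, k = 3L, stride = 2L, pad = 1L) {
  add_node(b, name, "maxpool", input, node_ch(b, input),
           k = as.integer(k), stride = as.integer(stride), pad = as.integer(pad))
}
add_up2 <- function(b, name, input) add_node(b, name, "up2", input, node_ch(b, input))
add_bilinear <- function(b, name, input, scale) {
  add_node(b, name, "bilinear", input, node_ch(b, input), scale = scale)
}
add_gap <- function(b, name, input) add_node(b, name, "gap", input, node_ch(b, input))
add_broadcast <- function(b, name, input, like) {
  add_node(b, name, "broadcast", c(input, like), node_ch(b, input))
}
add_head_prob <- function(b, name, input) {
  ch <- node_ch(b, input)
  if (!ch %in% c(1L, 2L)) abort("probability head expects 1 or 2 channels")
  add_node(b, name, if (ch == 2L) "fgprob" else "sigmoid", input, 1L)
}

conv_bn_relu <- function(b, prefix, input, out_ch, k, stride = 1L, pad = NULL,
                         dil = 1L) {
  cv <- add_conv(b, paste0(prefix, ".conv"), input, out_ch, k, stride, pad, dil)
  bn <- add_bn(b, paste0(prefix, ".bn"), cv)
  add_relu(b, paste0(prefix, ".relu"), bn)
}

# ---- forward ---------------------------------------------------------------

bcast_ch <- function(v, H, W, N) rep(rep(v, each = H * W), times = N)

# linear indices of the pixels a strided 1x1 convolution samples
stride_idx <- function(H, W, stride) {
  hi <- seq(1L, H, by = stride)
  wi <- seq(1L, W, by = stride)
  as.vector(outer(hi, (wi - 1L) * H, `+`))
}

conv_fwd <- function(x, W, b, k, stride, pad, dil) {
  d <- dim(x)
  span <- dil * (k - 1L) + 1L
  Ho <- (d[1L] + 2L * pad - span) %/% stride + 1L
  Wo <- (d[2L] + 2L * pad - span) %/% stride + 1L
  Cout <- ncol(W)
  one <- k == 1L
  if (one && stride > 1L) sub <- stride_idx(d[1L], d[2L], stride)
  out <- array(0, c(Ho, Wo, Cout, d[4L]))
  for (n in seq_len(d[4L])) {
    col <- if (one) {
      xm <- matrix(x[, , , n], d[1L] * d[2L], d[3L])
      if (stride > 1L) xm[sub, , drop = FALSE] else xm
    } else {
      im2col_cpp(x[, , , n], d[1L], d[2L], d[3L], k, stride, pad, dil)
    }
    y <- col %*% W  # (Ho*Wo) x Cout, already (Ho, Wo, Cout) column-major
    if (!is.null(b)) y <- y + rep(b, each = Ho * Wo)
    out[, , , n] <- y
  }
  out
}

conv_bwd <- function(x, dy, W, k, stride, pad, dil, want_dx = TRUE) {
  d <- dim(x); dd <- dim(dy)
  dW <- matrix(0, nrow(W), ncol(W))
  db <- numeric(ncol(W))
  dx <- if (want_dx) array(0, d) else NULL
  npix <- dd[1L] * dd[2L]
  one <- k == 1L
  if (one && stride > 1L) sub <- stride_idx(d[1L], d[2L], stride)
  for (n in seq_len(d[4L])) {
    dym <- matrix(dy[, , , n], npix, dd[3L])
    if (one) {
      xm <- matrix(x[, , , n], d[1L] * d[2L], d[3L])
      if (stride > 1L) xm <- xm[sub, , drop = FALSE]
      dW <- dW + crossprod(xm, dym)
      db <- db + colSums(dym)
      if (want_dx) {
        dcol <- tcrossprod(dym, W)
        dxm <- matrix(0, d[1L] * d[2L], d[3L])
        if (stride > 1L) dxm[sub, ] <- dcol else dxm <- dcol
        dx[, , , n] <- dxm
      }
    } else {
      col <- im2col_cpp(x[, , , n], d[1L], d[2L], d[3L], k, stride, pad, dil)
      dW <- dW + crossprod(col, dym)
      db <- db + colSums(dym)
      if (want_dx)
        dx[, , , n] <- col2im_cpp(tcrossprod(dym, W), d[1L], d[2L], d[3L],
                                  k, stride, pad, dil)
    }
  }
  list(dW = dW, db = db, dx = dx)
}

bn_stats <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1L] * d[2L], d[3L] * d[4L])
  mu <- rowMeans(matrix(colMeans(m), d[3L], d[4L]))
  ex2 <- rowMeans(matrix(colMeans(m * m), d[3L], d[4L]))
  list(mean = mu, var = pmax(ex2 - mu^2, 0))
}

maxpool_fwd <- function(x, k, stride, pad) {
  d <- dim(x)
  span <- k
  Ho <- (d[1L] + 2L * pad - span) %/% stride + 1L
  Wo <- (d[2L] + 2L * pad - span) %/% stride + 1L
  out <- array(-Inf, c(Ho, Wo, d[3L], d[4L]))
  arg <- array(0L, c(Ho, Wo, d[3L], d[4L]))
  hi_base <- (seq_len(Ho) - 1L) * stride - pad
  wi_base <- (seq_len(Wo) - 1L) * stride - pad
  for (kj in seq_len(k)) for (ki in seq_len(k)) {
    hi <- hi_base + ki  # 1-based source rows
    wi <- wi_base + kj
    hv <- hi >= 1L & hi <= d[1L]
    wv <- wi >= 1L & wi <= d[2L]
    if (!any(hv) || !any(wv)) next
    cand <- array(-Inf, c(Ho, Wo, d[3L], d[4L]))
    cand[hv, wv, , ] <- x[hi[hv], wi[wv], , , drop = FALSE]
    sel <- cand > out
    out[sel] <- cand[sel]
    arg[sel] <- ki + k * (kj - 1L)
  }
  list(out = out, arg = arg)
}

maxpool_bwd <- function(dy, arg, xdim, k, stride, pad) {
  dx <- array(0, xdim)
  d <- dim(dy)
  hi_base <- (seq_len(d[1L]) - 1L) * stride - pad
  wi_base <- (seq_len(d[2L]) - 1L) * stride - pad
  for (kj in seq_len(k)) for (ki in seq_len(k)) {
    code <- ki + k * (kj - 1L)
    sel <- arg == code
    if (!any(sel)) next
    hi <- hi_base + ki; wi <- wi_base + kj
    hv <- which(hi >= 1L & hi <= xdim[1L])
    wv <- which(wi >= 1L & wi <= xdim[2L])
    contrib <- array(0, d)
    contrib[sel] <- dy[sel]
    dx[hi[hv], wi[wv], , ] <- dx[hi[hv], wi[wv], , , drop = FALSE] +
      contrib[hv, wv, , , drop = FALSE]
  }
  dx
}

# dense interpolation matrix for 1-D bilinear resize (align_corners = FALSE)
resize_matrix <- function(n_out, n_in) {
  R <- matrix(0, n_out, n_in)
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  i0 <- pmin(pmax(floor(src), 0), n_in - 1)
  f <- src - i0
  i1 <- pmin(i0 + 1, n_in - 1)
  for (i in seq_len(n_out)) {
    R[i, i0[i] + 1] <- R[i, i0[i] + 1] + (1 - f[i])
    R[i, i1[i] + 1] <- R[i, i1[i] + 1] + f[i]
  }
  R
}

bilinear_fwd <- function(x, Rh, Rw) {
  d <- dim(x)
  out <- array(0, c(nrow(Rh), nrow(Rw), d[3L], d[4L]))
  for (n in seq_len(d[4L])) for (c in seq_len(d[3L]))
    out[, , c, n] <- Rh %*% x[, , c, n] %*% t(Rw)
  out
}

bilinear_bwd <- function(dy, Rh, Rw, xdim) {
  dx <- array(0, xdim)
  for (n in seq_len(xdim[4L])) for (c in seq_len(xdim[3L]))
    dx[, , c, n] <- crossprod(Rh, dy[, , c, n]) %*% Rw
  dx
}

forward_net <- function(model, x, training = FALSE, momentum = 0.1) {
  acts <- new.env(parent = emptyenv())
  cache <- new.env(parent = emptyenv())
  assign("input", x, envir = acts)
  params <- model$params
  buffers <- model$buffers
  eps <- 1e-5
  for (name in names(model$nodes)) {
    nd <- model$nodes[[name]]
    xin <- get(nd$inputs[1L], envir = acts)
    out <- switch(nd$op,
      conv = conv_fwd(xin, params[[paste0(name, ".W")]],
                      params[[paste0(name, ".b")]],
                      nd$k, nd$stride, nd$pad, nd$dil),
      bn = {
        d <- dim(xin)
        if (training) {
          st <- bn_stats(xin)
          buffers[[paste0(name, ".mean")]] <-
            (1 - momentum) * buffers[[paste0(name, ".mean")]] + momentum * st$mean
          buffers[[paste0(name, ".var")]] <-
            (1 - momentum) * buffers[[paste0(name, ".var")]] + momentum * st$var
        } else {
          st <- list(mean = buffers[[paste0(name, ".mean")]],
                     var = buffers[[paste0(name, ".var")]])
        }
        invstd <- 1 / sqrt(st$var + eps)
        assign(name, list(mean = st$mean, invstd = invstd), envir = cache)
        g <- params[[paste0(name, ".gamma")]]
        be <- params[[paste0(name, ".beta")]]
        A <- g * invstd
        B <- be - st$mean * A
        xin * bcast_ch(A, d[1L], d[2L], d[4L]) + bcast_ch(B, d[1L], d[2L], d[4L])
      },
      relu = pmax(xin, 0),
      add = xin + get(nd$inputs[2L], envir = acts),
      concat = {
        pieces <- lapply(nd$inputs, get, envir = acts)
        d1 <- dim(pieces[[1L]])
        out <- array(0, c(d1[1L], d1[2L], nd$ch, d1[4L]))
        off <- 0L
        for (p in pieces) {
          cc <- dim(p)[3L]
          out[, , off + seq_len(cc), ] <- p
          off <- off + cc
        }
        out
      },
      maxpool = {
        mp <- maxpool_fwd(xin, nd$k, nd$stride, nd$pad)
        assign(name, mp$arg, envir = cache)
        mp$out
      },
      up2 = {
        d <- dim(xin)
        xin[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), , ,
            drop = FALSE]
      },
      bilinear = {
        d <- dim(xin)
        Rh <- resize_matrix(round(d[1L] * nd$scale), d[1L])
        Rw <- resize_matrix(round(d[2L] * nd$scale), d[2L])
        assign(name, list(Rh = Rh, Rw = Rw), envir = cache)
        bilinear_fwd(xin, Rh, Rw)
      },
      gap = {
        d <- dim(xin)
        m <- matrix(xin, d[1L] * d[2L], d[3L] * d[4L])
        array(colMeans(m), c(1L, 1L, d[3L], d[4L]))
      },
      broadcast = {
        like <- get(nd$inputs[2L], envir = acts)
        d <- dim(like)
        array(rep(as.numeric(xin), each = d[1L] * d[2L]),
              c(d[1L], d[2L], dim(xin)[3L], dim(xin)[4L]))
      },
      sigmoid = 1 / (1 + exp(-xin)),
      fgprob = {
        d <- dim(xin)
        z <- xin[, , 2L, , drop = FALSE] - xin[, , 1L, , drop = FALSE]
        1 / (1 + exp(-z))
      },
      abort(paste0("unknown op ", nd$op))
    )
    assign(name, out, envir = acts)
  }
  model$buffers <- buffers
  list(out = get(model$output, envir = acts), acts = acts, cache = cache,
       buffers = buffers)
}

backward_net <- function(model, fwd, dout) {
  acts <- fwd$acts
  cache <- fwd$cache
  params <- model$params
  grads <- new.env(parent = emptyenv())
  dacts <- new.env(parent = emptyenv())
  assign(model$output, dout, envir = dacts)
  add_grad <- function(name, g) {
    if (exists(name, envir = dacts, inherits = FALSE))
      assign(name, get(name, envir = dacts, inherits = FALSE) + g, envir = dacts)
    else assign(name, g, envir = dacts)
  }
  eps <- 1e-5
  for (name in rev(names(model$nodes))) {
    if (!exists(name, envir = dacts, inherits = FALSE)) next
    dy <- get(name, envir = dacts, inherits = FALSE)
    rm(list = name, envir = dacts)
    nd <- model$nodes[[name]]
    xin_name <- nd$inputs[1L]
    xin <- get(xin_name, envir = acts)
    switch(nd$op,
      conv = {
        want_dx <- xin_name != "input"
        g <- conv_bwd(xin, dy, params[[paste0(name, ".W")]],
                      nd$k, nd$stride, nd$pad, nd$dil, want_dx)
        assign(paste0(name, ".W"), g$dW, envir = grads)
        if (nd$bias) assign(paste0(name, ".b"), g$db, envir = grads)
        if (want_dx) add_grad(xin_name, g$dx)
      },
      bn = {
        st <- get(name, envir = cache)
        d <- dim(xin)
        m <- d[1L] * d[2L] * d[4L]
        g <- params[[paste0(name, ".gamma")]]
        iv <- st$invstd; mu <- st$mean
        # per-channel sums over H, W, N
        csum <- function(a) {
          mm <- matrix(a, d[1L] * d[2L], d[3L] * d[4L])
          rowSums(matrix(colSums(mm), d[3L], d[4L]))
        }
        dbeta <- csum(dy)
        s_xy <- csum(dy * xin)
        dgamma <- iv * (s_xy - mu * dbeta)  # sum(dy * xhat) without xhat
        assign(paste0(name, ".gamma"), dgamma, envir = grads)
        assign(paste0(name, ".beta"), dbeta, envir = grads)
        # dx = A*(dy - dbeta/m - xhat*dgamma/m) rewritten as
        #      c1*dy + c2*xin + c3 with per-channel coefficients
        A <- g * iv
        c2 <- -A * iv * dgamma / m
        c3 <- -A * dbeta / m + A * mu * iv * dgamma / m
        add_grad(xin_name,
                 dy * bcast_ch(A, d[1L], d[2L], d[4L]) +
                 xin * bcast_ch(c2, d[1L], d[2L], d[4L]) +
                 bcast_ch(c3, d[1L], d[2L], d[4L]))
      },
      relu = add_grad(xin_name, dy * (xin > 0)),
      add = {
        add_grad(nd$inputs[1L], dy)
        add_grad(nd$inputs[2L], dy)
      },
      concat = {
        off <- 0L
        for (inp in nd$inputs) {
          cc <- dim(get(inp, envir = acts))[3L]
          add_grad(inp, dy[, , off + seq_len(cc), , drop = FALSE])
          off <- off + cc
        }
      },
      maxpool = {
        arg <- get(name, envir = cache)
        add_grad(xin_name, maxpool_bwd(dy, arg, dim(xin), nd$k, nd$stride, nd$pad))
      },
      up2 = {
        odd_r <- seq(1L, dim(dy)[1L], by = 2L)
        odd_c <- seq(1L, dim(dy)[2L], by = 2L)
        dx <- dy[odd_r, odd_c, , , drop = FALSE] +
          dy[odd_r + 1L, odd_c, , , drop = FALSE] +
          dy[odd_r, odd_c + 1L, , , drop = FALSE] +
          dy[odd_r + 1L, odd_c + 1L, , , drop = FALSE]
        add_grad(xin_name, dx)
      },
      bilinear = {
        rm_ <- get(name, envir = cache)
        add_grad(xin_name, bilinear_bwd(dy, rm_$Rh, rm_$Rw, dim(xin)))
      },
      gap = {
        d <- dim(xin)
        add_grad(xin_name,
                 array(rep(as.numeric(dy), each = d[1L] * d[2L]), d) / (d[1L] * d[2L]))
      },
      broadcast = {
        like <- get(nd$inputs[2L], envir = acts)
        d <- dim(like)
        dd <- dim(dy)
        mm <- matrix(dy, d[1L] * d[2L], dd[3L] * dd[4L])
        add_grad(xin_name, array(colSums(mm), c(1L, 1L, dd[3L], dd[4L])))
      },
      sigmoid = {
        p <- get(name, envir = acts)
        add_grad(xin_name, dy * p * (1 - p))
      },
      fgprob = {
        p <- get(name, envir = acts)
        g <- dy * p * (1 - p)
        d <- dim(xin)
        dx <- array(0, d)
        dx[, , 2L, ] <- g
        dx[, , 1L, ] <- -g
        add_grad(xin_name, dx)
      }
    )
    # this node's activation is no longer needed (reverse topological order)
    rm(list = name, envir = acts)
  }
  as.list(grads)
}

# ---- losses on (H, W, 1, N) probability arrays -----------------------------

loss_and_grad <- function(type, p, y, smooth = 1, eps = 1e-7) {
  d <- dim(p)
  N <- d[4L]
  grad <- array(0, d)
  loss <- 0
  for (n in seq_len(N)) {
    pn <- p[, , 1L, n]; yn <- y[, , 1L, n]
    if (type == "dl") {
      num <- 2 * sum(pn * yn) + smooth
      den <- sum(pn) + sum(yn) + smooth
      loss <- loss + 1 - num / den
      grad[, , 1L, n] <- -(2 * yn * den - num) / den^2
    } else if (type == "jl") {
      inter <- sum(pn * yn)
      uni <- sum(pn) + sum(yn) - inter
      loss <- loss + 1 - (inter + smooth) / (uni + smooth)
      grad[, , 1L, n] <- -(yn * (uni + smooth) - (inter + smooth) * (1 - yn)) /
        (uni + smooth)^2
    } else if (type == "bcel") {
      pc <- pmin(pmax(pn, eps), 1 - eps)
      loss <- loss + mean(-(yn * log(pc) + (1 - yn) * log(1 - pc)))
      grad[, , 1L, n] <- (-yn / pc + (1 - yn) / (1 - pc)) / length(pn)
    } else abort("loss must be one of dl, jl, bcel")
  }
  list(loss = loss / N, grad = grad / N)
}

# ---- Adam ------------------------------------------------------------------

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
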