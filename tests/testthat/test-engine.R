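# internal numerical checks of the layer-graph engine

test_that("analytic gradients match central differences on a mixed graph", {
  model <- tiny_model()
  set.seed(1)
  x <- array(runif(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  y <- array(rbinom(8 * 8 * 2, 1, 0.4), c(8, 8, 1, 2))
  for (loss in c("dl", "jl", "bcel")) {
    loss_of <- function(params) {
      model$params <- params
      fwd <- sacmetry:::forward_net(model, x, training = TRUE)
      sacmetry:::loss_and_grad(loss, fwd$out, y)$loss
    }
    fwd <- sacmetry:::forward_net(model, x, training = TRUE)
    lg <- sacmetry:::loss_and_grad(loss, fwd$out, y)
    gr <- sacmetry:::backward_net(model, fwd, lg$grad)
    h <- 1e-6
    set.seed(7)
    for (nm in names(gr)) {
      p <- model$params[[nm]]
      for (j in sample(length(p), min(3, length(p)))) {
        pp <- model$params; pp[[nm]][j] <- pp[[nm]][j] + h
        pm <- model$params; pm[[nm]][j] <- pm[[nm]][j] - h
        num <- (loss_of(pp) - loss_of(pm)) / (2 * h)
        an <- gr[[nm]][j]
        expect_equal(an, num, tolerance = 1e-4,
                     label = paste(loss, nm, "grad"))
      }
    }
  }
})

test_that("strided and dilated convolution agree with direct computation", {
  set.seed(3)
  x <- array(rnorm(7 * 9 * 2), c(7, 9, 2, 1))
  W <- matrix(rnorm(3 * 3 * 2 * 4), 3 * 3 * 2, 4)
  for (cfg in list(c(1, 1), c(2, 1), c(1, 2), c(2, 2))) {
    stride <- cfg[1]; dil <- cfg[2]
    pad <- dil
    y <- sacmetry:::conv_fwd(x, W, NULL, 3L, stride, pad, dil)
    # direct evaluation at one arbitrary output position
    ho <- dim(y)[1] %/% 2; wo <- dim(y)[2] %/% 2; co <- 2
    acc <- 0
    for (c in 1:2) for (kj in 1:3) for (ki in 1:3) {
      hi <- (ho - 1) * stride - pad + dil * (ki - 1) + 1
      wi <- (wo - 1) * stride - pad + dil * (kj - 1) + 1
      v <- if (hi >= 1 && hi <= 7 && wi >= 1 && wi <= 9) x[hi, wi, c, 1] else 0
      acc <- acc + v * W[(ki - 1) + 3 * (kj - 1) + 9 * (c - 1) + 1, co]
    }
    expect_equal(y[ho, wo, co, 1], acc, tolerance = 1e-12)
  }
})

test_that("batch norm normalizes within the batch and tracks running stats", {
  b <- sacmetry:::new_builder()
  b$nodes[["input"]] <- list(op = "input", inputs = character(0), ch = 2L)
  bn <- sacmetry:::add_bn(b, "bn", "input")
  nodes <- b$nodes; nodes[["input"]] <- NULL
  model <- structure(list(nodes = nodes, params = b$params, buffers = b$buffers,
                          output = bn), class = "sac_model")
  set.seed(4)
  x <- array(rnorm(6 * 6 * 2 * 3, mean = 5, sd = 2), c(6, 6, 2, 3))
  fwd <- sacmetry:::forward_net(model, x, training = TRUE)
  y1 <- fwd$out[, , 1, ]
  expect_equal(mean(y1), 0, tolerance = 1e-9)
  expect_equal(sd(as.vector(y1)) , 1, tolerance = 1e-2)
  expect_equal(fwd$buffers[["bn.mean"]][1], 0.1 * mean(x[, , 1, ]),
               tolerance = 1e-9)
})

test_that("maxpool picks window maxima and bilinear weights are a partition", {
  x <- array(0, c(4, 4, 1, 1))
  x[, , 1, 1] <- matrix(1:16, 4, 4)
  mp <- sacmetry:::maxpool_fwd(x, 2L, 2L, 0L)
  expect_equal(mp$out[, , 1, 1], matrix(c(6, 8, 14, 16), 2, 2))
  R <- sacmetry:::resize_matrix(12, 4)
  expect_equal(rowSums(R), rep(1, 12), tolerance = 1e-12)
  R2 <- sacmetry:::resize_matrix(4, 4)
  expect_equal(R2, diag(4), tolerance = 1e-12)
})

test_that("adam reduces a convex quadratic", {
  params <- list(w = c(5, -3))
  st <- sacmetry:::adam_state(params)
  for (i in 1:500) {
    g <- list(w = 2 * params$w)
    up <- sacmetry:::adam_step(params, g, st, lr = 0.05)
    params <- up$params; st <- up$state
  }
  expect_lt(sum(params$w^2), 1e-3)
})
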