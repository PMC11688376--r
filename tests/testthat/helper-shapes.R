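# shared fixtures: all generated in code, nothing on disk

# random simply connected blob (digitized perturbed ellipse)
random_blob <- function(seed, size = 80L) {
  set.seed(seed)
  a <- runif(1, 10, 30)
  b <- runif(1, 0.4, 1) * a
  p <- sac_params(a = a, b = b, angle = runif(1, 0, 180),
                  irregularity = runif(1, 0, 0.25), size = c(size, size))
  extract_largest_component(generate_sac(p, seed = seed)$mask)
}

pix_key <- function(m) paste(m[, 1], m[, 2])

# dense angle-sweep oracle for the minimum enclosing rectangle area
sweep_rect_area <- function(pts, step_deg = 0.01) {
  th <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  x <- pts[, 2]; y <- pts[, 1]
  u <- outer(x, cos(th)) + outer(y, sin(th))   # n x n_angles
  v <- -outer(x, sin(th)) + outer(y, cos(th))
  cmax <- function(m) do.call(pmax, asplit(m, 1))
  cmin <- function(m) do.call(pmin, asplit(m, 1))
  min((cmax(u) - cmin(u)) * (cmax(v) - cmin(v)))
}

# O(n^3) hull-vertex oracle: j and k are hull vertices iff every other point
# lies (weakly) on one side of the line through them
brute_hull_vertices <- function(pts) {
  n <- nrow(pts)
  x <- pts[, 2]; y <- pts[, 1]
  on_hull <- rep(FALSE, n)
  for (j in 1:(n - 1)) for (k in (j + 1):n) {
    cr <- (x[k] - x[j]) * (y - y[j]) - (y[k] - y[j]) * (x - x[j])
    if (all(cr <= 1e-9) || all(cr >= -1e-9)) on_hull[c(j, k)] <- TRUE
  }
  which(on_hull)
}

# tiny hand-built network exercising every op with few parameters
tiny_model <- function(seed = 42) {
  b <- sacmetry:::new_builder()
  b$nodes[["input"]] <- list(op = "input", inputs = character(0), ch = 3L)
  set.seed(seed)
  c1 <- sacmetry:::add_conv(b, "c1", "input", 4L, 3L, bias = TRUE)
  bn <- sacmetry:::add_bn(b, "b1", c1)
  r1 <- sacmetry:::add_relu(b, "r1", bn)
  mp <- sacmetry:::add_maxpool(b, "mp", r1)
  up <- sacmetry:::add_up2(b, "up", mp)
  cc <- sacmetry:::add_concat(b, "cat", c(up, r1))
  d1 <- sacmetry:::add_conv(b, "d1", cc, 3L, 1L, stride = 2L, bias = TRUE)
  u2 <- sacmetry:::add_up2(b, "u2", d1)
  gp <- sacmetry:::add_gap(b, "gp", u2)
  pc <- sacmetry:::add_conv(b, "pc", gp, 3L, 1L, bias = TRUE)
  bc <- sacmetry:::add_broadcast(b, "bc", pc, like = u2)
  ad <- sacmetry:::add_add(b, "ad", c(u2, bc))
  c2 <- sacmetry:::add_conv(b, "c2", ad, 2L, 1L, bias = TRUE)
  hp <- sacmetry:::add_head_prob(b, "prob", c2)
  nodes <- b$nodes
  nodes[["input"]] <- NULL
  structure(list(arch = "tiny", in_channels = 3L, out_channels = 2L,
                 nodes = nodes, params = b$params, buffers = b$buffers,
                 output = hp),
            class = "sac_model")
}

# small separable training set: rendered sac phantoms with their masks
smoke_training_set <- function(n, size = 64L, seed = 11) {
  set.seed(seed)
  imgs <- vector("list", n); msks <- vector("list", n)
  for (i in seq_len(n)) {
    a <- runif(1, size / 7, size / 3)
    b2 <- runif(1, 0.65, 1) * a
    p <- sac_params(a = a, b = b2, angle = runif(1, 0, 180),
                    spacing = 0.02, size = c(size, size))
    sac <- generate_sac(p, seed = seed * 100 + i)
    imgs[[i]] <- render_us_image(sac, noise_seed = seed * 200 + i)
    msks[[i]] <- sac$mask
  }
  list(images = imgs, masks = msks)
}
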