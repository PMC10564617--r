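make_grid_fixture <- function(H = 6, W = 6, p = 3, seed = 2) {
  ds <- make_lattice_dataset("st", H = H, W = W, s = 2, delta = 4, sigma = 1,
                             p = p, seed = seed)
  g <- map_to_grid(ds$coords)
  list(ds = ds, grid = rasterize(ds$pcs, g), nbr = neighbors(g))
}

test_that("inception blocks emit the documented channel counts", {
  fx <- make_grid_fixture()
  cfg <- network_config(p = 3, s = 4)
  out <- forward(fx$grid, cfg, seed = 1, details = TRUE)
  expect_equal(unname(out$shapes["block1"]), 256L)
  expect_equal(unname(out$shapes["block2"]), 128L)
  expect_equal(sum(cfg$block1), 256L)
  expect_equal(sum(cfg$block2), 128L)

  # response rows are probabilities over s domains for every occupied spot
  r <- out$resp
  expect_equal(dim(r), c(36L, 4L))
  expect_true(all(r > 0))
  expect_equal(rowSums(r), setNames(rep(1, 36), rownames(r)),
               tolerance = 1e-6)

  # channel mismatch is fatal with both shapes named
  expect_error(forward(fx$grid, network_config(p = 5, s = 4)),
               "p = 5.*p = 3")
})

test_that("losses match closed forms and combine convexly", {
  # all spots scribbled: similarity term vanishes
  r <- random_response(4, 4)
  lab <- max.col(r, ties.method = "first")
  expect_equal(loss_sim(r, lab, u = rep(1, 4)), 0)

  # uniform response, one unscribbled spot: -ln(1/4)
  ru <- matrix(0.25, 1, 4, dimnames = list("s01", NULL))
  expect_equal(loss_sim(ru, labels = 2L, u = 0L), -log(0.25),
               tolerance = 1e-6)
  expect_equal(loss_sim(ru, labels = 2L, u = 0L), 1.3863, tolerance = 1e-4)

  # argmax adherence: r = (0.3, 0.7), c = 2
  r2 <- matrix(c(0.3, 0.7), 1, 2, dimnames = list("s01", NULL))
  expect_equal(loss_sim(r2, labels = 2L, u = 0L), 0.35667, tolerance = 1e-4)

  # scribble loss closed forms
  empty <- scribble_set(c(s01 = NA_integer_), s = 2)
  expect_equal(loss_scr(r2, empty), 0)
  one <- scribble_set(c(s01 = 1L), s = 2)
  r3 <- matrix(c(0.8, 0.2), 1, 2, dimnames = list("s01", NULL))
  expect_equal(loss_scr(r3, one), 0.22314, tolerance = 1e-4)
  r4 <- matrix(c(1 - 1e-12, 1e-12), 1, 2, dimnames = list("s01", NULL))
  expect_equal(loss_scr(r4, one), 0, tolerance = 1e-9)

  # alpha mixing
  expect_equal(total_loss(1, 0.35667, 0.22314), 0.35667)
  expect_equal(total_loss(0, 0.35667, 0.22314), 0.22314)
  expect_equal(total_loss(0.5, 0.35667, 0.22314), 0.28991, tolerance = 1e-4)

  # probability contract
  rneg <- matrix(c(0, 1), 1, 2, dimnames = list("s01", NULL))
  expect_error(loss_sim(rneg, 2L, 0L), "positive")
  expect_error(loss_scr(rneg, one), "positive")
})

test_that("backpropagation matches finite differences", {
  set.seed(42)
  H <- 5; W <- 4; p <- 3; s <- 2; N <- H * W
  cfg <- network_config(p, s, block1 = c(5, 4, 3, 2), block2 = c(4, 3, 2, 2))
  params <- init_network(cfg, seed = 9)
  X <- matrix(rnorm(N * p), N, p)
  idx3 <- scribseg:::conv_index(H, W, 3L)
  idx5 <- scribseg:::conv_index(H, W, 5L)
  target <- sample(s, N, replace = TRUE)
  lossf <- function(pars) {
    out <- scribseg:::net_forward(pars, X, idx3, idx5)
    r <- scribseg:::row_softmax(out$logits)
    -sum(log(r[cbind(1:N, target)]))
  }
  out <- scribseg:::net_forward(params, X, idx3, idx5)
  r <- scribseg:::row_softmax(out$logits)
  dZ <- r
  dZ[cbind(1:N, target)] <- dZ[cbind(1:N, target)] - 1
  grads <- scribseg:::net_backward(dZ, params, out$caches)

  eps <- 1e-6
  paths <- list(c("conv0", "W"), c("bn0", "g"), c("inc1", "p2", "W"),
                c("inc1", "p3", "W"), c("inc1", "p4", "W"), c("bn1", "b"),
                c("inc2", "p2", "W"), c("inc2", "p4", "W"),
                c("convf", "W"), c("bnf", "g"))
  for (pa in paths) {
    g <- grads
    for (nm in pa) g <- g[[nm]]
    for (i in seq_len(min(3, length(g)))) {
      pp <- params
      v <- pp[[pa]]; v[i] <- v[i] + eps; pp[[pa]] <- v
      lp <- lossf(pp)
      v[i] <- v[i] - 2 * eps; pp[[pa]] <- v
      lm <- lossf(pp)
      num <- (lp - lm) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-4,
                   label = paste(paste(pa, collapse = "$"), i))
    }
  }
})

test_that("training is deterministic, descends, and ignores background cells", {
  fx <- make_grid_fixture(H = 8, W = 8, p = 3, seed = 12)
  scr <- make_scribbles(fx$ds, 0.25, seed = 5)
  cfg <- train_config(alpha = 0.5, max_iters = 40, seed = 21)

  fit1 <- train_model(fx$grid, scr, cfg)
  fit2 <- train_model(fx$grid, scr, cfg)
  expect_identical(fit1$labels, fit2$labels)
  expect_identical(fit1$loss_trace, fit2$loss_trace)

  # smoothed descent
  tr <- fit1$loss_trace
  expect_lt(mean(tail(tr, 5)), mean(head(tr, 5)))

  # response rows normalised at the optimum
  expect_equal(unname(rowSums(fit1$resp)), rep(1, nrow(fit1$resp)),
               tolerance = 1e-6)

  # scribble-free (fully unsupervised) mode runs: u == 0 everywhere
  none <- scribble_set(setNames(rep(NA_integer_, nrow(fx$ds$pcs)),
                                rownames(fx$ds$pcs)), s = 2)
  fit_u <- train_model(fx$grid, none, train_config(max_iters = 5, seed = 3))
  expect_length(fit_u$labels, 64L)

  # perturbing background cells leaves the fit unchanged
  holes <- fx$ds
  keep <- rownames(holes$pcs)[-(1:10)]
  co <- holes$coords[holes$coords$spot_id %in% keep, ]
  attr(co, "platform") <- "st"
  pcs <- holes$pcs[keep, ]
  class(pcs) <- c("pc_matrix", class(pcs))
  grid_h <- rasterize(pcs, map_to_grid(co))
  expect_gt(sum(!grid_h$mask), 0)
  scr_h <- scribble_set(scr$labels[keep], s = 2)
  f_a <- train_model(grid_h, scr_h, train_config(max_iters = 8, seed = 2))
  grid_h2 <- grid_h
  mat <- matrix(grid_h2$data, grid_h2$H * grid_h2$W, grid_h2$p)
  mat[!as.vector(grid_h2$mask), ] <- 99   # garbage in background cells
  grid_h2$data <- array(mat, dim(grid_h2$data))
  f_b <- train_model(grid_h2, scr_h, train_config(max_iters = 8, seed = 2))
  expect_identical(f_a$labels, f_b$labels)
  expect_equal(f_a$loss_trace, f_b$loss_trace)
})
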