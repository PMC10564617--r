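pcm <- function(x, ids = sprintf("s%02d", seq_len(nrow(x)))) {
  rownames(x) <- ids
  class(x) <- c("pc_matrix", class(x))
  x
}

test_that("cluster statistics follow the stated conventions", {
  pcs <- pcm(rbind(c(0, 0), c(2, 0)))
  lab <- setNames(c(1L, 1L), rownames(pcs))
  st <- cluster_stats(pcs, lab, s = 1)
  expect_equal(st[["1"]]$mean, c(pc1 = 1, pc2 = 0), ignore_attr = TRUE)
  expect_equal(sum(diag(st[["1"]]$sigma)), 2 + 2e-6, tolerance = 1e-12)
  expect_equal(st[["1"]]$trace, 2)                  # unridged trace

  # identical points: ridge only
  same <- pcm(matrix(1, 4, 3))
  st2 <- cluster_stats(same, setNames(rep(1L, 4), rownames(same)), s = 1)
  expect_equal(sum(diag(st2[["1"]]$sigma)), 3e-6, tolerance = 1e-18)
  expect_equal(st2[["1"]]$trace, 0)

  # permutation invariance
  set.seed(3)
  pcs3 <- pcm(matrix(rnorm(30), 10, 3))
  lab3 <- setNames(rep(1:2, 5), rownames(pcs3))
  perm <- sample(10)
  st_a <- cluster_stats(pcs3, lab3, s = 2)
  st_b <- cluster_stats(pcs3, lab3[perm], s = 2)
  expect_equal(st_a[["1"]]$mean, st_b[["1"]]$mean)
  expect_equal(st_a[["2"]]$sigma, st_b[["2"]]$sigma)

  # empty cluster flagged
  st4 <- cluster_stats(pcs3, lab3, s = 3)
  expect_equal(attr(st4, "empty"), 3L)
})

test_that("expression likelihood matches the Gaussian closed form and ranks assignments", {
  # standard normal at its mean: log density = -0.5 log(2 pi)
  stats1 <- structure(list(`1` = list(mean = 0, sigma = matrix(1, 1, 1),
                                      trace = 1, n = 2)),
                      class = "cluster_stats")
  y0 <- pcm(matrix(0, 1, 1), "s01")
  l0 <- log_expression_likelihood(y0, setNames(1L, "s01"), stats1)
  expect_equal(l0, -0.5 * log(2 * pi), tolerance = 1e-9)
  expect_equal(l0, -0.91894, tolerance = 1e-5)

  # moving a point off the mean strictly decreases the likelihood
  y1 <- pcm(matrix(2, 1, 1), "s01")
  expect_lt(log_expression_likelihood(y1, setNames(1L, "s01"), stats1), l0)

  # correct assignment of separated blobs beats the swapped one
  set.seed(11)
  pcs <- pcm(rbind(matrix(rnorm(40, 0), 20, 2),
                   matrix(rnorm(40, 8), 20, 2)))
  truth <- setNames(rep(1:2, each = 20), rownames(pcs))
  swapped <- setNames(rep(2:1, each = 20), rownames(pcs))
  st <- cluster_stats(pcs, truth, s = 2)
  expect_gt(log_expression_likelihood(pcs, truth, st),
            log_expression_likelihood(pcs, swapped, st))
})

test_that("Potts prior matches direct evaluation and normalises", {
  # visium spot, all 6 neighbours agree, gamma = 3, s = 7
  gv <- map_to_grid(full_visium_coords(3, 3))
  nv <- neighbors(gv)
  centre <- gv$spot_id[gv$grid_row == 1 &
                         gv$grid_col == min(gv$grid_col) + 1]
  labv <- setNames(rep(1L, nrow(gv)), gv$spot_id)
  pv <- potts_log_prior(labv, nv, gamma = 3, s = 7)
  expect_equal(unname(pv$probs[centre, 1]), exp(6) / (exp(6) + 6),
               tolerance = 1e-9)
  expect_equal(unname(pv$probs[centre, 1]), 0.98535, tolerance = 1e-5)

  # st spot with neighbours split 2/2, gamma = 2, s = 3, label 1
  co <- full_st_coords(3, 3)
  g <- map_to_grid(co)
  nb <- neighbors(g)
  m <- matrix(3L, 3, 3)
  m[1, 2] <- 1L; m[3, 2] <- 1L     # north and south of centre -> label 1
  m[2, 1] <- 2L; m[2, 3] <- 2L     # west and east -> label 2
  m[2, 2] <- 1L
  lab <- lattice_labels(m, co)
  ps <- potts_log_prior(lab, nb, gamma = 2, s = 3)
  cen <- co$spot_id[co$row == 1 & co$col == 1]
  expect_equal(unname(ps$probs[cen, 1]), exp(2) / (2 * exp(2) + 1),
               tolerance = 1e-9)
  expect_equal(unname(ps$probs[cen, 1]), 0.46831, tolerance = 1e-5)

  # rows sum to one
  expect_equal(unname(rowSums(ps$probs)), rep(1, 9), tolerance = 1e-12)

  # gamma = 0: uniform
  p0 <- potts_log_prior(lab, nb, gamma = 0, s = 3)
  expect_true(all(abs(p0$probs - 1 / 3) < 1e-12))
  expect_equal(p0$log_prior, 9 * log(1 / 3), tolerance = 1e-12)

  # isolated spot gets the uniform prior
  iso <- neighbors(map_to_grid(spot_coords(
    data.frame(spot_id = "solo", row = 0, col = 0), "st")))
  pi_ <- potts_log_prior(setNames(2L, "solo"), iso, gamma = 2, s = 4)
  expect_equal(unname(pi_$probs["solo", ]), rep(0.25, 4))
})

test_that("Potts prior equals brute force on every 2-labelling of a 3x3 lattice", {
  co <- full_st_coords(3, 3)
  g <- map_to_grid(co)
  nb <- neighbors(g)
  ids <- g$spot_id
  pos <- setNames(lapply(seq_len(9), function(i) c(g$grid_row[i],
                                                   g$grid_col[i])), ids)
  # independent brute-force evaluation, written against the formula directly
  brute <- function(lab, gamma, s) {
    total <- 0
    for (id in ids) {
      nbi <- nb[[id]]
      if (length(nbi) == 0) { total <- total + log(1 / s); next }
      weights <- vapply(1:s, function(k)
        exp(2 * gamma / length(nbi) * sum(lab[nbi] == k)), numeric(1))
      total <- total + log(weights[lab[[id]]] / sum(weights))
    }
    total
  }
  for (code in 0:511) {
    lab <- setNames(as.integer(intToBits(code)[1:9]) + 1L, ids)
    expect_equal(potts_log_prior(lab, nb, gamma = 2, s = 2)$log_prior,
                 brute(lab, 2, 2), tolerance = 1e-12)
  }
})

test_that("variance penalty is exact and merging clusters never increases q", {
  # arithmetic: traces (0.01, 0.02), lambda = 100 -> q = e^-3
  st <- structure(list(`1` = list(trace = 0.01), `2` = list(trace = 0.02)),
                  class = "cluster_stats")
  expect_equal(quasi_likelihood(st, 100), -3)
  expect_equal(exp(quasi_likelihood(st, 100)), 0.049787, tolerance = 1e-5)

  # zero within-cluster variance: log q = 0
  same <- pcm(rbind(matrix(0, 5, 2), matrix(5, 5, 2)))
  lab <- setNames(rep(1:2, each = 5), rownames(same))
  expect_equal(quasi_likelihood(cluster_stats(same, lab, s = 2)), 0)

  # law of total variance: merging separated clusters inflates the trace
  set.seed(21)
  for (i in 1:20) {
    pcs <- pcm(rbind(matrix(rnorm(30, 0), 15, 2),
                     matrix(rnorm(30, 4 + runif(1, 0, 4)), 15, 2)))
    split_lab <- setNames(rep(1:2, each = 15), rownames(pcs))
    merged <- setNames(rep(1L, 30), rownames(pcs))
    expect_lte(quasi_likelihood(cluster_stats(pcs, merged, s = 1)),
               quasi_likelihood(cluster_stats(pcs, split_lab, s = 2)))
  }
})

test_that("goodness decomposes additively and is label-permutation invariant", {
  fx_ds <- make_lattice_dataset("st", H = 8, W = 8, s = 3, delta = 4,
                                sigma = 1, p = 3, seed = 9)
  g <- map_to_grid(fx_ds$coords)
  nbr <- neighbors(g)
  gd <- goodness(fx_ds$pcs, fx_ds$truth, nbr, gamma = 2, lambda = 100, s = 3)
  expect_equal(gd$log_v, gd$log_expr + gd$log_potts + gd$log_q)
  expect_lte(gd$log_q, 0)
  expect_lte(gd$log_potts, 0)

  # permuting cluster ids leaves the score unchanged
  perm <- c(2L, 3L, 1L)
  gd2 <- goodness(fx_ds$pcs, setNames(perm[fx_ds$truth], names(fx_ds$truth)),
                  nbr, gamma = 2, lambda = 100, s = 3)
  expect_equal(gd2$log_v, gd$log_v, tolerance = 1e-9)

  # larger lambda weakly decreases log_v when variance is nonzero
  gd_hi <- goodness(fx_ds$pcs, fx_ds$truth, nbr, gamma = 2, lambda = 200,
                    s = 3)
  expect_lte(gd_hi$log_v, gd$log_v)
})

test_that("degenerate single-point grid search returns its only run as best", {
  ds <- make_lattice_dataset("st", H = 6, W = 6, s = 2, delta = 5, sigma = 1,
                             p = 3, seed = 14)
  g <- map_to_grid(ds$coords)
  grid <- rasterize(ds$pcs, g)
  nbr <- neighbors(g)
  scr <- make_scribbles(ds, 0.3, seed = 2)
  res <- grid_search(grid, ds$pcs, nbr, scr,
                     search = search_config(alpha_grid = 0.5, gamma = 2),
                     mode = "scribble",
                     train_cfg = train_config(max_iters = 5, seed = 8))
  expect_equal(nrow(res$table), 1L)
  expect_equal(res$best_alpha, 0.5)
  expect_equal(res$best_beta, 0)
  expect_length(res$best_labels, 36L)
})
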