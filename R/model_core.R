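#' Network configuration
#'
#' The segmentation network is: 1x1 conv (p -> p), ReLU, batch norm, a first
#' Inception block, ReLU, batch norm, a second Inception block, ReLU, batch
#' norm, a 1x1 conv to `s` channels, batch norm, and a channel-wise softmax
#' yielding the per-spot response map. Each Inception block runs four
#' parallel paths — 1x1 conv, 3x3 conv, 5x5 conv, and 3x3 max-pool followed
#' by a 1x1 conv — whose outputs are concatenated. Default path widths are
#' (160, 64, 16, 16) for block 1 (256 features) and (96, 16, 8, 8) for
#' block 2 (128 features).
#'
#' @param p Input channels (number of principal components).
#' @param s Output channels (number of spatial domains), `s >= 2`.
#' @param block1,block2 Integer path widths (1x1, 3x3, 5x5, pool path).
#' @return A `network_config`.
#' @export
network_config <- function(p, s,
                           block1 = c(160L, 64L, 16L, 16L),
                           block2 = c(96L, 16L, 8L, 8L)) {
  stopifnot(p >= 1, s >= 2, length(block1) == 4L, length(block2) == 4L,
            all(block1 >= 1), all(block2 >= 1))
  structure(list(p = as.integer(p), s = as.integer(s),
                 block1 = as.integer(block1), block2 = as.integer(block2)),
            class = "network_config")
}

init_inception <- function(c_in, widths) {
  list(p1 = init_conv(c_in, widths[1L], 1L),
       p2 = init_conv(c_in, widths[2L], 3L),
       p3 = init_conv(c_in, widths[3L], 5L),
       p4 = init_conv(c_in, widths[4L], 1L))
}

#' Initialise network parameters
#'
#' Fan-in uniform initialisation of every convolution, drawn from the seeded
#' RNG so two initialisations with the same seed are identical.
#'
#' @param cfg A [network_config()].
#' @param seed Integer seed.
#' @return Parameter list (opaque; pass to [forward()] / [train_model()]).
#' @export
init_network <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "network_config"))
  set.seed(seed)
  c1 <- sum(cfg$block1); c2 <- sum(cfg$block2)
  params <- list(
    conv0 = init_conv(cfg$p, cfg$p, 1L),
    bn0   = init_bn(cfg$p),
    inc1  = init_inception(cfg$p, cfg$block1),
    bn1   = init_bn(c1),
    inc2  = init_inception(c1, cfg$block2),
    bn2   = init_bn(c2),
    convf = init_conv(c2, cfg$s, 1L),
    bnf   = init_bn(cfg$s))
  attr(params, "cfg") <- cfg
  params
}

inception_forward <- function(X, inc, idx3, idx5) {
  f1 <- conv_forward(X, inc$p1, NULL)
  f2 <- conv_forward(X, inc$p2, idx3)
  f3 <- conv_forward(X, inc$p3, idx5)
  pl <- maxpool_forward(X, idx3)
  f4 <- conv_forward(pl$Y, inc$p4, NULL)
  list(Y = cbind(f1$Y, f2$Y, f3$Y, f4$Y),
       cache = list(f1 = f1$cache, f2 = f2$cache, f3 = f3$cache,
                    pool = pl$cache, f4 = f4$cache,
                    widths = c(ncol(f1$Y), ncol(f2$Y), ncol(f3$Y), ncol(f4$Y))))
}

inception_backward <- function(dY, inc, cache) {
  w <- cache$widths
  ends <- cumsum(w); starts <- ends - w + 1L
  b1 <- conv_backward(dY[, starts[1L]:ends[1L], drop = FALSE], inc$p1, cache$f1)
  b2 <- conv_backward(dY[, starts[2L]:ends[2L], drop = FALSE], inc$p2, cache$f2)
  b3 <- conv_backward(dY[, starts[3L]:ends[3L], drop = FALSE], inc$p3, cache$f3)
  b4 <- conv_backward(dY[, starts[4L]:ends[4L], drop = FALSE], inc$p4, cache$f4)
  dpool <- maxpool_backward(b4$dX, cache$pool)
  list(dX = b1$dX + b2$dX + b3$dX + dpool,
       grad = list(p1 = b1$grad, p2 = b2$grad, p3 = b3$grad, p4 = b4$grad))
}

net_forward <- function(params, X, idx3, idx5) {
  cv0 <- conv_forward(X, params$conv0, NULL)
  r0  <- relu_forward(cv0$Y)
  n0  <- bn_forward(r0$Y, params$bn0)
  i1  <- inception_forward(n0$Y, params$inc1, idx3, idx5)
  r1  <- relu_forward(i1$Y)
  n1  <- bn_forward(r1$Y, params$bn1)
  i2  <- inception_forward(n1$Y, params$inc2, idx3, idx5)
  r2  <- relu_forward(i2$Y)
  n2  <- bn_forward(r2$Y, params$bn2)
  cvf <- conv_forward(n2$Y, params$convf, NULL)
  nf  <- bn_forward(cvf$Y, params$bnf)
  list(logits = nf$Y,
       shapes = c(block1 = ncol(i1$Y), block2 = ncol(i2$Y)),
       caches = list(cv0 = cv0$cache, r0 = r0$cache, n0 = n0$cache,
                     i1 = i1$cache, r1 = r1$cache, n1 = n1$cache,
                     i2 = i2$cache, r2 = r2$cache, n2 = n2$cache,
                     cvf = cvf$cache, nf = nf$cache))
}

net_backward <- function(dZ, params, caches) {
  g <- list()
  bnf <- bn_backward(dZ, params$bnf, caches$nf);            g$bnf <- bnf$grad
  cvf <- conv_backward(bnf$dX, params$convf, caches$cvf);   g$convf <- cvf$grad
  n2  <- bn_backward(cvf$dX, params$bn2, caches$n2);        g$bn2 <- n2$grad
  r2  <- relu_backward(n2$dX, caches$r2)
  i2  <- inception_backward(r2, params$inc2, caches$i2);    g$inc2 <- i2$grad
  n1  <- bn_backward(i2$dX, params$bn1, caches$n1);         g$bn1 <- n1$grad
  r1  <- relu_backward(n1$dX, caches$r1)
  i1  <- inception_backward(r1, params$inc1, caches$i1);    g$inc1 <- i1$grad
  n0  <- bn_backward(i1$dX, params$bn0, caches$n0);         g$bn0 <- n0$grad
  r0  <- relu_backward(n0$dX, caches$r0)
  cv0 <- conv_backward(r0, params$conv0, caches$cv0);       g$conv0 <- cv0$grad
  g
}

grid_input_matrix <- function(grid) {
  X <- matrix(grid$data, grid$H * grid$W, grid$p)
  X[!as.vector(grid$mask), ] <- 0      # background values never reach the net
  X
}

#' Forward pass: response map for every occupied spot
#'
#' Runs the network on a grid tensor and returns, for each occupied spot,
#' the s-dimensional probability vector (channel-wise softmax of the final
#' batch-normalised activations). Rows sum to 1.
#'
#' @param grid A `grid_tensor`.
#' @param cfg A [network_config()]; `cfg$p` must equal `grid$p`.
#' @param params Parameters from [init_network()] (freshly initialised with
#'   `seed` if omitted).
#' @param seed Seed used when `params` is missing.
#' @param details If `TRUE`, also return the Inception block channel counts.
#' @return Matrix n x s of probabilities with spot-id rownames (sorted), or
#'   a list `(resp, shapes)` when `details = TRUE`.
#' @export
forward <- function(grid, cfg, params = NULL, seed = 1L, details = FALSE) {
  stopifnot(inherits(grid, "grid_tensor"), inherits(cfg, "network_config"))
  if (cfg$p != grid$p)
    stop("channel mismatch: network expects p = ", cfg$p,
         " but grid tensor has p = ", grid$p)
  if (is.null(params)) params <- init_network(cfg, seed)
  idx3 <- conv_index(grid$H, grid$W, 3L)
  idx5 <- conv_index(grid$H, grid$W, 5L)
  out <- net_forward(params, grid_input_matrix(grid), idx3, idx5)
  resp <- row_softmax(out$logits)[grid$spot_index$pos, , drop = FALSE]
  rownames(resp) <- grid$spot_index$spot_id
  colnames(resp) <- paste0("domain", seq_len(cfg$s))
  if (details) list(resp = resp, shapes = out$shapes) else resp
}

#' Feature-similarity loss (self-training cross-entropy)
#'
#' Sum over unscribbled spots of `-ln r[i, c_i]`, where `c_i` is the spot's
#' current argmax label. Scribbled spots (`u_i = 1`) contribute nothing.
#'
#' @param resp n x s response matrix, rows on the simplex.
#' @param labels Integer argmax labels `c_i`, length n.
#' @param u 0/1 scribble indicators, length n.
#' @return Non-negative scalar.
#' @export
loss_sim <- function(resp, labels, u) {
  stopifnot(nrow(resp) == length(labels), length(labels) == length(u))
  if (any(resp <= 0)) stop("response entries must be strictly positive")
  i <- which(u == 0)
  if (length(i) == 0L) return(0)
  -sum(log(resp[cbind(i, labels[i])]))
}

#' Scribble-adherence loss
#'
#' Sum over scribbled spots of `-ln r[i, w_i]`, `w_i` being the scribble
#' label. Minimising it pushes predicted labels to match the scribbles.
#'
#' @param resp n x s response matrix with spot-id rownames.
#' @param scr A `scribble_set` covering the same spots.
#' @return Non-negative scalar.
#' @export
loss_scr <- function(resp, scr) {
  stopifnot(inherits(scr, "scribble_set"), !is.null(rownames(resp)))
  if (any(resp <= 0)) stop("response entries must be strictly positive")
  w <- scr$labels[rownames(resp)]
  i <- which(!is.na(w))
  if (length(i) == 0L) return(0)
  -sum(log(resp[cbind(i, w[i])]))
}

#' Combined training objective
#'
#' Convex combination `alpha * L_sim + (1 - alpha) * L_scr`.
#'
#' @param alpha Mixing weight in `[0, 1]`.
#' @param lsim,lscr The two loss components.
#' @return Scalar.
#' @export
total_loss <- function(alpha, lsim, lscr) {
  stopifnot(alpha >= 0, alpha <= 1)
  alpha * lsim + (1 - alpha) * lscr
}

#' Training configuration
#'
#' @param alpha Similarity/scribble mixing weight in `[0, 1]`.
#' @param beta Scribble dropout rate in `[0, 1)`; 0 disables dropout
#'   (default for expert scribbles).
#' @param max_iters Gradient iterations.
#' @param learning_rate,momentum SGD-with-momentum settings.
#' @param seed Master seed for initialisation and dropout.
#' @return A `train_config`.
#' @export
train_config <- function(alpha = 0.5, beta = 0, max_iters = 300L,
                         learning_rate = 0.1, momentum = 0.9, seed = 1L) {
  stopifnot(alpha >= 0, alpha <= 1, beta >= 0, beta < 1, max_iters >= 1)
  structure(list(alpha = alpha, beta = beta, max_iters = as.integer(max_iters),
                 learning_rate = learning_rate, momentum = momentum,
                 seed = as.integer(seed)),
            class = "train_config")
}

sgd_step <- function(params, grads, vel, lr, mom) {
  walk <- function(p, g, v) {
    if (is.list(p)) {
      for (nm in names(g)) {
        res <- walk(p[[nm]], g[[nm]], v[[nm]])
        p[[nm]] <- res$p; v[[nm]] <- res$v
      }
      return(list(p = p, v = v))
    }
    v <- mom * v - lr * g
    list(p = p + v, v = v)
  }
  res <- walk(params, grads, vel)
  attr(res$p, "cfg") <- attr(params, "cfg")
  res
}

#' Train the segmentation network
#'
#' Iterates: (optional scribble dropout at rate `beta`) -> forward pass ->
#' argmax labels -> alpha-weighted cross-entropy loss -> SGD-with-momentum
#' step. The self-training targets `c_i` are recomputed from the current
#' response each iteration and treated as constants in the gradient. The
#' recorded loss trace is the printed sum over spots; the gradient step uses
#' the per-spot mean so the default learning rate is size-independent.
#'
#' @param grid A `grid_tensor`.
#' @param scr A `scribble_set` over the same spots (all-`NA` labels give the
#'   fully unsupervised mode).
#' @param cfg A [train_config()].
#' @param net_cfg A [network_config()]; defaults to the standard widths with
#'   `p = grid$p`, `s = scr$s`.
#' @return A `domain_fit`: `labels` (named, sorted by spot id), `resp`,
#'   `loss_trace`, `params`, `config`.
#' @export
train_model <- function(grid, scr, cfg = train_config(),
                        net_cfg = network_config(grid$p, scr$s)) {
  stopifnot(inherits(grid, "grid_tensor"), inherits(scr, "scribble_set"),
            inherits(cfg, "train_config"))
  if (net_cfg$p != grid$p)
    stop("channel mismatch: network expects p = ", net_cfg$p,
         " but grid tensor has p = ", grid$p)
  ids <- grid$spot_index$spot_id
  if (!all(ids %in% names(scr$labels)))
    stop("scribble set does not cover all occupied spots")

  set.seed(cfg$seed)
  params <- init_network(net_cfg, seed = cfg$seed)
  vel <- rapply(params, function(x) x * 0, how = "replace")
  idx3 <- conv_index(grid$H, grid$W, 3L)
  idx5 <- conv_index(grid$H, grid$W, 5L)
  X <- grid_input_matrix(grid)
  pos <- grid$spot_index$pos
  n_sp <- length(pos)
  s <- net_cfg$s
  w_full <- scr$labels[ids]
  trace <- numeric(cfg$max_iters)

  for (it in seq_len(cfg$max_iters)) {
    w_it <- if (cfg$beta > 0) scribble_dropout(scr, cfg$beta)$labels[ids]
            else w_full
    out <- net_forward(params, X, idx3, idx5)
    r_all <- row_softmax(out$logits)
    r <- r_all[pos, , drop = FALSE]
    lab <- max.col(r, ties.method = "first")
    u <- as.integer(!is.na(w_it))
    target <- ifelse(u == 1L, w_it, lab)
    weight <- ifelse(u == 1L, 1 - cfg$alpha, cfg$alpha)

    lsim <- -sum(log(r[cbind(which(u == 0L), lab[u == 0L])]))
    lscr <- if (any(u == 1L))
      -sum(log(r[cbind(which(u == 1L), w_it[u == 1L])])) else 0
    loss <- total_loss(cfg$alpha, lsim, lscr)
    if (!is.finite(loss))
      stop("non-finite loss at iteration ", it)
    trace[it] <- loss

    dZ <- matrix(0, nrow(out$logits), s)
    dR <- r
    dR[cbind(seq_len(n_sp), target)] <- dR[cbind(seq_len(n_sp), target)] - 1
    dZ[pos, ] <- dR * (weight / n_sp)
    grads <- net_backward(dZ, params, out$caches)
    step <- sgd_step(params, grads, vel, cfg$learning_rate, cfg$momentum)
    params <- step$p; vel <- step$v
  }

  out <- net_forward(params, X, idx3, idx5)
  r <- row_softmax(out$logits)[pos, , drop = FALSE]
  labels <- max.col(r, ties.method = "first")
  names(labels) <- ids
  rownames(r) <- ids
  colnames(r) <- paste0("domain", seq_len(s))
  structure(list(labels = labels, resp = r, loss_trace = trace,
                 params = params, config = cfg, net_cfg = net_cfg),
            class = "domain_fit")
}

#' @export
print.domain_fit <- function(x, ...) {
  cat("domain_fit:", length(x$labels), "spots,",
      x$net_cfg$s, "domains; alpha =", x$config$alpha,
      "beta =", x$config$beta, "\n")
  cat("  final loss:", utils::tail(x$loss_trace, 1L),
      "after", length(x$loss_trace), "iterations\n")
  invisible(x)
}
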