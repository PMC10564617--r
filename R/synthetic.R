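#' Synthetic lattice dataset with planted spatial domains
#'
#' Generates an H x W spot lattice (square for ST; hexagonal array
#' coordinates for Visium, sheared back to H x W by [map_to_grid()]) with
#' `s` planted contiguous domains. Domain mean PC vectors are drawn once and
#' rescaled so the nearest pair sits at distance `delta`; each spot's PC
#' vector is its domain mean plus isotropic Gaussian noise of s.d. `sigma`,
#' so `delta / sigma` controls separability. Layouts: `"bands"` slices the
#' rows into `s` contiguous strips (cortical-layer-like); `"blobs"` plants
#' `s - 1` discs in a background domain (tumour-focus-like). With
#' `mode = "counts"` the PCs are additionally pushed through a log-linear
#' Poisson model to integer gene counts, for exercising the preprocessing
#' path.
#'
#' @param platform `"st"` or `"visium"`.
#' @param H,W Lattice height and width (grid cells).
#' @param s Number of domains, `H * W >= s`.
#' @param layout `"bands"` or `"blobs"`.
#' @param delta Nearest-pair distance between domain means (> 0).
#' @param sigma Per-dimension noise s.d. (> 0).
#' @param p Number of PC dimensions.
#' @param seed Integer seed; regeneration is bit-identical.
#' @param mode `"pc"` (default; direct PC matrix) or `"counts"`.
#' @param n_genes Number of genes in count mode.
#' @return A `synthetic_dataset`: `pcs` (pc_matrix), `coords`
#'   (`spot_coords`), `truth` (named labels, sorted by spot id), `platform`,
#'   `params`, and in count mode `counts` (a `count_matrix`).
#' @export
make_lattice_dataset <- function(platform = c("st", "visium"),
                                 H = 24L, W = 24L, s = 3L,
                                 layout = c("bands", "blobs"),
                                 delta = 4, sigma = 1, p = 5L, seed = 1L,
                                 mode = c("pc", "counts"),
                                 n_genes = 100L) {
  platform <- match.arg(platform)
  layout <- match.arg(layout)
  mode <- match.arg(mode)
  stopifnot(H * W >= s, delta > 0, sigma > 0, p >= 1)
  set.seed(seed)

  gi <- rep(0:(H - 1L), times = W)          # grid rows
  gj <- rep(0:(W - 1L), each = H)           # grid cols
  if (platform == "visium") {
    # invert the shear: array (row, col) with row + col even
    row <- gi
    col <- 2L * gj - gi + 2L * H            # offset keeps cols positive
  } else {
    row <- gi; col <- gj
  }
  spot_id <- sprintf("s%03d_%03d", row, col)

  truth <- integer(H * W)
  if (layout == "bands") {
    truth <- as.integer(cut(gi, breaks = s, labels = FALSE))
  } else {
    truth[] <- 1L
    centers <- cbind(stats::runif(s - 1L, 0.2, 0.8) * (H - 1L),
                     stats::runif(s - 1L, 0.2, 0.8) * (W - 1L))
    radius <- 0.28 * min(H, W) / sqrt(s - 1L)
    for (k in seq_len(s - 1L)) {
      d2 <- (gi - centers[k, 1L])^2 + (gj - centers[k, 2L])^2
      truth[d2 <= radius^2] <- k + 1L
    }
  }

  # domain means scaled so the nearest pair is delta apart
  M <- matrix(stats::rnorm(s * p), s, p)
  dmin <- min(stats::dist(M))
  if (dmin == 0) stop("degenerate domain means; change seed")
  M <- M * (delta / dmin)
  pcs <- M[truth, , drop = FALSE] +
    matrix(stats::rnorm(H * W * p, sd = sigma), H * W, p)
  rownames(pcs) <- spot_id
  colnames(pcs) <- paste0("pc", seq_len(p))

  ord <- order(spot_id)
  spot_id <- spot_id[ord]
  truth <- stats::setNames(truth[ord], spot_id)
  coords <- spot_coords(
    data.frame(spot_id = spot_id, row = row[ord], col = col[ord],
               stringsAsFactors = FALSE),
    platform)

  ds <- list(pcs = structure(pcs[ord, , drop = FALSE],
                             class = c("pc_matrix", "matrix", "array")),
             coords = coords,
             truth = truth,
             platform = platform,
             params = list(H = H, W = W, s = s, layout = layout,
                           delta = delta, sigma = sigma, p = p, seed = seed,
                           mode = mode))
  if (mode == "counts") {
    L <- matrix(stats::rnorm(n_genes * p, sd = 1 / sqrt(p)), n_genes, p)
    eta <- 1.5 + unclass(ds$pcs) %*% t(L)
    lambda <- exp(pmin(eta, 8))
    counts <- matrix(stats::rpois(length(lambda), lambda),
                     nrow(lambda), ncol(lambda))
    dimnames(counts) <- list(rownames(ds$pcs),
                             sprintf("gene%04d", seq_len(n_genes)))
    ds$counts <- count_matrix(counts)
  }
  class(ds) <- "synthetic_dataset"
  ds
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  with(x$params, cat("synthetic_dataset:", H, "x", W, x$platform,
                     "lattice,", s, "domains (", layout, "), delta/sigma =",
                     delta / sigma, "\n"))
  invisible(x)
}

#' Stroke-like scribbles from planted truth
#'
#' Marks roughly `fraction` of each domain's spots with the true label by
#' running a random walk inside the domain (rook adjacency on the grid), so
#' scribbles are connected strokes rather than scattered spots. Every domain
#' receives at least one scribble.
#'
#' @param ds A `synthetic_dataset`.
#' @param fraction Target scribbled fraction per domain, `0 < fraction <= 1`.
#' @param seed Integer seed.
#' @return A `scribble_set` whose labels agree with `ds$truth`.
#' @export
make_scribbles <- function(ds, fraction, seed = 1L) {
  stopifnot(inherits(ds, "synthetic_dataset"), fraction > 0, fraction <= 1)
  set.seed(seed)
  gc <- map_to_grid(ds$coords)
  key <- paste(gc$grid_row, gc$grid_col)
  id_of <- stats::setNames(gc$spot_id, key)
  pos <- stats::setNames(lapply(seq_len(nrow(gc)), function(i)
    c(gc$grid_row[i], gc$grid_col[i])), gc$spot_id)
  lab <- rep(NA_integer_, nrow(gc))
  names(lab) <- gc$spot_id
  off <- cbind(c(1L, -1L, 0L, 0L), c(0L, 0L, 1L, -1L))

  for (dom in sort(unique(ds$truth))) {
    members <- names(ds$truth)[ds$truth == dom]
    target <- max(1L, round(fraction * length(members)))
    cur <- sample(members, 1L)
    marked <- cur
    guard <- 0L
    while (length(marked) < target && guard < 50L * target) {
      guard <- guard + 1L
      cand_keys <- paste(pos[[cur]][1L] + off[, 1L],
                         pos[[cur]][2L] + off[, 2L])
      cand <- id_of[cand_keys]
      cand <- cand[!is.na(cand)]
      cand <- cand[cand %in% members]
      if (length(cand) == 0L) {
        cur <- sample(members, 1L)        # stuck: restart the stroke
        next
      }
      cur <- if (length(cand) == 1L) cand else sample(cand, 1L)
      marked <- union(marked, cur)
    }
    lab[marked] <- dom
  }
  scr <- scribble_set(lab, ds$params$s)
  if (length(unique(scr$labels[!is.na(scr$labels)])) < ds$params$s)
    stop("fraction too small to cover every domain with a scribble")
  scr
}

#' Corrupt a labelling with independent label flips
#'
#' Each spot's label is replaced, with probability `flip_rate`, by a label
#' drawn uniformly from the other `s - 1` values. Emulates the mistakes a
#' non-spatial initial clustering makes.
#'
#' @param truth Named integer labels in `1..s`.
#' @param flip_rate Flip probability in `[0, 1)`.
#' @param s Number of labels (default `max(truth)`).
#' @param seed Integer seed.
#' @return Named integer labels, same names as `truth`.
#' @export
corrupt_labels <- function(truth, flip_rate, s = max(truth), seed = 1L) {
  stopifnot(flip_rate >= 0, flip_rate < 1)
  set.seed(seed)
  out <- truth
  flip <- stats::runif(length(truth)) < flip_rate
  if (any(flip)) {
    shift <- sample.int(s - 1L, sum(flip), replace = TRUE)
    out[flip] <- 1L + (truth[flip] - 1L + shift) %% s
  }
  out
}

#' Write a synthetic dataset in the dialects the readers consume
#'
#' Emits `coords.csv` (`spot_id,row,col`) plus either `counts.csv`
#' (spots x genes) or a 10x-style Matrix Market triplet under `mtx/`
#' (genes x spots `matrix.mtx`, `barcodes.tsv`, `features.tsv`), and
#' `truth.csv`. Count mode datasets only.
#'
#' @param ds A `synthetic_dataset` generated with `mode = "counts"`.
#' @param dir Output directory (created).
#' @param dialect `"csv"` or `"mtx10x"`.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir, dialect = c("csv", "mtx10x")) {
  dialect <- match.arg(dialect)
  if (is.null(ds$counts))
    stop("write_dataset needs a count-mode dataset (mode = 'counts')")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(spot_id = ds$coords$spot_id,
                              row = ds$coords$row, col = ds$coords$col),
                   file.path(dir, "coords.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(data.frame(spot_id = names(ds$truth),
                              label = as.integer(ds$truth)),
                   file.path(dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  cm <- ds$counts$counts
  if (dialect == "csv") {
    df <- data.frame(spot_id = rownames(cm), cm, check.names = FALSE)
    utils::write.csv(df, file.path(dir, "counts.csv"), row.names = FALSE,
                     quote = FALSE)
  } else {
    mdir <- file.path(dir, "mtx")
    dir.create(mdir, showWarnings = FALSE)
    Matrix::writeMM(Matrix::Matrix(t(cm), sparse = TRUE),
                    file.path(mdir, "matrix.mtx"))
    writeLines(rownames(cm), file.path(mdir, "barcodes.tsv"))
    writeLines(colnames(cm), file.path(mdir, "features.tsv"))
  }
  invisible(dir)
}
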