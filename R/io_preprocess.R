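#' Read a spot-by-gene count matrix and spot array coordinates
#'
#' Reads expression counts and array coordinates for a spatial transcriptomics
#' sample and intersects them on spot id. Two dialects are supported: a 10x
#' Matrix Market triplet (`matrix.mtx` genes x spots, `barcodes.tsv`,
#' `features.tsv`) and plain CSV (spots x genes with a header column of spot
#' ids). Coordinates come either from a Visium `tissue_positions` CSV
#' (`barcode,in_tissue,array_row,array_col,...`) or a generic
#' `spot_id,row,col` CSV.
#'
#' Spots present in both files are kept, ordered by spot id; spots lacking
#' coordinates are dropped with a warning. Zero overlap is an error.
#'
#' @param count_path For `dialect = "csv"`, a CSV file; for
#'   `dialect = "mtx10x"`, the directory holding the triplet.
#' @param coord_path Coordinate CSV.
#' @param dialect `"csv"` or `"mtx10x"`.
#' @param platform `"visium"` (hexagonal lattice, 6 neighbours) or `"st"`
#'   (square lattice, 4 neighbours).
#' @return A list with elements `counts` (a `count_matrix`) and `coords`
#'   (a `spot_coords` data frame).
#' @export
read_counts <- function(count_path, coord_path,
                        dialect = c("csv", "mtx10x"),
                        platform = c("visium", "st")) {
  dialect <- match.arg(dialect)
  platform <- match.arg(platform)
  if (!file.exists(count_path))
    stop("count file/directory not found: ", count_path)
  if (!file.exists(coord_path))
    stop("coordinate file not found: ", coord_path)

  if (dialect == "mtx10x") {
    mtx <- file.path(count_path, "matrix.mtx")
    bc  <- file.path(count_path, "barcodes.tsv")
    ft  <- file.path(count_path, "features.tsv")
    for (f in c(mtx, bc, ft))
      if (!file.exists(f)) stop("missing 10x triplet member: ", f)
    m <- tryCatch(Matrix::readMM(mtx),
                  error = function(e) stop("malformed Matrix Market file ",
                                           mtx, ": ", conditionMessage(e)))
    barcodes <- readLines(bc)
    features <- utils::read.delim(ft, header = FALSE,
                                  stringsAsFactors = FALSE)[[1]]
    if (nrow(m) != length(features) || ncol(m) != length(barcodes))
      stop("10x triplet dimension mismatch in ", count_path,
           ": matrix ", nrow(m), "x", ncol(m), ", ",
           length(features), " features, ", length(barcodes), " barcodes")
    counts <- t(as.matrix(m))            # spots x genes
    dimnames(counts) <- list(barcodes, features)
  } else {
    df <- tryCatch(
      utils::read.csv(count_path, check.names = FALSE,
                      stringsAsFactors = FALSE),
      error = function(e) stop("malformed CSV ", count_path, ": ",
                               conditionMessage(e)))
    counts <- as.matrix(df[, -1, drop = FALSE])
    rownames(counts) <- as.character(df[[1]])
    storage.mode(counts) <- "double"
  }
  cm <- count_matrix(counts)

  coords <- read_spot_coords(coord_path, platform)
  keep <- intersect(rownames(cm$counts), coords$spot_id)
  if (length(keep) == 0L)
    stop("no overlapping spots between ", count_path, " and ", coord_path)
  n_dropped <- nrow(cm$counts) - length(keep)
  if (n_dropped > 0L)
    warning(n_dropped, " spot(s) in the count matrix lack coordinates; dropped")
  keep <- sort(keep)
  cm$counts <- cm$counts[keep, , drop = FALSE]
  cm$spot_ids <- keep
  pl <- attr(coords, "platform")
  coords <- coords[match(keep, coords$spot_id), , drop = FALSE]
  rownames(coords) <- NULL
  attr(coords, "platform") <- pl      # data.frame subsetting drops it
  list(counts = cm, coords = coords)
}

#' Construct a validated count matrix
#'
#' @param counts Numeric spots x genes matrix with spot ids as rownames and
#'   gene ids as colnames; entries must be non-negative.
#' @return A `count_matrix` list: `counts`, `spot_ids`, `gene_ids`.
#' @export
count_matrix <- function(counts) {
  stopifnot(is.matrix(counts))
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix needs spot ids (rownames) and gene ids (colnames)")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate spot ids in count matrix")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate gene ids in count matrix")
  if (any(counts < 0)) stop("negative entries in count matrix")
  structure(list(counts = counts,
                 spot_ids = rownames(counts),
                 gene_ids = colnames(counts)),
            class = "count_matrix")
}

read_spot_coords <- function(coord_path, platform) {
  df <- tryCatch(
    utils::read.csv(coord_path, stringsAsFactors = FALSE),
    error = function(e) stop("malformed coordinate CSV ", coord_path, ": ",
                             conditionMessage(e)))
  nm <- tolower(names(df))
  if (all(c("barcode", "array_row", "array_col") %in% nm)) {
    # Visium tissue_positions dialect
    names(df) <- nm
    if ("in_tissue" %in% nm) df <- df[df$in_tissue == 1, , drop = FALSE]
    out <- data.frame(spot_id = as.character(df$barcode),
                      row = as.integer(df$array_row),
                      col = as.integer(df$array_col),
                      stringsAsFactors = FALSE)
  } else if (ncol(df) >= 3L) {
    out <- data.frame(spot_id = as.character(df[[1]]),
                      row = as.integer(df[[2]]),
                      col = as.integer(df[[3]]),
                      stringsAsFactors = FALSE)
  } else {
    stop("coordinate file ", coord_path,
         " must have columns spot_id,row,col or a tissue_positions header")
  }
  if (anyDuplicated(out$spot_id))
    stop("duplicate spot ids in ", coord_path)
  spot_coords(out, platform)
}

#' Construct validated spot coordinates
#'
#' @param df Data frame with columns `spot_id`, `row`, `col`.
#' @param platform `"visium"` or `"st"`. Visium array coordinates must satisfy
#'   the parity invariant `row + col` even (spaceranger convention).
#' @return A `spot_coords` data frame with a `platform` attribute.
#' @export
spot_coords <- function(df, platform = c("visium", "st")) {
  platform <- match.arg(platform)
  stopifnot(all(c("spot_id", "row", "col") %in% names(df)))
  if (platform == "visium") {
    bad <- (df$row + df$col) %% 2L != 0L
    if (any(bad))
      stop("visium parity violated (row+col odd) for spot(s): ",
           paste(utils::head(df$spot_id[bad], 5L), collapse = ", "))
  }
  attr(df, "platform") <- platform
  class(df) <- c("spot_coords", class(df))
  df
}

#' Library-size log-normalise a count matrix
#'
#' Scales each spot's counts to the median library size, then applies
#' `log1p`: entry (i, j) becomes `log1p(x_ij * m / L_i)` where `L_i` is spot
#' i's total count and `m` the median total. The result is invariant to a
#' global rescaling of every spot's counts.
#'
#' @param cm A `count_matrix`.
#' @return Numeric spots x genes matrix of normalised values.
#' @export
log_normalize <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  lib <- rowSums(cm$counts)
  if (any(lib == 0))
    stop("spot(s) with zero total counts: ",
         paste(utils::head(cm$spot_ids[lib == 0], 5L), collapse = ", "))
  m <- stats::median(lib)
  log1p(cm$counts * (m / lib))
}

#' Select highly variable genes
#'
#' Ranks genes by decreasing variance of the normalised expression values,
#' breaking ties by lexicographic gene id, and returns the top `h`.
#'
#' @param normed Normalised spots x genes matrix (gene ids as colnames).
#' @param h Number of genes to keep.
#' @return Character vector of gene ids, length `min(h, ncol(normed))`.
#' @export
select_hvg <- function(normed, h) {
  stopifnot(h >= 1)
  g <- ncol(normed)
  if (h > g) {
    warning("requested ", h, " HVGs but only ", g, " genes present; keeping all")
    h <- g
  }
  v <- apply(normed, 2L, stats::var)
  ids <- colnames(normed)
  ord <- order(-v, ids)
  ids[ord][seq_len(h)]
}

#' Principal components of the HVG expression matrix
#'
#' Column-centres the matrix and returns the top `p` principal-component
#' scores ordered by decreasing explained variance. Sign convention: within
#' each component, the loading of largest magnitude is positive, which makes
#' the decomposition deterministic.
#'
#' @param hvg_matrix Numeric n x h matrix (spot ids as rownames).
#' @param p Number of components, `p <= min(n, h)`.
#' @return A `pc_matrix`: numeric n x p score matrix with spot-id rownames.
#' @export
compute_pcs <- function(hvg_matrix, p) {
  n <- nrow(hvg_matrix); h <- ncol(hvg_matrix)
  if (p > min(n, h))
    stop("p = ", p, " exceeds min(n, h) = ", min(n, h))
  pc <- stats::prcomp(hvg_matrix, center = TRUE, scale. = FALSE, rank. = p)
  flip <- vapply(seq_len(p), function(k) {
    l <- pc$rotation[, k]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x[, seq_len(p), drop = FALSE], 2L, flip, `*`)
  colnames(scores) <- paste0("pc", seq_len(p))
  rownames(scores) <- rownames(hvg_matrix)
  class(scores) <- c("pc_matrix", class(scores))
  scores
}

#' Map platform array coordinates onto a rectangular grid
#'
#' Visium spots sit on a hexagonal lattice in array coordinates (row, col)
#' with row + col even. The shear `(i, j) = (row, (row + col) / 2)` places
#' them on a rectangular grid where the six physical hex neighbours of a spot
#' at (i, j) are exactly (i+1, j), (i-1, j), (i, j+1), (i, j-1), (i-1, j-1)
#' and (i+1, j+1). ST coordinates pass through unchanged (square lattice,
#' 4-neighbourhood).
#'
#' @param coords A `spot_coords` data frame.
#' @return The input with integer columns `grid_row`, `grid_col` appended.
#' @export
map_to_grid <- function(coords) {
  stopifnot(inherits(coords, "spot_coords"))
  platform <- attr(coords, "platform")
  if (platform == "visium") {
    bad <- (coords$row + coords$col) %% 2L != 0L
    if (any(bad))
      stop("visium parity violated for spot(s): ",
           paste(utils::head(coords$spot_id[bad], 5L), collapse = ", "))
    coords$grid_row <- as.integer(coords$row)
    coords$grid_col <- as.integer((coords$row + coords$col) %/% 2L)
  } else {
    coords$grid_row <- as.integer(coords$row)
    coords$grid_col <- as.integer(coords$col)
  }
  coords
}

#' Rasterise per-spot principal components onto a grid tensor
#'
#' Shifts grid coordinates so minima land at 0, then writes each spot's PC
#' vector into its cell of an H x W x p array. Cells without a spot are
#' zero-filled and masked out; they pad convolution receptive fields but
#' never enter losses or outputs.
#'
#' @param pcs A `pc_matrix` (n x p).
#' @param grid_coords Output of [map_to_grid()] covering the same spots.
#' @return A `grid_tensor`: list with `data` (H x W x p array), `mask`
#'   (H x W logical), `spot_index` (data frame `spot_id`, `grid_row`,
#'   `grid_col`, `pos` with 1-based cell position), `H`, `W`, `p`.
#' @export
rasterize <- function(pcs, grid_coords) {
  stopifnot(!is.null(grid_coords$grid_row))
  gc <- grid_coords[match(rownames(pcs), grid_coords$spot_id), , drop = FALSE]
  if (anyNA(gc$grid_row))
    stop("grid coordinates missing for some spots in the PC matrix")
  r <- gc$grid_row - min(gc$grid_row)
  c_ <- gc$grid_col - min(gc$grid_col)
  H <- max(r) + 1L; W <- max(c_) + 1L
  pos <- r + 1L + c_ * H                      # column-major cell index
  dup <- duplicated(pos) | duplicated(pos, fromLast = TRUE)
  if (any(dup)) {
    clash <- split(gc$spot_id[dup], pos[dup])[[1]]
    stop("two spots map to one grid cell: ", paste(clash, collapse = ", "))
  }
  p <- ncol(pcs)
  data <- array(0, dim = c(H, W, p))
  mat <- matrix(data, H * W, p)
  mat[pos, ] <- unclass(pcs)
  data <- array(mat, dim = c(H, W, p))
  mask <- matrix(FALSE, H, W)
  mask[pos] <- TRUE
  spot_index <- data.frame(spot_id = rownames(pcs),
                           grid_row = r, grid_col = c_, pos = pos,
                           stringsAsFactors = FALSE)
  ord <- order(spot_index$spot_id)
  spot_index <- spot_index[ord, , drop = FALSE]
  rownames(spot_index) <- NULL
  structure(list(data = data, mask = mask, spot_index = spot_index,
                 H = H, W = W, p = p),
            class = "grid_tensor")
}

#' Recover the PC matrix from a grid tensor
#'
#' Inverse of [rasterize()]: reads each occupied cell back into a spot x p
#' matrix ordered by spot id.
#'
#' @param grid A `grid_tensor`.
#' @return Numeric matrix with spot-id rownames.
#' @export
derasterize <- function(grid) {
  mat <- matrix(grid$data, grid$H * grid$W, grid$p)
  out <- mat[grid$spot_index$pos, , drop = FALSE]
  rownames(out) <- grid$spot_index$spot_id
  colnames(out) <- paste0("pc", seq_len(grid$p))
  out
}

neighbor_offsets <- function(platform) {
  if (platform == "visium")
    cbind(dr = c(1L, -1L, 0L, 0L, -1L, 1L),
          dc = c(0L,  0L, 1L, -1L, -1L, 1L))
  else
    cbind(dr = c(1L, -1L, 0L, 0L),
          dc = c(0L,  0L, 1L, -1L))
}

#' Spot adjacency under the platform topology
#'
#' Builds, for every spot, the list of occupied neighbouring spots: the six
#' sheared-hex offsets for Visium, the four rook offsets for ST. The relation
#' is symmetric by construction.
#'
#' @param grid_coords Output of [map_to_grid()].
#' @param platform `"visium"` or `"st"`; defaults to the coords' platform.
#' @return Named list: spot id -> character vector of neighbouring spot ids.
#' @export
neighbors <- function(grid_coords, platform = attr(grid_coords, "platform")) {
  stopifnot(!is.null(grid_coords$grid_row), platform %in% c("visium", "st"))
  off <- neighbor_offsets(platform)
  key <- paste(grid_coords$grid_row, grid_coords$grid_col)
  lookup <- stats::setNames(grid_coords$spot_id, key)
  out <- vector("list", nrow(grid_coords))
  names(out) <- grid_coords$spot_id
  for (i in seq_len(nrow(grid_coords))) {
    nk <- paste(grid_coords$grid_row[i] + off[, "dr"],
                grid_coords$grid_col[i] + off[, "dc"])
    hit <- lookup[nk]
    out[[i]] <- unname(hit[!is.na(hit)])
  }
  out[order(names(out))]
}

#' Full preprocessing: counts to grid tensor
#'
#' Convenience wrapper chaining [log_normalize()], [select_hvg()],
#' [compute_pcs()], [map_to_grid()], [rasterize()] and [neighbors()].
#'
#' @param cm A `count_matrix`.
#' @param coords A `spot_coords`.
#' @param h Number of highly variable genes (default 2000).
#' @param p Number of principal components.
#' @return List: `pcs`, `grid` (grid_tensor), `nbr` (neighbour index),
#'   `grid_coords`.
#' @export
preprocess <- function(cm, coords, h = 2000L, p) {
  normed <- log_normalize(cm)
  hvg <- select_hvg(normed, h)
  pcs <- compute_pcs(normed[, hvg, drop = FALSE], p)
  gc <- map_to_grid(coords)
  grid <- rasterize(pcs, gc)
  nbr <- neighbors(gc)
  list(pcs = pcs, grid = grid, nbr = nbr, grid_coords = gc)
}
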