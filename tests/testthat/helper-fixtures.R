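# Shared fixtures, built in code at test time.

# tiny count matrix with known structure
tiny_counts <- function() {
  m <- matrix(c(1, 3, 0,
                2, 0, 2,
                0, 1, 5), nrow = 3, byrow = TRUE,
              dimnames = list(c("sA", "sB", "sC"),
                              c("g1", "g2", "g3")))
  count_matrix(m)
}

# full H x W st-platform grid coordinates
full_st_coords <- function(H, W) {
  df <- expand.grid(row = 0:(H - 1), col = 0:(W - 1))
  df <- data.frame(spot_id = sprintf("s%02d_%02d", df$row, df$col),
                   row = df$row, col = df$col, stringsAsFactors = FALSE)
  spot_coords(df[order(df$spot_id), ], "st")
}

# full H x W visium lattice in array coordinates (row + col even)
full_visium_coords <- function(H, W) {
  gi <- rep(0:(H - 1), times = W)
  gj <- rep(0:(W - 1), each = H)
  row <- gi
  col <- 2L * gj - gi + 2L * H
  df <- data.frame(spot_id = sprintf("s%02d_%03d", row, col),
                   row = row, col = col, stringsAsFactors = FALSE)
  spot_coords(df[order(df$spot_id), ], "visium")
}

# labels on a 3 x 3 st lattice given as a matrix by (row, col)
lattice_labels <- function(mat, coords) {
  stats::setNames(mat[cbind(coords$row + 1L, coords$col + 1L)],
                  coords$spot_id)
}

# small trained-free response matrix on the simplex
random_response <- function(n, s, seed = 1) {
  set.seed(seed)
  z <- matrix(rexp(n * s), n, s)
  r <- z / rowSums(z)
  rownames(r) <- sprintf("s%02d", seq_len(n))
  r
}
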