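#' Construct a scribble set
#'
#' A scribble set records, for every spot, whether it carries a prior domain
#' label (`u_i = 1`) and if so which (`w_i` in `1..s`). Internally it is a
#' named integer vector over all spots with `NA` meaning unscribbled.
#'
#' @param labels Named integer vector over all spot ids; `NA` = unscribbled.
#' @param s Number of domains.
#' @return A `scribble_set`.
#' @export
scribble_set <- function(labels, s) {
  stopifnot(s >= 2, !is.null(names(labels)))
  lab <- as.integer(labels)
  names(lab) <- names(labels)
  bad <- !is.na(lab) & (lab < 1L | lab > s)
  if (any(bad))
    stop("scribble label(s) outside 1..", s, " for spot(s): ",
         paste(utils::head(names(lab)[bad], 5L), collapse = ", "))
  structure(list(labels = lab[order(names(lab))], s = as.integer(s)),
            class = "scribble_set")
}

#' @export
print.scribble_set <- function(x, ...) {
  cat("scribble_set:", sum(!is.na(x$labels)), "of", length(x$labels),
      "spots scribbled,", x$s, "domains\n")
  invisible(x)
}

#' Number of scribbled spots
#' @param scr A `scribble_set`.
#' @return Integer count of spots with `u_i = 1`.
#' @export
n_scribbled <- function(scr) sum(!is.na(scr$labels))

#' Read scribbles from a CSV file
#'
#' Expects a header `spot_id,label`; an empty label field (or an omitted
#' spot) means unscribbled. Labels must be integers in `1..s` and spot ids
#' must be known.
#'
#' @param path CSV path.
#' @param spot_ids All spot ids of the dataset.
#' @param s Number of domains.
#' @return A `scribble_set` over `spot_ids`.
#' @export
read_scribbles <- function(path, spot_ids, s) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character"))
  lab <- rep(NA_integer_, length(spot_ids))
  names(lab) <- spot_ids
  df <- df[!is.na(df[[2]]) & nzchar(trimws(df[[2]])), , drop = FALSE]
  if (nrow(df) > 0L) {
    unknown <- setdiff(df[[1]], spot_ids)
    if (length(unknown) > 0L)
      stop("unknown spot id(s) in ", path, ": ",
           paste(utils::head(unknown, 5L), collapse = ", "))
    val <- suppressWarnings(as.integer(df[[2]]))
    if (anyNA(val) || any(val < 1L | val > s))
      stop("scribble label(s) outside 1..", s, " in ", path)
    lab[df[[1]]] <- val
  }
  scribble_set(lab, s)
}

#' Write scribbles to CSV (same dialect read_scribbles consumes)
#' @param scr A `scribble_set`.
#' @param path Output CSV path.
#' @export
write_scribbles <- function(scr, path) {
  lab <- scr$labels
  df <- data.frame(spot_id = names(lab),
                   label = ifelse(is.na(lab), "", as.character(lab)),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Non-spatial initial clustering of the PC profiles
#'
#' Clusters spot PC vectors into `s` groups with a Gaussian mixture model
#' (mclust), ignoring spatial position. This seeds the automated scribble
#' pipeline. If the mixture fit degenerates (e.g. all points identical) the
#' fallback assigns every spot to one group.
#'
#' @param pcs A `pc_matrix` (n x p, spot-id rownames).
#' @param s Number of domains, `2 <= s <= n`.
#' @param seed Integer seed; the call is deterministic given the seed.
#' @return Named integer vector of labels in `1..s`, ordered by spot id.
#' @export
initial_cluster <- function(pcs, s, seed = 1L) {
  n <- nrow(pcs)
  if (n < s) stop("fewer spots (", n, ") than requested domains (", s, ")")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the caller frame
  fit <- tryCatch(
    mclust::Mclust(unclass(pcs), G = s, verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit) || is.null(fit$classification)) {
    lab <- rep(1L, n)
  } else {
    lab <- as.integer(fit$classification)
  }
  names(lab) <- rownames(pcs)
  lab[order(names(lab))]
}

#' Derive scribbles from an initial labelling by neighbour consensus
#'
#' A spot becomes a scribble, keeping its initial label, exactly when every
#' neighbouring spot carries the same initial label; all other labels are
#' cleared. Spots with incomplete neighbourhoods (tissue boundary) are judged
#' on their existing neighbours; with `strict = TRUE` they are disqualified
#' instead. Isolated spots qualify under the default rule.
#'
#' @param init Named integer labels over all spots.
#' @param nbr Neighbour index from [neighbors()].
#' @param s Number of domains (default `max(init)`).
#' @param strict Require a full-size neighbourhood (6 Visium / 4 ST)?
#' @param full_size Neighbourhood size used when `strict = TRUE`.
#' @return A `scribble_set`.
#' @export
auto_scribbles <- function(init, nbr, s = max(init), strict = FALSE,
                           full_size = NULL) {
  stopifnot(!is.null(names(init)), all(names(init) %in% names(nbr)))
  keep <- vapply(names(init), function(id) {
    nb <- nbr[[id]]
    if (strict && length(nb) < full_size) return(FALSE)
    all(init[nb] == init[[id]])
  }, logical(1))
  lab <- ifelse(keep, init, NA_integer_)
  names(lab) <- names(init)
  scribble_set(lab, s)
}

#' Bernoulli scribble dropout
#'
#' Each scribbled spot is independently retained with probability `1 - beta`;
#' retained labels are unchanged and no scribble is ever added. Called once
#' per training iteration in the automated pipeline so the network can
#' overrule occasional wrong scribbles. Draws from the current RNG stream.
#'
#' @param scr A `scribble_set`.
#' @param beta Dropout rate in `[0, 1)`.
#' @return A `scribble_set` whose scribbles are a subset of `scr`'s.
#' @export
scribble_dropout <- function(scr, beta) {
  stopifnot(beta >= 0, beta < 1)
  if (beta == 0) return(scr)
  lab <- scr$labels
  idx <- which(!is.na(lab))
  drop <- idx[stats::runif(length(idx)) < beta]
  lab[drop] <- NA_integer_
  scribble_set(lab, scr$s)
}
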