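#' Contingency table between predicted and reference partitions
#'
#' Crosses predicted domain labels with a reference annotation over shared
#' spots. Reference entries equal to `NA` or the string `"unannotated"` are
#' dropped before counting, so agreement is measured on annotated spots only.
#'
#' @param pred Named vector of predicted labels.
#' @param truth Named vector of reference labels; `NA`/`"unannotated"` spots
#'   are excluded.
#' @return A `contingency` object: counts `tab`, marginals `a`, `b`, and `n`.
#' @export
contingency <- function(pred, truth) {
  shared <- intersect(names(pred), names(truth))
  if (length(shared) == 0L) stop("no shared spot ids between partitions")
  t_ <- truth[shared]
  keep <- !is.na(t_) & t_ != "unannotated"
  if (!any(keep)) stop("zero annotated spots after exclusion")
  shared <- shared[keep]
  tab <- table(factor(pred[shared]), factor(truth[shared]))
  structure(list(tab = unclass(tab),
                 a = rowSums(tab), b = colSums(tab),
                 n = sum(tab)),
            class = "contingency")
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions, evaluated from the
#' contingency table \[n_ij\] with marginals a_i, b_j and total n:
#' \deqn{ARI = \frac{\sum_{ij} \binom{n_{ij}}{2} - [\sum_i \binom{a_i}{2}
#'   \sum_j \binom{b_j}{2}] / \binom{n}{2}}{\frac12[\sum_i \binom{a_i}{2} +
#'   \sum_j \binom{b_j}{2}] - [\sum_i \binom{a_i}{2}
#'   \sum_j \binom{b_j}{2}] / \binom{n}{2}}}
#' Identical partitions score 1. When both partitions are single-cluster the
#' formula is 0/0; by convention 1 is returned with a warning.
#'
#' @param x Either a `contingency` object or a named vector of predicted
#'   labels (then `truth` is required).
#' @param truth Optional named reference labels (see [contingency()]).
#' @return ARI in \[-1, 1\].
#' @export
ari <- function(x, truth = NULL) {
  tab <- if (inherits(x, "contingency")) x else contingency(x, truth)
  if (tab$n < 2L) stop("need at least 2 annotated spots")
  sum_nij <- sum(choose(tab$tab, 2))
  sum_a <- sum(choose(tab$a, 2))
  sum_b <- sum(choose(tab$b, 2))
  expected <- sum_a * sum_b / choose(tab$n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) {
    warning("degenerate partitions (both single-cluster); ARI defined as 1")
    return(1.0)
  }
  (sum_nij - expected) / (max_index - expected)
}
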