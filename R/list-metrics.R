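#' Ranked feature lists
#'
#' A ranked list is an ordering of feature identifiers, best first. It may be
#' partial: only the top \code{l} of the \code{p} features in the universe are
#' listed. All stability computations in the package operate on these objects
#' (or on plain vectors accepted by the individual distance functions).
#'
#' @param ids vector of feature identifiers, best first, no duplicates.
#' @param p size of the feature universe the list is drawn from.
#' @param weights optional per-feature weights aligned with \code{ids}.
#' @return An object of class \code{ranked_list}.
#' @export
ranked_list <- function(ids, p, weights = NULL) {
  stop_if_not_(!anyDuplicated(ids), "ranked list contains duplicated ids")
  stop_if_not_(length(ids) <= p, "list length %d exceeds universe size %d",
               length(ids), p)
  if (!is.null(weights))
    stop_if_not_(length(weights) == length(ids),
                 "weights must align with ids")
  structure(list(ids = ids, l = length(ids), p = as.integer(p),
                 weights = weights),
            class = "ranked_list")
}

#' @export
print.ranked_list <- function(x, ...) {
  cat(sprintf("Ranked list: top %d of %d features\n", x$l, x$p))
  show <- utils::head(x$ids, 10L)
  cat(" ", paste(show, collapse = ", "),
      if (x$l > 10L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

as_ids_ <- function(x) if (inherits(x, "ranked_list")) x$ids else x

# ranks of 1..p implied by an ordering over 1..p
ranks_of_ <- function(ord, p) {
  r <- integer(p)
  r[ord] <- seq_along(ord)
  r
}

#' Canberra distance between two complete ranked lists
#'
#' For two complete orderings of the same \code{p} features with rank
#' functions \eqn{\tau_1, \tau_2}, the Canberra distance is
#' \deqn{d = \sum_i |\tau_1(i) - \tau_2(i)| / (\tau_1(i) + \tau_2(i)).}
#' Ranks are 1-based. The distance is symmetric and zero iff the two
#' rankings coincide.
#'
#' @param t1,t2 complete orderings: vectors of feature ids (best first) or
#'   \code{ranked_list} objects with \code{l == p}.
#' @return The Canberra distance (a single number).
#' @export
canberra_full <- function(t1, t2) {
  i1 <- as_ids_(t1); i2 <- as_ids_(t2)
  stop_if_not_(length(i1) == length(i2), "lists have different lengths")
  stop_if_not_(setequal(i1, i2), "lists are over different feature universes")
  p <- length(i1)
  r1 <- seq_len(p)                       # rank of i1[k] in t1 is k
  r2 <- match(i1, i2)                    # rank of the same feature in t2
  sum(abs(r1 - r2) / (r1 + r2))
}

# Mean of |a-b|/(a+b) over b in `bs` for each a in `as` (vectorised in a).
mean_term_ <- function(as, bs) {
  vapply(as, function(a) mean(abs(a - bs) / (a + bs)), numeric(1))
}

#' Canberra distance between partial ranked lists
#'
#' Two partial lists of lengths \eqn{l_1, l_2} over a universe of \code{p}
#' features are compared through the set of all their completions: every
#' permutation of the unlisted features over the tail positions. The
#' \emph{complete} distance is the mean Canberra distance over all pairs of
#' completions; it is computed in closed form from per-feature expected
#' contributions (the rank of an unlisted feature is uniform over the tail
#' positions of its list, independently between the two lists). The
#' \emph{core} distance drops the term contributed by features unlisted in
#' both lists, which depends only on the discarded features and would
#' otherwise dominate short lists.
#'
#' @param t1,t2 partial orderings (vectors of ids, best first, or
#'   \code{ranked_list}s).
#' @param p universe size.
#' @param type \code{"complete"} or \code{"core"}.
#' @return The distance (a single number).
#' @export
canberra_partial <- function(t1, t2, p,
                             type = c("complete", "core")) {
  type <- match.arg(type)
  i1 <- as.character(as_ids_(t1)); i2 <- as.character(as_ids_(t2))
  if (inherits(t1, "ranked_list")) p <- t1$p
  stop_if_not_(!anyDuplicated(i1) && !anyDuplicated(i2),
               "duplicated ids in a list")
  l1 <- length(i1); l2 <- length(i2)
  stop_if_not_(l1 <= p && l2 <= p, "list longer than the universe")
  num <- suppressWarnings(as.numeric(c(i1, i2)))
  if (!anyNA(num))
    stop_if_not_(all(num >= 1 & num <= p),
                 "listed feature outside the universe 1..%d", p)

  r1 <- stats::setNames(seq_len(l1), i1)
  r2 <- stats::setNames(seq_len(l2), i2)
  tail1 <- if (l1 < p) (l1 + 1):p else integer(0)
  tail2 <- if (l2 < p) (l2 + 1):p else integer(0)

  both  <- intersect(i1, i2)
  only1 <- setdiff(i1, i2)
  only2 <- setdiff(i2, i1)
  n_unlisted <- p - length(both) - length(only1) - length(only2)
  stop_if_not_(n_unlisted >= 0,
               "listed features exceed the declared universe size")

  d <- 0
  if (length(both)) {
    a <- r1[both]; b <- r2[both]
    d <- d + sum(abs(a - b) / (a + b))
  }
  if (length(only1))
    d <- d + sum(mean_term_(r1[only1], tail2))
  if (length(only2))
    d <- d + sum(mean_term_(r2[only2], tail1))
  if (type == "complete" && n_unlisted > 0) {
    # every feature unlisted in both lists has the same expected term
    d <- d + n_unlisted * mean(mean_term_(tail1, tail2))
  }
  d
}

.expected_canberra_cache <- new.env(parent = emptyenv())

#' Expected Canberra distance between two random complete lists
#'
#' Exact expectation of the Canberra distance between two independent
#' uniformly random permutations of \code{p} features:
#' \deqn{E(p) = (1/p) \sum_{a=1}^p \sum_{b=1}^p |a-b|/(a+b),}
#' which follows from linearity: each feature's ranks in the two lists are
#' marginally uniform and independent. Evaluated exactly (blocked, O(p^2))
#' up to \code{exact_max}; beyond that the continuous-limit slope
#' \eqn{2\log 2 - 1} per feature is used.
#'
#' @param p universe size.
#' @param exact_max largest \code{p} evaluated exactly.
#' @return The expected distance.
#' @export
expected_canberra <- function(p, exact_max = 20000L) {
  p <- as.integer(p)
  stop_if_not_(p >= 1, "p must be >= 1")
  key <- as.character(p)
  hit <- .expected_canberra_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (p > exact_max) {
    val <- (2 * log(2) - 1) * p
  } else {
    b <- seq_len(p)
    s <- 0
    block <- 512L
    for (a0 in seq(1L, p, by = block)) {
      a <- a0:min(a0 + block - 1L, p)
      s <- s + sum(abs(outer(a, b, "-")) / outer(a, b, "+"))
    }
    val <- s / p
  }
  .expected_canberra_cache[[key]] <- val
  val
}

#' Stability indicator for a set of ranked lists
#'
#' The mean Canberra distance over all unordered pairs of lists, normalised
#' by the expected distance between two independent random permutations of
#' the universe (\code{\link{expected_canberra}}). The indicator is 0 for
#' identical lists, close to 1 for independently random lists, and bounded
#' by about 1.4 (attained by systematically reversed lists).
#'
#' @param lists a list of orderings (vectors or \code{ranked_list}s), or a
#'   matrix whose columns are complete orderings.
#' @param p universe size; inferred from \code{ranked_list} inputs or from
#'   complete lists when missing.
#' @param distance \code{"full"} for complete lists, \code{"complete"} or
#'   \code{"core"} for partial lists.
#' @return An object of class \code{stability_report} with fields
#'   \code{raw} (mean pairwise distance), \code{norm_const} and
#'   \code{value} (normalised indicator).
#' @export
stability_indicator <- function(lists, p = NULL,
                                distance = c("full", "complete", "core")) {
  distance <- match.arg(distance)
  if (is.matrix(lists)) lists <- lapply(seq_len(ncol(lists)), function(j) lists[, j])
  stop_if_not_(length(lists) >= 2, "need at least two lists")
  if (is.null(p)) {
    p <- if (inherits(lists[[1]], "ranked_list")) lists[[1]]$p
         else length(as_ids_(lists[[1]]))
  }
  n <- length(lists)
  if (distance == "full") {
    # rank matrix once, then vectorised pair sums
    R <- vapply(lists, function(l) {
      ids <- as_ids_(l)
      stop_if_not_(length(ids) == p, "full-list stability requires complete lists")
      match(as_ids_(lists[[1]]), ids)
    }, integer(p))
    total <- 0
    for (i in seq_len(n - 1)) {
      ri <- R[, i]
      for (j in (i + 1):n) {
        rj <- R[, j]
        total <- total + sum(abs(ri - rj) / (ri + rj))
      }
    }
  } else {
    total <- 0
    for (i in seq_len(n - 1))
      for (j in (i + 1):n)
        total <- total + canberra_partial(lists[[i]], lists[[j]], p,
                                          type = distance)
  }
  raw <- total / (n * (n - 1) / 2)
  e <- expected_canberra(p)
  structure(list(raw = raw, norm_const = e,
                 value = if (e > 0) raw / e else 0,
                 n_lists = n, p = p, distance = distance),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(
    "Stability indicator (%s distance, %d lists, p = %d): %.4f\n",
    x$distance, x$n_lists, x$p, x$value))
  cat(sprintf("  raw mean pairwise distance %.4f / expectation %.4f\n",
              x$raw, x$norm_const))
  invisible(x)
}

#' Matthews correlation coefficient
#'
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}.}
#' Any zero factor in the denominator yields 0 by convention (the degenerate
#' all-one-class prediction carries no correlation information).
#'
#' @param tp,tn,fp,fn non-negative confusion-matrix counts.
#' @return A value in \eqn{[-1, 1]}.
#' @export
mcc <- function(tp, tn, fp, fn) {
  stop_if_not_(all(c(tp, tn, fp, fn) >= 0), "confusion counts must be >= 0")
  num <- tp * tn - fp * fn
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  num / sqrt(den)
}

mcc_from_labels_ <- function(truth, pred, positive) {
  tp <- sum(truth == positive & pred == positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  mcc(tp, tn, fp, fn)
}

#' Precision and recall of a selected feature set
#'
#' Precision is the fraction of selected features that are true biomarkers;
#' recall is the fraction of true biomarkers selected. An empty selection has
#' precision reported as 0 with \code{empty_selection = TRUE}.
#'
#' @param selected vector of selected feature ids (may be empty).
#' @param truth vector of true biomarker ids (non-empty).
#' @return List with \code{precision}, \code{recall}, \code{tp},
#'   \code{empty_selection}.
#' @export
precision_recall <- function(selected, truth) {
  stop_if_not_(length(truth) > 0, "truth set is empty")
  tp <- length(intersect(selected, truth))
  empty <- length(selected) == 0
  list(precision = if (empty) 0 else tp / length(selected),
       recall = tp / length(truth),
       tp = tp,
       empty_selection = empty)
}

#' Area under the precision-recall curve of a full ranking
#'
#' Precision and recall are evaluated at every cutoff \code{1..p} along the
#' ranking; the area is accumulated step-wise over recall increments (each
#' true biomarker encountered at rank \code{k} contributes
#' \code{precision(k) / |truth|}).
#'
#' @param ranking complete ordering of the universe (vector of ids or
#'   \code{ranked_list}).
#' @param truth non-empty vector of true biomarker ids.
#' @return Area in \eqn{[0, 1]}.
#' @export
aupr <- function(ranking, truth) {
  ids <- as_ids_(ranking)
  stop_if_not_(length(truth) > 0, "truth set is empty")
  hit <- ids %in% truth
  k <- seq_along(ids)
  prec <- cumsum(hit) / k
  sum(prec[hit]) / length(truth)
}
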