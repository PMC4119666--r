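#' Per-community edge-weight and degree sums
#'
#' For each community `r` of a partition: `I_r`, the summed weight of the
#' edges with both ends in `r`, and `D_r`, the summed (weighted) degree of its
#' vertices. These are the ingredients of [modularity_q()]; the identities
#' `sum(D) == 2m` and `I_r <= D_r / 2` always hold.
#'
#' @param net an [network()] object.
#' @param membership community id per vertex (positional or named by vertex;
#'   any atomic type).
#' @return list with `I`, `D` (named by community id), `m` (total edge
#'   weight), `N` (number of communities).
#' @export
partition_stats <- function(net, membership) {
  stopifnot(inherits(net, "lpap_network"))
  memb <- align_membership(net, membership)
  ids <- unique(memb)
  m <- sum(net$weights)
  k <- vapply(net$wadj, sum, numeric(1))
  D <- vapply(ids, function(r) sum(k[memb == r]), numeric(1))
  ei <- memb[net$edges[, 1L]]
  ej <- memb[net$edges[, 2L]]
  I <- vapply(ids, function(r) sum(net$weights[ei == r & ej == r]), numeric(1))
  names(I) <- names(D) <- as.character(ids)
  list(I = I, D = D, m = m, N = length(ids))
}

align_membership <- function(net, membership) {
  if (inherits(membership, "lpap")) membership <- membership$membership
  if (!is.null(names(membership))) {
    ix <- match(net$vertices, names(membership))
    if (anyNA(ix)) stop("membership is missing vertices: ",
                        paste(net$vertices[is.na(ix)][1:3], collapse = ", "))
    membership <- membership[ix]
  } else if (length(membership) != net$n) {
    stop("membership length ", length(membership),
         " does not match vertex count ", net$n)
  }
  if (anyNA(membership)) stop("unassigned vertex in membership")
  as.vector(membership)
}

#' Modularity of a partition
#'
#' `Q = sum_r (I_r / m - (D_r / 2m)^2)` with `I_r` the internal edge weight
#' and `D_r` the degree sum of community `r`. On weighted networks all sums
#' use edge weights. The single-community partition scores exactly 0; bad
#' divisions can score below 0 (modularity is not confined to `[0, 1]`).
#'
#' @inheritParams partition_stats
#' @return the modularity, a real number `< 1`.
#' @export
modularity_q <- function(net, membership) {
  st <- partition_stats(net, membership)
  if (st$m <= 0) stop("modularity undefined on a network with no edges")
  sum(st$I / st$m - (st$D / (2 * st$m))^2)
}

#' Fraction of vertices classified correctly (FVCC)
#'
#' Accuracy of a detected partition against a known ground truth. Each
#' detected community is mapped to the truth community with which it shares
#' the most vertices (plurality; ties go to the truth community with the
#' lower id); a vertex counts as correct when it belongs to its community's
#' mapped truth group. Splitting one true community into several detected
#' pieces therefore still scores those vertices as correct.
#'
#' @param membership detected community per vertex (vector or `"lpap"` fit).
#' @param truth ground-truth community per vertex. Named vectors are aligned
#'   by name; unnamed vectors positionally (lengths must match).
#' @return a value in `[0, 1]`.
#' @export
fvcc <- function(membership, truth) {
  if (inherits(membership, "lpap")) membership <- membership$membership
  if (!is.null(names(membership)) && !is.null(names(truth))) {
    ix <- match(names(membership), names(truth))
    if (anyNA(ix)) stop("membership and truth cover different vertices")
    truth <- truth[ix]
  } else if (length(membership) != length(truth)) {
    stop("membership and truth cover different vertices")
  }
  n <- length(membership)
  truth_ids <- sort(unique(as.vector(truth)))
  correct <- 0L
  for (d in unique(as.vector(membership))) {
    tt <- truth[membership == d]
    cnt <- vapply(truth_ids, function(t) sum(tt == t), integer(1))
    correct <- correct + max(cnt)   # plurality; first (= lowest id) max wins
  }
  correct / n
}

#' Relative modularity change of the incomplete-update rule
#'
#' `delta_q(Q0, Qp) = (Qp - Q0) / Qp * 100`, in percent: the modularity cost
#' (negative) or gain (positive) of the gated algorithm `Qp` relative to the
#' baseline `Q0`.
#'
#' @param q0 baseline modularity (e.g. plain label propagation).
#' @param qp modularity of the gated/predicted variant; must be non-zero.
#' @return percentage.
#' @export
delta_q <- function(q0, qp) {
  if (qp == 0) stop("`qp` must be non-zero")
  (qp - q0) / qp * 100
}

#' Mean and standard deviation of repeated-run results
#'
#' Summaries are reported as `mean +/- sd` with the sample (n-1) standard
#' deviation; a single value gets sd 0.
#'
#' @param values numeric vector, length >= 1.
#' @return named numeric `c(mean, sd)`.
#' @export
summarize_runs <- function(values) {
  if (length(values) == 0L) stop("no values to summarise")
  s <- if (length(values) == 1L) 0 else stats::sd(values)
  c(mean = mean(values), sd = s)
}
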