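# RNG discipline: every generator and every benchmark run receives its own
# integer seed derived from the user's root seed plus a purpose tag, so
# experiments are reproducible and individual draws are independent of call
# order. The hash stays below 2^31 - 1.

#' Derive a reproducible sub-seed from a root seed and tags
#'
#' @param seed integer root seed.
#' @param ... tags (coerced to character) naming the consumer, e.g.
#'   `derive_seed(1, "gn", 3)` for the third benchmark network.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  tokens <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(tokens)) h <- (h * 131 + ch) %% 2147483629
  as.integer(h)
}

# Evaluate `expr` under `set.seed(seed)` without disturbing the caller's RNG
# state; seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# All unordered vertex pairs of 1..n as a 2-column integer matrix.
all_pairs <- function(n) {
  j <- rep.int(seq_len(n), seq_len(n) - 1L)  # j from 2..n, repeated
  i <- sequence(seq_len(n) - 1L)             # i < j
  cbind(i = i, j = j)
}

#' Planted-partition (Girvan-Newman style) benchmark network
#'
#' Generates the standard community-detection benchmark: `n_comm` planted
#' groups of `comm_size` vertices each (default four groups of 32, i.e. 128
#' vertices). Each intra-group pair is an edge independently with probability
#' `p_in = (mean_degree - z_out) / (comm_size - 1)` and each inter-group pair
#' with `p_out = z_out / (n - comm_size)`, so every vertex has expected total
#' degree `mean_degree` (16 by default) of which `z_out` is expected to leave
#' its group. Degrees are binomial around these expectations, not fixed
#' exactly. All edges have unit weight.
#'
#' @param z_out expected inter-group degree per vertex, in `[0, mean_degree]`.
#' @param n_comm,comm_size number and size of the planted groups.
#' @param mean_degree expected total degree per vertex.
#' @param seed integer seed; the same seed yields the identical network.
#' @return list with components `network` (an `"lpap_network"`) and `truth`
#'   (named integer vector: the planted group of every vertex).
#' @examples
#' gn <- generate_gn(z_out = 0, seed = 1)
#' # with z_out = 0 no edge crosses a planted group
#' @export
generate_gn <- function(z_out, n_comm = 4L, comm_size = 32L,
                        mean_degree = 16, seed = NULL) {
  if (z_out < 0 || z_out > mean_degree)
    stop("`z_out` must lie in [0, mean_degree]")
  n <- n_comm * comm_size
  truth <- rep(seq_len(n_comm), each = comm_size)
  p_in <- (mean_degree - z_out) / (comm_size - 1)
  p_out <- z_out / (n - comm_size)
  if (p_in > 1) stop("mean_degree too large for comm_size: p_in > 1")
  pairs <- all_pairs(n)
  same <- truth[pairs[, 1L]] == truth[pairs[, 2L]]
  keep <- with_seed(seed, stats::runif(nrow(pairs)) < ifelse(same, p_in, p_out))
  ids <- as.character(seq_len(n))
  net <- network(data.frame(u = ids[pairs[keep, 1L]], v = ids[pairs[keep, 2L]],
                            stringsAsFactors = FALSE),
                 vertices = ids)
  names(truth) <- ids
  list(network = net, truth = truth)
}

#' Giant connected component of an Erdos-Renyi random graph
#'
#' Draws `G(n, p)` with `p = mean_degree / (n - 1)` and returns its largest
#' connected component, renumbered `1..n'`. The size and edge count of the raw
#' graph are kept as attributes `parent_n` and `parent_m`.
#'
#' @param n number of vertices of the raw graph (>= 2).
#' @param mean_degree expected degree; must give `p < 1`.
#' @param seed integer seed.
#' @return an `"lpap_network"`; always connected. If the raw graph has no
#'   edges the component is a single isolated vertex.
#' @export
generate_er_giant <- function(n, mean_degree, seed = NULL) {
  if (n < 2) stop("`n` must be at least 2")
  p <- mean_degree / (n - 1)
  if (p <= 0 || p >= 1) stop("degenerate edge probability p = ", p)
  pairs <- all_pairs(n)
  keep <- with_seed(seed, stats::runif(nrow(pairs)) < p)
  e <- pairs[keep, , drop = FALSE]
  adj <- vector("list", n)
  for (r in seq_len(nrow(e))) {
    adj[[e[r, 1L]]] <- c(adj[[e[r, 1L]]], e[r, 2L])
    adj[[e[r, 2L]]] <- c(adj[[e[r, 2L]]], e[r, 1L])
  }
  for (k in seq_len(n)) if (is.null(adj[[k]])) adj[[k]] <- integer(0)
  comp <- bfs_components(adj)
  giant <- which(comp == which.max(tabulate(comp)))
  new_id <- match(seq_len(n), giant)  # old index -> new index or NA
  inside <- !is.na(new_id[e[, 1L]]) & !is.na(new_id[e[, 2L]])
  ids <- as.character(seq_along(giant))
  net <- network(
    data.frame(u = ids[new_id[e[inside, 1L]]], v = ids[new_id[e[inside, 2L]]],
               stringsAsFactors = FALSE),
    vertices = ids)
  attr(net, "parent_n") <- n
  attr(net, "parent_m") <- nrow(e)
  net
}

#' Complete graph
#'
#' All `n(n-1)/2` unit-weight edges; the canonical single-community network.
#'
#' @param n number of vertices (>= 2).
#' @return an `"lpap_network"`.
#' @export
generate_complete <- function(n) {
  if (n < 2) stop("`n` must be at least 2")
  pairs <- all_pairs(n)
  ids <- as.character(seq_len(n))
  network(data.frame(u = ids[pairs[, 1L]], v = ids[pairs[, 2L]],
                     stringsAsFactors = FALSE),
          vertices = ids)
}

#' Randomly reweight a network
#'
#' `weight_uniform()` draws each edge weight independently from the uniform
#' distribution on `(0, 1]` (zero is excluded: a zero weight would be
#' indistinguishable from a missing edge). `weight_discrete()` draws each
#' weight uniformly from a finite set of positive levels, `{1, 2, 3, 4}` by
#' default. Both keep the topology untouched.
#'
#' @param net an `"lpap_network"`.
#' @param seed integer seed.
#' @return a reweighted `"lpap_network"` with the same vertices and edges.
#' @export
weight_uniform <- function(net, seed = NULL) {
  stopifnot(inherits(net, "lpap_network"))
  m <- nrow(net$edges)
  w <- with_seed(seed, 1 - stats::runif(m))  # (0, 1]
  reweight(net, w)
}

#' @rdname weight_uniform
#' @param levels positive numeric vector of admissible weights.
#' @export
weight_discrete <- function(net, levels = c(1, 2, 3, 4), seed = NULL) {
  stopifnot(inherits(net, "lpap_network"))
  if (length(levels) == 0L || any(levels <= 0))
    stop("`levels` must be a non-empty set of positive reals")
  m <- nrow(net$edges)
  w <- with_seed(seed, levels[sample.int(length(levels), m, replace = TRUE)])
  reweight(net, as.numeric(w))
}

reweight <- function(net, w) {
  net$weights <- w
  # rebuild wadj aligned with adj; edge r contributes to both endpoints
  wadj <- vector("list", net$n)
  i <- net$edges[, 1L]; j <- net$edges[, 2L]
  ends <- c(i, j); other <- c(j, i); ww <- c(w, w)
  for (v in seq_len(net$n)) wadj[[v]] <- numeric(0)
  sp <- split(seq_along(ends), ends)
  for (nm in names(sp)) {
    ix <- sp[[nm]]
    v <- as.integer(nm)
    # keep the neighbour order already stored in adj
    ord <- match(net$adj[[v]], other[ix])
    wadj[[v]] <- ww[ix][ord]
  }
  net$wadj <- wadj
  net
}
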