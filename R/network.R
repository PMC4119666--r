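#' Construct an undirected network
#'
#' Builds the basic graph container used throughout the package: an undirected
#' network with positive edge weights. An unweighted network is the special
#' case where every weight equals 1. Vertex identifiers may be arbitrary
#' strings; internally they are mapped to `1..n` in order of first appearance
#' (or in the order of `vertices` when supplied), and the mapping is retained
#' so partitions can be written back under the original names.
#'
#' Self-loops are rejected: the label-update rule sums support over a vertex's
#' neighbours and never includes the vertex's own label. Duplicate edge lines
#' with identical weight are collapsed; duplicates with conflicting weights are
#' an error, since an undirected pair carries exactly one weight.
#'
#' @param edges a two- or three-column `data.frame` or matrix: endpoints and an
#'   optional positive weight. A zero-row input is allowed only when `vertices`
#'   is supplied (a network of isolated vertices).
#' @param vertices optional character vector of vertex identifiers fixing the
#'   vertex set and its order; must contain every endpoint in `edges`. Use it
#'   to declare isolated vertices.
#' @return an object of class `"lpap_network"` with fields `n` (vertex count),
#'   `vertices` (external ids), `edges` (integer matrix, one row per edge,
#'   first column < second), `weights`, and adjacency lists `adj`/`wadj`
#'   (neighbour indices and the matching edge weights per vertex).
#' @seealso [read_edge_list()], [degrees()], [lpap()]
#' @examples
#' net <- network(data.frame(from = c("a", "b", "a"), to = c("b", "c", "c")))
#' net$n          # 3
#' degrees(net)$m # 3 edges, a triangle
#' @export
network <- function(edges, vertices = NULL) {
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!is.data.frame(edges) || !(ncol(edges) %in% c(2L, 3L)))
    stop("`edges` must have 2 columns (unweighted) or 3 columns (weighted)")
  u <- as.character(edges[[1L]])
  v <- as.character(edges[[2L]])
  w <- if (ncol(edges) == 3L) as.numeric(edges[[3L]]) else rep(1, length(u))

  if (is.null(vertices)) {
    if (length(u) == 0L)
      stop("empty edge set: supply `vertices` to build an edgeless network")
    vertices <- unique(as.vector(rbind(u, v))) # first-appearance order
  } else {
    vertices <- as.character(vertices)
    if (anyDuplicated(vertices)) stop("duplicated vertex identifiers")
    missing <- setdiff(unique(c(u, v)), vertices)
    if (length(missing))
      stop("edge endpoints not in `vertices`: ", paste(missing, collapse = ", "))
  }
  iu <- match(u, vertices)
  iv <- match(v, vertices)
  if (any(bad <- !is.finite(w) | w <= 0))
    stop("non-positive or missing edge weight at edge ", which(bad)[1L])
  if (any(loop <- iu == iv))
    stop("self-loop at vertex '", u[which(loop)[1L]], "'")

  i <- pmin(iu, iv)
  j <- pmax(iu, iv)
  key <- paste(i, j)
  if (anyDuplicated(key)) {
    first <- match(key, key)
    if (any(conflict <- w != w[first]))
      stop("duplicate edge with conflicting weight: ",
           u[which(conflict)[1L]], " -- ", v[which(conflict)[1L]])
    keep <- !duplicated(key)
    i <- i[keep]; j <- j[keep]; w <- w[keep]
  }
  ord <- order(i, j)
  i <- i[ord]; j <- j[ord]; w <- w[ord]

  n <- length(vertices)
  adj <- vector("list", n)
  wadj <- vector("list", n)
  ends <- c(i, j)
  other <- c(j, i)
  ww <- c(w, w)
  sp <- split(seq_along(ends), ends)
  for (nm in names(sp)) {
    ix <- sp[[nm]]
    adj[[as.integer(nm)]] <- other[ix]
    wadj[[as.integer(nm)]] <- ww[ix]
  }
  for (k in seq_len(n)) {
    if (is.null(adj[[k]])) { adj[[k]] <- integer(0); wadj[[k]] <- numeric(0) }
  }
  structure(
    list(n = n, vertices = vertices,
         edges = cbind(i = i, j = j), weights = w,
         adj = adj, wadj = wadj),
    class = "lpap_network")
}

#' @export
print.lpap_network <- function(x, ...) {
  d <- degrees(x)
  cat(sprintf("Undirected network: %d vertices, %d edges (total weight %g)\n",
              x$n, nrow(x$edges), d$m))
  cat(sprintf("Mean (weighted) degree k0 = %g; %s\n",
              d$k0, if (all(x$weights == 1)) "unweighted" else "weighted"))
  invisible(x)
}

#' Weighted degrees, total edge weight and mean degree
#'
#' Returns per-vertex strengths `k_i = sum_j w_ij`, the total edge weight
#' `m = sum_i k_i / 2`, and the network mean degree `k0 = 2m/n`. On an
#' unweighted network these reduce to the usual degree, edge count and mean
#' degree.
#'
#' @param net an [network()] object.
#' @return list with components `k` (named numeric, per vertex), `m`, `k0`.
#' @export
degrees <- function(net) {
  stopifnot(inherits(net, "lpap_network"))
  k <- vapply(net$wadj, sum, numeric(1))
  names(k) <- net$vertices
  m <- sum(net$weights)
  list(k = k, m = m, k0 = if (net$n > 0) 2 * m / net$n else 0)
}

#' Read an undirected network from a plain-text edge list
#'
#' One edge per line, whitespace separated: `u v` (unweighted) or `u v w`
#' (weighted, `w` a positive real). Lines starting with `#` and blank lines
#' are skipped. Malformed lines, self-loops, non-positive weights and
#' conflicting duplicate edges are reported with their line number.
#'
#' @param path file path.
#' @param weighted logical; when `TRUE` every line must carry a third, numeric
#'   weight token. When `FALSE` all weights are set to 1.
#' @param vertex_path optional path to a one-identifier-per-line vertex file
#'   fixing the vertex set (used to declare isolated vertices).
#' @return an `"lpap_network"` object.
#' @export
read_edge_list <- function(path, weighted = FALSE, vertex_path = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "[ \t]+")
  want <- if (weighted) 3L else 2L
  nt <- lengths(toks)
  if (any(bad <- nt != want))
    stop(sprintf("line %d: expected %d tokens, found %d",
                 lineno[which(bad)[1L]], want, nt[which(bad)[1L]]))
  u <- vapply(toks, `[[`, "", 1L)
  v <- vapply(toks, `[[`, "", 2L)
  if (length(u) == 0L) stop("empty edge set in ", path)
  if (weighted) {
    w <- suppressWarnings(as.numeric(vapply(toks, `[[`, "", 3L)))
    if (any(bad <- !is.finite(w) | w <= 0))
      stop(sprintf("line %d: weight must be a positive real",
                   lineno[which(bad)[1L]]))
  } else w <- rep(1, length(u))
  vertices <- NULL
  if (!is.null(vertex_path)) {
    vl <- readLines(vertex_path, warn = FALSE)
    vertices <- trimws(vl[!grepl("^\\s*(#|$)", vl)])
  }
  tryCatch(
    network(data.frame(u, v, w, stringsAsFactors = FALSE), vertices = vertices),
    error = function(e) stop("in ", path, ": ", conditionMessage(e), call. = FALSE))
}

#' Write a network as a plain-text edge list
#'
#' Inverse of [read_edge_list()]: weights are printed with 15 significant
#' digits so that decimal inputs round-trip bit-exactly.
#'
#' @param net an `"lpap_network"` object.
#' @param path output file path.
#' @param header optional character vector of comment lines (written with a
#'   leading `#`).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path, header = NULL) {
  stopifnot(inherits(net, "lpap_network"))
  u <- net$vertices[net$edges[, 1L]]
  v <- net$vertices[net$edges[, 2L]]
  body <- if (all(net$weights == 1))
    paste(u, v, sep = "\t")
  else
    paste(u, v, sprintf("%.15g", net$weights), sep = "\t")
  if (!is.null(header)) body <- c(paste0("# ", header), body)
  writeLines(body, path)
  invisible(path)
}

#' Write a community membership file
#'
#' Two tab-separated columns, `vertex<TAB>community`, one line per vertex in
#' stable vertex order. Accepts either a fitted [lpap()] object or a
#' membership vector (named by vertex, or positional).
#'
#' @param x an `"lpap"` fit or a membership vector covering every vertex.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_partition <- function(x, path) {
  if (inherits(x, "lpap")) x <- x$membership
  if (length(x) == 0L) stop("empty partition")
  if (anyNA(x)) stop("unassigned vertex in partition")
  ids <- names(x)
  if (is.null(ids)) ids <- as.character(seq_along(x))
  writeLines(paste(ids, as.character(x), sep = "\t"), path)
  invisible(path)
}

#' Read a community membership file
#'
#' @param path file written by [save_partition()] (or any two-column
#'   `vertex<TAB>community` text file; `#` comments allowed).
#' @return named vector of community labels, names are vertex identifiers.
#' @export
read_partition <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  toks <- strsplit(trimws(lines[keep]), "[ \t]+")
  if (any(lengths(toks) != 2L)) stop("membership file needs 2 tokens per line")
  out <- vapply(toks, `[[`, "", 2L)
  names(out) <- vapply(toks, `[[`, "", 1L)
  out
}

# Connected components by breadth-first search over an adjacency list.
# `restrict`: optional integer vector of vertices; the search then runs in the
# induced subgraph and returns NA for vertices outside it.
bfs_components <- function(adj, restrict = NULL) {
  n <- length(adj)
  comp <- rep.int(NA_integer_, n)
  inside <- if (is.null(restrict)) rep.int(TRUE, n) else {
    x <- rep.int(FALSE, n); x[restrict] <- TRUE; x
  }
  cid <- 0L
  for (s in seq_len(n)) {
    if (!inside[s] || !is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      frontier <- queue
      queue <- integer(0)
      for (v in frontier) {
        for (u in adj[[v]]) {
          if (inside[u] && is.na(comp[u])) {
            comp[u] <- cid
            queue <- c(queue, u)
          }
        }
      }
    }
  }
  comp
}
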