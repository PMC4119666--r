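# The percolation view: a second network over the same vertex set, grown
# alongside a propagation run so that its connected components are exactly the
# label classes. A run that collapses into the trivial one-community solution
# therefore shows up as the emergence of a giant (eventually spanning)
# connected component, which is the structural event the prediction tie-break
# delays.

#' Create a percolation view
#'
#' Starts from `n` isolated vertices (mirroring the unique initial labels).
#' An edge set may be preseeded, mainly for constructing rule scenarios in
#' tests.
#'
#' @param n vertex count of the tracked network.
#' @param edges optional 2-column integer matrix of initial view-edges.
#' @return an object of class `"lpap_view"`: a list with `n` and adjacency
#'   list `adj`.
#' @export
percolation_view <- function(n, edges = NULL) {
  adj <- rep(list(integer(0)), n)
  view <- structure(list(n = n, adj = adj), class = "lpap_view")
  if (!is.null(edges))
    for (r in seq_len(nrow(edges)))
      view <- view_add_edge(view, edges[r, 1L], edges[r, 2L])
  view
}

view_add_edge <- function(view, a, b) {
  if (!(b %in% view$adj[[a]])) {
    view$adj[[a]] <- c(view$adj[[a]], b)
    view$adj[[b]] <- c(view$adj[[b]], a)
  }
  view
}

view_drop_vertex_edges <- function(view, i) {
  for (u in view$adj[[i]]) view$adj[[u]] <- setdiff(view$adj[[u]], i)
  view$adj[[i]] <- integer(0)
  view
}

#' Mirror one label update into the percolation view
#'
#' Applies the network-construction counterpart of a single label change of
#' vertex `i`. A no-op update keeps the view untouched. Otherwise all
#' view-edges at `i` are removed; if that disconnects `i`'s former label
#' class, the minimum number of repair edges is added between former-class
#' members to reconnect it; finally one edge attaches `i` to its new class —
#' preferentially to a member that is also a neighbour of `i` in the original
#' network, falling back to an arbitrary class member. Which admissible
#' vertex receives the edge is drawn at random; any choice yields the same
#' component structure, which is all the view tracks.
#'
#' @param view an `"lpap_view"`.
#' @param net the original `"lpap_network"` (source of neighbourhoods).
#' @param labels label vector *before* the update (`labels[i]` is the old
#'   label).
#' @param i vertex being relabelled.
#' @param new_label the adopted label; its class must be non-empty.
#' @return the updated view.
#' @export
mirror_update <- function(view, net, labels, i, new_label) {
  old <- labels[i]
  if (new_label == old) return(view)
  new_class <- which(labels == new_label)
  if (!length(new_class)) stop("new label names an empty class")
  former <- setdiff(which(labels == old), i)
  view <- view_drop_vertex_edges(view, i)
  if (length(former) > 1L) {
    comp <- bfs_components(view$adj, restrict = former)
    ids <- unique(comp[former])
    if (length(ids) > 1L) {
      anchor <- former[comp[former] == ids[1L]]
      for (cid in ids[-1L]) {
        members <- former[comp[former] == cid]
        view <- view_add_edge(view,
                              anchor[sample.int(length(anchor), 1L)],
                              members[sample.int(length(members), 1L)])
      }
    }
  }
  cand <- intersect(net$adj[[i]], new_class)
  if (!length(cand)) cand <- new_class
  view_add_edge(view, i, cand[sample.int(length(cand), 1L)])
}

#' Size of the largest connected component of the view
#'
#' Mirrors the size of the largest label class of the tracked labeling; `n`
#' once the run has collapsed into the trivial solution.
#'
#' @param view an `"lpap_view"`.
#' @return integer component size (1 in the all-singleton initial state).
#' @export
giant_component_size <- function(view) {
  max(tabulate(bfs_components(view$adj)))
}

#' Check that view components equal label classes
#'
#' @param view an `"lpap_view"`.
#' @param labels the tracked label vector.
#' @return `TRUE` iff the connected components of the view and the label
#'   classes define the same partition of the vertices.
#' @export
view_matches_labels <- function(view, labels) {
  comp <- bfs_components(view$adj)
  identical(match(comp, unique(comp)), match(labels, unique(labels)))
}

#' Replay a traced run through the percolation view
#'
#' Rebuilds the dual network-construction process from a fit produced with
#' `lpap(..., trace = TRUE)`: starting from isolated vertices, every recorded
#' label change is mirrored and the giant-component size recorded.
#'
#' @param fit an `"lpap"` object with a trace.
#' @param check when `TRUE`, verify after every mirrored update that view
#'   components equal label classes (stopping with an error otherwise).
#' @param seed optional seed for the view's internal random choices.
#' @return list with `view` (final `"lpap_view"`) and `giant` (data.frame:
#'   iteration, vertex, old, new, giant component size after each update).
#' @export
replay_percolation <- function(fit, check = FALSE, seed = NULL) {
  stopifnot(inherits(fit, "lpap"))
  if (is.null(fit$trace))
    stop("fit has no trace; rerun lpap() with trace = TRUE")
  net <- fit$network
  labels <- fit$initial_labels
  view <- percolation_view(net$n)
  tr <- fit$trace
  giant <- integer(nrow(tr))
  with_seed(seed, {
    for (r in seq_len(nrow(tr))) {
      i <- tr[r, "vertex"]
      stopifnot(labels[i] == tr[r, "old"])
      view <- mirror_update(view, net, labels, i, tr[r, "new"])
      labels[i] <- tr[r, "new"]
      if (check && !view_matches_labels(view, labels))
        stop("view diverged from labeling at update ", r)
      giant[r] <- giant_component_size(view)
    }
  })
  list(view = view,
       giant = data.frame(iteration = tr[, "iteration"],
                          vertex = tr[, "vertex"],
                          old = tr[, "old"], new = tr[, "new"],
                          giant = giant))
}
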