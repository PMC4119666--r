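#' Label propagation with prediction of the percolation transition
#'
#' Detects communities in an undirected (optionally weighted) network by
#' asynchronous label propagation. Every vertex starts with a unique label;
#' in each iteration the vertices are visited in a fresh random order and each
#' adopts a *maximal label* — a label maximising the (weight-)summed support
#' among its neighbours, always reading the latest labels. The run stops once
#' every vertex's label is maximal for it, and a final breadth-first pass
#' splits any label class whose induced subgraph is disconnected.
#'
#' Plain label propagation (`variant = "lpa"`; WLPA on weighted networks)
#' breaks support ties uniformly at random, which lets a single "monster"
#' community swallow the network. The percolation-prediction variant
#' (`variant = "lpap"`) treats label classes as connected components of a
#' growing dual network: from iteration `prediction_start` on, a
#' vertex facing several maximal labels computes the size each candidate
#' community would have after the update and adopts the label giving the
#' *smallest* one, delaying the giant-component (trivial-solution) onset. Ties
#' on the minimum keep the vertex's current label when it attains it.
#'
#' The incomplete-update gate skips the update of vertex `i` from iteration
#' `gate_start` (default 3) on when its neighbour purity `P_Ni` — the
#' weighted fraction of neighbours sharing its label — signals it is already
#' settled: `gate = "purity"` skips when `P_Ni >= epsilon`;
#' `gate = "purity-degree"` skips when `P_Ni * sign(k_i - k0) >= epsilon`, so
#' vertices with below-mean degree are always updated (their placement matters
#' most for the final division). With `epsilon >= 0.5` every skipped vertex
#' already satisfies the termination condition, so convergence is unaffected;
#' `gate = "purity"` with `epsilon < 0.5` can stall and is only stopped by
#' `max_iter` (a warning is issued up front).
#'
#' Isolated vertices keep their initial label and come out as singleton
#' communities. The run is a pure function of `(net, arguments, seed)`.
#'
#' @param net an [network()] object.
#' @param variant `"lpap"` (minimum-predicted-size tie-break) or `"lpa"`
#'   (uniform random tie-break; classic LPA/WLPA).
#' @param gate `"none"`, `"purity"`, or `"purity-degree"`.
#' @param epsilon gate threshold in `(0, 1]`.
#' @param prediction_start first iteration at which the size prediction is
#'   used for tie-breaking (`"lpap"` only). The default 1 applies it from the
#'   start, as in the algorithm's step-by-step formulation; during the very
#'   first updates all candidate communities have predicted size 2, so the
#'   choice is uniform there anyway, but the prediction starts steering as
#'   soon as classes grow mid-sweep, which is what holds the monster
#'   community back.
#' @param gate_start first iteration at which the gate is applied.
#' @param termination `"stable"` (default) stops after the first sweep in
#'   which no vertex changed its label: every vertex then re-chose its current
#'   label, so the maximal-label condition holds for all of them. Under this
#'   rule plain LPA keeps redrawing support-tied vertices from sweep to sweep
#'   and coalesces further before stopping, which is how a sparse random graph
#'   tends towards the single-community solution; LPAp resolves the same ties
#'   deterministically (minimum predicted size, current label kept when it
#'   attains it) and stops much earlier. `"condition"` instead stops as soon
#'   as every vertex's current label lies in its maximal *set* (ties count as
#'   satisfied), accepting the first tie-ridden fixed point reached even if
#'   random tie-breaking would still move labels around.
#' @param max_iter safety cap on iterations; hitting it flags the result as
#'   non-converged with a warning.
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @param trace logical; when `TRUE` the result records every label change as
#'   a row `(iteration, vertex, old, new)` plus the initial labels, enough to
#'   replay the run (see [replay_percolation()]).
#' @return an object of class `"lpap"`: a list with `membership` (named
#'   community ids `1..N` after the connectivity split), `n_communities`,
#'   `labels` (raw converged labels), `initial_labels`, `iterations`,
#'   `converged`, `modularity`, `sizes`, `trace` (or `NULL`), the `seed`, the
#'   settings, and the `network`.
#' @references The update rule, prediction step and gate are summarised in the
#'   methods vignette: `vignette("lpap-methods", package = "lpaperc")`.
#' @examples
#' gn <- generate_gn(z_out = 4, seed = 7)
#' fit <- lpap(gn$network, seed = 7)
#' fit
#' fvcc(fit$membership, gn$truth)
#' @export
lpap <- function(net, variant = c("lpap", "lpa"),
                 gate = c("none", "purity", "purity-degree"),
                 epsilon = 1,
                 prediction_start = 1L,
                 gate_start = 3L,
                 termination = c("stable", "condition"),
                 max_iter = 100L,
                 seed = NULL,
                 trace = FALSE) {
  stopifnot(inherits(net, "lpap_network"))
  variant <- match.arg(variant)
  gate <- match.arg(gate)
  termination <- match.arg(termination)
  if (gate != "none" && (epsilon <= 0 || epsilon > 1))
    stop("`epsilon` must be in (0, 1]")
  if (gate == "purity" && epsilon < 0.5)
    warning("purity-only gate with epsilon < 0.5: termination is no longer ",
            "guaranteed; max_iter applies")
  res <- with_seed(seed, run_engine(net, variant, gate, epsilon,
                                    as.integer(prediction_start),
                                    as.integer(gate_start),
                                    termination,
                                    as.integer(max_iter), trace))
  if (!res$converged)
    warning("label propagation hit max_iter = ", max_iter,
            " before convergence")
  split <- split_disconnected(net, res$labels)
  structure(
    list(membership = split,
         n_communities = max(split),
         labels = res$labels,
         initial_labels = res$initial_labels,
         iterations = res$iterations,
         converged = res$converged,
         modularity = modularity_q(net, split),
         sizes = as.integer(table(split)),
         trace = res$trace,
         seed = seed,
         variant = variant, gate = gate, epsilon = epsilon,
         prediction_start = prediction_start, gate_start = gate_start,
         termination = termination,
         network = net,
         call = match.call()),
    class = "lpap")
}

# The asynchronous sweep engine. Labels are integers 1..n; `counts` tracks the
# number of holders of each label and is maintained incrementally (the size
# prediction reads it mid-sweep).
run_engine <- function(net, variant, gate, epsilon,
                       prediction_start, gate_start, termination,
                       max_iter, trace) {
  n <- net$n
  adj <- net$adj
  wadj <- net$wadj
  deg <- vapply(wadj, sum, numeric(1))
  k0 <- if (n > 0) sum(deg) / n else 0
  labels <- sample.int(n)           # unique random initial labels
  initial <- labels
  counts <- rep.int(1L, n)
  predict_on <- variant == "lpap"
  tr <- if (trace) vector("list", 512L) else NULL
  tn <- 0L
  converged <- FALSE
  k <- 0L
  while (k < max_iter) {
    k <- k + 1L
    ord <- sample.int(n)
    changed <- 0L
    for (i in ord) {
      nb <- adj[[i]]
      if (!length(nb)) next                      # isolated: trivially settled
      w_nb <- wadj[[i]]
      tab <- rowsum(w_nb, labels[nb], reorder = FALSE)
      s <- tab[, 1L]
      cand <- as.integer(rownames(tab))
      cur <- labels[i]
      if (gate != "none" && k >= gate_start) {
        own <- s[match(cur, cand)]
        if (is.na(own)) own <- 0
        pur <- own / deg[i]
        skip <- if (gate == "purity") pur >= epsilon
                else pur * sign(deg[i] - k0) >= epsilon
        if (skip) next
      }
      mx <- max(s)
      M <- cand[s >= mx - 1e-9 * mx]
      if (length(M) == 1L) {
        new <- M
      } else if (!predict_on || k < prediction_start) {
        new <- M[sample.int(length(M), 1L)]
      } else {
        sizes <- counts[M] + (M != cur)          # community size after update
        mins <- M[sizes == min(sizes)]
        new <- if (cur %in% mins) cur
               else if (length(mins) == 1L) mins
               else mins[sample.int(length(mins), 1L)]
      }
      if (new != cur) {
        changed <- changed + 1L
        counts[cur] <- counts[cur] - 1L
        counts[new] <- counts[new] + 1L
        labels[i] <- new
        if (trace) {
          tn <- tn + 1L
          if (tn > length(tr)) tr <- c(tr, vector("list", length(tr)))
          tr[[tn]] <- c(k, i, cur, new)
        }
      }
    }
    done <- if (termination == "stable") changed == 0L
            else is_converged(net, labels)
    if (done) { converged <- TRUE; break }
  }
  trace_mat <- NULL
  if (trace) {
    trace_mat <- matrix(unlist(tr[seq_len(tn)]), ncol = 4L, byrow = TRUE,
                        dimnames = list(NULL, c("iteration", "vertex",
                                                "old", "new")))
  }
  list(labels = labels, initial_labels = initial, iterations = k,
       converged = converged, trace = trace_mat)
}

#' Neighbour-label support and maximal labels of one vertex
#'
#' The support of label `l` at vertex `i` is the summed weight of the edges
#' from `i` to neighbours currently holding `l`; on an unweighted network this
#' is simply the neighbour count. The maximal labels are the argmax set.
#'
#' @param net an [network()] object.
#' @param labels integer label vector over the vertices.
#' @param i vertex index.
#' @return list with `support` (named numeric, one entry per neighbouring
#'   label) and `maximal` (integer vector of labels attaining the maximum).
#' @export
label_support <- function(net, labels, i) {
  nb <- net$adj[[i]]
  if (!length(nb)) stop("vertex ", i, " is isolated: no neighbour support")
  tab <- rowsum(net$wadj[[i]], labels[nb], reorder = FALSE)
  s <- tab[, 1L]
  cand <- as.integer(rownames(tab))
  names(s) <- cand
  mx <- max(s)
  list(support = s, maximal = cand[s >= mx - 1e-9 * mx])
}

#' Predicted community sizes for candidate labels
#'
#' For each candidate label, the size its label class would have after vertex
#' `i` adopts it: the current holder count plus one, except when the candidate
#' is `i`'s current label (no membership change).
#'
#' @param labels integer label vector.
#' @param i vertex index.
#' @param candidates integer vector of candidate labels (typically the
#'   maximal set from [label_support()]).
#' @return numeric vector aligned with `candidates`.
#' @export
predicted_sizes <- function(labels, i, candidates) {
  counts <- vapply(candidates, function(l) sum(labels == l), numeric(1))
  counts + (candidates != labels[i])
}

#' Tie-break rule among maximal labels
#'
#' With a single maximal label that label is returned. With several and no
#' size information (`sizes = NULL`, the classic rule) one is drawn uniformly
#' at random. With predicted `sizes`, the label with the smallest predicted
#' community is chosen; if several attain the minimum, the vertex's `current`
#' label wins when it is among them, otherwise one minimiser is drawn at
#' random.
#'
#' @param maximal integer vector of maximal labels.
#' @param current the vertex's current label.
#' @param sizes optional numeric vector aligned with `maximal` (see
#'   [predicted_sizes()]).
#' @return the chosen label.
#' @export
choose_label <- function(maximal, current, sizes = NULL) {
  if (length(maximal) == 0L) stop("empty maximal set")
  if (length(maximal) == 1L) return(maximal)
  if (is.null(sizes)) return(maximal[sample.int(length(maximal), 1L)])
  if (length(sizes) != length(maximal))
    stop("`sizes` must align with `maximal`")
  mins <- maximal[sizes == min(sizes)]
  if (current %in% mins) return(current)
  if (length(mins) == 1L) return(mins)
  mins[sample.int(length(mins), 1L)]
}

#' Neighbour purity of a vertex
#'
#' The weighted fraction of a vertex's neighbourhood sharing its label:
#' `sum_{j in N_i} w_ij * [l_j == l_i] / k_i`. Unit weights reduce this to the
#' matching-neighbour fraction.
#'
#' @inheritParams label_support
#' @return a value in `[0, 1]`.
#' @export
neighbor_purity <- function(net, labels, i) {
  nb <- net$adj[[i]]
  if (!length(nb)) stop("vertex ", i, " is isolated: purity undefined")
  w <- net$wadj[[i]]
  sum(w[labels[nb] == labels[i]]) / sum(w)
}

#' Incomplete-update gate
#'
#' Decides whether a vertex's update is skipped. `"purity"` skips when
#' `purity >= epsilon`; `"purity-degree"` skips when
#' `purity * sign(k_i - k0) >= epsilon` (standard signum, `sign(0) = 0`), so a
#' vertex with degree below the network mean is never skipped for any
#' `epsilon > 0`.
#'
#' @param purity neighbour purity of the vertex.
#' @param k_i the vertex's (weighted) degree.
#' @param k0 network mean degree.
#' @param epsilon threshold in `(0, 1]`.
#' @param gate `"purity"` or `"purity-degree"`.
#' @return `TRUE` when the update is skipped.
#' @export
gate_skip <- function(purity, k_i, k0, epsilon,
                      gate = c("purity-degree", "purity")) {
  gate <- match.arg(gate)
  if (gate == "purity") purity >= epsilon
  else purity * sign(k_i - k0) >= epsilon
}

#' Termination condition
#'
#' `TRUE` when every non-isolated vertex currently holds one of its maximal
#' labels (support ties count as satisfied); isolated vertices are trivially
#' satisfied.
#'
#' @inheritParams label_support
#' @return logical flag.
#' @export
is_converged <- function(net, labels) {
  adj <- net$adj
  wadj <- net$wadj
  for (i in seq_len(net$n)) {
    nb <- adj[[i]]
    if (!length(nb)) next
    tab <- rowsum(wadj[[i]], labels[nb], reorder = FALSE)
    s <- tab[, 1L]
    own <- s[match(labels[i], as.integer(rownames(tab)))]
    if (is.na(own)) return(FALSE)
    if (own < max(s) - 1e-9 * max(s)) return(FALSE)
  }
  TRUE
}

#' Split disconnected label classes into connected communities
#'
#' Final step of a propagation run: a breadth-first search over each label
#' class separates vertices that share a label but are not connected inside
#' the class's induced subgraph, so every reported community is connected.
#'
#' @inheritParams label_support
#' @return named integer membership vector with community ids `1..N`, numbered
#'   by first vertex.
#' @export
split_disconnected <- function(net, labels) {
  if (length(labels) != net$n) stop("labeling must cover all vertices")
  # keep only monochromatic edges, then take connected components
  adj2 <- vector("list", net$n)
  for (v in seq_len(net$n)) {
    nb <- net$adj[[v]]
    adj2[[v]] <- nb[labels[nb] == labels[v]]
  }
  comp <- bfs_components(adj2)
  names(comp) <- net$vertices
  comp
}
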