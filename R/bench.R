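# Benchmark harness: the synthetic studies behind the package's headline
# claims, reproducible from a single root seed. Each (network, run, variant)
# cell draws its own derived seed, so every table is a pure function of the
# root seed and rerunning reproduces all non-timing fields exactly.

variant_args <- function(algorithm) {
  switch(algorithm,
    "LPA"     = list(variant = "lpa", gate = "none", epsilon = 1),
    "WLPA"    = list(variant = "lpa", gate = "none", epsilon = 1),
    "LPAp"    = ,
    "LPAp-c"  = list(variant = "lpap", gate = "none", epsilon = 1),
    "LPAp-N"  = list(variant = "lpap", gate = "purity", epsilon = 0.5),
    "LPAp-k"  = list(variant = "lpap", gate = "purity-degree", epsilon = 0.5),
    stop("unknown algorithm: ", algorithm))
}

run_cell <- function(nets, algorithm, n_runs, seed, tag, truths = NULL,
                     epsilon = NULL) {
  args <- variant_args(algorithm)
  if (!is.null(epsilon)) args$epsilon <- epsilon
  ncomm <- numeric(0); q <- numeric(0); acc <- numeric(0); tsec <- numeric(0)
  for (b in seq_along(nets)) {
    for (r in seq_len(n_runs)) {
      s <- derive_seed(seed, tag, algorithm, b, r)
      t0 <- proc.time()[["elapsed"]]
      fit <- do.call(lpap, c(list(net = nets[[b]], seed = s), args))
      tsec <- c(tsec, proc.time()[["elapsed"]] - t0)
      ncomm <- c(ncomm, fit$n_communities)
      q <- c(q, fit$modularity)
      if (!is.null(truths))
        acc <- c(acc, fvcc(fit$membership, truths[[b]]))
    }
  }
  list(ncomm = ncomm, q = q, fvcc = acc, time = tsec)
}

#' Single-community identification study
#'
#' Runs plain label propagation and the prediction variant on the three
#' network classes used to probe whether an algorithm over-divides networks
#' without community structure: one 128-vertex complete graph, ten giant
#' components of Erdos-Renyi graphs (128 vertices, mean degree 4), and ten
#' planted-partition benchmarks at `z_out = 8` (four fuzzy groups).
#' Optionally repeats everything on uniformly reweighted copies. Each
#' algorithm is run `n_runs` times per network; cells report the mean and
#' sample standard deviation of the community count.
#'
#' @param seed root seed; the study is a pure function of it.
#' @param n_networks number of random networks per stochastic class.
#' @param n_runs runs per network and algorithm.
#' @param weighting `"both"`, `"unweighted"` or `"weighted"`.
#' @return a `data.frame` (class `"lpap_experiment"`) with one row per
#'   (network class, weighting, algorithm): mean/sd of the community count,
#'   run counts, and mean wall-clock seconds (informational only).
#' @export
run_single_community_study <- function(seed, n_networks = 10L, n_runs = 10L,
                                       weighting = c("both", "unweighted",
                                                     "weighted")) {
  weighting <- match.arg(weighting)
  modes <- if (weighting == "both") c("unweighted", "weighted") else weighting
  base <- list(
    complete = list(generate_complete(128)),
    er = lapply(seq_len(n_networks), function(b)
      generate_er_giant(128, 4, seed = derive_seed(seed, "er", b))),
    gn = lapply(seq_len(n_networks), function(b)
      generate_gn(z_out = 8, seed = derive_seed(seed, "gn8", b))$network))
  rows <- list()
  for (mode in modes) {
    for (cls in names(base)) {
      nets <- base[[cls]]
      if (mode == "weighted")
        nets <- lapply(seq_along(nets), function(b)
          weight_uniform(nets[[b]], seed = derive_seed(seed, "wu", cls, b)))
      for (alg in c(if (mode == "weighted") "WLPA" else "LPA", "LPAp")) {
        cell <- run_cell(nets, alg, n_runs, seed, paste0("t1-", mode, "-", cls))
        s <- summarize_runs(cell$ncomm)
        rows[[length(rows) + 1L]] <- data.frame(
          network = cls, weighting = mode, algorithm = alg,
          n_networks = length(nets), n_runs = n_runs,
          communities_mean = s[["mean"]], communities_sd = s[["sd"]],
          time_mean = mean(cell$time))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  class(out) <- c("lpap_experiment", class(out))
  out
}

#' Variant comparison study at `z_out = 5`
#'
#' Generates ten planted-partition benchmarks at `z_out = 5` (and, unless
#' disabled, uniformly reweighted copies) and runs four variants on each:
#' plain LPA/WLPA, `LPAp-c` (prediction, complete updates, `epsilon = 1`),
#' `LPAp-N` (purity-only gate, `epsilon = 0.5`) and `LPAp-k` (purity-degree
#' gate, `epsilon = 0.5`). Reports mean/sd modularity per cell, the mean
#' wall-clock time (informational, hardware-dependent), and the relative
#' modularity change `delta_q` of `LPAp-k` against the plain baseline.
#'
#' @inheritParams run_single_community_study
#' @param z_out expected inter-group degree of the benchmark networks.
#' @param epsilon gate threshold applied to the gated variants.
#' @return a `data.frame` (class `"lpap_experiment"`) with one row per
#'   (weighting, algorithm) and attributes `delta_q` and `delta_t` (named by
#'   weighting mode).
#' @export
run_variant_study <- function(seed, z_out = 5, n_networks = 10L, n_runs = 10L,
                              epsilon = 0.5,
                              weighting = c("both", "unweighted", "weighted")) {
  weighting <- match.arg(weighting)
  modes <- if (weighting == "both") c("unweighted", "weighted") else weighting
  gns <- lapply(seq_len(n_networks), function(b)
    generate_gn(z_out = z_out, seed = derive_seed(seed, "gn", z_out, b))$network)
  rows <- list()
  dq <- c(); dt <- c()
  for (mode in modes) {
    nets <- if (mode == "weighted")
      lapply(seq_along(gns), function(b)
        weight_uniform(gns[[b]], seed = derive_seed(seed, "wu", b)))
    else gns
    algs <- c(if (mode == "weighted") "WLPA" else "LPA",
              "LPAp-c", "LPAp-N", "LPAp-k")
    cellq <- list()
    for (alg in algs) {
      eps <- if (alg %in% c("LPAp-N", "LPAp-k")) epsilon else NULL
      cell <- run_cell(nets, alg, n_runs, seed, paste0("t2-", mode),
                       epsilon = eps)
      cellq[[alg]] <- cell
      s <- summarize_runs(cell$q)
      rows[[length(rows) + 1L]] <- data.frame(
        weighting = mode, algorithm = alg,
        n_networks = n_networks, n_runs = n_runs,
        q_mean = s[["mean"]], q_sd = s[["sd"]],
        time_mean = mean(cell$time))
    }
    base <- algs[1L]
    dq[mode] <- delta_q(mean(cellq[[base]]$q), mean(cellq[["LPAp-k"]]$q))
    dt[mode] <- (mean(cellq[[base]]$time) - mean(cellq[["LPAp-k"]]$time)) /
      mean(cellq[["LPAp-k"]]$time) * 100
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  attr(out, "delta_q") <- dq
  attr(out, "delta_t") <- dt
  class(out) <- c("lpap_experiment", class(out))
  out
}

#' Accuracy sweep over the inter-community degree
#'
#' For each `z_out` value, generates `n_networks` planted-partition
#' benchmarks and runs each algorithm `n_runs` times per network, recording
#' the fraction of vertices classified correctly (FVCC, against the planted
#' groups) and the community count. As `z_out` grows the planted structure
#' fades and the FVCC means decay.
#'
#' @param z_out_values numeric vector in `[0, 16]`.
#' @inheritParams run_single_community_study
#' @param algorithms algorithm labels understood by the harness
#'   (`"LPA"`, `"LPAp"`, ...).
#' @param file optional path; when given the table is also written as CSV.
#' @return a `data.frame` (class `"lpap_experiment"`) with one row per
#'   (`z_out`, algorithm): FVCC mean/sd and community-count mean/sd.
#' @export
run_fvcc_sweep <- function(z_out_values, seed, n_networks = 10L, n_runs = 10L,
                           algorithms = c("LPA", "LPAp"), file = NULL) {
  if (any(z_out_values < 0 | z_out_values > 16))
    stop("`z_out_values` must lie in [0, 16]")
  rows <- list()
  for (z in z_out_values) {
    gen <- lapply(seq_len(n_networks), function(b)
      generate_gn(z_out = z, seed = derive_seed(seed, "sweep", z, b)))
    nets <- lapply(gen, `[[`, "network")
    truths <- lapply(gen, `[[`, "truth")
    for (alg in algorithms) {
      cell <- run_cell(nets, alg, n_runs, seed, paste0("sweep-", z),
                       truths = truths)
      sf <- summarize_runs(cell$fvcc)
      sn <- summarize_runs(cell$ncomm)
      rows[[length(rows) + 1L]] <- data.frame(
        z_out = z, algorithm = alg,
        n_networks = n_networks, n_runs = n_runs,
        fvcc_mean = sf[["mean"]], fvcc_sd = sf[["sd"]],
        communities_mean = sn[["mean"]], communities_sd = sn[["sd"]])
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  class(out) <- c("lpap_experiment", class(out))
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

#' @export
print.lpap_experiment <- function(x, digits = 2, ...) {
  cat("Seeded benchmark study (seed ", attr(x, "seed"), ")\n", sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  print(df, row.names = FALSE)
  if (!is.null(attr(x, "delta_q"))) {
    cat("delta_Q (%):", paste(names(attr(x, "delta_q")),
                              round(attr(x, "delta_q"), 1), collapse = "; "),
        "\n")
    cat("delta_t (%, informational):",
        paste(names(attr(x, "delta_t")), round(attr(x, "delta_t"), 1),
              collapse = "; "), "\n")
  }
  invisible(x)
}
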