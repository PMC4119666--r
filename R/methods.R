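#' @export
print.lpap <- function(x, ...) {
  alg <- if (x$variant == "lpap") "label propagation + percolation prediction"
         else "label propagation"
  cat(sprintf("Community detection by %s\n", alg))
  if (x$gate != "none")
    cat(sprintf("  incomplete updates: %s gate, epsilon = %g\n",
                x$gate, x$epsilon))
  cat(sprintf("  %d vertices, %d communities, Q = %.2f, %d iteration%s%s\n",
              x$network$n, x$n_communities, x$modularity, x$iterations,
              if (x$iterations == 1) "" else "s",
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' @export
summary.lpap <- function(object, ...) {
  structure(
    list(fit = object,
         size_summary = summary(object$sizes),
         m = sum(object$network$weights)),
    class = "summary.lpap")
}

#' @export
print.summary.lpap <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  total edge weight m = %g\n", x$m))
  cat("  community sizes:\n")
  print(x$size_summary)
  szs <- sort(x$fit$sizes, decreasing = TRUE)
  cat("  largest communities:", paste(utils::head(szs, 5), collapse = ", "),
      "\n")
  invisible(x)
}

#' Plot community sizes of a fit
#'
#' Barplot of the community sizes in decreasing order; a quick visual check
#' for a monster community (one bar spanning the whole network) versus a
#' balanced division.
#'
#' @param x an `"lpap"` fit.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.lpap <- function(x, ...) {
  graphics::barplot(sort(x$sizes, decreasing = TRUE),
                    xlab = "community (by size rank)",
                    ylab = "vertices",
                    main = sprintf("%d communities, Q = %.2f",
                                   x$n_communities, x$modularity), ...)
  invisible(x)
}

#' Communities of a fit as vertex-id lists
#'
#' @param fit an `"lpap"` fit.
#' @return list of character vectors, one per community.
#' @export
communities <- function(fit) {
  stopifnot(inherits(fit, "lpap"))
  split(names(fit$membership), fit$membership)
}
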