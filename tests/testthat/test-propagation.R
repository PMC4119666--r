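test_that("label support sums neighbour weights per label", {
  star <- network(data.frame(u = c("i", "i", "i"), v = c("a", "b", "c")))
  # neighbours a, b, c hold labels 4, 4, 3; i holds 9
  labs <- c(9L, 4L, 4L, 3L)
  s <- label_support(star, labs, 1L)
  expect_equal(s$support, c("4" = 2, "3" = 1))
  expect_equal(s$maximal, 4L)

  two <- network(data.frame(u = c("i", "i"), v = c("a", "b")))
  s2 <- label_support(two, c(9L, 4L, 3L), 1L)
  expect_setequal(s2$maximal, c(4L, 3L))     # tie

  w <- network(data.frame(u = c("i", "i", "i"), v = c("a", "b", "c"),
                          w = c(2, 1, 0.5)))
  s3 <- label_support(w, c(9L, 7L, 8L, 8L), 1L)
  expect_equal(unname(s3$support[c("7", "8")]), c(2, 1.5))
  expect_equal(s3$maximal, 7L)

  iso <- network(data.frame(u = "a", v = "b"), vertices = c("a", "b", "z"))
  expect_error(label_support(iso, c(1L, 1L, 2L), 3L), "isolated")
})

test_that("predicted sizes count the candidate class after the update", {
  # counts {4: 4, 3: 1}, focal vertex in neither class
  labs <- c(rep(4L, 4), 3L, 9L)
  expect_equal(predicted_sizes(labs, 6L, c(4L, 3L)), c(5, 2))
  # candidate equals the current label: no membership change
  labs2 <- c(rep(7L, 3), 2L)
  expect_equal(predicted_sizes(labs2, 1L, 7L), 3)
  # all-singleton start
  expect_equal(predicted_sizes(c(1L, 2L, 3L), 1L, 2L), 2)
})

test_that("the tie-break picks the smallest predicted community", {
  expect_equal(choose_label(c(4L, 3L), current = 9L, sizes = c(5, 2)), 3L)
  expect_equal(choose_label(7L, current = 1L), 7L)
  expect_equal(choose_label(7L, current = 1L, sizes = 12), 7L)
  # current label wins ties on the minimum
  expect_equal(choose_label(c(4L, 3L), current = 3L, sizes = c(2, 2)), 3L)
  # without sizes the draw is uniform
  set.seed(42)
  draws <- replicate(1e4, choose_label(c(1L, 2L), current = 9L))
  expect_lt(abs(mean(draws == 1L) - 0.5), 0.02)
})

test_that("neighbour purity is the weighted matching fraction", {
  star4 <- network(data.frame(u = rep("i", 4), v = c("a", "b", "c", "d")))
  expect_equal(neighbor_purity(star4, c(5L, 5L, 5L, 5L, 6L), 1L), 0.75)
  expect_equal(neighbor_purity(star4, rep(5L, 5), 1L), 1)
  w <- network(data.frame(u = c("i", "i"), v = c("a", "b"), w = c(2, 1)))
  expect_equal(neighbor_purity(w, c(5L, 5L, 6L), 1L), 2 / 3)
})

test_that("the incomplete-update gate spares low-degree vertices", {
  # below-mean degree: never skipped whatever the purity
  expect_false(gate_skip(1, k_i = 3, k0 = 4, epsilon = 0.5))
  expect_false(gate_skip(1, k_i = 3, k0 = 4, epsilon = 1e-9))
  # at the mean: sign is 0, product 0 < epsilon
  expect_false(gate_skip(0.9, k_i = 4, k0 = 4, epsilon = 0.5))
  # above the mean with high purity: skipped
  expect_true(gate_skip(0.8, k_i = 6, k0 = 4, epsilon = 0.5))
  # purity-only mode ignores the degree
  expect_true(gate_skip(0.8, k_i = 3, k0 = 4, epsilon = 0.5, gate = "purity"))
  expect_false(gate_skip(0.4, k_i = 3, k0 = 4, epsilon = 0.5, gate = "purity"))
})

test_that("the termination condition accepts maximal-set members", {
  fig <- two_triangle_bridge()
  expect_true(is_converged(fig, rep(4L, 6)))            # trivial state
  expect_true(is_converged(fig, c(1L, 1L, 1L, 2L, 2L, 2L)))
  # a label with zero support anywhere fails
  expect_false(is_converged(fig, c(9L, 1L, 1L, 2L, 2L, 2L)))
})

test_that("disconnected label classes are split by the final search", {
  twotri <- network(data.frame(u = c("a", "b", "a", "d", "e", "d"),
                               v = c("b", "c", "c", "e", "f", "f")))
  memb <- split_disconnected(twotri, rep(7L, 6))
  expect_equal(max(memb), 2L)
  expect_true(same_partition(memb, c(1, 1, 1, 2, 2, 2)))
  # already-connected classes are untouched
  memb2 <- split_disconnected(twotri, c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_true(same_partition(memb2, c(1, 1, 1, 2, 2, 2)))
  path <- network(data.frame(u = c("a", "b"), v = c("b", "c")))
  expect_equal(max(split_disconnected(path, c(1L, 2L, 1L))), 3L)
})

test_that("runs on disconnected networks keep components apart", {
  twotri <- network(data.frame(u = c("a", "b", "a", "d", "e", "d"),
                               v = c("b", "c", "c", "e", "f", "f")))
  for (s in 1:5) {
    fit <- lpap(twotri, seed = s)
    expect_equal(fit$n_communities, 2L)
    expect_true(fit$converged)
  }
})

test_that("every terminating run on the bridge graph is trivial or two triangles", {
  fig <- two_triangle_bridge()
  ok <- list(rep(1, 6), c(1, 1, 1, 2, 2, 2))
  for (s in 1:30) {
    for (v in c("lpa", "lpap")) {
      fit <- lpap(fig, variant = v, seed = derive_seed(s, v))
      hit <- any(vapply(ok, function(p) same_partition(fit$membership, p),
                        logical(1)))
      expect_true(hit, info = paste("variant", v, "seed", s))
    }
  }
})

test_that("runs are deterministic given network and seed", {
  net <- generate_gn(z_out = 5, seed = 3)$network
  a <- lpap(net, seed = 17, trace = TRUE)
  b <- lpap(net, seed = 17, trace = TRUE)
  expect_identical(a$membership, b$membership)
  expect_identical(a$trace, b$trace)
  expect_identical(a$initial_labels, b$initial_labels)
  expect_identical(a$iterations, b$iterations)
})

test_that("converged runs satisfy the maximal-label condition everywhere", {
  for (s in 1:6) {
    for (net in small_test_networks(s)) {
      for (cfg in list(list(variant = "lpa"),
                       list(variant = "lpap"),
                       list(variant = "lpap", gate = "purity-degree",
                            epsilon = 0.5),
                       list(variant = "lpap", gate = "purity",
                            epsilon = 0.5))) {
        fit <- suppressWarnings(
          do.call(lpap, c(list(net = net, seed = derive_seed(s, "conv")), cfg)))
        if (fit$converged) expect_true(is_converged(net, fit$labels))
      }
    }
  }
})

test_that("incremental label counts agree with a recount after the run", {
  net <- generate_gn(z_out = 4, seed = 5)$network
  fit <- lpap(net, seed = 21, trace = TRUE)
  lab <- fit$initial_labels
  if (!is.null(fit$trace) && nrow(fit$trace))
    for (r in seq_len(nrow(fit$trace))) {
      expect_identical(lab[[fit$trace[r, "vertex"]]], fit$trace[[r, "old"]])
      lab[fit$trace[r, "vertex"]] <- fit$trace[r, "new"]
    }
  expect_identical(lab, fit$labels)
})

test_that("prediction only changes tie handling", {
  # generic continuous weights make support ties measure-zero, so lpa and
  # lpap consume identical randomness and must produce identical runs
  net <- weight_uniform(generate_gn(z_out = 5, seed = 6)$network, seed = 13)
  a <- lpap(net, variant = "lpa", seed = 31, trace = TRUE)
  b <- lpap(net, variant = "lpap", seed = 31, trace = TRUE)
  expect_identical(a$trace, b$trace)
  expect_identical(a$membership, b$membership)
})

test_that("gated vertices already satisfy the termination condition", {
  # with the purity-degree gate and epsilon >= 0.5, a skipped vertex has
  # above-mean degree and majority support for its own label
  for (s in 1:5) {
    net <- small_test_networks(s)[[1L]]
    fit <- lpap(net, gate = "purity-degree", epsilon = 0.5,
                seed = derive_seed(s, "gatecheck"))
    if (fit$converged) expect_true(is_converged(net, fit$labels))
    d <- degrees(net)
    for (i in seq_len(net$n)) {
      if (length(net$adj[[i]]) == 0) next
      pur <- neighbor_purity(net, fit$labels, i)
      if (gate_skip(pur, d$k[[i]], d$k0, 0.5)) {
        expect_true(fit$labels[i] %in% label_support(net, fit$labels, i)$maximal)
      }
    }
  }
})

test_that("edge cases: isolated vertices, warnings, max_iter flag", {
  iso <- network(data.frame(u = "a", v = "b"), vertices = c("a", "b", "z"))
  fit <- lpap(iso, seed = 1)
  expect_true(fit$converged)
  expect_equal(fit$n_communities, 2L)
  expect_warning(lpap(iso, gate = "purity", epsilon = 0.3, seed = 1),
                 "epsilon < 0.5")
  # a forced non-convergent setting flags the result
  net <- generate_gn(z_out = 8, seed = 2)$network
  expect_warning(f2 <- lpap(net, variant = "lpa", max_iter = 1L, seed = 3),
                 "max_iter")
  expect_false(f2$converged)
})
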