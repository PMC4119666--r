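test_that("edge lists parse into valid networks", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# a comment", "a\tb", "b c", "a\tc"), p)
  net <- read_edge_list(p)
  expect_s3_class(net, "lpap_network")
  expect_equal(net$n, 3L)
  expect_equal(nrow(net$edges), 3L)
  expect_true(all(net$weights == 1))
  expect_equal(net$vertices, c("a", "b", "c"))  # first-appearance order

  writeLines("1\t2\t0.5", p)
  w <- read_edge_list(p, weighted = TRUE)
  d <- degrees(w)
  expect_equal(unname(d$k), c(0.5, 0.5))
  expect_equal(d$m, 0.5)
})

test_that("malformed input is rejected with a line number", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines("1\t1\t1.0", p)
  expect_error(read_edge_list(p, weighted = TRUE), "self-loop")
  writeLines(c("a\tb", "a"), p)
  expect_error(read_edge_list(p), "line 2")
  writeLines("a\tb\t-1", p)
  expect_error(read_edge_list(p, weighted = TRUE), "line 1")
  writeLines("# only comments", p)
  expect_error(read_edge_list(p), "empty edge set")
  writeLines(c("a\tb\t1", "b\ta\t2"), p)
  expect_error(read_edge_list(p, weighted = TRUE), "conflicting weight")
  # identical duplicates are idempotent
  writeLines(c("a\tb\t1.5", "b\ta\t1.5"), p)
  expect_equal(nrow(read_edge_list(p, weighted = TRUE)$edges), 1L)
})

test_that("degree accounting matches hand computations", {
  tri <- network(data.frame(u = c("a", "b", "a"), v = c("b", "c", "c")))
  d <- degrees(tri)
  expect_equal(unname(d$k), c(2, 2, 2))
  expect_equal(d$m, 3)
  expect_equal(d$k0, 2)

  half <- network(data.frame(u = c("a", "b", "a"), v = c("b", "c", "c"),
                             w = rep(0.5, 3)))
  dh <- degrees(half)
  expect_equal(unname(dh$k), c(1, 1, 1))
  expect_equal(dh$m, 1.5)

  fig <- two_triangle_bridge()
  df <- degrees(fig)
  expect_equal(df$m, 7)
  expect_equal(sum(df$k), 14)
})

test_that("2m equals the degree sum on generated networks", {
  for (s in 1:5) {
    net <- generate_gn(z_out = 5, seed = s)$network
    d <- degrees(net)
    expect_identical(sum(d$k), 2 * d$m)
    wnet <- weight_uniform(net, seed = s)
    dw <- degrees(wnet)
    expect_equal(sum(dw$k), 2 * dw$m, tolerance = 1e-12)
  }
})

test_that("edge-list writer/reader round-trips weights bit-exactly", {
  net <- weight_uniform(generate_gn(z_out = 3, seed = 4)$network, seed = 9)
  # decimal weights with <= 12 significant digits
  net <- reweight(net, signif(net$weights, 12))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, p, header = "round-trip fixture")
  back <- read_edge_list(p, weighted = TRUE)
  expect_equal(back$n, net$n)
  # vertex numbering may differ (first-appearance order); compare by name
  key <- function(x) {
    u <- x$vertices[x$edges[, 1L]]
    v <- x$vertices[x$edges[, 2L]]
    k <- paste(pmin(u, v), pmax(u, v))
    stats::setNames(x$weights, k)[order(k)]
  }
  expect_identical(key(back), key(net))
})

test_that("partition files round-trip and reject bad input", {
  p <- withr::local_tempfile(fileext = ".tsv")
  memb <- c(a = 1L, b = 1L, c = 2L)
  save_partition(memb, p)
  expect_equal(length(readLines(p)), 3L)
  back <- read_partition(p)
  expect_equal(names(back), names(memb))
  expect_true(same_partition(back, memb))
  expect_error(save_partition(integer(0), p), "empty")
  expect_error(save_partition(c(a = 1L, b = NA), p), "unassigned")
})

test_that("isolated vertices can be declared via a vertex file", {
  pe <- withr::local_tempfile(fileext = ".tsv")
  pv <- withr::local_tempfile(fileext = ".txt")
  writeLines("a\tb", pe)
  writeLines(c("a", "b", "lonely"), pv)
  net <- read_edge_list(pe, vertex_path = pv)
  expect_equal(net$n, 3L)
  expect_equal(degrees(net)$k[["lonely"]], 0)
  fit <- lpap(net, seed = 1)
  expect_equal(fit$n_communities, 2L)  # the pair plus a singleton
})
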