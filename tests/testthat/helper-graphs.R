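# Shared fixtures and independent oracles, all built in code.

# Six-vertex example: two triangles a-b-c and d-e-f joined by the bridge c-d.
# Its two-community division has Q = 5/14; the trivial division has Q = 0.
two_triangle_bridge <- function() {
  network(data.frame(u = c("a", "b", "a", "d", "e", "d", "c"),
                     v = c("b", "c", "c", "e", "f", "f", "d")))
}

# Canonical form of a partition given as a membership vector: community ids
# renumbered by first appearance, so two vectors describe the same set
# partition iff their canonical forms are identical.
canon_partition <- function(memb) match(memb, unique(memb))

same_partition <- function(a, b) identical(canon_partition(as.vector(a)),
                                           canon_partition(as.vector(b)))

# All set partitions of n elements as membership vectors (restricted growth
# strings). Bell(6) = 203, fine for exhaustive checks.
all_set_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, mx) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(mx + 1L)) grow(c(prefix, v), max(mx, v))
  }
  grow(integer(0), 0L)
  out
}

# Independent FVCC oracle: sum over detected communities of the largest
# overlap with any truth community, divided by n (no explicit mapping step).
fvcc_oracle <- function(membership, truth) {
  n <- length(membership)
  tot <- 0L
  for (d in unique(membership)) {
    tt <- truth[membership == d]
    tot <- tot + max(table(tt))
  }
  as.numeric(tot) / n
}

# A small pool of seeded test networks for property-style loops.
small_test_networks <- function(seed) {
  list(
    generate_gn(z_out = 1, n_comm = 4L, comm_size = 8L, mean_degree = 4,
                seed = derive_seed(seed, "gn-small"))$network,
    generate_er_giant(40, 3, seed = derive_seed(seed, "er-small")),
    weight_uniform(generate_gn(z_out = 2, n_comm = 2L, comm_size = 16L,
                               mean_degree = 6,
                               seed = derive_seed(seed, "gn2"))$network,
                   seed = derive_seed(seed, "wu")))
}
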