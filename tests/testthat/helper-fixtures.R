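# Shared fixtures: toy networks built in code, independent oracles.

# Two proteins joined by one PPI edge; no functions.
two_node_tm <- function(weights = node_class_weights()) {
  net <- build_network(
    ppi = data.frame(protein_a = "PA", protein_b = "PB",
                     stringsAsFactors = FALSE),
    annotations = data.frame(protein = character(0), func = character(0),
                             stringsAsFactors = FALSE),
    hierarchy = data.frame(child = character(0), parent = character(0),
                           stringsAsFactors = FALSE))
  build_transition_matrix(net, weights)
}

# Small random multiscale network (proteins + functions + annotations +
# hierarchy) as a transition matrix; deterministic per seed.
random_net <- function(seed, n_proteins = 30L, n_functions = 8L) {
  cfg <- simulation_config(n_proteins = n_proteins,
                           n_functions = n_functions,
                           ppi_attach_edges = 2L, annotation_rate = 1,
                           n_herbs = 2L, n_disease_proteins = 5L,
                           seed = seed)
  inter <- simulate_interactome(cfg)
  build_network(inter$ppi, inter$annotations, inter$hierarchy)
}

random_tm <- function(seed, n_proteins = 30L, n_functions = 8L,
                      weights = node_class_weights()) {
  build_transition_matrix(random_net(seed, n_proteins, n_functions),
                          weights)
}

# Independent upper-tail hypergeometric oracle: explicit combinatorial sum
# P(X >= k) for drawing n from M with N successes.
enum_hypergeom_upper <- function(k, n, N, M) {
  if (k == 0) return(1)
  i <- seq(k, min(n, N))
  sum(choose(N, i) * choose(M - N, n - i)) / choose(M, n)
}

# Hand-rolled Benjamini-Hochberg step-up, independent of p.adjust.
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Unbiased simple-random-walk transition matrix of a multiscale network,
# built directly from adjacency (ignores node classes).
unbiased_rw_matrix <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges[c("from", "to")],
                                     directed = FALSE,
                                     vertices = net$nodes$id)
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  A <- A[net$nodes$id, net$nodes$id]
  deg <- Matrix::rowSums(A)
  inv <- ifelse(deg > 0, 1 / deg, 0)
  Matrix::Diagonal(x = inv) %*% A
}

write_fixture_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
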