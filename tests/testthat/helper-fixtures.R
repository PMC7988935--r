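# Assemble a clone_map_data object directly from matrices, bypassing the
# join filters (gibbs tests need full control over every entry).
make_cmd <- function(A, D, omega, cluster = NULL, G = NULL) {
  counts <- allele_counts(A, D)
  geno <- clone_genotypes(omega)
  if (is.null(cluster)) cluster <- counts$cell_ids      # all singletons
  clustering <- input_clustering(counts$cell_ids, cluster)
  if (!is.null(G)) {
    dimnames(G) <- list(counts$cell_ids, clustering$cluster_ids)
  }
  structure(list(genotypes = geno, counts = counts, clustering = clustering,
                 G = G,
                 report = list(mutations = c(before = nrow(A), after = nrow(A)),
                               cells = c(before = ncol(A), after = ncol(A)),
                               clusters = c(before = length(clustering$cluster_ids),
                                            after = length(clustering$cluster_ids)),
                               cell_filter = "none (fixture)")),
            class = "clone_map_data")
}

# small random instance with guaranteed coverage, for property loops
random_cmd <- function(N, M, K, Q, seed) {
  set.seed(seed)
  repeat {
    D <- matrix(rpois(N * M, 1.2), N, M)
    if (all(rowSums(D) > 0) && all(colSums(D) > 0)) break
  }
  A <- matrix(rbinom(N * M, D, 0.4), N, M)
  omega <- matrix(rbinom(N * K, 1, 0.5), N, K)
  cluster <- paste0("q", sample.int(Q, M, replace = TRUE))
  # ensure all Q clusters appear
  cluster[seq_len(min(Q, M))] <- paste0("q", seq_len(min(Q, M)))
  G <- matrix(sample(0:3, M * Q, replace = TRUE), M, Q)
  cmd <- make_cmd(A, D, omega, cluster)
  G[cbind(seq_len(M), cmd$clustering$cluster_index)] <- 0
  dimnames(G) <- list(cmd$counts$cell_ids, cmd$clustering$cluster_ids)
  cmd$G <- G
  cmd
}
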