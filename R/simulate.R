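#' Simulation configuration
#'
#' Describes the synthetic study conditions: a tumor of K clones with a
#' perfect-phylogeny genotype structure, M cells partitioned into a
#' singleton-dominated clonotype clustering (Q multiplet clusters plus one
#' singleton cluster per remaining cell), sparse binomial allele counts,
#' genotype errors at rate `xi_true`, and a partially wrong input
#' clustering.
#'
#' @param K clones (default 4).
#' @param N mutations (default 80).
#' @param M cells (default 400).
#' @param Q multiplet clusters (default 50); the cells not placed in
#'   multiplets each form their own singleton cluster.
#' @param multiplet_fraction fraction of cells in multiplet clusters
#'   (default 0.5).
#' @param cluster_sizes optional explicit sizes (must sum to M; overrides
#'   Q/multiplet_fraction; sizes of 1 are singletons).
#' @param size_exponent power-law exponent of the multiplet size
#'   distribution (default 2).
#' @param coverage_rate fraction of (mutation, cell) entries with coverage
#'   (default 0.15).
#' @param depth_mean mean total UMI count on covered entries (default 2);
#'   depths are 1 + Poisson(depth_mean - 1) so covered entries have D >= 1.
#' @param theta0_true background alternative-allele rate (default 0.01).
#' @param theta_true per-position alternative-allele rates; NULL (default)
#'   draws them from Beta(2.25, 2.65).
#' @param xi_true genotype error rate applied to the true genotypes
#'   (default 0.05).
#' @param misclustered_fraction fraction of cells whose input cluster
#'   differs from their true cluster (default 0.05).
#' @param bcr_distance_scale mean BCR distance between unrelated clusters
#'   (default 4); misclustered cells sit at distance 1 from their true
#'   cluster.
#' @param seed RNG seed (default 1).
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(K = 4, N = 80, M = 400, Q = 50,
                       multiplet_fraction = 0.5, cluster_sizes = NULL,
                       size_exponent = 2, coverage_rate = 0.15,
                       depth_mean = 2, theta0_true = 0.01,
                       theta_true = NULL, xi_true = 0.05,
                       misclustered_fraction = 0.05,
                       bcr_distance_scale = 4, seed = 1) {
  stopifnot(K >= 2, N >= 1, M >= 1, Q >= 1)
  rates <- c(multiplet_fraction, coverage_rate, theta0_true, xi_true,
             misclustered_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (coverage_rate == 0) stop("coverage_rate = 0 yields no data")
  if (!is.null(cluster_sizes) && sum(cluster_sizes) != M) {
    stop("explicit cluster sizes must sum to M")
  }
  structure(list(K = K, N = N, M = M, Q = Q,
                 multiplet_fraction = multiplet_fraction,
                 cluster_sizes = cluster_sizes,
                 size_exponent = size_exponent,
                 coverage_rate = coverage_rate, depth_mean = depth_mean,
                 theta0_true = theta0_true, theta_true = theta_true,
                 xi_true = xi_true,
                 misclustered_fraction = misclustered_fraction,
                 bcr_distance_scale = bcr_distance_scale,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate clone genotypes with input errors
#'
#' Builds a random perfect-phylogeny genotype matrix: clone 1 is the base
#' (normal) clone with an all-zero genotype; every other clone attaches to
#' a random earlier clone and acquires a private block of mutations, its
#' genotype being the union of blocks along its root-to-leaf path. The N
#' mutations are partitioned over the K-1 branches with at least one
#' mutation per branch. The observed input genotypes are the truth with
#' each entry flipped independently with probability `xi_true`.
#'
#' Uses the current RNG state (seed upstream for reproducibility).
#'
#' @param K clones (>= 2).
#' @param N mutations (>= K-1).
#' @param xi_true flip probability of each genotype entry.
#' @return list with binary `C_true` (N x K) and `omega`
#'   (a [clone_genotypes]).
#' @export
simulate_genotypes <- function(K, N, xi_true = 0) {
  if (N < K - 1) {
    stop("need N >= K-1 so every non-base clone gets a private mutation")
  }
  parent <- c(NA, vapply(2:K, function(k) {
    if (k == 2) 1L else sample.int(k - 1, 1)
  }, integer(1)))
  # partition mutations over branches leading into clones 2..K
  extra <- if (K == 2) N - 1 else {
    as.vector(stats::rmultinom(1, N - (K - 1), rep(1, K - 1)))
  }
  n_branch <- 1 + extra
  branch_of_mut <- sample(rep(2:K, times = n_branch))   # shuffled order
  C_true <- matrix(0L, N, K)
  for (k in 2:K) {
    path <- k
    a <- k
    while (!is.na(parent[a])) {
      a <- parent[a]
      path <- c(path, a)
    }
    C_true[branch_of_mut %in% path, k] <- 1L
  }
  dimnames(C_true) <- list(paste0("chr1:", seq_len(N), ":A:T"),
                           paste0("C", seq_len(K)))
  flip <- matrix(stats::runif(N * K) < xi_true, N, K)
  omega <- ifelse(flip, 1L - C_true, C_true)
  dimnames(omega) <- dimnames(C_true)
  list(C_true = C_true, omega = clone_genotypes(omega))
}

# multiplet sizes (>= 2) from a truncated power law, adjusted to the target
.multiplet_sizes <- function(q, total, exponent) {
  stopifnot(total >= 2 * q)
  support <- 2:max(2, total - 2 * (q - 1))
  w <- support^(-exponent)
  sizes <- sample(support, q, replace = TRUE, prob = w)
  # repair the total while keeping every size >= 2
  diff <- total - sum(sizes)
  while (diff != 0) {
    i <- which.max(sizes)
    if (diff > 0) {
      sizes[i] <- sizes[i] + diff
      diff <- 0
    } else {
      take <- min(-diff, sizes[i] - 2)
      if (take == 0) i <- sample.int(q, 1)  # all at floor; rotate
      sizes[i] <- sizes[i] - take
      diff <- diff + take
    }
  }
  sort(sizes, decreasing = TRUE)
}

#' Simulate cells, counts, clustering, and distances
#'
#' Given true genotypes, builds the true cell clustering (multiplet sizes
#' from a truncated power law plus singletons), assigns every cluster a
#' true clone, then draws sparse allele-specific counts: each (mutation,
#' cell) entry is covered with probability `coverage_rate`, covered depths
#' are 1 + Poisson(depth_mean - 1), and alternative counts are binomial
#' with success `theta_i` where the cell's clone carries mutation i and
#' `theta0` elsewhere. The input clustering moves a fraction of
#' multiplet-cluster cells to a random other cluster; the BCR distance
#' matrix puts every cell at 0 from its input cluster, 1 from its true
#' cluster when misclustered, and unrelated clusters at
#' 2 + Poisson(bcr_distance_scale - 2).
#'
#' Uses the current RNG state.
#'
#' @param sim a [sim_config].
#' @param C_true binary N x K true genotype matrix.
#' @param omega a [clone_genotypes] (the error-bearing input genotypes).
#' @return list with `data` (a ready \code{clone_map_data}), `counts`,
#'   `clustering`, `G`, and `truth` (true clone of each cluster and cell,
#'   true cluster of each cell, theta/theta0/xi used, multiplet flag per
#'   cell).
#' @export
simulate_cells <- function(sim, C_true, omega) {
  K <- sim$K; N <- sim$N; M <- sim$M
  if (is.null(sim$cluster_sizes)) {
    n_mult_cells <- round(M * sim$multiplet_fraction)
    n_mult_cells <- max(n_mult_cells, 2 * sim$Q)
    sizes <- c(.multiplet_sizes(sim$Q, n_mult_cells, sim$size_exponent),
               rep(1L, M - n_mult_cells))
  } else {
    sizes <- sim$cluster_sizes
  }
  Qtot <- length(sizes)
  cluster_ids <- paste0("B", seq_len(Qtot))
  cell_ids <- paste0("cell", seq_len(M))
  true_cluster <- rep(seq_len(Qtot), times = sizes)
  clone_of_cluster <- sample.int(K, Qtot, replace = TRUE)
  clone_of_cell <- clone_of_cluster[true_cluster]

  theta <- if (is.null(sim$theta_true)) {
    stats::rbeta(N, 2.25, 2.65)
  } else {
    rep(sim$theta_true, length.out = N)
  }
  theta <- pmin(pmax(theta, 1e-6), 1 - 1e-6)

  covered <- matrix(stats::runif(N * M) < sim$coverage_rate, N, M)
  D <- matrix(0L, N, M)
  n_cov <- sum(covered)
  D[covered] <- 1L + stats::rpois(n_cov, max(sim$depth_mean - 1, 0))
  carries <- C_true[, clone_of_cell, drop = FALSE] == 1
  pmat <- matrix(sim$theta0_true, N, M)
  pmat[carries] <- theta[row(pmat)[carries]]
  A <- matrix(0L, N, M)
  A[covered] <- stats::rbinom(n_cov, D[covered], pmat[covered])
  counts <- allele_counts(A, D, mutation_ids = rownames(C_true),
                          cell_ids = cell_ids)

  # input clustering: move some multiplet cells to a random other cluster
  input_cluster <- true_cluster
  movable <- which(sizes[true_cluster] >= 2)
  n_move <- round(sim$misclustered_fraction * M)
  moved <- if (n_move > 0 && length(movable) > 0) {
    sample(movable, min(n_move, length(movable)))
  } else integer(0)
  cur_size <- tabulate(input_cluster, nbins = Qtot)
  kept_moves <- integer(0)
  for (j in moved) {
    if (cur_size[input_cluster[j]] <= 1) next   # never empty a cluster
    dest <- sample(setdiff(seq_len(Qtot), true_cluster[j]), 1)
    cur_size[input_cluster[j]] <- cur_size[input_cluster[j]] - 1
    cur_size[dest] <- cur_size[dest] + 1
    input_cluster[j] <- dest
    kept_moves <- c(kept_moves, j)
  }
  moved <- kept_moves
  clustering <- input_clustering(cell_ids, cluster_ids[input_cluster],
                                 cluster_ids = cluster_ids)

  G <- matrix(2 + stats::rpois(M * Qtot, max(sim$bcr_distance_scale - 2, 0)),
              M, Qtot, dimnames = list(cell_ids, cluster_ids))
  G[cbind(seq_len(M), true_cluster)] <- 1
  G[cbind(seq_len(M), input_cluster)] <- 0

  data <- structure(list(
    genotypes = omega, counts = counts, clustering = clustering, G = G,
    report = list(mutations = c(before = N, after = N),
                  cells = c(before = M, after = M),
                  clusters = c(before = Qtot, after = Qtot),
                  cell_filter = "none (simulated)")),
    class = "clone_map_data")

  list(data = data, counts = counts, clustering = clustering, G = G,
       truth = list(C_true = C_true, clone_of_cluster = clone_of_cluster,
                    clone_of_cell = clone_of_cell,
                    true_cluster = true_cluster,
                    input_cluster = input_cluster, moved_cells = moved,
                    theta = theta, theta0 = sim$theta0_true,
                    xi = sim$xi_true,
                    multiplet_cell = sizes[true_cluster] >= 2))
}

#' Simulate a complete dataset
#'
#' Seeds the RNG from the configuration and runs [simulate_genotypes()]
#' followed by [simulate_cells()].
#'
#' @param sim a [sim_config].
#' @return list with `data` (\code{clone_map_data}) and `truth`; identical
#'   for identical configurations.
#' @export
simulate_dataset <- function(sim = sim_config()) {
  stopifnot(inherits(sim, "sim_config"))
  set.seed(sim$seed)
  geno <- simulate_genotypes(sim$K, sim$N, sim$xi_true)
  out <- simulate_cells(sim, geno$C_true, geno$omega)
  out$truth$C_true <- geno$C_true
  out
}

#' Write a simulated dataset in the package's file formats
#'
#' @param simdata result of [simulate_dataset()].
#' @param dir output directory; writes genotypes.tsv, alt.mtx, total.mtx,
#'   mutations.txt, barcodes.txt, clusters.tsv, distances.tsv, truth.json.
#' @export
write_simulation <- function(simdata, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(simdata$data$genotypes, file.path(dir, "genotypes.tsv"))
  write_counts(simdata$data$counts, dir)
  write_clustering(simdata$data$clustering, file.path(dir, "clusters.tsv"))
  write_distances(simdata$data$G, file.path(dir, "distances.tsv"))
  tr <- simdata$truth
  jsonlite::write_json(
    list(clone_of_cluster = tr$clone_of_cluster,
         clone_of_cell = tr$clone_of_cell,
         true_cluster = tr$true_cluster,
         theta0 = tr$theta0, xi = tr$xi,
         multiplet_cell = tr$multiplet_cell),
    file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}

#' Exact posterior by enumeration (theta and xi clamped)
#'
#' Computes the exact marginals P(I_q = k), P(T_j = q) and the cell-level
#' clone probabilities by summing the unnormalized joint
#' P(I) P(T|p) P(C|Omega, xi) P(A|D, C, I, T, theta) over all joint
#' states, in log space. theta and xi are held fixed because jointly
#' marginalizing them with C has no closed form; the Gibbs variant under
#' comparison should clamp them identically. The sum over T factorizes
#' over cells given (I, C), so only the K^Q x 2^(N K) grid is enumerated
#' explicitly.
#'
#' @param data a \code{clone_map_data}.
#' @param theta0,theta clamped success probabilities.
#' @param xi clamped genotype error rate.
#' @param p optional [switch_probabilities]; default from data (see
#'   [gibbs_data()]).
#' @param c switch-prior strength when p is computed from distances.
#' @param max_states guard on the full joint size
#'   K^Q * Q^M * 2^(N K) (default 1e7).
#' @return list with `cluster_clone_prob` (Q x K), `cell_cluster_prob`
#'   (M x Q), `cell_clone_prob` (M x K), and `log_evidence`.
#' @export
enumerate_posterior <- function(data, theta0, theta, xi, p = NULL, c = 2,
                                max_states = 1e7) {
  gd <- gibbs_data(data, p = p, c = c)
  size <- gd$K^gd$Q * gd$Q^gd$M * 2^(gd$N * gd$K)
  if (size > max_states) {
    stop(sprintf("joint state space too large: %.3g > %.3g", size,
                 max_states))
  }
  theta <- rep(theta, length.out = gd$N)
  ll <- .loglik_mats(gd, theta0, theta)
  nC <- 2^(gd$N * gd$K)
  nI <- gd$K^gd$Q
  Idigits <- function(idx) (idx %/% gd$K^(seq_len(gd$Q) - 1)) %% gd$K + 1

  lw_all <- numeric(nC * nI)
  cc_acc <- matrix(0, gd$Q, gd$K)
  tq_acc <- matrix(0, gd$M, gd$Q)
  ck_acc <- matrix(0, gd$M, gd$K)
  # store per-state contributions, normalize at the end
  cc_list <- vector("list", nC * nI)
  s <- 0L
  for (ci in 0:(nC - 1)) {
    bits <- as.integer(intToBits(ci))[seq_len(gd$N * gd$K)]
    C <- matrix(bits, gd$N, gd$K)
    prior1 <- abs(gd$omega - xi)
    lpC <- sum(log(ifelse(C == 1, prior1, 1 - prior1)))
    if (!is.finite(lpC)) next                     # zero-prior C configuration
    cl_ll <- .cell_clone_loglik(ll, C)            # M x K
    for (ii in 0:(nI - 1)) {
      s <- s + 1L
      I <- Idigits(ii)
      lw_cells <- gd$logp + cl_ll[, I, drop = FALSE]   # M x Q
      mx <- apply(lw_cells, 1, max)
      wc <- exp(lw_cells - mx)
      rs <- rowSums(wc)
      lw <- lpC + sum(mx + log(rs)) - gd$Q * log(gd$K)
      Tpost <- wc / rs                            # P(T_j = q | C, I)
      idx <- (ci * nI + ii) + 1L
      lw_all[idx] <- lw
      cc_list[[idx]] <- list(I = I, Tpost = Tpost)
    }
  }
  keep <- which(vapply(cc_list, Negate(is.null), logical(1)))
  lws <- lw_all[keep]
  mx <- max(lws)
  w <- exp(lws - mx)
  w <- w / sum(w)
  for (s2 in seq_along(keep)) {
    st <- cc_list[[keep[s2]]]
    cc_acc[cbind(seq_len(gd$Q), st$I)] <-
      cc_acc[cbind(seq_len(gd$Q), st$I)] + w[s2]
    tq_acc <- tq_acc + w[s2] * st$Tpost
    # cell inherits the clone of its cluster: sum over q of Tpost * 1[I_q=k]
    for (k in seq_len(gd$K)) {
      qk <- which(st$I == k)
      if (length(qk)) {
        ck_acc[, k] <- ck_acc[, k] +
          w[s2] * rowSums(st$Tpost[, qk, drop = FALSE])
      }
    }
  }
  dimnames(cc_acc) <- list(gd$cluster_ids, gd$clone_ids)
  dimnames(tq_acc) <- list(gd$cell_ids, gd$cluster_ids)
  dimnames(ck_acc) <- list(gd$cell_ids, gd$clone_ids)
  list(cluster_clone_prob = cc_acc, cell_cluster_prob = tq_acc,
       cell_clone_prob = ck_acc,
       log_evidence = mx + log(sum(exp(lws - mx))))
}
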