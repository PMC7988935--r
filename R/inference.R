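#' Inference configuration
#'
#' @param max_iters Gibbs sweeps per chain (default 20000).
#' @param n_chains number of independently initialized chains (default 10).
#' @param burn_in_frac fraction of sweeps discarded as burn-in, in (0,1)
#'   (default 0.5).
#' @param thin record the cell-level (T) and genotype-level (C) summaries
#'   every `thin`-th retained sweep; I, xi and theta0 are recorded every
#'   sweep (default 1).
#' @param master_seed integer seed; every chain derives its own stream from
#'   (master_seed, chain index) so the full run is reproducible.
#' @param hp a [hyperparameters] object (includes the switch-prior
#'   strength c).
#' @param update_theta,update_xi,update_T,update_C set FALSE to clamp a
#'   block at its initial value (used for oracle comparisons on clamped
#'   models).
#' @param init optional named list overriding initial values (any of
#'   `theta0`, `theta`, `xi`, `I`, `T`, `C`); combined with the update
#'   flags this clamps parameters at chosen values.
#' @return object of class \code{inference_config}.
#' @export
inference_config <- function(max_iters = 20000, n_chains = 10,
                             burn_in_frac = 0.5, thin = 1, master_seed = 1,
                             hp = hyperparameters(),
                             update_theta = TRUE, update_xi = TRUE,
                             update_T = TRUE, update_C = TRUE, init = NULL) {
  stopifnot(max_iters >= 1, n_chains >= 1, thin >= 1,
            inherits(hp, "hyperparameters"))
  if (burn_in_frac <= 0 || burn_in_frac >= 1) {
    stop("burn_in_frac must lie strictly between 0 and 1")
  }
  if (floor(max_iters * (1 - burn_in_frac)) < 1) {
    stop("configuration retains zero post-burn-in samples")
  }
  structure(list(max_iters = as.integer(max_iters),
                 n_chains = as.integer(n_chains),
                 burn_in_frac = burn_in_frac, thin = as.integer(thin),
                 master_seed = as.integer(master_seed), hp = hp,
                 update_theta = update_theta, update_xi = update_xi,
                 update_T = update_T, update_C = update_C, init = init),
            class = "inference_config")
}

.chain_seed <- function(master_seed, chain_index) {
  as.integer((as.numeric(master_seed) + 104729 * chain_index) %% 2147483629)
}

#' Initialize a Gibbs chain
#'
#' Deterministic given (master seed, chain index): the corrected clustering
#' starts at the input clustering, the corrected genotypes at the input
#' genotypes, xi and the thetas at their prior means; only the
#' cluster-to-clone assignment I is drawn uniformly at random, which is
#' what differs between starting points.
#'
#' @param gd a [gibbs_data()] object.
#' @param config an [inference_config] object.
#' @param chain_index chain number (1-based).
#' @return a Gibbs state list (I, T, C, theta0, theta, xi).
#' @export
initialize_state <- function(gd, config, chain_index = 1) {
  hp <- config$hp
  set.seed(.chain_seed(config$master_seed, chain_index))
  if (gd$K == 1) warning("K = 1: all clusters assigned to the single clone")
  state <- list(I = sample.int(gd$K, gd$Q, replace = TRUE),
                T = gd$cluster_index,
                C = gd$omega,
                theta0 = hp$v0[1] / sum(hp$v0),
                theta = rep(hp$v1[1] / sum(hp$v1), gd$N),
                xi = hp$kappa[1] / sum(hp$kappa))
  for (nm in names(config$init)) state[[nm]] <- config$init[[nm]]
  state
}

#' Run one Gibbs chain
#'
#' Executes `max_iters` systematic sweeps in the fixed order I, theta, T,
#' C, xi, recording full traces of xi, theta0 and the log joint, the
#' cluster-assignment trace I, and post-burn-in tallies for all posterior
#' summaries. Fully reproducible from (master_seed, chain_index).
#'
#' @inheritParams initialize_state
#' @return object of class \code{gibbs_trace}.
#' @export
run_chain <- function(gd, config, chain_index = 1) {
  state <- initialize_state(gd, config, chain_index)  # also seeds the RNG
  n_it <- config$max_iters
  burn <- floor(n_it * config$burn_in_frac)
  xi_tr <- numeric(n_it); th0_tr <- numeric(n_it); lj_tr <- numeric(n_it)
  I_tr <- matrix(0L, n_it, gd$Q)
  cc_counts <- matrix(0, gd$Q, gd$K,
                      dimnames = list(gd$cluster_ids, gd$clone_ids))
  cellclone <- matrix(0, gd$M, gd$K,
                      dimnames = list(gd$cell_ids, gd$clone_ids))
  cellclust <- matrix(0, gd$M, gd$Q,
                      dimnames = list(gd$cell_ids, gd$cluster_ids))
  C_sum <- matrix(0, gd$N, gd$K, dimnames = dimnames(gd$omega))
  n_thin_kept <- 0L
  cell_seq <- seq_len(gd$M)

  for (it in seq_len(n_it)) {
    ll <- .loglik_mats(gd, state$theta0, state$theta)
    state$I <- .sample_I(state, gd, ll)
    if (config$update_theta) {
      th <- sample_theta(theta_stats(state, gd), config$hp)
      state$theta0 <- th$theta0
      state$theta <- th$theta
      ll <- .loglik_mats(gd, state$theta0, state$theta)
    }
    if (config$update_T) state$T <- .sample_T(state, gd, ll)
    if (config$update_C) state$C <- .sample_C(state, gd, ll)
    if (config$update_xi) {
      state$xi <- sample_xi(state$C, gd$omega, config$hp$kappa)
    }

    xi_tr[it] <- state$xi
    th0_tr[it] <- state$theta0
    lj <- .log_joint(state, gd, config$hp, ll = NULL)
    if (!is.finite(lj)) {
      stop(sprintf(paste0("non-finite log joint at iteration %d of chain %d ",
                          "(xi=%.3g, theta0=%.3g)"),
                   it, chain_index, state$xi, state$theta0))
    }
    lj_tr[it] <- lj
    I_tr[it, ] <- state$I
    if (it > burn) {
      cc_counts[cbind(seq_len(gd$Q), state$I)] <-
        cc_counts[cbind(seq_len(gd$Q), state$I)] + 1
      if ((it - burn) %% config$thin == 0L) {
        n_thin_kept <- n_thin_kept + 1L
        clone_of_cell <- state$I[state$T]
        cellclone[cbind(cell_seq, clone_of_cell)] <-
          cellclone[cbind(cell_seq, clone_of_cell)] + 1
        cellclust[cbind(cell_seq, state$T)] <-
          cellclust[cbind(cell_seq, state$T)] + 1
        C_sum <- C_sum + state$C
      }
    }
  }
  structure(list(xi = xi_tr, theta0 = th0_tr, log_joint = lj_tr,
                 I_trace = I_tr, burn = burn, n_kept = n_it - burn,
                 n_thin_kept = n_thin_kept, cc_counts = cc_counts,
                 cellclone_counts = cellclone, cellclust_counts = cellclust,
                 C_sum = C_sum, chain_index = chain_index,
                 seed = .chain_seed(config$master_seed, chain_index),
                 final_state = state),
            class = "gibbs_trace")
}

#' Cell-to-clone posterior probabilities from a trace
#'
#' At each retained sweep a cell inherits the clone of its current
#' corrected cluster (I composed with T); the posterior probability is the
#' fraction of retained sweeps spent in each clone, marginalizing over the
#' cluster correction. Rows sum to 1.
#'
#' @param trace a \code{gibbs_trace} (or list of traces, in which case the
#'   first is used).
#' @return M x K row-stochastic matrix.
#' @export
cell_clone_probabilities <- function(trace) {
  if (!inherits(trace, "gibbs_trace") && is.list(trace)) trace <- trace[[1]]
  stopifnot(inherits(trace, "gibbs_trace"), trace$n_thin_kept > 0)
  trace$cellclone_counts / trace$n_thin_kept
}

#' Summarize Gibbs chains into a posterior report
#'
#' Discards burn-in (already excluded from the per-chain tallies), selects
#' the chain with the highest mean post-burn-in log joint as the reporting
#' chain, and turns its tallies into posterior probability matrices and MAP
#' assignments (ties broken toward the lowest clone index and counted in
#' the diagnostics). Cross-chain agreement — the maximum absolute
#' difference in cluster-to-clone probabilities between the reporting chain
#' and every other chain, after clone-label alignment on the corrected
#' genotypes — is reported as a convergence diagnostic.
#'
#' @param traces list of \code{gibbs_trace} objects (>= 1).
#' @param config the [inference_config] used.
#' @return object of class \code{posterior_summary}.
#' @export
summarize_chains <- function(traces, config) {
  if (inherits(traces, "gibbs_trace")) traces <- list(traces)
  if (length(traces) == 0) stop("no completed chains to summarize")
  mean_lj <- vapply(traces, function(tr) {
    mean(tr$log_joint[(tr$burn + 1):length(tr$log_joint)])
  }, numeric(1))
  best <- which.max(mean_lj)
  tr <- traces[[best]]

  cluster_clone_prob <- tr$cc_counts / tr$n_kept
  cell_clone_prob <- tr$cellclone_counts / tr$n_thin_kept
  cell_cluster_prob <- tr$cellclust_counts / tr$n_thin_kept
  genotype_prob <- tr$C_sum / tr$n_thin_kept

  map_of <- function(pm) max.col(pm, ties.method = "first")
  n_ties <- function(pm) {
    sum(apply(pm, 1, function(r) sum(r == max(r)) > 1))
  }
  map_clone_of_cluster <- map_of(cluster_clone_prob)
  map_clone_of_cell <- map_of(cell_clone_prob)
  map_cluster_of_cell <- map_of(cell_cluster_prob)
  prev <- tabulate(map_clone_of_cell, nbins = ncol(cell_clone_prob))
  corrected_prevalence <- prev / sum(prev)
  names(corrected_prevalence) <- colnames(cell_clone_prob)

  cross <- NA_real_
  if (length(traces) > 1) {
    cross <- 0
    for (o in setdiff(seq_along(traces), best)) {
      tro <- traces[[o]]
      perm <- align_clone_labels(genotype_prob, tro$C_sum / tro$n_thin_kept)
      cross <- max(cross,
                   max(abs(cluster_clone_prob -
                           (tro$cc_counts / tro$n_kept)[, perm])))
    }
  }

  keep <- (tr$burn + 1):length(tr$xi)
  structure(list(
    cluster_clone_prob = cluster_clone_prob,
    cell_clone_prob = cell_clone_prob,
    cell_cluster_prob = cell_cluster_prob,
    genotype_prob = genotype_prob,
    xi_samples = tr$xi[keep], theta0_samples = tr$theta0[keep],
    map_clone_of_cluster = map_clone_of_cluster,
    map_clone_of_cell = map_clone_of_cell,
    map_cluster_of_cell = map_cluster_of_cell,
    corrected_prevalence = corrected_prevalence,
    best_chain = best,
    diagnostics = list(mean_log_joint = mean_lj,
                       max_cross_chain_diff = cross,
                       n_map_ties = n_ties(cell_clone_prob)),
    config = config),
    class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("posterior_summary:", nrow(x$cell_clone_prob), "cells,",
      nrow(x$cluster_clone_prob), "clusters,",
      ncol(x$cluster_clone_prob), "clones\n")
  cat("  posterior mean xi:", signif(mean(x$xi_samples), 3),
      " theta0:", signif(mean(x$theta0_samples), 3), "\n")
  cat("  corrected prevalences:",
      paste(signif(x$corrected_prevalence, 3), collapse = " "), "\n")
  invisible(x)
}

#' Run the full multi-chain inference
#'
#' @param data a \code{clone_map_data} object from [join_axes()] or
#'   [simulate_dataset()].
#' @param config an [inference_config] object.
#' @param p optional precomputed [switch_probabilities]; defaults to the
#'   softmax of the dataset's distance matrix at strength \code{config$hp$c}
#'   (uniform if the dataset has no distances).
#' @return a \code{posterior_summary}.
#' @export
run_inference <- function(data, config = inference_config(), p = NULL) {
  gd <- gibbs_data(data, p = p, c = config$hp$c)
  traces <- lapply(seq_len(config$n_chains), function(ch) {
    run_chain(gd, config, ch)
  })
  summarize_chains(traces, config)
}

# ---- clone label alignment --------------------------------------------------

# exhaustive lexicographic permutation generator (K <= 8 only)
.perms_lex <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- .perms_lex(k - 1L)
  out <- matrix(0L, 0, k)
  for (first in seq_len(k)) {
    rest <- setdiff(seq_len(k), first)
    out <- rbind(out, cbind(first, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# Hungarian algorithm (shortest augmenting path, O(n^3)) for square cost
# matrices; returns for each row its assigned column
.hungarian <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n)
  v <- numeric(n + 1)
  p <- integer(n + 1)      # p[jj]: row matched to column jj-1 (jj=1 virtual)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (jj in 2:(n + 1)) {
        if (!used[jj]) {
          cur <- cost[i0, jj - 1] - u[i0] - v[jj]
          if (cur < minv[jj]) { minv[jj] <- cur; way[jj] <- j0 }
          if (minv[jj] < delta) { delta <- minv[jj]; j1 <- jj }
        }
      }
      for (jj in seq_len(n + 1)) {
        if (used[jj]) {
          if (p[jj] > 0) u[p[jj]] <- u[p[jj]] + delta
          v[jj] <- v[jj] - delta
        } else {
          minv[jj] <- minv[jj] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0) break
    }
    repeat {
      j1 <- way[j0]; p[j0] <- p[j1]; j0 <- j1
      if (j0 == 1) break
    }
  }
  assignment <- integer(n)
  for (jj in 2:(n + 1)) assignment[p[jj]] <- jj - 1L
  assignment
}

#' Align clone labels between two corrected-genotype sets
#'
#' Two runs (or two methods) correcting the same input genotypes may end up
#' with permuted clone labels. This finds the permutation `perm` minimizing
#' the total column-wise L1 distance `sum_k ||a[,k] - b[,perm[k]]||_1`, so
#' that clones with the most similar corrected genotypes share a label.
#' For K <= 8 all K! permutations are scanned in lexicographic order (ties
#' resolve to the lexicographically smallest); larger K uses the Hungarian
#' assignment on the pairwise column-distance matrix.
#'
#' @param geno_a,geno_b N x K matrices in [0,1] over the same mutation
#'   axis.
#' @return integer permutation of 1..K: column k of `geno_a` matches column
#'   `perm[k]` of `geno_b`.
#' @export
align_clone_labels <- function(geno_a, geno_b) {
  if (!all(dim(geno_a) == dim(geno_b))) {
    stop("genotype matrices must have the same shape")
  }
  k <- ncol(geno_a)
  cost <- matrix(0, k, k)
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      cost[a, b] <- sum(abs(geno_a[, a] - geno_b[, b]))
    }
  }
  if (k <= 8) {
    perms <- .perms_lex(k)
    costs <- apply(perms, 1, function(pp) sum(cost[cbind(seq_len(k), pp)]))
    perms[which.min(costs), ]     # first minimum = lexicographically smallest
  } else {
    .hungarian(cost)
  }
}

# ---- pipeline output --------------------------------------------------------

.write_prob_matrix <- function(pm, id_col, path) {
  tab <- data.frame(rownames(pm), pm, check.names = FALSE)
  colnames(tab)[1] <- id_col
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run inference and write all outputs to a directory
#'
#' Joins the inputs, builds the switch prior, runs the multi-chain Gibbs
#' sampler, and writes: cluster_clone_prob.tsv, cell_clone_prob.tsv,
#' cell_cluster_prob.tsv, corrected_genotypes.tsv, assignments.tsv
#' (cell, MAP clone, MAP cluster, max probability), xi_trace.csv,
#' theta0_trace.csv and run_summary.json. Output bytes are a pure function
#' of (inputs, config, master seed).
#'
#' @param genotypes a [clone_genotypes] object.
#' @param counts an [allele_counts] object.
#' @param clustering an [input_clustering] object.
#' @param distances optional cells x clusters distance matrix.
#' @param config an [inference_config] object.
#' @param out_dir output directory (created if absent).
#' @param cell_filter passed to [join_axes()].
#' @return the \code{posterior_summary}, invisibly.
#' @export
run_pipeline <- function(genotypes, counts, clustering, distances = NULL,
                         config = inference_config(), out_dir,
                         cell_filter = "alt") {
  data <- join_axes(genotypes, counts, clustering, distances = distances,
                    cell_filter = cell_filter)
  post <- run_inference(data, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  .write_prob_matrix(post$cluster_clone_prob, "cluster",
                     file.path(out_dir, "cluster_clone_prob.tsv"))
  .write_prob_matrix(post$cell_clone_prob, "barcode",
                     file.path(out_dir, "cell_clone_prob.tsv"))
  .write_prob_matrix(post$cell_cluster_prob, "barcode",
                     file.path(out_dir, "cell_cluster_prob.tsv"))
  .write_prob_matrix(post$genotype_prob, "mutation_id",
                     file.path(out_dir, "corrected_genotypes.tsv"))

  clone_ids <- colnames(post$cell_clone_prob)
  cluster_ids <- colnames(post$cell_cluster_prob)
  assignments <- data.frame(
    barcode = rownames(post$cell_clone_prob),
    map_clone = clone_ids[post$map_clone_of_cell],
    map_cluster = cluster_ids[post$map_cluster_of_cell],
    max_probability = apply(post$cell_clone_prob, 1, max))
  utils::write.table(assignments, file.path(out_dir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(xi = post$xi_samples),
                     file.path(out_dir, "xi_trace.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(theta0 = post$theta0_samples),
                     file.path(out_dir, "theta0_trace.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)

  summary <- list(
    config = list(max_iters = config$max_iters, n_chains = config$n_chains,
                  burn_in_frac = config$burn_in_frac, thin = config$thin,
                  master_seed = config$master_seed, c = config$hp$c,
                  kappa = config$hp$kappa, v0 = config$hp$v0,
                  v1 = config$hp$v1),
    chain_seeds = vapply(seq_len(config$n_chains), function(ch) {
      .chain_seed(config$master_seed, ch)
    }, integer(1)),
    filter_report = data$report,
    best_chain = post$best_chain,
    diagnostics = post$diagnostics,
    posterior_mean_xi = mean(post$xi_samples),
    posterior_mean_theta0 = mean(post$theta0_samples),
    corrected_prevalence = as.list(post$corrected_prevalence))
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(post)
}
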