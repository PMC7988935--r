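#' Binomial log-likelihood of one allele-count entry
#'
#' Log-probability of observing `A_ij` alternative-allele transcripts out of
#' `D_ij` total, under the per-position success probability `theta_i` when
#' the assigned clone carries the mutation, and under the background rate
#' `theta0` otherwise. Entries without coverage (D = 0) contribute log 1 = 0.
#'
#' @param A_ij,D_ij non-negative integers, `A_ij <= D_ij` (vectorized).
#' @param carries_mut 0/1: does the clone carry the mutation at this
#'   position?
#' @param theta0,theta_i success probabilities in (0,1).
#' @return log-likelihood value(s).
#' @export
loglik_entry <- function(A_ij, D_ij, carries_mut, theta0, theta_i) {
  if (any(theta0 <= 0 | theta0 >= 1) || any(theta_i <= 0 | theta_i >= 1)) {
    stop("theta parameters must lie strictly inside (0,1)")
  }
  if (any(A_ij < 0) || any(A_ij > D_ij)) stop("need 0 <= A <= D")
  th <- ifelse(carries_mut == 1, theta_i, theta0)
  out <- ifelse(D_ij == 0, 0, stats::dbinom(A_ij, D_ij, th, log = TRUE))
  out
}

# Dense working copy of a joined dataset plus the switch prior; everything
# the samplers touch per sweep lives here precomputed.
#
# A, D: dense N x M; mask: D > 0; lc: binomial coefficient term (masked);
# omega: N x K; p/logp: M x Q.

#' Assemble the working dataset for the Gibbs sampler
#'
#' @param data a \code{clone_map_data} object from [join_axes()] (or the
#'   simulator).
#' @param p optional [switch_probabilities]; when NULL, computed from
#'   \code{data$G} with strength \code{c}, or uniform if no distances are
#'   available.
#' @param c prior strength used when p must be computed (default 2).
#' @return list of dense matrices and dimensions used by the samplers.
#' @export
gibbs_data <- function(data, p = NULL, c = 2) {
  stopifnot(inherits(data, "clone_map_data"))
  A <- as.matrix(data$counts$alt)
  D <- as.matrix(data$counts$total)
  N <- nrow(A); M <- ncol(A)
  K <- ncol(data$genotypes$omega)
  Q <- length(data$clustering$cluster_ids)
  if (is.null(p)) {
    p <- if (is.null(data$G)) {
      switch_probabilities(matrix(0, M, Q,
                                  dimnames = list(colnames(A),
                                                  data$clustering$cluster_ids)),
                           c = 0)
    } else {
      switch_probabilities(data$G, c = c)
    }
  }
  stopifnot(inherits(p, "switch_probabilities"),
            nrow(p$p) == M, ncol(p$p) == Q)
  mask <- D > 0
  list(A = A, D = D, mask = mask,
       lc = ifelse(mask, lchoose(D, A), 0),
       omega = data$genotypes$omega,
       p = p$p, logp = log(p$p),
       cluster_index = data$clustering$cluster_index,
       N = N, M = M, K = K, Q = Q,
       mutation_ids = rownames(A), cell_ids = colnames(A),
       clone_ids = colnames(data$genotypes$omega),
       cluster_ids = data$clustering$cluster_ids)
}

# per-entry log-likelihood matrices under theta0 (ll0) and theta_i (ll1);
# uncovered entries are exactly 0
.loglik_mats <- function(gd, theta0, theta) {
  ll1 <- gd$lc + gd$A * log(theta) + (gd$D - gd$A) * log1p(-theta)
  ll0 <- gd$lc + gd$A * log(theta0) + (gd$D - gd$A) * log1p(-theta0)
  ll1[!gd$mask] <- 0
  ll0[!gd$mask] <- 0
  list(ll0 = ll0, ll1 = ll1)
}

# M x K: log-likelihood of each cell's counts under each clone's genotype
.cell_clone_loglik <- function(ll, C) {
  t(ll$ll1) %*% C + t(ll$ll0) %*% (1 - C)
}

# row-wise normalization of a log-weight matrix; max-subtraction keeps the
# largest term at exp(0) so underflow can only hit negligible terms
.norm_rows <- function(lw) {
  mx <- apply(lw, 1, max)
  w <- exp(lw - mx)
  w / rowSums(w)
}

# one exact categorical draw per row of a log-weight matrix (Gumbel-max)
.sample_rows <- function(lw) {
  g <- -log(-log(stats::runif(length(lw))))
  max.col(lw + matrix(g, nrow(lw), ncol(lw)), ties.method = "first")
}

#' Conditional probabilities of cluster-to-clone assignments
#'
#' For every cluster q, the full conditional P(I_q = k | rest): a uniform
#' prior over clones times the product, over cells currently in q under the
#' corrected clustering T and over covered positions, of the binomial
#' likelihood under clone k's corrected genotype. A cluster currently empty
#' under T gets the uniform prior (its likelihood is an empty product).
#'
#' @param state Gibbs state: list with I, T, C, theta0, theta, xi.
#' @param gd a [gibbs_data()] object.
#' @param ll optional precomputed log-likelihood matrices.
#' @return Q x K row-stochastic matrix.
#' @export
clone_assignment_probs <- function(state, gd, ll = NULL) {
  if (is.null(ll)) ll <- .loglik_mats(gd, state$theta0, state$theta)
  cl_ll <- .cell_clone_loglik(ll, state$C)
  Z <- matrix(0, gd$M, gd$Q)
  Z[cbind(seq_len(gd$M), state$T)] <- 1
  lw <- t(Z) %*% cl_ll                 # Q x K, zero rows for empty clusters
  .norm_rows(lw)
}

.sample_I <- function(state, gd, ll) {
  cl_ll <- .cell_clone_loglik(ll, state$C)
  Z <- matrix(0, gd$M, gd$Q)
  Z[cbind(seq_len(gd$M), state$T)] <- 1
  .sample_rows(t(Z) %*% cl_ll)
}

#' Sufficient statistics for the allelic success probabilities
#'
#' Totals of alternative (`u`) and reference (`v`) transcript counts split
#' by whether the clone assigned to each cell's cluster carries the
#' mutation at each position: positions not carried pool into the
#' background totals `u0`, `v0`; carried positions accumulate per-position
#' totals `u[i]`, `v[i]`. Uncovered entries contribute zero, and every
#' covered read lands on exactly one side, so
#' `u0 + v0 + sum(u + v) == sum(D)`.
#'
#' @inheritParams clone_assignment_probs
#' @return list with scalars `u0`, `v0` and length-N vectors `u`, `v`.
#' @export
theta_stats <- function(state, gd) {
  clone_of_cell <- state$I[state$T]
  Cc <- state$C[, clone_of_cell, drop = FALSE]   # N x M carry indicator
  u <- rowSums(gd$A * Cc)
  v <- rowSums((gd$D - gd$A) * Cc)
  u0 <- sum(gd$A) - sum(u)
  v0 <- sum(gd$D - gd$A) - sum(v)
  list(u0 = u0, v0 = v0, u = u, v = v)
}

#' Conjugate update of the allelic success probabilities
#'
#' Draws `theta0 ~ Beta(alpha0 + u0, beta0 + v0)` and independently
#' `theta_i ~ Beta(alpha1 + u_i, beta1 + v_i)` (beta-binomial conjugacy).
#' Draws are clamped to the open interval to keep downstream logs finite.
#'
#' @param stats output of [theta_stats()].
#' @param hp a [hyperparameters] object.
#' @return list with `theta0` (scalar) and `theta` (length-N vector).
#' @export
sample_theta <- function(stats, hp) {
  eps <- 1e-12
  theta0 <- stats::rbeta(1, hp$v0[1] + stats$u0, hp$v0[2] + stats$v0)
  theta <- stats::rbeta(length(stats$u), hp$v1[1] + stats$u,
                        hp$v1[2] + stats$v)
  list(theta0 = min(max(theta0, eps), 1 - eps),
       theta = pmin(pmax(theta, eps), 1 - eps))
}

#' Conditional probabilities of corrected cluster memberships
#'
#' For every cell j, the full conditional P(T_j = q | rest): the switch
#' prior p_{j,q} times the cell's own likelihood under the clone currently
#' assigned to candidate cluster q. Cells without covered positions, or
#' configurations where all clusters map to the same clone, reduce exactly
#' to the switch prior.
#'
#' @inheritParams clone_assignment_probs
#' @return M x Q row-stochastic matrix.
#' @export
cluster_membership_probs <- function(state, gd, ll = NULL) {
  if (is.null(ll)) ll <- .loglik_mats(gd, state$theta0, state$theta)
  cl_ll <- .cell_clone_loglik(ll, state$C)
  .norm_rows(gd$logp + cl_ll[, state$I, drop = FALSE])
}

.sample_T <- function(state, gd, ll) {
  cl_ll <- .cell_clone_loglik(ll, state$C)
  .sample_rows(gd$logp + cl_ll[, state$I, drop = FALSE])
}

#' Conditional probabilities of corrected genotype entries
#'
#' For every (mutation i, clone k), the full conditional
#' P(C_{i,k} = 1 | rest). The prior is the input genotype flipped with
#' error rate xi, written compactly as `|Omega_{i,k} - xi|`; the likelihood
#' ratio pools the counts at position i over all cells whose corrected
#' cluster is currently assigned to clone k. With no such cells the
#' conditional equals the prior exactly. Entries are conditionally
#' independent given (I, T, theta, xi), so the whole matrix is updated as
#' one block.
#'
#' @inheritParams clone_assignment_probs
#' @return N x K matrix of probabilities of C = 1.
#' @export
genotype_update_probs <- function(state, gd, ll = NULL) {
  if (is.null(ll)) ll <- .loglik_mats(gd, state$theta0, state$theta)
  clone_of_cell <- state$I[state$T]
  W <- matrix(0, gd$M, gd$K)
  W[cbind(seq_len(gd$M), clone_of_cell)] <- 1
  L1 <- ll$ll1 %*% W                    # N x K pooled log-likelihoods
  L0 <- ll$ll0 %*% W
  prior1 <- abs(gd$omega - state$xi)
  lp1 <- log(prior1) + L1
  lp0 <- log1p(-prior1) + L0
  mx <- pmax(lp1, lp0)          # finite: prior1 and 1-prior1 never both 0
  e1 <- exp(lp1 - mx)
  e0 <- exp(lp0 - mx)
  e1 / (e1 + e0)
}

.sample_C <- function(state, gd, ll) {
  pr <- genotype_update_probs(state, gd, ll)
  C <- matrix(as.integer(stats::runif(length(pr)) < pr), gd$N, gd$K)
  dimnames(C) <- dimnames(gd$omega)
  C
}

#' Conjugate update of the genotype error rate
#'
#' Counts matches and mismatches between the corrected genotypes C and the
#' input genotypes Omega over all N x K entries and draws
#' `xi ~ Beta(kappa0 + #mismatches, kappa1 + #matches)` (beta-Bernoulli
#' conjugacy).
#'
#' @param C binary N x K corrected-genotype matrix.
#' @param omega a [clone_genotypes] object or binary matrix of equal shape.
#' @param kappa length-2 positive vector (kappa0, kappa1).
#' @return a draw of xi in (0,1).
#' @export
sample_xi <- function(C, omega, kappa) {
  om <- if (inherits(omega, "clone_genotypes")) omega$omega else omega
  if (!all(dim(C) == dim(om))) stop("C and omega must have the same shape")
  mism <- sum(C != om)
  eps <- 1e-12
  min(max(stats::rbeta(1, kappa[1] + mism, kappa[2] + (length(om) - mism)),
          eps), 1 - eps)
}

# log joint probability of the current state (up to the constant uniform
# prior on I); used for chain comparison and divergence checks
.log_joint <- function(state, gd, hp, ll = NULL) {
  if (is.null(ll)) ll <- .loglik_mats(gd, state$theta0, state$theta)
  clone_of_cell <- state$I[state$T]
  Cc <- state$C[, clone_of_cell, drop = FALSE]
  lik <- sum(ll$ll1 * Cc) + sum(ll$ll0 * (1 - Cc))
  prior1 <- abs(gd$omega - state$xi)
  pc <- sum(log(ifelse(state$C == 1, prior1, 1 - prior1)))
  pt <- sum(gd$logp[cbind(seq_len(gd$M), state$T)])
  lik + pc + pt - gd$Q * log(gd$K) +
    stats::dbeta(state$xi, hp$kappa[1], hp$kappa[2], log = TRUE) +
    stats::dbeta(state$theta0, hp$v0[1], hp$v0[2], log = TRUE) +
    sum(stats::dbeta(state$theta, hp$v1[1], hp$v1[2], log = TRUE))
}
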