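# Independent reference implementations used as oracles. These share no
# code path with the package internals: plain loops, stats::dbinom, and a
# naive enumeration of every joint state.

# exact posterior by brute-force enumeration over ALL joint states
# (I in K^Q, T in Q^M, C in 2^(N*K)), theta and xi clamped
brute_enumerate <- function(data, theta0, theta, xi, c = 2) {
  A <- as.matrix(data$counts$alt)
  D <- as.matrix(data$counts$total)
  omega <- data$genotypes$omega
  N <- nrow(A); M <- ncol(A); K <- ncol(omega)
  Q <- length(data$clustering$cluster_ids)
  theta <- rep(theta, length.out = N)
  G <- data$G
  p <- if (is.null(G)) matrix(1 / Q, M, Q) else {
    w <- exp(-c * G)
    w / rowSums(w)
  }

  entry_ll <- function(i, j, carries) {
    if (D[i, j] == 0) return(0)
    dbinom(A[i, j], D[i, j], if (carries) theta[i] else theta0, log = TRUE)
  }

  nI <- K^Q; nT <- Q^M; nC <- 2^(N * K)
  lws <- numeric(0)
  recs <- list()
  s <- 0L
  for (ci in 0:(nC - 1)) {
    C <- matrix((ci %/% 2^(seq_len(N * K) - 1)) %% 2, N, K)
    lpC <- 0
    for (i in 1:N) for (k in 1:K) {
      pr1 <- abs(omega[i, k] - xi)
      lpC <- lpC + log(if (C[i, k] == 1) pr1 else 1 - pr1)
    }
    if (!is.finite(lpC)) next
    for (ii in 0:(nI - 1)) {
      I <- (ii %/% K^(seq_len(Q) - 1)) %% K + 1
      for (ti in 0:(nT - 1)) {
        Tv <- (ti %/% Q^(seq_len(M) - 1)) %% Q + 1
        lw <- lpC - Q * log(K)
        for (j in 1:M) {
          lw <- lw + log(p[j, Tv[j]])
          k <- I[Tv[j]]
          for (i in 1:N) lw <- lw + entry_ll(i, j, C[i, k] == 1)
        }
        s <- s + 1L
        lws[s] <- lw
        recs[[s]] <- list(I = I, Tv = Tv)
      }
    }
  }
  mx <- max(lws)
  w <- exp(lws - mx); w <- w / sum(w)
  cc <- matrix(0, Q, K); tq <- matrix(0, M, Q); ck <- matrix(0, M, K)
  for (s2 in seq_along(w)) {
    I <- recs[[s2]]$I; Tv <- recs[[s2]]$Tv
    cc[cbind(1:Q, I)] <- cc[cbind(1:Q, I)] + w[s2]
    tq[cbind(1:M, Tv)] <- tq[cbind(1:M, Tv)] + w[s2]
    ck[cbind(1:M, I[Tv])] <- ck[cbind(1:M, I[Tv])] + w[s2]
  }
  list(cluster_clone_prob = cc, cell_cluster_prob = tq,
       cell_clone_prob = ck)
}

# per-cell assignment sampler (the predecessor model: every cell has its
# own clone label, no clustering layer); returns cell-to-clone posterior
ref_cell_sampler <- function(A, D, omega, hp, iters, burn, seed) {
  set.seed(seed)
  N <- nrow(A); M <- ncol(A); K <- ncol(omega)
  cov <- D > 0
  Z <- sample.int(K, M, replace = TRUE)
  C <- omega
  theta0 <- hp$v0[1] / sum(hp$v0)
  theta <- rep(hp$v1[1] / sum(hp$v1), N)
  xi <- hp$kappa[1] / sum(hp$kappa)
  counts <- matrix(0, M, K)
  for (it in seq_len(iters)) {
    # cell assignments
    for (j in 1:M) {
      lw <- numeric(K)
      for (k in 1:K) {
        th <- ifelse(C[, k] == 1, theta, theta0)
        lw[k] <- sum(dbinom(A[cov[, j], j], D[cov[, j], j],
                            th[cov[, j]], log = TRUE))
      }
      w <- exp(lw - max(lw))
      Z[j] <- sample.int(K, 1, prob = w)
    }
    # thetas
    Cc <- C[, Z, drop = FALSE]
    u <- rowSums(A * Cc); v <- rowSums((D - A) * Cc)
    u0 <- sum(A) - sum(u); v0 <- sum(D - A) - sum(v)
    theta0 <- rbeta(1, hp$v0[1] + u0, hp$v0[2] + v0)
    theta <- rbeta(N, hp$v1[1] + u, hp$v1[2] + v)
    theta0 <- min(max(theta0, 1e-12), 1 - 1e-12)
    theta <- pmin(pmax(theta, 1e-12), 1 - 1e-12)
    # genotypes
    for (i in 1:N) for (k in 1:K) {
      cells <- which(Z == k & cov[i, ])
      l1 <- sum(dbinom(A[i, cells], D[i, cells], theta[i], log = TRUE))
      l0 <- sum(dbinom(A[i, cells], D[i, cells], theta0, log = TRUE))
      pr1 <- abs(omega[i, k] - xi)
      lp1 <- log(pr1) + l1; lp0 <- log(1 - pr1) + l0
      m <- max(lp1, lp0)
      C[i, k] <- as.integer(runif(1) < exp(lp1 - m) /
                              (exp(lp1 - m) + exp(lp0 - m)))
    }
    # error rate
    mism <- sum(C != omega)
    xi <- rbeta(1, hp$kappa[1] + mism, hp$kappa[2] + length(omega) - mism)
    xi <- min(max(xi, 1e-12), 1 - 1e-12)
    if (it > burn) counts[cbind(1:M, Z)] <- counts[cbind(1:M, Z)] + 1
  }
  counts / (iters - burn)
}

# brute-force adjusted Rand index by explicit pair counting
brute_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (!sa && !sb) s00 <- s00 + 1
    else if (sa) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  np <- n * (n - 1) / 2
  expected <- (s11 + s10) * (s11 + s01) / np
  maxi <- ((s11 + s10) + (s11 + s01)) / 2
  if (maxi == expected) return(0)
  (s11 - expected) / (maxi - expected)
}
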