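.check_prob <- function(prob, tol = 1e-6) {
  if (any(prob < 0)) stop("probabilities must be non-negative")
  if (abs(sum(prob) - 1) > tol) {
    stop("probabilities must sum to 1 (got ", format(sum(prob)), ")")
  }
}

#' Normalized entropy of an assignment probability vector
#'
#' Shannon entropy divided by its maximum log(K), so the uniform
#' distribution scores 1 and a point mass scores 0. Lower values mean a
#' more concentrated (confident) assignment. The base of the logarithm
#' cancels; 0 log 0 is taken as 0, and K = 1 returns 0 by convention.
#'
#' @param prob non-negative vector summing to 1.
#' @return value in [0, 1].
#' @export
normalized_entropy <- function(prob) {
  .check_prob(prob)
  if (length(prob) == 1) return(0)
  nz <- prob[prob > 0]
  -sum(nz * log(nz)) / log(length(prob))
}

#' Gini index of an assignment probability vector
#'
#' Gini impurity `1 - sum(p^2)`, by default rescaled by `K/(K-1)` so that,
#' like the normalized entropy, the uniform distribution scores 1 and a
#' point mass 0. Set `normalize = FALSE` for the raw impurity (maximum
#' `(K-1)/K`).
#'
#' @param prob non-negative vector summing to 1, length >= 2.
#' @param normalize rescale to [0, 1] (default TRUE).
#' @return impurity value.
#' @export
gini_index <- function(prob, normalize = TRUE) {
  .check_prob(prob)
  k <- length(prob)
  if (k < 2) stop("Gini index needs at least two categories")
  g <- 1 - sum(prob^2)
  if (normalize) g * k / (k - 1) else g
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement of two labelings of the same items
#' (Hubert-Arabie correction), computed from the contingency table. Values
#' lie in [-1, 1]: 1 for identical partitions, about 0 for independent
#' ones; a degenerate all-in-one partition against anything scores 0.
#'
#' @param labels_a,labels_b equal-length label vectors (any type).
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("labelings must have equal length")
  }
  n <- length(labels_a)
  if (n < 2) stop("need at least two items")
  tab <- table(labels_a, labels_b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  total <- choose2(n)
  expected <- sum_a * sum_b / total
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(0)
  (sum_ij - expected) / (max_idx - expected)
}

#' Cluster-validity indices of a grouping in an embedding
#'
#' Measures how well a grouping of cells (e.g. their MAP clone assignment)
#' agrees with a low-dimensional expression embedding:
#' * Dunn index: minimum between-group distance over maximum within-group
#'   diameter (higher = better separated, more compact groups);
#' * RMSSTD: pooled within-group standard deviation across dimensions
#'   (lower = more compact);
#' * Calinski-Harabasz: `(SSB/(k-1)) / (SSW/(M-k))` (higher = better);
#' * connectivity: penalty for nearest neighbors falling outside their
#'   point's group, summing 1/l over each point's l-th of `k_nn` nearest
#'   neighbors in a different group (lower = better).
#'
#' Groups with a single member contribute a zero diameter to the Dunn
#' index (with a warning).
#'
#' @param embedding numeric matrix, M cells x d dimensions.
#' @param labels length-M grouping.
#' @param k_nn neighbors used by the connectivity measure (default 10).
#' @return list with `dunn`, `rmsstd`, `ch`, `connectivity`.
#' @export
cluster_validity <- function(embedding, labels, k_nn = 10) {
  embedding <- as.matrix(embedding)
  m <- nrow(embedding)
  d <- ncol(embedding)
  labels <- as.character(labels)
  stopifnot(length(labels) == m, d >= 1)
  groups <- split(seq_len(m), labels)
  k <- length(groups)
  if (k < 2) stop("need at least two non-empty groups")
  if (any(lengths(groups) == 1)) {
    warning("singleton group(s) contribute zero diameter to the Dunn index")
  }

  dm <- as.matrix(stats::dist(embedding))

  diam <- vapply(groups, function(idx) {
    if (length(idx) < 2) 0 else max(dm[idx, idx])
  }, numeric(1))
  min_between <- Inf
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      min_between <- min(min_between, min(dm[groups[[a]], groups[[b]]]))
    }
  }
  dunn <- min_between / max(diam)

  centroid <- function(idx) colMeans(embedding[idx, , drop = FALSE])
  grand <- colMeans(embedding)
  ssw <- 0; ssb <- 0
  for (idx in groups) {
    ce <- centroid(idx)
    ssw <- ssw + sum(sweep(embedding[idx, , drop = FALSE], 2, ce)^2)
    ssb <- ssb + length(idx) * sum((ce - grand)^2)
  }
  rmsstd <- sqrt(ssw / (d * (m - k)))
  ch <- (ssb / (k - 1)) / (ssw / (m - k))

  k_nn <- min(k_nn, m - 1)
  conn <- 0
  for (j in seq_len(m)) {
    nn <- order(dm[j, -j])      # indices into the vector without j
    others <- seq_len(m)[-j]
    nn <- others[nn[seq_len(k_nn)]]
    mismatch <- labels[nn] != labels[j]
    conn <- conn + sum(mismatch / seq_len(k_nn))
  }
  list(dunn = dunn, rmsstd = rmsstd, ch = ch, connectivity = conn)
}

#' Pielou's evenness of a cluster-size distribution
#'
#' Shannon entropy of the size proportions divided by log of the number of
#' clusters; 1 for equal sizes, approaching 0 when one cluster dominates.
#' Used to quantify the skew of clonotype-cluster sizes.
#'
#' @param cluster_sizes vector of positive integer sizes, length >= 2.
#' @return value in (0, 1].
#' @export
pielou_evenness <- function(cluster_sizes) {
  if (length(cluster_sizes) < 2) stop("need at least two clusters")
  if (any(cluster_sizes <= 0)) stop("cluster sizes must be positive")
  p <- cluster_sizes / sum(cluster_sizes)
  -sum(p * log(p)) / log(length(p))
}

#' Confidence report for an assignment probability matrix
#'
#' Per-cell normalized entropy and Gini index of the clone-assignment
#' probability rows, with means, optionally stratified into cells from
#' multiplet vs singleton input clusters.
#'
#' @param prob M x K row-stochastic matrix.
#' @param multiplet optional logical length-M vector: is the cell's input
#'   cluster a multiplet?
#' @return data.frame with one row per stratum (`all`, and when
#'   `multiplet` is given, `multiplet` / `singleton`): n cells, mean
#'   normalized entropy, mean Gini index.
#' @export
confidence_report <- function(prob, multiplet = NULL) {
  ent <- apply(prob, 1, normalized_entropy)
  gin <- apply(prob, 1, gini_index)
  strata <- list(all = seq_len(nrow(prob)))
  if (!is.null(multiplet)) {
    stopifnot(length(multiplet) == nrow(prob))
    strata$multiplet <- which(multiplet)
    strata$singleton <- which(!multiplet)
  }
  do.call(rbind, lapply(names(strata), function(s) {
    idx <- strata[[s]]
    data.frame(subset = s, n = length(idx),
               mean_normalized_entropy = mean(ent[idx]),
               mean_gini = mean(gin[idx]))
  }))
}
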