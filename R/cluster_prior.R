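#' BCR-derived cell-to-cluster distances
#'
#' Distance of every cell to every cluster, in units of differing BCR
#' mutations. Two modes are supported, chosen by the content of
#' `cell_bcr`:
#' * set mode: each cell carries a set of mutation identifiers; the distance
#'   to a cluster is the size of the symmetric difference between the cell's
#'   set and the cluster representative's set;
#' * sequence mode: each cell carries an aligned heavy-chain sequence; the
#'   distance is the Hamming distance to the representative sequence.
#'
#' When clusters are defined as cells with identical BCRs, the shared
#' BCR is the natural representative and need not be supplied; for
#' user-supplied clusterings whose members disagree, explicit
#' representatives are required.
#'
#' @param cell_bcr named list (set mode: character vectors of mutation ids)
#'   or named character vector (sequence mode), names = cell barcodes.
#'   Cells absent from `cell_bcr` are treated as BCR-missing and imputed
#'   via [impute_missing()].
#' @param clustering an [input_clustering] object.
#' @param cluster_rep optional named list/vector of per-cluster
#'   representatives (same mode as `cell_bcr`); by default the
#'   representative is taken from the cluster's first BCR-bearing member,
#'   which must agree with all other members.
#' @return numeric matrix, cells x clusters, with own-cluster distance 0.
#' @export
bcr_distances <- function(cell_bcr, clustering, cluster_rep = NULL) {
  stopifnot(inherits(clustering, "input_clustering"))
  cells <- clustering$cell_ids
  clusters <- clustering$cluster_ids
  seq_mode <- is.character(cell_bcr) && !is.list(cell_bcr)
  bcr_names <- names(cell_bcr)
  if (is.null(bcr_names)) stop("cell_bcr must be named by cell barcode")
  if (!all(bcr_names %in% cells)) {
    stop("cell absent from clustering: ",
         paste(utils::head(setdiff(bcr_names, cells), 3), collapse = ", "))
  }

  if (is.null(cluster_rep)) {
    cluster_rep <- stats::setNames(vector("list", length(clusters)), clusters)
    for (q in seq_along(clusters)) {
      members <- cells[clustering$cluster_index == q]
      members <- members[members %in% bcr_names]
      if (length(members) == 0) next  # BCR-less cluster; imputed later
      rep_q <- cell_bcr[[members[1]]]
      for (m in members[-1]) {
        same <- if (seq_mode) identical(cell_bcr[[m]], rep_q) else
          setequal(cell_bcr[[m]], rep_q)
        if (!same) {
          stop("cluster ", clusters[q], " members carry different BCRs; ",
               "supply cluster_rep explicitly")
        }
      }
      cluster_rep[[clusters[q]]] <- rep_q
    }
  } else if (is.character(cluster_rep) && !is.list(cluster_rep)) {
    cluster_rep <- as.list(cluster_rep)
  }

  pair_dist <- function(a, b) {
    if (seq_mode) {
      a <- strsplit(a, "")[[1]]
      b <- strsplit(b, "")[[1]]
      if (length(a) != length(b)) {
        stop("sequences of unequal length; align them first")
      }
      sum(a != b)
    } else {
      length(setdiff(a, b)) + length(setdiff(b, a))
    }
  }

  G <- matrix(NA_real_, length(cells), length(clusters),
              dimnames = list(cells, clusters))
  for (j in seq_along(cells)) {
    bj <- cell_bcr[[cells[j]]]
    if (is.null(bj)) next  # no BCR: row stays NA for impute_missing()
    for (q in seq_along(clusters)) {
      rq <- cluster_rep[[clusters[q]]]
      if (is.null(rq)) {
        G[j, q] <- NA_real_
      } else {
        G[j, q] <- pair_dist(bj, rq)
      }
    }
    G[j, clustering$cluster_index[j]] <- 0
  }
  G
}

#' Impute distances for cells without a BCR sequence
#'
#' Cells lacking a sequenced BCR (each forming its own singleton cluster)
#' get distance 0 to their own cluster and, to every other cluster, the
#' mean of all known cell-to-cluster distances.
#'
#' @param G numeric matrix, cells x clusters; rows of `no_bcr_cells` may be
#'   NA.
#' @param clustering an [input_clustering] object matching G's rows.
#' @param no_bcr_cells character vector of barcodes without BCR.
#' @return completed distance matrix.
#' @export
impute_missing <- function(G, clustering, no_bcr_cells) {
  stopifnot(inherits(clustering, "input_clustering"))
  no_bcr_cells <- as.character(no_bcr_cells)
  known_rows <- !(rownames(G) %in% no_bcr_cells)
  known <- G[known_rows, , drop = FALSE]
  known <- known[!is.na(known)]
  if (length(known) == 0) stop("no known distances to impute from")
  fill <- mean(known)
  for (cell in no_bcr_cells) {
    j <- match(cell, rownames(G))
    if (is.na(j)) stop("cell not in distance matrix: ", cell)
    G[j, ] <- fill
    G[j, clustering$cluster_index[match(cell, clustering$cell_ids)]] <- 0
  }
  if (anyNA(G)) stop("distance matrix still has missing entries after imputation")
  G
}

#' Cluster-switch probabilities from distances
#'
#' Converts the cell-to-cluster distance matrix G into the row-stochastic
#' switch-probability matrix p via a row-wise softmax of \code{-c * G},
#' computed in log space: \deqn{p_{j,q} = e^{-c G_{j,q}} / \sum_{q'}
#' e^{-c G_{j,q'}}.} With c = 0 every row is uniform; as c grows the mass
#' concentrates on the nearest cluster(s).
#'
#' @param G numeric matrix, cells x clusters, finite and non-negative.
#' @param c non-negative prior-strength constant (default 2).
#' @return object of class \code{switch_probabilities}: list with
#'   row-stochastic \code{p} and \code{c_used}.
#' @export
switch_probabilities <- function(G, c = 2) {
  if (length(c) != 1 || is.na(c) || c < 0) {
    stop("prior strength c must be a single non-negative number")
  }
  G <- as.matrix(G)
  if (anyNA(G) || any(!is.finite(G))) stop("G must be finite")
  lw <- -c * G
  lw <- lw - apply(lw, 1, max)            # shift-invariant, avoids underflow
  w <- exp(lw)
  p <- w / rowSums(w)
  dimnames(p) <- dimnames(G)
  structure(list(p = p, c_used = c), class = "switch_probabilities")
}

#' @export
print.switch_probabilities <- function(x, ...) {
  cat("switch_probabilities:", nrow(x$p), "cells x", ncol(x$p),
      "clusters, c =", x$c_used, "\n")
  invisible(x)
}
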