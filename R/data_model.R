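#' Clone genotype matrix
#'
#' Container for the binary clone-genotype matrix produced by an upstream
#' phylogeny tool (e.g. Canopy's top tree). Rows are somatic mutations,
#' columns are clones; an entry of 1 means the mutation is present in the
#' clone. The first clone is conventionally the base (normal) clone with an
#' all-zero genotype, but this is not enforced.
#'
#' @param omega binary matrix, N mutations x K clones, entries in \{0,1\}.
#' @param mutation_ids character vector of N unique mutation identifiers;
#'   the recommended dialect is \code{"chrom:pos:ref:alt"} with 1-based
#'   positions (VCF convention). Defaults to rownames of \code{omega}.
#' @param clone_ids character vector of K clone identifiers; defaults to
#'   colnames of \code{omega} or \code{"C1".."CK"}.
#' @return an object of class \code{clone_genotypes} with elements
#'   \code{omega} (integer matrix with dimnames), \code{mutation_ids},
#'   \code{clone_ids}.
#' @export
clone_genotypes <- function(omega, mutation_ids = rownames(omega),
                            clone_ids = colnames(omega)) {
  omega <- as.matrix(omega)
  if (is.null(mutation_ids)) {
    mutation_ids <- paste0("m", seq_len(nrow(omega)))
  }
  if (is.null(clone_ids)) {
    clone_ids <- paste0("C", seq_len(ncol(omega)))
  }
  mutation_ids <- as.character(mutation_ids)
  clone_ids <- as.character(clone_ids)
  if (nrow(omega) < 1L) {
    stop("clone genotypes need at least one mutation")
  }
  if (ncol(omega) < 2L) {
    stop("clone genotypes need at least two clones")
  }
  if (length(mutation_ids) != nrow(omega) || length(clone_ids) != ncol(omega)) {
    stop("axis id lengths do not match the genotype matrix")
  }
  if (anyDuplicated(mutation_ids)) {
    stop("duplicate mutation ids: ",
         paste(unique(mutation_ids[duplicated(mutation_ids)]), collapse = ", "))
  }
  if (anyNA(omega) || !all(omega %in% c(0, 1))) {
    bad <- unique(as.vector(omega[!(omega %in% c(0, 1))]))
    stop("genotype matrix must be binary; found entries: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  storage.mode(omega) <- "integer"
  dimnames(omega) <- list(mutation_ids, clone_ids)
  structure(list(omega = omega, mutation_ids = mutation_ids,
                 clone_ids = clone_ids),
            class = "clone_genotypes")
}

#' @export
print.clone_genotypes <- function(x, ...) {
  cat("clone_genotypes:", nrow(x$omega), "mutations x", ncol(x$omega),
      "clones;", sum(x$omega), "present entries\n")
  invisible(x)
}

#' Allele-specific UMI count matrices
#'
#' Paired sparse matrices of alternative-allele (\code{alt}) and total
#' (\code{total}) unique-transcript counts per mutation per cell. Entries
#' with zero total coverage carry no likelihood information and are kept
#' implicit in the sparse representation.
#'
#' @param alt,total non-negative integer matrices (dense or
#'   \code{Matrix} sparse), N mutations x M cells, with
#'   \code{alt <= total} elementwise.
#' @param mutation_ids,cell_ids axis identifiers (default taken from
#'   dimnames).
#' @return object of class \code{allele_counts} with sparse \code{alt},
#'   \code{total} (\code{dgCMatrix}) and the axis ids.
#' @export
allele_counts <- function(alt, total, mutation_ids = rownames(alt),
                          cell_ids = colnames(alt)) {
  alt <- methods::as(methods::as(Matrix::Matrix(alt, sparse = TRUE),
                                 "generalMatrix"), "CsparseMatrix")
  total <- methods::as(methods::as(Matrix::Matrix(total, sparse = TRUE),
                                   "generalMatrix"), "CsparseMatrix")
  if (!all(dim(alt) == dim(total))) {
    stop("alt and total matrices have different shapes: ",
         paste(dim(alt), collapse = "x"), " vs ",
         paste(dim(total), collapse = "x"))
  }
  if (is.null(mutation_ids)) mutation_ids <- paste0("m", seq_len(nrow(alt)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(ncol(alt)))
  mutation_ids <- as.character(mutation_ids)
  cell_ids <- as.character(cell_ids)
  if (length(mutation_ids) != nrow(alt) || length(cell_ids) != ncol(alt)) {
    stop("axis id lengths do not match the count matrices")
  }
  if (any(alt@x < 0) || any(total@x < 0)) {
    stop("counts must be non-negative")
  }
  excess <- alt - total
  if (any(excess@x > 0)) {
    idx <- which(as.matrix(excess) > 0, arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf("alt count exceeds total at mutation %s, cell %s (%d > %d)",
                 mutation_ids[idx[1]], cell_ids[idx[2]],
                 as.matrix(alt)[idx[1], idx[2]],
                 as.matrix(total)[idx[1], idx[2]]))
  }
  dimnames(alt) <- dimnames(total) <- list(mutation_ids, cell_ids)
  structure(list(alt = Matrix::drop0(alt), total = Matrix::drop0(total),
                 mutation_ids = mutation_ids, cell_ids = cell_ids),
            class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  cov <- Matrix::nnzero(x$total)
  cat("allele_counts:", nrow(x$alt), "mutations x", ncol(x$alt), "cells;",
      cov, sprintf("covered entries (%.1f%%)\n",
                   100 * cov / prod(dim(x$alt))))
  invisible(x)
}

#' Input cell clustering
#'
#' A non-overlapping, exhaustive partition of cells into clusters, e.g.
#' groups of cells sharing an identical BCR heavy-chain sequence. Clusters
#' of size one are singletons; clusters of size two or more are multiplets.
#'
#' @param cell_ids character vector of cell barcodes.
#' @param cluster vector (same length) of cluster labels, any type.
#' @param cluster_ids optional ordering of the distinct cluster labels;
#'   defaults to first-appearance order.
#' @return object of class \code{input_clustering} with elements
#'   \code{cell_ids}, \code{cluster_ids}, \code{cluster_index} (integer in
#'   1..Q per cell), \code{is_multiplet} (logical per cluster).
#' @export
input_clustering <- function(cell_ids, cluster, cluster_ids = NULL) {
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != length(cluster)) {
    stop("cell_ids and cluster must have equal length")
  }
  if (anyDuplicated(cell_ids)) {
    stop("duplicate cell ids in clustering")
  }
  cluster <- as.character(cluster)
  if (anyNA(cluster)) stop("missing cluster labels")
  if (is.null(cluster_ids)) cluster_ids <- unique(cluster)
  cluster_ids <- as.character(cluster_ids)
  if (!all(cluster %in% cluster_ids)) {
    stop("cluster labels outside cluster_ids")
  }
  if (!all(cluster_ids %in% cluster)) {
    stop("empty cluster(s): ",
         paste(setdiff(cluster_ids, cluster), collapse = ", "))
  }
  idx <- match(cluster, cluster_ids)
  sizes <- tabulate(idx, nbins = length(cluster_ids))
  structure(list(cell_ids = cell_ids, cluster_ids = cluster_ids,
                 cluster_index = idx, sizes = sizes,
                 is_multiplet = sizes >= 2L),
            class = "input_clustering")
}

#' @export
print.input_clustering <- function(x, ...) {
  cat("input_clustering:", length(x$cell_ids), "cells in",
      length(x$cluster_ids), "clusters (",
      sum(x$is_multiplet), "multiplet,", sum(!x$is_multiplet),
      "singleton )\n")
  invisible(x)
}

#' Model hyperparameters
#'
#' Beta-prior parameters of the model and the strength constant of the
#' cluster-switch prior. Defaults follow the published per-cell predecessor
#' model: the background allelic rate theta0 has prior mean ~0.01
#' (sequencing-error scale), the per-position alternative-allele rate
#' theta_i has prior mean ~0.46 (allelic expression with dropout), and the
#' genotype error rate xi has a weak prior with mean 0.1.
#'
#' @param c non-negative prior-strength constant of the switch prior
#'   (default 2).
#' @param kappa length-2 positive vector (kappa0, kappa1): beta prior on the
#'   genotype error rate xi.
#' @param v0 length-2 positive vector (alpha0, beta0): beta prior on theta0.
#' @param v1 length-2 positive vector (alpha1, beta1): beta prior on every
#'   theta_i.
#' @return object of class \code{hyperparameters}.
#' @export
hyperparameters <- function(c = 2, kappa = c(1, 9), v0 = c(0.3, 29.7),
                            v1 = c(2.25, 2.65)) {
  stopifnot(length(c) == 1, length(kappa) == 2, length(v0) == 2,
            length(v1) == 2)
  if (c < 0) stop("prior strength c must be non-negative")
  if (any(c(kappa, v0, v1) <= 0)) {
    stop("beta prior parameters must be strictly positive")
  }
  structure(list(c = as.numeric(c), kappa = as.numeric(kappa),
                 v0 = as.numeric(v0), v1 = as.numeric(v1)),
            class = "hyperparameters")
}

# ---- readers / writers ------------------------------------------------------

#' Read a clone-genotype table
#'
#' Expects a TSV with a header row of clone ids, a first column of mutation
#' ids, and a 0/1 body.
#'
#' @param path file path.
#' @return a [clone_genotypes] object, row/column order preserved.
#' @export
load_genotypes <- function(path) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (file.size(path) == 0) stop("empty genotype file: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character")
  if (nrow(tab) == 0 || ncol(tab) < 3) {
    stop("malformed genotype file (need >=1 mutation and >=2 clones): ", path)
  }
  ids <- tab[[1]]
  body <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                 dimnames = dimnames(body)))
  if (anyNA(num)) stop("non-numeric genotype entry in ", path)
  clone_genotypes(num, mutation_ids = ids, clone_ids = colnames(tab)[-1])
}

#' Write a clone-genotype table
#' @param g a [clone_genotypes] object.
#' @param path output TSV path.
#' @export
write_genotypes <- function(g, path) {
  tab <- data.frame(mutation_id = g$mutation_ids, g$omega,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_count_matrix <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- Matrix::readMM(path)
    methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  } else {
    m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
    Matrix::Matrix(m, sparse = TRUE)
  }
}

#' Read paired allele-count matrices
#'
#' Accepts MatrixMarket coordinate files (\code{.mtx}) or headerless dense
#' TSV; the two formats yield identical in-memory objects. Axis files list
#' one id per line in matrix order.
#'
#' @param alt_path,total_path count matrix files (mutations x cells).
#' @param mutations_path,cells_path one-id-per-line axis files.
#' @return an [allele_counts] object.
#' @export
load_counts <- function(alt_path, total_path, mutations_path, cells_path) {
  for (p in c(alt_path, total_path, mutations_path, cells_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  alt <- .read_count_matrix(alt_path)
  total <- .read_count_matrix(total_path)
  muts <- readLines(mutations_path)
  cells <- readLines(cells_path)
  muts <- muts[nzchar(muts)]
  cells <- cells[nzchar(cells)]
  if (nrow(alt) != length(muts) || ncol(alt) != length(cells)) {
    stop(sprintf("count matrix is %dx%d but axis files list %d mutations, %d cells",
                 nrow(alt), ncol(alt), length(muts), length(cells)))
  }
  allele_counts(alt, total, mutation_ids = muts, cell_ids = cells)
}

#' Write paired allele-count matrices
#'
#' @param counts an [allele_counts] object.
#' @param dir output directory; writes \code{alt.mtx}, \code{total.mtx},
#'   \code{mutations.txt}, \code{barcodes.txt}.
#' @export
write_counts <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(counts$alt, file.path(dir, "alt.mtx"))
  Matrix::writeMM(counts$total, file.path(dir, "total.mtx"))
  writeLines(counts$mutation_ids, file.path(dir, "mutations.txt"))
  writeLines(counts$cell_ids, file.path(dir, "barcodes.txt"))
  invisible(dir)
}

#' Read a cell clustering table
#'
#' TSV with two columns: barcode, cluster id (header optional, detected by
#' a `barcode` first field).
#' @param path file path.
#' @return an [input_clustering] object.
#' @export
load_clustering <- function(path) {
  if (!file.exists(path)) stop("clustering file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character")
  if (identical(tolower(tab[1, 1]), "barcode")) tab <- tab[-1, , drop = FALSE]
  input_clustering(tab[[1]], tab[[2]])
}

#' Write a cell clustering table
#' @param clustering an [input_clustering] object.
#' @param path output TSV path.
#' @export
write_clustering <- function(clustering, path) {
  tab <- data.frame(barcode = clustering$cell_ids,
                    cluster = clustering$cluster_ids[clustering$cluster_index])
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a cell-by-cluster distance matrix
#'
#' TSV with a header of cluster ids and a first column of cell barcodes.
#' @param path file path.
#' @return numeric matrix, cells x clusters, with dimnames.
#' @export
load_distances <- function(path) {
  if (!file.exists(path)) stop("distance file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, row.names = 1)
  G <- as.matrix(tab)
  if (anyNA(G) || any(!is.finite(G)) || any(G < 0)) {
    stop("distances must be finite and non-negative")
  }
  G
}

#' Write a cell-by-cluster distance matrix
#' @param G numeric matrix with cell rownames and cluster colnames.
#' @param path output TSV path.
#' @export
write_distances <- function(G, path) {
  tab <- data.frame(barcode = rownames(G), G, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- joining and filtering --------------------------------------------------

#' Join genotypes, counts, and clustering on shared axes
#'
#' Restricts the analysis to mutations present in both the clone genotypes
#' and the count matrices that have at least one variant (alternative) read
#' observed in at least one cell, then drops cells without evidence at any
#' retained mutation. Clusters emptied by the cell filter are removed and
#' the remaining clusters re-indexed. The distance matrix, when given, is
#' subset to the retained cells and clusters.
#'
#' @param genotypes a [clone_genotypes] object.
#' @param counts an [allele_counts] object.
#' @param clustering an [input_clustering] object covering the count cells.
#' @param distances optional numeric matrix, cells x clusters (rownames =
#'   barcodes, colnames = cluster ids).
#' @param cell_filter `"alt"` (default) keeps cells with >=1 alternative
#'   read at >=1 retained mutation; `"coverage"` keeps cells with >=1
#'   covered read.
#' @return object of class \code{clone_map_data}: the filtered
#'   \code{genotypes}, \code{counts}, \code{clustering}, \code{G} (or NULL)
#'   and a \code{report} list with before/after axis sizes.
#' @export
join_axes <- function(genotypes, counts, clustering, distances = NULL,
                      cell_filter = c("alt", "coverage")) {
  cell_filter <- match.arg(cell_filter)
  stopifnot(inherits(genotypes, "clone_genotypes"),
            inherits(counts, "allele_counts"),
            inherits(clustering, "input_clustering"))
  common <- intersect(genotypes$mutation_ids, counts$mutation_ids)
  if (length(common) == 0) stop("no common mutations between genotypes and counts")
  if (!all(counts$cell_ids %in% clustering$cell_ids)) {
    stop("cells missing from clustering: ",
         paste(utils::head(setdiff(counts$cell_ids, clustering$cell_ids), 3),
               collapse = ", "))
  }
  n_mut_before <- length(genotypes$mutation_ids)
  n_cell_before <- length(counts$cell_ids)
  n_clust_before <- length(clustering$cluster_ids)

  # keep genotype order; mutation must show >=1 alt read somewhere
  omega <- genotypes$omega[genotypes$mutation_ids %in% common, , drop = FALSE]
  alt <- counts$alt[rownames(omega), , drop = FALSE]
  total <- counts$total[rownames(omega), , drop = FALSE]
  keep_mut <- Matrix::rowSums(alt) > 0
  omega <- omega[keep_mut, , drop = FALSE]
  alt <- alt[keep_mut, , drop = FALSE]
  total <- total[keep_mut, , drop = FALSE]
  if (nrow(omega) == 0) stop("no common mutations with observed variant reads")

  keep_cell <- if (cell_filter == "alt") {
    Matrix::colSums(alt) > 0
  } else {
    Matrix::colSums(total) > 0
  }
  alt <- alt[, keep_cell, drop = FALSE]
  total <- total[, keep_cell, drop = FALSE]
  if (ncol(alt) == 0) stop("no cells left after filtering")

  cells <- colnames(alt)
  ci <- clustering$cluster_index[match(cells, clustering$cell_ids)]
  kept_clusters <- sort(unique(ci))
  new_clustering <- input_clustering(
    cells, clustering$cluster_ids[ci],
    cluster_ids = clustering$cluster_ids[kept_clusters])

  G <- NULL
  if (!is.null(distances)) {
    if (is.null(rownames(distances)) || is.null(colnames(distances))) {
      stop("distance matrix needs cell rownames and cluster colnames")
    }
    G <- distances[cells, new_clustering$cluster_ids, drop = FALSE]
  }

  new_geno <- clone_genotypes(omega)
  new_counts <- allele_counts(alt, total)
  structure(list(
    genotypes = new_geno, counts = new_counts, clustering = new_clustering,
    G = G,
    report = list(
      mutations = c(before = n_mut_before, after = nrow(omega)),
      cells = c(before = n_cell_before, after = ncol(alt)),
      clusters = c(before = n_clust_before,
                   after = length(new_clustering$cluster_ids)),
      cell_filter = cell_filter)),
    class = "clone_map_data")
}

#' @export
print.clone_map_data <- function(x, ...) {
  r <- x$report
  cat("clone_map_data:",
      sprintf("mutations %d->%d, cells %d->%d, clusters %d->%d\n",
              r$mutations["before"], r$mutations["after"],
              r$cells["before"], r$cells["after"],
              r$clusters["before"], r$clusters["after"]))
  invisible(x)
}
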