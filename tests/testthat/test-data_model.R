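test_that("genotype tables parse, validate, and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mutation_id\tC1\tC2",
               "chr1:100:A:T\t0\t1",
               "chr1:200:G:C\t0\t0",
               "chr2:5:T:A\t1\t1"), path)
  g <- load_genotypes(path)
  expect_s3_class(g, "clone_genotypes")
  expect_equal(dim(g$omega), c(3L, 2L))
  expect_equal(g$mutation_ids,
               c("chr1:100:A:T", "chr1:200:G:C", "chr2:5:T:A"))
  expect_equal(unname(g$omega[, 2]), c(1L, 0L, 1L))

  out <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, out)
  expect_equal(load_genotypes(out), g)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mutation_id\tC1\tC2", "m1\t2\t0", "m2\t0\t1"), bad)
  expect_error(load_genotypes(bad), "binary")

  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_error(load_genotypes(empty), basename(empty), fixed = TRUE)
})

test_that("genotype construction enforces the invariants", {
  expect_error(clone_genotypes(matrix(c(0, 1), 2, 1)), "two clones")
  m <- matrix(0, 2, 2)
  expect_error(clone_genotypes(m, mutation_ids = c("a", "a")), "duplicate")
  # an all-zero base clone is allowed
  expect_silent(clone_genotypes(cbind(C1 = c(0, 0), C2 = c(1, 0))))
})

test_that("allele counts validate A <= D and name the first offender", {
  ac <- allele_counts(matrix(c(1, 0), 1), matrix(c(2, 0), 1))
  expect_equal(Matrix::nnzero(ac$total), 1)
  expect_error(allele_counts(matrix(3), matrix(2),
                             mutation_ids = "mX", cell_ids = "cellY"),
               "mX.*cellY")
})

test_that("MatrixMarket and dense TSV readers yield identical objects", {
  set.seed(11)
  D <- matrix(rpois(12, 1.5), 3, 4)
  A <- matrix(rbinom(12, D, 0.5), 3, 4)
  dir <- withr::local_tempdir()
  Matrix::writeMM(Matrix::Matrix(A, sparse = TRUE), file.path(dir, "a.mtx"))
  Matrix::writeMM(Matrix::Matrix(D, sparse = TRUE), file.path(dir, "d.mtx"))
  write.table(A, file.path(dir, "a.tsv"), sep = "\t", row.names = FALSE,
              col.names = FALSE)
  write.table(D, file.path(dir, "d.tsv"), sep = "\t", row.names = FALSE,
              col.names = FALSE)
  writeLines(paste0("m", 1:3), file.path(dir, "muts.txt"))
  writeLines(paste0("c", 1:4), file.path(dir, "cells.txt"))
  from_mtx <- load_counts(file.path(dir, "a.mtx"), file.path(dir, "d.mtx"),
                          file.path(dir, "muts.txt"),
                          file.path(dir, "cells.txt"))
  from_tsv <- load_counts(file.path(dir, "a.tsv"), file.path(dir, "d.tsv"),
                          file.path(dir, "muts.txt"),
                          file.path(dir, "cells.txt"))
  expect_equal(as.matrix(from_mtx$alt), as.matrix(from_tsv$alt))
  expect_equal(as.matrix(from_mtx$total), as.matrix(from_tsv$total))

  # write-read round trip through the package writers
  back_dir <- withr::local_tempdir()
  write_counts(from_mtx, back_dir)
  back <- load_counts(file.path(back_dir, "alt.mtx"),
                      file.path(back_dir, "total.mtx"),
                      file.path(back_dir, "mutations.txt"),
                      file.path(back_dir, "barcodes.txt"))
  expect_equal(as.matrix(back$alt), as.matrix(from_mtx$alt))
})

test_that("clustering and distance tables round-trip", {
  cl <- input_clustering(paste0("c", 1:5), c("B1", "B1", "B2", "B3", "B3"))
  expect_equal(cl$is_multiplet, c(TRUE, FALSE, TRUE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clustering(cl, path)
  expect_equal(load_clustering(path), cl)

  G <- matrix(c(0, 1.5, 2, 0, 0.5, 3), 2, 3,
              dimnames = list(c("c1", "c2"), c("B1", "B2", "B3")))
  gpath <- withr::local_tempfile(fileext = ".tsv")
  write_distances(G, gpath)
  expect_equal(load_distances(gpath), G)
})

test_that("join_axes applies the stated filters and reports sizes", {
  # 5 mutations x 4 cells; m5 has no alt read anywhere -> dropped;
  # cell4 has coverage but no alt evidence at any mutation -> dropped
  A <- rbind(c(1, 0, 0, 0),
             c(0, 2, 0, 0),
             c(0, 0, 1, 0),
             c(1, 1, 0, 0),
             c(0, 0, 0, 0))
  D <- rbind(c(2, 0, 1, 1),
             c(0, 2, 1, 0),
             c(1, 0, 2, 1),
             c(1, 2, 0, 0),
             c(0, 1, 0, 2))
  omega <- matrix(rbinom(10, 1, 0.5), 5, 2)
  counts <- allele_counts(A, D)
  geno <- clone_genotypes(omega)
  clustering <- input_clustering(counts$cell_ids,
                                 c("B1", "B1", "B2", "B3"))
  joined <- join_axes(geno, counts, clustering)
  expect_equal(unname(joined$report$mutations), c(5L, 4L))
  expect_equal(unname(joined$report$cells), c(4L, 3L))
  expect_equal(unname(joined$report$clusters), c(3L, 2L))
  expect_false("m5" %in% joined$genotypes$mutation_ids)
  expect_false("cell4" %in% joined$counts$cell_ids)

  # every retained mutation and cell has alt evidence
  expect_true(all(Matrix::rowSums(joined$counts$alt) > 0))
  expect_true(all(Matrix::colSums(joined$counts$alt) > 0))

  # idempotence
  again <- join_axes(joined$genotypes, joined$counts, joined$clustering)
  expect_equal(as.matrix(again$counts$alt), as.matrix(joined$counts$alt))
  expect_equal(again$genotypes$omega, joined$genotypes$omega)
  expect_equal(again$clustering$cluster_index,
               joined$clustering$cluster_index)

  # empty intersection errors
  geno2 <- clone_genotypes(omega[1:2, ], mutation_ids = c("zz1", "zz2"))
  expect_error(join_axes(geno2, counts, clustering), "no common mutations")
})

test_that("coverage-based cell filter is available as the alternative reading", {
  A <- rbind(c(1, 0), c(1, 0))
  D <- rbind(c(2, 0), c(1, 3))   # cell2 covered at m2 but no alt reads
  counts <- allele_counts(A, D)
  geno <- clone_genotypes(matrix(c(0, 1, 1, 0), 2, 2))
  clustering <- input_clustering(counts$cell_ids, c("B1", "B2"))
  alt_mode <- join_axes(geno, counts, clustering, cell_filter = "alt")
  cov_mode <- join_axes(geno, counts, clustering, cell_filter = "coverage")
  expect_equal(unname(alt_mode$report$cells["after"]), 1L)
  expect_equal(unname(cov_mode$report$cells["after"]), 2L)
})
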