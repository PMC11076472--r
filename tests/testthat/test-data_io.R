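test_that("reading a delimited table preserves values, order and times", {
  d <- withr::local_tempdir()
  path <- file.path(d, "expr.tsv")
  writeLines(c("gene\tS1\tS2", "Per2\t1.5\t2.5", "Dbp\t0\t4", "Nr1d1\t3\t3"),
             path)
  m <- read_expression_table(path, times = c(0, 12))
  expect_equal(dim(m$values), c(3, 2))
  expect_equal(m$gene_ids, c("Per2", "Dbp", "Nr1d1"))
  expect_equal(m$times, c(0, 12))
  expect_equal(unname(m$values[1, ]), c(1.5, 2.5))
})

test_that("duplicate gene rows are averaged on read", {
  d <- withr::local_tempdir()
  path <- file.path(d, "dup.tsv")
  writeLines(c("gene\tS1\tS2", "Per2\t2\t2", "Per2\t4\t4", "Dbp\t1\t1"), path)
  m <- read_expression_table(path, times = c(0, 6))
  expect_equal(m$gene_ids, c("Per2", "Dbp"))
  expect_equal(unname(m$values["Per2", ]), c(3, 3))
})

test_that("malformed tables and mismatched times are rejected", {
  d <- withr::local_tempdir()
  bad <- file.path(d, "bad.tsv")
  writeLines(c("gene\tS1\tS2", "Per2\t1\t", "Dbp\t1\t2"), bad)
  expect_error(read_expression_table(bad, times = c(0, 6)))
  ok <- file.path(d, "ok.tsv")
  writeLines(c("gene\tS1\tS2", "Per2\t1\t2"), ok)
  expect_error(read_expression_table(ok, times = c(0, 6, 12)), "times length")
  nonnum <- file.path(d, "nonnum.tsv")
  writeLines(c("gene\tS1\tS2", "Per2\tx\t2"), nonnum)
  expect_error(read_expression_table(nonnum, times = c(0, 6)), "non-numeric")
})

test_that("average_duplicate_genes averages, keeps order, and is idempotent", {
  vals <- rbind(c(1, 3), c(3, 5), c(0, 0))
  out <- average_duplicate_genes(vals, c("A", "A", "B"))
  expect_equal(out$gene_ids, c("A", "B"))
  expect_equal(unname(out$values), rbind(c(2, 4), c(0, 0)))
  # no duplicates: unchanged
  out2 <- average_duplicate_genes(vals, c("A", "B", "C"))
  expect_equal(unname(out2$values), vals)
  # constants collapse to the constant
  out3 <- average_duplicate_genes(matrix(7, 5, 3), rep("G", 5))
  expect_equal(unname(out3$values), matrix(7, 1, 3))
  # idempotence
  again <- average_duplicate_genes(out$values, out$gene_ids)
  expect_equal(again, out)
})

test_that("read -> write -> read round-trips to full precision", {
  m <- simulate_bulk_timeseries(12, 9, 24, 4, 0.3, seed = 5)
  d <- withr::local_tempdir()
  p <- file.path(d, "rt.tsv")
  write_expression_table(m, p)
  m2 <- read_expression_table(p, m$times)
  expect_equal(unname(m2$values), unname(m$values), tolerance = 0)
  expect_equal(m2$gene_ids, m$gene_ids)
})

write_toy_10x <- function(dir, entries, genes, barcodes) {
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               paste(length(genes), length(barcodes), nrow(entries)),
               apply(entries, 1, paste, collapse = " ")),
             file.path(dir, "matrix.mtx"))
  writeLines(paste(genes, genes, sep = "\t"), file.path(dir, "features.tsv"))
  writeLines(barcodes, file.path(dir, "barcodes.tsv"))
}

test_that("10x-style sparse triplets load with annotations", {
  d <- withr::local_tempdir()
  genes <- c("Per1", "Per2", "Bmal1", "Dbp")
  bcs <- c("AAA", "CCC", "GGG")
  write_toy_10x(d, rbind(c(1, 1, 5), c(2, 2, 3), c(4, 3, 7)), genes, bcs)
  ann <- data.frame(barcode = bcs, cell_type = c("fib", "fib", "imm"),
                    sample = "ZT0")
  cm <- read_10x_mtx(d, ann, c(ZT0 = 0))
  expect_s3_class(cm, "cell_matrix")
  expect_equal(ncol(cm$counts), 3)
  expect_equal(as.numeric(cm$counts[1, 1]), 5)
  # missing barcode is named in the error
  expect_error(read_10x_mtx(d, ann[-2, ], c(ZT0 = 0)), "CCC")
})

test_that("explicit zeros in the triplet change nothing downstream", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  genes <- c("A", "B"); bcs <- c("c1", "c2")
  write_toy_10x(d1, rbind(c(1, 1, 2), c(2, 2, 3)), genes, bcs)
  write_toy_10x(d2, rbind(c(1, 1, 2), c(2, 1, 0), c(2, 2, 3)), genes, bcs)
  ann <- data.frame(barcode = bcs, cell_type = "t", sample = "s")
  cm1 <- read_10x_mtx(d1, ann, c(s = 0))
  cm2 <- read_10x_mtx(d2, ann, c(s = 0))
  pb1 <- make_pseudobulk(cm1); pb2 <- make_pseudobulk(cm2)
  expect_identical(pb1$values, pb2$values)
})

test_that("sparse and dense constructions agree downstream", {
  dense <- rbind(c(0, 2, 0), c(1, 0, 3))
  cm_d <- cell_matrix(dense, c("A", "B"), rep("t", 3), rep("s", 3), c(s = 0))
  cm_s <- cell_matrix(Matrix::Matrix(dense, sparse = TRUE), c("A", "B"),
                      rep("t", 3), rep("s", 3), c(s = 0))
  expect_identical(make_pseudobulk(cm_d)$values, make_pseudobulk(cm_s)$values)
})

test_that("model serialization round-trips predictions bit-identically", {
  mat <- simulate_bulk_timeseries(40, 12, 48, 2, 0.1, seed = 11)
  model <- train_taufisher(mat)
  d <- withr::local_tempdir()
  p <- file.path(d, "model.tfm")
  save_model(model, p)
  m2 <- load_model(p)
  expect_equal(length(m2$genes), length(model$genes))
  v <- mat$values[, 7]
  expect_identical(predict(model, v)$probabilities,
                   predict(m2, v)$probabilities)
  expect_identical(predict(model, v)$hour, predict(m2, v)$hour)
  # version mismatch refused, truncation rejected
  txt <- readLines(p)
  writeLines(sub('"schema_version": 1', '"schema_version": 99', txt), p)
  expect_error(load_model(p), "schema version")
  writeLines(head(txt, 10), p)
  expect_error(load_model(p))
})
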