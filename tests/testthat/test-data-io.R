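test_that("expr_matrix enforces its invariants with named errors", {
  m <- matrix(1:6, 3, 2, dimnames = list(c("a", "b", "c"), c("g1", "g2")))
  em <- expr_matrix(m, "counts")
  expect_s3_class(em, "expr_matrix")
  expect_equal(expr_scale(em), "counts")

  dup <- m; colnames(dup) <- c("g1", "g1")
  expect_error(expr_matrix(dup, "counts"), class = "gp_error_duplicate_ids")
  bad <- m * 1.0; bad[1, 1] <- NaN
  expect_error(expr_matrix(bad, "lognorm"), class = "gp_error_non_finite")
  neg <- m; neg[1, 1] <- -1L
  expect_error(expr_matrix(neg, "counts"), class = "gp_error_bad_counts")
  frac <- m * 1.0; frac[1, 1] <- 0.5
  expect_error(expr_matrix(frac, "counts"), class = "gp_error_bad_counts")
})

test_that("read_expression parses delimited text and flags malformed input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cell,g1,g2", "c1,1,2", "c2,0,3", "c3,4,0"), path)
  em <- read_expression(path, scale = "counts")
  expect_equal(dim(em), c(3L, 2L))
  expect_equal(colnames(em), c("g1", "g2"))
  expect_equal(rownames(em), c("c1", "c2", "c3"))
  expect_equal(expr_scale(em), "counts")
  expect_equal(as.numeric(em["c3", "g1"]), 4)

  expect_error(read_expression(file.path(tempdir(), "nope.csv")),
               class = "gp_error_missing_file")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cell,g1,g1", "c1,1,2"), dup)
  expect_error(read_expression(dup), class = "gp_error_duplicate_ids")

  txt <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cell,g1,g2", "c1,1,apple"), txt)
  expect_error(read_expression(txt), class = "gp_error_non_numeric")

  inf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cell,g1,g2", "c1,1,Inf"), inf)
  expect_error(read_expression(inf), class = "gp_error_non_finite")
})

test_that("expression write/read round-trips exactly, comma and tab", {
  em <- toy_expr(10, 5)
  for (sep in c(",", "\t")) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_expression(em, path, sep = sep)
    back <- read_expression(path, scale = "lognorm")
    expect_identical(mat(back), mat(em))
  }
})

test_that("harmonize_genes intersects, orders lexicographically, and is idempotent", {
  ref <- toy_expr(4, 3); colnames(ref) <- c("a", "b", "c")
  sp <- toy_expr(6, 3, seed = 7); colnames(sp) <- c("d", "c", "b")
  h <- suppressMessages(harmonize_genes(ref, sp))
  expect_equal(colnames(h$reference), c("b", "c"))
  expect_equal(colnames(h$spatial), c("b", "c"))
  # values follow their gene ids
  expect_equal(unname(h$spatial[, "c"]), unname(sp[, "c"]))

  # idempotent
  h2 <- harmonize_genes(h$reference, h$spatial)
  expect_identical(h2$reference, h$reference)
  expect_identical(h2$spatial, h$spatial)

  # same gene sets, different orders -> identical ordered output
  sp2 <- sp[, c(3, 2, 1)]
  h3 <- suppressMessages(harmonize_genes(ref, sp2))
  expect_identical(h3$spatial, h$spatial)

  disjoint <- toy_expr(4, 2); colnames(disjoint) <- c("x", "y")
  expect_error(harmonize_genes(ref, disjoint), class = "gp_error_empty_intersection")
})

test_that("panel files round-trip and reject duplicates/empties", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Coro1a", "Mafb"), path)
  p <- read_panel(path)
  expect_s3_class(p, "gene_panel")
  expect_length(p, 2L)
  expect_setequal(p$genes, c("Coro1a", "Mafb"))
  # rank placeholders preserve file order
  expect_equal(p$genes[which.max(p$scores)], "Coro1a")

  dup <- withr::local_tempfile(); writeLines(c("g1", "g1"), dup)
  expect_error(read_panel(dup), class = "gp_error_duplicate_ids")
  empty <- withr::local_tempfile(); writeLines(character(0), empty)
  expect_error(read_panel(empty), class = "gp_error_empty_file")

  set.seed(3)
  big <- gene_panel(sprintf("gene%03d", 1:200), runif(200), source = "sim")
  out <- withr::local_tempfile(fileext = ".tsv")
  write_panel(big, out)
  back <- read_panel(out, source = "sim")
  expect_identical(back$genes, big$genes)
  expect_equal(back$scores, big$scores)
})

test_that("spatial datasets validate shapes and round-trip through text files", {
  em <- toy_expr(8, 4)
  coords <- matrix(runif(16), 8, 2)
  sd1 <- spatial_dataset(em, coords, labels = rep(c("A", "B"), 4))
  expect_error(spatial_dataset(em, coords[1:5, ]), class = "gp_error_shape")

  ep <- withr::local_tempfile(fileext = ".csv")
  cp <- withr::local_tempfile(fileext = ".csv")
  lp <- withr::local_tempfile(fileext = ".csv")
  write_spatial(sd1, ep, cp, lp)
  back <- read_spatial(ep, cp, lp)
  expect_equal(mat(back$expr), mat(sd1$expr))
  expect_equal(back$coords, sd1$coords)
  expect_equal(back$labels, sd1$labels)
})
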