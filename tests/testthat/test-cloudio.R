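test_that("reader parses labeled lines, preserves order, validates labels", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0 0 0 0 1 1 1", "1 0 0 0 0 1 1 1", "5 5 0 0 0 1 0 0"), f)
  cl <- readLabeledTxt(f)
  expect_equal(nPoints(cl), 3L)
  expect_equal(semanticLabels(cl), c(1L, 1L, 0L))
  expect_equal(instanceLabels(cl), c(1L, 1L, 0L))
  expect_equal(cloudPoints(cl)[2, ], c(1, 0, 0))

  # comma-separated variant parses identically
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0,0,0,0,0,1,1,1", "1,0,0,0,0,1,1,1"), f2)
  expect_equal(nPoints(readLabeledTxt(f2)), 2L)

  # empty file -> empty cloud
  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), f3)
  expect_equal(nPoints(readLabeledTxt(f3)), 0L)
})

test_that("reader errors name the offending line and reject bad labels", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 2 3 0 0 1 1 1", "1 2 x 0 0 1 1 1"), f)
  expect_error(readLabeledTxt(f), "line 2")

  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 2 3 0 0 1 1 1", "1 2 3 0 0 1 1"), f2)
  expect_error(readLabeledTxt(f2), "line 2")

  # instance > 0 on a semantic-0 point violates the label contract
  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines("1 2 3 0 0 1 0 2", f3)
  expect_error(readLabeledTxt(f3), "instance")

  # semantic outside {0,1}
  f4 <- withr::local_tempfile(fileext = ".txt")
  writeLines("1 2 3 0 0 1 2 2", f4)
  expect_error(readLabeledTxt(f4), "semantic")
})

test_that("header lines at the file head are skipped with a message", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("//X Y Z Nx Ny Nz label1 label2", "0 0 0 0 0 1 1 1"), f)
  expect_message(cl <- readLabeledTxt(f), "skipped 1")
  expect_equal(nPoints(cl), 1L)
})

test_that("write/read round-trip is the identity; second write is byte-stable", {
  cl <- makeTinyCloud(40)
  f1 <- withr::local_tempfile(fileext = ".txt")
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLabeledTxt(cl, f1)
  back <- readLabeledTxt(f1)
  expect_equal(semanticLabels(back), semanticLabels(cl))
  expect_equal(instanceLabels(back), instanceLabels(cl))
  expect_equal(cloudPoints(back), cloudPoints(cl), tolerance = 1e-5)
  writeLabeledTxt(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("unlabeled clouds write 6 columns, labeled 8", {
  cl <- makeTinyCloud(5)
  bare <- labeledCloud(cloudPoints(cl), cloudNormals(cl))
  f <- withr::local_tempfile(fileext = ".txt")
  writeLabeledTxt(bare, f)
  expect_equal(length(strsplit(readLines(f)[1], " ")[[1]]), 6L)
  writeLabeledTxt(cl, f)
  expect_equal(length(strsplit(readLines(f)[1], " ")[[1]]), 8L)
  expect_equal(length(readLines(f)), 5L)
})

test_that("PLY export colors instances distinctly, background gray", {
  cl <- makeTinyCloud(60)
  cl@instance <- ifelse(cl@semantic == 1L, 1L + seq_len(60) %% 3L, 0L)
  f <- withr::local_tempfile(fileext = ".ply")
  exportPLY(cl, "instance", f)
  lines <- readLines(f)
  expect_true(any(grepl("element vertex 60", lines)))
  body <- lines[-seq_len(which(lines == "end_header"))]
  expect_equal(length(body), 60L)
  cols <- unique(vapply(strsplit(body, " "), function(v)
    paste(v[4:6], collapse = ","), character(1)))
  expect_equal(length(cols), 4L)  # 3 instances + gray background
  expect_true("128,128,128" %in% cols)
  expect_error(exportPLY(labeledCloud(cloudPoints(cl)), "semantic", f),
               "not present")
})
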