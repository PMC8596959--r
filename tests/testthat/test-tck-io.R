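test_that("TCK write/read round trip preserves geometry and metadata", {
  set.seed(42)
  for (n in c(0, 1, 7)) {
    t <- randomTractogram(n, nPoints = sample(2:20, 1))
    t@subject <- "s03"; t@session <- 5L
    t@connection <- "AMY"; t@hemisphere <- "R"
    f <- withr::local_tempfile(fileext = ".tck")
    writeTck(t, f)
    t2 <- readTck(f)
    expect_equal(nStreamlines(t2), n)
    expect_equal(t2@subject, "s03")
    expect_equal(t2@session, 5L)
    expect_equal(t2@connection, "AMY")
    expect_equal(t2@hemisphere, "R")
    # a second round trip is the identity: float32 values survive exactly
    f2 <- withr::local_tempfile(fileext = ".tck")
    writeTck(t2, f2)
    expect_identical(streamlines(readTck(f2)), streamlines(t2))
    expect_identical(readBin(f, "raw", file.size(f)),
                     readBin(f2, "raw", file.size(f2)))
  }
})

test_that("point counts and coordinate sums survive reading unchanged", {
  t <- tractogram(list(straightLine(nPoints = 3),
                       straightLine(from = c(1, 2, 3), nPoints = 5)))
  f <- withr::local_tempfile(fileext = ".tck")
  writeTck(t, f)
  t2 <- readTck(f)
  expect_equal(vapply(streamlines(t2), nrow, integer(1)), c(3L, 5L))
  # sum over the raw float payload equals the sum over parsed streamlines
  raw <- readBin(f, "raw", file.size(f))
  off <- grepRaw("\nEND\n", raw, fixed = TRUE) + 4L
  vals <- readBin(raw[(off + 1):length(raw)], "double",
                  n = (length(raw) - off) %/% 4, size = 4,
                  endian = "little")
  expect_equal(sum(vapply(streamlines(t2), sum, numeric(1))),
               sum(vals[is.finite(vals)]))
})

test_that("metadata comes from the sidecar filename convention", {
  t <- tractogram(list(straightLine()))
  d <- withr::local_tempdir()
  f <- file.path(d, "subj07_3_HPC_L.tck")
  writeTck(t, f)
  t2 <- readTck(f)
  expect_equal(t2@subject, "subj07")
  expect_equal(t2@session, 3L)
  expect_equal(t2@connection, "HPC")
  expect_equal(t2@hemisphere, "L")
  # non-conforming name leaves metadata unset
  f3 <- file.path(d, "bundle.tck")
  writeTck(tractogram(list(straightLine())), f3)
  expect_true(is.na(readTck(f3)@subject))
})

test_that("malformed and truncated files raise informative errors", {
  f <- withr::local_tempfile(fileext = ".tck")
  writeLines(c("not a tractogram", "END"), f)
  expect_error(readTck(f), "mrtrix tracks")

  # header line without a key-value separator
  con <- file(f, "wb")
  writeChar("mrtrix tracks\ndatatype: Float32LE\nbogus line\nEND\n", con,
            eos = NULL)
  close(con)
  expect_error(readTck(f), "bogus line")

  # valid header, binary cut off before the Inf terminator: removing the
  # last 6 floats drops the terminator and the second separator, so only
  # the first streamline is recovered
  t <- tractogram(list(straightLine(nPoints = 4), straightLine(nPoints = 4)))
  writeTck(t, f)
  raw <- readBin(f, "raw", file.size(f))
  writeBin(raw[1:(length(raw) - 24)], f)
  expect_error(readTck(f), "truncated.*1 streamline")
})

test_that("a one-point streamline violates the tractogram invariant", {
  expect_error(tractogram(list(matrix(c(1, 2, 3), 1, 3))),
               "at least 2 points")
  # and a file containing one is rejected on read
  f <- withr::local_tempfile(fileext = ".tck")
  hdr <- "mrtrix tracks\ndatatype: Float32LE\nfile: . 64\nEND\n"
  hdr <- paste0(hdr, strrep(" ", 64 - nchar(hdr) - 1), "\n")
  con <- file(f, "wb")
  writeChar(hdr, con, eos = NULL)
  writeBin(c(1, 2, 3, NaN, NaN, NaN, Inf, Inf, Inf), con, size = 4,
           endian = "little")
  close(con)
  expect_error(readTck(f), "at least 2 points")
})

test_that("writing the same tractogram twice is byte-identical", {
  set.seed(7)
  t <- randomTractogram(4)
  f1 <- withr::local_tempfile(fileext = ".tck")
  f2 <- withr::local_tempfile(fileext = ".tck")
  writeTck(t, f1); writeTck(t, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
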