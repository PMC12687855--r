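test_that("stream round trips are exact in binary and shared modes", {
  x <- md_float32(rand_md(c(16, 12, 6), seed = 1))
  for (binary in c(TRUE, FALSE)) {
    f <- tempfile()
    file_to_stream(x, f, flags = 4, binary = binary)
    expect_identical(collect_stream(f), x)
  }
})

test_that("a reader recovers dims, flags and metadata from the header", {
  x <- md_float32(rand_md(c(4, 3, 5), seed = 2))
  f <- tempfile()
  w <- open_stream_writer(f, dim(x), 4, binary = TRUE,
                          meta = c(producer = "mdstream"))
  for (s in 0:4) write_slice(w, extract_slice(x, 2, s),
                             meta = c(idx = as.character(s)))
  close_stream(w)
  r <- open_stream_reader(f)
  expect_equal(r$dims[1:3], c(4, 3, 5))
  expect_equal(r$flags, 4)
  expect_true(r$binary)
  expect_equal(unname(r$meta["producer"]), "mdstream")
  s0 <- read_slice(r)
  expect_equal(s0$index, 0)
  expect_equal(unname(s0$meta["idx"]), "0")
  close_stream(r)
})

test_that("the static header is byte-identical to the cfl header", {
  x <- rand_md(c(64, 64, 20), seed = 3)
  p <- tempfile(); write_cfl(p, x)
  hdr <- readLines(paste0(p, ".hdr"))
  f <- tempfile()
  file_to_stream(x, f, flags = 4, binary = TRUE)
  con <- file(f, "rb")
  first2 <- c(mdstream:::read_line_raw(con), mdstream:::read_line_raw(con))
  close(con)
  expect_identical(first2, hdr)
})

test_that("slice ordering is enforced on both ends", {
  x <- rand_md(c(4, 4, 3), seed = 4)
  f <- tempfile()
  w <- open_stream_writer(f, dim(x), 4, binary = TRUE)
  write_slice(w, extract_slice(x, 2, 0))
  expect_error(write_slice(w, extract_slice(x, 2, 2), index = 2),
               "out-of-order")
  close_stream(w)
  # a slice message with a skipped index is a protocol error on read:
  # flip the first "slice 0" byte to "slice 1" at the raw level
  raw <- readBin(f, "raw", n = file.size(f))
  pat <- charToRaw("slice 0 ")
  hit <- which(vapply(seq_len(length(raw) - length(pat) + 1), function(i)
    all(raw[i:(i + length(pat) - 1)] == pat), logical(1)))[1]
  raw[hit + 6] <- charToRaw("1")
  writeBin(raw, f)
  expect_error(collect_stream(f), "protocol error")
})

test_that("truncated payloads are reported, a slice-free stream is not", {
  x <- rand_md(c(8, 8, 2), seed = 5)
  f <- tempfile()
  file_to_stream(x, f, flags = 4, binary = TRUE)
  raw <- readBin(f, "raw", n = file.size(f))
  writeBin(raw[1:(length(raw) - 100)], f)
  expect_error(collect_stream(f), "truncated")
  # header-only stream: clean end before the first slice
  g <- tempfile()
  w <- open_stream_writer(g, c(8, 8, 2), 4, binary = TRUE)
  close_stream(w)
  r <- open_stream_reader(g)
  expect_null(read_slice(r))
  close_stream(r)
})

test_that("cross-process round trips through a FIFO are exact", {
  x <- md_float32(rand_md(c(32, 32, 10), seed = 6))
  for (binary in c(TRUE, FALSE)) {
    fp <- tempfile(fileext = ".fifo")
    job <- parallel::mcparallel(file_to_stream(x, fp, flags = 4,
                                               binary = binary))
    got <- collect_stream(fp)
    parallel::mccollect(job)
    unlink(fp)
    expect_identical(got, x)
  }
})

test_that("writers create missing FIFOs", {
  fp <- tempfile(fileext = ".fifo")
  expect_false(file.exists(fp))
  job <- parallel::mcparallel(
    file_to_stream(rand_md(c(2, 2, 2), seed = 7), fp, flags = 4,
                   binary = TRUE))
  got <- collect_stream(fp)
  parallel::mccollect(job)
  expect_equal(dim(got), c(2, 2, 2))
  unlink(fp)
})

test_that("a consumer never sees an incomplete slice under producer delays", {
  # randomized producer delays; every received slice must be complete and
  # must match the source (the synchronization contract)
  x <- md_float32(rand_md(c(16, 16, 8), seed = 8))
  fp <- tempfile(fileext = ".fifo")
  job <- parallel::mcparallel({
    set.seed(9)
    w <- open_stream_writer(fp, dim(x), 4, binary = TRUE)
    for (s in 0:7) {
      Sys.sleep(stats::runif(1, 0, 0.03))
      write_slice(w, extract_slice(x, 2, s))
    }
    close_stream(w)
  })
  r <- open_stream_reader(fp)
  for (s in 0:7) {
    sl <- read_slice(r)
    expect_equal(sl$index, s)
    expect_identical(array(sl$data, dim = c(16, 16, 1)),
                     extract_slice(x, 2, s))
  }
  expect_null(read_slice(r))
  close_stream(r)
  parallel::mccollect(job)
  unlink(fp)
})

test_that("capture to file then replay equals the live stream", {
  x <- md_float32(rand_md(c(8, 6, 4), seed = 10))
  cap <- tempfile()
  file_to_stream(x, cap, flags = 4, binary = TRUE)
  # replay from the captured file into a cfl pair
  out <- tempfile()
  stream_to_file(cap, out)
  expect_identical(read_cfl(out), x)
  # flags = 4 on a 3-d array emits N_2 slices
  r <- open_stream_reader(cap)
  expect_equal(r$n_slices, 4)
  close_stream(r)
})
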