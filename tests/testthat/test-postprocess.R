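# full-resolution grid over a length-3 query: lengths 1..3
toy_grid <- function(scores) {
  make_scan_result(3, scores, scan_params(min_length = 1))
}
# enumerate_windows order: (1,1) (2,1) (3,1) (1,2) (2,2) (1,3)

test_that("zero heritability is the identity and constants are fixed points", {
  withr::local_seed(4)
  res <- make_scan_result(12, stats::runif(nrow(
    enumerate_windows(12, scan_params(min_length = 3)))),
    scan_params(min_length = 3))
  expect_equal(rescore_inheritance(res, 0)$windows$score, res$windows$score)
  const <- make_scan_result(12, rep(2.5, nrow(res$windows)),
                            scan_params(min_length = 3))
  for (h in c(0.3, 0.93)) {
    expect_equal(rescore_inheritance(const, h)$windows$score,
                 rep(2.5, nrow(const$windows)))
  }
  expect_error(rescore_inheritance(res, 1), "\\[0, 1\\)")
  expect_error(rescore_inheritance(res, -0.1), "\\[0, 1\\)")
})

test_that("the inheritance recurrence matches a hand-evaluated 3-length grid", {
  # raw scores by window: L1: (1,5,3), L2: (4,2), L3: 8; h = 0.5
  res <- toy_grid(c(1, 5, 3, 4, 2, 8))
  out <- rescore_inheritance(res, 0.5)$windows$score
  # top row keeps raw: new(1,3) = 8
  # L2: both windows contained in (1,3): new = 0.5*raw + 0.5*8 -> 6, 5
  # L1 s=1: parent (1,2) only        -> 0.5*1 + 0.5*6        = 3.5
  # L1 s=2: parents (1,2) and (2,2)  -> 0.5*5 + 0.5*mean(6,5) = 5.25
  # L1 s=3: parent (2,2) only        -> 0.5*3 + 0.5*5         = 4
  expect_equal(out, c(3.5, 5.25, 4, 6, 5, 8))
})

test_that("rescored values are convex combinations of the raw grid", {
  withr::local_seed(10)
  n <- nrow(enumerate_windows(25, scan_params(min_length = 6)))
  raw <- stats::runif(n, 0, 9)
  res <- make_scan_result(25, raw, scan_params(min_length = 6))
  for (h in c(0.2, 0.93)) {
    out <- rescore_inheritance(res, h)$windows$score
    expect_gte(min(out), min(raw))
    expect_lte(max(out), max(raw))
  }
})

test_that("raising one raw score never lowers any rescored value", {
  withr::local_seed(12)
  n <- nrow(enumerate_windows(15, scan_params(min_length = 4)))
  raw <- stats::runif(n)
  res <- make_scan_result(15, raw, scan_params(min_length = 4))
  base <- rescore_inheritance(res, 0.7)$windows$score
  for (i in c(1, round(n / 2), n)) {
    raw2 <- raw
    raw2[i] <- raw2[i] + 5
    bumped <- rescore_inheritance(
      make_scan_result(15, raw2, scan_params(min_length = 4)),
      0.7)$windows$score
    expect_true(all(bumped >= base - 1e-12))
  }
})

test_that("rescoring follows containment parents on coarse length grids", {
  # lengths 6, 9, 12 over a length-12 query; parents at the next length up
  p <- scan_params(min_length = 6, length_step = 3)
  win <- enumerate_windows(12, p)
  raw <- rep(0, nrow(win))
  raw[win$length == 12] <- 6
  out <- rescore_inheritance(make_scan_result(12, raw, p), 0.5)$windows$score
  # every length-9 window is contained in (1,12): new = 0.5*0 + 0.5*6 = 3
  expect_equal(out[win$length == 9], rep(3, sum(win$length == 9)))
  # every length-6 window has at least one length-9 parent: new = 1.5
  expect_equal(out[win$length == 6], rep(1.5, sum(win$length == 6)))
})

test_that("residue profiles average the covering fixed-length windows", {
  n <- nrow(enumerate_windows(100, scan_params(min_length = 30)))
  res <- make_scan_result(100, rep(1.7, n), scan_params(min_length = 30))
  prof <- residue_scores(res, 30)
  expect_equal(nrow(prof), 100)
  expect_equal(prof$support[50], 30)   # interior residue: up to W windows
  expect_equal(prof$support[1], 1)     # terminus: only the first window
  expect_equal(prof$support[100], 1)
  expect_equal(prof$value, rep(1.7, 100))
  # brute-force support count at every position
  starts <- seq_len(100 - 30 + 1)
  bf <- vapply(1:100, function(i) sum(starts <= i & starts + 29 >= i),
               integer(1))
  expect_equal(prof$support, bf)
})

test_that("residue profiles weight positions by actual window scores", {
  p <- scan_params(min_length = 3)
  win <- enumerate_windows(10, p)
  sc <- ifelse(win$length == 3 & win$start == 4, 8, 0)
  prof <- residue_scores(make_scan_result(10, sc, p), 3)
  expect_equal(prof$value[5], 8 / 3)  # covered by starts 3,4,5; one scores 8
  expect_equal(prof$value[1], 0)
  expect_equal(which.max(prof$value), 4)
})

test_that("residue extrapolation demands a complete window row", {
  p <- scan_params(min_length = 6, position_step = 2)
  res <- make_scan_result(30, rep(1, nrow(enumerate_windows(30, p))), p)
  expect_error(residue_scores(res, 6), "position_step = 1")
  expect_error(residue_scores(
    make_scan_result(30, rep(1, nrow(enumerate_windows(
      30, scan_params(min_length = 10)))), scan_params(min_length = 10)), 6),
    "position_step = 1")
})
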