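test_that("window enumeration covers the length/position grid", {
  expect_equal(nrow(enumerate_windows(10, scan_params(min_length = 10))), 1)
  w <- enumerate_windows(8, scan_params(min_length = 6))
  expect_equal(nrow(w), 6)  # 3 + 2 + 1 placements
  expect_equal(w$length, c(6, 6, 6, 7, 7, 8))
  expect_error(enumerate_windows(5, scan_params(min_length = 6)),
               "exceeds query length")
  # the full query length is always reachable even off the length grid
  w2 <- enumerate_windows(10, scan_params(min_length = 6, length_step = 3))
  expect_true(10 %in% w2$length)
})

test_that("binomial tails match hand-derived probabilities", {
  expect_equal(binomial_tail(10, 10, 0.5), 0.0009765625)
  expect_equal(binomial_tail(7, 0, 0.3), 1.0)
  expect_equal(binomial_tail(5, 3, 0.2), 0.05792, tolerance = 1e-12)
  expect_error(binomial_tail(5, 3, 1.2), "between 0 and 1")
})

test_that("window scoring finds the minimum tail over hit-list prefixes", {
  s <- score_window(rep("NO", 8), Y = 5, N = 5)
  expect_equal(s$score, 0)
  expect_equal(s$min_probability, 1)

  s <- score_window(c("YES", "YES", "YES"), Y = 5, N = 5)
  expect_equal(s$min_probability, 0.125)
  expect_equal(s$k_at_min, 3)
  expect_equal(s$y_at_min, 3)
  expect_equal(s$score, -log10(0.125), tolerance = 1e-12)

  s <- score_window("YES", Y = 1, N = 999)
  expect_equal(s$score, 3.0, tolerance = 1e-12)

  s <- score_window(character(0), Y = 5, N = 5)
  expect_equal(s$score, 0)
  expect_equal(s$k_at_min, 0)
})

test_that("deep extreme prefixes score without underflow", {
  s <- score_window(rep("YES", 400), Y = 100, N = 900)
  expect_gt(s$score, 300)  # -400*log10(0.1) = 400; finite, not Inf/NaN
  expect_true(is.finite(s$score))
})

test_that("scores depend on the label fraction, not the database size", {
  labels <- c("YES", "NO", "YES", "YES", "NO")
  a <- score_window(labels, Y = 10, N = 30)
  b <- score_window(labels, Y = 20, N = 60)  # duplicated database, same p
  expect_equal(a$score, b$score)
  expect_equal(a$k_at_min, b$k_at_min)
})

test_that("a fragment identical to a database record ranks it first", {
  db <- planted_db(n_yes = 5, n_no = 5, seed = 9)
  frag <- as.character(db$records[["YES|Y03"]])
  r <- rank_hits(frag, db)
  expect_equal(r$id[1], "Y03")
  expect_equal(r$label[1], "YES")
})

test_that("an empty partition is rejected at database build time", {
  expect_error(labeled_database(Biostrings::AAStringSet(),
                                aaset(c(a = "MKTLV"))), "Y >= 1")
})

test_that("builtin and blast backends agree on well-separated rankings", {
  withr::local_seed(7)
  base <- random_protein(60)
  near <- vapply(c(2, 6, 10, 14, 18), function(k) mutate_k(base, k),
                 character(1))
  names(near) <- sprintf("n%02d", 1:5)
  bg <- vapply(1:15, function(i) random_protein(60), character(1))
  names(bg) <- sprintf("b%02d", 1:15)
  db <- labeled_database(aaset(near), aaset(bg))
  frag <- substr(base, 8, 50)
  top_builtin <- head(rank_hits(frag, db, "builtin")$id, 5)
  top_blast <- head(rank_hits(frag, db, "blast",
                              blast_dir = withr::local_tempdir())$id, 5)
  expect_equal(top_builtin, top_blast)
})

test_that("a scan localizes a motif shared only by YES records", {
  db <- planted_db(n_yes = 8, n_no = 8, motif = "CHWKDGYPRFEW",
                   len = 60, at = 25, seed = 4)
  withr::local_seed(101)
  q <- random_protein(40)
  substr(q, 15, 26) <- "CHWKDGYPRFEW"
  res <- scan_query(c(q1 = q), db, scan_params(min_length = 6))
  expect_equal(nrow(res$windows),
               nrow(enumerate_windows(40, scan_params(min_length = 6))))
  peak <- res$windows[which.max(res$windows$score), ]
  expect_true(window_overlaps(peak, c(15, 26)))

  # swapped labels: the motif region no longer scores
  db_swap <- labeled_database(
    aaset(stats::setNames(as.character(db$records[db$label == "NO"]),
                          db$id[db$label == "NO"])),
    aaset(stats::setNames(as.character(db$records[db$label == "YES"]),
                          db$id[db$label == "YES"])))
  res_swap <- scan_query(c(q1 = q), db_swap, scan_params(min_length = 6))
  motif_windows <- window_overlaps(res_swap$windows, c(15, 26))
  expect_lt(max(res_swap$windows$score[motif_windows]),
            0.25 * max(res$windows$score))
})

test_that("coarse grids are subsamples of the full-resolution scan", {
  db <- planted_db(n_yes = 5, n_no = 5, len = 40, at = 10, seed = 6)
  withr::local_seed(17)
  q <- c(q1 = random_protein(30))
  full <- scan_query(q, db, scan_params(min_length = 6))
  coarse <- scan_query(q, db, scan_params(min_length = 6, length_step = 3,
                                          position_step = 3))
  key <- function(w) paste(w$start, w$length)
  expect_true(all(key(coarse$windows) %in% key(full$windows)))
  m <- match(key(coarse$windows), key(full$windows))
  expect_equal(coarse$windows$score, full$windows$score[m])
})

test_that("parallel scans reproduce the serial result exactly", {
  db <- planted_db(n_yes = 5, n_no = 5, len = 40, at = 10, seed = 6)
  withr::local_seed(18)
  q <- c(q1 = random_protein(30))
  serial <- scan_query(q, db, scan_params(min_length = 6))
  par4 <- scan_query(q, db, scan_params(min_length = 6), n_jobs = 4L)
  expect_identical(serial$windows, par4$windows)
})
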