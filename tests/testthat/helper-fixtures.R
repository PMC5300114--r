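# shared helpers: tiny in-code fixtures, no files over a few hundred bytes

aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n) paste(sample(aa20, n, replace = TRUE),
                                    collapse = "")

# substitute exactly k positions with different residues
mutate_k <- function(x, k) {
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  for (i in sample(length(ch), k)) {
    ch[i] <- sample(setdiff(aa20, ch[i]), 1)
  }
  paste(ch, collapse = "")
}

aaset <- function(x) Biostrings::AAStringSet(x)

# one hit-table row in the shape read_hmm_hits() returns
make_hit <- function(protein_id, hmm_id, full_score,
                     env = data.frame(env_start = integer(),
                                      env_end = integer(),
                                      dom_score = numeric())) {
  df <- data.frame(protein_id = protein_id, hmm_id = hmm_id,
                   full_score = full_score, n_domains = nrow(env),
                   stringsAsFactors = FALSE)
  df$envelopes <- list(env)
  df
}

bind_hits <- function(...) do.call(rbind, list(...))

# a scan_result with a prescribed score vector, for postprocess/viz tests
make_scan_result <- function(query_length, scores,
                             params = scan_params(min_length = 1)) {
  win <- enumerate_windows(query_length, params)
  stopifnot(length(scores) == nrow(win))
  structure(list(
    query_id = "toy", query_length = query_length, params = params,
    Y = 1L, N = 1L,
    windows = data.frame(
      start = win$start, length = win$length,
      midpoint = win$start + (win$length - 1) / 2,
      score = scores, k_at_min = 1L, y_at_min = 1L,
      min_probability = 10^-scores)),
    class = "scan_result")
}

# single-attribute rule set used by the hand-built partition fixtures
toy_rules <- function(distance_bp = NULL) {
  yes <- if (is.null(distance_bp)) "YES: (HMM/ATTR.HMM>16)" else
    sprintf("YES: ([%d] HMM/ATTR.HMM>16)", distance_bp)
  parse_config(c("TARGET: HMM/TARG.HMM", "TARGET SCORE: 20",
                 yes, "NO: HMM/ATTR.HMM<12.5"))
}

# small labeled database with a motif shared only by YES records
planted_db <- function(n_yes = 10, n_no = 10, motif = "CHWKDGYPRFEW",
                       len = 60, at = 25, seed = 42) {
  withr::with_seed(seed, {
    yes <- vapply(seq_len(n_yes), function(i) {
      s <- random_protein(len)
      substr(s, at, at + nchar(motif) - 1) <- mutate_k(motif, 1)
      s
    }, character(1))
    no <- vapply(seq_len(n_no), function(i) random_protein(len), character(1))
    names(yes) <- sprintf("Y%02d", seq_len(n_yes))
    names(no) <- sprintf("N%02d", seq_len(n_no))
    labeled_database(aaset(yes), aaset(no))
  })
}

# brute-force binomial upper tail, independent of pbinom
bf_tail <- function(k, y, p) {
  if (y == 0) return(1)
  i <- y:k
  sum(choose(k, i) * p^i * (1 - p)^(k - i))
}

window_overlaps <- function(windows, span) {
  windows$start <= span[2] & (windows$start + windows$length - 1) >= span[1]
}
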