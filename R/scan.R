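#' Scan resolution and backend parameters
#'
#' `length_step` and `position_step` correspond to the classic `-j` and `-w`
#' resolution flags: `-j 1 -w 1` inspects every possible subsequence length
#' and position (highest resolution), while `-j 3 -w 3` samples every third
#' length and every third position for roughly a nine-fold speedup.
#'
#' @param min_length Shortest subsequence scanned, in residues (default 6;
#'   9 is a common alternative preset since alignment statistics for very
#'   short peptides are weak).
#' @param length_step,position_step Sampling steps `-j` and `-w` (>= 1).
#' @param max_hits Optional cap on the ranked hit-list depth scanned per
#'   window; `NULL` (default) scans the full list.
#' @param backend `"builtin"` (Smith-Waterman via Biostrings, BLOSUM62, no
#'   external executables) or `"blast"` (shells out to NCBI `makeblastdb` /
#'   `blastp`).
#' @return A `scan_params` object.
#' @export
scan_params <- function(min_length = 6L, length_step = 1L, position_step = 1L,
                        max_hits = NULL, backend = c("builtin", "blast")) {
  backend <- match.arg(backend)
  min_length <- as.integer(min_length)
  length_step <- as.integer(length_step)
  position_step <- as.integer(position_step)
  stopifnot(min_length >= 1L, length_step >= 1L, position_step >= 1L)
  if (!is.null(max_hits)) {
    max_hits <- as.integer(max_hits)
    stopifnot(max_hits >= 1L)
  }
  structure(list(min_length = min_length, length_step = length_step,
                 position_step = position_step, max_hits = max_hits,
                 backend = backend),
            class = "scan_params")
}

#' Combine YES and NO partitions into one labeled search database
#'
#' The two partitions are pooled into a single searchable set; each record
#' keeps its partition label, and record names are prefixed `YES|` / `NO|`
#' (the form also written for external BLAST databases). Both partitions must
#' be non-empty for scoring, since the binomial background rate is
#' `p = Y / (Y + N)`.
#'
#' @param yes,no Named `AAStringSet`s (typically the clustered YES and NO
#'   training partitions).
#' @return A `labeled_db` object with fields `records`, `id`, `label`, `Y`,
#'   `N`, `p`.
#' @export
labeled_database <- function(yes, no) {
  stopifnot(methods::is(yes, "XStringSet"), methods::is(no, "XStringSet"))
  if (length(yes) < 1L || length(no) < 1L) {
    stop("both partitions must contain at least one sequence (Y >= 1, N >= 1)")
  }
  if (anyDuplicated(names(yes)) || anyDuplicated(names(no))) {
    stop("duplicate ids within a partition")
  }
  S4Vectors::mcols(yes) <- NULL  # descriptions play no role in scoring
  S4Vectors::mcols(no) <- NULL
  records <- c(Biostrings::AAStringSet(yes), Biostrings::AAStringSet(no))
  id <- c(names(yes), names(no))
  label <- rep(c("YES", "NO"), c(length(yes), length(no)))
  names(records) <- paste(label, id, sep = "|")
  structure(list(records = records, id = id, label = label,
                 Y = length(yes), N = length(no),
                 p = length(yes) / (length(yes) + length(no))),
            class = "labeled_db")
}

#' @export
print.labeled_db <- function(x, ...) {
  cat("Labeled search database: ", x$Y, " YES + ", x$N, " NO sequences (p = ",
      signif(x$p, 4), ")\n", sep = "")
  invisible(x)
}

#' Enumerate the subsequence windows of a scan
#'
#' Lengths run from `min_length` upward in steps of `length_step`; the full
#' query length is always included when reachable. For each length `L`, start
#' positions run `1, 1 + w, ...` up to `query_length - L + 1`. At full
#' resolution the window count is the closed form
#' `sum over L of (query_length - L + 1)`.
#'
#' @param query_length Query length in residues.
#' @param params A [scan_params()] object.
#' @return A data frame of `start` (1-based) and `length`, ordered by
#'   (length, start).
#' @examples
#' nrow(enumerate_windows(204, scan_params(min_length = 6)))  # 19900
#' @export
enumerate_windows <- function(query_length, params = scan_params()) {
  stopifnot(inherits(params, "scan_params"))
  query_length <- as.integer(query_length)
  if (params$min_length > query_length) {
    stop("min_length (", params$min_length, ") exceeds query length (",
         query_length, ")")
  }
  lengths <- seq.int(params$min_length, query_length, by = params$length_step)
  if (lengths[length(lengths)] != query_length) {
    lengths <- c(lengths, query_length)
  }
  parts <- lapply(lengths, function(L) {
    starts <- seq.int(1L, query_length - L + 1L, by = params$position_step)
    data.frame(start = starts, length = L)
  })
  do.call(rbind, parts)
}

#' Upper-tail binomial probability P(X >= y)
#'
#' The probability that sampling `k` sequences from the training set, each
#' independently YES with probability `p`, yields `y` or more YES sequences.
#' This is sampling *with replacement* — a deliberate modeling choice; note
#' that ranked homology hits are not independent draws, so the resulting
#' scores compare regions of one query to each other but are not calibrated
#' significance values.
#'
#' @param k Number of draws (>= 1). Vectorized.
#' @param y YES count, `0 <= y <= k`.
#' @param p YES fraction of the training set, in (0, 1).
#' @return `P(X >= y)` for `X ~ Binomial(k, p)`.
#' @examples
#' binomial_tail(10, 10, 0.5)  # 0.5^10
#' @export
binomial_tail <- function(k, y, p) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly between 0 and 1")
  stopifnot(all(k >= 1), all(y >= 0), all(y <= k))
  stats::pbinom(y - 1, k, p, lower.tail = FALSE)
}

#' Score one ranked hit list by its minimum binomial tail
#'
#' Scans down the ranked labels; at each prefix depth `k` with `y` YES labels
#' seen so far, computes the binomial tail `P(X >= y | k, p)` with
#' `p = Y / (Y + N)`. The window's probability is the minimum over all depths
#' (1 for an empty list), and its score the negative log10 of that minimum.
#' Tails are evaluated on the log scale so deep, extreme prefixes do not
#' underflow.
#'
#' @param labels Character vector of `"YES"`/`"NO"` in rank order.
#' @param Y,N Label counts of the whole database.
#' @param max_hits Optional depth cap.
#' @return A list with `k_at_min` (smallest depth attaining the minimum),
#'   `y_at_min`, `min_probability` and `score`.
#' @export
score_window <- function(labels, Y, N, max_hits = NULL) {
  stopifnot(Y >= 1, N >= 1)
  p <- Y / (Y + N)
  n <- length(labels)
  if (!is.null(max_hits)) n <- min(n, max_hits)
  if (n == 0L) {
    return(list(k_at_min = 0L, y_at_min = 0L, min_probability = 1, score = 0))
  }
  y <- cumsum(labels[seq_len(n)] == "YES")
  k <- seq_len(n)
  logp <- stats::pbinom(y - 1, k, p, lower.tail = FALSE, log.p = TRUE)
  i <- which.min(logp)
  list(k_at_min = k[i], y_at_min = as.integer(y[i]),
       min_probability = exp(logp[i]), score = -logp[i] / log(10))
}

#' Rank database hits for one query fragment
#'
#' Returns at most one entry per database record (the record's best local
#' alignment), ordered best-first. The builtin backend computes
#' Smith-Waterman scores with BLOSUM62 (gap open 11, extend 1) and ranks by
#' raw score; records with no positive-scoring local alignment are dropped.
#' The blast backend runs `blastp` (task `blastp-short` for fragments under 30
#' residues, composition-based statistics off, E-value ceiling 10) and ranks
#' by E-value then bit score. Ties are broken by record id so rankings are
#' deterministic across runs.
#'
#' @param fragment Amino-acid string.
#' @param db A [labeled_database()].
#' @param backend Overrides the backend (default `"builtin"`).
#' @param blast_dir Directory holding (or receiving) the formatted BLAST
#'   database; defaults to a session temporary directory.
#' @return A data frame of `id`, `label`, `score` (and `evalue` for blast),
#'   ordered best-first. Zero hits yield zero rows.
#' @export
rank_hits <- function(fragment, db, backend = c("builtin", "blast"),
                      blast_dir = NULL) {
  backend <- match.arg(backend)
  stopifnot(inherits(db, "labeled_db"))
  fragment <- as.character(fragment)
  if (backend == "builtin") {
    sc <- Biostrings::pairwiseAlignment(
      db$records, Biostrings::AAString(fragment), type = "local",
      substitutionMatrix = .blosum62(), gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE)
    keep <- which(sc > 0)
    ord <- keep[order(-sc[keep], db$id[keep], method = "radix")]
    data.frame(id = db$id[ord], label = db$label[ord], score = sc[ord],
               stringsAsFactors = FALSE)
  } else {
    dbpath <- .blast_db_path(db, blast_dir)
    qf <- tempfile(fileext = ".fasta")
    on.exit(unlink(qf))
    writeLines(c(">frag", fragment), qf)
    hits <- .run_blastp(qf, dbpath, short = nchar(fragment) < 30L,
                        n_db = length(db$records))
    .rank_blast_hits(hits, db)
  }
}

# one best HSP per subject, ordered by (evalue, -bitscore, id)
.rank_blast_hits <- function(hits, db) {
  if (nrow(hits) == 0L) {
    return(data.frame(id = character(), label = character(),
                      score = numeric(), evalue = numeric(),
                      stringsAsFactors = FALSE))
  }
  best <- do.call(rbind, lapply(split(hits, hits$sseqid), function(h) {
    h[order(h$evalue, -h$bitscore)[1], , drop = FALSE]
  }))
  lab <- sub("\\|.*$", "", best$sseqid)
  id <- sub("^[A-Z]+\\|", "", best$sseqid)
  ord <- order(best$evalue, -best$bitscore, id, method = "radix")
  data.frame(id = id[ord], label = lab[ord], score = best$bitscore[ord],
             evalue = best$evalue[ord], stringsAsFactors = FALSE)
}

.require_exe <- function(exe) {
  if (Sys.which(exe) == "") {
    stop("'", exe, "' not found on PATH; use backend = \"builtin\" instead")
  }
}

.blast_db_path <- function(db, blast_dir = NULL) {
  .require_exe("makeblastdb")
  if (is.null(blast_dir)) {
    blast_dir <- file.path(tempdir(), "simbal_blastdb")
  }
  dir.create(blast_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(blast_dir, "trainingdb")
  if (!file.exists(paste0(path, ".pin")) &&
      !file.exists(paste0(path, ".pdb"))) {
    fa <- paste0(path, ".fasta")
    write_fasta(db$records, fa)
    out <- system2("makeblastdb",
                   c("-in", shQuote(fa), "-dbtype", "prot",
                     "-out", shQuote(path)),
                   stdout = TRUE, stderr = TRUE)
    if (!is.null(attr(out, "status"))) {
      stop("makeblastdb failed: ", paste(out, collapse = "\n"))
    }
  }
  path
}

.run_blastp <- function(query_fasta, dbpath, short, n_db) {
  .require_exe("blastp")
  outf <- tempfile(fileext = ".tsv")
  on.exit(unlink(outf))
  args <- c("-query", shQuote(query_fasta), "-db", shQuote(dbpath),
            "-task", if (short) "blastp-short" else "blastp",
            "-evalue", "10", "-seg", "no", "-comp_based_stats", "0",
            "-max_target_seqs", as.character(max(500L, n_db)),
            "-outfmt", shQuote("6 qseqid sseqid evalue bitscore"),
            "-out", shQuote(outf))
  msg <- system2("blastp", args, stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(msg, "status"))) {
    stop("blastp failed: ", paste(msg, collapse = "\n"))
  }
  if (!file.exists(outf) || file.size(outf) == 0L) {
    return(data.frame(qseqid = character(), sseqid = character(),
                      evalue = numeric(), bitscore = numeric(),
                      stringsAsFactors = FALSE))
  }
  utils::read.delim(outf, header = FALSE,
                    col.names = c("qseqid", "sseqid", "evalue", "bitscore"),
                    stringsAsFactors = FALSE)
}

#' Scan a query protein for YES-enriched signature regions
#'
#' Enumerates subsequence windows of the query at the requested resolution,
#' ranks each window's hits against the labeled training database, and scores
#' every window by its minimum binomial tail (see [score_window()]). This is
#' the core data-mining step: windows covering residues that discriminate the
#' YES partition from the NO partition rank many YES sequences at the top of
#' their hit lists and receive high scores.
#'
#' @param query A single named sequence: a length-1 `AAStringSet`, or a named
#'   character string.
#' @param db A [labeled_database()].
#' @param params A [scan_params()] object.
#' @param n_jobs Process-level parallelism over windows (forked workers);
#'   results are identical to a serial run since windows are scored
#'   independently and reassembled in (length, start) order.
#' @return A `scan_result`: `query_id`, `query_length`, `params`, `Y`, `N`,
#'   and a `windows` data frame with `start`, `length`, `midpoint`
#'   (`start + (length - 1) / 2`), `score`, `k_at_min`, `y_at_min`,
#'   `min_probability`.
#' @export
scan_query <- function(query, db, params = scan_params(), n_jobs = 1L) {
  stopifnot(inherits(db, "labeled_db"), inherits(params, "scan_params"))
  if (methods::is(query, "XStringSet")) {
    stopifnot(length(query) == 1L)
    qid <- names(query)
    qseq <- as.character(query)[[1]]
  } else {
    qseq <- as.character(query)[[1]]
    qid <- names(query)
  }
  if (is.null(qid)) qid <- "query"
  win <- enumerate_windows(nchar(qseq), params)
  frags <- substring(qseq, win$start, win$start + win$length - 1L)
  if (params$backend == "builtin") {
    worker <- function(i) {
      r <- rank_hits(frags[i], db, backend = "builtin")
      unlist(score_window(r$label, db$Y, db$N, params$max_hits))
    }
    rows <- if (n_jobs > 1L) {
      parallel::mclapply(seq_len(nrow(win)), worker, mc.cores = n_jobs)
    } else {
      lapply(seq_len(nrow(win)), worker)
    }
    stats <- do.call(rbind, rows)
  } else {
    stats <- .scan_blast(frags, db, params)
  }
  windows <- data.frame(
    start = win$start, length = win$length,
    midpoint = win$start + (win$length - 1) / 2,
    score = stats[, "score"],
    k_at_min = as.integer(stats[, "k_at_min"]),
    y_at_min = as.integer(stats[, "y_at_min"]),
    min_probability = stats[, "min_probability"])
  structure(list(query_id = qid, query_length = nchar(qseq), params = params,
                 Y = db$Y, N = db$N, windows = windows),
            class = "scan_result")
}

# batch all fragments into (at most) two blastp invocations: one per task
.scan_blast <- function(frags, db, params) {
  dbpath <- .blast_db_path(db)
  wid <- sprintf("w%07d", seq_along(frags))
  groups <- split(seq_along(frags), frags_short <- nchar(frags) < 30L)
  hit_tabs <- lapply(names(groups), function(short_key) {
    ix <- groups[[short_key]]
    qf <- tempfile(fileext = ".fasta")
    on.exit(unlink(qf))
    writeLines(paste0(">", wid[ix], "\n", frags[ix]), qf)
    .run_blastp(qf, dbpath, short = identical(short_key, "TRUE"),
                n_db = length(db$records))
  })
  hits <- do.call(rbind, hit_tabs)
  by_query <- split(hits, hits$qseqid)
  t(vapply(wid, function(w) {
    h <- by_query[[w]]
    r <- if (is.null(h)) {
      data.frame(label = character(), stringsAsFactors = FALSE)
    } else {
      .rank_blast_hits(h, db)
    }
    unlist(score_window(r$label, db$Y, db$N, params$max_hits))
  }, c(k_at_min = 0, y_at_min = 0, min_probability = 0, score = 0)))
}

#' @export
print.scan_result <- function(x, ...) {
  cat("SIMBAL scan of '", x$query_id, "' (", x$query_length, " aa): ",
      nrow(x$windows), " windows, training set ", x$Y, " YES / ", x$N,
      " NO\n", sep = "")
  top <- x$windows[which.max(x$windows$score), ]
  cat(sprintf("  peak score %.3f at window start %d, length %d (midpoint %.1f)\n",
              top$score, top$start, top$length, top$midpoint))
  invisible(x)
}
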