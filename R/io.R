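#' Read a protein FASTA file
#'
#' Reads amino-acid sequences into an [Biostrings::AAStringSet]. Record ids are
#' the first whitespace-delimited token of each header; the remainder of the
#' header is kept as a `description` metadata column. Residues are uppercased,
#' and any letter outside the 20 standard amino acids plus `X` (e.g. `B`, `Z`,
#' `J`, `U`, `O`, `*`) is mapped to `X` with a warning, so that downstream
#' aligners see a closed alphabet.
#'
#' @param path Path to a FASTA text file (plain or gzip).
#' @return An `AAStringSet` named by record id, with an `mcols()` column
#'   `description`. An empty file yields an empty set.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 a toy protein", "MKT", "LV"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  first <- .first_nonblank_line(path)
  if (is.null(first)) {
    return(Biostrings::AAStringSet())
  }
  if (!startsWith(first$text, ">")) {
    stop("not FASTA text: expected a '>' header at line ", first$line,
         " of ", path)
  }
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate FASTA id(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  if (any(Biostrings::width(seqs) == 0)) {
    stop("zero-length sequence record(s) in ", path, ": ",
         paste(ids[Biostrings::width(seqs) == 0], collapse = ", "))
  }
  res <- toupper(as.character(seqs))
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", res)
  if (any(bad)) {
    warning(sum(bad), " record(s) contained non-standard residues; mapped to X")
    res[bad] <- gsub("[^ACDEFGHIKLMNPQRSTVWYX]", "X", res[bad])
  }
  out <- Biostrings::AAStringSet(res)
  names(out) <- ids
  S4Vectors::mcols(out)$description <- unname(desc)
  out
}

.first_nonblank_line <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  n <- 0L
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) return(NULL)
    n <- n + 1L
    if (nzchar(trimws(line))) return(list(text = line, line = n))
  }
}

#' Write sequences to FASTA
#'
#' Inverse of [read_fasta()]: descriptions stored in `mcols(seqs)$description`
#' are appended to the id on the header line.
#'
#' @param seqs An `AAStringSet` with unique names.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(methods::is(seqs, "XStringSet"))
  hdr <- names(seqs)
  if (is.null(hdr) && length(seqs) > 0) {
    stop("sequences must be named")
  }
  d <- S4Vectors::mcols(seqs)$description
  if (!is.null(d)) {
    d[is.na(d)] <- ""
    hdr <- ifelse(nzchar(d), paste(hdr, d), hdr)
  }
  out <- seqs
  names(out) <- hdr
  Biostrings::writeXStringSet(out, path, width = 60L)
  invisible(path)
}

#' Read CDS gene features from a GFF3 file
#'
#' Extracts one feature per `CDS` line, resolving the protein id from the
#' attribute column by trying `id_attribute_keys` in order (annotation
#' pipelines differ in which attribute carries the protein accession).
#' Non-CDS feature types are ignored; CDS lines with no resolvable id are
#' skipped with a warning that reports the count.
#'
#' @param path Path to a GFF3 file.
#' @param id_attribute_keys Attribute names tried in order to obtain a protein
#'   id for each CDS.
#' @return A data frame with columns `protein_id`, `replicon_id`, `start`,
#'   `end` (1-based inclusive nucleotide positions) and `strand`.
#' @export
read_gff_features <- function(path, id_attribute_keys = c("protein_id", "ID")) {
  if (!file.exists(path)) {
    stop("GFF3 file not found: ", path)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "CDS"]
  if (length(gr) == 0L) {
    return(data.frame(protein_id = character(), replicon_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  md <- S4Vectors::mcols(gr)
  pid <- rep(NA_character_, length(gr))
  for (key in id_attribute_keys) {
    if (key %in% names(md)) {
      v <- as.character(md[[key]])
      fill <- is.na(pid) & !is.na(v) & nzchar(v)
      pid[fill] <- v[fill]
    }
  }
  skipped <- is.na(pid)
  if (any(skipped)) {
    warning(sum(skipped), " CDS feature(s) in ", path,
            " had none of the id attributes [",
            paste(id_attribute_keys, collapse = ", "), "]; skipped")
  }
  keep <- !skipped
  data.frame(
    protein_id = pid[keep],
    replicon_id = as.character(GenomicRanges::seqnames(gr))[keep],
    start = GenomicRanges::start(gr)[keep],
    end = GenomicRanges::end(gr)[keep],
    strand = as.character(GenomicRanges::strand(gr))[keep],
    stringsAsFactors = FALSE
  )
}

.empty_hits <- function() {
  out <- data.frame(protein_id = character(), hmm_id = character(),
                    full_score = numeric(), n_domains = integer(),
                    stringsAsFactors = FALSE)
  out$envelopes <- list()
  out
}

#' Read an HMMER3 tabular hit file
#'
#' Parses `hmmsearch --tblout` (per-sequence) or `--domtblout` (per-domain)
#' output. The target column is taken as the protein id and the query column
#' as the HMM id (the `hmmsearch` convention: query = profile, target =
#' sequence). Multiple data lines for one protein/HMM pair are merged into a
#' single hit keeping the maximum full-sequence score and the union of domain
#' envelopes.
#'
#' @param path Path to the tabular file. Lines beginning with `#` are ignored.
#' @param dialect `"domtblout"` (22+ columns, yields domain envelopes) or
#'   `"tblout"` (18+ columns, full-sequence scores only).
#' @return A data frame with one row per protein/HMM pair: `protein_id`,
#'   `hmm_id`, `full_score` (bit score), `n_domains`, and a list column
#'   `envelopes` of data frames with `env_start`, `env_end`, `dom_score`
#'   (1-based inclusive residue coordinates; empty for tblout).
#' @export
read_hmm_hits <- function(path, dialect = c("domtblout", "tblout")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("hit table not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) {
    return(.empty_hits())
  }
  need <- if (dialect == "tblout") 18L else 22L
  toks <- strsplit(trimws(lines), "[ \t]+")
  nt <- lengths(toks)
  if (any(nt < need)) {
    bad <- which(nt < need)[1]
    stop(sprintf(
      "%s requires >= %d whitespace-delimited columns; data line %d of %s has %d (wrong dialect?)",
      dialect, need, bad, path, nt[bad]))
  }
  col <- function(i) vapply(toks, `[[`, character(1), i)
  protein_id <- col(1L)
  if (dialect == "tblout") {
    hmm_id <- col(3L)
    full_score <- as.numeric(col(6L))
    env <- NULL
  } else {
    hmm_id <- col(4L)
    full_score <- as.numeric(col(8L))
    env <- data.frame(env_start = as.integer(col(20L)),
                      env_end = as.integer(col(21L)),
                      dom_score = as.numeric(col(14L)),
                      stringsAsFactors = FALSE)
    if (any(env$env_start > env$env_end)) {
      stop("domtblout envelope with env_start > env_end in ", path)
    }
  }
  if (any(is.na(full_score))) {
    stop("non-numeric full-sequence score in ", path, " (wrong dialect?)")
  }
  key <- paste(protein_id, hmm_id, sep = "\r")
  first <- !duplicated(key)
  groups <- split(seq_along(key), factor(key, levels = key[first]))
  rows <- lapply(groups, function(ix) {
    e <- if (is.null(env)) {
      data.frame(env_start = integer(), env_end = integer(),
                 dom_score = numeric(), stringsAsFactors = FALSE)
    } else {
      unique(env[ix, , drop = FALSE])
    }
    rownames(e) <- NULL
    list(protein_id = protein_id[ix[1]], hmm_id = hmm_id[ix[1]],
         full_score = max(full_score[ix]), envelopes = e)
  })
  out <- data.frame(
    protein_id = vapply(rows, `[[`, character(1), "protein_id"),
    hmm_id = vapply(rows, `[[`, character(1), "hmm_id"),
    full_score = vapply(rows, `[[`, numeric(1), "full_score"),
    stringsAsFactors = FALSE
  )
  out$n_domains <- vapply(rows, function(r) nrow(r$envelopes), integer(1))
  out$envelopes <- lapply(rows, `[[`, "envelopes")
  rownames(out) <- NULL
  out
}

.scan_table_columns <- c("start", "length", "midpoint", "score",
                         "k_at_min", "y_at_min", "min_probability")

#' Write a scan result as a tab-delimited table
#'
#' The scan table is the suite's plain-text interchange format: `#`-prefixed
#' header lines carry the scan metadata (query id and length, scan parameters,
#' YES/NO training counts), followed by a column header and one row per scored
#' window. Numbers are printed with 10 significant digits; [read_scan_table()]
#' inverts the file to that precision.
#'
#' @param result A `scan_result` from [scan_query()] (or a rescored copy).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_table <- function(result, path) {
  stopifnot(inherits(result, "scan_result"))
  if (nrow(result$windows) == 0L) {
    stop("scan result contains no windows")
  }
  p <- result$params
  meta <- c(
    "# simbal scan table",
    paste0("# query_id=", result$query_id),
    paste0("# query_length=", result$query_length),
    paste0("# min_length=", p$min_length),
    paste0("# length_step=", p$length_step),
    paste0("# position_step=", p$position_step),
    paste0("# max_hits=", if (is.null(p$max_hits)) "none" else p$max_hits),
    paste0("# backend=", p$backend),
    paste0("# Y=", result$Y),
    paste0("# N=", result$N)
  )
  w <- result$windows[, .scan_table_columns]
  fmt <- function(x) {
    if (is.numeric(x) && !is.integer(x)) sprintf("%.10g", x) else as.character(x)
  }
  body <- do.call(paste, c(lapply(w, fmt), sep = "\t"))
  writeLines(c(meta, paste(.scan_table_columns, collapse = "\t"), body), path)
  invisible(path)
}

#' Read a scan table written by [write_scan_table()]
#'
#' @param path Path to a scan table file.
#' @return A `scan_result` object.
#' @export
read_scan_table <- function(path) {
  if (!file.exists(path)) {
    stop("scan table not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  metaln <- lines[startsWith(lines, "#")]
  kv <- regmatches(metaln, regexec("^# ([a-zA-Z_]+)=(.*)$", metaln))
  kv <- kv[lengths(kv) == 3]
  meta <- stats::setNames(vapply(kv, `[[`, character(1), 3),
                          vapply(kv, `[[`, character(1), 2))
  body <- lines[!startsWith(lines, "#")]
  w <- utils::read.delim(text = body, stringsAsFactors = FALSE)
  if (!identical(names(w), .scan_table_columns)) {
    stop("unexpected scan table columns in ", path, ": ",
         paste(names(w), collapse = ", "))
  }
  max_hits <- meta[["max_hits"]]
  params <- scan_params(
    min_length = as.integer(meta[["min_length"]]),
    length_step = as.integer(meta[["length_step"]]),
    position_step = as.integer(meta[["position_step"]]),
    max_hits = if (identical(max_hits, "none")) NULL else as.integer(max_hits),
    backend = meta[["backend"]]
  )
  structure(list(
    query_id = meta[["query_id"]],
    query_length = as.integer(meta[["query_length"]]),
    params = params,
    Y = as.integer(meta[["Y"]]),
    N = as.integer(meta[["N"]]),
    windows = w
  ), class = "scan_result")
}
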