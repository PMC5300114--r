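#' Extract HMM-matched domain regions as standalone sequences
#'
#' For every domain envelope in `hits`, cuts the region
#' `[env_start - flank, env_end + flank]` (clamped to the sequence) out of the
#' source protein and exports it as its own record, pulling multiple domains
#' from a single protein when the protein has repeats or duplications.
#' Exported ids are `source_id/cut_start-cut_end`.
#'
#' @param seqs An `AAStringSet` containing every protein referenced by `hits`.
#' @param hits A hit data frame from [read_hmm_hits()] with domain envelopes
#'   (domtblout-derived).
#' @param flank Non-negative number of flanking residues to include on each
#'   side.
#' @return An `AAStringSet` of domain cuts with `mcols()` columns `source_id`,
#'   `ordinal`, `cut_start`, `cut_end`.
#' @export
extract_domains <- function(seqs, hits, flank = 0L) {
  stopifnot(methods::is(seqs, "XStringSet"), flank >= 0)
  flank <- as.integer(flank)
  rows <- list()
  ord_count <- new.env(parent = emptyenv())
  for (h in seq_len(nrow(hits))) {
    pid <- hits$protein_id[h]
    env <- hits$envelopes[[h]]
    if (is.null(env) || nrow(env) == 0L) next
    if (!pid %in% names(seqs)) {
      stop("hit references protein ", pid, " absent from the sequence set")
    }
    len <- Biostrings::width(seqs[pid])
    if (any(env$env_end > len)) {
      stop("envelope beyond sequence length for ", pid,
           " (length ", len, "); corrupt inputs?")
    }
    for (e in seq_len(nrow(env))) {
      n_prev <- if (exists(pid, ord_count)) get(pid, ord_count) else 0L
      assign(pid, n_prev + 1L, ord_count)
      cs <- max(1L, env$env_start[e] - flank)
      ce <- min(len, env$env_end[e] + flank)
      rows[[length(rows) + 1L]] <- data.frame(
        source_id = pid, ordinal = n_prev + 1L, cut_start = cs, cut_end = ce,
        residues = as.character(Biostrings::subseq(seqs[[pid]], cs, ce)),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    out <- Biostrings::AAStringSet()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      source_id = character(), ordinal = integer(),
      cut_start = integer(), cut_end = integer())
    return(out)
  }
  df <- do.call(rbind, rows)
  ids <- sprintf("%s/%d-%d", df$source_id, df$cut_start, df$cut_end)
  keep <- !duplicated(ids)
  df <- df[keep, , drop = FALSE]
  ids <- ids[keep]
  out <- Biostrings::AAStringSet(df$residues)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    source_id = df$source_id, ordinal = df$ordinal,
    cut_start = df$cut_start, cut_end = df$cut_end)
  out
}

#' Global percent identity between two sequences
#'
#' Needleman-Wunsch-style identity with free end gaps (an "overlap"
#' alignment): matches divided by alignment columns, excluding terminal-gap
#' columns, so that domain cuts with unequal flank lengths still compare on
#' their shared region. Returns 0 when the optimal overlap is empty.
#'
#' @param a,b Non-empty amino-acid strings (or `AAString`s).
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  stopifnot(nzchar(a), nzchar(b))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "overlap",
    substitutionMatrix = .blosum62(), gapOpening = 10, gapExtension = 0.5)
  ncols <- Biostrings::nchar(aln)
  if (is.na(ncols) || ncols == 0L) return(0)
  Biostrings::nmatch(aln) / ncols
}

.simbal_cache <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.simbal_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .simbal_cache$BLOSUM62 <- e$BLOSUM62
  }
  .simbal_cache$BLOSUM62
}

#' Reduce redundancy by greedy identity clustering
#'
#' UCLUST-style greedy centroid clustering: sequences are processed
#' longest-first (ties in input order); each sequence joins the first existing
#' centroid with [pairwise_identity()] at or above the threshold, otherwise it
#' founds a new centroid. The returned centroids are a subset of the input
#' records (no consensus chimeras), so no two survivors are more similar than
#' the threshold. Users preferring USEARCH/CD-HIT/blastclust can substitute
#' them freely: the contract is FASTA in, centroid FASTA out.
#'
#' @param seqs A named `AAStringSet`.
#' @param identity_threshold Identity fraction in (0, 1); default 0.8, i.e.
#'   surviving sequences are never 80% or more identical.
#' @return An `AAStringSet` of centroids in founding order, with an
#'   `assignment` attribute mapping every input id to its centroid id.
#' @export
cluster_nonredundant <- function(seqs, identity_threshold = 0.8) {
  stopifnot(methods::is(seqs, "XStringSet"),
            identity_threshold > 0, identity_threshold < 1)
  n <- length(seqs)
  if (n == 0L) {
    attr(seqs, "assignment") <- data.frame(id = character(),
                                           centroid = character(),
                                           stringsAsFactors = FALSE)
    return(seqs)
  }
  ord <- order(-Biostrings::width(seqs))  # stable: ties keep input order
  cent_idx <- integer(0)
  centroid_of <- character(n)
  for (i in ord) {
    joined <- FALSE
    for (ci in cent_idx) {
      if (pairwise_identity(seqs[[i]], seqs[[ci]]) >= identity_threshold) {
        centroid_of[i] <- names(seqs)[ci]
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      cent_idx <- c(cent_idx, i)
      centroid_of[i] <- names(seqs)[i]
    }
  }
  out <- seqs[cent_idx]
  attr(out, "assignment") <- data.frame(id = names(seqs),
                                        centroid = centroid_of,
                                        stringsAsFactors = FALSE)
  out
}
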