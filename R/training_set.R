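#' Parse a training-set configuration file
#'
#' The configuration grammar is `KEY: VALUE` lines with keys `TARGET`,
#' `TARGET SCORE`, `YES` and `NO`; `#` begins a comment line. A clause is
#' `PATH/NAME.HMM>score` (family present: some hit scoring strictly above) or
#' `PATH/NAME.HMM<score` (family absent: no hit scoring at or above). A `YES`
#' line may be a parenthesized comma-separated OR-group, optionally prefixed
#' inside the parentheses by `[N]`, a gene-neighborhood distance constraint in
#' base pairs. Separate `YES` lines are AND-ed groups; separate `NO` lines are
#' AND-ed clauses. HMM ids are normalized by dropping the directory part and a
#' trailing `.HMM`.
#'
#' @param text Configuration text: a single string or a character vector of
#'   lines.
#' @return A `partition_rules` object: `target_hmm`, `target_cutoff`,
#'   `yes_groups` (each a list with a `clauses` data frame and a `distance`
#'   flag), `no_clauses` (data frame), `yes_distance_bp` (integer or `NULL`).
#' @examples
#' rules <- parse_config(c(
#'   "TARGET: PFAM/PF04055.HMM",
#'   "TARGET SCORE: 29.4",
#'   "YES: ([500] TIGRFAM/TIGR03973.HMM>35)",
#'   "NO: TIGRFAM/TIGR03973.HMM<35"))
#' rules$yes_distance_bp
#' @export
parse_config <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  if (length(lines) == 0L || !any(nzchar(trimws(lines)))) {
    stop("empty configuration")
  }
  target_hmm <- NULL
  target_cutoff <- NULL
  yes_groups <- list()
  no_clauses <- list()
  distances <- integer(0)
  for (i in seq_along(lines)) {
    raw <- trimws(lines[i])
    if (!nzchar(raw) || startsWith(raw, "#")) next
    m <- regexec("^([A-Za-z][A-Za-z ]*?)\\s*:\\s*(.*)$", raw)
    parts <- regmatches(raw, m)[[1]]
    if (length(parts) != 3L) {
      stop("unparseable configuration line ", i, ": ", raw)
    }
    key <- toupper(parts[2])
    value <- trimws(parts[3])
    if (key == "TARGET") {
      if (!is.null(target_hmm)) stop("duplicate TARGET at line ", i)
      target_hmm <- .clean_hmm_id(value)
    } else if (key == "TARGET SCORE") {
      if (!is.null(target_cutoff)) stop("duplicate TARGET SCORE at line ", i)
      target_cutoff <- suppressWarnings(as.numeric(value))
      if (is.na(target_cutoff)) stop("non-numeric TARGET SCORE at line ", i)
    } else if (key == "NO") {
      no_clauses[[length(no_clauses) + 1L]] <- .parse_clause(value, i)
    } else if (key == "YES") {
      grp <- .parse_yes_group(value, i)
      yes_groups[[length(yes_groups) + 1L]] <- grp
      if (grp$distance) distances <- c(distances, grp$distance_bp)
    } else {
      stop("unknown configuration key '", parts[2], "' at line ", i)
    }
  }
  missing <- c(if (is.null(target_hmm)) "TARGET",
               if (is.null(target_cutoff)) "TARGET SCORE",
               if (length(yes_groups) == 0L) "YES",
               if (length(no_clauses) == 0L) "NO")
  if (length(missing) > 0) {
    stop("configuration is missing required key(s): ",
         paste(missing, collapse = ", "))
  }
  distances <- unique(distances)
  if (length(distances) > 1L) {
    stop("conflicting [N] distance constraints: ",
         paste(distances, collapse = ", "))
  }
  structure(list(
    target_hmm = target_hmm,
    target_cutoff = target_cutoff,
    yes_groups = lapply(yes_groups, function(g) g[c("clauses", "distance")]),
    no_clauses = do.call(rbind, no_clauses),
    yes_distance_bp = if (length(distances)) distances else NULL
  ), class = "partition_rules")
}

.clean_hmm_id <- function(x) {
  x <- sub(".*/", "", trimws(x))
  sub("\\.hmm$", "", x, ignore.case = TRUE)
}

.parse_clause <- function(txt, line) {
  m <- regexec("^(\\S+?)\\s*([<>])\\s*([-+0-9.eE]+)$", trimws(txt))
  parts <- regmatches(trimws(txt), m)[[1]]
  thr <- if (length(parts) == 4L) suppressWarnings(as.numeric(parts[4])) else NA
  if (length(parts) != 4L || is.na(thr) || !is.finite(thr)) {
    stop("unparseable clause at line ", line, ": ", txt)
  }
  data.frame(hmm_id = .clean_hmm_id(parts[2]),
             direction = if (parts[3] == ">") "above" else "below",
             threshold = thr, stringsAsFactors = FALSE)
}

.parse_yes_group <- function(value, line) {
  inner <- value
  if (startsWith(inner, "(")) {
    if (!endsWith(inner, ")")) {
      stop("unbalanced parentheses in YES group at line ", line)
    }
    inner <- trimws(substr(inner, 2L, nchar(inner) - 1L))
  }
  distance <- FALSE
  distance_bp <- NA_integer_
  m <- regexec("^\\[(\\d+)\\]\\s*(.*)$", inner)
  parts <- regmatches(inner, m)[[1]]
  if (length(parts) == 3L) {
    distance <- TRUE
    distance_bp <- as.integer(parts[2])
    inner <- parts[3]
  }
  clauses <- lapply(strsplit(inner, ",", fixed = TRUE)[[1]],
                    .parse_clause, line = line)
  list(clauses = do.call(rbind, clauses), distance = distance,
       distance_bp = distance_bp)
}

#' @export
print.partition_rules <- function(x, ...) {
  cat("Training-set partition rules\n")
  cat("  target:", x$target_hmm, "(full-sequence score >", x$target_cutoff, ")\n")
  for (g in x$yes_groups) {
    tag <- if (g$distance) sprintf(" [within %d bp]", x$yes_distance_bp) else ""
    cat("  YES", tag, ": ",
        paste(sprintf("%s %s %g", g$clauses$hmm_id,
                      ifelse(g$clauses$direction == "above", ">", "<"),
                      g$clauses$threshold), collapse = " OR "), "\n", sep = "")
  }
  cat("  NO  : ",
      paste(sprintf("%s %s %g", x$no_clauses$hmm_id,
                    ifelse(x$no_clauses$direction == "above", ">", "<"),
                    x$no_clauses$threshold), collapse = " AND "), "\n", sep = "")
  invisible(x)
}

.clause_satisfied <- function(hmm_id, direction, threshold, hits) {
  s <- if (is.null(hits) || nrow(hits) == 0L) numeric(0) else
    hits$full_score[hits$hmm_id == hmm_id]
  if (direction == "above") any(s > threshold) else !any(s >= threshold)
}

#' Classify a genome as YES-eligible, NO or indeterminate
#'
#' Evaluates the attribute-HMM criteria of a rule set against one genome's
#' hits. A genome is YES-eligible when every YES group has at least one
#' satisfied clause (groups AND-ed, clauses within a group OR-ed), NO when
#' every NO clause is satisfied (for a `below` clause, no hit at or above the
#' threshold — vacuously true with no hits at all), and indeterminate
#' otherwise. Genomes whose best attribute hit falls in the gray zone between
#' the NO and YES thresholds come out indeterminate and contribute nothing to
#' a training set. If a degenerate rule set makes a genome satisfy both sides,
#' YES-eligible takes precedence.
#'
#' @param hits A hit data frame (as from [read_hmm_hits()]) for one genome.
#' @param rules A `partition_rules` object.
#' @return `"YES-eligible"`, `"NO"` or `"indeterminate"`.
#' @export
evaluate_genome <- function(hits, rules) {
  stopifnot(inherits(rules, "partition_rules"))
  yes_ok <- all(vapply(rules$yes_groups, function(g) {
    any(vapply(seq_len(nrow(g$clauses)), function(i) {
      .clause_satisfied(g$clauses$hmm_id[i], g$clauses$direction[i],
                        g$clauses$threshold[i], hits)
    }, logical(1)))
  }, logical(1)))
  if (yes_ok) return("YES-eligible")
  no_ok <- all(vapply(seq_len(nrow(rules$no_clauses)), function(i) {
    .clause_satisfied(rules$no_clauses$hmm_id[i], rules$no_clauses$direction[i],
                      rules$no_clauses$threshold[i], hits)
  }, logical(1)))
  if (no_ok) "NO" else "indeterminate"
}

#' Nucleotide distance between two gene intervals
#'
#' Strand-agnostic gap between gene intervals on the same replicon: `Inf` when
#' the replicons differ, `0` when the intervals overlap or abut, otherwise the
#' number of nucleotides strictly between the nearest interval ends.
#'
#' @param a,b Single gene features: lists or one-row data frames with
#'   `replicon_id`, `start`, `end` (1-based inclusive).
#' @return A non-negative number, possibly `Inf`.
#' @export
gene_distance <- function(a, b) {
  if (as.character(a$replicon_id) != as.character(b$replicon_id)) {
    return(Inf)
  }
  max(0, max(a$start, b$start) - min(a$end, b$end) - 1)
}

#' Bundle one genome's sequences, hits and features
#'
#' @param genome_id Genome identifier.
#' @param proteins An `AAStringSet` of the genome's protein sequences.
#' @param hits Hit data frame for this genome (target and attribute HMMs).
#' @param features Optional gene feature data frame from
#'   [read_gff_features()]; required for distance-mode partitioning.
#' @return A `genome_record` object.
#' @export
genome_record <- function(genome_id, proteins, hits, features = NULL) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L,
            methods::is(proteins, "XStringSet"))
  structure(list(genome_id = genome_id, proteins = proteins,
                 hits = hits, features = features),
            class = "genome_record")
}

#' Partition target-family proteins into YES/NO/FAR training sets
#'
#' Applies a rule set genome by genome. Target proteins are those whose
#' target-HMM full-sequence score is strictly above the target cutoff. All
#' targets from NO genomes go to the NO set. From YES-eligible genomes,
#' without a distance rule all targets go to the YES set; with a distance rule,
#' targets whose gene lies within `yes_distance_bp` of an above-threshold
#' attribute gene (from a distance-tagged YES group) go to the YES set, and the
#' genome's remaining targets go to the FAR set — but only if the genome
#' contributed at least one YES record. A YES-eligible genome with no
#' near-enough target, and any indeterminate genome, contributes nothing.
#'
#' @param genomes A list of [genome_record()] objects.
#' @param rules A `partition_rules` object.
#' @return A `training_set` object: `AAStringSet`s `yes`, `no`, `far` and a
#'   `provenance` data frame (`genome_id`, `protein_id`, `partition`,
#'   `reason`).
#' @export
partition_targets <- function(genomes, rules) {
  stopifnot(inherits(rules, "partition_rules"))
  distance_mode <- !is.null(rules$yes_distance_bp)
  prov <- list()
  seqs <- list(YES = list(), NO = list(), FAR = list())
  grab <- function(g, pid) {
    if (!pid %in% names(g$proteins)) {
      stop("target protein ", pid, " has a hit but no sequence in genome ",
           g$genome_id)
    }
    g$proteins[pid]
  }
  add <- function(g, pid, partition, reason) {
    prov[[length(prov) + 1L]] <<- data.frame(
      genome_id = g$genome_id, protein_id = pid, partition = partition,
      reason = reason, stringsAsFactors = FALSE)
    seqs[[partition]][[length(seqs[[partition]]) + 1L]] <<- grab(g, pid)
  }
  for (g in genomes) {
    stopifnot(inherits(g, "genome_record"))
    hits <- g$hits
    th <- hits[hits$hmm_id == rules$target_hmm &
                 hits$full_score > rules$target_cutoff, , drop = FALSE]
    tids <- unique(th$protein_id)
    if (length(tids) == 0L) next
    verdict <- evaluate_genome(hits, rules)
    if (verdict == "NO") {
      for (pid in tids) add(g, pid, "NO", "NO genome")
    } else if (verdict == "YES-eligible" && !distance_mode) {
      for (pid in tids) add(g, pid, "YES", "YES genome")
    } else if (verdict == "YES-eligible") {
      if (is.null(g$features)) {
        stop("distance rule requires gene features, missing for genome ",
             g$genome_id)
      }
      anchors <- .anchor_features(g, rules)
      near <- logical(length(tids))
      dmin <- numeric(length(tids))
      for (i in seq_along(tids)) {
        tf <- g$features[g$features$protein_id == tids[i], , drop = FALSE]
        if (nrow(tf) == 0L) {
          stop("no gene feature for target protein ", tids[i], " in genome ",
               g$genome_id)
        }
        d <- Inf
        if (nrow(anchors) > 0L) {
          for (j in seq_len(nrow(anchors))) {
            d <- min(d, gene_distance(tf[1, ], anchors[j, ]))
          }
        }
        dmin[i] <- d
        near[i] <- d <= rules$yes_distance_bp
      }
      if (any(near)) {
        for (i in which(near)) {
          add(g, tids[i], "YES",
              sprintf("within %d bp of attribute gene", rules$yes_distance_bp))
        }
        for (i in which(!near)) {
          add(g, tids[i], "FAR",
              sprintf("attribute gene present but %s bp away",
                      format(dmin[i])))
        }
      }
      # YES-eligible genome with no qualifying target: contributes nothing
    }
    # indeterminate: contributes nothing
  }
  provenance <- if (length(prov)) do.call(rbind, prov) else
    data.frame(genome_id = character(), protein_id = character(),
               partition = character(), reason = character(),
               stringsAsFactors = FALSE)
  collect <- function(partition) {
    if (length(seqs[[partition]]) == 0L) return(Biostrings::AAStringSet())
    out <- do.call(c, seqs[[partition]])
    if (anyDuplicated(names(out))) {
      ix <- provenance$partition == partition
      names(out) <- paste(provenance$genome_id[ix], provenance$protein_id[ix],
                          sep = "|")
    }
    out
  }
  structure(list(yes = collect("YES"), no = collect("NO"),
                 far = collect("FAR"), provenance = provenance),
            class = "training_set")
}

# attribute genes anchoring the distance rule: proteins with a hit strictly
# above an 'above' clause threshold in a distance-tagged YES group
.anchor_features <- function(g, rules) {
  pids <- character(0)
  for (grp in rules$yes_groups) {
    if (!grp$distance) next
    cl <- grp$clauses
    for (i in seq_len(nrow(cl))) {
      if (cl$direction[i] != "above") next
      sel <- g$hits$hmm_id == cl$hmm_id[i] & g$hits$full_score > cl$threshold[i]
      pids <- c(pids, g$hits$protein_id[sel])
    }
  }
  pids <- unique(pids)
  if (is.null(g$features)) {
    return(data.frame(protein_id = character(), replicon_id = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  g$features[g$features$protein_id %in% pids, , drop = FALSE]
}

#' @export
print.training_set <- function(x, ...) {
  cat("Training set: ", length(x$yes), " YES, ", length(x$no), " NO, ",
      length(x$far), " FAR sequences from ",
      length(unique(x$provenance$genome_id)), " genome(s)\n", sep = "")
  invisible(x)
}
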