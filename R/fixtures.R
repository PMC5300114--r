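# Seeded synthetic genomes, hit tables and planted-signature training sets.
# All randomness flows from the single seed in the spec; no global RNG state
# leaks in or out.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

.random_protein <- function(n) {
  paste(sample(.AA20, n, replace = TRUE), collapse = "")
}

# substitute each position with a *different* residue with probability rate
.mutate_seq <- function(x, rate, keep = integer(0)) {
  if (rate <= 0) return(x)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  hit <- setdiff(hit, keep)
  for (i in hit) {
    chars[i] <- sample(setdiff(.AA20, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Plant a sequence signature into a base sequence
#'
#' Writes `motif` into `base` starting at `position`, then applies per-residue
#' substitutions at `mutation_rate` across the whole sequence (each mutated
#' position receives a different residue), optionally sparing a conserved
#' core. Deterministic for a given seed.
#'
#' @param base Amino-acid string.
#' @param motif Amino-acid string to plant (length >= 1).
#' @param position 1-based start; `position + nchar(motif) - 1` must not
#'   exceed `nchar(base)`.
#' @param mutation_rate Per-residue substitution probability in `[0, 1]`.
#' @param seed Integer seed.
#' @param conserved_core Optional integer positions never mutated.
#' @return The modified sequence string.
#' @export
plant_signature <- function(base, motif, position, mutation_rate = 0,
                            seed = 1L, conserved_core = integer(0)) {
  stopifnot(nchar(motif) >= 1L, position >= 1L)
  if (position + nchar(motif) - 1L > nchar(base)) {
    stop("motif does not fit: position ", position, " + motif length ",
         nchar(motif), " exceeds base length ", nchar(base))
  }
  substr(base, position, position + nchar(motif) - 1L) <- motif
  .with_seed(seed, .mutate_seq(base, mutation_rate, keep = conserved_core))
}

#' Specification for a synthetic genome set
#'
#' Describes a seeded population of toy genomes for exercising the whole
#' pipeline. Each genome carries target-family proteins drawn as mutated
#' copies of a common family consensus; with probability `p_attribute` a
#' genome additionally carries an attribute protein and exactly one "true"
#' target bearing the planted motif. The per-genome target counts emulate a
#' family where attribute-positive genomes average more target paralogs
#' (defaults 2.7 vs 1.5, matching a realistically diluted YES partition).
#'
#' @param n_genomes Number of genomes (default 40).
#' @param p_attribute Probability a genome carries the attribute family.
#' @param yes_targets_mean,no_targets_mean Mean target-family paralogs per
#'   attribute-positive / attribute-negative genome.
#' @param motif Amino-acid signature planted only in true targets (length
#'   >= 6).
#' @param motif_position 1-based residue offset of the motif.
#' @param mutation_rate Per-residue substitution rate applied to each true
#'   target's copy of the motif.
#' @param target_length Length of target-family proteins.
#' @param background_divergence Per-residue substitution rate from the family
#'   consensus for every target (motif region excepted in true targets);
#'   0.4 keeps family members recognizably homologous (~40% identity) while
#'   uninformative about the attribute.
#' @param distance_bp Distance constraint written into the generated
#'   configuration ([N] on the YES group); `NULL` generates a bag-of-genes
#'   configuration with no FAR set.
#' @param seed Integer seed; identical specs generate byte-identical outputs.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(n_genomes = 40L, p_attribute = 0.5,
                         yes_targets_mean = 2.7, no_targets_mean = 1.5,
                         motif = "CHWKDGYPRFEW", motif_position = 46L,
                         mutation_rate = 0.1, target_length = 120L,
                         background_divergence = 0.4, distance_bp = 500L,
                         seed = 101L) {
  stopifnot(n_genomes >= 1L, p_attribute >= 0, p_attribute <= 1,
            yes_targets_mean >= 1, no_targets_mean >= 0,
            nchar(motif) >= 6L, mutation_rate >= 0, mutation_rate <= 1,
            background_divergence >= 0, background_divergence < 1)
  if (motif_position + nchar(motif) - 1L > target_length) {
    stop("motif does not fit in a target of length ", target_length)
  }
  structure(list(n_genomes = as.integer(n_genomes), p_attribute = p_attribute,
                 yes_targets_mean = yes_targets_mean,
                 no_targets_mean = no_targets_mean, motif = motif,
                 motif_position = as.integer(motif_position),
                 mutation_rate = mutation_rate,
                 target_length = as.integer(target_length),
                 background_divergence = background_divergence,
                 distance_bp = if (is.null(distance_bp)) NULL else
                   as.integer(distance_bp),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

.FIXTURE_TARGET_HMM <- "TARGFAM"
.FIXTURE_ATTR_HMM <- "ATTRFAM"
.FIXTURE_TARGET_CUTOFF <- 25
.FIXTURE_ATTR_THRESHOLD <- 35

.fixture_config <- function(spec) {
  yes <- if (is.null(spec$distance_bp)) {
    sprintf("YES: (HMM/%s.HMM>%g)", .FIXTURE_ATTR_HMM, .FIXTURE_ATTR_THRESHOLD)
  } else {
    sprintf("YES: ([%d] HMM/%s.HMM>%g)", spec$distance_bp, .FIXTURE_ATTR_HMM,
            .FIXTURE_ATTR_THRESHOLD)
  }
  c("# synthetic fixture configuration",
    sprintf("TARGET: HMM/%s.HMM", .FIXTURE_TARGET_HMM),
    sprintf("TARGET SCORE: %g", .FIXTURE_TARGET_CUTOFF),
    yes,
    sprintf("NO: HMM/%s.HMM<%g", .FIXTURE_ATTR_HMM, .FIXTURE_ATTR_THRESHOLD))
}

#' Generate a seeded synthetic genome set
#'
#' Builds toy genomes, per-genome hit tables and a matching configuration so
#' every pipeline stage runs without downloads. Attribute-positive genomes
#' receive an attribute protein (scored well above the YES threshold), one
#' true target carrying the planted motif, and decoy target paralogs; other
#' genomes receive only decoys and no attribute hit. Gene features place the
#' true target within the distance constraint of the attribute gene and
#' decoys far beyond it. Hit tables are synthesized directly from the truth
#' table (scores drawn above the respective cutoffs) so the rule engine is
#' testable independently of any profile-HMM executable.
#'
#' @param spec A [fixture_spec()].
#' @return A `genome_set`: `genomes` (list of [genome_record()]), `config`
#'   (configuration lines), `rules` (parsed), `truth` (data frame with one
#'   row per protein: `genome_id`, `protein_id`, `role`, `verdict`,
#'   `expected_partition`), `query_id` (the first true target), `motif_span`
#'   (`c(start, end)`), and the generating `spec`.
#' @export
generate_genome_set <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  .with_seed(spec$seed, {
    consensus <- .random_protein(spec$target_length)
    attr_len <- 90L
    genomes <- vector("list", spec$n_genomes)
    truth <- list()
    for (gi in seq_len(spec$n_genomes)) {
      gid <- sprintf("G%03d", gi)
      replicon <- paste0(gid, "_chr")
      has_attr <- stats::runif(1) < spec$p_attribute
      pnum <- 0L
      next_pid <- function() {
        pnum <<- pnum + 1L
        sprintf("%s_P%02d", gid, pnum)
      }
      seq_list <- character(0)
      feat <- list()
      hit <- list()
      add_feature <- function(pid, start, len_nt) {
        feat[[length(feat) + 1L]] <<- data.frame(
          protein_id = pid, replicon_id = replicon, start = start,
          end = start + len_nt - 1L, strand = "+", stringsAsFactors = FALSE)
      }
      add_hit <- function(pid, hmm, score, plen) {
        hit[[length(hit) + 1L]] <<- list(
          protein_id = pid, hmm_id = hmm, full_score = score,
          envelopes = data.frame(env_start = 1L, env_end = plen,
                                 dom_score = score, stringsAsFactors = FALSE))
      }
      add_truth <- function(pid, role, verdict, expected) {
        truth[[length(truth) + 1L]] <<- data.frame(
          genome_id = gid, protein_id = pid, role = role, verdict = verdict,
          expected_partition = expected, stringsAsFactors = FALSE)
      }
      verdict <- if (has_attr) "YES-eligible" else "NO"
      if (has_attr) {
        # attribute protein near the replicon origin
        apid <- next_pid()
        seq_list[apid] <- .random_protein(attr_len)
        add_feature(apid, 10000L, attr_len * 3L + 3L)
        add_hit(apid, .FIXTURE_ATTR_HMM,
                round(stats::runif(1, 50, 120), 1), attr_len)
        add_truth(apid, "attribute", verdict, "none")
        attr_end <- 10000L + attr_len * 3L + 2L
        # one true target just downstream, inside the distance constraint
        tpid <- next_pid()
        s <- .mutate_seq(consensus, spec$background_divergence)
        mut_motif <- .mutate_seq(spec$motif, spec$mutation_rate)
        substr(s, spec$motif_position,
               spec$motif_position + nchar(spec$motif) - 1L) <- mut_motif
        seq_list[tpid] <- s
        gap <- sample(50:300, 1L)
        add_feature(tpid, attr_end + 1L + gap, spec$target_length * 3L + 3L)
        add_hit(tpid, .FIXTURE_TARGET_HMM,
                round(stats::runif(1, 40, 90), 1), spec$target_length)
        add_truth(tpid, "true_target", verdict,
                  "YES")
        n_decoys <- stats::rpois(1, max(0, spec$yes_targets_mean - 1))
      } else {
        n_decoys <- stats::rpois(1, spec$no_targets_mean)
      }
      if (n_decoys > 0) {
        for (d in seq_len(n_decoys)) {
          dpid <- next_pid()
          seq_list[dpid] <- .mutate_seq(consensus, spec$background_divergence)
          # decoy genes sit far from the attribute gene
          add_feature(dpid, 200000L + d * 100000L,
                      spec$target_length * 3L + 3L)
          add_hit(dpid, .FIXTURE_TARGET_HMM,
                  round(stats::runif(1, 40, 90), 1), spec$target_length)
          expected <- if (!has_attr) "NO" else
            if (is.null(spec$distance_bp)) "YES" else "FAR"
          add_truth(dpid, "decoy", verdict, expected)
        }
      }
      proteins <- Biostrings::AAStringSet(seq_list)
      hits <- if (length(hit)) {
        df <- data.frame(
          protein_id = vapply(hit, `[[`, character(1), "protein_id"),
          hmm_id = vapply(hit, `[[`, character(1), "hmm_id"),
          full_score = vapply(hit, `[[`, numeric(1), "full_score"),
          stringsAsFactors = FALSE)
        df$n_domains <- rep(1L, nrow(df))
        df$envelopes <- lapply(hit, `[[`, "envelopes")
        df
      } else {
        .empty_hits()
      }
      features <- if (length(feat)) do.call(rbind, feat) else NULL
      genomes[[gi]] <- genome_record(gid, proteins, hits, features)
    }
    truth <- do.call(rbind, truth)
    config <- .fixture_config(spec)
    true_targets <- truth$protein_id[truth$role == "true_target"]
    structure(list(
      genomes = genomes, config = config, rules = parse_config(config),
      truth = truth,
      query_id = if (length(true_targets)) true_targets[1] else NA_character_,
      motif_span = c(spec$motif_position,
                     spec$motif_position + nchar(spec$motif) - 1L),
      spec = spec
    ), class = "genome_set")
  })
}

#' @export
print.genome_set <- function(x, ...) {
  cat("Synthetic genome set: ", length(x$genomes), " genomes, ",
      sum(x$truth$role == "true_target"), " true targets, ",
      sum(x$truth$role == "decoy"), " decoys (seed ", x$spec$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Pull the default query sequence from a genome set
#'
#' Returns the first planted true target (the motif-bearing protein a scan is
#' expected to localize) as a length-1 `AAStringSet`.
#'
#' @param gs A `genome_set` from [generate_genome_set()].
#' @return A named `AAStringSet` of length 1.
#' @export
fixture_query <- function(gs) {
  stopifnot(inherits(gs, "genome_set"))
  if (is.na(gs$query_id)) {
    stop("genome set contains no true target (p_attribute = 0?)")
  }
  gid <- gs$truth$genome_id[gs$truth$protein_id == gs$query_id][1]
  for (g in gs$genomes) {
    if (g$genome_id == gid) return(g$proteins[gs$query_id])
  }
  stop("query genome not found")  # unreachable
}

.write_gff <- function(features, path) {
  lines <- "##gff-version 3"
  if (!is.null(features) && nrow(features) > 0) {
    lines <- c(lines, sprintf(
      "%s\tsimbal_fixture\tCDS\t%d\t%d\t.\t%s\t0\tID=cds-%s;protein_id=%s",
      features$replicon_id, features$start, features$end, features$strand,
      features$protein_id, features$protein_id))
  }
  writeLines(lines, path)
}

.write_domtbl <- function(hits, path) {
  header <- c(
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    paste0("#", strrep("-", 120)))
  lines <- character(0)
  for (i in seq_len(nrow(hits))) {
    env <- hits$envelopes[[i]]
    for (e in seq_len(nrow(env))) {
      tlen <- env$env_end[nrow(env)]
      lines <- c(lines, sprintf(
        "%s - %d %s - %d %.1e %.1f 0.0 %d %d %.1e %.1e %.1f 0.0 1 %d %d %d %d %d 0.95 -",
        hits$protein_id[i], tlen, hits$hmm_id[i], env$env_end[e] - env$env_start[e] + 1L,
        10^(-hits$full_score[i] / 10), hits$full_score[i], e, nrow(env),
        10^(-env$dom_score[e] / 10), 10^(-env$dom_score[e] / 10),
        env$dom_score[e], env$env_end[e] - env$env_start[e] + 1L,
        env$env_start[e], env$env_end[e], env$env_start[e], env$env_end[e]))
    }
  }
  writeLines(c(header, lines), path)
}

#' Write a genome set to a fixture directory
#'
#' Lays out the plain-text files the file-driven pipeline consumes:
#' `genomes/<id>.fasta` and `genomes/<id>.gff`, `hits/<id>.domtbl`
#' (HMMER3 domtblout format), `config.txt`, `truth.tsv` and `query.fasta`.
#'
#' @param gs A `genome_set`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome_set <- function(gs, dir) {
  stopifnot(inherits(gs, "genome_set"))
  dir.create(file.path(dir, "genomes"), showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "hits"), showWarnings = FALSE, recursive = TRUE)
  for (g in gs$genomes) {
    write_fasta(g$proteins, file.path(dir, "genomes",
                                      paste0(g$genome_id, ".fasta")))
    .write_gff(g$features, file.path(dir, "genomes",
                                     paste0(g$genome_id, ".gff")))
    .write_domtbl(g$hits, file.path(dir, "hits",
                                    paste0(g$genome_id, ".domtbl")))
  }
  writeLines(gs$config, file.path(dir, "config.txt"))
  utils::write.table(gs$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.na(gs$query_id)) {
    write_fasta(fixture_query(gs), file.path(dir, "query.fasta"))
  }
  invisible(dir)
}
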