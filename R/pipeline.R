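#' Run the full analysis workflow from a declarative configuration
#'
#' Wires the stages end-to-end over files: build the YES/NO/FAR training
#' partitions from per-genome FASTA + GFF + hit tables, optionally extract
#' matched domains, optionally (and advisedly) reduce redundancy within each
#' partition, scan the query, optionally rescore by inheritance, and render
#' the triangular heat map. Each stage reads the previous stage's declared
#' outputs, so every stage can equally be run by hand with the corresponding
#' exported function. Per-stage counts are logged to stderr and to
#' `run.log`; a `manifest.json` records the parameters, input digests and
#' package version. Any stage failure aborts with the stage name; partial
#' outputs are retained and the manifest is marked failed.
#'
#' @param workflow Path to a YAML workflow file, or an equivalent named list.
#'   Recognized top-level keys:
#'   \describe{
#'     \item{out_dir}{output directory (required)}
#'     \item{training}{`config` (rule file), `genomes` (directory of
#'       `<id>.fasta` + `<id>.gff`), `hits` (directory of `<id>.domtbl` /
#'       `<id>.tbl`)}
#'     \item{domains}{optional: `hmm_id`, `flank`}
#'     \item{cluster}{optional: `identity` (default 0.8)}
#'     \item{scan}{`query` (FASTA), plus any of `min_length`, `length_step`,
#'       `position_step`, `max_hits`, `backend`, `jobs`}
#'     \item{rescore}{optional: `heritability` (default 0.93)}
#'     \item{heatmap}{optional: `cap`, `format` (`png`/`svg`)}
#'   }
#' @return Invisibly, a list with the output paths and per-stage counts.
#' @export
run_pipeline <- function(workflow) {
  cfg <- if (is.character(workflow)) yaml::read_yaml(workflow) else workflow
  if (is.null(cfg$out_dir)) stop("workflow must name an out_dir")
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  cat("", file = logf)
  log_line <- function(...) {
    msg <- paste0(...)
    message(msg)
    cat(msg, "\n", file = logf, append = TRUE)
  }
  manifest <- list(
    command = "run_pipeline",
    parameters = cfg,
    tool_version = as.character(utils::packageVersion("simbal")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    status = "running")
  inputs <- c(cfg$training$config, cfg$scan$query)
  manifest$input_digests <- as.list(tools::md5sum(inputs[file.exists(inputs)]))
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  write_manifest()
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      manifest$status <<- paste0("failed at stage '", name, "'")
      write_manifest()
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  counts <- list()
  outputs <- list()

  ## stage 1: training set construction
  ts <- stage("build-training-set", {
    rules <- parse_config(readLines(cfg$training$config))
    genomes <- load_genome_dir(cfg$training$genomes, cfg$training$hits)
    log_line("build-training-set: ", length(genomes), " genome(s) read")
    partition_targets(genomes, rules)
  })
  counts$genomes_read <- length(unique(ts$provenance$genome_id))
  counts$yes <- length(ts$yes); counts$no <- length(ts$no)
  counts$far <- length(ts$far)
  log_line("build-training-set: YES=", counts$yes, " NO=", counts$no,
           " FAR=", counts$far)
  stage("build-training-set", {
    for (p in c("yes", "no", "far")) {
      f <- file.path(out_dir, paste0(p, ".fasta"))
      if (length(ts[[p]]) > 0) write_fasta(ts[[p]], f) else cat("", file = f)
      outputs[[paste0(p, "_fasta")]] <- f
    }
    utils::write.table(ts$provenance, file.path(out_dir, "provenance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  yes <- ts$yes
  no <- ts$no

  ## stage 2 (optional): domain extraction
  if (!is.null(cfg$domains)) {
    stage("extract-domains", {
      rules <- parse_config(readLines(cfg$training$config))
      genomes <- load_genome_dir(cfg$training$genomes, cfg$training$hits)
      all_hits <- do.call(rbind, lapply(genomes, `[[`, "hits"))
      sel <- all_hits[all_hits$hmm_id == cfg$domains$hmm_id, , drop = FALSE]
      flank <- if (is.null(cfg$domains$flank)) 0L else cfg$domains$flank
      for (p in c("yes", "no")) {
        part <- get(p)
        cuts <- extract_domains(
          part, sel[sel$protein_id %in% names(part), , drop = FALSE], flank)
        assign(p, cuts)
        write_fasta(cuts, file.path(out_dir, paste0(p, ".domains.fasta")))
      }
      log_line("extract-domains: ", length(yes), " YES / ", length(no),
               " NO domain cuts")
    })
  }

  ## stage 3 (optional, strongly recommended): non-redundification
  if (!is.null(cfg$cluster)) {
    stage("cluster", {
      idty <- if (is.null(cfg$cluster$identity)) 0.8 else cfg$cluster$identity
      yes <- cluster_nonredundant(yes, idty)
      no <- cluster_nonredundant(no, idty)
      write_fasta(yes, file.path(out_dir, "yes.nr.fasta"))
      write_fasta(no, file.path(out_dir, "no.nr.fasta"))
      log_line("cluster: ", length(yes), " YES / ", length(no),
               " NO centroids at identity ", idty)
    })
  }

  ## stage 4: scan
  res <- stage("scan", {
    query <- read_fasta(cfg$scan$query)
    sp <- scan_params(
      min_length = cfg$scan$min_length %||% 6L,
      length_step = cfg$scan$length_step %||% 1L,
      position_step = cfg$scan$position_step %||% 1L,
      max_hits = cfg$scan$max_hits,
      backend = cfg$scan$backend %||% "builtin")
    db <- labeled_database(yes, no)
    r <- scan_query(query[1], db, sp, n_jobs = cfg$scan$jobs %||% 1L)
    outputs$scan_tsv <- file.path(out_dir, "scan.tsv")
    write_scan_table(r, outputs$scan_tsv)
    log_line("scan: ", nrow(r$windows), " windows scored against Y=", db$Y,
             " N=", db$N)
    r
  })
  counts$windows_scored <- nrow(res$windows)

  ## stage 5 (optional): inheritance rescoring
  plot_input <- res
  if (!is.null(cfg$rescore)) {
    plot_input <- stage("rescore", {
      h <- cfg$rescore$heritability %||% 0.93
      rr <- rescore_inheritance(res, h)
      outputs$rescored_tsv <- file.path(out_dir, "rescored.tsv")
      write_scan_table(rr, outputs$rescored_tsv)
      log_line("rescore: heritability ", h)
      rr
    })
  }

  ## stage 6: heat map
  stage("heatmap", {
    fmt <- cfg$heatmap$format %||% "png"
    spec <- heatmap_spec(score_cap = cfg$heatmap$cap)
    outputs$heatmap <- file.path(out_dir, paste0("heatmap.", fmt))
    render_heatmap(plot_input, spec, outputs$heatmap)
    log_line("heatmap: ", outputs$heatmap)
  })

  manifest$status <- "ok"
  manifest$counts <- counts
  write_manifest()
  invisible(list(out_dir = out_dir, outputs = outputs, counts = counts,
                 result = res))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load per-genome files from fixture-style directories
#'
#' Reads every `<id>.fasta` in `genomes_dir` together with its `<id>.gff`
#' (when present) and its hit table from `hits_dir` (`<id>.domtbl` or
#' `<id>.tbl`, dispatched on extension).
#'
#' @param genomes_dir Directory of per-genome protein FASTA (+ GFF) files.
#' @param hits_dir Directory of per-genome HMMER3 tabular hit files.
#' @return A list of [genome_record()] objects.
#' @export
load_genome_dir <- function(genomes_dir, hits_dir) {
  fastas <- sort(list.files(genomes_dir, pattern = "\\.(fasta|fa|faa)$",
                            full.names = TRUE))
  if (length(fastas) == 0L) {
    stop("no FASTA files found in ", genomes_dir)
  }
  lapply(fastas, function(f) {
    gid <- sub("\\.[^.]+$", "", basename(f))
    proteins <- read_fasta(f)
    gff <- file.path(genomes_dir, paste0(gid, ".gff"))
    features <- if (file.exists(gff)) read_gff_features(gff) else NULL
    domtbl <- file.path(hits_dir, paste0(gid, ".domtbl"))
    tbl <- file.path(hits_dir, paste0(gid, ".tbl"))
    hits <- if (file.exists(domtbl)) {
      read_hmm_hits(domtbl, "domtblout")
    } else if (file.exists(tbl)) {
      read_hmm_hits(tbl, "tblout")
    } else {
      stop("no hit table (", gid, ".domtbl or .tbl) in ", hits_dir)
    }
    genome_record(gid, proteins, hits, features)
  })
}
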