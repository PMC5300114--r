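rhombo_config <- c(
  "TARGET: PFAM/PF01694.HMM",
  "TARGET SCORE: 21.9",
  "NO: TIGRFAM/TIGR03501.HMM<12.5",
  "NO: TIGRFAM/TIGR03867.HMM<16",
  "NO: TIGRFAM/TIGR04212.HMM<210",
  "NO: TIGRFAM/TIGR04179.HMM<40",
  paste0("YES: (TIGRFAM/TIGR03501.HMM>16, TIGRFAM/TIGR03867.HMM>20, ",
         "TIGRFAM/TIGR04212.HMM>295, TIGRFAM/TIGR04179.HMM>150)"))

sciff_config <- c(
  "TARGET: PFAM/PF04055.HMM",
  "TARGET SCORE: 29.4",
  "YES: ([500] TIGRFAM/TIGR03973.HMM>35)",
  "NO: TIGRFAM/TIGR03973.HMM<35")

test_that("the rhombosortase-style configuration parses to its printed rule set", {
  rules <- parse_config(rhombo_config)
  expect_equal(rules$target_hmm, "PF01694")
  expect_equal(rules$target_cutoff, 21.9)
  expect_null(rules$yes_distance_bp)
  expect_equal(nrow(rules$no_clauses), 4)
  expect_equal(rules$no_clauses$threshold, c(12.5, 16, 210, 40))
  expect_true(all(rules$no_clauses$direction == "below"))
  expect_length(rules$yes_groups, 1)
  g <- rules$yes_groups[[1]]
  expect_false(g$distance)
  expect_equal(g$clauses$hmm_id,
               c("TIGR03501", "TIGR03867", "TIGR04212", "TIGR04179"))
  expect_equal(g$clauses$threshold, c(16, 20, 295, 150))
  expect_true(all(g$clauses$direction == "above"))
})

test_that("the SCIFF-style distance configuration parses with its 500 bp rule", {
  rules <- parse_config(sciff_config)
  expect_equal(rules$target_hmm, "PF04055")
  expect_equal(rules$target_cutoff, 29.4)
  expect_equal(rules$yes_distance_bp, 500L)
  expect_true(rules$yes_groups[[1]]$distance)
  expect_equal(rules$yes_groups[[1]]$clauses$threshold, 35)
  expect_equal(rules$no_clauses$threshold, 35)
})

test_that("configuration validation names missing keys and bad lines", {
  expect_error(parse_config("TARGET: A/B.HMM"),
               "missing required key.*TARGET SCORE.*YES.*NO")
  expect_error(parse_config(c(rhombo_config, "TARGET: X.HMM")),
               "duplicate TARGET")
  expect_error(parse_config(c("TARGET: A.HMM", "TARGET SCORE: 5",
                              "YES: (B.HMM>1)", "NO: B.HMM=nonsense")),
               "line 4")
})

test_that("genome verdicts follow the YES/NO/gray-zone cutoff logic", {
  rules <- parse_config(rhombo_config)
  hit_at <- function(score) make_hit("px", "TIGR03501", score)
  expect_equal(evaluate_genome(hit_at(20), rules), "YES-eligible")
  # no attribute hits at all: every 'below' clause vacuously satisfied
  expect_equal(evaluate_genome(make_hit("x", "y", 1)[0, ], rules), "NO")
  # between noise (12.5) and trusted (16) cutoffs: gray zone
  expect_equal(evaluate_genome(hit_at(14), rules), "indeterminate")
  # boundary arithmetic: > is strict, < requires all strictly below
  expect_equal(evaluate_genome(hit_at(16), rules), "indeterminate")
  expect_equal(evaluate_genome(hit_at(12.4), rules), "NO")
})

test_that("gene distance is the strand-agnostic gap on a shared replicon", {
  f <- function(rep, s, e) list(replicon_id = rep, start = s, end = e)
  expect_equal(gene_distance(f("chr1", 100, 400), f("chr1", 350, 600)), 0)
  expect_equal(gene_distance(f("chr1", 100, 400), f("chr1", 401, 600)), 0)
  expect_equal(gene_distance(f("chr1", 100, 400), f("chr1", 501, 900)), 100)
  expect_equal(gene_distance(f("chr1", 501, 900), f("chr1", 100, 400)), 100)
  expect_equal(gene_distance(f("chr1", 100, 400), f("plasmid1", 501, 900)),
               Inf)
})

# three genomes: YES-eligible with two targets, NO with one, indeterminate
make_three_genomes <- function() {
  withr::with_seed(5, {
    g1 <- genome_record("gYES", aaset(c(t1 = random_protein(50),
                                        t2 = random_protein(50),
                                        a1 = random_protein(40))),
                        bind_hits(make_hit("t1", "TARG", 30),
                                  make_hit("t2", "TARG", 25),
                                  make_hit("a1", "ATTR", 20)))
    g2 <- genome_record("gNO", aaset(c(t3 = random_protein(50))),
                        make_hit("t3", "TARG", 40))
    g3 <- genome_record("gGRAY", aaset(c(t4 = random_protein(50),
                                         a2 = random_protein(40))),
                        bind_hits(make_hit("t4", "TARG", 33),
                                  make_hit("a2", "ATTR", 14)))
    list(g1, g2, g3)
  })
}

test_that("bag-of-genes partitioning sorts YES and NO genomes and drops gray ones", {
  ts <- partition_targets(make_three_genomes(), toy_rules())
  expect_setequal(names(ts$yes), c("t1", "t2"))
  expect_equal(names(ts$no), "t3")
  expect_length(ts$far, 0)
  expect_false("t4" %in% c(names(ts$yes), names(ts$no), names(ts$far)))
  expect_setequal(ts$provenance$partition, c("YES", "NO"))
})

test_that("distance rule splits near targets to YES and far paralogs to FAR", {
  feats <- data.frame(
    protein_id = c("a1", "tNear", "tFar"),
    replicon_id = "chr", start = c(1000, 2100, 90000),
    end = c(2000, 3000, 91000), strand = "+", stringsAsFactors = FALSE)
  g <- genome_record("g1",
                     aaset(c(a1 = "MKTLVAAA", tNear = "MKTLVCCC",
                             tFar = "MKTLVDDD")),
                     bind_hits(make_hit("a1", "ATTR", 50),
                               make_hit("tNear", "TARG", 30),
                               make_hit("tFar", "TARG", 30)),
                     feats)
  ts <- partition_targets(list(g), toy_rules(500))
  expect_equal(names(ts$yes), "tNear")  # gap 2100-2000-1 = 99 <= 500
  expect_equal(names(ts$far), "tFar")
  expect_length(ts$no, 0)
})

test_that("an attribute genome whose only target is far contributes nothing", {
  feats <- data.frame(protein_id = c("a1", "tFar"), replicon_id = "chr",
                      start = c(1000, 12000), end = c(2000, 13000),
                      strand = "+", stringsAsFactors = FALSE)
  g <- genome_record("g1", aaset(c(a1 = "MKTLVAAA", tFar = "MKTLVDDD")),
                     bind_hits(make_hit("a1", "ATTR", 50),
                               make_hit("tFar", "TARG", 30)), feats)
  ts <- partition_targets(list(g), toy_rules(500))
  expect_length(ts$yes, 0)
  expect_length(ts$far, 0)
  expect_equal(nrow(ts$provenance), 0)
})

test_that("distance mode without feature tables fails loudly for YES genomes", {
  g <- genome_record("gNoGff", aaset(c(a1 = "MKTLVAAA", t1 = "MKTLVDDD")),
                     bind_hits(make_hit("a1", "ATTR", 50),
                               make_hit("t1", "TARG", 30)))
  expect_error(partition_targets(list(g), toy_rules(500)), "gNoGff")
})

test_that("partitions are disjoint and respect cutoff monotonicity", {
  gs <- generate_genome_set(fixture_spec(n_genomes = 15, seed = 77))
  ts <- partition_targets(gs$genomes, gs$rules)
  key <- paste(ts$provenance$genome_id, ts$provenance$protein_id)
  expect_false(anyDuplicated(key) > 0)

  # raising the target cutoff can only shrink every partition
  sizes <- function(cutoff) {
    r <- gs$rules
    r$target_cutoff <- cutoff
    t2 <- partition_targets(gs$genomes, r)
    c(length(t2$yes), length(t2$no), length(t2$far))
  }
  s0 <- sizes(gs$rules$target_cutoff)
  for (cut in c(50, 70, 95)) {
    s1 <- sizes(cut)
    expect_true(all(s1 <= s0))
    s0 <- s1
  }
})

test_that("an unbounded distance rule reduces to bag-of-genes partitioning", {
  gs_inf <- generate_genome_set(fixture_spec(n_genomes = 15, seed = 31,
                                             distance_bp = 10^9))
  gs_nod <- generate_genome_set(fixture_spec(n_genomes = 15, seed = 31,
                                             distance_bp = NULL))
  ts_inf <- partition_targets(gs_inf$genomes, gs_inf$rules)
  ts_nod <- partition_targets(gs_nod$genomes, gs_nod$rules)
  expect_length(ts_inf$far, 0)
  expect_setequal(names(ts_inf$yes), names(ts_nod$yes))
  expect_setequal(names(ts_inf$no), names(ts_nod$no))
})

test_that("every NO-genome target lands in the NO partition (count conservation)", {
  gs <- generate_genome_set(fixture_spec(n_genomes = 20, seed = 13))
  ts <- partition_targets(gs$genomes, gs$rules)
  expected_no <- gs$truth$protein_id[gs$truth$expected_partition == "NO"]
  expect_setequal(names(ts$no), expected_no)
})
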