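test_that("self-alignment gives identity 1 and coverage 1", {
  s <- seed_proteins()
  for (nm in names(s)) {
    h <- local_align(s[[nm]], s[[nm]])
    expect_equal(h$identity, 1)
    expect_equal(h$query_coverage, 1)
    expect_equal(h$aln_columns, nchar(s[[nm]]))
  }
})

test_that("query coverage is the query span of the best local alignment", {
  ref <- seed_proteins()[["SCPA"]]
  # query = 10 junk + an 80-residue exact core + 10 junk: the local
  # alignment is the core, spanning query residues 11..90
  core <- substr(ref, 1, 80)
  query <- paste0(strrep("W", 10), core, strrep("W", 10))
  h <- local_align(query, core)
  expect_equal(h$query_start, 11)
  expect_equal(h$query_end, 90)
  expect_equal(h$query_coverage, 0.80)
})

test_that("aligner agrees with the exhaustive DP oracle on random short pairs", {
  sub <- oracle_sub_matrix()
  set.seed(77)
  alpha <- c("A", "C", "G", "T")
  for (rep in 1:150) {
    a <- paste(sample(alpha, sample(3:12, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alpha, sample(3:12, 1), replace = TRUE), collapse = "")
    mine <- local_align(a, b)$score
    want <- oracle_align_score(a, b, sub, 11, 1, local = TRUE)
    expect_equal(mine, want, info = paste(a, b))
  }
})

test_that("global alignment score matches the oracle and Biostrings", {
  sub <- oracle_sub_matrix()
  set.seed(78)
  alpha <- c("A", "C", "G", "T")
  for (rep in 1:40) {
    a <- paste(sample(alpha, sample(4:12, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alpha, sample(4:12, 1), replace = TRUE), collapse = "")
    mine <- kitescan:::global_align(a, b)$score
    want <- oracle_align_score(a, b, sub, 11, 1, local = FALSE)
    expect_equal(mine, want, info = paste(a, b))
  }
  # independent C implementation on longer sequences
  s <- seed_proteins()
  bio <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(s[["SCPB"]]), Biostrings::AAString(s[["SCPA"]]),
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
    type = "global")
  expect_equal(kitescan:::global_align(s[["SCPB"]], s[["SCPA"]])$score,
               Biostrings::score(bio))
})

test_that("measured identity degrades as substitutions accumulate", {
  ref <- seed_proteins()[["SCPB"]]
  mean_id <- vapply(c(0.9, 0.7, 0.5, 0.35), function(t) {
    mean(vapply(1:5, function(k) {
      local_align(ref, mutate_to_identity(ref, t, seed = 1000 * t + k))$identity
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_id) < 0))
  # measured identity tracks the realized substitution level closely
  expect_true(all(abs(mean_id - c(0.9, 0.7, 0.5, 0.35)) < 0.06))
})

test_that("alignment rejects empty or non-protein input, naming the position", {
  expect_error(local_align("", "ACD"), "non-empty")
  expect_error(local_align("ACD", "AC1D"), "position 3 of subject")
  expect_error(local_align("ACJD", "ACD"), "'J' at position 3 of query")
})

test_that("threshold classification uses strict inequalities per class", {
  rules <- threshold_rules()
  hit <- function(id, cov) list(identity = id, query_coverage = cov)
  # general rule boundary
  expect_false(classify_hit(hit(0.20, 0.80), "SCPB", rules))
  expect_false(classify_hit(hit(0.25, 0.70), "SCPB", rules))
  expect_true(classify_hit(hit(0.21, 0.71), "SCPB", rules))
  expect_true(classify_hit(hit(0.25, 0.80), "SCPB", rules))
  # ScpA-specific rule
  expect_true(classify_hit(hit(0.55, 0.30), "SCPA", rules))
  expect_false(classify_hit(hit(0.55, 0.30), "SCPB", rules))
  expect_false(classify_hit(hit(0.55, 0.30), "SMC", rules))
  expect_false(classify_hit(hit(0.50, 0.30), "SCPA", rules))
  expect_false(classify_hit(hit(0.55, 0.25), "SCPA", rules))
})

test_that("classification is monotone in identity and coverage", {
  rules <- threshold_rules()
  grid <- seq(0.05, 0.95, by = 0.05)
  for (tc in target_classes()) {
    for (cov in c(0.3, 0.75)) {
      acc <- vapply(grid, function(id) {
        classify_hit(list(identity = id, query_coverage = cov), tc, rules)
      }, logical(1))
      expect_true(all(diff(acc) >= 0))  # accept never flips back to reject
    }
    for (id in c(0.3, 0.6)) {
      acc <- vapply(grid, function(cov) {
        classify_hit(list(identity = id, query_coverage = cov), tc, rules)
      }, logical(1))
      expect_true(all(diff(acc) >= 0))
    }
  }
})

test_that("HMM E-value cutoffs are strict and class-specific", {
  expect_true(classify_hmm_hit(1e-5, "SCPB"))
  expect_true(classify_hmm_hit(1e-5, "SCPA"))
  expect_false(classify_hmm_hit(1e-4, "SCPA"))
  expect_false(classify_hmm_hit(1e-3, "SCPB"))
  expect_false(classify_hmm_hit(1e-5, "SMC"))
  expect_false(classify_hmm_hit(1e-100, "SMC"))
  expect_true(classify_hmm_hit(1e-101, "SMC"))
  expect_error(classify_hmm_hit(0, "SMC"), "positive")
  expect_error(classify_hmm_hit(-1, "SMC"), "positive")
})

test_that("BLAST 12-column tables parse into fractional identity and coverage", {
  row <- paste("SCPA", "LT042", "25.0", "80", "55", "3", "1", "80", "5",
               "84", "1e-12", "88.2", sep = "\t")
  hits <- read_hit_table(row, "blast_tab12", query_lengths = c(SCPA = 100L))
  expect_equal(hits$identity, 0.25)
  expect_equal(hits$query_coverage, 0.80)
  expect_equal(hits$evalue, 1e-12)
  expect_equal(hits$aln_columns, 80L)
  expect_error(read_hit_table(row, "blast_tab12",
                              query_lengths = c(OTHER = 10L)),
               "missing from query_lengths")
  bad <- "SCPA\tLT042\t25.0"
  expect_error(read_hit_table(bad, "blast_tab12",
                              query_lengths = c(SCPA = 100L)),
               "line 1.*12 columns")
})

test_that("HMMER tblout tables skip comments and keep E-values only", {
  txt <- c(
    "#                                            --- full sequence ----",
    "# target name  accession  query name accession  E-value score bias",
    "LT077          -          SCPB       -          2.3e-07  55.1  0.1",
    "LT102          -          SCPB       -          0.5      10.0  0.0"
  )
  hits <- read_hit_table(txt, "hmmer_tbl")
  expect_equal(nrow(hits), 2)
  expect_equal(hits$subject_id, c("LT077", "LT102"))
  expect_equal(hits$evalue, c(2.3e-7, 0.5))
  expect_true(all(is.na(hits$identity)))
  expect_equal(nrow(read_hit_table(character(0), "hmmer_tbl")), 0)
})
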