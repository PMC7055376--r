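test_that("string search matches the canonical product names, not decoys", {
  ann <- simple_annotation(c(
    "chromosome segregation protein SMC",
    "hypothetical protein",
    "segregation/condensation protein A",
    "Segregation and condensation protein B",
    "DNA polymerase sliding clamp"
  ))
  expect_equal(string_match(ann, "SMC")$locus_tag, "LT001")
  expect_equal(string_match(ann, "SCPA")$locus_tag, "LT003")
  # case-insensitive: RefSeq capitalisation varies
  expect_equal(string_match(ann, "SCPB")$locus_tag, "LT004")
  ann2 <- simple_annotation(c("hypothetical protein", "reverse gyrase"))
  for (tc in target_classes()) {
    expect_equal(nrow(string_match(ann2, tc)), 0)
  }
})

test_that("short tokens ScpA/ScpB match as substrings of longer products", {
  ann <- simple_annotation(c("ScpA family protein", "putative ScpB homolog"))
  expect_equal(string_match(ann, "SCPA")$locus_tag, "LT001")
  expect_equal(string_match(ann, "SCPB")$locus_tag, "LT002")
})

test_that("string evidence dominates homology evidence", {
  ann <- simple_annotation(c("segregation/condensation protein A"))
  fake_hit <- data.frame(query_id = "SCPA", subject_id = "LT001",
                         identity = 0.9, query_coverage = 0.9,
                         evalue = NA_real_, aln_columns = 100L,
                         target = "SCPA", stringsAsFactors = FALSE)
  calls <- call_occurrence(ann, homology_evidence = fake_hit)
  expect_equal(calls$status[calls$target == "SCPA"], "found_by_string")
})

test_that("homology fallback accepts passing hits and ignores failing ones", {
  ann <- simple_annotation(c("hypothetical protein"))
  hit <- function(id, cov, tc) {
    data.frame(query_id = tc, subject_id = "LT001", identity = id,
               query_coverage = cov, evalue = NA_real_, aln_columns = 50L,
               target = tc, stringsAsFactors = FALSE)
  }
  calls <- call_occurrence(ann, homology_evidence = hit(0.25, 0.80, "SCPB"))
  expect_equal(calls$status[calls$target == "SCPB"], "found_by_homology")
  expect_equal(calls$locus_tags[calls$target == "SCPB"][[1]], "LT001")
  calls2 <- call_occurrence(ann, homology_evidence = hit(0.25, 0.60, "SCPB"))
  expect_equal(calls2$status[calls2$target == "SCPB"], "absent")
  expect_length(calls2$locus_tags[calls2$target == "SCPB"][[1]], 0)
})

test_that("HMM-only evidence is classified by E-value", {
  ann <- simple_annotation(c("hypothetical protein"))
  hmm <- data.frame(query_id = "SCPB", subject_id = "LT001",
                    identity = NA_real_, query_coverage = NA_real_,
                    evalue = 1e-5, aln_columns = 0L, target = "SCPB",
                    stringsAsFactors = FALSE)
  calls <- call_occurrence(ann, homology_evidence = hmm)
  expect_equal(calls$status[calls$target == "SCPB"], "found_by_homology")
  hmm$target <- "SMC"
  hmm$query_id <- "SMC"
  calls2 <- call_occurrence(ann, homology_evidence = hmm)
  expect_equal(calls2$status[calls2$target == "SMC"], "absent")
})

test_that("a class found only as pseudogene is present with the pseudo mark", {
  ann <- simple_annotation(c("chromosome segregation protein SMC", "p2"),
                           pseudo = c(TRUE, FALSE))
  calls <- call_occurrence(ann)
  smc <- calls[calls$target == "SMC", ]
  expect_equal(smc$status, "found_by_string")
  expect_true(smc$is_pseudo)
  # mixed pseudo + intact paralogs: the class is not pseudo-flagged
  ann2 <- simple_annotation(rep("chromosome segregation protein SMC", 2),
                            pseudo = c(TRUE, FALSE))
  expect_false(call_occurrence(ann2)$is_pseudo[1])
})

test_that("paralogs collapse to one call with all loci recorded", {
  ann <- simple_annotation(rep("segregation/condensation protein A", 3))
  calls <- call_occurrence(ann)
  scpA <- calls[calls$target == "SCPA", ]
  expect_equal(scpA$n_loci, 3)
  expect_equal(nrow(scpA), 1)
})

test_that("adding a pattern can only turn absent into found_by_string", {
  ann <- simple_annotation(c("condensin kleisin subunit", "p2"))
  base <- call_occurrence(ann)
  expect_equal(base$status[base$target == "SCPA"], "absent")
  pats <- default_patterns()
  pats$SCPA <- c(pats$SCPA, "kleisin")
  ext <- call_occurrence(ann, patterns = pats)
  expect_equal(ext$status[ext$target == "SCPA"], "found_by_string")
  # previously found classes unchanged
  for (tc in c("SMC", "SCPB")) {
    expect_equal(ext$status[ext$target == tc],
                 base$status[base$target == tc])
  }
})

test_that("outliers list exactly the genomes with a missing class", {
  ann_all <- simple_annotation(c(
    "chromosome segregation protein SMC",
    "segregation/condensation protein A",
    "segregation and condensation protein B"
  ))
  ann_noB <- simple_annotation(c(
    "chromosome segregation protein SMC",
    "segregation/condensation protein A"
  ))
  ann_none <- simple_annotation(c("hypothetical protein"))
  calls <- rbind(
    cbind(call_occurrence(ann_all), species = "sp full"),
    {
      x <- call_occurrence(ann_noB)
      x$assembly_id <- "TESTB"
      cbind(x, species = "sp noB")
    },
    {
      x <- call_occurrence(ann_none)
      x$assembly_id <- "TESTC"
      cbind(x, species = "sp none")
    }
  )
  out <- find_outliers(calls)
  expect_equal(nrow(out), 2)
  expect_equal(out$missing[out$species == "sp noB"], "SCPB")
  expect_equal(out$missing[out$species == "sp none"], "SMC,SCPA,SCPB")
  # all-present cohort: empty outlier list
  all_ok <- cbind(call_occurrence(ann_all), species = "sp full")
  expect_equal(nrow(find_outliers(all_ok)), 0)
})

test_that("identical inputs give identical calls", {
  ann <- simple_annotation(c("ScpA-like protein", "hypothetical protein"))
  expect_identical(call_occurrence(ann), call_occurrence(ann))
})
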