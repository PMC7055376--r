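demo_cohort <- function() {
  rows <- rbind(
    genome_row("GCA001", species = "Thermococcus one"),
    genome_row("GCA002", species = "Thermococcus two", scpB = FALSE),
    genome_row("GCA003", species = "Halobacterium one",
               order = "Halobacteriales", class = "Halobacteria",
               scpB = FALSE),
    genome_row("GCA004", species = "Methanococcus one",
               order = "Methanococcales", class = "Methanococci",
               scpB = FALSE,
               smc_scpA_gap = NA_integer_, smc_scpA_remote = TRUE)
  )
  cohort_spec(rows, seed = 5)
}

test_that("report counts match the generating ground truth", {
  co <- generate_cohort(demo_cohort())
  anns <- lapply(names(co$gff), function(a) {
    t <- co$taxonomy[co$taxonomy$assembly_id == a, ]
    parse_gff3(co$gff[[a]], a,
               taxon(t$species, order = t$order, class_ = t$class,
                     phylum = t$phylum))
  })
  names(anns) <- names(co$gff)
  scans <- scan_cohort(anns, co$proteins)
  rep <- build_report(scans)
  an <- rep$analyses
  # truth: 4 smc, 4 scpA, 1 scpB; 3 smc-scpA neighbor pairs (GCA004's pair
  # is remote), 0 scpA-scpB neighbors (GCA001's pair has 2 genes between)
  expect_equal(sum(an$n_smc), 4)
  expect_equal(sum(an$n_scpA), 4)
  expect_equal(sum(an$n_scpB), 1)
  expect_equal(sum(an$n_smc_scpA_neighbors), 3)
  expect_equal(sum(an$n_scpA_scpB_neighbors), 0)
  expect_equal(sum(an$n_species), 4)
  # outliers: exactly the genomes lacking a class
  expect_setequal(rep$outliers$assembly_id,
                  c("GCA002", "GCA003", "GCA004"))
  expect_equal(rep$outliers$missing[rep$outliers$assembly_id == "GCA003"],
               "SCPB")
  # results part records scpA flanks
  expect_true(all(nzchar(rep$results$scpA_loci)))
})

test_that("empty cohort yields an all-empty report", {
  rep <- build_report(list())
  expect_equal(nrow(rep$analyses), 0)
  expect_equal(nrow(rep$outliers), 0)
})

test_that("per-species deduplication counts one assembly per species", {
  rows <- rbind(
    genome_row("GCB002", species = "Duplicated species", scpB = FALSE),
    genome_row("GCB001", species = "Duplicated species"),
    genome_row("GCB003", species = "Other species")
  )
  co <- generate_cohort(cohort_spec(rows, seed = 9))
  anns <- lapply(names(co$gff), function(a) {
    t <- co$taxonomy[co$taxonomy$assembly_id == a, ]
    parse_gff3(co$gff[[a]], a,
               taxon(t$species, order = t$order, class_ = t$class,
                     phylum = t$phylum))
  })
  names(anns) <- names(co$gff)
  rep <- build_report(scan_cohort(anns, co$proteins))
  expect_equal(sum(rep$analyses$n_species), 2)
  # GCB001 sorts first, so the species counts as scpB-positive
  expect_equal(sum(rep$analyses$n_scpB), 2)
})

test_that("paralogs count once per species in the occurrence columns", {
  ann <- simple_annotation(rep("segregation/condensation protein A", 2))
  scan <- list(annotation = ann, calls = call_occurrence(ann),
               synteny = pairwise_synteny(call_occurrence(ann), ann))
  rep <- build_report(list(scan))
  expect_equal(rep$analyses$n_scpA, 1)
})

test_that("HMM columns populate from supplied tables and subtract pseudogenes", {
  ann <- simple_annotation(
    c("chromosome segregation protein SMC",
      "segregation/condensation protein A",
      "segregation and condensation protein B"),
    pseudo = c(FALSE, FALSE, TRUE)
  )
  scan <- scan_genome(ann)
  hmm <- data.frame(
    assembly_id = "TEST1", target = c("SMC", "SCPA", "SCPB"),
    evalue = c(1e-120, 1e-9, 1e-9), stringsAsFactors = FALSE
  )
  rep0 <- build_report(list(scan))
  expect_true(is.na(rep0$analyses$n_smc_hmm))
  rep1 <- build_report(list(scan), hmm_calls = hmm)
  expect_equal(rep1$analyses$n_smc_hmm, 1)
  expect_equal(rep1$analyses$n_scpA_hmm, 1)
  # scpB present but pseudo-marked: subtracted in the HMM column only
  expect_equal(rep1$analyses$n_scpB_hmm, 0)
  expect_equal(rep1$analyses$n_scpB, 1)
  expect_equal(rep1$analyses$n_scpB_pseudo, 1)
  rep2 <- build_report(list(scan), hmm_calls = hmm,
                       hmm_subtract_pseudo = FALSE)
  expect_equal(rep2$analyses$n_scpB_hmm, 1)
})

test_that("report invariants hold on a seeded random cohort", {
  set.seed(31)
  rows <- do.call(rbind, lapply(1:12, function(k) {
    random_genome_row(sprintf("GCI%03d", k), sprintf("Inv species %03d", k))
  }))
  co <- generate_cohort(cohort_spec(rows, seed = 31))
  anns <- lapply(names(co$gff), function(a) {
    t <- co$taxonomy[co$taxonomy$assembly_id == a, ]
    parse_gff3(co$gff[[a]], a,
               taxon(t$species, order = t$order, class_ = t$class,
                     phylum = t$phylum))
  })
  names(anns) <- names(co$gff)
  scans <- scan_cohort(anns, co$proteins)
  rep <- build_report(scans)
  an <- rep$analyses
  expect_equal(sum(an$n_species), 12)
  for (col in setdiff(names(an), c("order", "n_species"))) {
    if (all(is.na(an[[col]]))) next
    expect_true(all(an[[col]] <= an$n_species), info = col)
  }
  expect_true(all(an$n_smc_scpA_neighbors <= pmin(an$n_smc, an$n_scpA)))
  expect_true(all(an$n_scpA_scpB_neighbors <= pmin(an$n_scpA, an$n_scpB)))
  # outlier complement: outliers = cohort - species with all three
  all_three <- sum(vapply(scans, function(s) {
    all(s$calls$status != "absent")
  }, logical(1)))
  expect_equal(nrow(rep$outliers), 12 - all_three)
  # consistency with occurrence calls
  expect_equal(sum(an$n_scpB), sum(vapply(scans, function(s) {
    s$calls$status[s$calls$target == "SCPB"] != "absent"
  }, logical(1))))
})

test_that("rendering is deterministic and the JSON/TSV round-trip is faithful", {
  co <- generate_cohort(demo_cohort())
  anns <- lapply(names(co$gff), function(a) {
    t <- co$taxonomy[co$taxonomy$assembly_id == a, ]
    parse_gff3(co$gff[[a]], a,
               taxon(t$species, order = t$order, class_ = t$class,
                     phylum = t$phylum))
  })
  names(anns) <- names(co$gff)
  rep <- build_report(scan_cohort(anns, co$proteins))
  t1 <- render_report(rep, "tsv")
  t2 <- render_report(rep, "tsv")
  expect_identical(t1, t2)
  j <- render_report(rep, "json")
  expect_identical(j, render_report(rep, "json"))
  back <- jsonlite::fromJSON(j)
  expect_equal(back$analyses$n_scpB, rep$analyses$n_scpB)
  expect_equal(back$analyses$order, rep$analyses$order)
  # TSV analyses section re-parses to identical counts
  lines <- t1
  a0 <- which(lines == "## Analyses")
  o0 <- which(lines == "## Outliers")
  tsv <- read.delim(text = paste(lines[(a0 + 1):(o0 - 1)], collapse = "\n"),
                    stringsAsFactors = FALSE)
  expect_equal(tsv$n_scpA, rep$analyses$n_scpA)
  expect_error(render_report(rep, "xml"))
})
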