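#!/usr/bin/env Rscript
# Build the demonstration cohort: a small archaeal-style panel whose
# orders carry the qualitative occurrence/synteny patterns the survey is
# designed to resolve -- an order with smc+scpA but no scpB, an order
# where scpB is present but remote from scpA, an order where smc and scpA
# are mostly juxtaposed, plus genomes with pseudogene marks and genes
# hidden behind "hypothetical protein" annotations.
#
# Output: results/cohort/ (GFF3 + protein FASTA + taxonomy + truth table)

library(kitescan)

dir.create("results", showWarnings = FALSE)

rows <- rbind(
  # Thermococcales-like: all three genes; smc-scpA adjacent in 3 of 4,
  # separated by two genes in the fourth; scpB always remote from scpA
  genome_row("GCD00001", species = "Thermococcus primus",
             scpA_scpB_gap = NA_integer_, scpA_scpB_remote = TRUE),
  genome_row("GCD00002", species = "Thermococcus secundus",
             scpA_scpB_gap = NA_integer_, scpA_scpB_remote = TRUE),
  genome_row("GCD00003", species = "Pyrococcus tertius",
             scpA_scpB_gap = NA_integer_, scpA_scpB_remote = TRUE),
  genome_row("GCD00004", species = "Thermococcus quartus",
             smc_scpA_gap = 2L,
             scpA_scpB_gap = NA_integer_, scpA_scpB_remote = TRUE),
  # Halobacteriales-like: no scpB anywhere; one genome hides scpA behind
  # a "hypothetical protein" annotation, one carries a pseudo-marked smc
  genome_row("GCD00005", species = "Halobacterium primum",
             order = "Halobacteriales", class = "Halobacteria",
             scpB = FALSE),
  genome_row("GCD00006", species = "Haloferax secundum",
             order = "Halobacteriales", class = "Halobacteria",
             scpB = FALSE, scpA_style = "hypothetical",
             scpA_identity = 0.45),
  genome_row("GCD00007", species = "Natronomonas tertia",
             order = "Halobacteriales", class = "Halobacteria",
             scpB = FALSE, smc_pseudo = TRUE),
  # Methanococcales-like: smc and scpA never juxtaposed; scpB mostly
  # absent, remote where present; longer scpA middle regions
  genome_row("GCD00008", species = "Methanococcus primus",
             order = "Methanococcales", class = "Methanococci",
             scpB = FALSE, smc_scpA_gap = NA_integer_,
             smc_scpA_remote = TRUE, scpA_insert = 16L),
  genome_row("GCD00009", species = "Methanotorris secundus",
             order = "Methanococcales", class = "Methanococci",
             smc_scpA_gap = NA_integer_, smc_scpA_remote = TRUE,
             scpA_scpB_gap = NA_integer_, scpA_scpB_remote = TRUE,
             scpA_insert = 16L),
  genome_row("GCD00010", species = "Methanocaldococcus tertius",
             order = "Methanococcales", class = "Methanococci",
             scpB = FALSE, smc_scpA_gap = 3L, scpA_insert = 16L),
  # An Archaeoglobales-like genome with a long, bacterial-length middle
  # region, and one genome missing all three genes
  genome_row("GCD00011", species = "Geoglobus primus",
             order = "Archaeoglobales", class = "Archaeoglobi",
             scpA_insert = 35L, scpA_scpB_gap = 4L),
  genome_row("GCD00012", species = "Methanopyrus absens",
             order = "Methanopyrales", class = "Methanopyri",
             smc = FALSE, scpA = FALSE, scpB = FALSE,
             smc_scpA_gap = NA_integer_, scpA_scpB_gap = NA_integer_)
)

spec <- cohort_spec(rows, seed = 20191001)
co <- generate_cohort(spec, out_dir = "results/cohort")

cat(sprintf("wrote results/cohort: %d genomes, %d orders\n",
            nrow(co$taxonomy), length(unique(co$taxonomy$order))))
cat(sprintf("truth: smc in %d, scpA in %d, scpB in %d genomes\n",
            sum(co$truth$smc_status != "absent"),
            sum(co$truth$scpA_status != "absent"),
            sum(co$truth$scpB_status != "absent")))
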