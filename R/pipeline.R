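# End-to-end runners: one genome (string search -> homology fallback ->
# synteny) and a cohort directory (GFF + FASTA + taxonomy -> three-part
# report).

#' Scan one genome for the three target genes
#'
#' Runs the product-string search; for any class without a string match,
#' aligns the class's query (seed) protein against the genome's proteome
#' with the built-in affine-gap aligner and applies the acceptance
#' thresholds; then computes pair adjacency for the classes called
#' present.
#'
#' Proteins shorter than the span needed to clear the coverage cutoff for
#' a class are not aligned against that class's query (they cannot pass).
#'
#' @param annotation A `kitescan_annotation`.
#' @param proteins Named character vector of the genome's proteins keyed
#'   by locus tag (may be `NULL`: no homology fallback).
#' @param patterns Pattern set, see [default_patterns()].
#' @param rules A [threshold_rules()].
#' @param scoring An [align_scoring()].
#' @param queries Named character vector of query proteins per class
#'   (default [seed_proteins()]).
#' @param circular Treat replicons as circular for adjacency.
#' @return List with `annotation`, `calls` ([call_occurrence()] output)
#'   and `synteny` ([pairwise_synteny()] output).
#' @export
scan_genome <- function(annotation, proteins = NULL,
                        patterns = default_patterns(),
                        rules = threshold_rules(),
                        scoring = align_scoring(),
                        queries = seed_proteins(),
                        circular = FALSE) {
  evidence <- NULL
  if (!is.null(proteins) && length(proteins)) {
    missing_classes <- Filter(function(tc) {
      nrow(string_match(annotation, tc, patterns)) == 0
    }, target_classes())
    hit_rows <- list()
    for (tc in missing_classes) {
      q <- queries[[tc]]
      if (is.null(q)) next
      qlen <- nchar(q)
      min_cov <- if (tc == "SCPA") {
        min(rules$general_coverage, rules$scpA_coverage)
      } else {
        rules$general_coverage
      }
      # a subject shorter than ~the required query span cannot pass
      cand <- proteins[nchar(proteins) >= 0.9 * min_cov * qlen]
      for (nm in names(cand)) {
        h <- local_align(q, cand[[nm]], scoring, query_id = tc,
                         subject_id = nm)
        if (classify_hit(h, tc, rules)) {
          h$target <- tc
          hit_rows[[length(hit_rows) + 1]] <- h
        }
      }
    }
    if (length(hit_rows)) {
      evidence <- do.call(rbind, hit_rows)
    }
  }
  calls <- call_occurrence(annotation, patterns, evidence, rules)
  syn <- pairwise_synteny(calls, annotation, circular = circular)
  list(annotation = annotation, calls = calls, synteny = syn)
}

#' Scan a cohort of genomes held in memory
#'
#' @param annotations Named list of `kitescan_annotation` objects.
#' @param proteins Named list (same names) of per-genome protein vectors,
#'   or `NULL`.
#' @param ... Passed to [scan_genome()].
#' @return List of per-genome [scan_genome()] results, in `annotations`
#'   order.
#' @export
scan_cohort <- function(annotations, proteins = NULL, ...) {
  lapply(names(annotations), function(a) {
    scan_genome(annotations[[a]],
                proteins = if (is.null(proteins)) NULL else proteins[[a]],
                ...)
  })
}

#' Scan a cohort directory and build the three-part report
#'
#' Expects the layout written by [generate_cohort()]: `gff/<assembly>.gff`
#' files, optional `proteins/<assembly>.faa` proteomes, and a
#' `taxonomy.tsv` sidecar.
#'
#' @param dir Cohort directory.
#' @param ... Passed to [scan_genome()].
#' @return A list with `scans` (per-genome results) and `report` (a
#'   `kitescan_report`).
#' @export
scan_directory <- function(dir, ...) {
  tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  gff_files <- sort(list.files(file.path(dir, "gff"), pattern = "\\.gff$",
                               full.names = TRUE))
  if (length(gff_files) == 0) {
    stop("no GFF files under ", file.path(dir, "gff"), call. = FALSE)
  }
  annotations <- list()
  proteins <- list()
  for (f in gff_files) {
    a <- sub("\\.gff$", "", basename(f))
    if (is.null(tax[[a]])) {
      stop("assembly ", a, " missing from taxonomy.tsv", call. = FALSE)
    }
    annotations[[a]] <- parse_gff3(f, assembly_id = a, taxonomy = tax[[a]])
    faa <- file.path(dir, "proteins", paste0(a, ".faa"))
    if (file.exists(faa)) {
      aa <- Biostrings::readAAStringSet(faa)
      proteins[[a]] <- setNames(as.character(aa), names(aa))
    }
  }
  scans <- scan_cohort(annotations, proteins, ...)
  list(scans = scans, report = build_report(scans))
}
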