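# Presence/absence calls for smc, scpA and scpB: product-string search
# first, affine-gap homology fallback second, pseudogene accounting.

#' Default product-name search patterns
#'
#' The annotation strings used to detect the three genes in RefSeq product
#' names. Matching is case-insensitive plain substring.
#'
#' @return Named list mapping target class to a character vector of
#'   patterns.
#' @export
default_patterns <- function() {
  list(
    SMC = c("chromosome segregation protein SMC"),
    SCPA = c("segregation/condensation protein A", "ScpA"),
    SCPB = c("segregation and condensation protein B", "ScpB")
  )
}

#' Match product names of a genome against a target's search strings
#'
#' @param annotation A `kitescan_annotation`.
#' @param target One of `"SMC"`, `"SCPA"`, `"SCPB"`.
#' @param patterns Pattern set as from [default_patterns()].
#' @return The matching rows of [searchable_features()], genome order
#'   preserved.
#' @export
string_match <- function(annotation, target, patterns = default_patterns()) {
  assert_target(target)
  pats <- patterns[[target]]
  if (is.null(pats) || !length(pats)) {
    stop("no patterns supplied for target ", target, call. = FALSE)
  }
  feats <- searchable_features(annotation)
  if (nrow(feats) == 0) {
    return(feats)
  }
  prod <- tolower(feats$product)
  hit <- rep(FALSE, nrow(feats))
  for (p in pats) {
    hit <- hit | grepl(tolower(p), prod, fixed = TRUE)
  }
  out <- feats[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call occurrence of the three target genes in one genome
#'
#' String evidence dominates: a class with any product-string match is
#' `found_by_string` regardless of supplied homology evidence. Classes
#' with no string match fall back to the supplied homology hits (alignment
#' identity/coverage, or HMM E-values), classified under `rules`; classes
#' with neither are `absent`. A class is flagged `is_pseudo` when every
#' feature supporting it carries a pseudogene mark.
#'
#' @param annotation A `kitescan_annotation`.
#' @param patterns Pattern set, see [default_patterns()].
#' @param homology_evidence Optional data frame of hits as returned by
#'   [local_align()]/[read_hit_table()], with a `target` column naming the
#'   class each hit is evidence for and `subject_id` naming the genome
#'   protein (locus tag).
#' @param rules A [threshold_rules()] object.
#' @return A data frame with one row per target class: `assembly_id`,
#'   `target`, `status` (found_by_string / found_by_homology / absent),
#'   `is_pseudo`, `locus_tags` (list column), `n_loci`.
#' @export
call_occurrence <- function(annotation, patterns = default_patterns(),
                            homology_evidence = NULL,
                            rules = threshold_rules()) {
  rows <- lapply(target_classes(), function(tc) {
    feats <- string_match(annotation, tc, patterns)
    if (nrow(feats) > 0) {
      return(list(target = tc, status = "found_by_string",
                  is_pseudo = all(feats$is_pseudo),
                  locus_tags = feats$locus_tag))
    }
    if (!is.null(homology_evidence) && nrow(homology_evidence) > 0) {
      ev <- homology_evidence[homology_evidence$target == tc, , drop = FALSE]
      if (nrow(ev) > 0) {
        pass <- vapply(seq_len(nrow(ev)), function(i) {
          h <- ev[i, ]
          if (!is.na(h$evalue) && (is.na(h$identity) || h$aln_columns == 0)) {
            classify_hmm_hit(h$evalue, tc, rules)
          } else {
            classify_hit(h, tc, rules)
          }
        }, logical(1))
        if (any(pass)) {
          tags <- unique(ev$subject_id[pass])
          tags <- tags[!is.na(tags) & nzchar(tags)]
          fidx <- match(tags, annotation$features$locus_tag)
          pseudo <- annotation$features$is_pseudo[fidx]
          pseudo <- pseudo[!is.na(pseudo)]
          return(list(target = tc, status = "found_by_homology",
                      is_pseudo = length(pseudo) > 0 && all(pseudo),
                      locus_tags = tags))
        }
      }
    }
    list(target = tc, status = "absent", is_pseudo = FALSE,
         locus_tags = character(0))
  })
  data.frame(
    assembly_id = annotation$assembly_id,
    target = vapply(rows, `[[`, character(1), "target"),
    status = vapply(rows, `[[`, character(1), "status"),
    is_pseudo = vapply(rows, `[[`, logical(1), "is_pseudo"),
    locus_tags = I(lapply(rows, `[[`, "locus_tags")),
    n_loci = vapply(rows, function(r) length(r$locus_tags), integer(1)),
    stringsAsFactors = FALSE
  )
}

#' List genomes in which any target gene is absent
#'
#' The "Outliers" part of the three-part report: species for which at
#' least one of the three genes could not be found by either the string
#' search or the homology fallback.
#'
#' @param calls A data frame of occurrence calls for a cohort (rows from
#'   [call_occurrence()] over several genomes) together with a `species`
#'   column, or a list of per-genome call data frames each carrying
#'   `assembly_id`.
#' @param species_of Optional named character vector mapping assembly_id
#'   to species (required when `calls` lacks a `species` column).
#' @return Data frame with columns `species`, `assembly_id`,
#'   `missing` (comma-separated absent classes).
#' @export
find_outliers <- function(calls, species_of = NULL) {
  if (is.list(calls) && !is.data.frame(calls)) {
    calls <- do.call(rbind, calls)
  }
  if (!("species" %in% names(calls))) {
    if (is.null(species_of)) {
      stop("supply 'species_of' when calls lack a species column",
           call. = FALSE)
    }
    calls$species <- unname(species_of[calls$assembly_id])
  }
  per <- split(calls, calls$assembly_id)
  rows <- lapply(per, function(g) {
    if (!all(target_classes() %in% g$target)) {
      stop("calls for assembly ", g$assembly_id[1],
           " do not cover all three target classes", call. = FALSE)
    }
    miss <- g$target[g$status == "absent"]
    if (length(miss) == 0) {
      return(NULL)
    }
    data.frame(species = g$species[1], assembly_id = g$assembly_id[1],
               missing = paste(miss[order(match(miss, target_classes()))],
                               collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(species = character(0), assembly_id = character(0),
                      missing = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
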