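# Aggregation into the three-part output (Results / Analyses / Outliers)
# and the per-order occurrence + juxtaposition table.

REPORT_COLUMNS <- c("order", "n_species", "n_smc", "n_scpA", "n_scpB",
                    "n_smc_hmm", "n_scpA_hmm", "n_scpB_hmm",
                    "n_smc_scpA_neighbors", "n_scpA_scpB_neighbors",
                    "n_smc_pseudo", "n_scpA_pseudo", "n_scpB_pseudo")

#' Build the three-part cohort report
#'
#' Aggregates per-genome occurrence and synteny calls into: Results (one
#' row per species with taxonomy, target loci and the products flanking
#' scpA), Analyses (per-order counts of species containing each gene,
#' neighboring pairs and pseudogene marks) and Outliers (species lacking
#' at least one gene). Species are counted at most once per column; when
#' several assemblies share a species name, only the first by assembly_id
#' sort contributes.
#'
#' @param cohort List with one element per genome, each a list with
#'   `annotation` (a `kitescan_annotation`), `calls` (from
#'   [call_occurrence()]) and `synteny` (from [pairwise_synteny()]), as
#'   produced by [scan_genome()].
#' @param hmm_calls Optional data frame (`assembly_id`, `target`,
#'   `evalue`) of per-genome HMM evidence; when supplied the HMM columns
#'   of the Analyses table are populated by [classify_hmm_hit()], with
#'   pseudogene-marked genes subtracted when `hmm_subtract_pseudo`.
#' @param rules [threshold_rules()] used for the HMM columns.
#' @param hmm_subtract_pseudo Subtract pseudogene-marked genes from the
#'   HMM columns (they remain counted in the string/alignment columns).
#' @param dedupe_species Count each species once (first assembly).
#' @return Object of class `kitescan_report`: list with `results`,
#'   `analyses`, `outliers`.
#' @export
build_report <- function(cohort, hmm_calls = NULL,
                         rules = threshold_rules(),
                         hmm_subtract_pseudo = TRUE,
                         dedupe_species = TRUE) {
  if (length(cohort) == 0) {
    return(structure(
      list(results = data.frame(),
           analyses = setNames(
             data.frame(character(0), matrix(integer(0), 0, 12)),
             REPORT_COLUMNS),
           outliers = data.frame(species = character(0),
                                 assembly_id = character(0),
                                 missing = character(0))),
      class = "kitescan_report"))
  }
  for (g in cohort) {
    if (is.null(g$annotation$taxonomy)) {
      stop("genome ", g$annotation$assembly_id, " lacks taxonomy",
           call. = FALSE)
    }
  }
  ord <- order(vapply(cohort, function(g) g$annotation$assembly_id,
                      character(1)))
  cohort <- cohort[ord]
  if (dedupe_species) {
    sp <- vapply(cohort, function(g) g$annotation$species, character(1))
    cohort <- cohort[!duplicated(sp)]
  }

  results <- do.call(rbind, lapply(cohort, function(g) {
    tax <- g$annotation$taxonomy
    loci <- function(tc) {
      row <- g$calls[g$calls$target == tc, ]
      paste(row$locus_tags[[1]], collapse = ",")
    }
    scpA_row <- g$calls[g$calls$target == "SCPA", ]
    up <- down <- ""
    if (scpA_row$status != "absent" && scpA_row$n_loci > 0) {
      fl <- flanking_products(g$annotation, scpA_row$locus_tags[[1]][1])
      if (!is.null(fl$upstream)) up <- fl$upstream$product
      if (!is.null(fl$downstream)) down <- fl$downstream$product
    }
    data.frame(
      assembly_id = g$annotation$assembly_id, species = tax$species,
      order = tax$order, class = tax$class_, phylum = tax$phylum,
      smc_loci = loci("SMC"), scpA_loci = loci("SCPA"),
      scpB_loci = loci("SCPB"),
      scpA_upstream_product = up, scpA_downstream_product = down,
      stringsAsFactors = FALSE
    )
  }))
  rownames(results) <- NULL

  per_order <- split(seq_along(cohort),
                     vapply(cohort, function(g) g$annotation$taxonomy$order,
                            character(1)))
  analyses <- do.call(rbind, lapply(names(per_order), function(o) {
    gs <- cohort[per_order[[o]]]
    status <- function(tc) {
      vapply(gs, function(g) {
        g$calls$status[g$calls$target == tc]
      }, character(1))
    }
    pseudo <- function(tc) {
      vapply(gs, function(g) {
        g$calls$is_pseudo[g$calls$target == tc] &&
          g$calls$status[g$calls$target == tc] != "absent"
      }, logical(1))
    }
    neigh <- function(which_pair) {
      sum(vapply(gs, function(g) {
        adj <- g$synteny[[which_pair]]
        !is.null(adj) && isTRUE(adj$neighbors)
      }, logical(1)))
    }
    hmm_col <- function(tc) {
      if (is.null(hmm_calls)) {
        return(NA_integer_)
      }
      n <- sum(vapply(gs, function(g) {
        ev <- hmm_calls[hmm_calls$assembly_id == g$annotation$assembly_id &
                        hmm_calls$target == tc, , drop = FALSE]
        any(vapply(ev$evalue, classify_hmm_hit, logical(1), target = tc,
                   rules = rules))
      }, logical(1)))
      if (hmm_subtract_pseudo) {
        n <- n - sum(pseudo(tc))
      }
      as.integer(max(n, 0L))
    }
    data.frame(
      order = o, n_species = length(gs),
      n_smc = sum(status("SMC") != "absent"),
      n_scpA = sum(status("SCPA") != "absent"),
      n_scpB = sum(status("SCPB") != "absent"),
      n_smc_hmm = hmm_col("SMC"), n_scpA_hmm = hmm_col("SCPA"),
      n_scpB_hmm = hmm_col("SCPB"),
      n_smc_scpA_neighbors = neigh("smc_scpA"),
      n_scpA_scpB_neighbors = neigh("scpA_scpB"),
      n_smc_pseudo = sum(pseudo("SMC")),
      n_scpA_pseudo = sum(pseudo("SCPA")),
      n_scpB_pseudo = sum(pseudo("SCPB")),
      stringsAsFactors = FALSE
    )
  }))
  analyses <- analyses[order(analyses$order), , drop = FALSE]
  rownames(analyses) <- NULL

  all_calls <- do.call(rbind, lapply(cohort, function(g) {
    cc <- g$calls
    cc$species <- g$annotation$species
    cc
  }))
  outliers <- find_outliers(all_calls)

  structure(list(results = results, analyses = analyses,
                 outliers = outliers),
            class = "kitescan_report")
}

#' @export
print.kitescan_report <- function(x, ...) {
  cat(sprintf("<kitescan_report> %d species, %d order(s), %d outlier(s)\n",
              nrow(x$results), nrow(x$analyses), nrow(x$outliers)))
  invisible(x)
}

#' Serialize a cohort report
#'
#' @param report A `kitescan_report`.
#' @param format `"tsv"` (three sections with `## Results` / `## Analyses`
#'   / `## Outliers` headers, fixed column order) or `"json"` (stable key
#'   order).
#' @return A character vector (tsv: one element per line; json: one
#'   string).
#' @export
render_report <- function(report, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "kitescan_report"))
  if (format == "json") {
    return(as.character(jsonlite::toJSON(
      list(results = report$results, analyses = report$analyses,
           outliers = report$outliers),
      dataframe = "rows", na = "null", auto_unbox = TRUE, digits = NA)))
  }
  section <- function(name, df) {
    c(paste0("## ", name),
      paste(names(df), collapse = "\t"),
      if (nrow(df)) {
        apply(df, 1, function(r) paste(as.character(r), collapse = "\t"))
      })
  }
  c(section("Results", report$results),
    section("Analyses", report$analyses),
    section("Outliers", report$outliers))
}
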