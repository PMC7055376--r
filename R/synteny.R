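# Gene-neighborhood relations: adjacency, intervening-gene counts and
# flanking products. All logic runs on searchable features (protein-coding
# + pseudogene) in genome order; strand is deliberately ignored and
# replicons are treated as linear unless `circular = TRUE`.

locate_locus <- function(feats, locus) {
  i <- match(locus, feats$locus_tag)
  if (is.na(i)) {
    stop("unknown locus: ", locus, call. = FALSE)
  }
  i
}

#' Count searchable genes between two loci
#'
#' Two genes "neighbor" each other when zero searchable genes lie strictly
#' between them on the same replicon; genes on different replicons are not
#' comparable ("remote").
#'
#' @param annotation A `kitescan_annotation`.
#' @param locus_a,locus_b Locus tags of the two genes (must differ).
#' @param circular Treat each replicon as circular: the intervening count
#'   is then the smaller of the two arcs.
#' @return A list of class `kitescan_adjacency`: `locus_a`, `locus_b`,
#'   `comparable`, `intervening` (NA when not comparable), `neighbors`.
#' @export
intervening_gene_count <- function(annotation, locus_a, locus_b,
                                   circular = FALSE) {
  if (identical(locus_a, locus_b)) {
    stop("locus_a and locus_b must differ", call. = FALSE)
  }
  feats <- searchable_features(annotation)
  ia <- locate_locus(feats, locus_a)
  ib <- locate_locus(feats, locus_b)
  if (feats$replicon_id[ia] != feats$replicon_id[ib]) {
    return(structure(list(locus_a = locus_a, locus_b = locus_b,
                          comparable = FALSE, intervening = NA_integer_,
                          neighbors = FALSE),
                     class = "kitescan_adjacency"))
  }
  lo <- min(ia, ib)
  hi <- max(ia, ib)
  between <- hi - lo - 1L
  if (circular) {
    n_rep <- sum(feats$replicon_id == feats$replicon_id[ia])
    around <- n_rep - (hi - lo) - 1L
    between <- min(between, around)
  }
  structure(list(locus_a = locus_a, locus_b = locus_b, comparable = TRUE,
                 intervening = between, neighbors = between == 0L),
            class = "kitescan_adjacency")
}

#' Immediate neighbors of a locus
#'
#' The previous and next searchable feature in genome order on the same
#' replicon; `NULL` at replicon ends. Used for the "genes flanking scpA"
#' column of the Results part.
#'
#' @param annotation A `kitescan_annotation`.
#' @param locus Locus tag.
#' @return List with `upstream` and `downstream`, each a one-row feature
#'   data frame or `NULL`.
#' @export
flanking_products <- function(annotation, locus) {
  feats <- searchable_features(annotation)
  i <- locate_locus(feats, locus)
  rep <- feats$replicon_id[i]
  up <- if (i > 1 && feats$replicon_id[i - 1] == rep) {
    feats[i - 1, , drop = FALSE]
  } else {
    NULL
  }
  down <- if (i < nrow(feats) && feats$replicon_id[i + 1] == rep) {
    feats[i + 1, , drop = FALSE]
  } else {
    NULL
  }
  list(upstream = up, downstream = down)
}

#' Adjacency of the smc-scpA and scpA-scpB gene pairs in one genome
#'
#' Adjacency is computed only for classes called present; when a class
#' matched several loci (paralogs), the pair minimizing the intervening
#' count is reported, preferring comparable (same-replicon) pairs over
#' remote ones.
#'
#' @param calls Occurrence calls for the genome (from [call_occurrence()]).
#' @param annotation The corresponding `kitescan_annotation`.
#' @param circular Passed to [intervening_gene_count()].
#' @return List with `smc_scpA` and `scpA_scpB`, each a
#'   `kitescan_adjacency` or `NULL` when either member is absent.
#' @export
pairwise_synteny <- function(calls, annotation, circular = FALSE) {
  loci_of <- function(tc) {
    row <- calls[calls$target == tc, ]
    if (nrow(row) == 0 || row$status == "absent") {
      return(NULL)
    }
    row$locus_tags[[1]]
  }
  best_pair <- function(la, lb) {
    if (is.null(la) || is.null(lb)) {
      return(NULL)
    }
    best <- NULL
    for (a in la) {
      for (b in lb) {
        if (identical(a, b)) next
        adj <- intervening_gene_count(annotation, a, b, circular = circular)
        if (is.null(best)) {
          best <- adj
        } else if (adj$comparable &&
                   (!best$comparable || adj$intervening < best$intervening)) {
          best <- adj
        }
      }
    }
    best
  }
  smc <- loci_of("SMC")
  scpA <- loci_of("SCPA")
  scpB <- loci_of("SCPB")
  list(smc_scpA = best_pair(smc, scpA), scpA_scpB = best_pair(scpA, scpB))
}
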