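# Annotation model: parse RefSeq-style GFF3 into one record per gene with
# the product text searched by the occurrence module.

#' Construct a taxon label set
#'
#' Taxonomic labels attached to a genome. Missing ranks are carried as the
#' explicit markers `"(No class)"` / `"(No order)"` so that per-order
#' aggregation keeps such genomes as their own row rather than dropping
#' them.
#'
#' @param species Species name (required, non-empty).
#' @param order,class_,phylum Higher ranks; `NA` or `""` is replaced by the
#'   explicit "(No ...)" marker.
#' @return A named list of class `kitescan_taxon`.
#' @export
taxon <- function(species, order = NA, class_ = NA, phylum = NA) {
  if (!is.character(species) || length(species) != 1 || !nzchar(species)) {
    stop("'species' must be a non-empty string", call. = FALSE)
  }
  fill <- function(x, marker) {
    if (length(x) != 1 || is.na(x) || !nzchar(x)) marker else as.character(x)
  }
  structure(
    list(
      species = species,
      order = fill(order, "(No order)"),
      class_ = fill(class_, "(No class)"),
      phylum = fill(phylum, "(No phylum)")
    ),
    class = "kitescan_taxon"
  )
}

# Split a GFF3 column-9 attribute string into a named character vector.
# Values are percent-decoded.
parse_gff3_attributes <- function(x) {
  if (is.na(x) || x == "." || !nzchar(x)) {
    return(character(0))
  }
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  keys <- sub("=.*$", "", parts)
  vals <- sub("^[^=]*=", "", parts)
  vals <- vapply(vals, function(v) {
    if (grepl("%", v, fixed = TRUE)) URLdecode(v) else v
  }, character(1), USE.NAMES = FALSE)
  names(vals) <- trimws(keys)
  vals
}

#' Parse a RefSeq-style GFF3 annotation into a genome model
#'
#' Reads GFF3 text (9 tab-separated columns, `#` comment lines,
#' percent-encoded attribute values) and unifies RefSeq's split
#' gene/child rows into one record per gene: the `product` text is taken
#' from the gene row itself or, failing that, from the first CDS child
#' whose `Parent` matches the gene's `ID`. Pseudogene status is recognised
#' from any of `pseudo=true`, `gene_biotype=pseudogene`, or a
#' `pseudogene` feature type. Missing `locus_tag`s are synthesised as
#' `REPLICON:START-END` so downstream adjacency logic always has unique
#' keys.
#'
#' @param x Path to a GFF3 file, or a character vector of GFF3 lines.
#' @param assembly_id Assembly identifier attached to the result.
#' @param taxonomy A [taxon()] object.
#' @return An object of class `kitescan_annotation`: a list with
#'   `assembly_id`, `species`, `taxonomy` and `features`, a data frame
#'   sorted by (replicon_id, start, end) with one row per gene and columns
#'   `replicon_id`, `start`, `end`, `strand`, `feature_type`, `locus_tag`,
#'   `product`, `is_pseudo`, `searchable`.
#' @export
parse_gff3 <- function(x, assembly_id, taxonomy) {
  if (!inherits(taxonomy, "kitescan_taxon")) {
    stop("'taxonomy' must be a kitescan_taxon (see taxon())", call. = FALSE)
  }
  lines <- if (length(x) == 1 && !grepl("\n", x, fixed = TRUE) &&
               file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }

  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(new_annotation(assembly_id, taxonomy, empty_feature_frame()))
  }

  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_ok <- lengths(fields) == 9
  if (any(!ncol_ok)) {
    bad <- which(!ncol_ok)[1]
    stop(sprintf("GFF3 parse error at line %d: expected 9 tab-separated columns, found %d",
                 lineno[bad], lengths(fields)[bad]), call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 9, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  bad_coord <- which(is.na(start) | is.na(end))
  if (length(bad_coord)) {
    stop(sprintf("GFF3 parse error at line %d: non-numeric coordinates '%s'/'%s'",
                 lineno[bad_coord[1]], m[bad_coord[1], 4], m[bad_coord[1], 5]),
         call. = FALSE)
  }

  attrs <- lapply(m[, 9], parse_gff3_attributes)
  getattr <- function(a, key) {
    v <- a[key]
    if (is.na(v)) "" else unname(v)
  }
  type <- m[, 3]
  ids <- vapply(attrs, getattr, character(1), key = "ID")
  parents <- vapply(attrs, getattr, character(1), key = "Parent")
  products <- vapply(attrs, getattr, character(1), key = "product")
  locus <- vapply(attrs, getattr, character(1), key = "locus_tag")
  biotype <- vapply(attrs, getattr, character(1), key = "gene_biotype")
  pseudo_attr <- vapply(attrs, getattr, character(1), key = "pseudo")
  strand <- ifelse(m[, 7] %in% c("+", "-"), m[, 7], "unknown")

  is_gene_row <- type %in% c("gene", "pseudogene")
  is_child <- !is_gene_row & nzchar(parents)
  orphan <- !is_gene_row & !nzchar(parents)

  row_pseudo <- tolower(pseudo_attr) %in% c("true", "1") |
    biotype == "pseudogene" | type == "pseudogene"

  # index children by parent id
  child_of <- split(which(is_child), parents[is_child])

  gene_rows <- which(is_gene_row | orphan)
  feat <- lapply(gene_rows, function(i) {
    kids <- if (nzchar(ids[i])) child_of[[ids[i]]] else NULL
    kid_types <- type[kids]
    prod <- products[i]
    if (!nzchar(prod) && length(kids)) {
      with_prod <- kids[nzchar(products[kids])]
      if (length(with_prod)) prod <- products[with_prod[1]]
    }
    has_cds <- any(kid_types == "CDS") || type[i] == "CDS"
    pseudo <- row_pseudo[i] || any(row_pseudo[kids])
    lt <- locus[i]
    if (!nzchar(lt) && length(kids)) {
      with_lt <- kids[nzchar(locus[kids])]
      if (length(with_lt)) lt <- locus[with_lt[1]]
    }
    if (!nzchar(lt)) {
      lt <- sprintf("%s:%d-%d", m[i, 1], start[i], end[i])
    }
    data.frame(
      replicon_id = m[i, 1], start = start[i], end = end[i],
      strand = strand[i],
      feature_type = if (pseudo && type[i] == "gene") "pseudogene" else type[i],
      locus_tag = lt, product = prod, is_pseudo = pseudo,
      searchable = has_cds || pseudo,
      stringsAsFactors = FALSE
    )
  })
  features <- do.call(rbind, feat)
  features <- features[order(features$replicon_id, features$start,
                             features$end), , drop = FALSE]
  rownames(features) <- NULL
  # uniquify any colliding locus tags (synthesised keys must be unique)
  dup <- duplicated(features$locus_tag)
  if (any(dup)) {
    features$locus_tag[dup] <- paste0(features$locus_tag[dup], "_",
                                      seq_len(sum(dup)))
  }
  new_annotation(assembly_id, taxonomy, features)
}

empty_feature_frame <- function() {
  data.frame(
    replicon_id = character(0), start = integer(0), end = integer(0),
    strand = character(0), feature_type = character(0),
    locus_tag = character(0), product = character(0),
    is_pseudo = logical(0), searchable = logical(0),
    stringsAsFactors = FALSE
  )
}

new_annotation <- function(assembly_id, taxonomy, features) {
  structure(
    list(
      assembly_id = as.character(assembly_id),
      species = taxonomy$species,
      taxonomy = taxonomy,
      features = features
    ),
    class = "kitescan_annotation"
  )
}

#' @export
print.kitescan_annotation <- function(x, ...) {
  cat(sprintf("<kitescan_annotation> %s (%s): %d features on %d replicon(s)\n",
              x$assembly_id, x$species, nrow(x$features),
              length(unique(x$features$replicon_id))))
  invisible(x)
}

#' Features that can carry a product name
#'
#' Returns the protein-coding (CDS-bearing) and pseudogene features of an
#' annotation in genome order; these are the rows scanned by the product
#' string search and counted as "intervening genes" by the synteny module.
#'
#' @param annotation A `kitescan_annotation`.
#' @return A data frame, subset of `annotation$features`.
#' @export
searchable_features <- function(annotation) {
  stopifnot(inherits(annotation, "kitescan_annotation"))
  f <- annotation$features[annotation$features$searchable, , drop = FALSE]
  rownames(f) <- NULL
  f
}

#' Read a taxonomy sidecar table
#'
#' A tab-separated table with columns `assembly_id`, `species`, `order`,
#' `class`, `phylum` mapping each assembly to its taxonomic labels.
#'
#' @param path Path to the TSV file.
#' @return A named list of [taxon()] objects keyed by assembly_id.
#' @export
read_taxonomy <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("assembly_id", "species", "order", "class", "phylum")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("taxonomy table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    taxon(tab$species[i], order = tab$order[i], class_ = tab$class[i],
          phylum = tab$phylum[i])
  })
  names(out) <- tab$assembly_id
  out
}
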