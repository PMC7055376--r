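# ScpA middle-region length: project two reference residue anchors (the
# end of helix alpha-3 and the start of the next conserved helix) through
# an alignment and count the target residues strictly between the mapped
# columns. In the reference kleisin the anchors are residues 75 and 107,
# bracketing a 31-residue middle region.

#' Reference anchors bracketing the ScpA middle region
#'
#' @param ref_id Identifier of the reference sequence/row.
#' @param left_anchor,right_anchor 1-based residue indices on the
#'   reference; defaults 75 and 107 bracket a 31-residue middle region.
#' @return List of class `kitescan_anchors`.
#' @export
anchor_set <- function(ref_id = "ScpA_ref", left_anchor = 75L,
                       right_anchor = 107L) {
  left_anchor <- as.integer(left_anchor)
  right_anchor <- as.integer(right_anchor)
  if (is.na(left_anchor) || is.na(right_anchor) || left_anchor < 1 ||
      left_anchor >= right_anchor) {
    stop("anchors must satisfy 1 <= left_anchor < right_anchor",
         call. = FALSE)
  }
  structure(list(ref_id = ref_id, left_anchor = left_anchor,
                 right_anchor = right_anchor),
            class = "kitescan_anchors")
}

#' Default middle-region length bins
#'
#' Length classes observed across the archaeal and bacterial kleisins:
#' short archaeal 30-47 residues, intermediate 48-60, bacterial-like
#' 61-72; anything else is out of range. The 61-66 overlap between the
#' longer archaeal lengths and the bacterial range is resolved in favor of
#' `bacterial_like` by length alone (binning is descriptive; it does not
#' claim ScpB binding).
#'
#' @return Named list with `short_archaeal`, `intermediate`,
#'   `bacterial_like`, each `c(min, max)` inclusive.
#' @export
region_breakpoints <- function() {
  list(short_archaeal = c(30L, 47L), intermediate = c(48L, 60L),
       bacterial_like = c(61L, 72L))
}

#' Bin a middle-region length
#'
#' @param length Non-negative integer residue count.
#' @param breakpoints As from [region_breakpoints()].
#' @return One of `"short_archaeal"`, `"intermediate"`,
#'   `"bacterial_like"`, `"out_of_range"`.
#' @export
bin_length <- function(length, breakpoints = region_breakpoints()) {
  stopifnot(length >= 0)
  for (bin in names(breakpoints)) {
    rng <- breakpoints[[bin]]
    if (length >= rng[1] && length <= rng[2]) {
      return(bin)
    }
  }
  "out_of_range"
}

middle_from_aligned <- function(ref_aln, tgt_aln, anchors, sequence_id,
                                method) {
  ref_chars <- strsplit(ref_aln, "", fixed = TRUE)[[1]]
  tgt_chars <- strsplit(tgt_aln, "", fixed = TRUE)[[1]]
  is_res <- !(ref_chars %in% c("-", "."))
  pos <- cumsum(is_res)
  pos[!is_res] <- NA
  if (max(pos, na.rm = TRUE) < anchors$right_anchor) {
    stop("reference has fewer residues than right_anchor", call. = FALSE)
  }
  col_l <- which(!is.na(pos) & pos == anchors$left_anchor)
  col_r <- which(!is.na(pos) & pos == anchors$right_anchor)
  inside <- tgt_chars[seq_len(length(tgt_chars)) > col_l &
                      seq_len(length(tgt_chars)) < col_r]
  len <- sum(!(inside %in% c("-", ".")))
  data.frame(sequence_id = sequence_id, length = len, method = method,
             bin = bin_length(len), stringsAsFactors = FALSE)
}

#' Middle-region length by pairwise anchor projection
#'
#' Globally aligns the target against the reference (affine gaps) and
#' counts the target residues in alignment columns strictly between the
#' columns holding the two reference anchor residues. Global rather than
#' local alignment is used because both kleisin termini are conserved and
#' both anchors must be aligned; gaps never shift an anchor (the column
#' actually holding the reference residue defines the boundary).
#'
#' @param target Target protein sequence (string).
#' @param reference Reference protein sequence (string).
#' @param anchors An [anchor_set()]; must fit within the reference.
#' @param scoring An [align_scoring()] object.
#' @param sequence_id Identifier recorded in the result.
#' @return One-row data frame: `sequence_id`, `length`, `method`
#'   (`"pairwise"`), `bin`.
#' @export
middle_region_pairwise <- function(target, reference,
                                   anchors = anchor_set(),
                                   scoring = align_scoring(),
                                   sequence_id = "target") {
  if (anchors$right_anchor > nchar(reference)) {
    stop("anchors fall outside the reference (length ",
         nchar(reference), ")", call. = FALSE)
  }
  aln <- global_align(reference, target, scoring)
  middle_from_aligned(aln$a, aln$b, anchors, sequence_id, "pairwise")
}

#' Middle-region lengths from a multiple alignment
#'
#' Locates the alignment columns of the reference anchor residues and, for
#' every row, counts the non-gap characters strictly between them.
#'
#' @param alignment Named character vector of equal-length aligned rows
#'   (gaps `-` or `.`), e.g. from [read_alignment()].
#' @param ref_row_id Name of the reference row.
#' @param anchors An [anchor_set()].
#' @return Data frame with one row per alignment row (reference included):
#'   `sequence_id`, `length`, `method` (`"msa"`), `bin`.
#' @export
middle_region_msa <- function(alignment, ref_row_id,
                              anchors = anchor_set()) {
  if (is.null(names(alignment)) || any(!nzchar(names(alignment)))) {
    stop("alignment rows must be named", call. = FALSE)
  }
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1) {
    stop("ragged alignment: rows differ in width", call. = FALSE)
  }
  if (!(ref_row_id %in% names(alignment))) {
    stop("reference row not found: ", ref_row_id, call. = FALSE)
  }
  ref <- alignment[[ref_row_id]]
  out <- lapply(names(alignment), function(id) {
    middle_from_aligned(ref, alignment[[id]], anchors, id, "msa")
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a protein multiple alignment
#'
#' @param path Path to an aligned FASTA or Stockholm file.
#' @param format `"fasta"` or `"stockholm"`.
#' @return Named character vector of aligned rows.
#' @export
read_alignment <- function(path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  if (format == "fasta") {
    aa <- Biostrings::readAAStringSet(path)
    setNames(as.character(aa), names(aa))
  } else {
    lines <- readLines(path, warn = FALSE)
    body <- lines[!grepl("^(#|//|\\s*$)", lines)]
    if (length(body) == 0) {
      return(character(0))
    }
    parts <- strsplit(trimws(body), "\\s+")
    ids <- vapply(parts, `[`, character(1), 1)
    seqs <- vapply(parts, `[`, character(1), 2)
    # interleaved blocks: concatenate per id, preserving first-seen order
    ord <- unique(ids)
    setNames(vapply(ord, function(i) {
      paste(seqs[ids == i], collapse = "")
    }, character(1)), ord)
  }
}
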