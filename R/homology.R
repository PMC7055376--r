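# Homology evidence: a self-contained Gotoh affine-gap aligner producing
# identity/coverage, readers for BLAST/HMMER tabular output, and the
# per-class acceptance thresholds.

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

#' Alignment scoring parameters
#'
#' Protein-BLAST-style affine-gap scoring: a gap of length k costs
#' `gap_open + k * gap_extend`. The default matrix is BLOSUM62 with the
#' ambiguity residue X rescored to 0 against everything.
#'
#' @param matrix Substitution matrix name; only `"BLOSUM62"` is bundled.
#' @param gap_open Gap opening penalty (default 11, BLAST protein default).
#' @param gap_extend Gap extension penalty (default 1).
#' @return A list of class `kitescan_scoring` with the numeric matrix in
#'   `$sub` (rows/cols in `AA_ALPHABET` order).
#' @export
align_scoring <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  if (!identical(matrix, "BLOSUM62")) {
    stop("unknown substitution matrix: ", matrix, call. = FALSE)
  }
  if (gap_extend > gap_open) {
    stop("gap_extend must not exceed gap_open", call. = FALSE)
  }
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
  m["X", ] <- 0
  m[, "X"] <- 0
  structure(
    list(matrix = matrix, sub = m, gap_open = gap_open,
         gap_extend = gap_extend),
    class = "kitescan_scoring"
  )
}

# Encode a protein string as 0-based indices into AA_ALPHABET; errors name
# the position of the first non-alphabet character.
encode_protein <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1 || !nzchar(seq)) {
    stop(what, " must be a non-empty protein string", call. = FALSE)
  }
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  idx <- match(chars, AA_ALPHABET)
  if (anyNA(idx)) {
    p <- which(is.na(idx))[1]
    stop(sprintf("invalid residue '%s' at position %d of %s",
                 chars[p], p, what), call. = FALSE)
  }
  idx - 1L
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman with affine gaps (Gotoh). Identity is the number of
#' identical aligned residue pairs divided by the alignment length
#' including gap columns (the BLAST pident convention); query coverage is
#' the query span of the single best local alignment divided by the query
#' length.
#'
#' @param query,subject Protein sequences (single strings; standard amino
#'   acids plus X).
#' @param scoring An [align_scoring()] object.
#' @param query_id,subject_id Identifiers recorded in the hit.
#' @return One-row data frame of class `kitescan_hit`: `query_id`,
#'   `subject_id`, `identity`, `query_coverage` (fractions),
#'   `evalue` (NA; the built-in aligner does not compute E-values),
#'   `aln_columns`, `score`, `query_start`, `query_end`.
#' @export
local_align <- function(query, subject, scoring = align_scoring(),
                        query_id = "query", subject_id = "subject") {
  qi <- encode_protein(query, "query")
  si <- encode_protein(subject, "subject")
  res <- .gotoh_align(qi, si, scoring$sub, scoring$gap_open,
                      scoring$gap_extend, TRUE)
  cols <- length(res$a_idx)
  nid <- if (cols) sum(!is.na(res$a_idx) & !is.na(res$b_idx) &
                       res$a_idx == res$b_idx) else 0L
  span <- if (cols) res$a_end - res$a_start + 1L else 0L
  structure(
    data.frame(
      query_id = query_id, subject_id = subject_id,
      identity = if (cols) nid / cols else 0,
      query_coverage = span / length(qi),
      evalue = NA_real_, aln_columns = cols, score = res$score,
      query_start = if (cols) res$a_start else NA_integer_,
      query_end = if (cols) res$a_end else NA_integer_,
      stringsAsFactors = FALSE
    ),
    class = c("kitescan_hit", "data.frame")
  )
}

# Global (Needleman-Wunsch-Gotoh) alignment; returns aligned strings.
# Used by the regions module for anchor projection.
global_align <- function(a, b, scoring = align_scoring()) {
  ai <- encode_protein(a, "sequence a")
  bi <- encode_protein(b, "sequence b")
  res <- .gotoh_align(ai, bi, scoring$sub, scoring$gap_open,
                      scoring$gap_extend, FALSE)
  decode <- function(idx) {
    ch <- ifelse(is.na(idx), "-", AA_ALPHABET[idx + 1L])
    paste(ch, collapse = "")
  }
  list(score = res$score, a = decode(res$a_idx), b = decode(res$b_idx))
}

#' The homology acceptance thresholds
#'
#' Alignment-based rule: identity above 20% with query coverage above 70%
#' counts for any class; additionally identity above 50% with coverage
#' above 25% counts for ScpA (whose conserved N-terminus often is the only
#' aligned part). HMM rule: E-value below 1e-4 for ScpA and ScpB, below
#' 1e-100 for Smc. All inequalities are strict.
#'
#' @param general_identity,general_coverage General rule cutoffs
#'   (fractions; defaults 0.20, 0.70).
#' @param scpA_identity,scpA_coverage ScpA-specific rule cutoffs
#'   (defaults 0.50, 0.25).
#' @param hmm_evalue Named numeric vector of E-value cutoffs per class.
#' @return A list of class `kitescan_rules`.
#' @export
threshold_rules <- function(general_identity = 0.20, general_coverage = 0.70,
                            scpA_identity = 0.50, scpA_coverage = 0.25,
                            hmm_evalue = c(SCPA = 1e-4, SCPB = 1e-4,
                                           SMC = 1e-100)) {
  fr <- c(general_identity = general_identity,
          general_coverage = general_coverage,
          scpA_identity = scpA_identity, scpA_coverage = scpA_coverage)
  if (any(fr <= 0 | fr >= 1)) {
    stop("identity/coverage thresholds must lie in (0, 1)", call. = FALSE)
  }
  if (any(hmm_evalue <= 0)) {
    stop("E-value thresholds must be positive", call. = FALSE)
  }
  structure(
    list(general_identity = general_identity,
         general_coverage = general_coverage,
         scpA_identity = scpA_identity, scpA_coverage = scpA_coverage,
         hmm_evalue = hmm_evalue),
    class = "kitescan_rules"
  )
}

#' Classify an alignment hit under the per-class acceptance thresholds
#'
#' @param hit A one-row hit (from [local_align()] or [read_hit_table()])
#'   or any list with `identity` and `query_coverage` fractions.
#' @param target Target class the hit is evidence for.
#' @param rules A [threshold_rules()] object.
#' @return `TRUE` when the hit passes: identity strictly above the general
#'   identity cutoff and coverage strictly above the general coverage
#'   cutoff for any class, or the ScpA-specific rule when
#'   `target = "SCPA"`.
#' @export
classify_hit <- function(hit, target, rules = threshold_rules()) {
  assert_target(target)
  id <- hit$identity
  cov <- hit$query_coverage
  general <- id > rules$general_identity && cov > rules$general_coverage
  if (target == "SCPA") {
    return(general || (id > rules$scpA_identity && cov > rules$scpA_coverage))
  }
  general
}

#' Classify an HMM-search hit by its E-value
#'
#' @param evalue Positive E-value of the hit.
#' @param target Target class.
#' @param rules A [threshold_rules()] object.
#' @return `TRUE` when `evalue` is strictly below the class cutoff.
#' @export
classify_hmm_hit <- function(evalue, target, rules = threshold_rules()) {
  assert_target(target)
  if (!is.numeric(evalue) || length(evalue) != 1 || is.na(evalue) ||
      evalue <= 0) {
    stop("'evalue' must be a positive number", call. = FALSE)
  }
  evalue < rules$hmm_evalue[[target]]
}

#' Read an external homology hit table
#'
#' Adapter for externally run searches. `blast_tab12` is the 12-column
#' BLAST tabular dialect (`-outfmt 6`: qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore); identity is
#' rescaled from percent to fraction and query coverage computed from
#' qstart/qend against `query_lengths`. `hmmer_tbl` is the HMMER3
#' `--tblout` dialect (whitespace-separated, `#` comments); rows populate
#' the E-value only.
#'
#' @param x Path to the table, or a character vector of its lines.
#' @param dialect `"blast_tab12"` or `"hmmer_tbl"`.
#' @param query_lengths Named integer vector of query sequence lengths
#'   (required for `blast_tab12`).
#' @return A data frame of hits with columns `query_id`, `subject_id`,
#'   `identity`, `query_coverage`, `evalue`, `aln_columns`.
#' @export
read_hit_table <- function(x, dialect = c("blast_tab12", "hmmer_tbl"),
                           query_lengths = NULL) {
  dialect <- match.arg(dialect)
  lines <- if (length(x) == 1 && !grepl("\n", x, fixed = TRUE) &&
               file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  empty <- data.frame(query_id = character(0), subject_id = character(0),
                      identity = numeric(0), query_coverage = numeric(0),
                      evalue = numeric(0), aln_columns = integer(0),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0) {
    return(empty)
  }
  if (dialect == "blast_tab12") {
    if (is.null(query_lengths)) {
      stop("'query_lengths' is required for blast_tab12", call. = FALSE)
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) != 12)
    if (length(bad)) {
      stop(sprintf("hit-table parse error at line %d: expected 12 columns, found %d",
                   lineno[bad[1]], lengths(fields)[bad[1]]), call. = FALSE)
    }
    m <- matrix(unlist(fields), ncol = 12, byrow = TRUE)
    qid <- m[, 1]
    unknown <- setdiff(unique(qid), names(query_lengths))
    if (length(unknown)) {
      stop("query id(s) missing from query_lengths: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    qlen <- unname(query_lengths[qid])
    qstart <- as.integer(m[, 7])
    qend <- as.integer(m[, 8])
    data.frame(
      query_id = qid, subject_id = m[, 2],
      identity = as.numeric(m[, 3]) / 100,
      query_coverage = (abs(qend - qstart) + 1) / qlen,
      evalue = as.numeric(m[, 11]),
      aln_columns = as.integer(m[, 4]),
      stringsAsFactors = FALSE
    )
  } else {
    fields <- strsplit(trimws(lines), "\\s+")
    bad <- which(lengths(fields) < 5)
    if (length(bad)) {
      stop(sprintf("hit-table parse error at line %d: too few columns for hmmer_tbl",
                   lineno[bad[1]]), call. = FALSE)
    }
    m <- do.call(rbind, lapply(fields, `[`, 1:5))
    # tblout: target name, accession, query name, accession, full-seq E-value
    data.frame(
      query_id = m[, 3], subject_id = m[, 1],
      identity = NA_real_, query_coverage = NA_real_,
      evalue = as.numeric(m[, 5]),
      aln_columns = 0L,
      stringsAsFactors = FALSE
    )
  }
}
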