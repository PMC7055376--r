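# Synthetic cohorts: mock genomes (GFF3 + protein FASTA) with controlled
# occurrence, annotation style, pseudogene flags, synteny and sequence
# divergence, plus the ground-truth table the pipeline must reproduce.

DECOY_PRODUCTS <- c(
  "DNA polymerase sliding clamp",
  "30S ribosomal protein S4",
  "50S ribosomal protein L7Ae",
  "ABC transporter ATP-binding protein",
  "archaeal histone A",
  "methyl-coenzyme M reductase subunit alpha",
  "V-type ATP synthase subunit B",
  "reverse gyrase",
  "CRISPR-associated endonuclease Cas1",
  "elongation factor 1-alpha",
  "proteasome subunit beta",
  "thermosome subunit",
  "glyceraldehyde-3-phosphate dehydrogenase",
  "translation initiation factor IF-2",
  "DNA topoisomerase VI subunit A",
  "tRNA pseudouridine synthase D",
  "S-adenosylmethionine synthase",
  "hypothetical protein",
  "phosphoenolpyruvate synthase",
  "ferredoxin oxidoreductase gamma subunit"
)

#' Bundled seed proteins for the three target classes
#'
#' Fixed synthetic reference sequences (no real sequence is
#' redistributed), length-matched to the proteins the survey targets:
#' Smc 1180 aa, ScpA 220 aa, ScpB 190 aa. The ScpA entry doubles as the
#' anchor-projection reference of the regions stage.
#'
#' @return Named character vector with entries `SMC`, `SCPA`, `SCPB`.
#' @export
seed_proteins <- function() {
  path <- system.file("extdata", "seed_proteins_synthetic.fasta",
                      package = "kitescan", mustWork = TRUE)
  aa <- Biostrings::readAAStringSet(path)
  setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
}

random_protein <- function(len) {
  paste(sample(AA_ALPHABET[1:20], len, replace = TRUE), collapse = "")
}

#' Mutate a protein to a target identity by substitutions only
#'
#' Substitutes `round(L * (1 - target_identity))` positions, chosen
#' without replacement, each to a uniformly drawn different residue.
#' Length is preserved and the realized identity is within 1/(2L) of the
#' target by construction.
#'
#' @param sequence Protein string.
#' @param target_identity Fraction in (0, 1].
#' @param seed Integer seed (deterministic output per seed).
#' @return Mutated protein string.
#' @export
mutate_to_identity <- function(sequence, target_identity, seed) {
  if (!is.numeric(target_identity) || target_identity <= 0 ||
      target_identity > 1) {
    stop("'target_identity' must lie in (0, 1]", call. = FALSE)
  }
  if (target_identity == 1) {
    return(sequence)
  }
  with_seed(seed, {
    chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
    n_sub <- round(length(chars) * (1 - target_identity))
    pos <- sample(length(chars), n_sub)
    for (p in pos) {
      alt <- setdiff(AA_ALPHABET[1:20], chars[p])
      chars[p] <- sample(alt, 1)
    }
    paste(chars, collapse = "")
  })
}

#' Insert a random segment into the ScpA middle region
#'
#' Inserts `k` random residues as one contiguous block at a position drawn
#' uniformly strictly between the two anchors, so the expected measured
#' middle-region length grows by exactly `k`.
#'
#' @param scpA_seq Protein string.
#' @param k Number of residues to insert (>= 0).
#' @param anchors An [anchor_set()] valid for `scpA_seq`.
#' @param seed Integer seed.
#' @return Protein string of length `nchar(scpA_seq) + k`.
#' @export
insert_middle_segment <- function(scpA_seq, k, anchors = anchor_set(),
                                  seed = 1L) {
  if (k < 0) {
    stop("'k' must be non-negative", call. = FALSE)
  }
  if (anchors$right_anchor > nchar(scpA_seq)) {
    stop("anchors fall outside the sequence", call. = FALSE)
  }
  if (k == 0) {
    return(scpA_seq)
  }
  with_seed(seed, {
    # insert after position p, left_anchor <= p < right_anchor
    p <- sample(seq(anchors$left_anchor, anchors$right_anchor - 1L), 1)
    seg <- random_protein(k)
    paste0(substr(scpA_seq, 1, p), seg,
           substr(scpA_seq, p + 1, nchar(scpA_seq)))
  })
}

#' Define a synthetic cohort
#'
#' One row per genome. Presence, annotation style (canonical product name
#' vs "hypothetical protein"), pseudogene flags, divergence from the seed
#' proteins, pair adjacency and the scpA middle-region insertion are all
#' controlled per genome; a single integer seed makes the whole cohort
#' reproducible byte for byte.
#'
#' @param genomes Data frame with columns `assembly_id`, `species`,
#'   `order`, `class`, `phylum`; logical `smc`, `scpA`, `scpB` (presence);
#'   character `smc_style`, `scpA_style`, `scpB_style` (`"canonical"` or
#'   `"hypothetical"`); logical `smc_pseudo`, `scpA_pseudo`,
#'   `scpB_pseudo`; numeric `smc_identity`, `scpA_identity`,
#'   `scpB_identity` in (0, 1]; integer `smc_scpA_gap`, `scpA_scpB_gap`
#'   (intervening searchable genes, `NA` = pair not co-resident or a
#'   member absent); logical `smc_scpA_remote`, `scpA_scpB_remote`;
#'   integer `scpA_insert` (middle-region insertion length);
#'   integer `n_filler`.
#' @param seed Integer cohort seed.
#' @return Validated list of class `kitescan_cohort_spec`.
#' @export
cohort_spec <- function(genomes, seed = 1L) {
  need <- c("assembly_id", "species", "order", "class", "phylum",
            "smc", "scpA", "scpB",
            "smc_style", "scpA_style", "scpB_style",
            "smc_pseudo", "scpA_pseudo", "scpB_pseudo",
            "smc_identity", "scpA_identity", "scpB_identity",
            "smc_scpA_gap", "scpA_scpB_gap",
            "smc_scpA_remote", "scpA_scpB_remote",
            "scpA_insert", "n_filler")
  missing <- setdiff(need, names(genomes))
  if (length(missing)) {
    stop("cohort spec lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(genomes$assembly_id)) {
    stop("assembly_id values must be unique", call. = FALSE)
  }
  for (i in seq_len(nrow(genomes))) {
    g <- genomes[i, ]
    for (pair in list(c("smc", "scpA"), c("scpA", "scpB"))) {
      key <- paste0(pair[1], "_", pair[2])
      gap <- g[[paste0(key, "_gap")]]
      remote <- g[[paste0(key, "_remote")]]
      both <- g[[pair[1]]] && g[[pair[2]]]
      if ((isTRUE(remote) || !is.na(gap)) && !both) {
        stop(sprintf("genome %s: adjacency requested for pair %s but a member is absent",
                     g$assembly_id, key), call. = FALSE)
      }
      if (both && !isTRUE(remote) && is.na(gap)) {
        stop(sprintf("genome %s: pair %s present on the same replicon needs a gap value",
                     g$assembly_id, key), call. = FALSE)
      }
      if (!is.na(gap) && isTRUE(remote)) {
        stop(sprintf("genome %s: pair %s cannot be both remote and gapped",
                     g$assembly_id, key), call. = FALSE)
      }
    }
    for (tc in c("smc", "scpA", "scpB")) {
      if (g[[tc]]) {
        idv <- g[[paste0(tc, "_identity")]]
        if (is.na(idv) || idv <= 0 || idv > 1) {
          stop(sprintf("genome %s: %s_identity must lie in (0, 1]",
                       g$assembly_id, tc), call. = FALSE)
        }
        # below ~40% identity, local-alignment end trimming can push the
        # measured query coverage across the 70% cutoff either way, so
        # the expected verdict would depend on alignment noise rather
        # than the spec'd divergence
        if (g[[paste0(tc, "_style")]] == "hypothetical" && idv < 0.40) {
          stop(sprintf(
            "genome %s: hypothetical %s needs identity >= 0.40 so the homology fallback verdict is determined",
            g$assembly_id, tc), call. = FALSE)
        }
      }
    }
    gaps <- sum(c(g$smc_scpA_gap, g$scpA_scpB_gap), na.rm = TRUE)
    if (g$n_filler < gaps + 2) {
      stop(sprintf("genome %s: n_filler (%d) too small for requested gaps (%d)",
                   g$assembly_id, g$n_filler, gaps), call. = FALSE)
    }
  }
  # decoy leakage guard: no decoy product may substring-match a pattern
  pats <- tolower(unlist(default_patterns()))
  for (d in tolower(DECOY_PRODUCTS[DECOY_PRODUCTS != "hypothetical protein"])) {
    if (any(vapply(pats, function(p) grepl(p, d, fixed = TRUE), logical(1)))) {
      stop("decoy product leaks a search pattern: ", d, call. = FALSE)
    }
  }
  structure(list(genomes = genomes, seed = as.integer(seed)),
            class = "kitescan_cohort_spec")
}

canonical_product <- function(tc) {
  switch(tc,
         SMC = "chromosome segregation protein SMC",
         SCPA = "segregation/condensation protein A",
         SCPB = "segregation and condensation protein B")
}

# Build GFF3 text for one genome from an ordered gene plan.
# plan: data.frame replicon, locus_tag, product, pseudo, kind (CDS/tRNA),
# aa_len
render_gff3 <- function(plan, assembly_id) {
  lines <- c("##gff-version 3")
  enc <- function(x) {
    x <- gsub("%", "%25", x, fixed = TRUE)
    x <- gsub(";", "%3B", x, fixed = TRUE)
    x <- gsub("=", "%3D", x, fixed = TRUE)
    x <- gsub(",", "%2C", x, fixed = TRUE)
    x
  }
  for (rep in unique(plan$replicon)) {
    sub <- plan[plan$replicon == rep, , drop = FALSE]
    pos <- 101L
    for (i in seq_len(nrow(sub))) {
      g <- sub[i, ]
      width <- g$aa_len * 3L + 3L
      start <- pos
      end <- pos + width - 1L
      pos <- end + 51L
      gid <- paste0("gene-", g$locus_tag)
      pseudo_attr <- if (g$pseudo) ";pseudo=true" else ""
      lines <- c(lines, sprintf(
        "%s\tRefSeq\tgene\t%d\t%d\t.\t%s\t.\tID=%s;locus_tag=%s%s",
        rep, start, end, g$strand, gid, g$locus_tag, pseudo_attr))
      child_type <- g$kind
      cid <- paste0(tolower(child_type), "-", g$locus_tag)
      lines <- c(lines, sprintf(
        "%s\tRefSeq\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s;product=%s%s",
        rep, child_type, start, end, g$strand, cid, gid,
        enc(g$product), pseudo_attr))
    }
  }
  lines
}

genome_seed <- function(cohort_seed, i, salt = 0L) {
  (as.numeric(cohort_seed) * 7919 + i * 104729 + salt * 31) %% 2147483647
}

#' Generate a synthetic cohort of genomes
#'
#' Produces, per genome, RefSeq-style GFF3 text and a protein FASTA that
#' honor the requested presence, annotation style, pseudogene flags,
#' adjacency and divergence exactly, together with the taxonomy sidecar
#' and the ground-truth table (expected occurrence statuses, adjacency
#' and scpA middle-region length). Identical spec + seed give
#' byte-identical output.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Optional directory; when given, writes
#'   `gff/<assembly>.gff`, `proteins/<assembly>.faa`, `taxonomy.tsv` and
#'   `truth.tsv` under it.
#' @return (Invisibly when writing) a list with `gff` (named list of
#'   character vectors), `proteins` (named list of named character
#'   vectors), `taxonomy` (data frame), `truth` (data frame).
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "kitescan_cohort_spec"))
  seeds <- seed_proteins()
  genomes <- spec$genomes
  gff <- list()
  proteins <- list()
  truth_rows <- list()

  for (i in seq_len(nrow(genomes))) {
    g <- genomes[i, ]
    gs <- genome_seed(spec$seed, i)

    # --- which classes exist, their products and proteins
    class_info <- list()
    for (tc in target_classes()) {
      low <- switch(tc, SMC = "smc", SCPA = "scpA", SCPB = "scpB")
      if (!g[[low]]) next
      style <- g[[paste0(low, "_style")]]
      idv <- g[[paste0(low, "_identity")]]
      base <- seeds[[tc]]
      if (tc == "SCPA" && g$scpA_insert > 0) {
        base <- insert_middle_segment(base, g$scpA_insert,
                                      seed = genome_seed(spec$seed, i, 1L))
      }
      prot <- mutate_to_identity(base, idv, genome_seed(spec$seed, i,
                                                        2L + match(tc, target_classes())))
      class_info[[tc]] <- list(
        style = style,
        product = if (style == "canonical") canonical_product(tc) else "hypothetical protein",
        pseudo = isTRUE(g[[paste0(low, "_pseudo")]]),
        protein = prot
      )
    }

    # --- gene plan
    plan <- with_seed(gs, {
      n_fill <- g$n_filler
      gap_a <- if (!is.na(g$smc_scpA_gap)) g$smc_scpA_gap else 0L
      gap_b <- if (!is.na(g$scpA_scpB_gap)) g$scpA_scpB_gap else 0L
      filler_products <- sample(DECOY_PRODUCTS, n_fill, replace = TRUE)
      filler_len <- sample(80:200, n_fill, replace = TRUE)
      smc_remote <- isTRUE(g$smc_scpA_remote)
      scpB_remote <- isTRUE(g$scpA_scpB_remote)

      mk <- function(n) {
        if (n == 0) return(NULL)
        idx <- seq_len(n) + mk_counter
        mk_counter <<- mk_counter + n
        data.frame(replicon = "chr", locus_tag = "", kind = "CDS",
                   product = filler_products[idx], pseudo = FALSE,
                   aa_len = filler_len[idx], strand = "+", role = "filler",
                   stringsAsFactors = FALSE)
      }
      mk_counter <- 0L
      target_row <- function(tc, replicon) {
        ci <- class_info[[tc]]
        data.frame(replicon = replicon, locus_tag = "", kind = "CDS",
                   product = ci$product, pseudo = ci$pseudo,
                   aa_len = nchar(ci$protein),
                   strand = sample(c("+", "-"), 1), role = tc,
                   stringsAsFactors = FALSE)
      }

      used <- gap_a + gap_b
      spare <- n_fill - used
      n_lead <- spare %/% 2
      n_trail <- spare - n_lead

      rows <- list(mk(n_lead))
      if (!is.null(class_info$SMC) && !smc_remote) {
        rows <- c(rows, list(target_row("SMC", "chr")))
        rows <- c(rows, list(mk(gap_a)))
      }
      if (!is.null(class_info$SCPA)) {
        rows <- c(rows, list(target_row("SCPA", "chr")))
      }
      if (!is.null(class_info$SCPB) && !scpB_remote) {
        rows <- c(rows, list(mk(gap_b)))
        rows <- c(rows, list(target_row("SCPB", "chr")))
      }
      rows <- c(rows, list(mk(n_trail)))
      plan <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
      # a decoy RNA gene: present in the GFF, never searchable
      trna <- data.frame(replicon = "chr", locus_tag = "", kind = "tRNA",
                         product = "tRNA-Gly", pseudo = FALSE, aa_len = 25L,
                         strand = "+", role = "rna",
                         stringsAsFactors = FALSE)
      plan <- rbind(plan[1, , drop = FALSE], trna,
                    plan[-1, , drop = FALSE])
      if (!is.null(class_info$SMC) && smc_remote) {
        extra <- data.frame(replicon = "pls2", locus_tag = "", kind = "CDS",
                            product = sample(DECOY_PRODUCTS, 1),
                            pseudo = FALSE,
                            aa_len = sample(80:200, 1), strand = "+",
                            role = "filler", stringsAsFactors = FALSE)
        plan <- rbind(plan, extra, target_row("SMC", "pls2"))
      }
      if (!is.null(class_info$SCPB) && scpB_remote) {
        extra <- data.frame(replicon = "pls1", locus_tag = "", kind = "CDS",
                            product = sample(DECOY_PRODUCTS, 1),
                            pseudo = FALSE,
                            aa_len = sample(80:200, 1), strand = "+",
                            role = "filler", stringsAsFactors = FALSE)
        plan <- rbind(plan, extra, target_row("SCPB", "pls1"))
      }
      plan
    })
    plan$locus_tag <- sprintf("%s_%04d", g$assembly_id,
                              seq_len(nrow(plan)) * 5L)

    # --- proteins (searchable CDS rows only; pseudogenes keep a product
    # but contribute no protein, as in RefSeq proteomes)
    prot <- character(0)
    for (j in seq_len(nrow(plan))) {
      if (plan$kind[j] != "CDS" || plan$pseudo[j]) next
      role <- plan$role[j]
      if (role %in% target_classes()) {
        prot[plan$locus_tag[j]] <- class_info[[role]]$protein
      } else {
        prot[plan$locus_tag[j]] <- with_seed(
          genome_seed(spec$seed, i, 100L + j), random_protein(plan$aa_len[j]))
      }
    }

    gff[[g$assembly_id]] <- render_gff3(plan, g$assembly_id)
    proteins[[g$assembly_id]] <- prot

    # --- ground truth
    status_of <- function(tc) {
      ci <- class_info[[tc]]
      if (is.null(ci)) return("absent")
      if (ci$style == "canonical") return("found_by_string")
      if (ci$pseudo) return("absent")  # no protein emitted to align
      "found_by_homology"
    }
    locus_of <- function(tc) {
      j <- which(plan$role == tc)
      if (length(j)) plan$locus_tag[j[1]] else NA_character_
    }
    adjacency_truth <- function(pair_key, a, b) {
      if (status_of(a) == "absent" || status_of(b) == "absent") {
        return(list(comparable = NA, intervening = NA_integer_,
                    neighbors = NA))
      }
      if (isTRUE(g[[paste0(pair_key, "_remote")]])) {
        return(list(comparable = FALSE, intervening = NA_integer_,
                    neighbors = FALSE))
      }
      gap <- g[[paste0(pair_key, "_gap")]]
      list(comparable = TRUE, intervening = as.integer(gap),
           neighbors = gap == 0L)
    }
    adj_a <- adjacency_truth("smc_scpA", "SMC", "SCPA")
    adj_b <- adjacency_truth("scpA_scpB", "SCPA", "SCPB")
    region_len <- if (!is.null(class_info$SCPA) && g$scpA_identity >= 0.5) {
      31L + g$scpA_insert
    } else {
      NA_integer_
    }
    truth_rows[[i]] <- data.frame(
      assembly_id = g$assembly_id, species = g$species, order = g$order,
      class = g$class, phylum = g$phylum,
      smc_status = status_of("SMC"), scpA_status = status_of("SCPA"),
      scpB_status = status_of("SCPB"),
      smc_pseudo = !is.null(class_info$SMC) && class_info$SMC$pseudo &&
        status_of("SMC") != "absent",
      scpA_pseudo = !is.null(class_info$SCPA) && class_info$SCPA$pseudo &&
        status_of("SCPA") != "absent",
      scpB_pseudo = !is.null(class_info$SCPB) && class_info$SCPB$pseudo &&
        status_of("SCPB") != "absent",
      smc_locus = locus_of("SMC"), scpA_locus = locus_of("SCPA"),
      scpB_locus = locus_of("SCPB"),
      smc_scpA_comparable = adj_a$comparable,
      smc_scpA_intervening = adj_a$intervening,
      smc_scpA_neighbors = adj_a$neighbors,
      scpA_scpB_comparable = adj_b$comparable,
      scpA_scpB_intervening = adj_b$intervening,
      scpA_scpB_neighbors = adj_b$neighbors,
      scpA_region_length = region_len,
      stringsAsFactors = FALSE
    )
  }

  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  taxonomy <- data.frame(
    assembly_id = genomes$assembly_id, species = genomes$species,
    order = genomes$order, class = genomes$class, phylum = genomes$phylum,
    stringsAsFactors = FALSE
  )
  out <- list(gff = gff, proteins = proteins, taxonomy = taxonomy,
              truth = truth)
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "gff"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(out_dir, "proteins"), recursive = TRUE,
               showWarnings = FALSE)
    for (a in names(gff)) {
      writeLines(gff[[a]], file.path(out_dir, "gff", paste0(a, ".gff")))
      p <- proteins[[a]]
      writeLines(as.vector(rbind(paste0(">", names(p)), unname(p))),
                 file.path(out_dir, "proteins", paste0(a, ".faa")))
    }
    write.table(taxonomy, file.path(out_dir, "taxonomy.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Default values for a cohort-spec genome row
#'
#' Convenience for building specs: returns a one-row data frame with all
#' genes present, canonical annotation, identity 0.9 to the seed proteins,
#' smc and scpA adjacent, scpA and scpB separated by two genes, no
#' pseudogenes, no middle-region insertion, 12 filler genes.
#'
#' @param assembly_id,species,order,class,phylum Labels.
#' @param ... Overrides for any [cohort_spec()] column.
#' @return One-row data frame.
#' @export
genome_row <- function(assembly_id, species = paste0(assembly_id, " sp."),
                       order = "Thermococcales", class = "Thermococci",
                       phylum = "Euryarchaeota", ...) {
  row <- data.frame(
    assembly_id = assembly_id, species = species, order = order,
    class = class, phylum = phylum,
    smc = TRUE, scpA = TRUE, scpB = TRUE,
    smc_style = "canonical", scpA_style = "canonical",
    scpB_style = "canonical",
    smc_pseudo = FALSE, scpA_pseudo = FALSE, scpB_pseudo = FALSE,
    smc_identity = 0.9, scpA_identity = 0.9, scpB_identity = 0.9,
    smc_scpA_gap = 0L, scpA_scpB_gap = 2L,
    smc_scpA_remote = FALSE, scpA_scpB_remote = FALSE,
    scpA_insert = 0L, n_filler = 12L,
    stringsAsFactors = FALSE
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(row)) {
      stop("unknown cohort-spec column: ", nm, call. = FALSE)
    }
    row[[nm]] <- dots[[nm]]
  }
  # presence implies style/pseudo fields are read; absence nulls adjacency
  if (!row$smc || !row$scpA) {
    row$smc_scpA_gap <- NA_integer_
    row$smc_scpA_remote <- FALSE
  }
  if (!row$scpA || !row$scpB) {
    row$scpA_scpB_gap <- NA_integer_
    row$scpA_scpB_remote <- FALSE
  }
  row
}
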