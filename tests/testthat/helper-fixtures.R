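# Small hand-built GFF fixtures and the seeded cohort matrix used by the
# closure suite.

gff_gene <- function(rep, start, end, lt, product, strand = "+",
                     pseudo = FALSE, child = "CDS") {
  p <- if (pseudo) ";pseudo=true" else ""
  c(sprintf("%s\tRefSeq\tgene\t%d\t%d\t.\t%s\t.\tID=gene-%s;locus_tag=%s%s",
            rep, start, end, strand, lt, lt, p),
    sprintf("%s\tRefSeq\t%s\t%d\t%d\t.\t%s\t.\tID=c-%s;Parent=gene-%s;product=%s%s",
            rep, child, start, end, strand, lt, lt, product, p))
}

demo_taxon <- function(species = "Thermococcus testii") {
  taxon(species, order = "Thermococcales", class_ = "Thermococci",
        phylum = "Euryarchaeota")
}

# annotation with loci at known offsets: products in genome order
simple_annotation <- function(products, pseudo = rep(FALSE, length(products)),
                              replicon = rep("chr", length(products)),
                              child = rep("CDS", length(products))) {
  lines <- "##gff-version 3"
  for (i in seq_along(products)) {
    lines <- c(lines, gff_gene(replicon[i], i * 1000, i * 1000 + 500,
                               sprintf("LT%03d", i), products[i],
                               pseudo = pseudo[i], child = child[i]))
  }
  parse_gff3(lines, assembly_id = "TEST1", taxonomy = demo_taxon())
}

# Deck of genome rows covering presence x style x pseudo x adjacency
# combinations; dealt across cohorts by the closure suite.
combination_rows <- function() {
  i <- 0
  nm <- function() {
    i <<- i + 1
    list(assembly_id = sprintf("GCF%05d", i),
         species = sprintf("Archaeon sp%05d", i))
  }
  g <- function(...) {
    a <- nm()
    do.call(genome_row, c(list(assembly_id = a$assembly_id,
                               species = a$species), list(...)))
  }
  rows <- list(
    # presence combinations (all canonical)
    g(),
    g(scpB = FALSE),
    g(smc = FALSE, smc_scpA_gap = NA_integer_),
    g(scpA = FALSE, smc_scpA_gap = NA_integer_, scpA_scpB_gap = NA_integer_),
    g(smc = FALSE, scpB = FALSE, smc_scpA_gap = NA_integer_,
      scpA_scpB_gap = NA_integer_),
    g(scpA = FALSE, scpB = FALSE, smc_scpA_gap = NA_integer_,
      scpA_scpB_gap = NA_integer_),
    g(smc = FALSE, scpA = FALSE, smc_scpA_gap = NA_integer_,
      scpA_scpB_gap = NA_integer_),
    g(smc = FALSE, scpA = FALSE, scpB = FALSE,
      smc_scpA_gap = NA_integer_, scpA_scpB_gap = NA_integer_),
    # hypothetical annotation per class (homology fallback)
    g(smc_style = "hypothetical", smc_identity = 0.40),
    g(scpA_style = "hypothetical", scpA_identity = 0.40),
    g(scpB_style = "hypothetical", scpB_identity = 0.40),
    g(smc_style = "hypothetical", scpA_style = "hypothetical",
      scpB_style = "hypothetical", smc_identity = 0.45,
      scpA_identity = 0.45, scpB_identity = 0.45),
    # ScpA N-terminus-only rule territory: high identity
    g(scpA_style = "hypothetical", scpA_identity = 0.60),
    # pseudogene marks
    g(smc_pseudo = TRUE),
    g(scpA_pseudo = TRUE),
    g(scpB_pseudo = TRUE),
    g(smc_pseudo = TRUE, scpB_pseudo = TRUE),
    # hypothetical + pseudo: no protein emitted, expect absent
    g(scpB_style = "hypothetical", scpB_pseudo = TRUE,
      scpB_identity = 0.40),
    # adjacency spectrum
    g(smc_scpA_gap = 1L),
    g(smc_scpA_gap = 2L),
    g(scpA_scpB_gap = 0L),
    g(scpA_scpB_gap = 5L),
    g(smc_scpA_gap = NA_integer_, smc_scpA_remote = TRUE),
    g(scpA_scpB_gap = NA_integer_, scpA_scpB_remote = TRUE),
    g(smc_scpA_gap = NA_integer_, smc_scpA_remote = TRUE,
      scpA_scpB_gap = NA_integer_, scpA_scpB_remote = TRUE),
    # middle-region insertions
    g(scpA_insert = 18L),
    g(scpA_insert = 35L),
    # divergence at high identity
    g(smc_identity = 0.95, scpA_identity = 0.55, scpB_identity = 0.75)
  )
  rows
}

random_genome_row <- function(id, species) {
  presence <- sample(c(TRUE, FALSE), 3, replace = TRUE, prob = c(0.8, 0.2))
  style <- sample(c("canonical", "hypothetical"), 3, replace = TRUE,
                  prob = c(0.75, 0.25))
  pseudo <- sample(c(FALSE, TRUE), 3, replace = TRUE, prob = c(0.9, 0.1))
  # hypothetical + pseudo never emits a protein; keep such genes canonical
  style[pseudo] <- "canonical"
  adjacency <- function(both) {
    if (!both) {
      return(list(gap = NA_integer_, remote = FALSE))
    }
    pick <- sample(c("gap", "remote"), 1, prob = c(0.8, 0.2))
    if (pick == "remote") {
      list(gap = NA_integer_, remote = TRUE)
    } else {
      list(gap = sample(0:4, 1), remote = FALSE)
    }
  }
  adj_a <- adjacency(presence[1] && presence[2])
  adj_b <- adjacency(presence[2] && presence[3])
  genome_row(
    id, species = species,
    order = sample(c("Thermococcales", "Halobacteriales",
                     "Methanococcales", "(No order)"), 1),
    smc = presence[1], scpA = presence[2], scpB = presence[3],
    smc_style = style[1], scpA_style = style[2], scpB_style = style[3],
    smc_pseudo = presence[1] && pseudo[1],
    scpA_pseudo = presence[2] && pseudo[2],
    scpB_pseudo = presence[3] && pseudo[3],
    smc_identity = round(sample(c(0.4, 0.5, 0.8, 0.95), 1), 2),
    scpA_identity = sample(c(0.4, 0.6, 0.9), 1),
    scpB_identity = sample(c(0.4, 0.6, 0.9), 1),
    smc_scpA_gap = adj_a$gap, smc_scpA_remote = adj_a$remote,
    scpA_scpB_gap = adj_b$gap, scpA_scpB_remote = adj_b$remote,
    scpA_insert = sample(c(0L, 0L, 5L, 18L), 1),
    n_filler = sum(adj_a$gap, adj_b$gap, na.rm = TRUE) + sample(8:14, 1)
  )
}

# The seeded cohort matrix: n_cohorts cohorts whose first genomes walk
# through every combination row, padded with random genomes.
closure_matrix <- function(n_cohorts = 30, seed = 20191001) {
  deck <- combination_rows()
  set.seed(seed)
  sizes <- c(rep(4:8, length.out = n_cohorts - 2), 20, 50)
  deal <- rep(seq_len(n_cohorts), length.out = length(deck))
  lapply(seq_len(n_cohorts), function(ci) {
    mine <- deck[deal == ci]
    n_random <- max(0, sizes[ci] - length(mine))
    extra <- lapply(seq_len(n_random), function(k) {
      random_genome_row(sprintf("GCR%02d%03d", ci, k),
                        sprintf("Archaeon r%02d.%03d", ci, k))
    })
    genomes <- do.call(rbind, c(mine, extra))
    cohort_spec(genomes, seed = seed + ci)
  })
}

# Verify a pipeline run against the generator's ground truth; returns a
# character vector of mismatch descriptions (empty = exact agreement).
closure_mismatches <- function(scans, truth) {
  bad <- character(0)
  note <- function(...) bad <<- c(bad, sprintf(...))
  for (s in scans) {
    a <- s$annotation$assembly_id
    tr <- truth[truth$assembly_id == a, ]
    for (tc in target_classes()) {
      low <- switch(tc, SMC = "smc", SCPA = "scpA", SCPB = "scpB")
      want <- tr[[paste0(low, "_status")]]
      got <- s$calls$status[s$calls$target == tc]
      if (got != want) note("%s %s status: got %s want %s", a, tc, got, want)
      wantp <- tr[[paste0(low, "_pseudo")]]
      gotp <- s$calls$is_pseudo[s$calls$target == tc]
      if (gotp != wantp) note("%s %s pseudo: got %s want %s", a, tc, gotp, wantp)
    }
    for (pair in c("smc_scpA", "scpA_scpB")) {
      adj <- s$synteny[[pair]]
      comp <- tr[[paste0(pair, "_comparable")]]
      if (is.na(comp)) {
        if (!is.null(adj)) note("%s %s: expected no adjacency call", a, pair)
        next
      }
      if (is.null(adj)) {
        note("%s %s: missing adjacency call", a, pair)
        next
      }
      if (adj$comparable != comp) {
        note("%s %s comparable: got %s want %s", a, pair, adj$comparable, comp)
      }
      if (isTRUE(comp)) {
        want_i <- tr[[paste0(pair, "_intervening")]]
        if (adj$intervening != want_i) {
          note("%s %s intervening: got %d want %d", a, pair,
               adj$intervening, want_i)
        }
      }
    }
  }
  bad
}

# Independent per-order aggregation of the truth table (the oracle side
# of the report-count comparison).
truth_order_counts <- function(truth) {
  truth <- truth[order(truth$assembly_id), ]
  truth <- truth[!duplicated(truth$species), ]
  do.call(rbind, lapply(split(truth, truth$order), function(tt) {
    data.frame(
      order = tt$order[1], n_species = nrow(tt),
      n_smc = sum(tt$smc_status != "absent"),
      n_scpA = sum(tt$scpA_status != "absent"),
      n_scpB = sum(tt$scpB_status != "absent"),
      n_smc_scpA_neighbors = sum(tt$smc_scpA_neighbors %in% TRUE),
      n_scpA_scpB_neighbors = sum(tt$scpA_scpB_neighbors %in% TRUE),
      n_smc_pseudo = sum(tt$smc_pseudo),
      n_scpA_pseudo = sum(tt$scpA_pseudo),
      n_scpB_pseudo = sum(tt$scpB_pseudo),
      stringsAsFactors = FALSE
    )
  }))
}
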