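# Shared fixtures, built in code.

# Minimal hand-laid taxonomy:
#   root(1) > Bacteria(2) > order O(40) > family F(30) >
#   genus G1(20) > {SpA(11) > strainA(111), SpB(12)}
#   genus G2(21) > SpC(13)
tiny_tax <- function() {
  as_taxonomy(tibble::tribble(
    ~taxid, ~parent, ~rank, ~name,
    1L, 1L, "no rank", "root",
    2L, 1L, "superkingdom", "Bacteria",
    40L, 2L, "order", "OrderO",
    30L, 40L, "family", "FamilyF",
    20L, 30L, "genus", "GenusG1",
    21L, 30L, "genus", "GenusG2",
    11L, 20L, "species", "SpA",
    12L, 20L, "species", "SpB",
    13L, 21L, "species", "SpC",
    111L, 11L, "strain", "SpA str. 1"
  ))
}

# Small, fast community design for end-to-end tests: 4 targets whose
# fractions clear the 0.5% abundance cutoff, 4 decoys at 0.3% below it.
small_design <- function(...) {
  community_design(
    n_species = 4, n_decoys = 4,
    fractions = c(0.40, 0.25, 0.15, 0.10),
    genome_sizes = c(50000, 30000, 20000, 15000),
    decoy_fraction = 0.003, decoy_genome_size = 8000,
    total_bases = 1e5,
    frag_meanlog = log(800), frag_sdlog = 0.4, min_contig_len = 300,
    ...
  )
}

# Parse an emulated classifier's text in its own dialect and complete
# missing rows (blast emits nothing for unclassified queries).
parsed_assignments <- function(sim, style) {
  a <- switch(style,
    kaiju = parse_kaiju(sim$classifier_text$kaiju),
    kraken2 = parse_kraken2_output(sim$classifier_text$kraken2),
    blast = blast_to_assignments(parse_blast_tab(sim$classifier_text$blast),
                                 sim$tax)
  )
  complete_assignments(a, sim$contigs$id, classifier = style)
}

run_md3 <- function(sim, abundance_min_pct = 0.5, coverage_min_pct = 0.1,
                    style = "kaiju") {
  gs <- genome_sizes(sim$design$species$taxid, sim$assemblies)
  md3_annotate(
    parsed_assignments(sim, style), sim$contigs, sim$genes, gs,
    sim$assemblies, parse_paf(sim$paf), sim$tax,
    abundance_min_pct = abundance_min_pct,
    coverage_min_pct = coverage_min_pct
  )
}

# Brute-force species profile: naive loops over contigs, independent of
# the dplyr implementation.
brute_profile <- function(assignments, contigs, gsize, tax) {
  bases <- list()
  for (i in seq_len(nrow(assignments))) {
    tx <- assignments$taxid[[i]]
    if (is.na(tx)) next
    sp <- resolve_to_rank(tax, tx, "species")
    if (is.na(sp)) next
    len <- contigs$length[contigs$id == assignments$seq_id[[i]]]
    key <- as.character(sp)
    bases[[key]] <- (bases[[key]] %||% 0) + len
  }
  if (length(bases) == 0L) {
    return(tibble::tibble(species_taxid = integer(), assigned_bases = numeric(),
                          abundance_pct = numeric(), coverage_pct = numeric()))
  }
  tot <- sum(unlist(bases))
  out <- tibble::tibble(
    species_taxid = as.integer(names(bases)),
    assigned_bases = unname(unlist(bases))
  )
  out$abundance_pct <- 100 * out$assigned_bases / tot
  gs <- gsize$genome_size[match(out$species_taxid, gsize$species_taxid)]
  out$coverage_pct <- 100 * out$assigned_bases / gs
  out[order(out$species_taxid), ]
}

brute_select <- function(prof, ab_min, cov_min) {
  sel <- integer(0)
  for (i in seq_len(nrow(prof))) {
    if (!is.na(prof$coverage_pct[[i]]) &&
        prof$abundance_pct[[i]] >= ab_min &&
        prof$coverage_pct[[i]] >= cov_min) {
      sel <- c(sel, prof$species_taxid[[i]])
    }
  }
  sort(sel)
}

# Random small community of contig assignments for oracle tests.
random_community <- function(tax, n_contigs, gsize) {
  species <- tax$nodes$taxid[tax$nodes$rank %in% c("species", "strain", "genus")]
  taxid <- sample(c(species, NA_integer_), n_contigs, replace = TRUE)
  tibble::tibble(
    seq_id = sprintf("c%03d", seq_len(n_contigs)),
    taxid = as.integer(taxid),
    classifier = "synthetic",
    score = NA_real_
  )
}

# Independent table-11 translation oracle built on seqinr (a different
# codebase from the Biostrings-backed implementation).
oracle_translate <- function(nt) {
  aa <- paste(seqinr::translate(strsplit(nt, "")[[1]], numcode = 11),
              collapse = "")
  start <- substr(nt, 1, 3)
  if (start %in% c("ATG", "GTG", "TTG")) {
    aa <- paste0("M", substring(aa, 2))
  }
  sub("\\*$", "", aa)
}

random_cds <- function(n_codons) {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  body <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste0(sample(body, 1), paste(sample(body, n_codons - 2, replace = TRUE),
                                collapse = ""), sample(c("TAA", "TAG", "TGA"), 1))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
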