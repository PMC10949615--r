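# The three gene-annotation strategies.
#
# MD1: classify the predicted genes directly.
# MD2: classify the contigs and hand each contig's label to its genes.
# MD3 (ConDiGA): classify the contigs, select the most confident species by
#   relative sequence abundance and genome coverage, then assign genes to a
#   selected species by their best alignment against its reference genome.
#
# An annotation is a tibble with exactly one row per predicted gene:
# gene_id, species_taxid (NA = unknown), method, evidence.

new_annotation <- function(df, method) {
  df <- as_tibble(df)
  df$method <- method
  class(df) <- c("condiga_annotation", class(df))
  df
}

annotation_tbl <- function(gene_id, species_taxid, method, evidence) {
  new_annotation(
    tibble(
      gene_id = as.character(gene_id),
      species_taxid = as.integer(species_taxid),
      evidence = as.character(evidence)
    ),
    method
  )
}

#' Direct gene annotation (MD1)
#'
#' Every predicted gene is labeled with its own classifier call resolved to
#' species rank; unclassified genes and calls above species become unknown
#' (`NA`).
#'
#' @param gene_assignments Assignment tibble (one row per gene), e.g. from
#'   [parse_kaiju()], [parse_kraken2_output()] or [blast_to_assignments()].
#' @param tax A `condiga_taxonomy`.
#' @return Annotation tibble (`condiga_annotation`), one row per gene.
#' @export
md1_annotate <- function(gene_assignments, tax) {
  dup <- gene_assignments %>%
    dplyr::distinct(.data$seq_id, .data$classifier) %>%
    dplyr::count(.data$seq_id) %>%
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    stopf("gene %s has assignments from multiple classifiers; pass one classifier at a time",
      dup$seq_id[[1]])
  }
  if (anyDuplicated(gene_assignments$seq_id)) {
    stopf("duplicate assignment rows for gene %s; collapse multi-hit output first (see blast_to_assignments)",
      gene_assignments$seq_id[duplicated(gene_assignments$seq_id)][1])
  }
  sp <- resolve_to_rank(tax, remap_taxids(tax, gene_assignments$taxid), "species")
  annotation_tbl(
    gene_assignments$seq_id, sp, "md1",
    paste0(gene_assignments$classifier, ":", gene_assignments$taxid)
  )
}

#' Contig-label propagation (MD2)
#'
#' Each gene inherits the species-resolved label of the contig it sits on;
#' genes on unclassified or above-species contigs become unknown.
#'
#' @param contig_assignments Assignment tibble, one row per contig.
#' @param genes Gene tibble with `gene_id` and `contig_id` (e.g. from
#'   [parse_gff_genes()]).
#' @param tax A `condiga_taxonomy`.
#' @return Annotation tibble, one row per gene.
#' @export
md2_annotate <- function(contig_assignments, genes, tax) {
  i <- match(genes$contig_id, contig_assignments$seq_id)
  if (anyNA(i)) {
    stopf("gene %s references contig %s absent from the contig assignments",
      genes$gene_id[is.na(i)][1], genes$contig_id[is.na(i)][1])
  }
  sp_by_contig <- resolve_to_rank(
    tax, remap_taxids(tax, contig_assignments$taxid), "species"
  )
  annotation_tbl(
    genes$gene_id, sp_by_contig[i], "md2",
    paste0("contig:", genes$contig_id)
  )
}

#' Species profile from contig assignments
#'
#' Aggregates classified contigs into per-species statistics: assigned bases
#' (sum of contig lengths resolved to the species), relative sequence
#' abundance (percent of all species-resolved contig bases) and genome
#' coverage (percent of the species' genome size covered by assigned bases;
#' an approximation that can exceed 100 since classifiers emit no
#' coordinates).
#'
#' @param contig_assignments Assignment tibble, one row per contig.
#' @param contigs Tibble with `id` and `length` (e.g. from [read_fasta()]),
#'   covering every assigned contig.
#' @param genome_size_table Tibble `species_taxid` / `genome_size` (see
#'   [genome_sizes()]); species missing from it get `NA` coverage.
#' @param tax A `condiga_taxonomy`.
#' @param weighting `"bases"` (default) weights species by contig length;
#'   `"contigs"` by contig count.
#' @return A `condiga_profile` tibble sorted by abundance: `species_taxid`,
#'   `species_name`, `n_contigs`, `assigned_bases`, `abundance_pct`,
#'   `coverage_pct`, `selected` (all `FALSE` until
#'   [select_confident_species()]).
#' @export
species_profile <- function(contig_assignments, contigs, genome_size_table,
                            tax, weighting = c("bases", "contigs")) {
  weighting <- match.arg(weighting)
  i <- match(contig_assignments$seq_id, contigs$id)
  assigned <- !is.na(contig_assignments$taxid)
  if (anyNA(i[assigned])) {
    stopf("no length available for assigned contig %s",
      contig_assignments$seq_id[assigned & is.na(i)][1])
  }
  len <- contigs$length[i]
  if (any(len[assigned] < 0, na.rm = TRUE)) stopf("negative contig length")
  sp <- resolve_to_rank(tax, remap_taxids(tax, contig_assignments$taxid), "species")
  df <- tibble(species_taxid = sp, length = len)[!is.na(sp), ]
  prof <- df %>%
    dplyr::group_by(.data$species_taxid) %>%
    dplyr::summarise(
      n_contigs = dplyr::n(),
      assigned_bases = sum(.data$length),
      .groups = "drop"
    )
  w <- if (weighting == "bases") prof$assigned_bases else prof$n_contigs
  prof$abundance_pct <- if (nrow(prof)) 100 * w / sum(w) else numeric(0)
  gs <- genome_size_table$genome_size[
    match(prof$species_taxid, as.integer(genome_size_table$species_taxid))
  ]
  prof$coverage_pct <- 100 * prof$assigned_bases / gs
  prof$species_name <- taxon_name(tax, prof$species_taxid)
  prof$selected <- FALSE
  prof <- prof %>%
    dplyr::arrange(dplyr::desc(.data$abundance_pct), .data$species_taxid) %>%
    dplyr::select("species_taxid", "species_name", "n_contigs",
                  "assigned_bases", "abundance_pct", "coverage_pct", "selected")
  class(prof) <- c("condiga_profile", class(prof))
  prof
}

#' Select the most confident species
#'
#' Flags species passing both the relative-sequence-abundance and the
#' genome-coverage thresholds. Both comparisons are inclusive (`>=`) by
#' default; species with unknown genome size (`NA` coverage) are never
#' selected. Defaults are the real-sample preset (abundance 0.01, coverage
#' 0.1); see [threshold_preset()] for the synthetic-community preset
#' (0.5 / 0.1).
#'
#' @param profile A `condiga_profile` from [species_profile()].
#' @param abundance_min_pct,coverage_min_pct Thresholds in percent.
#' @param inclusive Use `>=` (default) or strict `>` comparisons.
#' @return The profile with `selected` updated (thresholds stored as
#'   attributes). Extract the selected set with [selected_species()].
#' @export
select_confident_species <- function(profile, abundance_min_pct = 0.01,
                                     coverage_min_pct = 0.1,
                                     inclusive = TRUE) {
  stopifnot(abundance_min_pct >= 0, coverage_min_pct >= 0)
  cmp <- if (inclusive) `>=` else `>`
  profile$selected <- !is.na(profile$coverage_pct) &
    cmp(profile$abundance_pct, abundance_min_pct) &
    cmp(profile$coverage_pct, coverage_min_pct)
  attr(profile, "thresholds") <- c(
    abundance_min_pct = abundance_min_pct, coverage_min_pct = coverage_min_pct
  )
  profile
}

#' @rdname select_confident_species
#' @export
selected_species <- function(profile) {
  sort(profile$species_taxid[profile$selected])
}

#' Threshold presets
#'
#' `"real-sample"`: abundance >= 0.01 percent, coverage >= 0.1 percent
#' (fecal/complex communities). `"synthetic-community"`: abundance >= 0.5
#' percent, coverage >= 0.1 percent (defined mock communities).
#'
#' @param name Preset name.
#' @return Named numeric vector `abundance_min_pct`, `coverage_min_pct`.
#' @export
threshold_preset <- function(name = c("real-sample", "synthetic-community")) {
  name <- match.arg(name)
  switch(name,
    "real-sample" = c(abundance_min_pct = 0.01, coverage_min_pct = 0.1),
    "synthetic-community" = c(abundance_min_pct = 0.5, coverage_min_pct = 0.1)
  )
}

#' Choose the reference assembly for a species
#'
#' Priority: RefSeq category `"reference genome"` over
#' `"representative genome"` over anything else; ties broken by assembly
#' level (Complete Genome > Chromosome > Scaffold > Contig), then latest
#' release date, then lexicographically smallest accession.
#'
#' @param species_taxid Single species taxid.
#' @param assemblies Tibble from [parse_assembly_summary()].
#' @return One-row tibble, the chosen assembly.
#' @export
choose_reference_assembly <- function(species_taxid, assemblies) {
  rows <- assemblies[assemblies$species_taxid == species_taxid, ]
  if (nrow(rows) == 0L) {
    stopf("no assembly available for species taxid %s", species_taxid)
  }
  cat_rank <- match(rows$refseq_category,
    c("reference genome", "representative genome"))
  cat_rank[is.na(cat_rank)] <- 3L
  lvl_rank <- match(rows$assembly_level,
    c("Complete Genome", "Chromosome", "Scaffold", "Contig"))
  lvl_rank[is.na(lvl_rank)] <- 5L
  ord <- order(cat_rank, lvl_rank,
    dplyr::desc(as.Date(rows$seq_rel_date, optional = TRUE)),
    rows$assembly_accession)
  rows[ord[[1]], ]
}

#' Assign genes to species by best alignment
#'
#' Keeps primary alignments only; per gene the best alignment has maximal
#' residue matches, ties broken by maximal block length, then maximal mapq,
#' then the lexicographically smallest species taxid, making the assignment
#' deterministic. Genes with no primary alignment become unknown.
#'
#' @param alignments Tibble from [parse_paf()].
#' @param target_to_species Tibble `target_id` / `species_taxid` mapping each
#'   alignment target (reference sequence or accession) to its species.
#' @param gene_ids Character vector of all predicted genes (so unaligned
#'   genes are reported as unknown).
#' @param method Method tag recorded in the annotation (default `"md3"`).
#' @return Annotation tibble, one row per gene in `gene_ids`.
#' @export
assign_genes_by_best_alignment <- function(alignments, target_to_species,
                                           gene_ids, method = "md3") {
  sp <- target_to_species$species_taxid[
    match(alignments$target_id, target_to_species$target_id)
  ]
  if (anyNA(sp) && nrow(alignments)) {
    stopf("alignment target %s is not mapped to a species",
      alignments$target_id[is.na(sp)][1])
  }
  best <- alignments %>%
    dplyr::mutate(species_taxid = as.integer(sp)) %>%
    dplyr::filter(.data$primary) %>%
    dplyr::arrange(
      .data$query_id, dplyr::desc(.data$matches), dplyr::desc(.data$block_len),
      dplyr::desc(.data$mapq), as.character(.data$species_taxid)
    ) %>%
    dplyr::distinct(.data$query_id, .keep_all = TRUE)
  i <- match(gene_ids, best$query_id)
  annotation_tbl(
    gene_ids, best$species_taxid[i], method,
    ifelse(is.na(i), NA_character_,
      paste0("paf:", best$target_id[i], ":", best$matches[i]))
  )
}

#' Contigs-directed gene annotation (MD3 / ConDiGA)
#'
#' The full three-stage pipeline: profile the contig classifications,
#' select the most confident species, and assign every predicted gene to
#' one of them by its best alignment. Alignments to references of
#' non-selected species are discarded, so only selected species can appear
#' as labels; everything else is unknown.
#'
#' @inheritParams species_profile
#' @inheritParams select_confident_species
#' @param genes Gene tibble with `gene_id` (and `contig_id`).
#' @param assemblies Tibble from [parse_assembly_summary()] mapping the
#'   alignment targets (`assembly_accession`) to species.
#' @param alignments PAF tibble of gene-vs-reference alignments.
#' @return List with `annotation` (one row per gene) and `profile`
#'   (selection flags set).
#' @export
md3_annotate <- function(contig_assignments, contigs, genes,
                         genome_size_table, assemblies, alignments, tax,
                         abundance_min_pct = 0.01, coverage_min_pct = 0.1,
                         inclusive = TRUE, weighting = "bases") {
  profile <- species_profile(contig_assignments, contigs, genome_size_table,
                             tax, weighting = weighting)
  profile <- select_confident_species(profile, abundance_min_pct,
                                      coverage_min_pct, inclusive)
  sel <- selected_species(profile)
  t2s <- assemblies %>%
    dplyr::transmute(target_id = .data$assembly_accession,
                     species_taxid = as.integer(.data$species_taxid))
  keep <- t2s$species_taxid[match(alignments$target_id, t2s$target_id)] %in% sel
  ann <- assign_genes_by_best_alignment(
    alignments[keep, , drop = FALSE], t2s, genes$gene_id, method = "md3"
  )
  list(annotation = ann, profile = profile)
}

#' Summarize an annotation, optionally against a truth map
#'
#' @param annotation Annotation tibble.
#' @param truth Optional tibble `gene_id` / `species_taxid` with the true
#'   species of each gene (`NA` allowed).
#' @param tax Optional taxonomy to attach species names.
#' @return List with `species` (per-species gene counts, descending) and
#'   `summary` (one row: totals, annotation rate, species count, and
#'   species-level precision/recall when `truth` is given).
#' @export
tabulate_annotation <- function(annotation, truth = NULL, tax = NULL) {
  labeled <- !is.na(annotation$species_taxid)
  species <- annotation[labeled, ] %>%
    dplyr::count(.data$species_taxid, name = "n_genes") %>%
    dplyr::arrange(dplyr::desc(.data$n_genes), .data$species_taxid)
  if (!is.null(tax)) {
    species$species_name <- taxon_name(tax, species$species_taxid)
  }
  summary <- tibble(
    total_genes = nrow(annotation),
    labeled_genes = sum(labeled),
    unknown_genes = sum(!labeled),
    annotation_rate = if (nrow(annotation)) sum(labeled) / nrow(annotation) else NA_real_,
    n_species = nrow(species)
  )
  if (!is.null(truth)) {
    tr <- truth$species_taxid[match(annotation$gene_id, truth$gene_id)]
    correct <- labeled & !is.na(tr) & annotation$species_taxid == tr
    summary$precision <- if (any(labeled)) sum(correct) / sum(labeled) else NA_real_
    summary$recall <- if (any(!is.na(tr))) sum(correct) / sum(!is.na(tr)) else NA_real_
  }
  list(species = species, summary = summary)
}
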