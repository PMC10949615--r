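# End-to-end runner: wire the annotation strategies over files on disk,
# write the annotation TSV, protein FASTA, profile TSV and a JSON manifest.

#' Assemble a run configuration
#'
#' Paths point at files in the formats the pipeline consumes (see the
#' format readers). `classifier_path` is the per-gene classifier output
#' for md1 and the per-contig output for md2/md3.
#'
#' @param strategy `"md1"`, `"md2"` or `"md3"`.
#' @param classifier `"kaiju"`, `"kraken2"` or `"blast"`.
#' @param contigs_path Contig FASTA (md2/md3).
#' @param gff_path Gene GFF (gene coordinates + sequences).
#' @param genes_fasta_path Optional gene nucleotide FASTA (preferred over
#'   GFF-extracted sequences when both are given).
#' @param classifier_path Classifier output file.
#' @param taxonomy_path Taxonomy (`nodes.dmp` or 4-column TSV).
#' @param names_path Optional `names.dmp`.
#' @param assembly_summary_path Assembly summary (md3).
#' @param paf_path Gene-vs-reference PAF (md3).
#' @param genome_size_path Optional `species_taxid`/`genome_size` TSV.
#' @param abundance_min_pct,coverage_min_pct,inclusive,weighting Selection
#'   parameters (see [select_confident_species()], [species_profile()]);
#'   defaults are the real-sample preset.
#' @param out_dir Output directory.
#' @return A `condiga_config` list.
#' @export
condiga_config <- function(strategy = c("md3", "md1", "md2"),
                           classifier = c("kaiju", "kraken2", "blast"),
                           contigs_path = NULL, gff_path = NULL,
                           genes_fasta_path = NULL, classifier_path = NULL,
                           taxonomy_path = NULL, names_path = NULL,
                           assembly_summary_path = NULL, paf_path = NULL,
                           genome_size_path = NULL,
                           abundance_min_pct = 0.01, coverage_min_pct = 0.1,
                           inclusive = TRUE, weighting = "bases",
                           out_dir = ".") {
  structure(list(
    strategy = match.arg(strategy), classifier = match.arg(classifier),
    contigs_path = contigs_path, gff_path = gff_path,
    genes_fasta_path = genes_fasta_path, classifier_path = classifier_path,
    taxonomy_path = taxonomy_path, names_path = names_path,
    assembly_summary_path = assembly_summary_path, paf_path = paf_path,
    genome_size_path = genome_size_path,
    abundance_min_pct = abundance_min_pct,
    coverage_min_pct = coverage_min_pct,
    inclusive = inclusive, weighting = weighting, out_dir = out_dir
  ), class = "condiga_config")
}

#' Read a YAML run configuration
#'
#' Keys mirror the arguments of [condiga_config()].
#'
#' @param path YAML file.
#' @return A `condiga_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(condiga_config, vals)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run an annotation strategy end to end
#'
#' Parses the configured inputs, runs the chosen strategy, and writes
#' `annotation.tsv`, `proteins.fasta` (+ `proteins.tsv` sidecar),
#' `profile.tsv` (md3 only) and `manifest.json` (counts, species list,
#' thresholds, input checksums) under `out_dir`.
#'
#' @param config A `condiga_config` (or YAML path).
#' @return Invisibly, a list with `annotation`, `profile` (md3 or `NULL`),
#'   `db` and `manifest`.
#' @export
run_condiga <- function(config) {
  if (is.character(config)) config <- read_config(config)
  cfg <- config
  for (p in c("contigs_path", "gff_path", "classifier_path", "taxonomy_path",
              "assembly_summary_path", "paf_path")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stopf("stage 'inputs' failed: %s '%s' does not exist", p, cfg[[p]])
    }
  }
  tax <- stage("taxonomy",
    load_taxonomy(cfg$taxonomy_path, names_source = cfg$names_path))
  contigs <- if (!is.null(cfg$contigs_path)) {
    stage("contigs", read_fasta(cfg$contigs_path))
  }
  genes <- stage("genes", {
    g <- parse_gff_genes(cfg$gff_path, contigs)
    if (!is.null(cfg$genes_fasta_path)) {
      fa <- read_fasta(cfg$genes_fasta_path)
      i <- match(g$gene_id, fa$id)
      g$nt_seq[!is.na(i)] <- fa$seq[i[!is.na(i)]]
    }
    g
  })
  read_assign <- function(path) {
    switch(cfg$classifier,
      kaiju = parse_kaiju(path),
      kraken2 = parse_kraken2_output(path),
      blast = blast_to_assignments(parse_blast_tab(path), tax)
    )
  }
  profile <- NULL
  if (cfg$strategy == "md1") {
    ann <- stage("annotate", {
      a <- complete_assignments(read_assign(cfg$classifier_path), genes$gene_id)
      md1_annotate(a, tax)
    })
  } else {
    contig_assign <- stage("classify", {
      complete_assignments(read_assign(cfg$classifier_path), contigs$id)
    })
    if (cfg$strategy == "md2") {
      ann <- stage("annotate", md2_annotate(contig_assign, genes, tax))
    } else {
      if (is.null(cfg$paf_path)) {
        stopf("stage 'assign' failed: strategy md3 requires paf_path")
      }
      assemblies <- stage("assemblies",
        parse_assembly_summary(cfg$assembly_summary_path))
      gsize <- stage("genome_sizes", {
        st <- if (!is.null(cfg$genome_size_path)) {
          readr::read_tsv(cfg$genome_size_path, col_types = "id",
                          progress = FALSE)
        }
        genome_sizes(unique(assemblies$species_taxid), assemblies, st)
      })
      aln <- stage("assign", parse_paf(cfg$paf_path))
      res <- stage("annotate", md3_annotate(
        contig_assign, contigs, genes, gsize, assemblies, aln, tax,
        abundance_min_pct = cfg$abundance_min_pct,
        coverage_min_pct = cfg$coverage_min_pct,
        inclusive = cfg$inclusive, weighting = cfg$weighting
      ))
      ann <- res$annotation
      profile <- res$profile
    }
  }
  db <- stage("build-db", build_protein_db(genes, ann, tax))
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  readr::write_tsv(as_tibble(ann), out("annotation.tsv"))
  write_protein_fasta(db, out("proteins.fasta"), sidecar = out("proteins.tsv"))
  if (!is.null(profile)) readr::write_tsv(as_tibble(profile), out("profile.tsv"))
  tab <- tabulate_annotation(ann, tax = tax)
  inputs <- purrr::compact(cfg[grepl("_path$", names(cfg))])
  manifest <- list(
    strategy = cfg$strategy, classifier = cfg$classifier,
    thresholds = list(abundance_min_pct = cfg$abundance_min_pct,
                      coverage_min_pct = cfg$coverage_min_pct),
    total_genes = tab$summary$total_genes,
    labeled_genes = tab$summary$labeled_genes,
    unknown_genes = tab$summary$unknown_genes,
    annotation_rate = tab$summary$annotation_rate,
    n_species = tab$summary$n_species,
    species = tab$species$species_taxid,
    skipped_proteins = attr(db, "skipped"),
    input_md5 = purrr::map_chr(inputs, ~ unname(tools::md5sum(.x)))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(annotation = ann, profile = profile, db = db,
                 manifest = manifest))
}
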