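test_that("the whole fixture set is deterministic under a fixed seed", {
  d <- small_design(chimera_rate = 0.05, unclassified_rate = 0.1)
  s1 <- simulate_community(d, seed = 17)
  s2 <- simulate_community(d, seed = 17)
  expect_identical(s1$contigs, s2$contigs)
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$classifier_text, s2$classifier_text)
  expect_identical(s1$paf, s2$paf)
  expect_identical(s1$peptides, s2$peptides)
  s3 <- simulate_community(d, seed = 18)
  expect_false(identical(s1$contigs$seq, s3$contigs$seq))
})

test_that("genomes, contigs and coordinates respect the design", {
  d <- small_design()
  gen <- generate_genomes(d, seed = 2)
  expect_equal(gen$genomes$length, d$species$genome_size)
  expect_equal(nrow(gen$assemblies), nrow(d$species))
  expect_true(all(!is.na(gen$assemblies$genome_size)))

  frag <- fragment_to_contigs(gen, d, seed = 2)
  # realized bases per species equal the designed fractions exactly
  bases <- tapply(frag$contigs$length[match(frag$truth$contig_id,
                                            frag$contigs$id)],
                  frag$truth$species_taxid, sum)
  expect_equal(unname(bases[as.character(d$species$taxid)]),
               round(d$species$fraction * d$total_bases),
               ignore_attr = TRUE)
  expect_true(all(frag$contigs$length >= d$min_contig_len))
  expect_false(any(frag$truth$chimeric))  # chimera rate 0

  # zero species -> empty outputs
  d0 <- community_design(n_species = 0, n_decoys = 0, fractions = numeric(0),
                         genome_sizes = numeric(0))
  expect_equal(nrow(generate_genomes(d0, 1)$genomes), 0L)
})

test_that("chimeric contigs keep their majority-species truth", {
  d <- small_design(chimera_rate = 0.5)
  frag <- fragment_to_contigs(generate_genomes(d, 4), d, seed = 4)
  chim <- frag$truth[frag$truth$chimeric, ]
  expect_gt(nrow(chim), 0)
  expect_true(all(!is.na(chim$minor_species_taxid)))
  expect_true(all(chim$minor_species_taxid != chim$species_taxid))
  # lengths unchanged by splicing: totals still match the design
  bases <- tapply(frag$contigs$length[match(frag$truth$contig_id,
                                            frag$contigs$id)],
                  frag$truth$species_taxid, sum)
  expect_equal(sum(bases), sum(round(d$species$fraction * d$total_bases)))
})

test_that("planted genes are in-bounds, stranded, and translate cleanly", {
  sim <- simulate_community(small_design(), seed = 5)
  genes <- sim$genes
  expect_gt(nrow(genes), 0)
  clen <- sim$contigs$length[match(genes$contig_id, sim$contigs$id)]
  expect_true(all(genes$start >= 1 & genes$end <= clen))
  expect_true(all((genes$end - genes$start + 1L) %% 3L == 0L))
  expect_true(all(genes$strand %in% c("+", "-")))
  # genes are recoverable from the contigs via the GFF
  extracted <- parse_gff_genes(sim$gff, sim$contigs)
  expect_equal(extracted$nt_seq, genes$nt_seq)
  # and translate without internal stops
  expect_no_error(translate_cds(genes$nt_seq))

  d0 <- small_design(gene_density = 0)
  expect_equal(nrow(simulate_community(d0, seed = 5)$genes), 0L)
})

test_that("emulated classifiers round-trip truth through their dialects", {
  d <- small_design()
  sim <- simulate_community(d, seed = 6)
  for (style in c("kaiju", "kraken2", "blast")) {
    a <- parsed_assignments(sim, style)
    sp <- resolve_to_rank(sim$tax, a$taxid, "species")
    truth <- sim$contig_truth$species_taxid[
      match(a$seq_id, sim$contig_truth$contig_id)]
    expect_equal(sp, truth, ignore_attr = TRUE)  # all rates 0 -> identity
  }

  all_u <- emulate_classifier(sim$contig_truth, sim$tax,
                              small_design(unclassified_rate = 1),
                              style = "kaiju", seed = 6)
  expect_true(all(is.na(parse_kaiju(all_u)$taxid)))
})

test_that("classifier error modes land where the design puts them", {
  d <- small_design(error_rate = 0.3, above_species_rate = 0.3,
                    strain_rate = 0.2, unclassified_rate = 0.2)
  sim0 <- simulate_community(small_design(), seed = 9)
  txt <- emulate_classifier(sim0$contig_truth, sim0$tax, d,
                            style = "kaiju", seed = 9)
  a <- parse_kaiju(txt)
  ranks <- unname(sim0$tax$rank[as.character(a$taxid)])
  expect_true(any(is.na(a$taxid)))
  expect_true(any(ranks == "genus", na.rm = TRUE))
  expect_true(any(ranks == "strain", na.rm = TRUE))
  decoys <- d$species$taxid[d$species$is_decoy]
  truth <- sim0$contig_truth$species_taxid[
    match(a$seq_id, sim0$contig_truth$contig_id)]
  expect_true(any(a$taxid %in% decoys & a$taxid != truth, na.rm = TRUE))
})

test_that("emulated alignments let best-hit assignment recover truth", {
  sim <- simulate_community(small_design(), seed = 10)
  t2s <- tibble::tibble(target_id = sim$assemblies$assembly_accession,
                        species_taxid = sim$assemblies$species_taxid)
  ann <- assign_genes_by_best_alignment(parse_paf(sim$paf), t2s,
                                        sim$genes$gene_id)
  expect_equal(ann$species_taxid, sim$gene_truth$species_taxid[
    match(ann$gene_id, sim$gene_truth$gene_id)])

  # decoy hits carry strictly fewer matches than the true primary hit
  paf <- parse_paf(sim$paf)
  best <- tapply(paf$matches[paf$primary], paf$query_id[paf$primary], max)
  true_sp <- sim$gene_truth$species_taxid[
    match(names(best), sim$gene_truth$gene_id)]
  top_target <- t2s$species_taxid[match(
    paf$target_id[paf$primary][match(names(best),
      paf$query_id[paf$primary])], t2s$target_id)]
  expect_equal(unname(top_target), true_sp)
})

test_that("emulated peptides reproduce designed abundances within noise", {
  sim <- simulate_community(small_design(), seed = 12)
  ann_truth <- md1_annotate(tibble::tibble(
    seq_id = sim$gene_truth$gene_id, taxid = sim$gene_truth$species_taxid,
    classifier = "synthetic", score = NA_real_), sim$tax)
  mg <- mg_abundance(ann_truth)
  mp <- mp_abundance(sim$peptides)
  cmp <- dplyr::inner_join(mg, mp, by = "species_taxid",
                           suffix = c("_mg", "_mp"))
  expect_gt(nrow(cmp), 3)
  expect_true(all(abs(cmp$fraction_mg - cmp$fraction_mp) < 0.15))

  none <- emulate_peptides(sim$genes[0, ], ann_truth, sim$design, seed = 1)
  expect_equal(nrow(none), 0L)
})

test_that("simulate_community writes every fixture file in its dialect", {
  dir <- withr::local_tempdir()
  sim <- simulate_community(small_design(), seed = 14, dir = dir)
  expect_true(all(file.exists(sim$files)))
  expect_equal(read_fasta(sim$files[["contigs"]])$seq, sim$contigs$seq)
  tax <- load_taxonomy(sim$files[["taxonomy"]])
  expect_equal(nrow(tax$nodes), nrow(sim$tax$nodes))
  asm <- parse_assembly_summary(sim$files[["assembly_summary"]])
  expect_equal(asm$species_taxid, sim$assemblies$species_taxid)
  expect_equal(nrow(parse_paf(sim$files[["paf"]])),
               nrow(parse_paf(sim$paf)))
  expect_equal(read_peptides(sim$files[["peptides"]])$peptide,
               sim$peptides$peptide)
})
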