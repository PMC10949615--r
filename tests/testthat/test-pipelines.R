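make_assign <- function(ids, taxids) {
  tibble::tibble(seq_id = ids, taxid = as.integer(taxids),
                 classifier = "synthetic", score = NA_real_)
}

test_that("species profile computes abundance and coverage from contig bases", {
  tax <- tiny_tax()
  a <- make_assign(c("c1", "c2", "c3"), c(11L, 11L, 12L))
  contigs <- tibble::tibble(id = c("c1", "c2", "c3"),
                            length = c(6000L, 3000L, 1000L))
  gs <- tibble::tibble(species_taxid = c(11L, 12L),
                       genome_size = c(1e6, 2e6))
  prof <- species_profile(a, contigs, gs, tax)
  expect_equal(prof$species_taxid, c(11L, 12L))
  expect_equal(prof$abundance_pct, c(90, 10))
  expect_equal(prof$coverage_pct, c(0.9, 0.05))
  expect_equal(sum(prof$abundance_pct), 100, tolerance = 1e-9)

  # selection at the mock-community thresholds: SpB fails coverage
  sel <- select_confident_species(prof, 0.5, 0.1)
  expect_equal(selected_species(sel), 11L)

  # inclusive boundary: abundance exactly at the cutoff is kept
  prof2 <- species_profile(
    make_assign(c("x", "y"), c(11L, 12L)),
    tibble::tibble(id = c("x", "y"), length = c(1L, 9999L)),
    tibble::tibble(species_taxid = c(11L, 12L), genome_size = c(10, 10)),
    tax
  )
  expect_equal(sort(prof2$abundance_pct), c(0.01, 99.99))
  expect_true(11L %in% selected_species(select_confident_species(prof2, 0.01, 0.1)))
  expect_false(11L %in% selected_species(
    select_confident_species(prof2, 0.01, 0.1, inclusive = FALSE)))

  empty <- species_profile(make_assign("c9", NA), tibble::tibble(id = "c9", length = 5L), gs, tax)
  expect_equal(nrow(empty), 0L)
  expect_error(
    species_profile(make_assign("zz", 11L), contigs, gs, tax),
    "no length"
  )
})

test_that("contig-count weighting is available as an alternative", {
  tax <- tiny_tax()
  a <- make_assign(c("c1", "c2", "c3"), c(11L, 12L, 12L))
  contigs <- tibble::tibble(id = c("c1", "c2", "c3"),
                            length = c(8000L, 1000L, 1000L))
  gs <- tibble::tibble(species_taxid = c(11L, 12L), genome_size = c(1e5, 1e5))
  by_bases <- species_profile(a, contigs, gs, tax)
  by_count <- species_profile(a, contigs, gs, tax, weighting = "contigs")
  expect_equal(by_bases$abundance_pct[by_bases$species_taxid == 11L], 80)
  expect_equal(by_count$abundance_pct[by_count$species_taxid == 11L], 100 / 3)
})

test_that("md1 lifts strains, drops above-species calls, conserves genes", {
  tax <- tiny_tax()
  a <- make_assign(c("g1", "g2", "g3"), c(111L, 20L, NA))
  ann <- md1_annotate(a, tax)
  expect_equal(nrow(ann), 3L)
  expect_equal(ann$species_taxid, c(11L, NA_integer_, NA_integer_))
  expect_error(
    md1_annotate(dplyr::bind_rows(a, make_assign("g1", 12L)), tax),
    "duplicate"
  )
})

test_that("md2 propagates contig labels to genes", {
  tax <- tiny_tax()
  ca <- make_assign(c("c1", "c2", "c3"), c(11L, NA, 12L))
  genes <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    contig_id = c("c1", "c1", "c2", "c3")
  )
  ann <- md2_annotate(ca, genes, tax)
  expect_equal(ann$species_taxid, c(11L, 11L, NA, 12L))
  expect_error(
    md2_annotate(ca, tibble::tibble(gene_id = "g9", contig_id = "c99"), tax),
    "absent from the contig assignments"
  )
})

test_that("reference assemblies are chosen by the stated priority chain", {
  mk <- function(acc, cat, lvl, date) {
    tibble::tibble(assembly_accession = acc, species_taxid = 11L,
                   refseq_category = cat, assembly_level = lvl,
                   seq_rel_date = date, genome_size = 1e6)
  }
  asm <- dplyr::bind_rows(
    mk("GCF_B.1", "representative genome", "Complete Genome", "2019/01/01"),
    mk("GCF_A.1", "reference genome", "Contig", "2015/01/01")
  )
  expect_equal(choose_reference_assembly(11L, asm)$assembly_accession, "GCF_A.1")
  asm2 <- dplyr::bind_rows(
    mk("GCF_C.1", "na", "Contig", "2018/01/01"),
    mk("GCF_D.1", "na", "Contig", "2021/06/01")
  )
  expect_equal(choose_reference_assembly(11L, asm2)$assembly_accession, "GCF_D.1")
  expect_equal(choose_reference_assembly(11L, asm2[1, ])$assembly_accession, "GCF_C.1")
  expect_error(choose_reference_assembly(99L, asm), "no assembly")
})

test_that("best-alignment assignment follows the deterministic tie chain", {
  t2s <- tibble::tibble(target_id = c("refA", "refB"),
                        species_taxid = c(11L, 12L))
  paf <- parse_paf(paste0(
    "g1\t900\t0\t899\t+\trefA\t1000\t0\t899\t850\t899\t60\ttp:A:P\n",
    "g1\t900\t0\t899\t+\trefB\t1000\t0\t899\t820\t899\t60\ttp:A:P\n",
    "g3\t600\t0\t599\t+\trefA\t1000\t0\t599\t500\t600\t60\ttp:A:P\n",
    "g3\t600\t0\t549\t+\trefB\t1000\t0\t549\t500\t550\t60\ttp:A:P\n",
    "g4\t600\t0\t599\t+\trefB\t1000\t0\t599\t999\t999\t60\ttp:A:S\n"
  ))
  ann <- assign_genes_by_best_alignment(paf, t2s, c("g1", "g2", "g3", "g4"))
  expect_equal(ann$species_taxid[ann$gene_id == "g1"], 11L)  # max matches
  expect_true(is.na(ann$species_taxid[ann$gene_id == "g2"])) # no alignment
  expect_equal(ann$species_taxid[ann$gene_id == "g3"], 11L)  # block tiebreak
  expect_true(is.na(ann$species_taxid[ann$gene_id == "g4"])) # secondary only
  expect_equal(nrow(ann), 4L)

  # determinism: shuffled input rows give an identical map
  withr::with_seed(5, {
    shuf <- paf[sample(nrow(paf)), ]
    expect_equal(assign_genes_by_best_alignment(shuf, t2s, c("g1", "g2", "g3", "g4")), ann)
  })
  expect_error(
    assign_genes_by_best_alignment(
      parse_paf("g\t10\t0\t9\t+\tmystery\t100\t0\t9\t9\t10\t60"),
      t2s, "g"),
    "not mapped"
  )
})

test_that("md3 restricts labels to selected species and conserves genes", {
  sim <- simulate_community(small_design(chimera_rate = 0.05,
                                         above_species_rate = 0.05,
                                         unclassified_rate = 0.05),
                            seed = 3)
  res <- run_md3(sim)
  sel <- selected_species(res$profile)
  labels <- unique(stats::na.omit(res$annotation$species_taxid))
  expect_true(all(labels %in% sel))                        # closure
  expect_equal(nrow(res$annotation), nrow(sim$genes))      # conservation
  targets <- sim$design$species$taxid[!sim$design$species$is_decoy]
  expect_setequal(sel, targets)                            # planted recovery

  # zero selected species -> everything unknown
  res0 <- run_md3(sim, abundance_min_pct = 1000)
  expect_true(all(is.na(res0$annotation$species_taxid)))
})

test_that("single-species communities collapse to one label", {
  d <- community_design(
    n_species = 1, n_decoys = 0, fractions = 0.9,
    genome_sizes = 50000, total_bases = 3e4,
    frag_meanlog = log(800), frag_sdlog = 0.3, min_contig_len = 300
  )
  sim <- simulate_community(d, seed = 8)
  res <- run_md3(sim)
  aligned <- !is.na(res$annotation$species_taxid)
  expect_true(any(aligned))
  expect_equal(unique(res$annotation$species_taxid[aligned]),
               d$species$taxid[1])
})

test_that("profile and selection match a brute-force oracle on random communities", {
  tax <- tiny_tax()
  gs <- tibble::tibble(species_taxid = c(11L, 12L, 13L),
                       genome_size = c(5e4, 1e5, NA))
  withr::with_seed(99, {
    for (rep in 1:25) {
      n <- sample(5:50, 1)
      a <- random_community(tax, n, gs)
      contigs <- tibble::tibble(id = a$seq_id,
                                length = sample(200:3000, n, replace = TRUE))
      prof <- species_profile(a, contigs, gs, tax)
      oracle <- brute_profile(a, contigs, gs, tax)
      got <- prof[order(prof$species_taxid),
                  c("species_taxid", "assigned_bases", "abundance_pct",
                    "coverage_pct")]
      expect_equal(as.data.frame(got), as.data.frame(oracle),
                   tolerance = 1e-12, ignore_attr = TRUE)
      ab <- sample(c(0.01, 0.5, 5, 20), 1); cv <- sample(c(0.1, 1, 50), 1)
      expect_equal(
        selected_species(select_confident_species(prof, ab, cv)),
        brute_select(oracle, ab, cv)
      )
    }
  })
})

test_that("raising either threshold never enlarges the selected set", {
  sim <- simulate_community(small_design(), seed = 13)
  gs <- genome_sizes(sim$design$species$taxid, sim$assemblies)
  prof <- species_profile(parsed_assignments(sim, "kaiju"), sim$contigs, gs,
                          sim$tax)
  grid_ab <- c(0, 0.1, 0.5, 2, 10, 30)
  grid_cv <- c(0, 0.1, 1, 10, 60)
  for (cv in grid_cv) {
    prev <- NULL
    for (ab in grid_ab) {
      cur <- selected_species(select_confident_species(prof, ab, cv))
      if (!is.null(prev)) expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
  for (ab in grid_ab) {
    prev <- NULL
    for (cv in grid_cv) {
      cur <- selected_species(select_confident_species(prof, ab, cv))
      if (!is.null(prev)) expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("tabulation reports counts, rates, and truth-based accuracy", {
  tax <- tiny_tax()
  ann <- md1_annotate(make_assign(paste0("g", 1:4), c(11L, 11L, 12L, NA)), tax)
  tab <- tabulate_annotation(ann, tax = tax)
  expect_equal(tab$summary$annotation_rate, 0.75)
  expect_equal(tab$summary$n_species, 2L)
  expect_equal(tab$species$n_genes, c(2L, 1L))

  truth <- tibble::tibble(gene_id = paste0("g", 1:4),
                          species_taxid = c(11L, 11L, 12L, 13L))
  perfect <- tabulate_annotation(
    md1_annotate(make_assign(paste0("g", 1:4), truth$species_taxid), tax),
    truth = truth
  )
  expect_equal(perfect$summary$precision, 1)
  expect_equal(perfect$summary$recall, 1)
})

test_that("annotation objects expose tidy/glance summaries", {
  tax <- tiny_tax()
  ann <- md1_annotate(make_assign(paste0("g", 1:4), c(11L, 11L, 12L, NA)), tax)
  td <- tidy(ann)
  expect_equal(td$fraction, c(2 / 3, 1 / 3))
  gl <- glance(ann)
  expect_equal(gl$total_genes, 4L)
  expect_equal(gl$unknown_genes, 1L)
})
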