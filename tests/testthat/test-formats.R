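test_that("FASTA parses, preserves descriptions, and flags malformed input", {
  fa <- read_fasta(">a first record\nACGT\n")
  expect_equal(fa$id, "a")
  expect_equal(fa$desc, "a first record")
  expect_equal(fa$seq, "ACGT")
  expect_equal(fa$length, 4L)
  expect_equal(nrow(read_fasta("")), 0L)
  expect_error(read_fasta(">a\nAC GT"), "line 2")
  expect_error(read_fasta(">a\nACGT\n>\nAC"), "empty sequence id")
  expect_error(read_fasta("ACGT"), "line 1")
})

test_that("FASTA round-trips and agrees with an independent reader", {
  recs <- withr::with_seed(11, tibble::tibble(
    id = sprintf("seq%03d", 1:100),
    desc = sprintf("seq%03d some description %d", 1:100, 1:100),
    seq = vapply(sample(1:200, 100, replace = TRUE), function(n)
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
      ""),
    length = NA_integer_
  ))
  recs$length <- nchar(recs$seq)
  txt <- write_fasta(recs, width = 60)
  back <- read_fasta(txt)
  expect_equal(back$id, recs$id)
  expect_equal(back$desc, recs$desc)
  expect_equal(back$seq, recs$seq)

  # independent reader: Biostrings
  tmp <- withr::local_tempfile(fileext = ".fa")
  writeLines(txt, tmp)
  bs <- Biostrings::readDNAStringSet(tmp)
  expect_equal(unname(as.character(bs)), recs$seq)
  expect_equal(unname(names(bs)), recs$desc)
})

test_that("kaiju output parses C and U rows", {
  a <- parse_kaiju("C\tc1\t562\nU\tc2\t0\n")
  expect_equal(a$seq_id, c("c1", "c2"))
  expect_equal(a$taxid, c(562L, NA_integer_))
  expect_equal(unique(a$classifier), "kaiju")
  expect_equal(nrow(parse_kaiju("")), 0L)
  expect_error(parse_kaiju("C\tc1\tabc"), "non-integer taxid")
})

test_that("kraken2 output parses both --use-names and bare-taxid dialects", {
  a <- parse_kraken2_output(paste0(
    "C\tc1\tEscherichia coli (taxid 562)\t1500\t0:10\n",
    "C\tc2\t562\t1500\t0:10\n",
    "U\tc9\tunclassified (taxid 0)\t900\t\n"
  ))
  expect_equal(a$taxid, c(562L, 562L, NA_integer_))
  expect_error(parse_kraken2_output("C\tc1\tno id here\t1\t"), "taxid")
})

test_that("22-field BLAST rows parse with multi-valued staxids", {
  row <- paste(c("g1", "ref|x|", "562;561", "E. coli", "E. coli", "Bacteria",
                 "99.100", "900", "1000", "5000000", "5", "1", "1", "1",
                 "900", "10", "909", "some title with spaces", "1e-100",
                 "1234.5", "90", "90"), collapse = "\t")
  h <- parse_blast_tab(row)
  expect_equal(h$staxids[[1]], c(562L, 561L))
  expect_equal(h$pident, 99.1)
  expect_equal(h$stitle, "some title with spaces")
  expect_error(parse_blast_tab(paste(rep("x", 21), collapse = "\t")),
               "22 fields")
})

test_that("BLAST multi-hit collapse keeps max bitscore and LCAs ties", {
  tax <- tiny_tax()
  mk <- function(q, tx, bits) {
    paste(c(q, "s", tx, "n", "n", "B", "99", "100", "100", "1000", "0", "0",
            "0", "1", "100", "1", "100", "t", "1e-10", bits, "90", "90"),
          collapse = "\t")
  }
  hits <- parse_blast_tab(c(mk("g1", "11", "500"), mk("g1", "12", "400"),
                            mk("g2", "11", "300"), mk("g2", "12", "300")))
  a <- blast_to_assignments(hits, tax)
  expect_equal(a$taxid[a$seq_id == "g1"], 11L)       # max bitscore wins
  expect_equal(a$taxid[a$seq_id == "g2"], 20L)       # tie -> LCA = genus
})

test_that("PAF rows parse per the column spec, with tp tags and round-trip", {
  p <- parse_paf("g1\t900\t0\t899\t+\trefA\t1000000\t100\t999\t850\t899\t60\ttp:A:P")
  expect_equal(p$query_id, "g1")
  expect_equal(p$matches, 850)
  expect_equal(p$block_len, 899)
  expect_equal(p$q_start, 1L)   # 0-based half-open converted to 1-based
  expect_equal(p$t_start, 101)
  expect_true(p$primary)
  p2 <- parse_paf("g1\t900\t0\t899\t+\trefA\t1000000\t100\t999\t850\t899\t60\ttp:A:S")
  expect_false(p2$primary)
  p3 <- parse_paf("g1\t900\t0\t899\t+\trefA\t1000000\t100\t999\t850\t899\t60")
  expect_true(p3$primary)  # absent tag defaults to primary
  expect_equal(nrow(parse_paf("")), 0L)
  expect_error(parse_paf("a\tb\tc"), ">= 12 columns")

  rt <- parse_paf(write_paf(p))
  expect_equal(rt, p)
})

test_that("GFF genes extract spliced, strand-oriented sequences", {
  contigs <- read_fasta(">c1\nACGTACGTA\n>c2\nACGT\n")
  g <- parse_gff_genes(paste0(
    "##gff-version 3\n",
    "c1\tsim\tCDS\t1\t9\t.\t+\t0\tID=g1\n",
    "c2\tsim\tCDS\t1\t4\t.\t-\t0\tID=g2\n"
  ), contigs)
  expect_equal(g$nt_seq[g$gene_id == "g1"], "ACGTACGTA")
  # revcomp(ACGT) = ACGT (palindrome), checked by hand
  expect_equal(g$nt_seq[g$gene_id == "g2"], "ACGT")
  expect_error(
    parse_gff_genes("c1\tsim\tCDS\t5\t12\t.\t+\t0\tID=g3", contigs),
    "coordinate error"
  )
})

test_that("assembly summaries parse with and without genome_size", {
  txt <- paste0(
    "#comment\n",
    "#assembly_accession\tspecies_taxid\trefseq_category\tassembly_level\tseq_rel_date\tgenome_size\n",
    "GCF_1.1\t562\treference genome\tComplete Genome\t2020/01/01\t4600000\n",
    "GCF_2.1\t563\tna\tContig\t2019/05/05\t5000000\n"
  )
  a <- parse_assembly_summary(txt)
  expect_equal(nrow(a), 2L)
  expect_equal(a$genome_size, c(4600000, 5000000))

  no_size <- parse_assembly_summary(paste0(
    "#assembly_accession\tspecies_taxid\trefseq_category\tassembly_level\tseq_rel_date\n",
    "GCF_1.1\t562\tna\tContig\t2020/01/01\n"
  ))
  expect_true(is.na(no_size$genome_size))

  hdr_only <- parse_assembly_summary(
    "#assembly_accession\tspecies_taxid\trefseq_category\tassembly_level\tseq_rel_date\n")
  expect_equal(nrow(hdr_only), 0L)
  expect_error(parse_assembly_summary("#foo\tbar\nx\ty\n"), "species_taxid")
})

test_that("genome sizes fall back from summary to table to reference FASTA", {
  assemblies <- parse_assembly_summary(paste0(
    "#assembly_accession\tspecies_taxid\trefseq_category\tassembly_level\tseq_rel_date\tgenome_size\n",
    "GCF_1.1\t11\tna\tContig\t2020/01/01\t1000\n"
  ))
  st <- tibble::tibble(species_taxid = 12L, genome_size = 2000)
  fa <- list("13" = ">chr1\nACGTACGT\n>chr2\nAC\n")
  gs <- genome_sizes(c(11L, 12L, 13L, 14L), assemblies, st, fa)
  expect_equal(gs$genome_size, c(1000, 2000, 10, NA))
})
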