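# Seeded synthetic-community fixtures: genomes, contigs, genes, classifier
# outputs, alignments and peptide tables, all in the real dialects, so every
# pipeline stage runs end-to-end with no downloads. All randomness flows
# from one integer seed; each stage draws a derived child stream so stages
# are individually reproducible.

#' Describe a synthetic community
#'
#' The default design mirrors a defined mock community: 12 target species
#' whose community fractions (2-20 percent of contig bases) and genome
#' coverages clear the confident-species thresholds, plus decoy species
#' whose fractions are constructed below the abundance cutoff. Target
#' fractions are realized by construction, not sampled, so threshold tests
#' are sharp.
#'
#' @param n_species Number of target species (default 12).
#' @param n_decoys Number of sub-threshold decoy species (default 40).
#' @param fractions Community fraction of contig bases per target species;
#'   defaults to a spread from 20 down to 2 percent.
#' @param genome_sizes Genome size per target species in bases (defaults
#'   200 kb down to 50 kb, largest fraction paired with largest genome so
#'   non-overlapping fragmentation is feasible).
#' @param decoy_fraction Community fraction per decoy (default 0.002, below
#'   the 0.5 percent synthetic-community abundance cutoff).
#' @param decoy_genome_size Decoy genome size (default 20 kb).
#' @param total_bases Total contig bases in the community (default 5e5).
#' @param frag_meanlog,frag_sdlog Lognormal contig-length parameters
#'   (default meanlog log(1500), sdlog 0.5).
#' @param min_contig_len Minimum contig length (default 500).
#' @param chimera_rate Fraction of contigs whose second half is spliced from
#'   another species' genome (default 0).
#' @param gene_len_range Min/max CDS length in codons including start and
#'   stop (default 100-300 codons).
#' @param gene_density Target fraction of each contig covered by genes
#'   (default 0.5; 0 disables gene planting).
#' @param error_rate,above_species_rate,unclassified_rate,strain_rate
#'   Classifier emulation rates: mislabel to a random decoy, report the
#'   genus instead of the species, report unclassified, or report the
#'   strain below the true species (all default 0; rates must sum to <= 1).
#' @param mp_scale Per-target-species peptide intensity scale factors
#'   (default all 1).
#' @return A `condiga_design` list with a `species` tibble (name, taxid,
#'   genome_size, fraction, is_decoy, mp_scale) and the generation
#'   parameters.
#' @export
community_design <- function(n_species = 12, n_decoys = 40,
                             fractions = NULL, genome_sizes = NULL,
                             decoy_fraction = 0.002,
                             decoy_genome_size = 20000,
                             total_bases = 5e5,
                             frag_meanlog = log(1500), frag_sdlog = 0.5,
                             min_contig_len = 500,
                             chimera_rate = 0,
                             gene_len_range = c(100, 300),
                             gene_density = 0.5,
                             error_rate = 0, above_species_rate = 0,
                             unclassified_rate = 0, strain_rate = 0,
                             mp_scale = NULL) {
  if (is.null(fractions)) {
    base <- c(0.20, 0.15, 0.11, 0.09, 0.07, 0.055, 0.045, 0.04,
              0.035, 0.03, 0.025, 0.02)
    fractions <- if (n_species <= 12L) base[seq_len(n_species)] else
      rep(0.88 / n_species, n_species)
  }
  stopifnot(length(fractions) == n_species)
  if (is.null(genome_sizes)) {
    genome_sizes <- round(seq(200000, 50000, length.out = n_species))
    genome_sizes <- genome_sizes[rank(-fractions, ties.method = "first")]
  }
  stopifnot(length(genome_sizes) == n_species)
  if (any(fractions * total_bases > genome_sizes)) {
    stopf("community fraction exceeds genome size for species %d; shrink total_bases",
      which(fractions * total_bases > genome_sizes)[1])
  }
  total_frac <- sum(fractions) + n_decoys * decoy_fraction
  if (total_frac > 1 + 1e-9) {
    stopf("community fractions sum to %.3f > 1", total_frac)
  }
  stopifnot(error_rate + above_species_rate + unclassified_rate + strain_rate <= 1)
  n <- n_species + n_decoys
  species <- tibble(
    name = c(sprintf("Target species %d", seq_len(n_species)),
             if (n_decoys) sprintf("Decoy species %d", seq_len(n_decoys))),
    taxid = 1000L + seq_len(n),
    genome_size = c(genome_sizes, rep(decoy_genome_size, n_decoys)),
    fraction = c(fractions, rep(decoy_fraction, n_decoys)),
    is_decoy = rep(c(FALSE, TRUE), c(n_species, n_decoys)),
    mp_scale = c(mp_scale %||% rep(1, n_species), rep(1, n_decoys))
  )
  structure(
    list(
      species = species,
      total_bases = total_bases,
      frag_meanlog = frag_meanlog, frag_sdlog = frag_sdlog,
      min_contig_len = min_contig_len,
      chimera_rate = chimera_rate,
      gene_len_range = gene_len_range, gene_density = gene_density,
      error_rate = error_rate, above_species_rate = above_species_rate,
      unclassified_rate = unclassified_rate, strain_rate = strain_rate
    ),
    class = "condiga_design"
  )
}

# Taxonomy scaffold for a design: each species gets its own genus and a
# strain below it; genera are paired into families, families into orders,
# so rank rollups have structure to collapse.
design_taxonomy <- function(design) {
  sp <- design$species
  n <- nrow(sp)
  genus <- 2000L + seq_len(n)
  family <- 3000L + (seq_len(n) - 1L) %/% 2L
  order <- 4000L + (seq_len(n) - 1L) %/% 4L
  strain <- 5000L + seq_len(n)
  nodes <- dplyr::bind_rows(
    tibble(taxid = 1L, parent = 1L, rank = "no rank", name = "root"),
    tibble(taxid = 2L, parent = 1L, rank = "superkingdom", name = "Bacteria"),
    tibble(taxid = unique(order), parent = 2L, rank = "order",
           name = sprintf("Order %d", unique(order) - 4000L)),
    tibble(taxid = unique(family), parent = unique(order)[
             (seq_along(unique(family)) - 1L) %/% 2L + 1L],
           rank = "family", name = sprintf("Family %d", unique(family) - 3000L)),
    tibble(taxid = genus, parent = family, rank = "genus",
           name = sprintf("Genus %d", seq_len(n))),
    tibble(taxid = sp$taxid, parent = genus, rank = "species", name = sp$name),
    tibble(taxid = strain, parent = sp$taxid, rank = "strain",
           name = paste(sp$name, "strain 1"))
  )
  as_taxonomy(nodes)
}

#' Generate reference genomes, taxonomy and assembly metadata
#'
#' Genomes are i.i.d. uniform-base DNA of the designed sizes; the taxonomy
#' places every species under its own genus (genera paired into families,
#' families into orders) with one strain below each species; the assembly
#' summary carries one accession per species with `genome_size` filled.
#'
#' @param design A `condiga_design`.
#' @param seed Integer seed.
#' @return List: `genomes` (tibble `id`/`desc`/`seq`/`length`/
#'   `species_taxid`), `tax` (`condiga_taxonomy`), `assemblies` (tibble in
#'   [parse_assembly_summary()] layout).
#' @export
generate_genomes <- function(design, seed = 1L) {
  sp <- design$species
  genomes <- withr::with_seed(child_seed(seed, 1L), {
    purrr::map_chr(sp$genome_size, random_dna)
  })
  acc <- sprintf("GCF_%06d.1", sp$taxid)
  list(
    genomes = tibble(
      id = acc, desc = paste(acc, sp$name), seq = genomes,
      length = nchar(genomes), species_taxid = sp$taxid
    ),
    tax = design_taxonomy(design),
    assemblies = tibble(
      assembly_accession = acc,
      species_taxid = sp$taxid,
      refseq_category = "representative genome",
      assembly_level = "Complete Genome",
      seq_rel_date = "2022/01/01",
      genome_size = as.numeric(sp$genome_size)
    )
  )
}

# Non-overlapping fragment lengths summing exactly to `target`.
fragment_lengths <- function(target, meanlog, sdlog, min_len) {
  lens <- integer(0)
  remaining <- target
  while (remaining > 0L) {
    l <- max(min_len, round(stats::rlnorm(1, meanlog, sdlog)))
    l <- min(l, remaining)
    if (remaining - l < min_len) l <- remaining
    lens <- c(lens, l)
    remaining <- remaining - l
  }
  lens
}

#' Fragment genomes into assembly-like contigs
#'
#' Cuts non-overlapping fragments from each genome; per-species contig
#' bases equal `round(fraction * total_bases)` exactly (realized by
#' construction; species whose base target falls below `min_contig_len`
#' contribute no contigs). With a nonzero chimera rate, a contig's second half is
#' replaced by a same-length slice of another species' genome while the
#' truth keeps the first (majority) species — the mis-assembly mode that
#' trips contig-label propagation.
#'
#' @param genomes List from [generate_genomes()].
#' @param design The `condiga_design`.
#' @param seed Integer seed.
#' @return List: `contigs` (FASTA-layout tibble) and `truth` (tibble
#'   `contig_id`, `species_taxid`, `chimeric`, `minor_species_taxid`).
#' @export
fragment_to_contigs <- function(genomes, design, seed = 1L) {
  sp <- design$species
  g <- genomes$genomes
  withr::with_seed(child_seed(seed, 2L), {
    pieces <- purrr::pmap(
      list(sp$taxid, sp$fraction, g$seq[match(sp$taxid, g$species_taxid)]),
      function(taxid, fraction, genome) {
        target <- round(fraction * design$total_bases)
        if (target < design$min_contig_len) return(NULL)
        lens <- fragment_lengths(target, design$frag_meanlog,
                                 design$frag_sdlog, design$min_contig_len)
        ends <- cumsum(lens)
        tibble(
          species_taxid = taxid,
          seq = substring(genome, ends - lens + 1L, ends)
        )
      }
    )
    df <- dplyr::bind_rows(pieces)
    df$contig_id <- sprintf("ctg_%05d", seq_len(nrow(df)))
    df$chimeric <- stats::runif(nrow(df)) < design$chimera_rate
    df$minor_species_taxid <- NA_integer_
    for (k in which(df$chimeric)) {
      other <- sample(setdiff(sp$taxid, df$species_taxid[[k]]), 1L)
      og <- g$seq[g$species_taxid == other]
      len <- nchar(df$seq[[k]])
      half <- len %/% 2L
      if (half >= 1L && nchar(og) > half) {
        start <- sample.int(nchar(og) - half, 1L)
        df$seq[[k]] <- paste0(
          substring(df$seq[[k]], 1L, len - half),
          substring(og, start, start + half - 1L)
        )
        df$minor_species_taxid[[k]] <- other
      } else {
        df$chimeric[[k]] <- FALSE
      }
    }
    list(
      contigs = tibble(
        id = df$contig_id, desc = df$contig_id, seq = df$seq,
        length = nchar(df$seq)
      ),
      truth = tibble(
        contig_id = df$contig_id, species_taxid = df$species_taxid,
        chimeric = df$chimeric, minor_species_taxid = df$minor_species_taxid
      )
    )
  })
}

# A random ORF of n_codons total (start + body + stop), table-11 clean.
random_orf <- function(n_codons) {
  codons <- c(t(outer(c("A", "C", "G", "T"),
    c(t(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))),
    paste0)))
  body <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste0("ATG",
    paste(sample(body, n_codons - 2L, replace = TRUE), collapse = ""),
    "TAA")
}

#' Plant ORF-like genes into contigs
#'
#' Writes start-codon..stop-codon open reading frames (no internal table-11
#' stops, both strands) into the contig sequences until roughly
#' `gene_density` of each contig is covered. Every planted gene translates
#' cleanly by construction.
#'
#' @param contigs Contig tibble (from [fragment_to_contigs()]).
#' @param design The `condiga_design`.
#' @param seed Integer seed.
#' @return List: `contigs` (sequences with genes written in), `genes`
#'   (tibble `gene_id`, `contig_id`, `start`, `end`, `strand`, `nt_seq`),
#'   `gff` (GFF3 text).
#' @export
plant_genes <- function(contigs, design, seed = 1L) {
  if (design$gene_density <= 0) {
    return(list(contigs = contigs,
                genes = tibble(gene_id = character(), contig_id = character(),
                               start = integer(), end = integer(),
                               strand = character(), nt_seq = character()),
                gff = "##gff-version 3\n"))
  }
  withr::with_seed(child_seed(seed, 3L), {
    rows <- purrr::map(seq_len(nrow(contigs)), function(ci) {
      clen <- contigs$length[[ci]]
      budget <- design$gene_density * clen
      pos <- 1L
      out <- list()
      used <- 0L
      while (used < budget) {
        gap <- sample(10:100, 1L)
        n_cod <- sample(design$gene_len_range[1]:design$gene_len_range[2], 1L)
        glen <- 3L * n_cod
        start <- pos + gap
        end <- start + glen - 1L
        if (end > clen) break
        out[[length(out) + 1L]] <- tibble(
          contig_id = contigs$id[[ci]], start = start, end = end,
          strand = sample(c("+", "-"), 1L), n_cod = n_cod
        )
        pos <- end + 1L
        used <- used + glen
      }
      dplyr::bind_rows(out)
    })
    genes <- dplyr::bind_rows(rows)
    if (nrow(genes) == 0L) {
      return(list(contigs = contigs, genes = tibble(
        gene_id = character(), contig_id = character(), start = integer(),
        end = integer(), strand = character(), nt_seq = character()
      ), gff = "##gff-version 3\n"))
    }
    genes$gene_id <- sprintf("gene_%05d", seq_len(nrow(genes)))
    genes$nt_seq <- vapply(genes$n_cod, random_orf, "")
    seqs <- contigs$seq
    idx <- match(genes$contig_id, contigs$id)
    for (k in seq_len(nrow(genes))) {
      ins <- if (genes$strand[[k]] == "+") genes$nt_seq[[k]] else
        revcomp(genes$nt_seq[[k]])
      i <- idx[[k]]
      seqs[[i]] <- paste0(
        substring(seqs[[i]], 1L, genes$start[[k]] - 1L), ins,
        substring(seqs[[i]], genes$end[[k]] + 1L)
      )
    }
    contigs$seq <- seqs
    gff <- paste0(
      "##gff-version 3\n",
      paste(sprintf("%s\tcondiga_sim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
        genes$contig_id, genes$start, genes$end, genes$strand, genes$gene_id),
        collapse = "\n"),
      "\n"
    )
    list(contigs = contigs,
         genes = genes[, c("gene_id", "contig_id", "start", "end",
                           "strand", "nt_seq")],
         gff = gff)
  })
}

#' Emulate a taxonomic classifier over known truth
#'
#' Per sequence: with `error_rate` the label is swapped to a random decoy
#' species; with `above_species_rate` the genus is reported; with
#' `strain_rate` the strain below the true species; with
#' `unclassified_rate` the sequence is unclassified; otherwise the true
#' species. Output is serialized in the requested tool's dialect so the
#' format parsers are exercised end-to-end.
#'
#' @param truth Tibble `contig_id` (or `seq_id`) and `species_taxid`.
#' @param tax The community taxonomy.
#' @param design The `condiga_design` (rates and decoy pool).
#' @param style `"kaiju"`, `"kraken2"` or `"blast"`.
#' @param seed Integer seed.
#' @return Character scalar: the classifier output text. BLAST emits no row
#'   for unclassified sequences (use [complete_assignments()] downstream).
#' @export
emulate_classifier <- function(truth, tax, design,
                               style = c("kaiju", "kraken2", "blast"),
                               seed = 1L) {
  style <- match.arg(style)
  ids <- if ("contig_id" %in% names(truth)) truth$contig_id else truth$seq_id
  sp <- truth$species_taxid
  decoys <- design$species$taxid[design$species$is_decoy]
  if (length(decoys) == 0L) decoys <- design$species$taxid
  withr::with_seed(child_seed(seed, 4L + match(style, c("kaiju", "kraken2", "blast"))), {
    u <- stats::runif(length(ids))
    p1 <- design$error_rate
    p2 <- p1 + design$above_species_rate
    p3 <- p2 + design$strain_rate
    p4 <- p3 + design$unclassified_rate
    out <- sp
    err <- u < p1
    out[err] <- sample(decoys, sum(err), replace = TRUE)
    abv <- u >= p1 & u < p2
    out[abv] <- resolve_to_rank(tax, sp[abv], "genus")
    stn <- u >= p2 & u < p3
    out[stn] <- sp[stn] + 4000L  # strain taxid offset in design_taxonomy()
    unc <- u >= p3 & u < p4
    out[unc] <- NA_integer_
    serialize_classifier(ids, out, tax, style)
  })
}

serialize_classifier <- function(ids, taxids, tax, style) {
  cls <- ifelse(is.na(taxids), "U", "C")
  lines <- switch(style,
    kaiju = sprintf("%s\t%s\t%d", cls, ids,
                    ifelse(is.na(taxids), 0L, taxids)),
    kraken2 = sprintf("%s\t%s\t%s\t%d\t0:1", cls, ids,
      ifelse(is.na(taxids), "unclassified (taxid 0)",
        sprintf("%s (taxid %d)", taxon_name(tax, taxids), taxids)),
      1000L),
    blast = {
      keep <- !is.na(taxids)
      sprintf(paste0(
        "%s\tref|%d|\t%d\t%s\t%s\tBacteria\t98.5\t900\t1000\t50000\t10\t1\t1",
        "\t1\t900\t100\t999\t%s genome\t1e-50\t%.1f\t90\t90"),
        ids[keep], taxids[keep], taxids[keep],
        taxon_name(tax, taxids[keep]), taxon_name(tax, taxids[keep]),
        taxon_name(tax, taxids[keep]), 1500 + (seq_len(sum(keep)) %% 7))
    }
  )
  if (length(lines) == 0L) "" else paste0(paste(lines, collapse = "\n"), "\n")
}

#' Fill in unclassified rows for sequences a classifier skipped
#'
#' BLAST tabular output has no row for queries without hits; the annotation
#' pipelines expect one assignment row per sequence.
#'
#' @param assignments Assignment tibble.
#' @param seq_ids All sequence ids that should be present.
#' @param classifier Classifier tag for the filled rows.
#' @return Assignment tibble with one row per id in `seq_ids`.
#' @export
complete_assignments <- function(assignments, seq_ids,
                                 classifier = assignments$classifier[1]) {
  missing <- setdiff(seq_ids, assignments$seq_id)
  dplyr::bind_rows(
    assignments,
    tax_assignment(missing, NA_integer_, classifier %||% "synthetic")
  )
}

#' Emulate minimap2 gene-vs-reference alignments
#'
#' Every gene gets one primary alignment to its true species' reference
#' with high match count; with probability `decoy_hit_rate` an extra
#' primary alignment to a random other reference with strictly fewer
#' matches, plus a secondary copy, exercising the best-alignment and
#' primary-only rules.
#'
#' @param genes Gene tibble (`gene_id`, `nt_seq`).
#' @param gene_truth Tibble `gene_id` / `species_taxid`.
#' @param references Assembly tibble (`assembly_accession`,
#'   `species_taxid`, `genome_size`).
#' @param decoy_hit_rate Probability of an extra weaker hit (default 0.3).
#' @param seed Integer seed.
#' @return PAF text (see [parse_paf()]).
#' @export
emulate_paf <- function(genes, gene_truth, references, decoy_hit_rate = 0.3,
                        seed = 1L) {
  if (nrow(genes) == 0L) return("")
  withr::with_seed(child_seed(seed, 8L), {
    sp <- gene_truth$species_taxid[match(genes$gene_id, gene_truth$gene_id)]
    len <- nchar(genes$nt_seq)
    ref_i <- match(sp, references$species_taxid)
    acc <- references$assembly_accession[ref_i]
    glen <- references$genome_size[ref_i]
    t_start <- floor(stats::runif(nrow(genes)) * pmax(glen - len, 1)) + 1
    matches <- pmax(1, round(len * stats::runif(nrow(genes), 0.92, 0.99)))
    primary <- tibble(
      query_id = genes$gene_id, query_len = len,
      q_start = 1L, q_end = len, strand = "+",
      target_id = acc, target_len = as.numeric(glen),
      t_start = t_start, t_end = t_start + len - 1,
      matches = matches, block_len = as.numeric(len),
      mapq = 60L, primary = TRUE
    )
    extra <- stats::runif(nrow(genes)) < decoy_hit_rate &
      vapply(sp, function(s) any(references$species_taxid != s), TRUE)
    decoy <- primary[extra, ]
    if (nrow(decoy)) {
      other <- vapply(sp[extra], function(s) {
        cand <- which(references$species_taxid != s)
        if (length(cand) == 1L) cand else sample(cand, 1L)
      }, integer(1))
      decoy$target_id <- references$assembly_accession[other]
      decoy$target_len <- as.numeric(references$genome_size[other])
      decoy$matches <- pmax(1, round(decoy$matches *
        stats::runif(nrow(decoy), 0.5, 0.9)))
      sec <- decoy
      sec$primary <- FALSE
      decoy <- dplyr::bind_rows(decoy, sec)
    }
    write_paf(dplyr::bind_rows(primary, decoy))
  })
}

#' Emulate quantified tryptic peptides
#'
#' Cuts each gene's translated protein after K/R residues, drops fragments
#' shorter than 6 residues, and assigns lognormal intensities scaled by the
#' species' `mp_scale` design factor. A peptide's species set is the set of
#' species whose proteins contain it (`shared_fraction` additionally tags
#' that share of peptides with a second random species).
#'
#' @param genes Gene tibble (`gene_id`, `nt_seq`).
#' @param annotation Annotation tibble giving each gene's species (use the
#'   truth map for design-faithful abundances).
#' @param design The `condiga_design`.
#' @param shared_fraction Fraction of peptides marked as shared (default 0).
#' @param seed Integer seed.
#' @return Peptide tibble (`peptide`, `intensity`, `species` list-column).
#' @export
emulate_peptides <- function(genes, annotation, design, shared_fraction = 0,
                             seed = 1L) {
  empty <- tibble(peptide = character(), intensity = numeric(),
                  species = list())
  if (nrow(genes) == 0L) return(empty)
  withr::with_seed(child_seed(seed, 9L), {
    sp <- annotation$species_taxid[match(genes$gene_id, annotation$gene_id)]
    aa <- translate_cds(genes$nt_seq)
    pep <- stringr::str_extract_all(aa, "[^KR]*[KR]|[^KR]+$")
    df <- tibble(
      peptide = unlist(pep),
      species_taxid = rep(sp, lengths(pep))
    ) %>%
      dplyr::filter(nchar(.data$peptide) >= 6L, !is.na(.data$species_taxid)) %>%
      dplyr::distinct(.data$peptide, .data$species_taxid)
    if (nrow(df) == 0L) return(empty)
    # a peptide seen in several species' proteins is naturally shared
    by_pep <- df %>%
      dplyr::group_by(.data$peptide) %>%
      dplyr::summarise(species = list(sort(unique(.data$species_taxid))),
                       .groups = "drop")
    scale <- design$species$mp_scale[
      match(purrr::map_int(by_pep$species, 1L), design$species$taxid)
    ]
    by_pep$intensity <- stats::rlnorm(nrow(by_pep), log(1e6), 0.8) *
      dplyr::coalesce(scale, 1)
    extra <- stats::runif(nrow(by_pep)) < shared_fraction
    by_pep$species[extra] <- purrr::map(by_pep$species[extra], function(s) {
      sort(unique(c(s, sample(design$species$taxid, 1L))))
    })
    by_pep[, c("peptide", "intensity", "species")]
  })
}

#' Write a peptide table as TSV
#'
#' @param peptides Tibble from [emulate_peptides()] / [read_peptides()].
#' @param path Optional path; text returned when `NULL`.
#' @export
write_peptides <- function(peptides, path = NULL) {
  txt <- paste0(
    "peptide\tintensity\tspecies\n",
    paste(sprintf("%s\t%g\t%s", peptides$peptide, peptides$intensity,
      purrr::map_chr(peptides$species, paste, collapse = ";")),
      collapse = "\n"),
    "\n"
  )
  if (nrow(peptides) == 0L) txt <- "peptide\tintensity\tspecies\n"
  if (is.null(path)) return(txt)
  readr::write_file(txt, path)
  invisible(path)
}

#' Generate a complete synthetic-community fixture set
#'
#' Runs every generator in sequence and (optionally) writes all files in
#' their real dialects: contig FASTA, gene GFF and FASTA, taxonomy TSV,
#' assembly summary, kaiju/kraken2/blast classifier outputs, gene-vs-
#' reference PAF, peptide TSV, and the truth tables.
#'
#' @param design A `condiga_design`.
#' @param seed Integer seed driving all stages.
#' @param dir Optional output directory; created if missing.
#' @param shared_peptide_fraction Passed to [emulate_peptides()].
#' @return List of all in-memory fixtures (`design`, `tax`, `genomes`,
#'   `assemblies`, `contigs`, `contig_truth`, `genes`, `gene_truth`, `gff`,
#'   `classifier_text` per style, `paf`, `peptides`) plus `files` (named
#'   paths) when `dir` is given.
#' @export
simulate_community <- function(design = community_design(), seed = 1L,
                               dir = NULL, shared_peptide_fraction = 0) {
  gen <- generate_genomes(design, seed)
  frag <- fragment_to_contigs(gen, design, seed)
  pg <- plant_genes(frag$contigs, design, seed)
  gene_truth <- tibble(
    gene_id = pg$genes$gene_id,
    species_taxid = frag$truth$species_taxid[
      match(pg$genes$contig_id, frag$truth$contig_id)
    ]
  )
  classifier_text <- purrr::map(
    stats::setNames(nm = c("kaiju", "kraken2", "blast")),
    ~ emulate_classifier(frag$truth, gen$tax, design, style = .x, seed = seed)
  )
  paf <- emulate_paf(pg$genes, gene_truth, gen$assemblies, seed = seed)
  peptides <- emulate_peptides(pg$genes, gene_truth, design,
                               shared_fraction = shared_peptide_fraction,
                               seed = seed)
  out <- list(
    design = design, tax = gen$tax, genomes = gen$genomes,
    assemblies = gen$assemblies,
    contigs = pg$contigs, contig_truth = frag$truth,
    genes = pg$genes, gene_truth = gene_truth, gff = pg$gff,
    classifier_text = classifier_text, paf = paf, peptides = peptides
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    p <- function(f) file.path(dir, f)
    files <- c(
      contigs = p("contigs.fna"), genes_gff = p("genes.gff"),
      genes_fna = p("genes.fna"), taxonomy = p("taxonomy.tsv"),
      assembly_summary = p("assembly_summary.txt"),
      kaiju = p("kaiju.out"), kraken2 = p("kraken2.out"),
      blast = p("blast22.tsv"), paf = p("genes_vs_refs.paf"),
      peptides = p("peptides.tsv"),
      contig_truth = p("truth_contigs.tsv"), gene_truth = p("truth_genes.tsv")
    )
    write_fasta(out$contigs, files[["contigs"]])
    readr::write_file(out$gff, files[["genes_gff"]])
    write_fasta(tibble(id = out$genes$gene_id, desc = out$genes$gene_id,
                       seq = out$genes$nt_seq), files[["genes_fna"]])
    readr::write_file(taxonomy_tsv(out$tax), files[["taxonomy"]])
    readr::write_file(assembly_summary_text(out$assemblies),
                      files[["assembly_summary"]])
    readr::write_file(out$classifier_text$kaiju, files[["kaiju"]])
    readr::write_file(out$classifier_text$kraken2, files[["kraken2"]])
    readr::write_file(out$classifier_text$blast, files[["blast"]])
    readr::write_file(out$paf, files[["paf"]])
    write_peptides(out$peptides, files[["peptides"]])
    readr::write_tsv(out$contig_truth, files[["contig_truth"]])
    readr::write_tsv(gene_truth, files[["gene_truth"]])
    out$files <- files
  }
  out
}

taxonomy_tsv <- function(tax) {
  paste0(paste(sprintf("%d\t%d\t%s\t%s", tax$nodes$taxid, tax$nodes$parent,
    tax$nodes$rank, tax$nodes$name), collapse = "\n"), "\n")
}

assembly_summary_text <- function(assemblies) {
  paste0(
    "#assembly_accession\tspecies_taxid\trefseq_category\tassembly_level\tseq_rel_date\tgenome_size\n",
    paste(sprintf("%s\t%d\t%s\t%s\t%s\t%.0f",
      assemblies$assembly_accession, assemblies$species_taxid,
      assemblies$refseq_category, assemblies$assembly_level,
      assemblies$seq_rel_date, assemblies$genome_size), collapse = "\n"),
    "\n"
  )
}
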