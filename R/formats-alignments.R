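# PAF alignments, GFF gene models, NCBI assembly summaries, genome sizes.

#' Parse minimap2 PAF alignments
#'
#' Reads the 12 mandatory PAF columns plus the `tp:A:` tag (primary vs
#' secondary; primary when the tag is absent). PAF's 0-based half-open
#' coordinates are converted to 1-based inclusive at this boundary; matches
#' is PAF column 10 and block length column 11.
#'
#' @param source Path, string, or lines.
#' @return Tibble: `query_id`, `query_len`, `q_start`, `q_end`, `strand`,
#'   `target_id`, `target_len`, `t_start`, `t_end`, `matches`, `block_len`,
#'   `mapq`, `primary`.
#' @export
parse_paf <- function(source) {
  lines <- read_lines_any(source)
  lines <- lines[nzchar(lines)]
  empty <- tibble(
    query_id = character(), query_len = integer(),
    q_start = integer(), q_end = integer(), strand = character(),
    target_id = character(), target_len = numeric(),
    t_start = numeric(), t_end = numeric(),
    matches = numeric(), block_len = numeric(), mapq = integer(),
    primary = logical()
  )
  if (length(lines) == 0L) return(empty)
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 12L)) {
    stopf("PAF parse error at line %d: expected >= 12 columns, got %d",
      which(nf < 12L)[1], nf[which(nf < 12L)[1]])
  }
  col <- function(i) vapply(f, `[[`, "", i)
  tp <- vapply(f, function(x) {
    tag <- grep("^tp:A:", x[-(1:12)], value = TRUE)
    if (length(tag)) substring(tag[[1]], 6L) else "P"
  }, "")
  tibble(
    query_id = col(1), query_len = as.integer(col(2)),
    q_start = as.integer(col(3)) + 1L, q_end = as.integer(col(4)),
    strand = col(5),
    target_id = col(6), target_len = as.numeric(col(7)),
    t_start = as.numeric(col(8)) + 1, t_end = as.numeric(col(9)),
    matches = as.numeric(col(10)), block_len = as.numeric(col(11)),
    mapq = as.integer(col(12)),
    primary = tp != "S"
  )
}

#' Serialize alignments back to PAF text
#'
#' Inverse of [parse_paf()] for fixtures and round-trip tests.
#'
#' @param aln Tibble in [parse_paf()] layout.
#' @param path Optional path; text returned when `NULL`.
#' @export
write_paf <- function(aln, path = NULL) {
  rows <- sprintf(
    "%s\t%d\t%d\t%d\t%s\t%s\t%.0f\t%.0f\t%.0f\t%.0f\t%.0f\t%d\ttp:A:%s",
    aln$query_id, aln$query_len, aln$q_start - 1L, aln$q_end, aln$strand,
    aln$target_id, aln$target_len, aln$t_start - 1, aln$t_end,
    aln$matches, aln$block_len, aln$mapq,
    ifelse(aln$primary, "P", "S")
  )
  txt <- if (nrow(aln)) paste0(paste(rows, collapse = "\n"), "\n") else ""
  if (is.null(path)) return(txt)
  readr::write_file(txt, path)
  invisible(path)
}

#' Parse gene models from GFF and extract their sequences
#'
#' Accepts MetaGeneMark-style GFF (CDS/gene features, 1-based inclusive
#' coordinates). The gene id is taken from an `ID=` or `gene_id` attribute,
#' falling back to `gene_<n>` in file order. Minus-strand genes are
#' reverse-complemented so `nt_seq` always starts at the start codon.
#'
#' @param source Path, string, or lines of GFF.
#' @param contigs Contig tibble from [read_fasta()].
#' @return Tibble: `gene_id`, `contig_id`, `start`, `end`, `strand`, `nt_seq`.
#' @export
parse_gff_genes <- function(source, contigs) {
  lines <- read_lines_any(source)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  empty <- tibble(
    gene_id = character(), contig_id = character(),
    start = integer(), end = integer(), strand = character(),
    nt_seq = character()
  )
  if (length(lines) == 0L) return(empty)
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 8L)) {
    stopf("GFF parse error at line %d: expected >= 8 columns", which(nf < 8L)[1])
  }
  type <- vapply(f, `[[`, "", 3L)
  keep <- type %in% c("CDS", "gene")
  f <- f[keep]
  if (length(f) == 0L) return(empty)
  attrs <- vapply(f, function(x) if (length(x) >= 9L) x[[9]] else "", "")
  id <- stringr::str_match(attrs, "(?:^|;)\\s*(?:ID|gene_id)[=\\s]\"?([^;\"]+)\"?")[, 2]
  id <- ifelse(is.na(id), paste0("gene_", seq_along(f)), trimws(id))
  g <- tibble(
    gene_id = id,
    contig_id = vapply(f, `[[`, "", 1L),
    start = as.integer(vapply(f, `[[`, "", 4L)),
    end = as.integer(vapply(f, `[[`, "", 5L)),
    strand = vapply(f, `[[`, "", 7L)
  )
  g$nt_seq <- extract_gene_seq(g, contigs)
  g
}

extract_gene_seq <- function(genes, contigs) {
  idx <- match(genes$contig_id, contigs$id)
  if (anyNA(idx)) {
    stopf("gene %s references unknown contig %s",
      genes$gene_id[is.na(idx)][1], genes$contig_id[is.na(idx)][1])
  }
  clen <- contigs$length[idx]
  bad <- genes$start < 1L | genes$end > clen | genes$start > genes$end
  if (any(bad)) {
    stopf("coordinate error for gene %s: %d..%d outside contig %s (length %d)",
      genes$gene_id[bad][1], genes$start[bad][1], genes$end[bad][1],
      genes$contig_id[bad][1], clen[bad][1])
  }
  s <- substring(contigs$seq[idx], genes$start, genes$end)
  neg <- genes$strand == "-"
  if (any(neg)) s[neg] <- revcomp(s[neg])
  s
}

#' Parse an NCBI assembly_summary.txt
#'
#' Header lines start with `#`; the last header line names the columns.
#' Returns one row per assembly with the fields the reference-selection
#' logic needs; `genome_size` is `NA` when the file predates that column.
#'
#' @param source Path, string, or lines.
#' @return Tibble: `assembly_accession`, `species_taxid`, `refseq_category`,
#'   `assembly_level`, `seq_rel_date`, `genome_size`.
#' @export
parse_assembly_summary <- function(source) {
  lines <- read_lines_any(source)
  lines <- lines[nzchar(lines)]
  hdr_idx <- which(startsWith(lines, "#"))
  data_lines <- lines[setdiff(seq_along(lines), hdr_idx)]
  if (length(hdr_idx) == 0L) stopf("assembly_summary: missing '#' header line")
  hdr <- sub("^#\\s*", "", lines[max(hdr_idx)])
  cols <- strsplit(hdr, "\t", fixed = TRUE)[[1]]
  if (!"species_taxid" %in% cols) {
    stopf("assembly_summary: required column 'species_taxid' not found")
  }
  empty <- tibble(
    assembly_accession = character(), species_taxid = integer(),
    refseq_category = character(), assembly_level = character(),
    seq_rel_date = character(), genome_size = numeric()
  )
  if (length(data_lines) == 0L) return(empty)
  f <- strsplit(data_lines, "\t", fixed = TRUE)
  get <- function(name, default = NA_character_) {
    i <- match(name, cols)
    if (is.na(i)) return(rep(default, length(f)))
    vapply(f, function(x) if (length(x) >= i) x[[i]] else default, "")
  }
  tibble(
    assembly_accession = get("assembly_accession"),
    species_taxid = as.integer(get("species_taxid")),
    refseq_category = dplyr::coalesce(get("refseq_category"), "na"),
    assembly_level = get("assembly_level"),
    seq_rel_date = get("seq_rel_date"),
    genome_size = suppressWarnings(as.numeric(get("genome_size")))
  )
}

#' Resolve per-species genome sizes
#'
#' Tries, in order: the `genome_size` column of the assembly summary; an
#' explicit `species_taxid` / `genome_size` table; the total length of a
#' reference FASTA per species. Species resolvable by none of the sources
#' get `NA` (they can never be selected as confident).
#'
#' @param species_taxids Integer vector of species to resolve.
#' @param assemblies Optional tibble from [parse_assembly_summary()].
#' @param size_table Optional tibble with `species_taxid`, `genome_size`.
#' @param reference_fastas Optional named list `species_taxid -> FASTA source`.
#' @return Tibble: `species_taxid`, `genome_size`.
#' @export
genome_sizes <- function(species_taxids, assemblies = NULL, size_table = NULL,
                         reference_fastas = NULL) {
  out <- tibble(species_taxid = as.integer(unique(species_taxids)),
                genome_size = NA_real_)
  if (!is.null(assemblies) && "genome_size" %in% names(assemblies)) {
    a <- assemblies %>%
      dplyr::filter(!is.na(.data$genome_size)) %>%
      dplyr::distinct(.data$species_taxid, .keep_all = TRUE)
    i <- match(out$species_taxid, a$species_taxid)
    out$genome_size <- a$genome_size[i]
  }
  if (!is.null(size_table)) {
    i <- match(out$species_taxid, as.integer(size_table$species_taxid))
    fill <- is.na(out$genome_size) & !is.na(i)
    out$genome_size[fill] <- as.numeric(size_table$genome_size)[i[fill]]
  }
  if (!is.null(reference_fastas)) {
    for (k in names(reference_fastas)) {
      j <- which(out$species_taxid == as.integer(k) & is.na(out$genome_size))
      if (length(j)) {
        out$genome_size[j] <- sum(read_fasta(reference_fastas[[k]])$length)
      }
    }
  }
  out
}
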