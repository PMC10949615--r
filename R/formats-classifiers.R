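# Readers for per-sequence taxonomic classifier outputs. All of them return
# the package's common assignment currency: one row per sequence with columns
# seq_id, taxid (NA = unclassified), classifier, score.

tax_assignment <- function(seq_id, taxid, classifier, score = NA_real_) {
  tibble(
    seq_id = as.character(seq_id),
    taxid = as.integer(taxid),
    classifier = classifier,
    score = as.numeric(score)
  )
}

#' Parse Kaiju classified output
#'
#' Kaiju's 3+-column format: status (`C`/`U`), sequence id, taxid. `U` rows
#' yield `NA` taxids.
#'
#' @param source Path, string, or lines.
#' @return Assignment tibble (`seq_id`, `taxid`, `classifier`, `score`).
#' @export
parse_kaiju <- function(source) {
  lines <- read_lines_any(source)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(tax_assignment(character(), integer(), character()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 3L)) {
    stopf("kaiju parse error at line %d: expected >= 3 columns", which(nf < 3L)[1])
  }
  status <- vapply(f, `[[`, "", 1L)
  id <- vapply(f, `[[`, "", 2L)
  tx_raw <- vapply(f, `[[`, "", 3L)
  tx <- suppressWarnings(as.integer(tx_raw))
  bad <- status == "C" & is.na(tx)
  if (any(bad)) {
    stopf("kaiju parse error at line %d: non-integer taxid '%s'",
      which(bad)[1], tx_raw[which(bad)[1]])
  }
  tx[status == "U"] <- NA_integer_
  tax_assignment(id, tx, "kaiju")
}

#' Parse Kraken2 standard (per-read/contig) output
#'
#' 5-column format; with `--use-names` column 3 is `"Name (taxid N)"`,
#' otherwise a bare integer. `U` rows yield `NA`.
#'
#' @param source Path, string, or lines.
#' @return Assignment tibble.
#' @export
parse_kraken2_output <- function(source) {
  lines <- read_lines_any(source)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(tax_assignment(character(), integer(), character()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 3L)) {
    stopf("kraken2 parse error at line %d: expected >= 3 columns", which(nf < 3L)[1])
  }
  status <- vapply(f, `[[`, "", 1L)
  id <- vapply(f, `[[`, "", 2L)
  col3 <- vapply(f, `[[`, "", 3L)
  m <- stringr::str_match(col3, "\\(taxid (\\d+)\\)\\s*$")[, 2]
  tx <- suppressWarnings(ifelse(is.na(m), as.integer(col3), as.integer(m)))
  bad <- status == "C" & is.na(tx)
  if (any(bad)) {
    stopf("kraken2 parse error at line %d: cannot extract taxid from '%s'",
      which(bad)[1], col3[which(bad)[1]])
  }
  tx[status == "U"] <- NA_integer_
  tax_assignment(id, tx, "kraken2")
}

#' Parse a Kraken2 report file
#'
#' Read-only convenience: the annotation pipelines work from per-sequence
#' calls, not from the report.
#'
#' @param source Path, string, or lines.
#' @return Tibble: `pct`, `clade_reads`, `direct_reads`, `rank_code`,
#'   `taxid`, `name`.
#' @export
parse_kraken2_report <- function(source) {
  lines <- read_lines_any(source)
  lines <- lines[nzchar(lines)]
  df <- readr::read_tsv(I(lines),
    col_names = c("pct", "clade_reads", "direct_reads", "rank_code",
                  "taxid", "name"),
    col_types = "diicic", progress = FALSE
  )
  df$name <- trimws(df$name)
  df
}

BLAST22_COLS <- c(
  "qseqid", "sseqid", "staxids", "sscinames", "scomnames", "sskingdoms",
  "pident", "length", "qlen", "slen", "mismatch", "gapopen", "gaps",
  "qstart", "qend", "sstart", "send", "stitle", "evalue", "bitscore",
  "qcovs", "qcovhsp"
)

#' Parse 22-field tabular BLAST output
#'
#' The extended `-outfmt 6` dialect with taxonomy columns
#' (`qseqid sseqid staxids sscinames scomnames sskingdoms pident length qlen
#' slen mismatch gapopen gaps qstart qend sstart send stitle evalue bitscore
#' qcovs qcovhsp`). `staxids` may hold several `;`-separated ids and is
#' returned as a list-column of integer vectors.
#'
#' @param source Path, string, or lines.
#' @return Tibble with one row per hit and the 22 named columns.
#' @export
parse_blast_tab <- function(source) {
  lines <- read_lines_any(source)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- tibble(qseqid = character())
    return(out)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf != 22L)) {
    stopf("blast parse error at row %d: expected 22 fields, got %d",
      which(nf != 22L)[1], nf[which(nf != 22L)[1]])
  }
  m <- matrix(unlist(f), ncol = 22L, byrow = TRUE)
  colnames(m) <- BLAST22_COLS
  df <- as_tibble(m)
  num_cols <- c("pident", "qlen", "slen", "length", "mismatch", "gapopen",
                "gaps", "qstart", "qend", "sstart", "send", "evalue",
                "bitscore", "qcovs", "qcovhsp")
  df <- dplyr::mutate(df, dplyr::across(dplyr::all_of(num_cols), as.numeric))
  df$staxids <- purrr::map(strsplit(df$staxids, ";", fixed = TRUE),
                           ~ as.integer(.x))
  df
}

#' Collapse BLAST hits to one assignment per query
#'
#' With multiple HSP rows per query, the row with maximal bitscore wins;
#' bitscore ties are collapsed to the lowest common ancestor of all tied
#' taxids (multi-valued `staxids` are treated the same way).
#'
#' @param hits Tibble from [parse_blast_tab()].
#' @param tax A `condiga_taxonomy` (for the LCA of tied hits).
#' @return Assignment tibble (`classifier = "blast"`, `score` = bitscore).
#' @export
blast_to_assignments <- function(hits, tax) {
  if (nrow(hits) == 0L) return(tax_assignment(character(), integer(), character()))
  hits %>%
    dplyr::group_by(.data$qseqid) %>%
    dplyr::filter(.data$bitscore == max(.data$bitscore)) %>%
    dplyr::summarise(
      taxid = {
        ids <- remap_taxids(tax, unique(unlist(.data$staxids)))
        if (length(ids) == 1L) ids else lca(tax, ids)
      },
      score = .data$bitscore[[1]],
      .groups = "drop"
    ) %>%
    dplyr::transmute(
      seq_id = .data$qseqid,
      taxid = as.integer(.data$taxid),
      classifier = "blast",
      score = .data$score
    )
}
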