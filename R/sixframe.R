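# Naive six-frame translation of contigs and the longest-alignment
# annotation rule used for six-frame databases.

FRAMES <- c("+1", "+2", "+3", "-1", "-2", "-3")

translate_frame <- function(seq, offset) {
  n <- nchar(seq)
  len <- (n - offset) %/% 3L
  if (any(keep <- len > 0L)) {
    sub <- substring(seq, offset + 1L, offset + 3L * len)
    out <- rep("", length(seq))
    out[keep] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(sub[keep]),
      if.fuzzy.codon = "solve", no.init.codon = TRUE
    ))
    out
  } else {
    rep("", length(seq))
  }
}

#' Naive six-frame translation
#'
#' Translates frames +1..+3 of each sequence and +1..+3 of its reverse
#' complement (reported as -1..-3) under the standard code, keeping stop
#' codons as `*`. Codons containing `N` translate to `X`. The amino-acid
#' length of each frame is `floor((n - offset) / 3)`.
#'
#' @param contigs Tibble with `id` and `seq` (or a bare character vector of
#'   DNA sequences).
#' @return Tibble: `contig_id`, `frame` (`"+1"`..`"-3"`), `aa`.
#' @export
six_frame_translate <- function(contigs) {
  if (is.character(contigs)) {
    contigs <- tibble(
      id = names(contigs) %||% paste0("seq", seq_along(contigs)),
      seq = unname(contigs)
    )
  }
  if (nrow(contigs) == 0L) {
    return(tibble(contig_id = character(), frame = character(), aa = character()))
  }
  fwd <- toupper(contigs$seq)
  rev <- revcomp(fwd)
  res <- purrr::map2(rep(c(TRUE, FALSE), each = 3L), rep(0:2, 2L),
    function(is_fwd, off) translate_frame(if (is_fwd) fwd else rev, off))
  tibble(
    contig_id = rep(contigs$id, times = 6L),
    frame = rep(FRAMES, each = nrow(contigs)),
    aa = unlist(res, use.names = FALSE)
  ) %>%
    dplyr::arrange(match(.data$contig_id, contigs$id), match(.data$frame, FRAMES))
}

#' Split frame translations into stop-free fragments
#'
#' For database building the full-frame strings can be cut at stop codons;
#' fragments shorter than `min_len` residues are dropped.
#'
#' @param frames Tibble from [six_frame_translate()].
#' @param min_len Minimum fragment length in residues (default 20).
#' @return Tibble: `contig_id`, `frame`, `fragment` (1-based index within the
#'   frame), `aa`.
#' @export
frame_fragments <- function(frames, min_len = 20L) {
  frames %>%
    dplyr::mutate(parts = strsplit(.data$aa, "*", fixed = TRUE)) %>%
    dplyr::select(-"aa") %>%
    tidyr::unnest_longer("parts", values_to = "aa", indices_to = "fragment") %>%
    dplyr::filter(nchar(.data$aa) >= min_len) %>%
    dplyr::select("contig_id", "frame", "fragment", "aa")
}

#' Write six-frame translations as FASTA
#'
#' Headers follow `<contig>|frame=<f>` (plus `|frag=<i>` in fragment mode).
#'
#' @param frames Tibble from [six_frame_translate()] or [frame_fragments()].
#' @param path Optional path; text returned when `NULL`.
#' @export
write_sixframe_fasta <- function(frames, path = NULL) {
  hdr <- paste0(frames$contig_id, "|frame=", frames$frame)
  if ("fragment" %in% names(frames)) {
    hdr <- paste0(hdr, "|frag=", frames$fragment)
  }
  write_fasta(tibble(id = hdr, desc = hdr, seq = frames$aa), path)
}

#' Read an MMseqs2 createtsv-style alignment table
#'
#' Expects tab-separated columns `query_id`, `species_taxid`, `aln_len`,
#' `query_len`, `identity` (identity as a fraction in \[0,1\]).
#'
#' @param source Path, string, or lines (a header line is detected and
#'   skipped).
#' @return Tibble of hits for [meta6ft_annotate()].
#' @export
read_sixframe_hits <- function(source) {
  lines <- read_lines_any(source)
  lines <- lines[nzchar(lines)]
  if (length(lines) && grepl("^query", lines[[1]])) lines <- lines[-1]
  readr::read_tsv(I(lines),
    col_names = c("query_id", "species_taxid", "aln_len", "query_len",
                  "identity"),
    col_types = "ciiid", progress = FALSE
  )
}

#' Annotate six-frame queries by longest qualifying alignment
#'
#' Hits must have over 10 percent sequence identity and over 10 percent
#' alignment fraction (alignment length over query length; both strictly
#' greater). Among qualifying hits the longest alignment wins; ties go to
#' the lexicographically smallest species taxid. Queries with no qualifying
#' hit are unknown.
#'
#' @param hits Tibble: `query_id`, `species_taxid`, `aln_len`, `query_len`,
#'   `identity` (fraction in \[0,1\]).
#' @param query_ids Optional character vector of all queries (so hitless
#'   queries appear as unknown); defaults to the queries present in `hits`.
#' @param min_identity,min_fraction Strict lower bounds (defaults 0.10).
#' @return Annotation tibble (`method = "meta6ft"`), one row per query.
#' @export
meta6ft_annotate <- function(hits, query_ids = NULL,
                             min_identity = 0.10, min_fraction = 0.10) {
  if (any(hits$aln_len > hits$query_len)) {
    stopf("alignment longer than query for %s",
      hits$query_id[hits$aln_len > hits$query_len][1])
  }
  query_ids <- query_ids %||% unique(hits$query_id)
  best <- hits %>%
    dplyr::filter(.data$identity > min_identity,
                  .data$aln_len / .data$query_len > min_fraction) %>%
    dplyr::arrange(.data$query_id, dplyr::desc(.data$aln_len),
                   as.character(.data$species_taxid)) %>%
    dplyr::distinct(.data$query_id, .keep_all = TRUE)
  i <- match(query_ids, best$query_id)
  annotation_tbl(
    query_ids, best$species_taxid[i], "meta6ft",
    ifelse(is.na(i), NA_character_, paste0("aln_len:", best$aln_len[i]))
  )
}
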