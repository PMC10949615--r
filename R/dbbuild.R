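# Translate annotated genes into the final protein sequence database.

#' Translate coding sequences under the bacterial genetic code
#'
#' Table 11 by default. The initial codon is rendered as `M` when it is a
#' valid table-11 start (ATG/GTG/TTG); the trailing stop codon is dropped;
#' an internal stop is an error naming its codon position. Codons containing
#' ambiguous bases translate to `X`.
#'
#' @param nt Character vector of CDS nucleotide sequences (each length
#'   divisible by 3).
#' @param code NCBI genetic code id (default `"11"`).
#' @return Character vector of protein sequences.
#' @examples
#' translate_cds(c("ATGGCCTAA", "GTGAAATAA"))
#' @export
translate_cds <- function(nt, code = "11") {
  nt <- toupper(nt)
  bad <- nchar(nt) %% 3L != 0L | nchar(nt) == 0L
  if (any(bad)) {
    stopf("CDS length not a positive multiple of 3 (sequence %d, length %d)",
      which(bad)[1], nchar(nt)[bad][1])
  }
  gc <- Biostrings::getGeneticCode(code)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(nt), genetic.code = gc,
    if.fuzzy.codon = "solve", no.init.codon = TRUE
  ))
  starts <- substring(nt, 1L, 3L)
  is_start <- starts %in% c("ATG", "GTG", "TTG")
  aa[is_start] <- paste0("M", substring(aa[is_start], 2L))
  aa <- sub("\\*$", "", aa)
  star <- regexpr("*", aa, fixed = TRUE)
  if (any(star > 0L)) {
    i <- which(star > 0L)[1]
    stopf("internal stop codon in sequence %d at codon %d", i, star[i])
  }
  aa
}

#' Build a protein sequence database from annotated genes
#'
#' One entry per translatable gene. Genes whose CDS fails to translate
#' (internal stop, bad length) or translate to all-`X` are skipped with a
#' warning and counted in the `skipped` attribute — so entries + skipped
#' equals the gene count. The same gene set under different annotation
#' strategies yields the same sequence multiset; only the taxonomic labels
#' differ.
#'
#' @param genes Gene tibble with `gene_id`, `contig_id`, `nt_seq`.
#' @param annotation Annotation tibble covering every gene in `genes`.
#' @param tax Optional taxonomy for species names; unannotated entries are
#'   labeled `"unknown"`.
#' @return Tibble (`condiga_proteindb`): `protein_id`, `aa`, `species_taxid`,
#'   `species_label`, `contig_id`, `strategy`; attribute `skipped` holds the
#'   count of untranslatable genes.
#' @export
build_protein_db <- function(genes, annotation, tax = NULL) {
  i <- match(genes$gene_id, annotation$gene_id)
  if (anyNA(i)) {
    stopf("gene %s missing from the annotation map", genes$gene_id[is.na(i)][1])
  }
  nt <- toupper(genes$nt_seq)
  aa <- rep(NA_character_, nrow(genes))
  valid <- nchar(nt) %% 3L == 0L & nchar(nt) > 0L
  if (any(valid)) {
    gc11 <- Biostrings::getGeneticCode("11")
    tr <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(nt[valid]), genetic.code = gc11,
      if.fuzzy.codon = "solve", no.init.codon = TRUE
    ))
    is_start <- substring(nt[valid], 1L, 3L) %in% c("ATG", "GTG", "TTG")
    tr[is_start] <- paste0("M", substring(tr[is_start], 2L))
    tr <- sub("\\*$", "", tr)
    tr[grepl("*", tr, fixed = TRUE)] <- NA_character_  # internal stop
    aa[valid] <- tr
  }
  ok <- !is.na(aa) & nzchar(aa) & !grepl("^X+$", aa)
  if (any(!ok)) {
    warn(sprintf("%d gene(s) skipped as untranslatable", sum(!ok)))
  }
  sp <- annotation$species_taxid[i]
  label <- if (!is.null(tax)) taxon_name(tax, sp) else as.character(sp)
  label[is.na(sp)] <- "unknown"
  db <- tibble(
    protein_id = genes$gene_id[ok],
    aa = aa[ok],
    species_taxid = sp[ok],
    species_label = label[ok],
    contig_id = genes$contig_id[ok],
    strategy = annotation$method[i][ok]
  )
  attr(db, "skipped") <- sum(!ok)
  class(db) <- c("condiga_proteindb", class(db))
  db
}

#' Write a protein database as FASTA (plus optional TSV sidecar)
#'
#' Headers use a UniProt-like dialect so search engines pick up the
#' taxonomy: `><protein_id> OS=<species label> OX=<taxid> strategy=<tag>`,
#' with `OS=unknown OX=0` for unannotated entries.
#'
#' @param db Tibble from [build_protein_db()].
#' @param path Optional FASTA path; text returned when `NULL`.
#' @param sidecar Optional path for a `protein_id` / `species_label` /
#'   `species_taxid` / `strategy` TSV.
#' @export
write_protein_fasta <- function(db, path = NULL, sidecar = NULL) {
  hdr <- sprintf(
    "%s OS=%s OX=%d strategy=%s",
    db$protein_id, db$species_label,
    ifelse(is.na(db$species_taxid), 0L, db$species_taxid),
    db$strategy
  )
  if (!is.null(sidecar)) {
    readr::write_tsv(
      db[, c("protein_id", "species_label", "species_taxid", "strategy")],
      sidecar
    )
  }
  write_fasta(tibble(id = db$protein_id, desc = hdr, seq = db$aa), path)
}
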