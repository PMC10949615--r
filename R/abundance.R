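# Metagenome vs metaproteome taxon abundance and per-taxon log2 ratios.
#
# MG abundance counts the genes assigned to each species; MP abundance sums
# the quantified intensities of each species' identified peptides. Both are
# normalized to fractions and compared per taxon as log2(MG/MP) after
# rolling species up each requested rank.

#' Metagenomic species abundance from a gene annotation
#'
#' Fraction of species-labeled genes per species (unknown genes excluded).
#'
#' @param annotation Annotation tibble.
#' @return Tibble: `species_taxid`, `fraction` (sums to 1 when any gene is
#'   labeled).
#' @export
mg_abundance <- function(annotation) {
  df <- annotation %>%
    dplyr::filter(!is.na(.data$species_taxid)) %>%
    dplyr::count(.data$species_taxid, name = "n")
  tibble(
    species_taxid = df$species_taxid,
    fraction = if (nrow(df)) df$n / sum(df$n) else numeric(0)
  )
}

#' Read a peptide quantification table
#'
#' Tab-separated `peptide`, `intensity`, `species` columns; `species` holds
#' zero or more `;`-joined species taxids matched by the peptide's protein
#' groups (empty = unknown-only peptide).
#'
#' @param source Path, string, or lines (header line optional).
#' @return Tibble: `peptide`, `intensity`, `species` (list-column of integer
#'   vectors).
#' @export
read_peptides <- function(source) {
  lines <- read_lines_any(source)
  lines <- lines[nzchar(lines)]
  if (length(lines) && grepl("^peptide\t", lines[[1]])) lines <- lines[-1]
  df <- readr::read_tsv(I(lines),
    col_names = c("peptide", "intensity", "species"),
    col_types = "cdc", progress = FALSE
  )
  df$species <- purrr::map(strsplit(dplyr::coalesce(df$species, ""), ";"),
                           ~ as.integer(.x[nzchar(.x)]))
  df
}

#' Metaproteomic species abundance from peptide intensities
#'
#' Species-unique peptides (matching protein groups of exactly one species)
#' contribute their full intensity to that species; peptides shared between
#' species are excluded by default or split equally with
#' `shared = "split"`. Totals are normalized to fractions.
#'
#' @param peptides Tibble from [read_peptides()] (or with the same columns).
#' @param shared `"exclude"` (default) or `"split"`.
#' @return Tibble: `species_taxid`, `fraction`.
#' @export
mp_abundance <- function(peptides, shared = c("exclude", "split")) {
  shared <- match.arg(shared)
  if (any(peptides$intensity < 0)) {
    stopf("negative peptide intensity for %s",
      peptides$peptide[peptides$intensity < 0][1])
  }
  nsp <- lengths(peptides$species)
  keep <- if (shared == "exclude") nsp == 1L else nsp >= 1L
  df <- peptides[keep, ]
  long <- tibble(
    species_taxid = as.integer(unlist(df$species)),
    weight = rep(df$intensity / pmax(lengths(df$species), 1L),
                 lengths(df$species))
  )
  out <- long %>%
    dplyr::group_by(.data$species_taxid) %>%
    dplyr::summarise(total = sum(.data$weight), .groups = "drop")
  tibble(
    species_taxid = out$species_taxid,
    fraction = if (nrow(out) && sum(out$total) > 0) out$total / sum(out$total) else numeric(0)
  )
}

roll_to_rank <- function(ab, tax, rank) {
  up <- resolve_to_rank(tax, ab$species_taxid, rank)
  tibble(taxon_id = up, fraction = ab$fraction) %>%
    dplyr::filter(!is.na(.data$taxon_id)) %>%
    dplyr::group_by(.data$taxon_id) %>%
    dplyr::summarise(fraction = sum(.data$fraction), .groups = "drop") %>%
    dplyr::mutate(fraction = .data$fraction / sum(.data$fraction))
}

#' Per-rank MG/MP abundance ratios
#'
#' Rolls species fractions up each lineage to every requested rank,
#' renormalizes within rank on each side, and reports
#' `log2(rel_mg / rel_mp)` per taxon. Taxa present on only one side get an
#' `NA` ratio (rather than +/-Inf).
#'
#' @param mg,mp Tibbles `species_taxid` / `fraction` from [mg_abundance()] /
#'   [mp_abundance()].
#' @param tax A `condiga_taxonomy` containing every species in `mg`/`mp`.
#' @param ranks Ranks to report (ordered root-most first in the output).
#' @return A `condiga_ratio` tibble: `taxon_id`, `taxon_name`, `rank`,
#'   `rel_mg`, `rel_mp`, `log2_ratio`.
#' @export
rank_rollup_ratio <- function(mg, mp, tax,
                              ranks = c("order", "family", "genus", "species")) {
  missing <- setdiff(c(mg$species_taxid, mp$species_taxid),
                     tax$nodes$taxid)
  if (length(missing)) {
    stopf("species taxid %s absent from taxonomy", missing[[1]])
  }
  ranks <- ranks[order(match(ranks, condiga_ranks))]
  out <- purrr::map_dfr(ranks, function(r) {
    g <- roll_to_rank(mg, tax, r)
    p <- roll_to_rank(mp, tax, r)
    dplyr::full_join(
      dplyr::rename(g, rel_mg = "fraction"),
      dplyr::rename(p, rel_mp = "fraction"),
      by = "taxon_id"
    ) %>%
      dplyr::mutate(
        rank = r,
        log2_ratio = dplyr::if_else(
          !is.na(.data$rel_mg) & !is.na(.data$rel_mp) &
            .data$rel_mg > 0 & .data$rel_mp > 0,
          log2(.data$rel_mg / .data$rel_mp),
          NA_real_
        )
      )
  })
  out$taxon_name <- taxon_name(tax, out$taxon_id)
  out <- out %>%
    dplyr::select("taxon_id", "taxon_name", "rank", "rel_mg", "rel_mp",
                  "log2_ratio") %>%
    dplyr::arrange(match(.data$rank, condiga_ranks), .data$taxon_id)
  class(out) <- c("condiga_ratio", class(out))
  out
}

#' Write the long-format rank/ratio table
#'
#' Suitable for cladogram tools: one row per taxon per rank.
#'
#' @param ratios Tibble from [rank_rollup_ratio()].
#' @param path Output TSV path.
#' @export
write_ratio_tsv <- function(ratios, path) {
  readr::write_tsv(as_tibble(ratios), path)
  invisible(path)
}
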