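# Taxonomy: load NCBI taxdump-style tables (or a plain 4-column TSV), resolve
# taxa to named ranks, compute lineages and lowest common ancestors.

#' Canonical rank order used throughout the package
#'
#' Ordered from root-most to leaf-most. Classifier calls below `species`
#' (e.g. strains) are lifted to species before any abundance accounting;
#' calls above species are treated as unresolved at species level.
#'
#' @export
condiga_ranks <- c(
  "superkingdom", "phylum", "class", "order",
  "family", "genus", "species", "strain"
)

#' Load a taxonomy from taxdump files or a 4-column TSV
#'
#' Accepts either the NCBI taxdump dialect (`nodes.dmp` / `names.dmp`,
#' pipe-tab delimited) or a single 4-column TSV with columns
#' `taxid`, `parent`, `rank`, `name`. When `names_source` is given, names of
#' class `"scientific name"` are preferred.
#'
#' @param nodes_source Path, single string, or character vector of lines:
#'   `nodes.dmp` or the 4-column TSV.
#' @param names_source Optional `names.dmp` source (taxdump dialect only).
#' @param merged_source Optional `merged.dmp` source; old taxids are remapped
#'   at load time via [remap_taxids()].
#' @return A `condiga_taxonomy` object: node table plus fast lookup vectors.
#' @examples
#' tax <- load_taxonomy(c("1\t1\tno rank\troot", "2\t1\tspecies\tSpA"))
#' resolve_to_rank(tax, 2, "species")
#' @export
load_taxonomy <- function(nodes_source, names_source = NULL,
                          merged_source = NULL) {
  lines <- read_lines_any(nodes_source)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stopf("taxonomy source is empty")
  if (grepl("\t\\|", lines[[1]])) {
    nodes <- parse_nodes_dmp(lines)
    if (!is.null(names_source)) {
      nm <- parse_names_dmp(read_lines_any(names_source))
      nodes$name <- unname(nm[as.character(nodes$taxid)])
      nodes$name[is.na(nodes$name)] <- as.character(nodes$taxid[is.na(nodes$name)])
    } else {
      nodes$name <- as.character(nodes$taxid)
    }
  } else {
    df <- readr::read_tsv(I(lines),
      col_names = c("taxid", "parent", "rank", "name"),
      col_types = "iicc", progress = FALSE
    )
    nodes <- df
  }
  tax <- new_taxonomy(nodes)
  if (!is.null(merged_source)) {
    attr(tax, "merged") <- parse_merged_dmp(read_lines_any(merged_source))
  }
  tax
}

parse_nodes_dmp <- function(lines) {
  f <- strsplit(lines, "\t\\|\t?")
  tibble(
    taxid = as.integer(vapply(f, `[[`, "", 1L)),
    parent = as.integer(vapply(f, `[[`, "", 2L)),
    rank = trimws(vapply(f, `[[`, "", 3L)),
    name = NA_character_
  )
}

parse_names_dmp <- function(lines) {
  lines <- lines[nzchar(lines)]
  f <- strsplit(lines, "\t\\|\t?")
  taxid <- vapply(f, `[[`, "", 1L)
  name <- vapply(f, `[[`, "", 2L)
  class <- trimws(gsub("\t\\|.*$", "",
    vapply(f, function(x) if (length(x) >= 4L) x[[4]] else "", "")))
  keep <- class == "scientific name"
  # fall back to first name seen for taxids without a scientific name
  out <- name[keep]
  names(out) <- taxid[keep]
  missing <- setdiff(unique(taxid), names(out))
  if (length(missing)) {
    first <- name[match(missing, taxid)]
    names(first) <- missing
    out <- c(out, first)
  }
  out
}

parse_merged_dmp <- function(lines) {
  lines <- lines[nzchar(lines)]
  f <- strsplit(lines, "\t\\|\t?")
  stats::setNames(
    as.integer(vapply(f, `[[`, "", 2L)),
    vapply(f, `[[`, "", 1L)
  )
}

#' Build a taxonomy from a node table
#'
#' @param nodes Data frame with columns `taxid`, `parent`, `rank`, `name`.
#' @return A `condiga_taxonomy`.
#' @export
as_taxonomy <- function(nodes) new_taxonomy(as_tibble(nodes))

new_taxonomy <- function(nodes) {
  nodes$taxid <- as.integer(nodes$taxid)
  nodes$parent <- as.integer(nodes$parent)
  if (anyDuplicated(nodes$taxid)) {
    stopf("duplicate taxid(s): %s",
      paste(unique(nodes$taxid[duplicated(nodes$taxid)]), collapse = ", "))
  }
  key <- as.character(nodes$taxid)
  parent <- stats::setNames(nodes$parent, key)
  root <- nodes$taxid[nodes$taxid == nodes$parent]
  if (length(root) != 1L) {
    stopf("taxonomy must have exactly one root (taxid == parent); found %d",
      length(root))
  }
  orphan <- !(nodes$parent %in% nodes$taxid)
  if (any(orphan)) {
    stopf("orphan parent id(s): node %s points to missing parent %s",
      nodes$taxid[orphan][1], nodes$parent[orphan][1])
  }
  # cycle check: iteratively mark nodes whose parent chain reaches root
  depth <- stats::setNames(rep(NA_integer_, nrow(nodes)), key)
  depth[as.character(root)] <- 0L
  repeat {
    todo <- is.na(depth)
    if (!any(todo)) break
    pd <- depth[as.character(parent[todo])]
    reach <- !is.na(pd)
    if (!any(reach)) {
      stopf("cycle detected in taxonomy involving taxid %s",
        names(depth)[todo][1])
    }
    depth[names(depth)[todo][reach]] <- pd[reach] + 1L
  }
  structure(
    list(
      nodes = nodes,
      parent = parent,
      rank = stats::setNames(nodes$rank, key),
      name = stats::setNames(nodes$name, key),
      depth = depth,
      root = root
    ),
    class = "condiga_taxonomy"
  )
}

#' @export
print.condiga_taxonomy <- function(x, ...) {
  cat(sprintf(
    "<condiga_taxonomy> %d nodes, root=%d, %d species\n",
    nrow(x$nodes), x$root, sum(x$nodes$rank == "species")
  ))
  invisible(x)
}

#' Remap merged/deleted taxids
#'
#' Applies the `merged.dmp` remap table loaded alongside the taxonomy.
#' Ids found in neither the tree nor the remap table raise an error
#' (classifier databases and taxdumps drift; silent dropping hides that).
#'
#' @param tax A `condiga_taxonomy`.
#' @param taxids Integer vector.
#' @return Integer vector of remapped ids.
#' @export
remap_taxids <- function(tax, taxids) {
  merged <- attr(tax, "merged")
  key <- as.character(taxids)
  known <- key %in% names(tax$parent)
  if (!is.null(merged)) {
    hit <- !known & key %in% names(merged)
    taxids[hit] <- unname(merged[key[hit]])
    known <- known | hit
  }
  if (!all(known | is.na(taxids))) {
    stopf("taxid(s) not in taxonomy or merged table: %s",
      paste(utils::head(taxids[!known & !is.na(taxids)], 5), collapse = ", "))
  }
  as.integer(taxids)
}

#' Full lineage of a taxon
#'
#' @param tax A `condiga_taxonomy`.
#' @param taxid Single taxid present in the tree.
#' @return Integer vector from root down to `taxid` (inclusive).
#' @export
lineage <- function(tax, taxid) {
  key <- as.character(taxid)
  if (!key %in% names(tax$parent)) stopf("unknown taxid: %s", key)
  out <- integer(0)
  cur <- as.integer(taxid)
  repeat {
    out <- c(cur, out)
    if (cur == tax$root) break
    cur <- unname(tax$parent[as.character(cur)])
  }
  out
}

#' Resolve taxa to a named rank
#'
#' Walks each lineage upward (starting at the taxid itself) and returns the
#' first ancestor whose rank equals `rank`; `NA` when the lineage never passes
#' through that rank, i.e. the call sits above it. Strain-level calls are
#' thereby lifted to species; genus-level calls resolve to `NA` at species.
#'
#' @param tax A `condiga_taxonomy`.
#' @param taxids Integer vector of taxids present in the tree (`NA` allowed,
#'   passed through).
#' @param rank Target rank string, e.g. `"species"`.
#' @return Integer vector, same length as `taxids`; `NA` where unresolvable.
#' @export
resolve_to_rank <- function(tax, taxids, rank = "species") {
  uniq <- unique(taxids[!is.na(taxids)])
  res <- vapply(uniq, function(id) {
    key <- as.character(id)
    if (!key %in% names(tax$parent)) stopf("unknown taxid: %s", key)
    cur <- as.integer(id)
    repeat {
      if (unname(tax$rank[as.character(cur)]) == rank) return(cur)
      if (cur == tax$root) return(NA_integer_)
      cur <- unname(tax$parent[as.character(cur)])
    }
  }, integer(1))
  unname(res[match(taxids, uniq)])
}

#' Lowest common ancestor
#'
#' Deepest node ancestral to (or equal to) every input taxid.
#'
#' @param tax A `condiga_taxonomy`.
#' @param taxids Non-empty integer vector of taxids present in the tree.
#' @return Single taxid.
#' @export
lca <- function(tax, taxids) {
  taxids <- unique(taxids[!is.na(taxids)])
  if (length(taxids) == 0L) stopf("lca() needs at least one taxid")
  common <- lineage(tax, taxids[[1]])
  for (id in taxids[-1]) {
    common <- intersect(common, lineage(tax, id))
  }
  common[[length(common)]]
}

#' Name of a taxon
#'
#' @param tax A `condiga_taxonomy`.
#' @param taxids Integer vector.
#' @return Character vector of scientific names (`NA` for `NA` input).
#' @export
taxon_name <- function(tax, taxids) {
  unname(tax$name[as.character(taxids)])
}
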