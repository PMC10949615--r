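# broom-style accessors for the package's result objects.

#' @export
print.condiga_annotation <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<condiga_annotation> %s: %d genes, %d labeled (%.1f%%), %d species\n",
    x$method[1] %||% "?", g$total_genes, g$labeled_genes,
    100 * g$annotation_rate, g$n_species
  ))
  NextMethod()
}

#' Per-species gene counts of an annotation
#'
#' @param x A `condiga_annotation`.
#' @param ... Unused.
#' @return Tibble: `species_taxid`, `n_genes`, `fraction` (of labeled
#'   genes), descending.
#' @export
tidy.condiga_annotation <- function(x, ...) {
  out <- tabulate_annotation(x)$species
  out$fraction <- if (nrow(out)) out$n_genes / sum(out$n_genes) else numeric(0)
  out
}

#' One-row summary of an annotation
#'
#' @param x A `condiga_annotation`.
#' @param ... Unused.
#' @return Tibble: totals, annotation rate, species count.
#' @export
glance.condiga_annotation <- function(x, ...) {
  tabulate_annotation(x)$summary
}

#' One-row summary of a species profile
#'
#' @param x A `condiga_profile`.
#' @param ... Unused.
#' @return Tibble: species counts, selected count, bases profiled, and the
#'   thresholds applied (NA before selection).
#' @export
glance.condiga_profile <- function(x, ...) {
  th <- attr(x, "thresholds") %||%
    c(abundance_min_pct = NA_real_, coverage_min_pct = NA_real_)
  tibble(
    n_species = nrow(x),
    n_selected = sum(x$selected),
    total_assigned_bases = sum(x$assigned_bases),
    abundance_min_pct = unname(th[["abundance_min_pct"]]),
    coverage_min_pct = unname(th[["coverage_min_pct"]])
  )
}
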