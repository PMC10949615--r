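# FASTA reading/writing with line-numbered diagnostics and exact
# description round-trips.

IUPAC_DNA <- "ACGTUNRYSWKMBDHV"

#' Read a FASTA file into a tibble
#'
#' @param source Path, single string, or character vector of lines.
#' @param type `"DNA"` validates residues against the IUPAC nucleotide
#'   alphabet; `"AA"` accepts amino acids (and `*`); `"any"` skips residue
#'   validation.
#' @return Tibble with columns `id` (first token of the header), `desc`
#'   (full header after `>`), `seq` (uppercase), `length`.
#' @examples
#' read_fasta(">a first\nACGT")
#' @export
read_fasta <- function(source, type = c("DNA", "AA", "any")) {
  type <- match.arg(type)
  lines <- read_lines_any(source)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble(id = character(), desc = character(),
                  seq = character(), length = integer()))
  }
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[[1]]) stopf("FASTA parse error at line 1: expected '>' header")
  desc <- trimws(sub("^>", "", lines[is_hdr]))
  if (any(!nzchar(desc))) {
    stopf("FASTA parse error at line %d: empty sequence id",
      which(is_hdr & !nzchar(trimws(sub("^>", "", lines))))[1])
  }
  id <- sub("\\s.*$", "", desc)
  if (anyDuplicated(id)) {
    stopf("duplicate FASTA id: %s", id[duplicated(id)][1])
  }
  seq_lines <- toupper(lines)
  alphabet <- switch(type,
    DNA = IUPAC_DNA,
    AA = "ACDEFGHIKLMNPQRSTVWYXBZJUO*",
    any = NULL
  )
  if (!is.null(alphabet)) {
    pat <- sprintf("^[%s]*$", alphabet)
    bad <- !is_hdr & !grepl(pat, seq_lines)
    if (any(bad)) {
      stopf("FASTA parse error at line %d: invalid residue in '%s'",
        which(bad)[1], lines[which(bad)[1]])
    }
  }
  grp <- cumsum(is_hdr)
  seqs <- vapply(
    split(seq_lines[!is_hdr], factor(grp[!is_hdr], levels = seq_along(id))),
    paste, "", collapse = ""
  )
  tibble(id = id, desc = desc, seq = unname(seqs),
         length = nchar(unname(seqs)))
}

#' Write sequences as FASTA text
#'
#' @param records Tibble with columns `id`/`seq` and optionally `desc`
#'   (written as the full header when present).
#' @param path Optional file path; when `NULL` the FASTA text is returned
#'   as a single string.
#' @param width Line width for sequence wrapping (default 60).
#' @return `path` invisibly, or the FASTA text.
#' @export
write_fasta <- function(records, path = NULL, width = 60L) {
  hdr <- if ("desc" %in% names(records) && !all(is.na(records$desc))) {
    records$desc
  } else {
    records$id
  }
  chunks <- purrr::map2_chr(records$seq, hdr, function(s, h) {
    n <- nchar(s)
    starts <- seq(1L, max(n, 1L), by = width)
    body <- if (n == 0L) "" else
      paste(substring(s, starts, pmin(starts + width - 1L, n)), collapse = "\n")
    paste0(">", h, "\n", body)
  })
  txt <- paste0(paste(chunks, collapse = "\n"), "\n")
  if (nrow(records) == 0L) txt <- ""
  if (is.null(path)) return(txt)
  readr::write_file(txt, path)
  invisible(path)
}
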