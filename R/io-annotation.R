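#' Gene-to-category annotation map
#'
#' Maps genes to sets of category terms (e.g. GO biological processes) and
#' defines the universe of genes eligible for overrepresentation testing.
#'
#' @param gene2term data.frame with columns `gene` and `term`.
#' @param term_names optional named character vector, term id -> readable
#'   name.
#' @param universe optional character vector; defaults to all genes in the
#'   map.  Every annotated gene must belong to the universe.
#' @return an object of class `annotation_map`.
#' @export
annotation_map <- function(gene2term, term_names = NULL, universe = NULL) {
  gene2term <- data.frame(gene = as.character(gene2term$gene),
                          term = as.character(gene2term$term),
                          stringsAsFactors = FALSE)
  if (any(!nzchar(gene2term$term)))
    stop_mssnet("annotation terms must be non-empty strings")
  gene2term <- unique(gene2term)
  if (is.null(universe)) universe <- sort(unique(gene2term$gene))
  else {
    universe <- unique(as.character(universe))
    out <- setdiff(gene2term$gene, universe)
    if (length(out) > 0)
      stop_mssnet("%d annotated gene(s) missing from the universe (e.g. %s)",
                  length(out), out[1])
  }
  structure(list(gene2term = gene2term, term_names = term_names,
                 universe = universe),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("annotation_map: %d gene-term pairs, %d terms, universe %d\n",
              nrow(x$gene2term), length(unique(x$gene2term$term)),
              length(x$universe)))
  invisible(x)
}

#' Genes annotated to a term
#' @param ann an `annotation_map`.
#' @param term term id.
#' @return character vector of gene ids.
#' @export
term_genes <- function(ann, term) {
  ann$gene2term$gene[ann$gene2term$term == term]
}

#' Read a gene-to-category annotation map
#'
#' Two formats: `tsv2col` is `gene<TAB>term` (one pair per line); `gaf` is
#' GAF 2.x, using column 2 (DB object symbol) and column 5 (GO id), skipping
#' rows whose qualifier (column 4) contains `NOT`.
#'
#' @param path file path.
#' @param format `"tsv2col"` or `"gaf"`.
#' @param universe optional path to a one-id-per-line universe file, or a
#'   character vector; defaults to all genes in the map.
#' @return an [annotation_map].
#' @export
read_annotation_map <- function(path, format = c("tsv2col", "gaf"),
                                universe = NULL) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "!") &
                   !startsWith(lines, "#")]
  if (format == "tsv2col") {
    toks <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(toks) < 2))
      stop_mssnet("tsv2col annotation line %d has fewer than 2 columns",
                  which(lengths(toks) < 2)[1])
    df <- data.frame(gene = vapply(toks, `[`, "", 1L),
                     term = vapply(toks, `[`, "", 2L))
  } else {
    toks <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(toks) < 15))
      stop_mssnet("GAF data row %d has fewer than 15 columns",
                  which(lengths(toks) < 15)[1])
    qual <- vapply(toks, `[`, "", 4L)
    keep <- !grepl("(^|\\|)NOT($|\\|)", qual)
    df <- data.frame(gene = vapply(toks, `[`, "", 2L)[keep],
                     term = vapply(toks, `[`, "", 5L)[keep])
  }
  if (is.character(universe) && length(universe) == 1 &&
      file.exists(universe))
    universe <- trimws(readLines(universe))
  annotation_map(df, universe = universe)
}
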