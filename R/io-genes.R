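#' Parse an amino-acid substitution token
#'
#' Tokens follow the `<ref><position><alt>` convention, e.g. `"S55N"`.
#' Reference and alternate residues must be distinct single-letter amino
#' acid codes and the position must be >= 1.
#'
#' @param token character scalar, e.g. `"S55N"`.
#' @return list with `ref`, `pos` (integer) and `alt`.
#' @examples
#' parse_substitution("S55N")
#' @export
parse_substitution <- function(token) {
  m <- regmatches(token, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", token))[[1]]
  if (length(m) != 4)
    stop_mssnet("malformed substitution token '%s'", token)
  ref <- toupper(m[2]); alt <- toupper(m[4]); pos <- as.integer(m[3])
  if (!(ref %in% AA_ALPHABET) || !(alt %in% AA_ALPHABET))
    stop_mssnet("substitution token '%s' uses a non-amino-acid code", token)
  if (ref == alt)
    stop_mssnet("substitution token '%s' has identical ref and alt residues",
                token)
  if (pos < 1) stop_mssnet("substitution token '%s' has position < 1", token)
  list(ref = ref, pos = pos, alt = alt)
}

#' Read a mutated-gene list
#'
#' One gene per line; an optional second tab-separated column carries the
#' amino-acid substitution (e.g. `Rad51D<TAB>S55N`), an optional third a
#' protein accession.  Order is preserved; duplicate (gene, substitution)
#' rows are collapsed with a warning.
#'
#' @param path TSV path.
#' @param aliases optional alias table (see [read_alias_table()]).
#' @return data.frame with columns `gene`, `substitution` (`NA` when the
#'   line carried a bare gene id) and `accession`.
#' @export
read_gene_list <- function(path, aliases = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  gene <- character(0); sub <- character(0); acc <- character(0)
  for (ln in lines) {
    tok <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    tok <- trimws(tok)
    if (!nzchar(tok[1])) stop_mssnet("empty gene id in mutation list")
    if (grepl("[ \t]", tok[1]))
      stop_mssnet("gene id '%s' contains whitespace", tok[1])
    s <- if (length(tok) >= 2 && nzchar(tok[2])) tok[2] else NA_character_
    if (!is.na(s)) parse_substitution(s)  # validates, errors name the token
    gene <- c(gene, tok[1])
    sub <- c(sub, s)
    acc <- c(acc, if (length(tok) >= 3 && nzchar(tok[3])) tok[3]
             else NA_character_)
  }
  if (!is.null(aliases)) gene <- apply_aliases(gene, read_alias_table(aliases))
  key <- paste(gene, sub, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warn_mssnet("collapsed %d duplicate mutation record(s)", sum(dup))
    gene <- gene[!dup]; sub <- sub[!dup]; acc <- acc[!dup]
  }
  data.frame(gene = gene, substitution = sub, accession = acc,
             stringsAsFactors = FALSE)
}
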