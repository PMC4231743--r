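# Proteome and gene-set I/O. A proteome is a plain tibble (protein, gene,
# sequence) — one row per isoform — with gene symbols case-normalised so
# that non-redundant gene counting is well defined. Records whose header
# yields no gene symbol are kept with gene = NA and excluded from the
# universe, but their count is reported, never silently dropped.

new_proteome <- function(df, n_unmapped = 0L) {
  stopifnot(all(c("protein", "gene", "sequence") %in% names(df)))
  out <- tibble::as_tibble(df[, c("protein", "gene", "sequence")])
  attr(out, "n_unmapped") <- n_unmapped
  class(out) <- c("proteome", class(tibble::tibble()))
  out
}

#' Number of non-redundant genes in a proteome
#'
#' Distinct (case-normalised) gene symbols, counting each gene once no
#' matter how many isoforms it has. Unmapped records (gene `NA`) are not
#' counted.
#'
#' @param proteome A proteome tibble.
#' @return Integer count.
#' @export
n_genes <- function(proteome) {
  length(unique(proteome$gene[!is.na(proteome$gene)]))
}

#' Read a multi-isoform protein FASTA as a proteome
#'
#' Parses the FASTA with `Biostrings::readAAStringSet()` and extracts one
#' gene symbol per record from the header. Sequences are uppercased and a
#' trailing stop `*` stripped. Gene symbols are trimmed and uppercased so
#' isoforms collapse to non-redundant genes regardless of capitalisation.
#'
#' @param path FASTA file path.
#' @param header_rule How to pull the gene symbol out of a header:
#'   * an integer: field index after splitting the header on `delim`
#'     (e.g. `3` for `sp|Q12345|GENE1 description` with the default delim);
#'   * a function taking the header string and returning a gene symbol
#'     (or `NA`);
#'   * a data frame with columns `protein`, `gene` mapping the first
#'     whitespace-delimited header token to a symbol.
#' @param delim Regex splitting headers into fields for the integer rule.
#'   The default splits on `|` and whitespace.
#' @return A proteome tibble (`protein`, `gene`, `sequence`); the number of
#'   records with no extractable symbol is stored in `attr(, "n_unmapped")`
#'   and reported with a message.
#' @export
read_fasta_proteome <- function(path, header_rule = 1L, delim = "[|[:space:]]+") {
  if (!file.exists(path)) {
    rlang::abort(sprintf("FASTA file not found: %s", path), class = "slim_io_error")
  }
  aa <- tryCatch(Biostrings::readAAStringSet(path),
                 error = function(e) rlang::abort(
                   sprintf("could not read FASTA %s: %s", path, conditionMessage(e)),
                   class = "slim_io_error"))
  if (length(aa) == 0L) {
    rlang::abort(sprintf("FASTA %s contains no records", path), class = "slim_io_error")
  }
  headers <- names(aa)
  protein <- vapply(stringi::stri_split_regex(headers, "\\s+", n = 2L),
                    `[[`, character(1), 1)
  gene <- extract_gene_symbols(headers, protein, header_rule, delim)
  gene <- toupper(trimws(gene))
  gene[!nzchar(gene) | is.na(gene)] <- NA_character_
  n_unmapped <- sum(is.na(gene))
  if (n_unmapped == length(aa)) {
    rlang::abort(sprintf("no record in %s yields a gene symbol under the header rule", path),
                 class = "slim_io_error")
  }
  if (n_unmapped > 0L) {
    message(sprintf("%d of %d records had no extractable gene symbol (kept, excluded from universe)",
                    n_unmapped, length(aa)))
  }
  new_proteome(tibble::tibble(protein = protein, gene = gene,
                              sequence = prep_sequence(as.character(aa))),
               n_unmapped = n_unmapped)
}

extract_gene_symbols <- function(headers, protein, header_rule, delim) {
  if (is.function(header_rule)) {
    return(vapply(headers, function(h) {
      g <- header_rule(h)
      if (length(g) != 1L || is.na(g)) NA_character_ else as.character(g)
    }, character(1), USE.NAMES = FALSE))
  }
  if (is.data.frame(header_rule)) {
    stopifnot(all(c("protein", "gene") %in% names(header_rule)))
    return(header_rule$gene[match(protein, header_rule$protein)])
  }
  if (is.numeric(header_rule) && length(header_rule) == 1L) {
    fields <- stringi::stri_split_regex(headers, delim)
    return(vapply(fields, function(f) {
      if (length(f) >= header_rule) f[[header_rule]] else NA_character_
    }, character(1)))
  }
  rlang::abort("header_rule must be a field index, a function, or a protein->gene table",
               class = "slim_io_error")
}

#' Construct a gene set
#'
#' A named set of gene symbols used purely as a label set (here, genes whose
#' transcripts oscillate with a ~24 h period in a reference expression
#' dataset). Symbols are trimmed, uppercased and deduplicated.
#'
#' @param symbols Character vector of gene symbols.
#' @param name Label for the set.
#' @param universe_size Optional total gene count of the originating
#'   expression dataset (metadata only; the screen's universe is always the
#'   proteome, optionally intersected with an explicit universe list).
#' @return A `gene_set` object (list with `name`, `symbols`,
#'   `universe_size`).
#' @export
gene_set <- function(symbols, name = "gene_set", universe_size = NULL) {
  symbols <- unique(toupper(trimws(symbols)))
  symbols <- symbols[nzchar(symbols) & !is.na(symbols)]
  if (length(symbols) == 0L) {
    rlang::abort("gene set is empty", class = "slim_io_error")
  }
  structure(list(name = name, symbols = sort(symbols),
                 universe_size = universe_size),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set %s: %d symbols%s>\n", x$name, length(x$symbols),
              if (is.null(x$universe_size)) ""
              else sprintf(", universe %d", x$universe_size)))
  invisible(x)
}

#' Read a gene-set list file
#'
#' One gene symbol per line; blank lines and `#` comments are ignored.
#'
#' @param path File path.
#' @inheritParams gene_set
#' @return A `gene_set`.
#' @export
read_gene_set <- function(path, name = NULL, universe_size = NULL) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("gene set file not found: %s", path), class = "slim_io_error")
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  gene_set(lines, name = name %||% basename(path), universe_size = universe_size)
}

#' Genes carrying a motif
#'
#' Collapses a hit table to the non-redundant set of genes with at least one
#' hit of the named pattern on at least one isoform. This is the per-gene
#' prevalence unit used throughout the enrichment screen.
#'
#' @param proteome The scanned proteome (used to restrict to mapped genes).
#' @param hits Hit tibble from [scan_proteome()].
#' @param pattern_name Name of a pattern present in the scan.
#' @return Sorted character vector of gene symbols.
#' @export
genes_with_motif <- function(proteome, hits, pattern_name) {
  known <- attr(hits, "patterns") %||% unique(hits$pattern)
  if (!pattern_name %in% known) {
    rlang::abort(sprintf("pattern '%s' was not in the scan", pattern_name),
                 class = "slim_io_error")
  }
  g <- hits$gene[hits$pattern == pattern_name]
  sort(unique(g[!is.na(g)]))
}
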