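# Scanning: find every distinct (start, end) span at which a compiled
# pattern's element list can be satisfied. Variable-width wildcards are
# handled by enumerating repeat allocations; each allocation is a
# fixed-length regex applied with a lookahead so overlapping starts are
# all reported. Coordinates are 1-based inclusive, matching residue
# numbering conventions such as "P72A".

prep_sequence <- function(x) {
  x <- toupper(x)
  stringi::stri_replace_all_regex(x, "\\*+$", "")
}

# Core vectorised scanner: pattern against a character vector of
# (already prepared) sequences. Returns tibble(seq_idx, start, end).
scan_core <- function(pattern, seqs) {
  out <- vector("list", 0L)
  for (alloc in pattern_regexes(pattern)) {
    loc <- stringi::stri_locate_all_regex(seqs, paste0("(?=", alloc$regex, ")"),
                                          omit_no_match = TRUE)
    ns <- vapply(loc, nrow, integer(1))
    if (sum(ns) == 0L) next
    starts <- unlist(lapply(loc, function(m) m[, 1]), use.names = FALSE)
    out[[length(out) + 1L]] <- tibble::tibble(
      seq_idx = rep.int(seq_along(seqs), ns),
      start = as.integer(starts),
      end = as.integer(starts) + alloc$length - 1L)
  }
  if (length(out) == 0L) {
    return(tibble::tibble(seq_idx = integer(), start = integer(), end = integer()))
  }
  hits <- dplyr::distinct(dplyr::bind_rows(out))
  dplyr::arrange(hits, .data$seq_idx, .data$start, .data$end)
}

#' Scan one protein sequence for a motif
#'
#' Reports every distinct span (1-based, inclusive) at which the pattern
#' matches. A wildcard at either pattern edge must be satisfied by an actual
#' residue — spans never extend past the sequence boundary. Where a repeat
#' range allows two widths from the same start, both spans are reported;
#' per-gene prevalence counting downstream collapses them.
#'
#' Sequences are uppercased and a trailing stop `*` is stripped before
#' scanning. Nonstandard letters (B, J, O, U, X, Z) match no pattern
#' element, wildcards included.
#'
#' @param pattern A `motif_pattern` (or raw pattern string).
#' @param sequence Protein sequence string; empty gives an empty result.
#' @param protein_id,gene_symbol Identifiers copied into the hit rows.
#' @return Tibble with columns `pattern`, `gene`, `protein`, `start`,
#'   `end`, `peptide`, sorted by `(start, end)`.
#' @examples
#' pxdls <- parse_pattern("PXDLSX(1,2)[KR]", "PXDLS_stringent")
#' scan_sequence(pxdls, "PADLSGK")
#' @export
scan_sequence <- function(pattern, sequence, protein_id = NA_character_,
                          gene_symbol = NA_character_) {
  pattern <- as_motif_pattern(pattern)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq <- prep_sequence(sequence)
  hits <- scan_core(pattern, seq)
  tibble::tibble(
    pattern = rep(pattern$name, nrow(hits)),
    gene = rep(gene_symbol, nrow(hits)),
    protein = rep(protein_id, nrow(hits)),
    start = hits$start, end = hits$end,
    peptide = stringi::stri_sub(seq, hits$start, hits$end))
}

#' Scan a whole proteome for a set of motifs
#'
#' Applies [scan_sequence()] to every isoform for every pattern and binds
#' the results in deterministic order (pattern registry order, then gene,
#' protein, start, end). Identical isoforms yield identical hit rows; the
#' per-gene collapse happens in [genes_with_motif()].
#'
#' @param proteome A proteome tibble from [read_fasta_proteome()] or
#'   [synthetic_proteome()].
#' @param patterns Patterns: registry tibble (default [motif_registry()]),
#'   list of `motif_pattern`s, or character vector of raw strings.
#' @return Hit tibble (`pattern`, `gene`, `protein`, `start`, `end`,
#'   `peptide`) carrying the scanned pattern names in
#'   `attr(, "patterns")`.
#' @export
scan_proteome <- function(proteome, patterns = motif_registry()) {
  ptab <- as_pattern_table(patterns)
  seqs <- prep_sequence(proteome$sequence)
  res <- lapply(seq_len(nrow(ptab)), function(i) {
    hits <- scan_core(ptab$pattern[[i]], seqs)
    tibble::tibble(
      pattern = rep(ptab$name[i], nrow(hits)),
      gene = proteome$gene[hits$seq_idx],
      protein = proteome$protein[hits$seq_idx],
      start = hits$start, end = hits$end,
      peptide = stringi::stri_sub(seqs[hits$seq_idx], hits$start, hits$end))
  })
  out <- dplyr::bind_rows(res)
  out <- dplyr::arrange(out,
                        match(.data$pattern, ptab$name),
                        .data$gene, .data$protein, .data$start, .data$end)
  attr(out, "patterns") <- ptab$name
  out
}
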