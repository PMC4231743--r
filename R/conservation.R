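# Ortholog motif conservation: per-species presence/position reports for a
# motif (typically the PXDLS family), the computational reduction of a
# conservation schematic. No alignment is performed; each species is
# scanned independently, so a record is identical whether its sequence is
# supplied alone or with others.

#' The PXDLS variant cascade, broadest first
#'
#' The five family variants ordered broad-to-stringent: the broad
#' `PX[NDS]L[VTSAC]X(1,2)[KR]` is tried first, the core `PXDLS` last.
#'
#' @return Registry-shaped tibble of the five variants in cascade order.
#' @export
pxdls_cascade <- function() {
  reg <- motif_registry(group = "pxdls_variant")
  order <- c("PXDLS_broad", "PXDLS_consensus", "PXDLS_stringent",
             "PXDLS_relaxed", "PXDLS_core")
  reg[match(order, reg$name), ]
}

resolve_scan_patterns <- function(pattern) {
  if (is.character(pattern) && length(pattern) == 1L &&
      tolower(pattern) %in% c("pxdls", "pxdls-family", "pxdls_family")) {
    return(pxdls_cascade())
  }
  as_pattern_table(pattern)
}

#' Motif conservation report across ortholog sequences
#'
#' Scans one sequence per species (the first FASTA record of each file) for
#' a motif and reports presence, hit coordinates and matched peptides. With
#' `pattern = "pxdls"` the PXDLS variant cascade is used: variants are tried
#' broad-to-stringent and the first variant with a hit defines the
#' species' record.
#'
#' @param orthologs Either a named character vector of FASTA paths
#'   (names = species labels), or a data frame with columns `species` and
#'   `path` (or `species` and `sequence` for in-memory input).
#' @param pattern `"pxdls"` (the family cascade), a `motif_pattern`, or a
#'   raw pattern string.
#' @return Tibble, one row per species in input order: `species`,
#'   `protein`, `pattern`, `motif_present`, `n_hits`, `start`, `end`,
#'   `peptide` (first hit; `NA` when absent) and a list-column `hits` of
#'   full per-species hit tibbles.
#' @export
conservation_report <- function(orthologs, pattern = "pxdls") {
  tab <- normalise_orthologs(orthologs)
  ptab <- resolve_scan_patterns(pattern)
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    seq <- prep_sequence(tab$sequence[i])
    hits <- tibble::tibble()
    used <- ptab$name[1]
    for (j in seq_len(nrow(ptab))) {
      h <- scan_sequence(ptab$pattern[[j]], seq,
                         protein_id = tab$protein[i], gene_symbol = NA_character_)
      if (nrow(h)) { hits <- h; used <- ptab$name[j]; break }
    }
    present <- nrow(hits) > 0L
    tibble::tibble(
      species = tab$species[i], protein = tab$protein[i], pattern = used,
      motif_present = present, n_hits = nrow(hits),
      start = if (present) hits$start[1] else NA_integer_,
      end = if (present) hits$end[1] else NA_integer_,
      peptide = if (present) hits$peptide[1] else NA_character_,
      hits = list(hits))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("slim_conservation", class(tibble::tibble()))
  out
}

normalise_orthologs <- function(orthologs) {
  if (is.character(orthologs)) {
    orthologs <- tibble::tibble(
      species = names(orthologs) %||% basename(orthologs), path = unname(orthologs))
  }
  stopifnot(is.data.frame(orthologs), "species" %in% names(orthologs))
  if ("sequence" %in% names(orthologs)) {
    prot <- if ("protein" %in% names(orthologs)) orthologs$protein
            else orthologs$species
    return(tibble::tibble(species = orthologs$species, protein = prot,
                          sequence = orthologs$sequence))
  }
  stopifnot("path" %in% names(orthologs))
  recs <- lapply(orthologs$path, function(p) {
    if (!file.exists(p)) {
      rlang::abort(sprintf("ortholog FASTA not found: %s", p), class = "slim_io_error")
    }
    aa <- Biostrings::readAAStringSet(p)
    if (length(aa) == 0L) {
      rlang::abort(sprintf("ortholog FASTA %s is empty", p), class = "slim_io_error")
    }
    # first record per file, per the report's contract
    list(protein = stringi::stri_split_regex(names(aa)[1], "\\s+")[[1]][1],
         sequence = as.character(aa[[1]]))
  })
  tibble::tibble(species = orthologs$species,
                 protein = vapply(recs, `[[`, character(1), "protein"),
                 sequence = vapply(recs, `[[`, character(1), "sequence"))
}

#' Position of the first PXDLS-family motif anchor
#'
#' The motif anchor is the first residue of a motif instance — for the
#' PXDLS family, conventionally the leading proline used in mutant names
#' such as P72A. Returns the smallest hit start across the family's variant
#' patterns (or across whatever patterns are supplied), together with the
#' variant that matches there.
#'
#' @param sequence Protein sequence string.
#' @param pattern `"pxdls"` for the family cascade, or patterns as in
#'   [conservation_report()].
#' @return One-row tibble `anchor`, `pattern`, `peptide`; when no variant
#'   hits, `anchor` is `NA` and `pattern` is `"absent"` (no error).
#' @examples
#' motif_anchor_position("MGSPADLSGKAAA")$anchor  # 4
#' @export
motif_anchor_position <- function(sequence, pattern = "pxdls") {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  ptab <- resolve_scan_patterns(pattern)
  seq <- prep_sequence(sequence)
  best <- NULL
  for (j in seq_len(nrow(ptab))) {
    h <- scan_core(ptab$pattern[[j]], seq)
    if (nrow(h) && (is.null(best) || min(h$start) < best$anchor)) {
      i <- which.min(h$start)
      best <- list(anchor = h$start[i], pattern = ptab$name[j],
                   peptide = stringi::stri_sub(seq, h$start[i], h$end[i]))
    }
  }
  if (is.null(best)) {
    return(tibble::tibble(anchor = NA_integer_, pattern = "absent",
                          peptide = NA_character_))
  }
  tibble::tibble(anchor = as.integer(best$anchor), pattern = best$pattern,
                 peptide = best$peptide)
}

#' Presence/position plot for a conservation report
#'
#' One row per species, a point at each motif hit start, filled by
#' presence — a minimal stand-in for a conservation schematic.
#'
#' @param object A [conservation_report()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot slim_conservation
#' @export
autoplot.slim_conservation <- function(object, ...) {
  plot_conservation(object)
}

#' @rdname autoplot.slim_conservation
#' @param report A [conservation_report()] tibble.
#' @export
plot_conservation <- function(report, ...) {
  pts <- tidyr::unnest(report[, c("species", "hits")], "hits")
  base <- ggplot2::ggplot(report,
                          ggplot2::aes(y = factor(.data$species,
                                                  levels = rev(report$species)))) +
    ggplot2::labs(x = "residue position", y = NULL) +
    ggplot2::theme_minimal()
  if (nrow(pts)) {
    base <- base + ggplot2::geom_point(
      data = pts, ggplot2::aes(x = .data$start, y = factor(.data$species,
                                                           levels = rev(report$species))),
      colour = "darkgreen", size = 3)
  }
  base
}
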