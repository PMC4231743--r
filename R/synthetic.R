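# Synthetic proteomes with planted motif-enrichment structure. The
# generator emulates the shape of the screen's inputs — a multi-isoform
# proteome keyed by gene symbol plus a "circadian" label set — with i.i.d.
# background residues and one concrete motif instance spliced into one
# isoform of each planted gene. Class-dependent planting probabilities set
# the true forward enrichment, (p_circ - p_non)/p_non * 100, up to chance
# background matches.

#' Background residue frequency presets
#'
#' `"uniform"` gives 1/20 per standard residue (chance-match rates then have
#' a simple closed form); `"swissprot"` is a Swiss-Prot-like composition
#' (approximate database-wide residue frequencies, renormalised over the 20
#' standard letters).
#'
#' @param preset `"uniform"` or `"swissprot"`.
#' @return Named numeric vector over [AA_STANDARD], summing to 1.
#' @export
background_freqs <- function(preset = c("uniform", "swissprot")) {
  preset <- match.arg(preset)
  if (preset == "uniform") {
    f <- rep(1 / 20, 20)
  } else {
    f <- c(A = 8.25, C = 1.38, D = 5.46, E = 6.71, F = 3.86, G = 7.07,
           H = 2.27, I = 5.91, K = 5.80, L = 9.65, M = 2.41, N = 4.06,
           P = 4.74, Q = 3.93, R = 5.52, S = 6.65, T = 5.36, V = 6.85,
           W = 1.10, Y = 2.92)
    f <- f / sum(f)
  }
  stats::setNames(as.numeric(f), AA_STANDARD)
}

# One sampled concrete peptide per requested instance: wildcard repeats
# drawn uniformly in their range, every element position drawn from its
# permitted residue set.
instantiate_pattern <- function(pattern, n = 1L) {
  allowed <- lapply(pattern$elements, function(e) {
    a <- switch(e$kind,
      "wildcard" = AA_STANDARD,
      "fixed-class" = e$residues,
      "negated-class" = setdiff(AA_STANDARD, e$residues))
    if (length(a) == 0L) {
      rlang::abort("element permits no residue (negated class covers the alphabet)",
                   class = "slim_pattern_error")
    }
    a
  })
  vapply(seq_len(n), function(i) {
    paste(unlist(lapply(seq_along(pattern$elements), function(j) {
      e <- pattern$elements[[j]]
      reps <- if (e$max > e$min) sample(seq.int(e$min, e$max), 1L) else e$min
      sample(allowed[[j]], reps, replace = TRUE)
    })), collapse = "")
  }, character(1))
}

#' Splice a concrete motif instance into a sequence
#'
#' Overwrites the residues at `position` onward with a freshly instantiated
#' match of `pattern` (wildcards and classes sampled; negated classes
#' instantiated with a permitted residue), so that the returned sequence is
#' guaranteed to match the pattern at exactly that start.
#'
#' @param sequence Protein sequence string.
#' @param pattern A `motif_pattern` (or raw string).
#' @param position 1-based splice start; the instance must fit within the
#'   sequence.
#' @param seed Optional seed for a reproducible instantiation.
#' @return The modified sequence; the planted peptide is available as
#'   `attr(, "peptide")`.
#' @examples
#' s <- splice_motif_instance(strrep("A", 50), "PXDLSX(1,2)[KR]", 10, seed = 1)
#' scan_sequence("PXDLSX(1,2)[KR]", s)$start
#' @export
splice_motif_instance <- function(sequence, pattern, position, seed = NULL) {
  pattern <- as_motif_pattern(pattern)
  stopifnot(length(sequence) == 1L, position >= 1L)
  pep <- if (is.null(seed)) instantiate_pattern(pattern)
         else withr::with_seed(seed, instantiate_pattern(pattern))
  if (position + nchar(pep) - 1L > nchar(sequence)) {
    rlang::abort("motif instance does not fit at this position", class = "slim_count_error")
  }
  stringi::stri_sub(sequence, position, position + nchar(pep) - 1L) <- pep
  attr(sequence, "peptide") <- pep
  sequence
}

# Draw n sequences with i.i.d. residues and the given lengths.
random_sequences <- function(lengths, freqs) {
  total <- sum(lengths)
  letters <- sample(AA_STANDARD, total, replace = TRUE, prob = freqs)
  big <- stringi::stri_flatten(letters)
  to <- cumsum(lengths)
  stringi::stri_sub(big, to - lengths + 1L, to)
}

#' Generate a synthetic proteome with planted motif enrichment
#'
#' Builds `n_genes` genes with 1 or more isoforms each, i.i.d. background
#' residues, and a circadian label on a fixed fraction of genes. Each gene
#' independently receives one planted instance of `pattern` — spliced into
#' one of its isoforms at a random position — with probability
#' `p_motif_circadian` (circadian genes) or `p_motif_noncircadian`
#' (the rest), so the planted forward enrichment is
#' `(p_motif_circadian - p_motif_noncircadian) / p_motif_noncircadian * 100`
#' before chance background matches.
#'
#' Defaults mirror the screen's study conditions: a circadian fraction of
#' 0.127 (2777 of 21,865 genes) and planting probabilities 0.25 / 0.20, a
#' planted +25% forward enrichment.
#'
#' @param n_genes Number of genes.
#' @param frac_circadian Fraction of genes labelled circadian, in (0, 1).
#' @param isoforms Integer range `c(min, max)` of isoforms per gene.
#' @param seq_len Integer range `c(min, max)` of sequence lengths; the
#'   minimum must be at least the pattern's maximum span.
#' @param background `"uniform"`, `"swissprot"`, or a named frequency
#'   vector over [AA_STANDARD].
#' @param p_motif_circadian,p_motif_noncircadian Planting probabilities.
#' @param pattern Planted pattern; default the stringent PXDLS variant
#'   `PXDLSX(1,2)[KR]`.
#' @param seed Mandatory integer seed; the output is deterministic given it.
#' @return List of class `slim_synthesis`:
#'   * `proteome` — proteome tibble;
#'   * `circadian` — [gene_set()] of the circadian labels;
#'   * `truth` — per-gene tibble (`gene`, `circadian`, `planted`,
#'     `protein`, `position`, `peptide`) plus the configuration and
#'     `expected_forward_pct` as attributes.
#' @export
synthetic_proteome <- function(n_genes = 20000L, frac_circadian = 0.127,
                               isoforms = c(1L, 2L), seq_len = c(80L, 300L),
                               background = "uniform",
                               p_motif_circadian = 0.25,
                               p_motif_noncircadian = 0.20,
                               pattern = parse_pattern("PXDLSX(1,2)[KR]", "PXDLS_stringent"),
                               seed) {
  if (missing(seed)) rlang::abort("a seed is mandatory", class = "slim_count_error")
  pattern <- as_motif_pattern(pattern)
  stopifnot(n_genes >= 2L, frac_circadian > 0, frac_circadian < 1,
            length(isoforms) == 2L, isoforms[1] >= 1L, isoforms[2] >= isoforms[1],
            length(seq_len) == 2L, seq_len[2] >= seq_len[1],
            p_motif_circadian >= 0, p_motif_circadian <= 1,
            p_motif_noncircadian >= 0, p_motif_noncircadian <= 1)
  if (seq_len[1] < pattern$max_len) {
    rlang::abort("minimum sequence length is shorter than the pattern's maximum span",
                 class = "slim_count_error")
  }
  freqs <- if (is.character(background)) background_freqs(background)
           else background[AA_STANDARD]

  withr::with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    m <- max(1L, round(n_genes * frac_circadian))
    circ <- rep(FALSE, n_genes)
    circ[sample.int(n_genes, m)] <- TRUE

    iso_n <- sample(seq.int(isoforms[1], isoforms[2]), n_genes, replace = TRUE)
    gene_of <- rep.int(seq_len(n_genes), iso_n)
    protein <- paste0(genes[gene_of], ".", sequence(iso_n))
    lens <- sample(seq.int(seq_len[1], seq_len[2]), length(gene_of), replace = TRUE)
    seqs <- random_sequences(lens, freqs)

    planted <- stats::runif(n_genes) <
      ifelse(circ, p_motif_circadian, p_motif_noncircadian)
    first_iso <- match(seq_len(n_genes), gene_of)
    plant_row <- rep(NA_integer_, n_genes)
    plant_pos <- rep(NA_integer_, n_genes)
    plant_pep <- rep(NA_character_, n_genes)
    idx <- which(planted)
    if (length(idx)) {
      peps <- instantiate_pattern(pattern, length(idx))
      rows <- first_iso[idx] +
        floor(stats::runif(length(idx)) * iso_n[idx])  # which isoform
      pos <- 1L + floor(stats::runif(length(idx)) *
                          (lens[rows] - nchar(peps) + 1L))
      stringi::stri_sub(seqs[rows], pos, pos + nchar(peps) - 1L) <- peps
      plant_row[idx] <- rows
      plant_pos[idx] <- pos
      plant_pep[idx] <- peps
    }

    truth <- tibble::tibble(
      gene = genes, circadian = circ, planted = planted,
      protein = ifelse(is.na(plant_row), NA_character_, protein[plant_row]),
      position = plant_pos, peptide = plant_pep)
    attr(truth, "config") <- list(
      n_genes = n_genes, frac_circadian = frac_circadian, isoforms = isoforms,
      seq_len = seq_len, background = freqs,
      p_motif_circadian = p_motif_circadian,
      p_motif_noncircadian = p_motif_noncircadian,
      pattern = pattern, seed = seed)
    attr(truth, "expected_forward_pct") <-
      if (p_motif_noncircadian > 0)
        (p_motif_circadian - p_motif_noncircadian) / p_motif_noncircadian * 100
      else NA_real_

    structure(
      list(proteome = new_proteome(tibble::tibble(
             protein = protein, gene = genes[gene_of], sequence = seqs)),
           circadian = gene_set(genes[circ], name = "circadian_synthetic"),
           truth = truth),
      class = "slim_synthesis")
  })
}

#' @export
print.slim_synthesis <- function(x, ...) {
  cfg <- attr(x$truth, "config")
  cat(sprintf("<slim_synthesis: %d genes (%d isoforms), %d circadian, %d planted '%s', seed %d>\n",
              cfg$n_genes, nrow(x$proteome), sum(x$truth$circadian),
              sum(x$truth$planted), cfg$pattern$name, cfg$seed))
  invisible(x)
}

#' Write a proteome as FASTA / a gene set as a list file
#'
#' FASTA headers are `>protein gene`, readable back with
#' `read_fasta_proteome(path, header_rule = 2)`.
#'
#' @param proteome Proteome tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(proteome, path) {
  hdr <- ifelse(is.na(proteome$gene), proteome$protein,
                paste(proteome$protein, proteome$gene))
  writeLines(paste0(">", hdr, "\n", proteome$sequence), path)
  invisible(path)
}

#' @param set A [gene_set()].
#' @rdname write_proteome_fasta
#' @export
write_gene_set <- function(set, path) {
  writeLines(set$symbols, path)
  invisible(path)
}

#' Synthetic ortholog stand-in with a planted motif anchor
#'
#' Builds a random background sequence of the requested length and splices
#' one PXDLS-family instance so that the first family hit starts exactly at
#' `anchor` (backgrounds producing an accidental earlier hit are
#' regenerated). These are synthetic stand-ins — random sequences sharing
#' only length and motif-anchor coordinate with the proteins they emulate —
#' for use where the real ortholog FASTA records are unavailable.
#'
#' @param length Sequence length in residues.
#' @param anchor 1-based start of the planted motif instance.
#' @param seed Integer seed.
#' @param pattern Planted variant; default the broad family pattern.
#' @return Sequence string.
#' @export
synthetic_ortholog <- function(length, anchor, seed,
                               pattern = parse_pattern("PX[NDS]L[VTSAC]X(1,2)[KR]", "PXDLS_broad")) {
  pattern <- as_motif_pattern(pattern)
  stopifnot(anchor >= 1L, anchor + pattern$max_len - 1L <= length)
  fam <- motif_registry(group = "pxdls_variant")
  for (try in seq_len(100L)) {
    s <- withr::with_seed(seed + (try - 1L) * 7919L, {
      bg <- random_sequences(length, background_freqs("uniform"))
      splice_motif_instance(bg, pattern, anchor)
    })
    firsts <- vapply(fam$pattern, function(p) {
      h <- scan_core(p, s)
      if (nrow(h)) min(h$start) else NA_integer_
    }, integer(1))
    if (min(firsts, na.rm = TRUE) == anchor) return(as.character(s))
  }
  rlang::abort("could not generate a clean synthetic ortholog", class = "slim_count_error")
}

#' Synthetic ortholog panel at the published mutant anchors
#'
#' Three synthetic stand-in sequences (see [synthetic_ortholog()]) matching
#' the lengths and PXDLS-anchor coordinates of the proteins whose motif
#' mutants are named P72A (REV-ERB-alpha, mouse, 615 aa), P440A (NRIP1,
#' human, 1158 aa) and P1133A (CBP, mouse, 2441 aa). Only the coordinates
#' are real; the sequences are random.
#'
#' @param seed Integer seed.
#' @return Tibble with `species`, `protein` (stand-in label), `anchor`,
#'   `sequence`.
#' @export
synthetic_ortholog_panel <- function(seed = 42L) {
  spec <- tibble::tibble(
    species = c("mouse REV-ERBalpha", "human NRIP1", "mouse CBP"),
    protein = c("REVERBA_synthetic", "NRIP1_synthetic", "CBP_synthetic"),
    length = c(615L, 1158L, 2441L),
    anchor = c(72L, 440L, 1133L))
  spec$sequence <- vapply(seq_len(nrow(spec)), function(i) {
    synthetic_ortholog(spec$length[i], spec$anchor[i], seed = seed + i)
  }, character(1))
  spec[, c("species", "protein", "anchor", "sequence")]
}
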