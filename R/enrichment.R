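# Bidirectional percent enrichment of motif-bearing genes in a gene set.
#
# Counts: N universe genes, n motif-positive genes, M set genes, k
# motif-positive set genes. The two ratio comparisons are
#   forward    = (k/M - n/N) / (n/N) * 100   (motif within the set)
#   reciprocal = (k/n - M/N) / (M/N) * 100   (set within the motif carriers)
# Both compare k against its independence expectation nM/N, so they always
# share a sign. A p-value layer (hypergeometric and permutation) is provided
# as a labelled extension; the headline outputs are the percent statistics.

check_counts <- function(N, n, M, k) {
  stopifnot(length(N) == 1L, length(n) == 1L, length(M) == 1L, length(k) == 1L)
  if (any(is.na(c(N, n, M, k))) || any(c(N, n, M, k) < 0) ||
      n > N || M > N || k > min(n, M)) {
    rlang::abort(sprintf("invalid counts: N=%s n=%s M=%s k=%s (need 0 <= k <= min(n, M); n, M <= N)",
                         N, n, M, k),
                 class = "slim_count_error")
  }
}

undefined_enrichment <- function(which) {
  rlang::abort(sprintf("enrichment undefined: %s (a zero denominator is not zero enrichment)", which),
               class = "slim_undefined_enrichment")
}

#' Percent enrichment of a motif within a gene set
#'
#' `forward_enrichment()` compares the motif-positive fraction among set
#' genes (circadian ratio, k/M) with the motif-positive fraction in the
#' whole universe (general population ratio, n/N), as a signed percent
#' excess. `reciprocal_enrichment()` swaps the roles: the set fraction
#' among motif carriers (motif ratio, k/n) against the set fraction in the
#' universe (general circadian ratio, M/N). Negative values mean depletion;
#' k = 0 gives exactly -100.
#'
#' When the reference denominator is zero (no motif-positive gene, or an
#' empty set) the statistic is undefined and a classed error
#' (`slim_undefined_enrichment`) is raised — 0 would falsely claim the
#' count sits exactly at expectation.
#'
#' @param N Universe gene count (> 0).
#' @param n Motif-positive genes in the universe.
#' @param M Set genes in the universe.
#' @param k Motif-positive set genes; `0 <= k <= min(n, M)`.
#' @return Signed percent (double).
#' @examples
#' forward_enrichment(10000, 100, 1000, 20)    # +100
#' reciprocal_enrichment(10000, 100, 1000, 20) # +100
#' @export
forward_enrichment <- function(N, n, M, k) {
  check_counts(N, n, M, k)
  if (N == 0) undefined_enrichment("empty universe")
  if (n == 0) undefined_enrichment("no motif-positive genes (n = 0)")
  if (M == 0) undefined_enrichment("empty gene set (M = 0)")
  general_population_ratio <- n / N
  circadian_ratio <- k / M
  (circadian_ratio - general_population_ratio) / general_population_ratio * 100
}

#' @rdname forward_enrichment
#' @export
reciprocal_enrichment <- function(N, n, M, k) {
  check_counts(N, n, M, k)
  if (N == 0) undefined_enrichment("empty universe")
  if (n == 0) undefined_enrichment("no motif-positive genes (n = 0)")
  if (M == 0) undefined_enrichment("empty gene set (M = 0)")
  general_circadian_ratio <- M / N
  motif_ratio <- k / n
  (motif_ratio - general_circadian_ratio) / general_circadian_ratio * 100
}

#' Hypergeometric over-representation p-value
#'
#' One-sided upper-tail probability of observing at least `k` motif-positive
#' genes in a size-`M` draw without replacement from a universe of `N` genes
#' of which `n` are motif-positive. An extension beyond the percent
#' statistics; computed with [stats::phyper()].
#'
#' @inheritParams forward_enrichment
#' @return p-value in (0, 1]; `k = 0` gives exactly 1.
#' @export
hypergeom_enrichment_p <- function(N, n, M, k) {
  check_counts(N, n, M, k)
  stats::phyper(k - 1, m = n, n = N - n, k = M, lower.tail = FALSE)
}

#' Permutation p-value for motif over-representation
#'
#' Resamples size-`M` gene sets uniformly without replacement from the
#' universe, recomputes the overlap `k*` with the fixed motif-positive set,
#' and reports `(1 + #\{k* >= k\}) / (1 + n_perm)`.
#'
#' @inheritParams forward_enrichment
#' @param n_perm Number of permutations (>= 100).
#' @param seed Mandatory integer seed.
#' @return p-value in (0, 1].
#' @export
permutation_enrichment_p <- function(N, n, M, k, n_perm = 1000L, seed) {
  check_counts(N, n, M, k)
  stopifnot(n_perm >= 100L, !missing(seed))
  withr::with_seed(seed, {
    # genes 1..n are the motif-positive ones; a uniform size-M draw's overlap
    exceed <- vapply(seq_len(n_perm), function(i) {
      sum(sample.int(N, M) <= n) >= k
    }, logical(1))
    (1 + sum(exceed)) / (1 + n_perm)
  })
}

#' Run the motif enrichment screen
#'
#' Scans the proteome for every pattern, collapses hits to non-redundant
#' motif-positive genes, and reports both percent-enrichment directions per
#' pattern, with optional significance columns. The universe is the set of
#' mapped proteome genes, intersected with `universe` when supplied; the
#' gene set is intersected with that universe.
#'
#' Patterns with no motif-positive gene have undefined enrichment; they are
#' flagged (`undefined = TRUE`, percents `NA`), never dropped and never
#' coerced to 0 (set `undefined_policy = "error"` to fail instead).
#'
#' @param proteome Proteome tibble.
#' @param set A [gene_set()] (or character vector of symbols).
#' @param patterns Patterns as in [scan_proteome()]; default the 17-pattern
#'   registry.
#' @param universe Optional character vector restricting the universe (e.g.
#'   the expression dataset's gene list).
#' @param n_perm Permutations for the permutation p-value column; 0 (the
#'   default) skips it.
#' @param seed Seed for the permutation column (required if `n_perm > 0`).
#' @param bh Add a Benjamini-Hochberg adjusted column (`bh_fdr`) over the
#'   hypergeometric p-values? Off by default; the percent statistics carry
#'   no correction.
#' @param undefined_policy `"flag"` (default) or `"error"`.
#' @return A `slim_screen` tibble, one row per pattern in input order:
#'   `pattern`, `raw`, `N`, `n`, `M`, `k`, `forward_pct`, `reciprocal_pct`,
#'   `p_hypergeom`, optional `p_perm` / `bh_fdr`, `undefined`.
#' @examples
#' syn <- synthetic_proteome(n_genes = 300, seed = 1)
#' run_screen(syn$proteome, syn$circadian,
#'            patterns = motif_registry(group = "pxdls_variant"))
#' @export
run_screen <- function(proteome, set, patterns = motif_registry(),
                       universe = NULL, n_perm = 0L, seed = NULL,
                       bh = FALSE, undefined_policy = c("flag", "error")) {
  undefined_policy <- match.arg(undefined_policy)
  if (is.character(set)) set <- gene_set(set)
  stopifnot(inherits(set, "gene_set"))
  ptab <- as_pattern_table(patterns)

  univ <- unique(proteome$gene[!is.na(proteome$gene)])
  if (!is.null(universe)) univ <- intersect(univ, toupper(trimws(universe)))
  N <- length(univ)
  set_in_univ <- intersect(set$symbols, univ)
  M <- length(set_in_univ)
  if (M == 0L) {
    rlang::abort("gene set is disjoint from the screen universe", class = "slim_count_error")
  }

  hits <- scan_proteome(proteome, ptab)
  if (n_perm > 0L && is.null(seed)) {
    rlang::abort("permutation p-values need an explicit seed", class = "slim_count_error")
  }

  rows <- lapply(seq_len(nrow(ptab)), function(i) {
    pos <- intersect(genes_with_motif(proteome, hits, ptab$name[i]), univ)
    n <- length(pos)
    k <- length(intersect(pos, set_in_univ))
    undefined <- n == 0L
    if (undefined && undefined_policy == "error") {
      undefined_enrichment(sprintf("pattern '%s' has no motif-positive genes", ptab$name[i]))
    }
    tibble::tibble(
      pattern = ptab$name[i],
      raw = if ("raw" %in% names(ptab)) ptab$raw[i] else ptab$pattern[[i]]$raw,
      N = N, n = n, M = M, k = k,
      forward_pct = if (undefined) NA_real_ else forward_enrichment(N, n, M, k),
      reciprocal_pct = if (undefined) NA_real_ else reciprocal_enrichment(N, n, M, k),
      p_hypergeom = if (undefined) NA_real_ else hypergeom_enrichment_p(N, n, M, k),
      p_perm = if (n_perm > 0L && !undefined)
        permutation_enrichment_p(N, n, M, k, n_perm = n_perm, seed = seed + i)
        else NA_real_,
      undefined = undefined)
  })
  out <- dplyr::bind_rows(rows)
  if (n_perm == 0L) out$p_perm <- NULL
  if (bh) out$bh_fdr <- stats::p.adjust(out$p_hypergeom, method = "BH")
  attr(out, "gene_set") <- set$name
  attr(out, "universe_restricted") <- !is.null(universe)
  class(out) <- c("slim_screen", class(tibble::tibble()))
  out
}

#' Write a screen table as TSV
#'
#' @param screen A `slim_screen` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(screen, path) {
  utils::write.table(as.data.frame(screen), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a motif screen
#'
#' @param x A `slim_screen`.
#' @param ... Unused.
#' @return A plain tibble of the per-pattern results.
#' @method tidy slim_screen
#' @export
tidy.slim_screen <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  attr(out, "gene_set") <- NULL
  attr(out, "universe_restricted") <- NULL
  out
}

#' One-row summary of a motif screen
#'
#' @param x A `slim_screen`.
#' @param ... Unused.
#' @return Tibble with universe and set sizes, pattern counts, the top
#'   forward enrichment and the pattern achieving it.
#' @method glance slim_screen
#' @export
glance.slim_screen <- function(x, ...) {
  def <- x[!x$undefined, ]
  top <- if (nrow(def)) which.max(def$forward_pct) else NA_integer_
  tibble::tibble(
    n_patterns = nrow(x),
    n_undefined = sum(x$undefined),
    N = x$N[1], M = x$M[1],
    max_forward_pct = if (nrow(def)) def$forward_pct[top] else NA_real_,
    top_pattern = if (nrow(def)) def$pattern[top] else NA_character_)
}

#' Bar chart of percent enrichment per motif
#'
#' Mirrors the screen's headline figure: one bar pair per pattern, forward
#' (motif within the set) and reciprocal (set within the motif carriers)
#' percent enrichment. Undefined patterns are dropped from the plot with a
#' caption note.
#'
#' @param object A `slim_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot slim_screen
#' @export
autoplot.slim_screen <- function(object, ...) {
  df <- tidy(object)
  dropped <- sum(df$undefined)
  df <- df[!df$undefined, ]
  long <- tidyr::pivot_longer(df, c("forward_pct", "reciprocal_pct"),
                              names_to = "direction", values_to = "pct")
  long$direction <- ifelse(long$direction == "forward_pct",
                           "motif in set", "set in motif carriers")
  long$pattern <- factor(long$pattern, levels = rev(unique(df$pattern)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pattern, y = .data$pct,
                                     fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "enrichment (%)", fill = NULL,
                  caption = if (dropped) sprintf("%d undefined pattern(s) omitted", dropped)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
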