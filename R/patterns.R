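# Pattern dialect: PROSITE/fuzzpro-style motif notation.
#   X            wildcard, any of the 20 standard residues
#   [ABC]        fixed class
#   [^P] / [∧P]  negated class (typographic wedge accepted, normalised to "^")
#   X(1,2)       wildcard repeated 1 to 2 times (repeats attach to X only)
# Any other uppercase standard residue letter is a singleton fixed class.

#' The 20 standard amino-acid one-letter codes
#'
#' Alphabetically ordered vector of the standard residue letters. Wildcards
#' and negated classes are defined over this alphabet; ambiguity/nonstandard
#' letters (B, J, O, U, X, Z) never match any pattern element.
#'
#' @format Character vector of length 20.
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

pattern_error <- function(msg, raw) {
  rlang::abort(sprintf("invalid motif pattern %s: %s", encodeString(raw, quote = "\""), msg),
               class = "slim_pattern_error")
}

#' Parse a motif pattern string
#'
#' Compiles a pattern written in the PROSITE/fuzzpro-style dialect into a
#' `motif_pattern` object: an ordered list of elements, each a fixed class,
#' a negated class, or a wildcard with a repeat range. Only wildcards may
#' carry a repeat, mirroring the dialect as printed (e.g. `X(1,2)`).
#'
#' The typographic wedge `∧` is accepted as the negation mark and normalised
#' to `^`. Commas inside a bracketed class are ignored (some printings write
#' `[K,R]` for `[KR]`).
#'
#' @param raw Pattern string, e.g. `"PX[NDS]LSX(1,2)[KR]"`.
#' @param name Short label for the pattern; defaults to the normalised string.
#' @return A `motif_pattern`: list with `name`, `raw` (canonical form),
#'   `elements` (list of elements with `kind`, `residues`, `min`, `max`),
#'   `min_len` and `max_len`.
#' @examples
#' p <- parse_pattern("PX[NDS]LSX(1,2)[KR]", "PXDLS")
#' p$min_len  # 7
#' p$max_len  # 8
#' @export
parse_pattern <- function(raw, name = NULL) {
  stopifnot(is.character(raw), length(raw) == 1L, !is.na(raw))
  norm <- stringi::stri_replace_all_fixed(raw, "∧", "^")
  norm <- stringi::stri_replace_all_regex(norm, "\\s+", "")
  if (!nzchar(norm)) pattern_error("empty pattern", raw)
  if (stringi::stri_detect_regex(norm, "[^A-Z\\[\\]\\(\\)\\^,0-9]")) {
    pattern_error("contains characters outside the dialect", raw)
  }

  chars <- stringi::stri_sub(norm, seq_len(nchar(norm)), length = 1L)
  elements <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      close <- which(chars == "]" & seq_along(chars) > i)[1]
      if (is.na(close)) pattern_error("unbalanced '['", raw)
      inner <- chars[seq(i + 1L, length.out = close - i - 1L)]
      negated <- length(inner) > 0L && inner[1] == "^"
      if (negated) inner <- inner[-1]
      inner <- inner[inner != ","]
      if (length(inner) == 0L) pattern_error("empty residue class", raw)
      if (any(!inner %in% AA_STANDARD)) {
        pattern_error(sprintf("class contains non-standard letter '%s'",
                              inner[!inner %in% AA_STANDARD][1]), raw)
      }
      elements[[length(elements) + 1L]] <- list(
        kind = if (negated) "negated-class" else "fixed-class",
        residues = unique(inner), min = 1L, max = 1L)
      i <- close + 1L
    } else if (ch == "(") {
      close <- which(chars == ")" & seq_along(chars) > i)[1]
      if (is.na(close)) pattern_error("unbalanced '('", raw)
      spec <- paste0(chars[seq(i + 1L, length.out = close - i - 1L)], collapse = "")
      if (!stringi::stri_detect_regex(spec, "^[0-9]+(,[0-9]+)?$")) {
        pattern_error(sprintf("malformed repeat '(%s)'", spec), raw)
      }
      bounds <- as.integer(stringi::stri_split_fixed(spec, ",")[[1]])
      lo <- bounds[1]
      hi <- if (length(bounds) == 2L) bounds[2] else bounds[1]
      if (lo < 1L || hi < lo) pattern_error(sprintf("invalid repeat range (%s)", spec), raw)
      last <- length(elements)
      if (last == 0L) pattern_error("repeat with no preceding element", raw)
      if (elements[[last]]$kind != "wildcard" ||
          elements[[last]]$min != 1L || elements[[last]]$max != 1L) {
        pattern_error("repeats may only follow a single wildcard X", raw)
      }
      elements[[last]]$min <- lo
      elements[[last]]$max <- hi
      i <- close + 1L
    } else if (ch %in% c("]", ")", "^", ",")) {
      pattern_error(sprintf("unexpected '%s'", ch), raw)
    } else if (ch == "X") {
      elements[[length(elements) + 1L]] <- list(
        kind = "wildcard", residues = character(), min = 1L, max = 1L)
      i <- i + 1L
    } else {
      if (!ch %in% AA_STANDARD) {
        pattern_error(sprintf("'%s' is not a standard residue letter", ch), raw)
      }
      elements[[length(elements) + 1L]] <- list(
        kind = "fixed-class", residues = ch, min = 1L, max = 1L)
      i <- i + 1L
    }
  }
  if (length(elements) == 0L) pattern_error("no elements", raw)

  min_len <- sum(vapply(elements, `[[`, integer(1), "min"))
  max_len <- sum(vapply(elements, `[[`, integer(1), "max"))
  canonical <- format_elements(elements)
  structure(
    list(name = if (is.null(name)) canonical else name,
         raw = canonical, elements = elements,
         min_len = min_len, max_len = max_len),
    class = "motif_pattern")
}

format_elements <- function(elements) {
  paste(vapply(elements, function(e) {
    body <- switch(e$kind,
      "wildcard" = "X",
      "fixed-class" = if (length(e$residues) == 1L) e$residues
                      else paste0("[", paste(e$residues, collapse = ""), "]"),
      "negated-class" = paste0("[^", paste(e$residues, collapse = ""), "]"))
    if (e$min == 1L && e$max == 1L) body
    else paste0(body, "(", e$min, ",", e$max, ")")
  }, character(1)), collapse = "")
}

#' @export
format.motif_pattern <- function(x, ...) {
  sprintf("<motif_pattern %s: %s (span %d-%d)>", x$name, x$raw, x$min_len, x$max_len)
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# Expand a compiled pattern into one fixed-length ICU regex per repeat
# allocation. Every element is rendered as an explicit class over the 20
# standard letters, so nonstandard sequence letters can never match.
pattern_regexes <- function(pattern) {
  counts <- lapply(pattern$elements, function(e) seq.int(e$min, e$max))
  n_alloc <- prod(lengths(counts))
  if (n_alloc > 10000L) {
    rlang::abort("pattern expands to too many repeat allocations", class = "slim_pattern_error")
  }
  grid <- expand.grid(counts, KEEP.OUT.ATTRS = FALSE)
  piece <- vapply(pattern$elements, function(e) {
    switch(e$kind,
      "wildcard" = paste0("[", paste(AA_STANDARD, collapse = ""), "]"),
      "fixed-class" = if (length(e$residues) == 1L) e$residues
                      else paste0("[", paste(e$residues, collapse = ""), "]"),
      "negated-class" = paste0("[", paste(setdiff(AA_STANDARD, e$residues), collapse = ""), "]"))
  }, character(1))
  lapply(seq_len(nrow(grid)), function(r) {
    reps <- as.integer(grid[r, ])
    list(regex = paste(rep(piece, times = reps), collapse = ""),
         length = sum(reps))
  })
}

as_motif_pattern <- function(x) {
  if (inherits(x, "motif_pattern")) return(x)
  if (is.character(x) && length(x) == 1L) return(parse_pattern(x))
  rlang::abort("expected a motif_pattern or a single pattern string",
               class = "slim_pattern_error")
}

# name, raw, group for the built-in patterns, in printed order
.registry_spec <- list(
  list("WRPW",             "[WFY]RP[WFY]",                 "screen"),
  list("TRAF6",            "PX[QE]XX[DFYWE]",              "screen"),
  list("RGD",              "RGD",                          "screen"),
  list("PXDLS",            "PX[NDS]LSX(1,2)[KR]",          "screen"),
  list("PTAP",             "XP[TS]APX",                    "screen"),
  list("PPXY",             "PPXY",                         "screen"),
  list("PDZ",              "X[ST]X[LV]",                   "screen"),
  list("PAM2",             "SX[LFP]NXXAXXF",               "screen"),
  list("NPF",              "XNPFX",                        "screen"),
  list("LXXLL",            "[^P]L[^P][^P]LL[^P]",          "screen"),
  list("LXCXE",            "[LI]XCX[DE]",                  "screen"),
  list("CaM",              "[ILV]QXXXRXXXX[RK]XX[FILVWY]", "screen"),
  list("PXDLS_broad",      "PX[NDS]L[VTSAC]X(1,2)[KR]",    "pxdls_variant"),
  list("PXDLS_relaxed",    "PX[NDS]LS",                    "pxdls_variant"),
  list("PXDLS_core",       "PXDLS",                        "pxdls_variant"),
  list("PXDLS_consensus",  "PX[NDS]LSX(1,2)[KR]",          "pxdls_variant"),
  list("PXDLS_stringent",  "PXDLSX(1,2)[KR]",              "pxdls_variant")
)

#' Built-in motif registry
#'
#' The 17 built-in patterns: the 12 protein-interaction motifs of the
#' proteome-wide screen (WRPW, TRAF6, RGD, PXDLS, PTAP, PPXY, PDZ-binding,
#' PAM2, NPF, LXXLL, LXCXE, calmodulin-binding) plus the 5 variants of the
#' CtBP-binding PXDLS family, from the broad `PX[NDS]L[VTSAC]X(1,2)[KR]`
#' down to the stringent `PXDLSX(1,2)[KR]`.
#'
#' @param group Optional filter: `"screen"` (the 12 screen motifs) or
#'   `"pxdls_variant"` (the 5 PXDLS family variants).
#' @return A tibble with columns `name`, `raw`, `group`, `min_len`,
#'   `max_len` and a list-column `pattern` of compiled [parse_pattern()]
#'   objects, in registry order.
#' @examples
#' motif_registry()
#' motif_registry(group = "pxdls_variant")$raw
#' @export
motif_registry <- function(group = NULL) {
  pats <- lapply(.registry_spec, function(s) parse_pattern(s[[2]], name = s[[1]]))
  out <- tibble::tibble(
    name = vapply(.registry_spec, `[[`, character(1), 1),
    raw = vapply(pats, `[[`, character(1), "raw"),
    group = vapply(.registry_spec, `[[`, character(1), 3),
    min_len = vapply(pats, `[[`, integer(1), "min_len"),
    max_len = vapply(pats, `[[`, integer(1), "max_len"),
    pattern = pats)
  if (!is.null(group)) {
    group <- match.arg(group, c("screen", "pxdls_variant"))
    out <- out[out$group == group, ]
  }
  out
}

# Coerce flexible user input (registry tibble, list of patterns, character
# vector of raw strings, single motif_pattern) to a registry-shaped tibble.
as_pattern_table <- function(patterns) {
  if (inherits(patterns, "motif_pattern")) patterns <- list(patterns)
  if (is.character(patterns)) {
    nm <- if (is.null(names(patterns))) patterns else names(patterns)
    patterns <- Map(parse_pattern, patterns, nm)
  }
  if (is.data.frame(patterns)) {
    stopifnot(all(c("name", "pattern") %in% names(patterns)))
    return(tibble::as_tibble(patterns[, intersect(c("name", "raw", "group", "pattern"),
                                                  names(patterns))]))
  }
  stopifnot(is.list(patterns), all(vapply(patterns, inherits, logical(1), "motif_pattern")))
  tibble::tibble(
    name = vapply(patterns, `[[`, character(1), "name"),
    raw = vapply(patterns, `[[`, character(1), "raw"),
    pattern = unname(patterns))
}

#' Read and write pattern files
#'
#' Plain-text pattern files carry one `name<TAB>pattern` per line; blank
#' lines and `#` comments are ignored. The registry exports to the same
#' format.
#'
#' @param path File path.
#' @return `read_patterns()` returns a registry-shaped tibble (see
#'   [motif_registry()]); `write_patterns()` returns `path` invisibly.
#' @export
read_patterns <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("pattern file not found: %s", path), class = "slim_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    rlang::abort("pattern file contains no patterns", class = "slim_io_error")
  }
  parts <- stringi::stri_split_fixed(lines, "\t", n = 2L)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    rlang::abort(sprintf("line %d is not 'name<TAB>pattern'", which(bad)[1]),
                 class = "slim_io_error")
  }
  pats <- lapply(parts, function(p) parse_pattern(p[2], name = p[1]))
  as_pattern_table(pats)
}

#' @param patterns A registry-shaped tibble or list of `motif_pattern`s.
#' @rdname read_patterns
#' @export
write_patterns <- function(patterns, path) {
  tab <- as_pattern_table(patterns)
  writeLines(paste(tab$name, tab$raw, sep = "\t"), path)
  invisible(path)
}
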