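# Brute-force reference matcher, independent of the regex-based scanner.
# Tests every substring whose length lies in [min_len, max_len]
# element-by-element over all repeat allocations, by direct recursion over
# the element list.

oracle_element_matches <- function(element, residue) {
  switch(element$kind,
    "wildcard" = residue %in% AA_STANDARD,
    "fixed-class" = residue %in% element$residues,
    "negated-class" = residue %in% setdiff(AA_STANDARD, element$residues))
}

# does elements[ei..] match chars[pos..end_pos] exactly (consuming all)?
oracle_match_from <- function(elements, ei, chars, pos, end_pos) {
  if (ei > length(elements)) return(pos == end_pos + 1L)
  e <- elements[[ei]]
  for (reps in seq.int(e$min, e$max)) {
    if (pos + reps - 1L > end_pos) break
    ok <- all(vapply(seq_len(reps), function(r) {
      oracle_element_matches(e, chars[pos + r - 1L])
    }, logical(1)))
    if (ok && oracle_match_from(elements, ei + 1L, chars, pos + reps, end_pos)) {
      return(TRUE)
    }
  }
  FALSE
}

oracle_scan <- function(pattern, sequence) {
  sequence <- toupper(sub("\\*+$", "", sequence))
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  hits <- list()
  for (start in seq_len(max(n - pattern$min_len + 1L, 0L))) {
    for (len in seq.int(pattern$min_len, pattern$max_len)) {
      end <- start + len - 1L
      if (end > n) break
      if (oracle_match_from(pattern$elements, 1L, chars, start, end)) {
        hits[[length(hits) + 1L]] <- c(start, end)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  m <- do.call(rbind, hits)
  out <- data.frame(start = m[, 1], end = m[, 2])
  out[order(out$start, out$end), , drop = FALSE]
}

# Random pattern over the dialect: <= max_elements elements mixing
# singletons, classes, negated classes and (possibly repeated) wildcards.
random_pattern <- function(max_elements = 8L) {
  n_el <- sample(2:max_elements, 1)
  parts <- vapply(seq_len(n_el), function(i) {
    kind <- sample(c("single", "class", "negated", "wild", "wildrep"), 1,
                   prob = c(0.35, 0.2, 0.1, 0.25, 0.1))
    switch(kind,
      single = sample(AA_STANDARD, 1),
      class = paste0("[", paste(sample(AA_STANDARD, sample(2:4, 1)), collapse = ""), "]"),
      negated = paste0("[^", paste(sample(AA_STANDARD, sample(1:2, 1)), collapse = ""), "]"),
      wild = "X",
      wildrep = sprintf("X(%d,%d)", sample(1:2, 1), sample(2:3, 1)))
  }, character(1))
  raw <- paste(parts, collapse = "")
  # wildrep may produce (2,2) etc.; ensure min<=max by regeneration on error
  tryCatch(parse_pattern(raw), error = function(e) random_pattern(max_elements))
}

# Random sequence enriched in the planted pattern's residues so matches occur.
random_test_sequence <- function(pattern, max_len = 200L) {
  n <- sample(0:max_len, 1)
  pool <- c(AA_STANDARD, unlist(lapply(pattern$elements, `[[`, "residues")))
  if (runif(1) < 0.15) pool <- c(pool, c("B", "J", "O", "U", "Z", "X"))
  paste(sample(pool, n, replace = TRUE), collapse = "")
}
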