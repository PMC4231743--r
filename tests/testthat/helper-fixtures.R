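# Small in-code fixtures shared across test files.

write_tmp_fasta <- function(records) {
  # records: named character vector, names = headers (without ">")
  path <- tempfile(fileext = ".faa")
  writeLines(paste0(">", names(records), "\n", unname(records)), path)
  path
}

write_tmp_lines <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}

# Proteome in which the screen counts are known by construction:
# genes GC1, GC2 circadian (GC1 has the stringent PXDLS variant on both of
# its isoforms, GC2 none), GN1..GN3 non-circadian (GN1 carries the motif).
toy_construction <- function() {
  motif <- "PADLSGK"
  bg <- strrep("AGV", 20)
  proteome <- tibble::tibble(
    protein = c("GC1.1", "GC1.2", "GC2.1", "GN1.1", "GN2.1", "GN3.1"),
    gene = c("GC1", "GC1", "GC2", "GN1", "GN2", "GN3"),
    sequence = c(paste0(bg, motif, bg), paste0(motif, bg), bg,
                 paste0(bg, motif), bg, bg))
  list(proteome = proteome,
       set = gene_set(c("GC1", "GC2"), name = "toy_circadian"),
       # N=5 genes, n=2 motif-positive (GC1, GN1), M=2, k=1
       N = 5L, n = 2L, M = 2L, k = 1L)
}
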