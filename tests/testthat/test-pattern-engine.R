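# Pattern dialect parsing and sequence scanning.

test_that("parse_pattern compiles the dialect's element kinds and spans", {
  p <- parse_pattern("PX[NDS]LSX(1,2)[KR]", "PXDLS")
  expect_length(p$elements, 7)
  expect_equal(vapply(p$elements, `[[`, character(1), "kind"),
               c("fixed-class", "wildcard", "fixed-class", "fixed-class",
                 "fixed-class", "wildcard", "fixed-class"))
  expect_equal(p$elements[[3]]$residues, c("N", "D", "S"))
  expect_equal(c(p$elements[[6]]$min, p$elements[[6]]$max), c(1L, 2L))
  expect_equal(c(p$min_len, p$max_len), c(7L, 8L))

  w <- parse_pattern("[WFY]RP[WFY]")
  expect_length(w$elements, 4)
  expect_equal(c(w$min_len, w$max_len), c(4L, 4L))
})

test_that("the typographic wedge is accepted as the negation mark", {
  p <- parse_pattern("[∧P]L[∧P][∧P]LL[∧P]", "LXXLL")
  expect_length(p$elements, 7)
  kinds <- vapply(p$elements, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "negated-class"), 4)
  expect_equal(p$raw, "[^P]L[^P][^P]LL[^P]")
  expect_identical(p$raw, parse_pattern("[^P]L[^P][^P]LL[^P]")$raw)
})

test_that("malformed patterns raise parse errors", {
  expect_error(parse_pattern("P[NDS"), class = "slim_pattern_error")
  expect_error(parse_pattern("PX(1,2"), class = "slim_pattern_error")
  expect_error(parse_pattern("P(1,2)X"), class = "slim_pattern_error")  # repeat on non-wildcard
  expect_error(parse_pattern("[KR](1,2)"), class = "slim_pattern_error")
  expect_error(parse_pattern("P[]LS"), class = "slim_pattern_error")
  expect_error(parse_pattern(""), class = "slim_pattern_error")
  expect_error(parse_pattern("PX(2,1)L"), class = "slim_pattern_error")
  expect_error(parse_pattern("PBX"), class = "slim_pattern_error")  # B not a standard residue
})

test_that("compiled patterns round-trip to their canonical raw form", {
  raws <- c("PX[NDS]LSX(1,2)[KR]", "[WFY]RP[WFY]", "RGD", "X[ST]X[LV]",
            "[^P]L[^P][^P]LL[^P]", "[ILV]QXXXRXXXX[RK]XX[FILVWY]")
  for (r in raws) {
    expect_identical(parse_pattern(r)$raw, r)
    expect_identical(parse_pattern(parse_pattern(r)$raw)$raw, r)
  }
  # commas inside a class are tolerated and normalised away
  expect_identical(parse_pattern("PX[NDS]LSX(1,2)[K,R]")$raw, "PX[NDS]LSX(1,2)[KR]")
})

test_that("the built-in registry holds the 12 screen motifs and 5 PXDLS variants", {
  reg <- motif_registry()
  expect_equal(nrow(reg), 17)
  expect_equal(sum(reg$group == "screen"), 12)
  expect_equal(sum(reg$group == "pxdls_variant"), 5)
  expect_equal(reg$raw[reg$name == "RGD"], "RGD")
  expect_true("PXDLSX(1,2)[KR]" %in% reg$raw)
  # raw strings survive a parse round-trip byte-identically
  expect_identical(vapply(reg$raw, function(r) parse_pattern(r)$raw, character(1),
                          USE.NAMES = FALSE),
                   reg$raw)
})

test_that("scanning reports all distinct spans with 1-based inclusive coordinates", {
  hit <- scan_sequence("PXDLSX(1,2)[KR]", "PADLSGK", "prot1", "gene1")
  expect_equal(nrow(hit), 1)
  expect_equal(c(hit$start, hit$end), c(1L, 7L))
  expect_equal(hit$peptide, "PADLSGK")
  expect_equal(hit$protein, "prot1")

  # both repeat widths from one start are distinct spans
  two <- scan_sequence("PXDLSX(1,2)[KR]", "PADLSKRK")
  expect_equal(two$start, c(1L, 1L))
  expect_equal(two$end, c(7L, 8L))

  expect_equal(nrow(scan_sequence("PX[NDS]LSX(1,2)[KR]", "ASASAASASAASASA")), 0)
  one <- scan_sequence("PX[NDS]LSX(1,2)[KR]", "PLNLSAAR")
  expect_equal(c(one$start, one$end), c(1L, 8L))
})

test_that("edge wildcards must consume real residues (no boundary matching)", {
  expect_equal(nrow(scan_sequence("XNPFX", "NPFA")), 0)
  expect_equal(nrow(scan_sequence("XNPFX", "ANPF")), 0)
  expect_equal(scan_sequence("XNPFX", "ANPFA")$start, 1L)
})

test_that("sequence handling: case, trailing stop, empty and nonstandard letters", {
  expect_equal(scan_sequence("RGD", "aargdaa")$start, 3L)
  expect_equal(scan_sequence("RGD", "AARGD*")$start, 3L)
  expect_equal(nrow(scan_sequence("RGD", "")), 0)
  # B J O U X Z fail wildcards and classes alike
  expect_equal(nrow(scan_sequence("RGD", "RGB")), 0)
  expect_equal(nrow(scan_sequence("PXP", "PXP")), 0)
  expect_equal(nrow(scan_sequence("PXP", "PUP")), 0)
})

test_that("a negated class matches exactly the complement on an alphabet sweep", {
  sweep <- paste(AA_STANDARD, collapse = "")
  hits <- scan_sequence("[^P]", sweep)
  expect_equal(nrow(hits), 19)
  expect_false("P" %in% hits$peptide)
})

test_that("fixed-length patterns yield only full-width hits and shifts are equivariant", {
  set.seed(401)
  for (i in 1:25) {
    p <- random_pattern()
    s <- random_test_sequence(p, max_len = 120)
    hits <- scan_sequence(p, s)
    if (p$min_len == p$max_len && nrow(hits)) {
      expect_true(all(hits$end - hits$start + 1L == p$min_len))
    }
    # prepend residues that cannot introduce a new hit start: shift by k
    shifted <- scan_sequence(p, paste0("BBBB", s))
    expect_equal(shifted$start, hits$start + 4L)
    expect_equal(shifted$end, hits$end + 4L)
  }
})

test_that("scanner agrees with the brute-force oracle on random instances", {
  set.seed(402)
  for (i in 1:120) {
    p <- random_pattern()
    s <- random_test_sequence(p)
    got <- scan_sequence(p, s)[, c("start", "end")]
    want <- oracle_scan(p, s)
    expect_equal(as.data.frame(got), want, ignore_attr = TRUE,
                 label = sprintf("pattern %s on %s", p$raw, s))
  }
})

test_that("scan_proteome is deterministic, ordered, and keeps per-isoform rows", {
  toy <- toy_construction()
  hits <- scan_proteome(toy$proteome, motif_registry(group = "pxdls_variant"))
  # GC1 has the motif on both isoforms: two rows, one gene
  strhits <- hits[hits$pattern == "PXDLS_stringent", ]
  expect_equal(sort(unique(strhits$protein[strhits$gene == "GC1"])), c("GC1.1", "GC1.2"))
  expect_equal(genes_with_motif(toy$proteome, hits, "PXDLS_stringent"),
               c("GC1", "GN1"))
  expect_identical(hits, scan_proteome(toy$proteome, motif_registry(group = "pxdls_variant")))

  empty <- scan_proteome(toy$proteome[0, ], motif_registry()[1:2, ])
  expect_equal(nrow(empty), 0)
})

test_that("pattern files round-trip through the name<TAB>pattern format", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_patterns(motif_registry(), path)
  back <- read_patterns(path)
  expect_equal(back$name, motif_registry()$name)
  expect_equal(back$raw, motif_registry()$raw)
  expect_error(read_patterns(write_tmp_lines("# only a comment")),
               class = "slim_io_error")
})
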