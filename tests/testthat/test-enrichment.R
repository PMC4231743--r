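# The bidirectional percent-enrichment statistics and the significance layer.

test_that("forward and reciprocal enrichment match hand-computed values", {
  expect_equal(forward_enrichment(10000, 100, 1000, 20), 100)
  expect_equal(reciprocal_enrichment(10000, 100, 1000, 20), 100)
  # worked example: n/N = 0.03, k/M = 0.045 -> +50%; k/n = 0.3, M/N = 0.2 -> +50%
  expect_equal(forward_enrichment(1000, 30, 200, 9), 50)
  expect_equal(reciprocal_enrichment(1000, 30, 200, 9), 50)
  # depletion is signed
  expect_lt(forward_enrichment(1000, 100, 100, 2), 0)
})

test_that("enrichment is 0 at independence and -100 at k = 0", {
  expect_equal(forward_enrichment(1000, 100, 50, 5), 0)    # k = nM/N
  expect_equal(reciprocal_enrichment(1000, 100, 50, 5), 0)
  expect_equal(forward_enrichment(1000, 100, 50, 0), -100)
  expect_equal(reciprocal_enrichment(1000, 100, 50, 0), -100)
})

test_that("both statistics are invariant under scaling all counts", {
  for (f in c(2, 10, 37)) {
    expect_equal(forward_enrichment(300 * f, 40 * f, 60 * f, 13 * f),
                 forward_enrichment(300, 40, 60, 13))
    expect_equal(reciprocal_enrichment(300 * f, 40 * f, 60 * f, 13 * f),
                 reciprocal_enrichment(300, 40, 60, 13))
  }
})

test_that("undefined enrichment is a typed error, never coerced to 0", {
  expect_error(forward_enrichment(100, 0, 10, 0), class = "slim_undefined_enrichment")
  expect_error(reciprocal_enrichment(100, 0, 10, 0), class = "slim_undefined_enrichment")
  expect_error(forward_enrichment(100, 10, 0, 0), class = "slim_undefined_enrichment")
  expect_error(forward_enrichment(100, 10, 20, 15), class = "slim_count_error")
  expect_error(forward_enrichment(100, 120, 20, 5), class = "slim_count_error")
})

test_that("forward and reciprocal enrichment share a sign on every valid tuple (N <= 30)", {
  zsign <- function(x) sign(x) * (abs(x) > 1e-9)  # fp-safe sign
  bad <- 0L
  for (N in 1:30) for (n in 1:N) for (M in 1:N) for (k in 0:min(n, M)) {
    f <- forward_enrichment(N, n, M, k)
    r <- reciprocal_enrichment(N, n, M, k)
    if (zsign(f) != zsign(r)) bad <- bad + 1L
  }
  expect_equal(bad, 0L)
})

test_that("hypergeometric p equals exact enumeration over all draws (N <= 12)", {
  # independent enumeration: all size-M subsets of 1..N, successes 1..n
  enum_p <- function(N, n, M, k) {
    draws <- utils::combn(N, M)
    mean(colSums(draws <= n) >= k)
  }
  expect_equal(hypergeom_enrichment_p(5, 2, 2, 2), 0.1)  # 1 of C(5,2)=10 draws
  set.seed(31)
  for (i in 1:40) {
    N <- sample(2:12, 1); n <- sample(1:N, 1); M <- sample(1:N, 1)
    k <- sample(0:min(n, M), 1)
    expect_equal(hypergeom_enrichment_p(N, n, M, k), enum_p(N, n, M, k),
                 label = sprintf("N=%d n=%d M=%d k=%d", N, n, M, k))
  }
  expect_equal(hypergeom_enrichment_p(50, 10, 10, 0), 1)
  # monotone decreasing in k at fixed (N, n, M) over the full support
  ps <- vapply(0:4, function(k) hypergeom_enrichment_p(12, 5, 4, k), numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("permutation p is seeded, degenerate-safe, and tracks the hypergeometric", {
  expect_identical(permutation_enrichment_p(100, 20, 30, 10, n_perm = 200, seed = 5),
                   permutation_enrichment_p(100, 20, 30, 10, n_perm = 200, seed = 5))
  expect_equal(permutation_enrichment_p(10, 10, 10, 10, n_perm = 100, seed = 1), 1)

  set.seed(32)
  for (i in 1:8) {
    N <- sample(30:80, 1); n <- sample(5:20, 1); M <- sample(5:20, 1)
    k <- sample(0:min(n, M), 1)
    n_perm <- 800
    p_exact <- hypergeom_enrichment_p(N, n, M, k)
    p_perm <- permutation_enrichment_p(N, n, M, k, n_perm = n_perm, seed = 100 + i)
    se <- sqrt(p_exact * (1 - p_exact) / n_perm)
    expect_lt(abs(p_perm - p_exact), 3 * se + 2 / n_perm,
              label = sprintf("perm vs exact at N=%d n=%d M=%d k=%d", N, n, M, k))
  }
})

test_that("run_screen reproduces constructed counts and flags undefined patterns", {
  toy <- toy_construction()
  pats <- motif_registry()[motif_registry()$name %in% c("PXDLS_stringent", "WRPW"), ]
  scr <- run_screen(toy$proteome, toy$set, patterns = pats)
  row <- scr[scr$pattern == "PXDLS_stringent", ]
  expect_equal(c(row$N, row$n, row$M, row$k), c(toy$N, toy$n, toy$M, toy$k))
  expect_equal(row$forward_pct, forward_enrichment(toy$N, toy$n, toy$M, toy$k))
  expect_equal(row$reciprocal_pct, reciprocal_enrichment(toy$N, toy$n, toy$M, toy$k))
  # WRPW absent from the toy proteome: flagged, not dropped, not zero
  wrpw <- scr[scr$pattern == "WRPW", ]
  expect_true(wrpw$undefined)
  expect_true(is.na(wrpw$forward_pct))
  expect_error(run_screen(toy$proteome, toy$set, patterns = pats,
                          undefined_policy = "error"),
               class = "slim_undefined_enrichment")
  expect_error(run_screen(toy$proteome, gene_set(c("ZZZ1", "ZZZ2")), patterns = pats),
               class = "slim_count_error")
})

test_that("a full registry screen yields 17 rows with broom and ggplot methods", {
  syn <- synthetic_proteome(n_genes = 250, seq_len = c(60, 120), seed = 99)
  scr <- run_screen(syn$proteome, syn$circadian, bh = TRUE)
  expect_equal(nrow(scr), 17)
  expect_equal(scr$pattern, motif_registry()$name)
  expect_true(all(scr$k <= pmin(scr$n, scr$M)))
  expect_s3_class(tidy(scr), "tbl_df")
  g <- glance(scr)
  expect_equal(g$n_patterns, 17)
  expect_s3_class(autoplot(scr), "ggplot")
  # TSV serialization round-trips the counts
  path <- withr::local_tempfile(fileext = ".tsv")
  write_screen_tsv(scr, path)
  back <- utils::read.delim(path)
  expect_equal(back$k, scr$k)
})
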