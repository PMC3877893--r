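test_that("conservation profile gives minimal covering codes per column", {
  aln <- as_alignment(seq_set(
    c("x", "y", "z"),
    c("AACA", "ACCA", "ATGA")  # cols: {A}, {A,C,T}, {C,G}, {A}
  ))
  prof <- conservation_profile(aln)
  expect_equal(prof$consensus, c("A", "H", "S", "A"))
  expect_equal(prof$degeneracy, c(1L, 3L, 2L, 1L))
  expect_equal(prof$gap_fraction, rep(0, 4))
})

test_that("profile expands input ambiguity codes and tracks gap fraction", {
  aln <- as_alignment(seq_set(c("x", "y"), c("RT-", "GTA")))
  prof <- conservation_profile(aln)
  expect_equal(prof$consensus[1], "R")  # R union G = {A,G}
  expect_equal(prof$gap_fraction[3], 0.5)
})

test_that("degeneracy counts distinct plain expansions (brute force)", {
  expect_equal(primer_degeneracy("ACGT"), 1)
  for (p in c("TTVGGYTAYGAYTTYGG", "AGACCARGAACGRACTTC", "NAY", "RYSWKM")) {
    expect_equal(primer_degeneracy(p), length(oracle_expand(p)), info = p)
  }
  expect_error(primer_degeneracy("ACQ"), "illegal IUPAC")
})

test_that("degeneracy is multiplicative over concatenation", {
  set.seed(7)
  codes <- names(IUPAC_SETS)
  for (i in 1:20) {
    a <- paste(sample(codes, 5, replace = TRUE), collapse = "")
    b <- paste(sample(codes, 4, replace = TRUE), collapse = "")
    expect_equal(primer_degeneracy(paste0(a, b)),
                 primer_degeneracy(a) * primer_degeneracy(b))
  }
})

test_that("reverse complement is an involution on IUPAC strings", {
  set.seed(8)
  codes <- names(IUPAC_SETS)
  for (i in 1:25) {
    s <- paste(sample(codes, sample(5:15, 1), replace = TRUE), collapse = "")
    expect_equal(revcomp_iupac(revcomp_iupac(s)), s)
  }
  expect_equal(revcomp_iupac("RYKMBVDHSWN"), "NWSDHBVKMRY")
})

test_that("Wallace-rule Tm ranges match enumeration, including the bounds shortcut", {
  expect_equal(melting_temp("AAAA"), c(8, 8))
  expect_equal(melting_temp("ACGT"), c(12, 12))
  expect_equal(melting_temp("AY"), c(4, 6))
  # per-position bounds agree with enumeration when both are feasible
  for (p in c("TTVGGYTAYGAYTTYGG", "NNRY", "BDHV")) {
    expect_equal(melting_temp(p, enumerate_limit = 1e6),
                 melting_temp(p, enumerate_limit = 0), info = p)
  }
})

test_that("design on invariant sequences ranks the leftmost window first", {
  seqs <- rep(paste(rep(c("ACGTGGATCCTTGGAACAGT"), 10), collapse = ""), 6)
  aln <- as_alignment(seq_set(sprintf("t%d", 1:6), seqs))
  pairs <- design_primer_pairs(aln, primer_length = c(17, 17),
                               product_length = c(100, 200))
  expect_gt(nrow(pairs), 0)
  expect_true(all(pairs$total_degeneracy == 1))
  expect_equal(pairs$forward_start[1], 0L)
})

test_that("design recovers an implanted conserved primer pair", {
  set.seed(42)
  n <- 6; ncol_aln <- 900
  fwd_site <- "TTAGGCTACGACTTCGG"     # 17 bases at columns [50, 67)
  rev_site <- "GAAGTTCGTTCTTGGTCT"    # 18 bases at columns [836, 854)
  mat <- matrix("", n, ncol_aln)
  for (j in seq_len(ncol_aln)) mat[, j] <- sample(c("A", "C", "G", "T"), n, TRUE)
  for (i in seq_len(n)) {
    mat[i, 51:67] <- strsplit(fwd_site, "")[[1]]
    mat[i, 837:854] <- strsplit(rev_site, "")[[1]]
  }
  aln <- as_alignment(seq_set(sprintf("t%d", 1:n),
                              apply(mat, 1, paste, collapse = "")))
  pairs <- design_primer_pairs(aln, primer_length = c(17, 18),
                               max_degeneracy = 96,
                               product_length = c(800, 810))
  expect_gt(nrow(pairs), 0)
  expect_equal(pairs$forward_start[1], 50L)
  expect_true(any(pairs$forward_start == 50 & pairs$reverse_end == 854 &
                    pairs$nominal_product_length == 804))
})

test_that("design returns an empty table when every window is too degenerate", {
  set.seed(43)
  n <- 6
  mat <- matrix(sample(c("A", "C", "G", "T"), n * 200, TRUE), n, 200)
  aln <- as_alignment(seq_set(sprintf("t%d", 1:n),
                              apply(mat, 1, paste, collapse = "")))
  pairs <- design_primer_pairs(aln, primer_length = c(17, 17),
                               max_degeneracy = 96,
                               product_length = c(50, 200))
  expect_equal(nrow(pairs), 0)
})

test_that("the published screening pair has the documented footprint", {
  pp <- cbt_primer_pair()
  expect_equal(pp$forward$degeneracy, 48)
  expect_equal(pp$reverse$degeneracy, 4)
  expect_equal(pp$nominal_product_length, 804L)
  expect_gte(pp$nominal_product_length,
             nchar(pp$forward$sequence) + nchar(pp$reverse$sequence))
  expect_error(degenerate_primer("p", "ACGTACG"), "length")
  expect_error(primer_pair(pp$forward, pp$forward, 804), "orientation")
})
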