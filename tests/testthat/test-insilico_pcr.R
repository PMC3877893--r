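test_that("IUPAC matching is base-set intersection", {
  expect_true(iupac_match("Y", "C"))
  expect_false(iupac_match("R", "Y"))
  expect_true(iupac_match("N", "G"))
  expect_true(iupac_match("S", "B"))
  expect_false(iupac_match("W", "S"))
  expect_error(iupac_match("X", "A"), "illegal")
})

test_that("find_sites locates constructed sites on both strands", {
  set.seed(11)
  primer <- "TTVGGYTAYGAYTTYGG"
  expansion <- "TTAGGCTACGACTTCGG"
  tpl <- paste0(random_dna(37), expansion, random_dna(50))
  hits <- find_sites(primer, tpl)
  expect_equal(hits$start, 37L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$mismatches, 0L)

  hits_rc <- find_sites("AAAA", "TTTT")
  expect_equal(hits_rc$start, 0L)
  expect_equal(hits_rc$strand, "-")

  expect_equal(nrow(find_sites(primer, "ACGT")), 0L)  # template too short
})

test_that("find_sites equals the full-expansion substring oracle", {
  set.seed(12)
  primers <- c("TTVGGYTAYGAYTTYGG", "AGACCARGAACGRACTTC", "GGNACRTAYG")
  for (primer in primers) {
    for (rep in 1:8) {
      tpl <- random_dna(1000)
      # implant a couple of expansions to guarantee non-trivial hits
      exp1 <- sample(oracle_expand(primer), 1)
      exp2 <- oracle_revcomp_plain(sample(oracle_expand(primer), 1))
      substr(tpl, 101, 100 + nchar(exp1)) <- exp1
      substr(tpl, 501, 500 + nchar(exp2)) <- exp2
      mine <- find_sites(primer, tpl)
      oracle <- oracle_find_sites(primer, tpl)
      expect_equal(mine$start, oracle$start, info = primer)
      expect_equal(mine$strand, oracle$strand, info = primer)
    }
  }
})

test_that("mismatch counting is monotone in the allowance", {
  set.seed(13)
  primer <- "ACGTACGTAC"
  for (rep in 1:10) {
    tpl <- random_dna(300)
    h0 <- find_sites(primer, tpl, max_mismatch = 0)
    h2 <- find_sites(primer, tpl, max_mismatch = 2)
    h3 <- find_sites(primer, tpl, max_mismatch = 3)
    key <- function(h) paste(h$start, h$strand)
    expect_true(all(key(h0) %in% key(h2)))
    expect_true(all(key(h2) %in% key(h3)))
    expect_true(all(h3$mismatches <= 3))
  }
})

test_that("pcr_products excises the implanted product and flags negatives", {
  set.seed(14)
  pp <- cbt_primer_pair()
  core <- random_dna(769)
  insert <- paste0("TTAGGCTACGACTTCGG", core,
                   oracle_revcomp_plain("AGACCAAGAACGAACTTC"))
  tpl <- paste0(random_dna(200), insert, random_dna(150))
  hits <- pcr_products(pp, tpl)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 200L)
  expect_equal(hits$product_length, 804L)
  expect_equal(hits$product, insert)
  expect_equal(hits$mismatches_fwd + hits$mismatches_rev, 0L)
  # negative template: no sites at all
  expect_equal(nrow(pcr_products(pp, random_dna(900))), 0L)
})

test_that("two forward sites before one reverse site yield two products", {
  pp <- primer_pair(
    degenerate_primer("F", "ACGTACGTAC", "forward"),
    degenerate_primer("R", "GGCCGGCCGG", "reverse"),
    nominal_product_length = 60
  )
  tpl <- paste0("ACGTACGTAC", "ACGTACGTAC", random_dna(40),
                oracle_revcomp_plain("GGCCGGCCGG"))
  hits <- pcr_products(pp, tpl, product_length_range = c(20, 200))
  hits <- hits[hits$primer_left == "F" & hits$primer_right == "R", ]
  expect_equal(nrow(hits), 2L)
  expect_equal(abs(diff(hits$product_length)), 10L)
})

test_that("products are strand-symmetric under template reverse complement", {
  set.seed(15)
  pp <- cbt_primer_pair()
  for (rep in 1:5) {
    core <- random_dna(300)
    tpl <- paste0(random_dna(60), "TTAGGCTACGACTTCGG", core,
                  oracle_revcomp_plain("AGACCAAGAACGAACTTC"), random_dna(80))
    fwd_hits <- pcr_products(pp, tpl, product_length_range = c(50, 1000))
    rc_hits <- pcr_products(pp, revcomp_iupac(tpl),
                            product_length_range = c(50, 1000))
    expect_equal(sort(vapply(rc_hits$product, revcomp_iupac, character(1),
                             USE.NAMES = FALSE)),
                 sort(fwd_hits$product))
    # coordinates map: start' = n - end
    expect_equal(sort(nchar(tpl) - rc_hits$end), sort(fwd_hits$start))
  }
})

test_that("pcr_screen tallies positives and negatives per template", {
  set.seed(16)
  pp <- cbt_primer_pair()
  pos <- paste0(random_dna(50), "TTAGGCTACGACTTCGG", random_dna(300),
                oracle_revcomp_plain("AGACCAAGAACGAACTTC"), random_dna(50))
  neg <- random_dna(500)
  res <- pcr_screen(pp, seq_set(c("p", "n"), c(pos, neg)),
                    product_length_range = c(50, 1000))
  expect_equal(res$screen$positive, c(TRUE, FALSE))
  expect_equal(res$screen$n_products, c(1L, 0L))
})
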