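test_that("Yule species trees have the requested shape and are seeded", {
  tr <- simulate_species_tree(4, seed = 3)
  expect_equal(length(tr$tip.label), 4L)
  un <- ape::unroot(tr)
  expect_equal(sum(un$edge[, 2] > length(un$tip.label)), 1L)  # one internal edge
  expect_identical(write_newick(simulate_species_tree(9, seed = 5)),
                   write_newick(simulate_species_tree(9, seed = 5)))
  expect_false(identical(write_newick(simulate_species_tree(9, seed = 5)),
                         write_newick(simulate_species_tree(9, seed = 6))))
  expect_equal(sort(tr$tip.label), sprintf("t%03d", 1:4))
})

test_that("mean pendant branch length tracks an independent Yule simulator", {
  n <- 10; lambda <- 1
  mean_pendant <- function(tree) {
    n_tip <- length(tree$tip.label)
    mean(tree$edge.length[tree$edge[, 2] <= n_tip])
  }
  mine <- mean(vapply(1:100, function(s) {
    mean_pendant(simulate_species_tree(n, lambda, seed = s))
  }, numeric(1)))
  # independent bare-bones Yule: track per-lineage birth times only
  set.seed(4242)
  indep <- replicate(300, {
    births <- c(0, 0); t <- 0; k <- 2
    while (k < n) {
      t <- t + rexp(1, k * lambda)
      i <- sample.int(k, 1)
      births[i] <- t; births <- c(births, t)
      k <- k + 1
    }
    t <- t + rexp(1, n * lambda)
    mean(t - births)
  })
  expect_gt(mine, mean(indep) / 2)
  expect_lt(mine, mean(indep) * 2)
})

test_that("HGT events change the topology and are fully recorded", {
  sp <- simulate_species_tree(10, seed = 7)
  none <- apply_hgt(sp, 0, seed = 1)
  expect_equal(robinson_foulds(none$gene_tree, sp)$rf_distance, 0L)
  expect_equal(nrow(none$events), 0L)
  one <- apply_hgt(sp, 1, seed = 2)
  expect_gt(robinson_foulds(one$gene_tree, sp)$rf_distance, 0L)
  expect_equal(nrow(one$events), 1L)
  three <- apply_hgt(sp, 3, seed = 3)
  expect_equal(nrow(three$events), 3L)
  expect_true(all(three$events$recipient %in% sp$tip.label))
})

test_that("zero-length branches copy the root everywhere", {
  tr <- read_newick("((a:0,b:0):0,(c:0,d:0):0);")
  ev <- evolve_sequences(tr, substitution_model(), 120, seed = 5)
  expect_equal(length(unique(ev$sequences$residues)), 1L)
  expect_equal(ev$sequences$residues[1], ev$root)
})

test_that("simulated transition/transversion proportions match the K80 closed form", {
  # two taxa separated by t = 0.1 at kappa = 4: expected P and Q come from
  # the transition matrix row (probability of observing a transition /
  # transversion at distance t)
  m <- substitution_model(kappa = 4, p_inv = 0, n_categories = 1)
  t <- 0.1
  P_exp <- transition_probability(m, t)[1, 3]      # A -> G
  Q_exp <- 2 * transition_probability(m, t)[1, 2]  # A -> C or T
  tr <- read_newick("(x:0.1,y:0);")
  props <- vapply(1:20, function(s) {
    ev <- evolve_sequences(tr, m, 10000, seed = s)
    a <- strsplit(ev$sequences$residues[1], "")[[1]]
    b <- strsplit(ev$sequences$residues[2], "")[[1]]
    purine <- c("A", "G")
    diff <- a != b
    ts <- diff & ((a %in% purine) == (b %in% purine))
    c(mean(ts), mean(diff & !ts))
  }, numeric(2))
  expect_lt(abs(mean(props[1, ]) - P_exp), 0.15 * P_exp)
  expect_lt(abs(mean(props[2, ]) - Q_exp), 0.15 * Q_exp)
})

test_that("half-invariant models leave at least 40% of sites constant", {
  m <- substitution_model(kappa = 4, alpha = 1, p_inv = 0.5)
  tr <- read_newick(paste0("((a:0.2,b:0.2):0.1,(c:0.2,d:0.2):0.1,",
                           "(e:0.2,f:0.2):0.1);"))
  rooted <- ape::root(tr, outgroup = "a", resolve.root = TRUE)
  ev <- evolve_sequences(rooted, m, 2000, seed = 8)
  mat <- do.call(rbind, strsplit(ev$alignment$residues, ""))
  const <- mean(apply(mat, 2, function(col) length(unique(col)) == 1L))
  expect_gte(const, 0.40)
})

test_that("implanted amplicons are exactly recoverable by in-silico PCR", {
  set.seed(91)
  pp <- cbt_primer_pair()
  cores <- seq_set(c("t1", "t2", "t3"), replicate(3, random_dna(769)))
  imp <- implant_amplicon(cores, pp, flank_length = 250, seed = 9)
  expect_equal(imp$coordinates$product_length, rep(804L, 3))
  for (i in 1:3) {
    hits <- pcr_products(pp, imp$templates[i, , drop = FALSE],
                         product_length_range = c(700, 900))
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$start, imp$coordinates$start[i])
    expect_equal(hits$end, imp$coordinates$end[i])
  }
  # negative-control analogue: strip the forward site from one template
  broken <- imp$templates
  substr(broken$residues[1], 251, 267) <- strrep("A", 17)
  hits <- pcr_products(pp, broken[1, , drop = FALSE],
                       product_length_range = c(700, 900))
  expect_equal(nrow(hits), 0L)
})

test_that("paralog families diverge as configured", {
  m <- substitution_model()
  tr <- simulate_species_tree(6, seed = 10)
  tr <- cyanoscreen:::.rescale_depth(tr, 0.1)
  root <- random_dna(600)
  near <- emit_paralogs(root, 0.01, tr, m, seed = 11)
  expect_true(all(grepl("_G$", near$id)))
  identity <- function(a, b) {
    mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  }
  a_fam <- cyanoscreen:::evolve_root_down(root, tr, m, seed = 12)
  ids <- vapply(seq_len(nrow(near)), function(i) {
    identity(a_fam$residues[i], near$residues[i])
  }, numeric(1))
  expect_gt(mean(ids), 0.7)   # shallow tree + tiny divergence stay similar
  far <- emit_paralogs(root, 1.0, tr, m, seed = 13)
  ids_far <- vapply(seq_len(nrow(far)), function(i) {
    identity(a_fam$residues[i], far$residues[i])
  }, numeric(1))
  expect_lt(mean(ids_far), mean(ids))
})

test_that("emit_dataset writes the full artifact set deterministically", {
  spec <- simulation_spec(n_taxa = 6, n_hgt_events = 1, core_length = 200,
                          seed = 14)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  b1 <- emit_dataset(spec, d1)
  b2 <- emit_dataset(spec, d2)
  files <- c("genomes.fasta", "genes.fasta", "amplicons.fasta",
             "species_tree.nwk", "gene_tree.nwk", "hgt_events.tsv",
             "amplicon_coordinates.tsv", "class_labels.tsv")
  expect_true(all(file.exists(file.path(d1, files))))
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  expect_equal(nrow(b1$labels), 12L)  # 6 A + 6 G
  expect_setequal(unique(b1$labels$label), c("A", "G"))
  expect_equal(b1$hgt_events$event, 1L)
  # truth amplicon coordinates are what PCR recovers at 0 mismatches
  scr <- pcr_screen(spec$primer_pair, b1$genomes,
                    product_length_range = c(150, 300))
  expect_true(all(scr$screen$positive))
  expect_equal(scr$hits$start, b1$amplicon_coordinates$start)
})
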