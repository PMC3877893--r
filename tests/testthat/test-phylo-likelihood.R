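two_tip_tree <- function(t1, t2) {
  structure(list(
    edge = matrix(c(3L, 3L, 1L, 2L), 2, 2),
    edge.length = c(t1, t2),
    tip.label = c("x", "y"), Nnode = 1L
  ), class = "phylo", order = "cladewise")
}

test_that("identical sequences at zero distance give L * log(1/4)", {
  L <- 40L
  aln <- as_alignment(seq_set(c("x", "y"), rep(random_dna(L), 2)))
  m <- substitution_model(p_inv = 0)
  ll <- log_likelihood(two_tip_tree(0, 0), aln, m)
  expect_equal(ll, L * log(0.25), tolerance = 1e-10)
})

test_that("pruning equals brute-force enumeration on a 4-taxon tree", {
  skip_if_not_installed("Matrix")
  set.seed(51)
  tr <- read_newick("((a:0.12,b:0.3):0.08,(c:0.2,d:0.05):0.08);")
  aln <- as_alignment(seq_set(
    c("a", "b", "c", "d"),
    c("ACGTN", "AC-TA", "GCGTA", "ACTTA")  # includes gap and ambiguity
  ))
  for (rep in 1:3) {
    m <- substitution_model(kappa = runif(1, 0.5, 8),
                            alpha = runif(1, 0.2, 2),
                            p_inv = runif(1, 0, 0.4), n_categories = 3)
    expect_equal(log_likelihood(tr, aln, m), oracle_loglik(tr, aln, m),
                 tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to re-rooting (pulley principle)", {
  set.seed(52)
  tr <- read_newick("((a:0.1,b:0.25):0.07,(c:0.15,d:0.3):0.07,e:0.2);")
  rooted <- ape::root(tr, outgroup = "e", resolve.root = TRUE)
  ev <- evolve_sequences(rooted, substitution_model(), 300, seed = 9)
  m <- substitution_model()
  base <- log_likelihood(tr, ev$alignment, m)
  for (og in c("a", "c", "e")) {
    rr <- ape::root(tr, outgroup = og, resolve.root = FALSE)
    expect_equal(log_likelihood(rr, ev$alignment, m), base,
                 tolerance = 1e-8, info = og)
  }
})

test_that("alpha -> Inf with p_inv = 0 collapses K2P+G+I to plain K2P", {
  set.seed(53)
  tr <- read_newick("((a:0.1,b:0.2):0.05,(c:0.12,d:0.22):0.05);")
  ev <- evolve_sequences(ape::root(tr, outgroup = "a", resolve.root = TRUE),
                         substitution_model(), 250, seed = 10)
  flat <- substitution_model(kappa = 4, alpha = 1e6, p_inv = 0,
                             n_categories = 5)
  plain <- substitution_model(kappa = 4, alpha = 1, p_inv = 0,
                              n_categories = 1)
  expect_equal(log_likelihood(tr, ev$alignment, flat),
               log_likelihood(tr, ev$alignment, plain), tolerance = 1e-6)
})

test_that("two-taxon ML branch length equals the closed-form K2P distance", {
  set.seed(54)
  tr <- two_tip_tree(0.08, 0.08)
  rooted <- tr
  ev <- evolve_sequences(rooted, substitution_model(p_inv = 0,
                                                    n_categories = 1),
                         2000, seed = 11)
  # kappa is fitted too: the closed-form K2P distance profiles over both
  # t and kappa, so the comparable ML fit must leave kappa free
  m <- substitution_model(p_inv = 0, n_categories = 1)
  opt <- optimize_phylo(tr, ev$alignment, m, fit_model = TRUE,
                        fit_params = "kappa",
                        tol = 1e-9, max_sweeps = 200, warn = FALSE)
  ml_len <- sum(opt$tree$edge.length)
  d <- k2p_distance(ev$alignment$residues[1], ev$alignment$residues[2])
  expect_lt(abs(ml_len - d$distance), 1e-4)
})

test_that("likelihood agrees with an independent implementation (phangorn)", {
  skip_if_not_installed("phangorn")
  set.seed(55)
  tr <- read_newick(paste0("((a:0.1,b:0.2):0.06,(c:0.15,d:0.1):0.04,",
                           "(e:0.2,f:0.12):0.08);"))
  ev <- evolve_sequences(ape::root(tr, outgroup = "a", resolve.root = TRUE),
                         substitution_model(), 500, seed = 12)
  m <- substitution_model(kappa = 4, alpha = 0.5, p_inv = 0,
                          n_categories = 5)
  mine <- log_likelihood(tr, ev$alignment, m)
  dat <- phangorn::phyDat(do.call(rbind, strsplit(ev$alignment$residues, "")),
                          type = "DNA")
  names(dat) <- ev$alignment$id
  fit <- phangorn::pml(tr, dat, bf = rep(0.25, 4),
                       Q = c(1, 4, 1, 1, 4, 1), k = 5, shape = 0.5, inv = 0)
  expect_equal(mine, fit$logLik, tolerance = 1e-4)
})

test_that("leaf/alignment mismatches are rejected", {
  aln <- as_alignment(seq_set(c("x", "z"), c("ACGT", "ACGA")))
  expect_error(log_likelihood(two_tip_tree(0.1, 0.1), aln,
                              substitution_model()),
               "differ")
})
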