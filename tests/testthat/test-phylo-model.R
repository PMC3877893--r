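test_that("K2P distance matches the closed form and reports components", {
  same <- k2p_distance("ACGTACGT", "ACGTACGT")
  expect_equal(same$distance, 0)
  expect_equal(same$p_transitions, 0)

  # 100 sites, 10 transitions (A->G), 5 transversions (A->C)
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 10), strrep("C", 5), strrep("A", 85))
  d <- k2p_distance(a, b)
  expect_equal(d$p_transitions, 0.1)
  expect_equal(d$q_transversions, 0.05)
  expect_equal(d$sites_compared, 100L)
  expect_equal(d$distance, -0.5 * log(0.75) - 0.25 * log(0.90),
               tolerance = 1e-12)
})

test_that("pairwise deletion skips gapped and ambiguous sites", {
  d <- k2p_distance("ACGT-NACGT", "ACGTTTACGA")
  expect_equal(d$sites_compared, 8L)  # gap and N columns dropped
  expect_error(k2p_distance("----", "ACGT"), "no comparable sites")
  expect_error(k2p_distance("ACG", "ACGT"), "length")
})

test_that("K2P distance is symmetric and errors cleanly at saturation", {
  set.seed(41)
  for (rep in 1:10) {
    a <- random_dna(200); b <- random_dna(200)
    da <- tryCatch(k2p_distance(a, b)$distance, error = function(e) NA)
    db <- tryCatch(k2p_distance(b, a)$distance, error = function(e) NA)
    expect_equal(da, db)
  }
  expect_error(k2p_distance(strrep("A", 50), strrep("G", 50)), "saturated")
})

test_that("discrete gamma rates are slice means with mean exactly one", {
  for (alpha in c(0.2, 0.5, 1, 2, 10)) {
    r <- gamma_category_rates(alpha, 5)
    expect_length(r, 5)
    expect_equal(mean(r), 1, tolerance = 1e-12)
    expect_true(all(diff(r) > 0))
    skip_if_not_installed("phangorn")
    ph <- phangorn::discrete.gamma(alpha, 5)
    expect_equal(r, ph / mean(ph), tolerance = 1e-8)
  }
  expect_equal(gamma_category_rates(0.5, 1), 1)
})

test_that("transition probabilities hit the limit cases", {
  m <- substitution_model(kappa = 4)
  expect_equal(transition_probability(m, 0), diag(4),
               ignore_attr = TRUE)
  far <- transition_probability(m, 500)
  expect_equal(as.numeric(far), rep(0.25, 16), tolerance = 1e-8)
  P <- transition_probability(m, 0.3)
  expect_equal(rowSums(P), rep(1, 4), ignore_attr = TRUE)
})

test_that("transition probabilities match the matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  m_grid <- expand.grid(kappa = c(0.5, 1, 2, 4, 10),
                        t = c(0.01, 0.1, 0.5, 1, 3))
  for (i in seq_len(nrow(m_grid))) {
    kappa <- m_grid$kappa[i]; t <- m_grid$t[i]
    mine <- transition_probability(substitution_model(kappa = kappa), t)
    expect_equal(unname(as.matrix(mine)), oracle_expm_pmat(kappa, t),
                 tolerance = 1e-10,
                 info = sprintf("kappa=%g t=%g", kappa, t))
  }
})

test_that("kappa = 1 reduces to the Jukes-Cantor closed form", {
  m <- substitution_model(kappa = 1)
  for (t in c(0.05, 0.2, 1)) {
    P <- transition_probability(m, t)
    jc_same <- 0.25 + 0.75 * exp(-4 * t / 3)
    jc_diff <- 0.25 - 0.25 * exp(-4 * t / 3)
    expect_equal(unname(diag(P)), rep(jc_same, 4), tolerance = 1e-12)
    expect_equal(P[1, 2], jc_diff, tolerance = 1e-12)
    expect_equal(P[1, 3], jc_diff, tolerance = 1e-12)
  }
})

test_that("neighbor joining recovers closed forms and additive trees", {
  # 3 taxa: pendant length b_A = (d_AB + d_AC - d_BC) / 2
  D <- matrix(c(0, 0.3, 0.5, 0.3, 0, 0.4, 0.5, 0.4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  bA <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "A")]
  expect_equal(bA, (0.3 + 0.5 - 0.4) / 2, tolerance = 1e-10)

  # additive 5-taxon matrix from a known tree is exactly recovered
  truth <- read_newick("((a:0.1,b:0.2):0.05,(c:0.15,d:0.1):0.07,e:0.3);")
  D5 <- ape::cophenetic.phylo(truth)
  rec <- nj_tree(D5)
  expect_equal(robinson_foulds(rec, truth)$rf_distance, 0L)
  expect_equal(ape::cophenetic.phylo(rec)[rownames(D5), colnames(D5)], D5,
               tolerance = 1e-10)
})

test_that("NJ topology is invariant to taxon order and validates input", {
  truth <- read_newick("((a:0.1,b:0.2):0.05,(c:0.15,d:0.1):0.07,e:0.3);")
  D5 <- ape::cophenetic.phylo(truth)
  perm <- c("d", "a", "e", "b", "c")
  rec1 <- nj_tree(D5)
  rec2 <- nj_tree(D5[perm, perm])
  expect_equal(robinson_foulds(rec1, rec2)$rf_distance, 0L)
  bad <- D5; bad[1, 2] <- Inf; bad[2, 1] <- Inf
  expect_error(nj_tree(bad), "non-finite")
  expect_error(nj_tree(D5[1:2, 1:2]), "at least 3")
})
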