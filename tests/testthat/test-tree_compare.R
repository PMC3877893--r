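# read a Newick whose internal-node labels are bootstrap supports
supported_tree <- function(newick) read_newick(newick)

test_that("clade extraction respects the support threshold", {
  # fully supported tree: n - 3 non-trivial clades
  tr <- ape::rtree(7)
  tr$node.label <- rep("100", tr$Nnode)
  cs <- extract_clades(tr, threshold = 70)
  expect_length(cs$clades, 7 - 3)
  expect_length(extract_clades(tr, threshold = 101)$clades, 0)
  expect_error(extract_clades(ape::rtree(5), 70), "bootstrap")
})

test_that("a six-taxon fixture keeps exactly the high-support edge", {
  tr <- supported_tree("(((a:1,b:1)95:1,(c:1,d:1)60:1)40:1,e:1,f:1);")
  cs <- extract_clades(tr, threshold = 70)
  expect_length(cs$clades, 1L)
  expect_equal(cs$clades[[1]]$members, c("a", "b"))
  expect_equal(cs$clades[[1]]$support, 95)
  # monotone: lowering the threshold only adds clades
  cs50 <- extract_clades(tr, threshold = 50)
  expect_gte(length(cs50$clades), length(cs$clades))
})

test_that("Robinson-Foulds matches explicit split enumeration", {
  t1 <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  t2 <- read_newick("((A:1,C:1):1,(B:1,D:1):1);")
  expect_equal(robinson_foulds(t1, t1)$rf_distance, 0L)
  r <- robinson_foulds(t1, t2)
  expect_equal(r$rf_distance, 2L)
  expect_equal(r$max_rf, 2L)
  expect_equal(r$normalized_rf, 1)
})

test_that("RF equals phangorn on fuzzed tree pairs", {
  skip_if_not_installed("phangorn")
  set.seed(81)
  for (rep in 1:100) {
    n <- sample(4:10, 1)
    t1 <- ape::rtree(n)
    t2 <- ape::rtree(n)
    mine <- robinson_foulds(t1, t2)$rf_distance
    ph <- phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2))
    expect_equal(mine, ph)
  }
})

test_that("RF behaves as a metric on fuzzed triples", {
  set.seed(82)
  for (rep in 1:20) {
    n <- sample(5:8, 1)
    trees <- lapply(1:3, function(i) ape::rtree(n))
    d12 <- robinson_foulds(trees[[1]], trees[[2]])$rf_distance
    d21 <- robinson_foulds(trees[[2]], trees[[1]])$rf_distance
    d13 <- robinson_foulds(trees[[1]], trees[[3]])$rf_distance
    d23 <- robinson_foulds(trees[[2]], trees[[3]])$rf_distance
    expect_equal(d12, d21)
    expect_lte(d13, d12 + d23)
    expect_equal(robinson_foulds(trees[[1]], trees[[1]])$rf_distance, 0L)
  }
})

test_that("pruning to shared leaves merges pendant branch lengths", {
  t1 <- read_newick("((a:0.1,b:0.2):0.3,(c:0.4,d:0.5):0.6,e:0.7);")
  t2 <- read_newick("((a:1,b:1):1,(c:1,e:1):1);")
  pr <- prune_shared(t1, t2)
  expect_setequal(pr$t1$tip.label, c("a", "b", "c", "e"))
  # dropping d merges c's pendant (0.4) with the internal edge (0.6)
  c_len <- pr$t1$edge.length[pr$t1$edge[, 2] ==
                               which(pr$t1$tip.label == "c")]
  expect_equal(c_len, 1.0)
  expect_error(prune_shared(t1, read_newick("(a:1,b:1,(x:1,y:1):1);")),
               "share only")
})

test_that("displaced-taxon search recovers a single moved taxon", {
  # species tree and a gene tree where only "f" moved
  sp <- read_newick(paste0("((a:1,b:1):1,((c:1,d:1):1,",
                           "(e:1,f:1):1):1,(g:1,h:1):1);"))
  gn <- read_newick(paste0("(((a:1,f:1):1,b:1):1,((c:1,d:1):1,",
                           "e:1):1,(g:1,h:1):1);"))
  d <- displaced_taxa(sp, gn)
  expect_equal(d$taxon[1], "f")
  expect_equal(d$rf_after_removal[1], 0L)
  expect_true(all(diff(c(robinson_foulds(sp, gn)$rf_distance,
                         d$rf_after_removal)) < 0))
  # congruent trees yield an empty list
  expect_equal(nrow(displaced_taxa(sp, sp)), 0L)
})

test_that("novel clades require >= 2 query taxa and no chemotype member", {
  tr <- supported_tree(paste0(
    "(((q1:1,q2:1)90:1,(q3:1,q4:1)85:1)88:1,",
    "((anno1:1,anno2:1)91:1,(anno3:1,q5:1)92:1)89:1,anno4:1);"))
  ann <- c(q1 = "query", q2 = "query", q3 = "query", q4 = "query",
           q5 = "query", anno1 = "anacyclamide", anno2 = "patellamide",
           anno3 = "microcyclamide", anno4 = "trichamide")
  cs <- extract_clades(tr, threshold = 70)
  res <- flag_novel_clades(cs, ann)
  members <- lapply(res$novel, `[[`, "members")
  # the maximal pure-query clade {q1..q4}; its sub-clades are absorbed
  expect_true(list(c("q1", "q2", "q3", "q4")) %in% members ||
                any(vapply(members, identical, logical(1),
                           y = c("q1", "q2", "q3", "q4"))))
  expect_false(any(vapply(members, function(m) "q5" %in% m, logical(1))))
  expect_equal(res$loners, "q5")
  expect_error(flag_novel_clades(cs, ann[-1]), "unannotated")
})

test_that("no supported clades means no novel clades", {
  tr <- supported_tree("((a:1,b:1)10:1,(c:1,d:1)20:1);")
  cs <- extract_clades(tr, threshold = 70)
  res <- flag_novel_clades(cs, c(a = "query", b = "query",
                                 c = "query", d = "query"))
  expect_length(res$novel, 0)
})
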