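# Independent oracles used across tests. These deliberately avoid the code
# paths they check: expansion-based string search, exhaustive alignment
# enumeration, brute-force likelihood summation with matrix-exponential
# transition probabilities, and split-set enumeration via phangorn.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# every plain string a degenerate IUPAC pattern denotes (expand.grid based)
oracle_expand <- function(x) {
  sets <- IUPAC_SETS[strsplit(x, "")[[1]]]
  grid <- do.call(expand.grid, c(sets, stringsAsFactors = FALSE))
  unique(apply(grid, 1L, paste, collapse = ""))
}

oracle_revcomp_plain <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# all primer sites by full expansion + fixed substring search, both strands,
# forward-strand 0-based coordinates (mismatch-free matching only)
oracle_find_sites <- function(primer, template) {
  hits <- list()
  for (exp_ in oracle_expand(primer)) {
    for (strand in c("+", "-")) {
      needle <- if (strand == "+") exp_ else oracle_revcomp_plain(exp_)
      p <- gregexpr(needle, template, fixed = TRUE)[[1]]
      # gregexpr misses overlapping matches; rescan manually
      starts <- integer(0)
      from <- 1L
      while (TRUE) {
        hit <- regexpr(needle, substr(template, from, nchar(template)),
                       fixed = TRUE)
        if (hit == -1L) break
        starts <- c(starts, from + hit - 1L)
        from <- from + hit
      }
      if (length(starts)) {
        hits[[length(hits) + 1L]] <- data.frame(start = starts - 1L,
                                                strand = strand)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(0), strand = character(0)))
  }
  out <- unique(do.call(rbind, hits))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exhaustive global alignment score under affine gaps (gap of length L costs
# open + (L-1) * extend); enumerates every alignment of a and b
oracle_nw_score <- function(a, b, match = 1, mismatch = -1,
                            gap_open = -4, gap_extend = -1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  score_pair <- function(ra, rb) {
    s <- 0; run_a <- FALSE; run_b <- FALSE
    for (i in seq_along(ra)) {
      if (ra[i] == "-") {
        s <- s + if (run_a) gap_extend else gap_open
        run_a <- TRUE; run_b <- FALSE
      } else if (rb[i] == "-") {
        s <- s + if (run_b) gap_extend else gap_open
        run_b <- TRUE; run_a <- FALSE
      } else {
        s <- s + if (ra[i] == rb[i]) match else mismatch
        run_a <- run_b <- FALSE
      }
    }
    s
  }
  best <- -Inf
  recurse <- function(i, j, ra, rb) {
    if (i > length(a) && j > length(b)) {
      best <<- max(best, score_pair(ra, rb))
      return(invisible())
    }
    if (i <= length(a) && j <= length(b)) {
      recurse(i + 1L, j + 1L, c(ra, a[i]), c(rb, b[j]))
    }
    if (i <= length(a)) recurse(i + 1L, j, c(ra, a[i]), c(rb, "-"))
    if (j <= length(b)) recurse(i, j + 1L, c(ra, "-"), c(rb, b[j]))
  }
  recurse(1L, 1L, character(0), character(0))
  best
}

# brute-force tree likelihood: sums over all internal-node state
# assignments, with transition probabilities from a matrix exponential of
# the K80 rate matrix (independent of the package's closed form)
oracle_expm_pmat <- function(kappa, d) {
  beta <- 1 / (kappa + 2)
  Q <- matrix(beta, 4, 4)
  # order A, C, G, T; transitions A<->G (1,3) and C<->T (2,4)
  Q[1, 3] <- Q[3, 1] <- Q[2, 4] <- Q[4, 2] <- kappa * beta
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  as.matrix(Matrix::expm(Q * d))
}

oracle_loglik <- function(tree, alignment, model) {
  bases <- c("A", "C", "G", "T")
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  mat <- do.call(rbind, strsplit(alignment$residues, ""))
  rownames(mat) <- alignment$id
  mat <- mat[tree$tip.label, , drop = FALSE]
  compat <- function(ch) {
    if (ch == "-") bases else IUPAC_SETS[[ch]]
  }
  K <- model$n_categories
  rates <- model$category_rates
  total <- 0
  internals <- (n_tip + 1L):n_node
  grid <- do.call(expand.grid, rep(list(1:4), length(internals)))
  Pcache <- lapply(seq_len(K), function(k) {
    lapply(seq_len(nrow(tree$edge)), function(e) {
      oracle_expm_pmat(model$kappa, tree$edge.length[e] * rates[k])
    })
  })
  for (site in seq_len(ncol(mat))) {
    sets <- lapply(mat[, site], compat)
    m <- length(Reduce(intersect, sets))
    var_part <- 0
    for (k in seq_len(K)) {
      P <- Pcache[[k]]
      lik <- 0
      for (g in seq_len(nrow(grid))) {
        assign_ <- as.integer(grid[g, ])
        state_of <- function(nd) assign_[match(nd, internals)]
        term <- 0.25
        ok <- TRUE
        for (e in seq_len(nrow(tree$edge))) {
          par <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
          x <- state_of(par)
          if (ch <= n_tip) {
            # sum over compatible leaf states
            term <- term * sum(P[[e]][x, match(sets[[ch]], bases)])
          } else {
            term <- term * P[[e]][x, state_of(ch)]
          }
          if (term == 0) { ok <- FALSE; break }
        }
        if (ok) lik <- lik + term
      }
      var_part <- var_part + lik
    }
    site_lik <- model$p_inv * m / 4 + (1 - model$p_inv) * var_part / K
    total <- total + log(site_lik)
  }
  total
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random seq_set of ungapped sequences
random_records <- function(n, len_range = c(20, 60)) {
  seq_set(sprintf("s%02d", seq_len(n)),
          vapply(seq_len(n), function(i) {
            random_dna(sample(seq(len_range[1], len_range[2]), 1L))
          }, character(1)),
          description = ifelse(seq_len(n) %% 2 == 0, "even record", ""))
}
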