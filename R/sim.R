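## Synthetic-data generator: the testing ground truth the wet-lab screen
## lacked. Simulates a Yule species tree, horizontal transfers of the gene
## (SPR moves), sequence evolution under K2P+G+I, implanted degenerate
## primer-binding sites flanking the evolved core, and a diverged paralogous
## G-gene family. Every operation is a pure function of (spec, seed).

#' Derive a reproducible sub-seed from a master seed and a stage label
#'
#' Polynomial rolling hash of the label folded into the seed, kept below
#' 2^31 so it is always a valid R integer.
#'
#' @param seed master integer seed.
#' @param label stage name.
#' @return integer sub-seed.
#' @export
derive_seed <- function(seed, label) {
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 131 + code) %% 2147483629
  as.integer((abs(as.numeric(seed)) + h) %% 2147483629)
}

#' Simulation settings for the synthetic screen
#'
#' Defaults describe the standard study conditions: 12 taxa, 2 horizontal
#' transfers, the K2P+G+I model with kappa = 4, alpha = 0.5, p_inv = 0.1 and
#' 5 rate categories, the published CBT primer pair with a 769-base evolved
#' core (so the implanted product footprint totals 804 bases), G-paralogs at
#' divergence 1.0 substitutions/site, and indel-free evolution so the true
#' alignment is trivially known.
#'
#' @param n_taxa number of taxa (>= 4; default 12).
#' @param birth_rate Yule speciation rate (default 1).
#' @param n_hgt_events number of horizontal transfers (default 2;
#'   must be < n_taxa).
#' @param model a "substitution_model" (default kappa 4, alpha 0.5,
#'   p_inv 0.1, 5 categories).
#' @param core_length evolved bases between the primer sites (default 769).
#' @param primer_pair a "primer_pair" (default [cbt_primer_pair()]).
#' @param paralog_divergence expected substitutions/site separating the
#'   G-gene family from the A-gene root (default 1.0).
#' @param indel_rate single-base deletion rate per site per unit branch
#'   length (default 0).
#' @param flank_length random flank on each side of the implanted amplicon
#'   in genomic templates (default 300).
#' @param tree_scale expected root-to-tip depth (substitutions/site) the
#'   species tree is rescaled to before sequence evolution (default 0.3, a
#'   strong but unsaturated signal).
#' @param seed master seed (default 1).
#' @return list of class "simulation_spec".
#' @export
simulation_spec <- function(n_taxa = 12L, birth_rate = 1, n_hgt_events = 2L,
                            model = substitution_model(),
                            core_length = 769L,
                            primer_pair = cbt_primer_pair(),
                            paralog_divergence = 1.0, indel_rate = 0,
                            flank_length = 300L, tree_scale = 0.3,
                            seed = 1L) {
  stopifnot(n_taxa >= 4L, n_hgt_events < n_taxa, birth_rate > 0,
            core_length >= 100L, paralog_divergence >= 0, indel_rate >= 0,
            tree_scale > 0)
  structure(
    list(n_taxa = as.integer(n_taxa), birth_rate = birth_rate,
         n_hgt_events = as.integer(n_hgt_events), model = model,
         core_length = as.integer(core_length), primer_pair = primer_pair,
         paralog_divergence = paralog_divergence, indel_rate = indel_rate,
         flank_length = as.integer(flank_length), tree_scale = tree_scale,
         seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

#' Simulate a Yule (pure-birth) species tree
#'
#' Lineages split at rate `birth_rate` each; the process runs until `n_taxa`
#' lineages exist plus one final waiting time, so pendant branches have
#' positive length. Leaf labels are t001..tN in birth order.
#'
#' @param n_taxa number of leaves (>= 4).
#' @param birth_rate per-lineage speciation rate (> 0).
#' @param seed integer seed.
#' @return a rooted "phylo" tree.
#' @export
simulate_species_tree <- function(n_taxa, birth_rate = 1, seed = 1L) {
  stopifnot(n_taxa >= 4L)
  set.seed(seed)
  parent <- c(0L, 1L, 1L); birth <- c(0, 0, 0); end <- rep(NA_real_, 3L)
  active <- c(2L, 3L)
  t <- 0
  while (length(active) < n_taxa) {
    k <- length(active)
    t <- t + stats::rexp(1L, rate = k * birth_rate)
    i <- active[sample.int(k, 1L)]
    end[i] <- t
    parent <- c(parent, i, i); birth <- c(birth, t, t)
    end <- c(end, NA_real_, NA_real_)
    active <- c(setdiff(active, i), length(parent) - 1L, length(parent))
  }
  t_end <- t + stats::rexp(1L, rate = n_taxa * birth_rate)
  end[active] <- t_end
  is_leaf <- seq_along(parent) %in% active
  leaf_label <- character(length(parent))
  leaf_label[sort(active)] <- sprintf("t%03d", seq_len(n_taxa))
  build <- function(i) {
    if (is_leaf[i]) return(leaf_label[i])
    kids <- which(parent == i)
    sub <- vapply(kids, function(k) {
      sprintf("%s:%.8f", build(k), end[k] - birth[k])
    }, character(1))
    sprintf("(%s)", paste(sub, collapse = ","))
  }
  read_newick(paste0(build(1L), ";"))
}

#' Apply horizontal gene transfers to a species tree
#'
#' Each event prunes a uniformly chosen recipient leaf and regrafts it onto
#' a uniformly chosen edge of the remaining tree (a subtree-prune-regraft
#' move), redrawing (bounded retries) whenever the move fails to change the
#' unrooted topology. Events are recorded in order.
#'
#' @param species_tree a "phylo" with >= 6 leaves.
#' @param n_events number of transfers (< leaves - 2).
#' @param seed integer seed.
#' @return list: `gene_tree` (a "phylo"), `events` (data.frame: `event`,
#'   `recipient`, `donor_split` — the leaf set below the regraft edge).
#' @export
apply_hgt <- function(species_tree, n_events, seed = 1L) {
  n_tip <- length(species_tree$tip.label)
  stopifnot(n_events < n_tip - 2L)
  set.seed(seed)
  tree <- species_tree
  events <- list()
  for (ev in seq_len(n_events)) {
    placed <- FALSE
    for (try in seq_len(50L)) {
      recipient <- sample(tree$tip.label, 1L)
      pruned <- ape::drop.tip(tree, recipient)
      sets <- .node_leafsets(pruned)
      pruned <- ape::reorder.phylo(pruned, "postorder")
      e_row <- sample.int(nrow(pruned$edge), 1L)
      child <- pruned$edge[e_row, 2L]
      pend_len <- tree$edge.length[tree$edge[, 2L] ==
                                     which(tree$tip.label == recipient)]
      cand <- phytools::bind.tip(
        pruned, recipient, edge.length = pend_len,
        where = child, position = pruned$edge.length[e_row] / 2
      )
      if (robinson_foulds(cand, tree)$rf_distance > 0L) {
        donor_set <- sets[[child]]
        events[[ev]] <- data.frame(
          event = ev, recipient = recipient,
          donor_split = paste(sort(donor_set), collapse = "|"),
          stringsAsFactors = FALSE
        )
        tree <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("no topology-changing regraft found after 50 retries",
                      call. = FALSE)
  }
  list(gene_tree = tree,
       events = if (length(events)) do.call(rbind, events) else
         data.frame(event = integer(0), recipient = character(0),
                    donor_split = character(0), stringsAsFactors = FALSE))
}

#' Evolve sequences along a tree under K2P+G+I
#'
#' The root sequence is uniform over ACGT. Each site draws, once for the
#' whole tree, either invariant status (probability p_inv) or a rate
#' category; descendants then mutate via the K2P transition probabilities at
#' each edge's length times the site rate. With `indel_rate > 0`, single-base
#' deletions occur per site per edge with probability
#' `indel_rate * edge_length` and appear as gaps in the true alignment.
#'
#' @param tree a rooted "phylo" with branch lengths.
#' @param model a "substitution_model".
#' @param length number of sites (>= 100).
#' @param indel_rate single-base deletion rate (default 0).
#' @param seed integer seed.
#' @return list: `alignment` (the true "seq_alignment", gapped iff
#'   indel_rate > 0), `sequences` (ungapped "seq_set"), `root` (the root
#'   sequence string), `site_rates` (numeric; 0 marks invariant sites).
#' @export
evolve_sequences <- function(tree, model, length, indel_rate = 0, seed = 1L) {
  stopifnot(length >= 100L)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  tree <- ape::reorder.phylo(tree, "postorder")
  root <- n_tip + 1L
  invariant <- stats::runif(length) < model$p_inv
  cat_idx <- sample.int(model$n_categories, length, replace = TRUE)
  site_rate <- ifelse(invariant, 0, model$category_rates[cat_idx])
  seqs <- matrix(0L, n_node, length)  # base indices 1..4; 0 = deleted
  seqs[root, ] <- sample.int(4L, length, replace = TRUE)
  edge_order <- rev(seq_len(nrow(tree$edge)))  # preorder: parents first
  for (e in edge_order) {
    par <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    t_e <- tree$edge.length[e]
    child <- seqs[par, ]
    for (k in seq_len(model$n_categories)) {
      P <- transition_probability(model, t_e, model$category_rates[k])
      for (b in 1:4) {
        sel <- which(!invariant & cat_idx == k & seqs[par, ] == b)
        if (length(sel)) {
          child[sel] <- sample.int(4L, length(sel), replace = TRUE,
                                   prob = P[b, ])
        }
      }
    }
    deleted <- which(seqs[par, ] == 0L)
    if (length(deleted)) child[deleted] <- 0L
    if (indel_rate > 0) {
      del <- stats::runif(length) < indel_rate * t_e
      child[del] <- 0L
    }
    seqs[ch, ] <- child
  }
  rows <- vapply(seq_len(n_tip), function(i) {
    ch <- c("-", bases)[seqs[i, ] + 1L]
    paste(ch, collapse = "")
  }, character(1))
  aln <- as_alignment(seq_set(tree$tip.label, rows))
  list(alignment = aln,
       sequences = seq_set(tree$tip.label, degap(rows)),
       root = paste(bases[seqs[root, ]], collapse = ""),
       site_rates = site_rate)
}

#' Implant primer-flanked amplicons into random genomic context
#'
#' For each evolved core sequence, writes one random plain expansion of the
#' forward primer and the reverse complement of one random expansion of the
#' reverse primer immediately flanking the core, embedded in random flank
#' sequence. The recorded product footprint is forward length + core length
#' + reverse length (804 bases for the default CBT pair and a 769-base
#' core).
#'
#' @param cores ungapped "seq_set" of evolved core sequences.
#' @param pair a "primer_pair" (degeneracies <= 1e4).
#' @param flank_length random flank length on each side (default 300).
#' @param seed integer seed.
#' @return list: `templates` ("seq_set", ids = core ids), `coordinates`
#'   (data.frame: `taxon`, `start`, `end` 0-based half-open,
#'   `product_length`).
#' @export
implant_amplicon <- function(cores, pair, flank_length = 300L, seed = 1L) {
  if (pair$forward$degeneracy > 1e4 || pair$reverse$degeneracy > 1e4) {
    stop("primer degeneracy above the 1e4 implant limit", call. = FALSE)
  }
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  rand_seq <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")
  rows <- list(); tmpl <- character(nrow(cores))
  for (i in seq_len(nrow(cores))) {
    fwd <- iupac_sample_expansion(pair$forward$sequence)
    rev_rc <- revcomp_iupac(iupac_sample_expansion(pair$reverse$sequence))
    left <- rand_seq(flank_length); right <- rand_seq(flank_length)
    insert <- paste0(fwd, cores$residues[i], rev_rc)
    tmpl[i] <- paste0(left, insert, right)
    rows[[i]] <- data.frame(
      taxon = cores$id[i], start = flank_length,
      end = flank_length + nchar(insert),
      product_length = nchar(insert), stringsAsFactors = FALSE
    )
  }
  list(templates = seq_set(cores$id, tmpl),
       coordinates = do.call(rbind, rows))
}

#' Emit a diverged paralogous (G-gene) family
#'
#' Duplicates the A-family root sequence, evolves it along an elongated
#' branch of length `paralog_divergence`, then down the same tree; the
#' resulting family carries label G.
#'
#' @param root_seq the ancestral core as a single sequence string.
#' @param paralog_divergence branch length (substitutions/site) separating
#'   the duplicate from the A root (> 0).
#' @param tree the "phylo" the family evolves down.
#' @param model a "substitution_model".
#' @param seed integer seed.
#' @return "seq_set" with ids `<taxon>_G`.
#' @export
emit_paralogs <- function(root_seq, paralog_divergence, tree, model,
                          seed = 1L) {
  stopifnot(paralog_divergence > 0)
  set.seed(seed)
  # evolve the duplicated root along the divergence branch (rate 1)
  bases <- c("A", "C", "G", "T")
  P <- transition_probability(model, paralog_divergence, 1)
  root <- match(strsplit(toupper(root_seq), "")[[1]], bases)
  g_root <- vapply(root, function(b) {
    sample.int(4L, 1L, prob = P[b, ])
  }, integer(1))
  g_root_seq <- paste(bases[g_root], collapse = "")
  # then down the tree, with the same model but its own seed stream
  fam <- evolve_root_down(g_root_seq, tree, model,
                          seed = derive_seed(seed, "paralog-family"))
  seq_set(paste0(fam$id, "_G"), fam$residues)
}

## Evolve a fixed root sequence down a tree (no indels); helper shared by
## emit_paralogs. Gamma/invariant site assignments are drawn fresh.
evolve_root_down <- function(root_seq, tree, model, seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  L <- nchar(root_seq)
  n_tip <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "postorder")
  invariant <- stats::runif(L) < model$p_inv
  cat_idx <- sample.int(model$n_categories, L, replace = TRUE)
  seqs <- matrix(0L, n_tip + tree$Nnode, L)
  seqs[n_tip + 1L, ] <- match(strsplit(toupper(root_seq), "")[[1]], bases)
  for (e in rev(seq_len(nrow(tree$edge)))) {
    par <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    child <- seqs[par, ]
    for (k in seq_len(model$n_categories)) {
      P <- transition_probability(model, tree$edge.length[e],
                                  model$category_rates[k])
      for (b in 1:4) {
        sel <- which(!invariant & cat_idx == k & seqs[par, ] == b)
        if (length(sel)) {
          child[sel] <- sample.int(4L, length(sel), replace = TRUE,
                                   prob = P[b, ])
        }
      }
    }
    seqs[ch, ] <- child
  }
  seq_set(tree$tip.label, vapply(seq_len(n_tip), function(i) {
    paste(bases[seqs[i, ]], collapse = "")
  }, character(1)))
}

## Rescale a tree so its mean root-to-tip depth equals `depth`.
.rescale_depth <- function(tree, depth) {
  d <- ape::node.depth.edgelength(tree)
  mean_depth <- mean(d[seq_along(tree$tip.label)])
  tree$edge.length <- tree$edge.length * depth / mean_depth
  tree
}

#' Generate the full synthetic dataset with recorded ground truth
#'
#' Simulates the species tree (rescaled to the spec's expected root-to-tip
#' depth), applies the horizontal transfers, evolves the A-gene core family
#' on the gene tree and the G-paralog family on the species tree, implants
#' primer-flanked amplicons into genomic templates (the G paralog is
#' embedded further downstream in each template, without primer sites of its
#' own), and writes all artifacts to `out_dir`:
#' genomes.fasta, genes.fasta, amplicons.fasta, species_tree.nwk,
#' gene_tree.nwk, hgt_events.tsv, amplicon_coordinates.tsv,
#' class_labels.tsv. Byte-identical for a fixed spec.
#'
#' @param spec a "simulation_spec".
#' @param out_dir output directory (created if missing); NULL skips writing.
#' @return invisibly, a "truth_bundle" list: `species_tree`, `gene_tree`,
#'   `hgt_events`, `true_alignment`, `amplicon_coordinates`, `labels`,
#'   `genomes`, `genes`, `amplicons`, `spec`.
#' @export
emit_dataset <- function(spec, out_dir = NULL) {
  sp_tree <- simulate_species_tree(spec$n_taxa, spec$birth_rate,
                                   derive_seed(spec$seed, "species-tree"))
  sp_tree <- .rescale_depth(sp_tree, spec$tree_scale)
  hgt <- apply_hgt(sp_tree, spec$n_hgt_events,
                   derive_seed(spec$seed, "hgt"))
  evo <- evolve_sequences(hgt$gene_tree, spec$model, spec$core_length,
                          spec$indel_rate,
                          derive_seed(spec$seed, "evolve-a"))
  g_fam <- if (spec$paralog_divergence > 0) {
    emit_paralogs(evo$root, spec$paralog_divergence, sp_tree, spec$model,
                  derive_seed(spec$seed, "paralog"))
  } else {
    NULL
  }
  imp <- implant_amplicon(evo$sequences, spec$primer_pair,
                          spec$flank_length,
                          derive_seed(spec$seed, "implant"))
  # genomic templates: [flank A-amplicon flank] + spacer + G gene
  set.seed(derive_seed(spec$seed, "genome"))
  genomes <- imp$templates
  if (!is.null(g_fam)) {
    spacer <- vapply(seq_len(nrow(genomes)), function(i) {
      paste(sample(c("A", "C", "G", "T"), 200L, replace = TRUE),
            collapse = "")
    }, character(1))
    genomes$residues <- paste0(genomes$residues, spacer, g_fam$residues)
  }
  a_genes <- seq_set(paste0(evo$sequences$id, "_A"), evo$sequences$residues)
  genes <- if (is.null(g_fam)) a_genes else
    seq_set(c(a_genes$id, g_fam$id), c(a_genes$residues, g_fam$residues))
  labels <- data.frame(
    sequence_id = genes$id,
    taxon = sub("_(A|G)$", "", genes$id),
    label = sub("^.*_", "", genes$id),
    stringsAsFactors = FALSE
  )
  amplicons <- seq_set(imp$coordinates$taxon, vapply(
    seq_len(nrow(imp$coordinates)), function(i) {
      substr(genomes$residues[i], imp$coordinates$start[i] + 1L,
             imp$coordinates$end[i])
    }, character(1)))
  bundle <- structure(
    list(species_tree = sp_tree, gene_tree = hgt$gene_tree,
         hgt_events = hgt$events, true_alignment = evo$alignment,
         amplicon_coordinates = imp$coordinates, labels = labels,
         genomes = genomes, genes = genes, amplicons = amplicons,
         spec = spec),
    class = "truth_bundle"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(genomes, file.path(out_dir, "genomes.fasta"))
    write_fasta(genes, file.path(out_dir, "genes.fasta"))
    write_fasta(amplicons, file.path(out_dir, "amplicons.fasta"))
    write_newick_file(sp_tree, file.path(out_dir, "species_tree.nwk"))
    write_newick_file(hgt$gene_tree, file.path(out_dir, "gene_tree.nwk"))
    write_tsv_report(hgt$events, file.path(out_dir, "hgt_events.tsv"))
    write_tsv_report(imp$coordinates,
                     file.path(out_dir, "amplicon_coordinates.tsv"))
    write_tsv_report(labels, file.path(out_dir, "class_labels.tsv"))
  }
  invisible(bundle)
}
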