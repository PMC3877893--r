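## End-to-end orchestration of the screen: simulate-or-ingest -> in-silico
## PCR -> A/G classification -> alignment -> ML tree + bootstrap -> gene/
## reference tree comparison -> report. One flat key=value config, one seed,
## deterministic artifacts with a checksum manifest.

.config_defaults <- function() {
  list(
    simulate = TRUE,
    input_fasta = NA_character_,      # genomic templates (when not simulating)
    reference_tree = NA_character_,   # Newick reference (16S-side) tree
    annotations = NA_character_,      # TSV: taxon, chemotype|query
    panel_a = NA_character_, panel_g = NA_character_,
    primer_fwd = "TTVGGYTAYGAYTTYGG", primer_rev = "AGACCARGAACGRACTTC",
    nominal_product = 804L,
    max_mismatch = 0L, product_min = 400L, product_max = 1200L,
    k = 11L, classify_threshold = 0.05,
    taxa = 12L, hgt = 2L, kappa = 4, alpha = 0.5, pinv = 0.1,
    categories = 5L, core = 769L, paralog_divergence = 1.0,
    indel_rate = 0, tree_scale = 0.3,
    fit_model = TRUE,
    bootstrap = 1000L,
    gene_threshold = 70, ref_threshold = 50,
    displacement_budget = 5L,
    seed = 1L,
    out_dir = "cyanoscreen_out",
    resume = FALSE
  )
}

.config_types <- function() {
  d <- .config_defaults()
  vapply(d, function(v) {
    if (is.logical(v)) "logical" else if (is.numeric(v)) "numeric" else "character"
  }, character(1))
}

#' Validate a flat key=value pipeline configuration file
#'
#' Lines are `key = value`; '#' starts a comment. Unknown keys, type
#' mismatches and missing referenced paths are rejected with the offending
#' line number. Omitted keys take their documented defaults (1000 bootstrap
#' replicates; support display thresholds 70 for the gene tree and 50 for
#' the reference tree; the published CBT primer pair).
#'
#' @param path configuration file path.
#' @return a validated "pipeline_config" list.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  cfg <- .config_defaults()
  types <- .config_types()
  errs <- character(0)
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[i])
    if (!nzchar(trimws(line))) next
    if (!grepl("=", line, fixed = TRUE)) {
      errs <- c(errs, sprintf("line %d: expected 'key = value'", i)); next
    }
    key <- trimws(sub("=.*$", "", line))
    val <- trimws(sub("^[^=]*=", "", line))
    if (!key %in% names(cfg)) {
      errs <- c(errs, sprintf("line %d: unknown key '%s'", i, key)); next
    }
    parsed <- switch(
      types[[key]],
      logical = {
        if (!toupper(val) %in% c("TRUE", "FALSE", "YES", "NO")) NULL
        else toupper(val) %in% c("TRUE", "YES")
      },
      numeric = {
        v <- suppressWarnings(as.numeric(val)); if (is.na(v)) NULL else v
      },
      character = val
    )
    if (is.null(parsed)) {
      errs <- c(errs, sprintf("line %d: key '%s' expects a %s value, got '%s'",
                              i, key, types[[key]], val))
      next
    }
    cfg[[key]] <- parsed
  }
  for (key in c("input_fasta", "reference_tree", "annotations",
                "panel_a", "panel_g")) {
    p <- cfg[[key]]
    if (!is.na(p) && !file.exists(p)) {
      errs <- c(errs, sprintf("key '%s': referenced path does not exist: %s",
                              key, p))
    }
  }
  if (!cfg$simulate && is.na(cfg$input_fasta)) {
    errs <- c(errs, "simulate = FALSE requires input_fasta")
  }
  if (cfg$bootstrap < 0) errs <- c(errs, "bootstrap must be >= 0")
  for (key in c("gene_threshold", "ref_threshold")) {
    if (cfg[[key]] < 0 || cfg[[key]] > 100) {
      errs <- c(errs, sprintf("key '%s' must lie in [0, 100]", key))
    }
  }
  if (length(errs)) {
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' In-memory pipeline configuration
#'
#' Programmatic equivalent of [validate_config()]: defaults overridden by
#' named arguments.
#'
#' @param ... settings to override (see [validate_config()] for keys).
#' @return a "pipeline_config" list.
#' @export
pipeline_config <- function(...) {
  cfg <- .config_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

.stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full screening pipeline
#'
#' Stages: (1) simulate the synthetic dataset or ingest user FASTA; (2)
#' in-silico PCR with the configured primer pair; (3) A/G classification of
#' the amplicons (a strain is positive iff at least one amplicon classifies
#' as A); (4) progressive alignment of the A amplicons; (5) K2P+G+I ML tree
#' with optional bootstrap supports; (6) comparison against the reference
#' tree: Robinson-Foulds incongruence, displaced-taxon (lateral-transfer
#' candidate) ranking and, when supports are available, novel-clade
#' flagging; (7) a screen report and checksum manifest. All artifacts land
#' in `out_dir` and are identical for identical config + seed.
#'
#' @param config a "pipeline_config".
#' @return invisibly, a list with the stage results: `truth` (synthetic runs
#'   only), `screen`, `classification`, `positives`, `alignment`, `tree`
#'   (with supports when bootstrapped), `fitted_model`, `incongruence`,
#'   `displaced`, `novel`, `report`, `manifest`.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)

  ## stage 1: inputs
  truth <- NULL
  if (isTRUE(config$simulate)) {
    spec <- simulation_spec(
      n_taxa = config$taxa, n_hgt_events = config$hgt,
      model = substitution_model(config$kappa, config$alpha, config$pinv,
                                 config$categories),
      core_length = config$core,
      primer_pair = primer_pair(
        degenerate_primer("CBT_AF", config$primer_fwd, "forward"),
        degenerate_primer("CBT_AR", config$primer_rev, "reverse"),
        nominal_product_length = config$nominal_product
      ),
      paralog_divergence = config$paralog_divergence,
      indel_rate = config$indel_rate, tree_scale = config$tree_scale,
      seed = derive_seed(seed, "simulate")
    )
    truth <- emit_dataset(spec, file.path(out_dir, "sim"))
    templates <- truth$genomes
    reference_tree <- truth$species_tree
    .stage_log("simulate", nrow(templates), " genomic templates, ",
               nrow(truth$hgt_events), " HGT events")
  } else {
    templates <- read_fasta(config$input_fasta)
    reference_tree <- if (!is.na(config$reference_tree)) {
      read_newick_file(config$reference_tree)
    } else NULL
    .stage_log("ingest", nrow(templates), " templates from ",
               config$input_fasta)
  }
  pair <- primer_pair(
    degenerate_primer("CBT_AF", config$primer_fwd, "forward"),
    degenerate_primer("CBT_AR", config$primer_rev, "reverse"),
    nominal_product_length = config$nominal_product
  )

  ## stage 2: in-silico PCR
  pcr <- pcr_screen(pair, templates, max_mismatch = config$max_mismatch,
                    product_length_range = c(config$product_min,
                                             config$product_max))
  write_tsv_report(pcr$screen, file.path(out_dir, "pcr_screen.tsv"))
  if (!is.null(pcr$hits) && nrow(pcr$hits)) {
    amp_ids <- make.unique(pcr$hits$template_id, sep = "_amp")
    amplicons <- seq_set(amp_ids, pcr$hits$product)
    write_fasta(amplicons, file.path(out_dir, "amplicons.fasta"))
  } else {
    amplicons <- NULL
  }
  .stage_log("pcr", sum(pcr$screen$positive), "/", nrow(templates),
             " templates with products")
  if (is.null(amplicons)) {
    stop("pipeline aborted at stage 'pcr': no amplicons recovered",
         call. = FALSE)
  }

  ## stage 3: classification
  if (!is.na(config$panel_a) && !is.na(config$panel_g)) {
    panel <- build_panel(read_fasta(config$panel_a),
                         read_fasta(config$panel_g), k = config$k)
  } else if (!is.null(truth)) {
    a_refs <- truth$genes[truth$labels$label == "A", , drop = FALSE]
    g_refs <- truth$genes[truth$labels$label == "G", , drop = FALSE]
    if (!nrow(g_refs)) {
      panel <- NULL
    } else {
      panel <- build_panel(a_refs, g_refs, k = config$k)
    }
  } else {
    panel <- NULL
  }
  if (!is.null(panel)) {
    classification <- classify_all(amplicons, panel,
                                   threshold = config$classify_threshold)
    write_tsv_report(classification,
                     file.path(out_dir, "classification.tsv"))
    a_amplicons <- amplicons[classification$label == "A", , drop = FALSE]
  } else {
    classification <- NULL
    a_amplicons <- amplicons
  }
  positive_templates <- unique(sub("_amp[0-9]*$", "", a_amplicons$id))
  .stage_log("classify", nrow(a_amplicons), " amplicons kept as A-gene; ",
             length(positive_templates), " positive strains")
  if (nrow(a_amplicons) < 4L) {
    stop("pipeline aborted at stage 'classify': fewer than 4 A amplicons (",
         paste(a_amplicons$id, collapse = ", "), ")", call. = FALSE)
  }

  ## stage 4: alignment (one amplicon per template: the first A call)
  aln_path <- file.path(out_dir, "alignment.fasta")
  if (isTRUE(config$resume) && file.exists(aln_path)) {
    alignment <- as_alignment(read_fasta(aln_path))
    .stage_log("align", "resumed from ", aln_path)
  } else {
    keep <- !duplicated(sub("_amp[0-9]*$", "", a_amplicons$id))
    aln_input <- seq_set(sub("_amp[0-9]*$", "", a_amplicons$id)[keep],
                         a_amplicons$residues[keep])
    alignment <- progressive_align(aln_input)
    write_fasta(alignment, aln_path)
    .stage_log("align", nrow(alignment), " sequences, ",
               attr(alignment, "columns"), " columns")
  }

  ## stage 5: ML tree
  tree_path <- file.path(out_dir, "gene_tree.nwk")
  fit_path <- file.path(out_dir, "model_fit.tsv")
  searched_logL <- NA_real_
  if (isTRUE(config$resume) && file.exists(tree_path) &&
      file.exists(fit_path)) {
    best_tree <- read_newick_file(tree_path)
    fit <- read_tsv_report(fit_path)
    fitted_model <- substitution_model(fit$kappa, fit$alpha, fit$p_inv,
                                       fit$n_categories)
    searched_logL <- fit$logL
    .stage_log("tree", "resumed from ", tree_path)
  } else {
    D <- k2p_distance_matrix(alignment, on_saturation = "cap")
    start <- nj_tree(D)
    model0 <- substitution_model(config$kappa, config$alpha, config$pinv,
                                 config$categories)
    opt <- suppressWarnings(
      optimize_phylo(start, alignment, model0, fit_model = config$fit_model)
    )
    searched <- nni_search(opt$tree, alignment, opt$model)
    best_tree <- searched$tree
    fitted_model <- opt$model
    searched_logL <- searched$logL
    if (config$bootstrap > 0) {
      best_tree <- bootstrap_support(
        alignment, fitted_model,
        bootstrap_config(config$bootstrap, derive_seed(seed, "bootstrap")),
        best_tree
      )
    }
    write_newick_file(best_tree, tree_path)
    write_tsv_report(
      data.frame(kappa = fitted_model$kappa, alpha = fitted_model$alpha,
                 p_inv = fitted_model$p_inv,
                 n_categories = fitted_model$n_categories,
                 logL = searched_logL),
      fit_path
    )
    .stage_log("tree", "logL = ", sprintf("%.2f", searched_logL),
               "; kappa = ", sprintf("%.2f", fitted_model$kappa))
  }

  ## stage 6: comparison
  incongruence <- NULL; displaced <- NULL; novel <- NULL
  if (!is.null(reference_tree)) {
    incongruence <- robinson_foulds(best_tree, reference_tree)
    displaced <- displaced_taxa(best_tree, reference_tree,
                                budget = config$displacement_budget)
    write_tsv_report(
      data.frame(shared_taxa = incongruence$shared_taxa,
                 rf_distance = incongruence$rf_distance,
                 max_rf = incongruence$max_rf,
                 normalized_rf = incongruence$normalized_rf),
      file.path(out_dir, "incongruence.tsv")
    )
    write_tsv_report(displaced, file.path(out_dir, "displaced_taxa.tsv"))
    .stage_log("compare", "RF = ", incongruence$rf_distance, "/",
               incongruence$max_rf, "; ", nrow(displaced),
               " displaced taxon candidates")
  }
  if (config$bootstrap > 0) {
    clades <- extract_clades(best_tree, threshold = config$gene_threshold)
    ann <- if (!is.na(config$annotations)) {
      tab <- read_tsv_report(config$annotations)
      stats::setNames(tab[[2L]], tab[[1L]])
    } else {
      stats::setNames(rep("query", length(best_tree$tip.label)),
                      best_tree$tip.label)
    }
    novel <- flag_novel_clades(clades, ann)
    novel_df <- if (length(novel$novel)) {
      do.call(rbind, lapply(novel$novel, function(cl) {
        data.frame(members = paste(cl$members, collapse = ","),
                   support = cl$support, stringsAsFactors = FALSE)
      }))
    } else {
      data.frame(members = character(0), support = numeric(0))
    }
    write_tsv_report(novel_df, file.path(out_dir, "novel_clades.tsv"))
  }

  ## stage 7: report + manifest
  report <- data.frame(
    template_id = templates$id,
    positive = templates$id %in% positive_templates,
    n_amplicons = vapply(templates$id, function(id) {
      sum(pcr$hits$template_id == id)
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  write_tsv_report(report, file.path(out_dir, "screen_report.tsv"))
  artifacts <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  artifacts <- artifacts[!grepl("manifest\\.tsv$", artifacts)]
  manifest <- data.frame(
    file = sub(paste0("^", out_dir, "/?"), "", artifacts),
    md5 = unname(tools::md5sum(artifacts)),
    stringsAsFactors = FALSE
  )
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  write_tsv_report(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(list(
    truth = truth, screen = pcr$screen, classification = classification,
    positives = positive_templates, alignment = alignment,
    tree = best_tree, fitted_model = fitted_model, logL = searched_logL,
    incongruence = incongruence, displaced = displaced, novel = novel,
    report = report, manifest = manifest
  ))
}
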