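# End-to-end experiment orchestration: simulate (or load) a clade, remove the
# test species, estimate branch lengths and model parameters, reconstruct
# ancestral nodes, build the five reference flavors, map reads from the test
# species, and report one metrics row per reference.

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("experiment stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Successive ancestral nodes of a test species' attachment point
#'
#' After pruning the test species, returns the labels of the k successive
#' ancestors of its former attachment point, shallowest first: node 1 is the
#' most recent common ancestor of the sister lineage and its sibling.
#'
#' @param tree rooted ape `phylo` with node labels
#' @param test_species tip label of the test species
#' @param k number of ancestors (default 3)
#' @return character vector of k internal-node labels of the pruned tree,
#'   shallowest first
#' @export
select_ancestral_nodes <- function(tree, test_species, k = 3L) {
  tree <- ensure_node_labels(tree)
  g <- .tree_graph(tree)
  i <- match(test_species, tree$tip.label)
  if (is.na(i)) stop("test_species must be a leaf of the tree")
  p <- g$parent[i]
  sib <- setdiff(g$children[[p]], i)
  sib_tips <- g$labels[unlist(lapply(sib, .subtree_tips, g = g))]
  pruned <- prune_species(tree, test_species)
  gp <- .tree_graph(pruned)
  sib_root <- if (length(sib_tips) == 1L) match(sib_tips, gp$labels)
              else ape::getMRCA(pruned, sib_tips)
  # binary attachment: the attachment node vanished with the pruning, so
  # node 1 is the parent of the sister clade in the pruned tree (the MRCA of
  # the sister lineage and its sibling); at a multifurcation the attachment
  # node survives and is node 1 itself
  v <- if (length(sib) > 1L) sib_root else gp$parent[sib_root]
  out <- character(0)
  while (length(out) < k) {
    if (is.na(v) || v == 0L) {
      stop("only ", length(out), " ancestral node(s) available above the ",
           "attachment point of ", test_species, "; k = ", k, " exceeds that")
    }
    out <- c(out, gp$labels[v])
    v <- if (v == gp$root) 0L else gp$parent[v]
  }
  out
}

# Invoke an external mapper through a command template with {ref}, {fq1},
# {fq2} and {out} placeholders; the output must be plain-text SAM.
.external_map <- function(template, reads, reference) {
  td <- tempfile("extmap")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  paths <- list(ref = file.path(td, "ref.fa"), fq1 = file.path(td, "r1.fq"),
                fq2 = file.path(td, "r2.fq"), out = file.path(td, "out.sam"))
  write_fasta(reference, paths$ref)
  write_fastq(reads, paths$fq1, paths$fq2)
  cmd <- template
  for (key in names(paths))
    cmd <- gsub(paste0("{", key, "}"), paths[[key]], cmd, fixed = TRUE)
  status <- system(cmd)
  if (status != 0L) stop("external mapper failed (exit ", status, "): ", cmd)
  rec <- read_sam(paths$out)
  data.table::setattr(rec, "total_reads", 2L * nrow(reads))
  rec
}

# Remove a species' rows from every block (the anchor cannot be removed).
.drop_species <- function(blocks, species) {
  out <- lapply(blocks, function(b) {
    if (b$rows$species[1] == species)
      stop("cannot remove the anchor species ", species, " from the alignment")
    j <- which(b$rows$species != species)
    .new_maf_block(b$rows[j, , drop = FALSE], b$score)
  })
  structure(out, class = "maf")
}

#' Default substitution model for the clade simulator
#'
#' A songbird-flavored GTR+Gamma: transition-enriched exchangeabilities,
#' mild AT bias, alpha = 0.8 with 4 categories.
#'
#' @return a `substitution_model`
#' @export
default_clade_model <- function() {
  substitution_model("GTR",
    rates = c(AC = 1.1, AG = 4.5, AT = 0.8, CG = 1.0, CT = 4.5, GT = 1.0),
    base_freqs = c(A = 0.30, C = 0.20, G = 0.20, T = 0.30),
    alpha = 0.8, k = 4L)
}

#' Assemble a run configuration
#'
#' Defaults describe the scaled-down in silico experiment the package is
#' tested on: a 5 Mb clade on the 15-species fixture tree, 100,000 error-free
#' 100 bp read pairs, minCol = 100 block filtering, the >90% missing mask,
#' and MAPQ >= 20 metric filters.
#'
#' @param test_species tip label whose reads are simulated and whose lineage
#'   is removed before reconstruction
#' @param ... overrides for any configuration field (see Details in the
#'   package vignette); unknown fields raise an error
#' @return a `run_config` list
#' @export
experiment_config <- function(test_species, ...) {
  cfg <- list(
    test_species = test_species,
    sister = NULL,                     # default: inferred from the tree
    tree = bird_clade_tree(),
    model = default_clade_model(),     # generative model for the simulator
    root_length = c(chr1 = 5e6),
    indel_rate = 0.001,
    indel_mean_len = 3,
    anchor_species = "TAEGU",
    k_nodes = 3L,
    min_col = 100L,
    max_missing_frac = 0.9,
    n_pairs = 100000L,
    read_len = 100L,
    fragment_mean = 500,
    fragment_sd = 50,
    error_rate = 0,
    seed = 1L,
    estimate = TRUE,                   # estimate branch lengths + model
    est_family = "GTR",
    est_max_cols = 10000L,             # columns used for branch lengths
    model_est_cols = 5000L,            # columns used for model parameters
    est_rounds = 10L,                  # optimizer round caps (runtime guard)
    model_rounds = 3L,
    init_branch = 0.05,
    seed_len = 12L,
    seed_step = 7L,
    max_mismatch = 30L,
    min_mapq = 20L,
    mapper_cmd = NULL,                 # external mapper template, e.g.
                                       # "bwa mem {ref} {fq1} {fq2} > {out}"
                                       # (default: built-in toy mapper)
    sim = NULL,                        # optionally a prebuilt clade_simulation
    outdir = NULL,
    write_references = FALSE,
    log = TRUE)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Run the full mapping-efficiency experiment
#'
#' Builds the reference flavors (test-species genome, sister genome, sister
#' aligned fraction, ancestral aligned fraction and hybrid per selected
#' node), simulates reads from the test species, maps them with the built-in
#' toy mapper, and evaluates each reference.  Deterministic given seed and
#' configuration.
#'
#' @param config a `run_config` from [experiment_config()]
#' @return data.frame with one row per reference: reference, node,
#'   total_length, missing, mapped_pct, breadth_pct, mean_depth.  When
#'   `config$outdir` is set, metrics (TSV + JSON) and a manifest are written
#'   there, plus reference FASTAs if `write_references` is TRUE.
#' @export
run_experiment <- function(config) {
  cfg <- config
  say <- function(...) if (isTRUE(cfg$log)) message("[paleoref] ", ...)
  tree <- ensure_node_labels(cfg$tree)
  test <- cfg$test_species
  if (!test %in% tree$tip.label) stop("test_species is not a tip of the tree")

  sim <- .stage("simulate-clade", {
    if (!is.null(cfg$sim)) cfg$sim
    else evolve_clade(tree, cfg$model, cfg$root_length, cfg$indel_rate,
                      cfg$indel_mean_len, seed = cfg$seed,
                      anchor_species = cfg$anchor_species,
                      keep_node_rows = FALSE)
  })
  sister <- cfg$sister %||% sister_species(tree, test)
  nodes <- .stage("select-nodes", select_ancestral_nodes(tree, test, cfg$k_nodes))
  pruned <- prune_species(tree, test)
  say("test species ", test, ", sister ", sister, ", ancestral nodes ",
      paste(nodes, collapse = " < "))

  blocks <- .stage("filter-maf", {
    b <- .drop_species(sim$blocks, test)
    b <- filter_min_columns(b, cfg$min_col)
    dedupe_best_hit(b)
  })
  say(length(sim$blocks), " truth blocks; ", length(blocks),
      " after minCol=", cfg$min_col, " + best-hit dedup")
  if (!length(blocks)) stop("no alignment blocks survive filtering")

  species_set <- pruned$tip.label
  fit <- .stage("estimate", {
    if (!cfg$estimate) {
      list(tree = pruned, model = cfg$model)
    } else {
      pat_bl <- site_patterns_from_blocks(blocks, species_set,
                                          max_cols = cfg$est_max_cols)
      pat_md <- site_patterns_from_blocks(blocks, species_set,
                                          max_cols = cfg$model_est_cols)
      ft <- pruned
      ft$edge.length <- rep(cfg$init_branch, nrow(ft$edge))
      md <- substitution_model(cfg$est_family, base_freqs = rep(0.25, 4),
                               alpha = 1, k = 4L)
      ft <- optimize_branch_lengths(ft, md, pat_bl, max_rounds = cfg$est_rounds)
      md <- estimate_model_params(ft, pat_md, family = cfg$est_family,
                                  k = 4L, max_rounds = cfg$model_rounds)
      ft <- optimize_branch_lengths(ft, md, pat_bl, max_rounds = cfg$est_rounds)
      say("estimated tree length ", signif(sum(ft$edge.length), 4),
          " (log-likelihood ", signif(attr(ft, "loglik"), 8), ")")
      list(tree = ft, model = md)
    }
  })

  segs <- .stage("reconstruct", {
    reconstruct_nodes(blocks, fit$tree, fit$model, nodes,
                      species_set = species_set,
                      max_missing_frac = cfg$max_missing_frac,
                      sister_species = sister)
  })
  tot_cols <- sum(vapply(blocks, function(b) as.numeric(b$n_columns), numeric(1)))
  kept_cols <- sum(vapply(segs, function(s) length(s[[1]]$columns), numeric(1)))
  say("masking: ", format(kept_cols, big.mark = ","), " of ",
      format(tot_cols, big.mark = ","), " alignment columns retained")

  refs <- .stage("build-refs", {
    out <- list(test_species = sim$genomes[[test]],
                sister_genome = sim$genomes[[sister]],
                sister_aligned_fraction = build_aligned_fraction(
                  blocks, species_id = sister, species_set = species_set,
                  max_missing_frac = cfg$max_missing_frac))
    for (nd in nodes) {
      out[[paste0("ancestral_", nd, "_aligned_fraction")]] <-
        ancestral_genome(segs, nd)
      plan <- plan_replacements(lapply(segs, `[[`, nd), sim$genomes[[sister]])
      say("node ", nd, ": ", sum(vapply(plan, nrow, integer(1))),
          " replaced intervals on the sister genome")
      out[[paste0("ancestral_", nd, "_hybrid")]] <-
        build_hybrid(sim$genomes[[sister]], plan)$genome
    }
    out
  })

  reads <- .stage("simulate-reads", {
    simulate_reads(sim$genomes[[test]], cfg$n_pairs, cfg$read_len,
                   cfg$fragment_mean, cfg$fragment_sd, cfg$error_rate,
                   seed = cfg$seed + 101L)
  })

  rows <- .stage("map-evaluate", {
    lapply(names(refs), function(nm) {
      rec <- if (is.null(cfg$mapper_cmd))
        toy_map(reads, refs[[nm]], seed_len = cfg$seed_len,
                seed_step = cfg$seed_step, max_mismatch = cfg$max_mismatch)
      else .external_map(cfg$mapper_cmd, reads, refs[[nm]])
      m <- compute_metrics(rec, refs[[nm]], min_mapq = cfg$min_mapq)
      say(sprintf("%-40s mapped %6.2f%%  breadth %6.2f%%  depth %.3fX",
                  nm, m$mapped_pct, m$breadth_pct, m$mean_depth))
      data.frame(reference = nm,
                 node = if (grepl("^ancestral_", nm))
                   sub("^ancestral_([^_]+)_.*$", "\\1", nm) else NA_character_,
                 total_length = m$ref_total_length, missing = m$ref_missing,
                 mapped_pct = m$mapped_pct, breadth_pct = m$breadth_pct,
                 mean_depth = m$mean_depth, stringsAsFactors = FALSE)
    })
  })
  metrics <- do.call(rbind, rows)

  if (!is.null(cfg$outdir)) .stage("write-output", {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    write.table(metrics, file.path(cfg$outdir, "metrics.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(metrics, file.path(cfg$outdir, "metrics.json"),
                         dataframe = "rows", digits = NA)
    scal <- cfg[!vapply(cfg, is.object, logical(1))]
    scal <- scal[!vapply(scal, is.null, logical(1))]
    cfgfile <- file.path(cfg$outdir, "config.json")
    jsonlite::write_json(scal, cfgfile, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    manifest <- list(
      package = "paleoref",
      version = as.character(utils::packageVersion("paleoref")),
      r_version = R.version.string,
      seed = cfg$seed,
      config_hash = unname(tools::md5sum(cfgfile)),
      tree = ape::write.tree(tree),
      nodes = nodes, sister = sister, test_species = test)
    jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                         auto_unbox = TRUE)
    if (isTRUE(cfg$write_references))
      for (nm in names(refs))
        write_fasta(refs[[nm]], file.path(cfg$outdir, paste0(nm, ".fa")))
  })

  attr(metrics, "nodes") <- nodes
  attr(metrics, "sister") <- sister
  attr(metrics, "fit") <- fit
  metrics
}
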