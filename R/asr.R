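# Marginal (empirical-Bayes) ancestral sequence reconstruction.
#
# For each alignment column the posterior distribution over states at every
# internal node is obtained from the inside-outside message scheme; the Gamma
# mixture is collapsed by weighting each category's posterior by its own
# posterior probability given the column (empirical Bayes), which falls out
# of keeping the per-category partials on a shared scale.  The called allele
# is the posterior mode, with ties broken by higher stationary frequency and
# then alphabetically.

#' Marginal ancestral posteriors for one alignment column
#'
#' @inheritParams column_log_likelihood
#' @return matrix (internal nodes x 4), rows named by node label, columns
#'   A,C,G,T; each row sums to 1.  With an all-missing column the root (and
#'   every node) returns the stationary distribution.
#' @export
marginal_posteriors <- function(tree, model, column) {
  g <- .tree_graph(ensure_node_labels(tree))
  extra <- setdiff(names(column), g$labels[seq_len(g$ntip)])
  if (length(extra))
    stop("column references species absent from tree: ", paste(extra, collapse = ", "))
  tips <- g$labels[seq_len(g$ntip)]
  states <- matrix(NA_integer_, length(tips), 1L, dimnames = list(tips, NULL))
  got <- intersect(tips, names(column))
  if (length(got))
    states[got, 1L] <- .STATE_LOOKUP[utf8ToInt(paste(column[got], collapse = ""))]
  ctx <- .model_context(model)
  pmats <- .branch_pmats(g, ctx)
  down <- .peel_down(g, ctx, states, pmats)
  internal <- setdiff(seq_len(g$nnode), seq_len(g$ntip))
  up <- .peel_up(g, ctx, down, need_A = internal, pmats = pmats)
  out <- t(vapply(internal, function(v)
    drop(.node_posterior(ctx, up$A[[v]], down$D[[v]])), numeric(4)))
  dimnames(out) <- list(g$labels[internal], BASES)
  out
}

#' Call the modal allele from a site posterior
#'
#' Argmax of the posterior; ties are broken by higher stationary frequency,
#' then alphabetically, so calls are deterministic.
#'
#' @param p numeric vector of 4 posterior probabilities (A,C,G,T), or a
#'   matrix with 4 columns (one call per row)
#' @param base_freqs stationary frequencies used for tie-breaking
#'   (default uniform)
#' @return a base in \{A,C,G,T\} (vector for matrix input)
#' @export
call_allele <- function(p, base_freqs = c(0.25, 0.25, 0.25, 0.25)) {
  if (is.null(dim(p))) p <- matrix(p, 1L)
  stopifnot(ncol(p) == 4L)
  ord <- order(-unname(base_freqs), BASES)   # pi desc, then alphabetical
  idx <- max.col(p[, ord, drop = FALSE], ties.method = "first")
  BASES[ord][idx]
}

#' Columns retained under the missing-data mask
#'
#' A column is dropped iff its missing fraction over `species_set` is
#' strictly greater than `max_missing_frac` (the ">90% missing" rule); both
#' gaps and N count as missing, and species absent from the block are missing
#' in every column.
#'
#' @param block a MAF block
#' @param species_set species over which missingness is measured (the
#'   reconstruction species; the test species is excluded upstream)
#' @param max_missing_frac maximum tolerated missing fraction (default 0.9)
#' @return strictly increasing 1-based column indices of retained columns
#' @export
mask_columns <- function(block, species_set, max_missing_frac = 0.9) {
  n <- length(species_set)
  if (n == 0L) stop("species_set is empty")
  present <- intersect(species_set, block$rows$species)
  n_absent <- n - length(present)
  if (!length(present)) {
    miss <- rep(n, block$n_columns)
  } else {
    miss <- rep(n_absent, block$n_columns)
    for (sp in present) {
      txt <- block$rows$text[match(sp, block$rows$species)]
      miss <- miss + is.na(.STATE_LOOKUP[as.integer(charToRaw(txt))])
    }
  }
  which(miss / n <= max_missing_frac)
}

# Placement of a species' row over a set of retained columns: forward-strand
# 0-based half-open interval, snapping inward past gap columns at the ends.
# NULL if the species is absent or fully gapped over the retained columns.
.row_placement <- function(block, species, columns) {
  i <- match(species, block$rows$species)
  if (is.na(i) || !length(columns)) return(NULL)
  row <- block$rows[i, ]
  nongap <- charToRaw(row$text) != as.raw(45L)   # '-'
  cs <- cumsum(nongap)
  sel <- columns[nongap[columns]]
  if (!length(sel)) return(NULL)
  # strand-relative base offsets of first/last covered base
  b1 <- cs[sel[1]] - 1L
  b2 <- cs[sel[length(sel)]]
  s <- row$start + b1
  e <- row$start + b2
  if (row$strand == "-") { tmp <- s; s <- row$src_size - e; e <- row$src_size - tmp }
  list(seq_name = row$seq_name, start = as.numeric(s), end = as.numeric(e),
       strand = row$strand)
}

.new_segment <- function(node_id, block_index, columns, sequence, posteriors,
                         max_prob, anchor_placement, sister_placement, score) {
  structure(list(node_id = node_id, block_index = block_index,
                 columns = columns, sequence = sequence,
                 posteriors = posteriors, max_prob = max_prob,
                 anchor_placement = anchor_placement,
                 sister_placement = sister_placement, score = score),
            class = "ancestral_segment")
}

#' @export
print.ancestral_segment <- function(x, ...) {
  cat("ancestral segment:", x$node_id, "block", x$block_index, "-",
      length(x$columns), "called bases\n")
  invisible(x)
}

#' Reconstruct one internal node over one MAF block
#'
#' Applies the missing-data mask, computes marginal posteriors for every
#' retained column, and calls the modal allele.  Species in the tree but
#' absent from the block are treated as missing data throughout the block.
#'
#' @inheritParams mask_columns
#' @param tree rooted ape `phylo` (tips are the reconstruction species)
#' @param model a `substitution_model`
#' @param node_id internal-node label to reconstruct
#' @param sister_species optional species whose placement interval is
#'   recorded on the segment (for hybrid splicing)
#' @param block_index provenance index stored on the segment
#' @return an `ancestral_segment` (empty when no column is retained)
#' @export
reconstruct_node_over_block <- function(block, tree, model, node_id,
                                        species_set = tree$tip.label,
                                        max_missing_frac = 0.9,
                                        sister_species = NULL,
                                        block_index = NA_integer_) {
  segs <- reconstruct_nodes(list(block), tree, model, node_id,
                            species_set = species_set,
                            max_missing_frac = max_missing_frac,
                            sister_species = sister_species,
                            keep_posteriors = TRUE)
  seg <- segs[[1]][[node_id]]
  seg$block_index <- block_index
  seg
}

#' Reconstruct internal nodes over many MAF blocks
#'
#' Batch version of [reconstruct_node_over_block()]: columns from all blocks
#' are collapsed to shared site patterns so large alignments are processed
#' with a handful of vectorized pruning passes.
#'
#' @inheritParams reconstruct_node_over_block
#' @param blocks list of MAF blocks
#' @param node_ids internal-node labels to reconstruct
#' @param keep_posteriors store the full per-column posterior matrix on each
#'   segment (default FALSE: only the per-column maximum posterior is kept,
#'   which bounds memory on genome-scale runs)
#' @param chunk_patterns number of site patterns processed per pruning pass
#' @return list (per block) of lists (per node) of `ancestral_segment`s
#' @export
reconstruct_nodes <- function(blocks, tree, model, node_ids,
                              species_set = tree$tip.label,
                              max_missing_frac = 0.9,
                              sister_species = NULL,
                              keep_posteriors = FALSE,
                              chunk_patterns = 100000L) {
  tree <- ensure_node_labels(tree)
  g <- .tree_graph(tree)
  node_v <- match(node_ids, g$labels)
  if (anyNA(node_v) || any(node_v <= g$ntip))
    stop("not internal node label(s): ",
         paste(node_ids[is.na(node_v) | node_v <= g$ntip], collapse = ", "))
  ctx <- .model_context(model)
  tips <- g$labels[seq_len(g$ntip)]

  # retained columns and state matrices per block
  keep <- lapply(blocks, mask_columns, species_set = species_set,
                 max_missing_frac = max_missing_frac)
  states <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    if (!length(keep[[i]])) next
    m <- .block_states(blocks[[i]], tips)
    states[[i]] <- m[, keep[[i]], drop = FALSE]
  }
  widths <- vapply(states, function(m) if (is.null(m)) 0L else ncol(m), integer(1))
  total <- sum(widths)

  per_node <- setNames(vector("list", length(node_ids)), node_ids)

  if (total > 0L) {
    cp <- .collapse_patterns(do.call(cbind, states[widths > 0L]))
    npat <- length(cp$weights)
    pmats <- .branch_pmats(g, ctx)
    starts <- seq(1L, npat, by = chunk_patterns)
    # per-pattern posterior for each node, assembled chunk by chunk
    pat_post <- setNames(lapply(node_ids, function(nd)
      matrix(NA_real_, npat, 4L, dimnames = list(NULL, BASES))), node_ids)
    for (s0 in starts) {
      idx <- s0:min(s0 + chunk_patterns - 1L, npat)
      sub <- cp$patterns[, idx, drop = FALSE]
      down <- .peel_down(g, ctx, sub, pmats)
      up <- .peel_up(g, ctx, down, need_A = node_v, pmats = pmats)
      for (j in seq_along(node_ids)) {
        v <- node_v[j]
        pat_post[[j]][idx, ] <- .node_posterior(ctx, up$A[[v]], down$D[[v]])
      }
    }
    # calls and call posteriors at pattern level, expanded per column by
    # indexing (the full per-column posterior matrix is only materialized on
    # request: it is 32 bytes/column/node)
    for (j in seq_along(node_ids)) {
      pp <- pat_post[[j]]
      pat_call <- call_allele(pp, ctx$pi)
      pat_maxp <- pp[cbind(seq_len(npat), max.col(pp, "first"))]
      per_node[[j]] <- list(
        call = pat_call[cp$index],
        maxp = pat_maxp[cp$index],
        full = if (keep_posteriors) pp[cp$index, , drop = FALSE])
    }
  } else {
    for (nd in node_ids)
      per_node[[nd]] <- list(call = character(0), maxp = numeric(0),
                             full = if (keep_posteriors)
                               matrix(NA_real_, 0L, 4L,
                                      dimnames = list(NULL, BASES)))
  }

  # split per block and attach placements
  out <- vector("list", length(blocks))
  off <- 0L
  anchor_sp <- if (length(blocks)) blocks[[1]]$rows$species[1] else NA_character_
  for (i in seq_along(blocks)) {
    w <- widths[i]
    cols <- keep[[i]]
    bi <- blocks[[i]]
    anchor_pl <- if (w) .row_placement(bi, bi$rows$species[1], cols) else NULL
    sister_pl <- if (w && !is.null(sister_species))
      .row_placement(bi, sister_species, cols) else NULL
    sc <- if (is.na(bi$score)) bi$n_columns else bi$score
    segs <- setNames(vector("list", length(node_ids)), node_ids)
    for (j in seq_along(node_ids)) {
      rng <- if (w) off + seq_len(w) else integer(0)
      segs[[j]] <- .new_segment(
        node_id = node_ids[j], block_index = i, columns = cols,
        sequence = paste(per_node[[j]]$call[rng], collapse = ""),
        posteriors = if (keep_posteriors && w)
          per_node[[j]]$full[rng, , drop = FALSE] else NULL,
        max_prob = per_node[[j]]$maxp[rng],
        anchor_placement = anchor_pl, sister_placement = sister_pl,
        score = sc)
    }
    out[[i]] <- segs
    off <- off + w
  }
  out
}

#' Write reconstructed segments as FASTA contigs
#'
#' Contigs are named `<node>|<anchor_seq>:<start>-<end>|block<i>`; blocks with
#' no retained columns contribute nothing.
#'
#' @param segments list (per block) of lists (per node) from
#'   [reconstruct_nodes()]
#' @param node_id which node to export
#' @param path output FASTA path
#' @export
write_ancestral_fasta <- function(segments, node_id, path) {
  g <- ancestral_genome(segments, node_id)
  write_fasta(g, path)
}

#' Assemble the per-block contigs of one reconstructed node into a genome
#' @inheritParams write_ancestral_fasta
#' @return a `genome`, one contig per contributing block
#' @export
ancestral_genome <- function(segments, node_id) {
  seqs <- character(0)
  for (i in seq_along(segments)) {
    seg <- segments[[i]][[node_id]]
    if (is.null(seg) || !nzchar(seg$sequence)) next
    ap <- seg$anchor_placement
    nm <- if (!is.null(ap))
      sprintf("%s|%s:%d-%d|block%d", node_id, ap$seq_name, ap$start, ap$end, i)
    else sprintf("%s|unplaced|block%d", node_id, i)
    seqs[nm] <- seg$sequence
  }
  genome(seqs)
}
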