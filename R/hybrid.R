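# Reference-genome construction: sister/ancestral aligned fractions and the
# hybrid genome (sister backbone with alignable intervals replaced by
# reconstructed ancestral sequence).

#' Plan ancestral replacements on the sister genome
#'
#' Collects the sister placements of the given ancestral segments, validates
#' them against the sister sequence lengths, and resolves overlapping
#' candidates by keeping the segment from the higher-scoring block (ties by
#' input order).  Segments without a sister placement are skipped and counted.
#'
#' @param segments list of `ancestral_segment`s (one node), e.g. the per-block
#'   entries from [reconstruct_nodes()]
#' @param sister a `genome`
#' @return a `replacement_plan`: per sister sequence, a sorted table of
#'   disjoint intervals (0-based half-open, with strand) and replacement
#'   strings; attribute `n_skipped` counts placement-less segments
#' @export
plan_replacements <- function(segments, sister) {
  if (length(segments) && is.null(segments[[1]]$node_id))
    stop("segments must be a list of ancestral_segment objects")
  lens <- nchar(unclass(sister))
  usable <- !vapply(segments, function(s)
    is.null(s$sister_placement) || !nzchar(s$sequence), logical(1))
  skipped <- sum(!usable)
  plan <- setNames(vector("list", length(sister)), names(sister))
  if (any(usable)) {
    segs <- segments[usable]
    tab <- data.frame(
      seq_name = vapply(segs, function(s) s$sister_placement$seq_name, ""),
      start = vapply(segs, function(s) s$sister_placement$start, 0),
      end = vapply(segs, function(s) s$sister_placement$end, 0),
      strand = vapply(segs, function(s) s$sister_placement$strand, ""),
      replacement = vapply(segs, `[[`, "", "sequence"),
      block_index = vapply(segs, function(s) as.integer(s$block_index), 0L),
      node_id = vapply(segs, `[[`, "", "node_id"),
      score = vapply(segs, function(s) as.numeric(s$score %||% 0), 0),
      stringsAsFactors = FALSE)
    bad_seq <- !tab$seq_name %in% names(sister)
    if (any(bad_seq))
      stop("block ", tab$block_index[bad_seq][1], ": sister sequence ",
           tab$seq_name[bad_seq][1], " not in genome")
    oob <- tab$start < 0 | tab$end > lens[tab$seq_name] | tab$start > tab$end
    if (any(oob))
      stop("block ", tab$block_index[oob][1], ": placement [",
           tab$start[oob][1], ",", tab$end[oob][1],
           ") outside sister sequence ", tab$seq_name[oob][1],
           " (length ", lens[[tab$seq_name[oob][1]]], ")")
    for (nm in unique(tab$seq_name)) {
      rows <- tab[tab$seq_name == nm, , drop = FALSE]
      ord <- order(-rows$score, seq_len(nrow(rows)))   # best first, then input
      so <- order(rows$start)
      if (!is.unsorted(rows$start[so], strictly = FALSE) &&
          all(rows$end[so][-nrow(rows)] <= rows$start[so][-1])) {
        plan[[nm]] <- rows[so, , drop = FALSE]          # already disjoint
        next
      }
      keep <- logical(nrow(rows))
      kstart <- numeric(0); kend <- numeric(0)          # kept, sorted by start
      for (i in ord) {
        pos <- findInterval(rows$start[i], kstart)
        clash <- (pos >= 1L && kend[pos] > rows$start[i]) ||
                 (pos < length(kstart) && kstart[pos + 1L] < rows$end[i])
        if (!clash) {
          keep[i] <- TRUE
          kstart <- append(kstart, rows$start[i], after = pos)
          kend <- append(kend, rows$end[i], after = pos)
        }
      }
      kept <- rows[keep, , drop = FALSE]
      plan[[nm]] <- kept[order(kept$start), , drop = FALSE]
    }
  }
  for (nm in names(plan))
    if (is.null(plan[[nm]]))
      plan[[nm]] <- data.frame(seq_name = character(0), start = numeric(0),
                               end = numeric(0), strand = character(0),
                               replacement = character(0),
                               block_index = integer(0), node_id = character(0),
                               score = numeric(0), stringsAsFactors = FALSE)
  structure(plan, class = "replacement_plan", n_skipped = skipped)
}

#' @export
print.replacement_plan <- function(x, ...) {
  n <- sum(vapply(x, nrow, integer(1)))
  cat("replacement plan:", n, "interval(s) across", length(x), "sequence(s);",
      attr(x, "n_skipped"), "segment(s) without placement skipped\n")
  invisible(x)
}

#' Build a hybrid genome from a sister genome and a replacement plan
#'
#' Each planned interval of the sister sequence is excised and the ancestral
#' replacement string spliced in (reverse-complemented first for minus-strand
#' placements, so the spliced text reads on the sister's forward strand).
#' Sequence lengths obey
#' `new = old - sum(interval widths) + sum(replacement widths)` exactly and
#' bases outside the intervals are untouched.
#'
#' @param sister a `genome`
#' @param plan a `replacement_plan` from [plan_replacements()]
#' @return list with `genome` (the hybrid) and `intervals`, a BED-like table
#'   mapping each replaced interval from sister to hybrid coordinates
#'   (0-based half-open)
#' @export
build_hybrid <- function(sister, plan) {
  out <- unclass(sister)
  maps <- list()
  for (nm in names(sister)) {
    tab <- plan[[nm]]
    if (is.null(tab) || !nrow(tab)) next
    s <- sister[[nm]]
    pieces <- character(2L * nrow(tab) + 1L)
    new_start <- numeric(nrow(tab)); new_end <- numeric(nrow(tab))
    prev <- 0; pos <- 0
    for (r in seq_len(nrow(tab))) {
      left <- substr(s, prev + 1L, tab$start[r])     # untouched stretch
      rep_seq <- if (tab$strand[r] == "-") .revcomp(tab$replacement[r])
                 else tab$replacement[r]
      pieces[2L * r - 1L] <- left
      pieces[2L * r] <- rep_seq
      pos <- pos + nchar(left)
      new_start[r] <- pos
      pos <- pos + nchar(rep_seq)
      new_end[r] <- pos
      prev <- tab$end[r]
    }
    pieces[2L * nrow(tab) + 1L] <- substr(s, prev + 1L, nchar(s))
    out[[nm]] <- paste(pieces, collapse = "")
    maps[[nm]] <- data.frame(seq_name = nm, old_start = tab$start,
                             old_end = tab$end, new_start = new_start,
                             new_end = new_end, strand = tab$strand,
                             block_index = tab$block_index,
                             node_id = tab$node_id, stringsAsFactors = FALSE)
  }
  intervals <- if (length(maps)) do.call(rbind, maps) else
    data.frame(seq_name = character(0), old_start = numeric(0),
               old_end = numeric(0), new_start = numeric(0),
               new_end = numeric(0), strand = character(0),
               block_index = integer(0), node_id = character(0))
  rownames(intervals) <- NULL
  list(genome = genome(out), intervals = intervals)
}

#' Build an aligned-fraction reference
#'
#' For a species: each filtered block contributes one contig, the species'
#' ungapped row restricted to the mask-retained columns.  For an ancestral
#' node (via `segments`): each block's called sequence becomes a contig.
#' Adjacent blocks are never merged, since block adjacency does not guarantee
#' genomic adjacency; contig names carry block provenance.
#'
#' @param blocks list of filtered/deduplicated MAF blocks
#' @param species_id species whose aligned fraction to extract (exclusive
#'   with `segments`)
#' @param segments output of [reconstruct_nodes()] for an ancestral node
#' @param node_id node label (required with `segments`)
#' @param species_set,max_missing_frac masking parameters, as in
#'   [mask_columns()]
#' @return a `genome`, one contig per contributing block
#' @export
build_aligned_fraction <- function(blocks, species_id = NULL, segments = NULL,
                                   node_id = NULL,
                                   species_set = NULL, max_missing_frac = 0.9) {
  if (!is.null(segments)) {
    if (is.null(node_id)) stop("node_id is required with segments")
    return(ancestral_genome(segments, node_id))
  }
  if (is.null(species_id)) stop("give either species_id or segments")
  if (is.null(species_set)) stop("species_set is required for masking")
  seqs <- character(0)
  found <- FALSE
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    j <- match(species_id, b$rows$species)
    if (is.na(j)) next
    found <- TRUE
    cols <- mask_columns(b, species_set, max_missing_frac)
    if (!length(cols)) next
    raw <- charToRaw(b$rows$text[j])[cols]
    raw <- raw[raw != as.raw(45L)]
    if (!length(raw)) next
    pl <- .row_placement(b, species_id, cols)
    nm <- sprintf("%s|%s:%d-%d|block%d", species_id, pl$seq_name,
                  pl$start, pl$end, i)
    seqs[nm] <- rawToChar(raw)
  }
  if (!found) stop("species ", species_id, " absent from every block")
  genome(seqs)
}
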