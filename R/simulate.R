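# Synthetic clade and read simulation.
#
# evolve_clade() evolves a root genome along a rooted tree under the same
# GTR/HKY85(+Gamma) model the inference side assumes: per-site Gamma rate
# categories are drawn once at the root and inherited (site-specific rates),
# substitutions are drawn from P(t * r) per branch, and indels arrive as a
# Poisson process per branch with geometric lengths.  The whole clade evolves
# inside one global alignment coordinate system (insertions add columns,
# deletions add gaps), so the emitted truth MAF is exact by construction:
# blocks are the runs between indel breakpoints, within which every genome is
# either fully present or fully gapped.
#
# simulate_reads() samples error-free (by default) paired-end reads in the
# style of wgsim, with truth coordinates encoded in the read names.

.GAP <- as.raw(255L)
.CHR_LUT <- local({
  lut <- rep(as.raw(45L), 256L)           # '-'
  lut[1:4] <- charToRaw("ACGT")           # codes 0..3 at indices 1..4
  lut
})
.codes_to_text <- function(row) rawToChar(.CHR_LUT[as.integer(row) + 1L])

# Evolve one contig; returns rows (list by node id, raw vectors over global
# columns), the category vector, breakpoints, and the per-branch event log.
.evolve_contig <- function(g, ctx, L0, indel_rate, indel_mean_len) {
  K <- ctx$K
  nv <- g$nnode
  rows <- vector("list", nv)
  root <- g$root
  rows[[root]] <- as.raw(sample.int(4L, L0, replace = TRUE, prob = ctx$pi) - 1L)
  catv <- as.raw(sample.int(K, L0, replace = TRUE))
  bp <- numeric(0)                        # boundaries in 0..C
  log_rows <- list()

  preorder <- rev(g$postorder)
  for (v in preorder) {
    if (v == root) next
    t <- g$blen[v]
    parent_row <- rows[[g$parent[v]]]
    row <- parent_row
    idx <- which(row != .GAP)
    Lb <- length(idx)
    n_sub <- 0L
    if (Lb && t > 0) {
      Pk <- lapply(ctx$cat_rates, function(r) .ptrans(ctx$eigen, t * r))
      b <- as.integer(row[idx]) + 1L
      kk <- as.integer(catv[idx])
      pst <- numeric(Lb)
      for (k in seq_len(K)) {
        sel <- kk == k
        pst[sel] <- diag(Pk[[k]])[b[sel]]
      }
      chg <- which(runif(Lb) > pst)
      n_sub <- length(chg)
      if (n_sub) {
        for (k in seq_len(K)) for (bb in 1:4) {
          sel <- chg[kk[chg] == k & b[chg] == bb]
          if (!length(sel)) next
          pr <- Pk[[k]][bb, ]; pr[bb] <- 0
          row[idx[sel]] <- as.raw(sample.int(4L, length(sel), replace = TRUE,
                                             prob = pr) - 1L)
        }
      }
    }

    n_ins <- 0L; n_del <- 0L; ins_bases <- 0L; del_bases <- 0L
    ins_g <- numeric(0); ins_len <- integer(0)
    if (Lb && t > 0 && indel_rate > 0) {
      n_ev <- rpois(1L, indel_rate * t * Lb)
      if (n_ev > 0L) {
        is_ins <- runif(n_ev) < 0.5
        lens <- rgeom(n_ev, 1 / indel_mean_len) + 1L
        # deletions: non-overlapping within the branch (greedy with one
        # resampling pass for rejected events)
        dl <- lens[!is_ins]
        if (length(dl)) {
          placed <- matrix(0, 0, 2)        # base-coordinate [start, end]
          for (attempt in 1:2) {
            if (!length(dl)) break
            st <- sample.int(Lb, length(dl), replace = TRUE)
            en <- pmin(st + dl - 1L, Lb)
            keep <- logical(length(dl))
            ord <- order(st)
            for (i in ord) {
              if (!nrow(placed) || all(en[i] < placed[, 1] | st[i] > placed[, 2])) {
                placed <- rbind(placed, c(st[i], en[i]))
                keep[i] <- TRUE
              }
            }
            dl <- dl[!keep]
          }
          if (nrow(placed)) {
            for (r in seq_len(nrow(placed))) {
              cols <- idx[placed[r, 1]:placed[r, 2]]
              row[cols] <- .GAP
              bp <- c(bp, cols[1] - 1, cols[length(cols)])
              del_bases <- del_bases + length(cols)
            }
            n_del <- nrow(placed)
          }
        }
        il <- lens[is_ins]
        if (length(il)) {
          p <- sample.int(Lb + 1L, length(il), replace = TRUE) - 1L   # after base p
          ins_g <- ifelse(p == 0L, 0, idx[pmax(p, 1L)])
          ins_len <- as.integer(il)
          n_ins <- length(il); ins_bases <- sum(il)
        }
      }
    }

    # materialize insertions: expand every placed row, the category vector
    # and the breakpoint set into the new column space
    if (n_ins) {
      ord <- order(ins_g)
      gg <- as.integer(ins_g[ord]); ll <- as.integer(ins_len[ord])
      cum <- cumsum(ll)
      C <- length(catv)
      newC <- C + cum[length(cum)]
      # contiguous old-column runs delimited by the insertion points; the
      # expansion itself is run-wise memcpy in C++
      run_old_start <- c(0L, gg) + 1L
      run_len <- c(gg, C) - c(0L, gg)
      run_new_start <- as.integer(run_old_start + c(0L, cum))
      expanded <- expand_rows_cpp(c(rows, list(row, catv)),
                                  run_old_start, run_new_start, run_len,
                                  newC, 255L)
      rows <- expanded[seq_len(nv)]
      row <- expanded[[nv + 1L]]
      catv <- expanded[[nv + 2L]]
      bp <- bp + c(0, cum)[findInterval(bp - 0.5, gg) + 1L]
      gnew <- gg + c(0L, cum[-length(cum)])
      for (i in seq_along(gnew)) {
        seg <- (gnew[i] + 1L):(gnew[i] + ll[i])
        row[seg] <- as.raw(sample.int(4L, ll[i], replace = TRUE, prob = ctx$pi) - 1L)
        catv[seg] <- as.raw(sample.int(ctx$K, ll[i], replace = TRUE))
        bp <- c(bp, gnew[i], gnew[i] + ll[i])
      }
    }

    rows[[v]] <- row
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      node = g$labels[v], branch_length = t, substitutions = n_sub,
      insertions = n_ins, deletions = n_del,
      ins_bases = ins_bases, del_bases = del_bases)
  }
  list(rows = rows, catv = catv, bp = sort(unique(c(0, bp, length(catv)))),
       events = do.call(rbind, log_rows))
}

#' Evolve a clade of genomes along a known tree
#'
#' @param tree rooted ape `phylo` with branch lengths (substitutions/site)
#' @param model a `substitution_model` (the same family the inference modules
#'   assume, so parameter and sequence recovery are well-posed)
#' @param root_length length(s) of the root genome; a named vector yields a
#'   multi-contig genome (default: one 10 kb contig named chr1)
#' @param indel_rate expected indel events per site per unit branch length
#'   (default 0.001; see the methods vignette for why this is deliberately
#'   below biological values)
#' @param indel_mean_len mean indel length, geometric (default 3)
#' @param seed RNG seed; identical seed and configuration give bit-identical
#'   output
#' @param anchor_species leaf used as the MAF anchor (default: first tip)
#' @param keep_node_rows store per-block aligned rows for internal nodes
#'   (truth for reconstruction accuracy checks; default TRUE — disable on
#'   genome-scale runs to save memory)
#' @return a `clade_simulation`: tree, model, per-node `genome`s (tips and
#'   internal nodes), truth MAF `blocks` (leaf rows, anchor first), optional
#'   `node_rows`, per-branch `event_log`, and bookkeeping fields
#' @export
evolve_clade <- function(tree, model, root_length = c(chr1 = 10000L),
                         indel_rate = 0.001, indel_mean_len = 3,
                         seed = 1L, anchor_species = NULL,
                         keep_node_rows = TRUE) {
  stopifnot(all(root_length >= 1), indel_rate >= 0, indel_mean_len >= 1)
  tree <- ensure_node_labels(tree)
  g <- .tree_graph(tree)
  ctx <- .model_context(model)
  if (is.null(anchor_species)) anchor_species <- tree$tip.label[1]
  if (!anchor_species %in% tree$tip.label)
    stop("anchor_species must be a tip label")
  if (is.null(names(root_length)))
    names(root_length) <- paste0("chr", seq_along(root_length))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  leaf_ids <- seq_len(g$ntip)
  node_ids <- (g$ntip + 1L):g$nnode
  # anchor first, then remaining leaves in tip order
  anchor_id <- match(anchor_species, g$labels)
  leaf_order <- c(anchor_id, setdiff(leaf_ids, anchor_id))

  genomes_chr <- lapply(seq_len(g$nnode), function(i) character(0))
  blocks <- list()
  node_rows <- if (keep_node_rows)
    setNames(lapply(node_ids, function(i) list()), g$labels[node_ids])
  events <- list()
  dropped <- 0L

  for (ci in seq_along(root_length)) {
    cname <- names(root_length)[ci]
    sim <- .evolve_contig(g, ctx, as.integer(root_length[ci]),
                          indel_rate, indel_mean_len)
    events[[ci]] <- sim$events
    # ungapped genomes
    for (v in seq_len(g$nnode)) {
      r <- sim$rows[[v]]
      genomes_chr[[v]][cname] <- .codes_to_text(r[r != .GAP])
    }
    # truth blocks between breakpoints (leaf coordinates only are needed)
    cs <- vector("list", g$nnode)
    for (v in leaf_order) cs[[v]] <- cumsum(sim$rows[[v]] != .GAP)
    bp <- sim$bp
    at <- function(v, b) if (b > 0) as.numeric(cs[[v]][b]) else 0
    for (k in seq_len(length(bp) - 1L)) {
      b1 <- bp[k]; b2 <- bp[k + 1L]
      cols <- (b1 + 1L):b2
      present <- vapply(leaf_order, function(v) sim$rows[[v]][b1 + 1L] != .GAP,
                        logical(1))
      if (!present[1L]) { dropped <- dropped + 1L; next }   # anchor gapped
      rows_v <- leaf_order[present]
      df <- data.frame(
        species = g$labels[rows_v], seq_name = cname,
        start = vapply(rows_v, at, numeric(1), b = b1),
        size = vapply(rows_v, function(v) at(v, b2) - at(v, b1), numeric(1)),
        strand = "+",
        src_size = vapply(rows_v, function(v) at(v, length(cs[[v]])), numeric(1)),
        text = vapply(rows_v, function(v) .codes_to_text(sim$rows[[v]][cols]),
                      character(1)),
        stringsAsFactors = FALSE)
      blk <- .new_maf_block(df, score = NA_real_)
      blocks[[length(blocks) + 1L]] <- blk
      if (keep_node_rows) {
        bi <- length(blocks)
        for (v in node_ids) {
          lab <- g$labels[v]
          node_rows[[lab]][[bi]] <-
            if (sim$rows[[v]][b1 + 1L] == .GAP) NA_character_
            else .codes_to_text(sim$rows[[v]][cols])
        }
      }
    }
  }

  ev <- do.call(rbind, events)
  ev <- do.call(rbind, lapply(split(ev, ev$node), function(d)
    data.frame(node = d$node[1], branch_length = d$branch_length[1],
               substitutions = sum(d$substitutions), insertions = sum(d$insertions),
               deletions = sum(d$deletions), ins_bases = sum(d$ins_bases),
               del_bases = sum(d$del_bases))))
  rownames(ev) <- NULL

  structure(list(
    tree = tree, model = model, seed = seed,
    params = list(root_length = root_length, indel_rate = indel_rate,
                  indel_mean_len = indel_mean_len),
    anchor_species = anchor_species,
    genomes = setNames(lapply(seq_len(g$nnode), function(v)
      genome(genomes_chr[[v]])), g$labels),
    blocks = structure(blocks, class = "maf"),
    node_rows = node_rows,
    event_log = ev,
    n_dropped_blocks = dropped), class = "clade_simulation")
}

#' @export
print.clade_simulation <- function(x, ...) {
  cat("clade simulation:", length(x$tree$tip.label), "leaves,",
      length(x$blocks), "truth blocks,",
      sum(nchar(unclass(x$genomes[[x$anchor_species]]))), "bp anchor genome",
      "(seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Simulate error-free paired-end reads (wgsim style)
#'
#' Fragments are sampled uniformly over positions whose span contains no N
#' (rejected fragments are resampled up to 1000 times); mate 1 is the
#' fragment 5' end, mate 2 the reverse complement of the 3' end.  Read names
#' encode the truth: `<seq>_<frag_start>_<frag_end>_<pair#>` with 1-based
#' inclusive coordinates.
#'
#' @param g a `genome`
#' @param n_pairs number of read pairs
#' @param read_len read length (default 100)
#' @param fragment_mean,fragment_sd fragment-length distribution
#'   (defaults 500 and 50, the wgsim defaults)
#' @param error_rate per-base error probability (default 0, as in the
#'   evaluation protocol); errors substitute a uniformly chosen different base
#' @param seed RNG seed
#' @return a `read_pairs` object: data.frame with columns `name`, `read1`,
#'   `read2`
#' @export
simulate_reads <- function(g, n_pairs, read_len = 100L, fragment_mean = 500,
                           fragment_sd = 50, error_rate = 0, seed = 1L) {
  stopifnot(fragment_mean >= read_len)
  lens <- nchar(unclass(g))
  eligible <- lens >= fragment_mean
  if (!any(lens >= read_len)) stop("genome shorter than the read length")
  if (!any(eligible)) eligible <- lens >= read_len

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  if (n_pairs == 0L)
    return(structure(data.frame(name = character(0), read1 = character(0),
                                read2 = character(0)), class = c("read_pairs", "data.frame")))

  contigs <- names(g)[eligible]
  clens <- lens[eligible]
  ci <- sample.int(length(contigs), n_pairs, replace = TRUE,
                   prob = clens / sum(clens))
  flen <- pmax(round(rnorm(n_pairs, fragment_mean, fragment_sd)), read_len)
  flen <- pmin(flen, clens[ci])
  start <- floor(runif(n_pairs) * (clens[ci] - flen + 1)) + 1
  frag_end <- start + flen - 1

  # reject fragments containing N, resample up to 1000 rounds
  any_n <- any(grepl("N", unclass(g)[contigs], fixed = TRUE))
  has_n <- function(i) {
    s <- substr(unclass(g)[[contigs[ci[i]]]], start[i], frag_end[i])
    grepl("N", s, fixed = TRUE)
  }
  bad <- if (any_n) which(vapply(seq_len(n_pairs), has_n, logical(1))) else integer(0)
  tries <- 0L
  while (length(bad) && tries < 1000L) {
    tries <- tries + 1L
    start[bad] <- floor(runif(length(bad)) * (clens[ci[bad]] - flen[bad] + 1)) + 1
    frag_end[bad] <- start[bad] + flen[bad] - 1
    bad <- bad[vapply(bad, has_n, logical(1))]
  }
  if (length(bad))
    warning(length(bad), " fragments still contain N after 1000 resampling rounds")

  seqs <- unclass(g)[contigs]
  r1 <- substr(seqs[ci], start, start + read_len - 1)
  r2 <- .revcomp(substr(seqs[ci], frag_end - read_len + 1, frag_end))
  if (error_rate > 0) {
    r1 <- .add_errors(r1, error_rate)
    r2 <- .add_errors(r2, error_rate)
  }
  name <- sprintf("%s_%d_%d_%d", contigs[ci], as.integer(start),
                  as.integer(frag_end), seq_len(n_pairs))
  structure(data.frame(name = name, read1 = r1, read2 = r2,
                       stringsAsFactors = FALSE),
            class = c("read_pairs", "data.frame"))
}

.add_errors <- function(reads, rate) {
  n <- length(reads)
  if (!n) return(reads)
  len <- nchar(reads[1])
  m <- matrix(.STATE_LOOKUP[as.integer(charToRaw(paste(reads, collapse = "")))],
              nrow = len)
  hit <- which(matrix(runif(len * n) < rate, nrow = len), arr.ind = FALSE)
  if (length(hit)) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    m[hit] <- ((m[hit] - 1L + shift) %% 4L) + 1L
  }
  apply_cols <- vapply(seq_len(n), function(j)
    rawToChar(charToRaw("ACGT")[m[, j]]), character(1))
  apply_cols
}

#' Write read pairs to FASTQ
#'
#' All base qualities are "I" (error-free simulation).
#'
#' @param pairs a `read_pairs` object
#' @param path1,path2 output FASTQ paths for mates 1 and 2
#' @export
write_fastq <- function(pairs, path1, path2) {
  for (m in 1:2) {
    reads <- if (m == 1) pairs$read1 else pairs$read2
    qual <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
    lines <- as.vector(rbind(paste0("@", pairs$name, "/", m), reads, "+", qual))
    writeLines(lines, if (m == 1) path1 else path2)
  }
  invisible(c(path1, path2))
}

#' Read paired FASTQ files
#' @param path1,path2 FASTQ paths for mates 1 and 2
#' @return a `read_pairs` object
#' @export
read_fastq_pairs <- function(path1, path2) {
  l1 <- readLines(path1); l2 <- readLines(path2)
  name <- sub("/[12]$", "", sub("^@", "", l1[seq(1, length(l1), 4)]))
  structure(data.frame(name = name,
                       read1 = toupper(l1[seq(2, length(l1), 4)]),
                       read2 = toupper(l2[seq(2, length(l2), 4)]),
                       stringsAsFactors = FALSE),
            class = c("read_pairs", "data.frame"))
}

#' Default 15-species songbird-like fixture tree
#'
#' A rooted 15-leaf topology shaped like the passerine clade used throughout
#' the package examples: STUVU has a shallow (~20 My-like) sister RHAIN, and
#' PTEME a deep (~40 My-like) sister SYLVI, with branch lengths in expected
#' substitutions per site (roughly 0.002 per My).
#'
#' @param depth_scale multiply all branch lengths (default 1)
#' @return an ape `phylo` with labeled internal nodes
#' @export
bird_clade_tree <- function(depth_scale = 1) {
  nwk <- paste0(
    "((((((((STUVU:0.040,RHAIN:0.040):0.016,DICEX:0.056):0.010,",
    "(PROCA:0.050,ZOSLA:0.050):0.016):0.008,(PTEME:0.080,SYLVI:0.080):0.006):0.006,",
    "((SERCA:0.042,GEOFO:0.042):0.014,(SETCO:0.040,ZONAL:0.040):0.016):0.024):0.008,",
    "(PASDO:0.055,FICAL:0.055):0.025):0.010,PARMA:0.090):0.014,TAEGU:0.104);")
  phy <- read_newick(nwk)
  phy$edge.length <- phy$edge.length * depth_scale
  phy
}
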