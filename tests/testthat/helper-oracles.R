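# Independent oracles used across the suite: exhaustive enumeration for
# likelihoods/posteriors, per-position pileup for coverage metrics, and plain
# string surgery for hybrid splicing.  These deliberately share no code with
# the package internals.

# Exhaustive enumeration over all internal-node state assignments.
# Returns list(loglik, post) where post is a (internal nodes x 4) matrix of
# marginal posteriors (rows named by node label).
enum_pruning <- function(phy, model, column) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  root <- ntip + 1L
  parent <- integer(nnode); parent[phy$edge[, 2]] <- phy$edge[, 1]
  blen <- numeric(nnode); blen[phy$edge[, 2]] <- phy$edge.length
  labs <- c(phy$tip.label, phy$node.label)
  pi <- model$base_freqs
  rates <- if (is.null(model$alpha)) 1 else gamma_category_rates(model$alpha, model$k)
  int_ids <- root:nnode
  assigns <- as.matrix(expand.grid(rep(list(1:4), length(int_ids))))
  joint <- numeric(nrow(assigns))
  for (r in rates) {
    P <- lapply(seq_len(nnode), function(v)
      if (v == root) NULL else transition_matrix(model, blen[v], r))
    # joint probability of every internal-state assignment, vectorized over
    # the assignment rows
    pr <- pi[assigns[, 1]]                    # int_ids[1] is the root
    for (v in setdiff(int_ids, root))
      pr <- pr * P[[v]][cbind(assigns[, match(parent[v], int_ids)],
                              assigns[, match(v, int_ids)])]
    for (tp in seq_len(ntip)) {
      st <- column[[labs[tp]]]
      code <- match(st, c("A", "C", "G", "T"))
      if (is.na(code)) next                   # missing tip: factor 1
      pr <- pr * P[[tp]][cbind(assigns[, match(parent[tp], int_ids)], code)]
    }
    joint <- joint + pr / length(rates)
  }
  total <- sum(joint)
  post <- matrix(0, length(int_ids), 4,
                 dimnames = list(labs[int_ids], c("A", "C", "G", "T")))
  for (j in seq_along(int_ids))
    for (x in 1:4)
      post[j, x] <- sum(joint[assigns[, j] == x]) / total
  list(loglik = log(total), post = post)
}

# Random valid GTR+Gamma model.
rand_model <- function(k = 4L, with_gamma = TRUE) {
  rates <- runif(6, 0.3, 3); names(rates) <- c("AC", "AG", "AT", "CG", "CT", "GT")
  pi <- runif(4, 0.5, 1.5); pi <- pi / sum(pi)
  substitution_model("GTR", rates = rates, base_freqs = pi,
                     alpha = if (with_gamma) runif(1, 0.3, 2) else NULL, k = k)
}

# Random rooted tree with labeled internal nodes and modest branch lengths.
rand_tree <- function(ntip) {
  phy <- ape::rtree(ntip, rooted = TRUE, br = function(n) runif(n, 0.01, 0.5))
  ensure_node_labels(phy)
}

# Random alignment columns over a tree's tips, with occasional missing data.
rand_columns <- function(phy, ncol, p_missing = 0.15) {
  tips <- phy$tip.label
  m <- matrix(sample(c("A", "C", "G", "T"), length(tips) * ncol, replace = TRUE),
              length(tips), ncol, dimnames = list(tips, NULL))
  miss <- matrix(runif(length(m)) < p_missing, nrow(m))
  m[miss] <- sample(c("N", "-"), sum(miss), replace = TRUE)
  m
}

# Brute-force metrics from SAM-like records: per-position depth loop.
brute_metrics <- function(records, reference, total_reads, min_mapq = 20L) {
  lens <- nchar(unclass(reference))
  depth <- lapply(lens, function(n) integer(n))
  names(depth) <- names(reference)
  n_pass <- 0L
  for (i in seq_len(nrow(records))) {
    flag <- records$flag[i]
    if (bitwAnd(flag, 0x4) || bitwAnd(flag, 0x100) || bitwAnd(flag, 0x200) ||
        bitwAnd(flag, 0x800)) next
    if (is.na(records$rname[i]) || records$mapq[i] < min_mapq) next
    n_pass <- n_pass + 1L
    ops <- regmatches(records$cigar[i],
                      gregexpr("[0-9]+[MIDNSHP=X]", records$cigar[i]))[[1]]
    at <- records$pos[i]
    for (op in ops) {
      n <- as.integer(sub(".$", "", op))
      o <- sub("^[0-9]+", "", op)
      if (o %in% c("M", "=", "X", "D")) {
        for (p in at:(at + n - 1L))
          depth[[records$rname[i]]][p] <- depth[[records$rname[i]]][p] + 1L
        at <- at + n
      } else if (o == "N") at <- at + n
    }
  }
  covered <- 0L; non_missing <- 0L; dsum <- 0
  for (nm in names(reference)) {
    ok <- !genome_missing_mask(reference, nm)
    non_missing <- non_missing + sum(ok)
    covered <- covered + sum(depth[[nm]][ok] >= 1L)
    dsum <- dsum + sum(depth[[nm]][ok])
  }
  list(mapped_pct = 100 * n_pass / total_reads,
       breadth_pct = if (non_missing) 100 * covered / non_missing else 0,
       mean_depth = if (non_missing) dsum / non_missing else 0)
}

# Brute-force hybrid splice: direct string surgery, one interval at a time
# from the right so earlier coordinates stay valid.
brute_splice <- function(sister, plan) {
  out <- unclass(sister)
  rc <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  for (nm in names(plan)) {
    tab <- plan[[nm]]
    if (is.null(tab) || !nrow(tab)) next
    tab <- tab[order(-tab$start), ]
    s <- out[[nm]]
    for (r in seq_len(nrow(tab))) {
      rep_seq <- if (tab$strand[r] == "-") rc(tab$replacement[r]) else tab$replacement[r]
      s <- paste0(substr(s, 1, tab$start[r]), rep_seq,
                  substr(s, tab$end[r] + 1, nchar(s)))
    }
    out[[nm]] <- s
  }
  out
}

.rc_str <- function(s) chartr("ACGT", "TGCA",
                              paste(rev(strsplit(s, "")[[1]]), collapse = ""))

# A small hand-specified MAF text used in several tests.
fixture_maf_text <- function() {
  c("##maf version=1",
    "",
    "a score=500",
    "s anc.chr1 0 5 + 100 ACGTA",
    "s sis.chr2 10 4 + 50 AC-TA",
    "",
    "a score=300",
    "s anc.chr1 50 4 + 100 AAAA",
    "s sis.chr2 20 4 - 50 CCCC",
    "")
}

# Deterministic seed scoping that restores the RNG afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
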