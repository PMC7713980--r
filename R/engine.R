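# Internal likelihood engine: site-pattern collapse and vectorized
# Felsenstein pruning over all patterns at once.
#
# Partial likelihoods are stored per node as a list of K matrices (one per
# Gamma category), each 4 x P (states x patterns).  Numerical scaling is
# shared across categories (one factor per pattern per node) so that the
# per-category likelihoods stay directly comparable, which the
# empirical-Bayes category weighting of the posteriors relies on.

# Collapse an S x C integer state matrix (NA = missing) into unique site
# patterns with multiplicities.  Exact: patterns are keyed in base 6, chunked
# over rows so the key always fits a double.
.collapse_patterns <- function(states) {
  S <- nrow(states); C <- ncol(states)
  if (C == 0L)
    return(list(patterns = states, weights = numeric(0), index = integer(0)))
  m <- states
  m[is.na(m)] <- 5L
  groups <- split(seq_len(S), ceiling(seq_len(S) / 20L))
  keyparts <- lapply(groups, function(rows) {
    sub <- if (length(rows) == S) m else m[rows, , drop = FALSE]
    as.vector(matrix(6^(seq_along(rows) - 1), 1) %*% sub)
  })
  key <- if (length(keyparts) == 1L) keyparts[[1]]
         else do.call(paste, c(keyparts, sep = "_"))
  first <- !duplicated(key)
  index <- match(key, key[first])
  list(patterns = states[, first, drop = FALSE],
       weights = as.numeric(tabulate(index, sum(first))),
       index = index)
}

# State matrix (species x columns, integer codes, NA = missing) for one MAF
# block, over a fixed species ordering.  Species absent from the block are
# all-missing (MULTIZ blocks need not contain every species).
.block_states <- function(block, species) {
  C <- block$n_columns
  out <- matrix(NA_integer_, length(species), C,
                dimnames = list(species, NULL))
  hit <- match(species, block$rows$species)
  for (i in which(!is.na(hit)))
    out[i, ] <- .encode_states(block$rows$text[hit[i]])
  out
}

#' Collect site patterns from MAF blocks
#'
#' Builds the (species x columns) state matrix over the given species set and
#' collapses it to unique site patterns with multiplicities, the form consumed
#' by the likelihood and optimization functions.
#'
#' @param blocks list of MAF blocks
#' @param species character vector of species (tree tip labels)
#' @param max_cols optional cap on the number of alignment columns used
#'   (columns are taken in block order; mirrors restricting estimation to a
#'   subset of the alignment, as with a single chromosome)
#' @param seq_names optional anchor sequence name(s): only blocks anchored on
#'   these sequences are used (e.g. estimate on the largest chromosome only)
#' @return list with `patterns` (species x P integer matrix, NA = missing)
#'   and `weights` (pattern multiplicities)
#' @export
site_patterns_from_blocks <- function(blocks, species, max_cols = Inf,
                                      seq_names = NULL) {
  mats <- list(); used <- 0
  for (b in blocks) {
    if (!is.null(seq_names) && !b$rows$seq_name[1] %in% seq_names) next
    if (used >= max_cols) break
    m <- .block_states(b, species)
    if (ncol(m) > max_cols - used) m <- m[, seq_len(max_cols - used), drop = FALSE]
    used <- used + ncol(m)
    mats[[length(mats) + 1L]] <- m
  }
  if (!length(mats)) stop("no alignment columns available")
  cp <- .collapse_patterns(do.call(cbind, mats))
  list(patterns = cp$patterns, weights = cp$weights)
}

# Per-branch, per-category transition matrices.
.branch_pmats <- function(g, ctx) {
  out <- vector("list", g$nnode)
  for (v in seq_len(g$nnode)) {
    if (v == g$root) next
    out[[v]] <- lapply(ctx$cat_rates, function(r) .ptrans(ctx$eigen, g$blen[v] * r))
  }
  out
}

.colmax4 <- function(m) pmax(m[1L, ], m[2L, ], m[3L, ], m[4L, ])

# Tip partial likelihoods: unit vector for an observed state, all-ones for
# missing data (N and - alike).
.tip_partial <- function(states_row) {
  P <- length(states_row)
  D <- matrix(1, 4L, P)
  obs <- which(!is.na(states_row))
  if (length(obs)) {
    D[, obs] <- 0
    D[cbind(states_row[obs], obs)] <- 1
  }
  D
}

# Downward (tips -> root) pruning pass.
# patterns: S x P integer matrix whose rownames match tree tip labels.
.peel_down <- function(g, ctx, patterns, pmats = .branch_pmats(g, ctx)) {
  K <- ctx$K
  P <- ncol(patterns)
  tip_row <- match(g$labels[seq_len(g$ntip)], rownames(patterns))
  if (anyNA(tip_row))
    stop("patterns are missing tree tips: ",
         paste(g$labels[seq_len(g$ntip)][is.na(tip_row)], collapse = ", "))
  D <- vector("list", g$nnode)
  M <- vector("list", g$nnode)
  logscale <- numeric(P)
  for (v in g$postorder) {
    if (v <= g$ntip) {
      Dv <- rep(list(.tip_partial(patterns[tip_row[v], ])), K)
    } else {
      Dv <- vector("list", K)
      for (k in seq_len(K)) {
        acc <- NULL
        for (ch in g$children[[v]])
          acc <- if (is.null(acc)) M[[ch]][[k]] else acc * M[[ch]][[k]]
        Dv[[k]] <- acc
      }
      s <- .colmax4(Dv[[1]])
      if (K > 1L) for (k in 2:K) s <- pmax(s, .colmax4(Dv[[k]]))
      s[s <= 0] <- 1         # contradictory pattern: keep zeros, no rescale
      inv <- rep(1 / s, each = 4L)
      for (k in seq_len(K)) Dv[[k]] <- Dv[[k]] * inv
      logscale <- logscale + log(s)
    }
    D[[v]] <- Dv
    if (v != g$root) {
      M[[v]] <- lapply(seq_len(K), function(k) pmats[[v]][[k]] %*% Dv[[k]])
    }
  }
  list(D = D, M = M, logscale = logscale)
}

# Total log-likelihood from a completed downward pass.
.down_loglik <- function(g, ctx, down, weights) {
  lik <- 0
  for (k in seq_len(ctx$K))
    lik <- lik + colSums(ctx$pi * down$D[[g$root]][[k]])
  sum(weights * (log(pmax(lik / ctx$K, 1e-300)) + down$logscale))
}

# Upward (root -> tips) pass.  For every non-root node v with parent u:
#   Pre_v = A_u * prod of sibling messages   (vector at u, before branch v)
#   A_v   = t(P_v) %*% Pre_v                 (after crossing branch v)
# A_root = pi.  Scaling is shared across categories, and since only ratios
# matter downstream (posterior normalization, branch-length line search), the
# scale logs are not tracked here.
#
# need_A: node ids whose A is required (posteriors); pre_all: compute Pre for
# every non-root node (branch-length optimization).
.peel_up <- function(g, ctx, down, need_A = integer(), pre_all = FALSE,
                     pmats = .branch_pmats(g, ctx)) {
  K <- ctx$K
  P <- length(down$logscale)
  A <- vector("list", g$nnode)
  Pre <- vector("list", g$nnode)
  marked <- logical(g$nnode)
  marked[need_A] <- TRUE
  for (v in g$postorder) if (marked[v] && g$parent[v]) marked[g$parent[v]] <- TRUE
  if (pre_all) marked[] <- TRUE
  A[[g$root]] <- rep(list(matrix(ctx$pi, 4L, P)), K)
  for (v in rev(g$postorder)) {            # parents before children
    if (v <= g$ntip || is.null(A[[v]])) next
    chs <- g$children[[v]]
    for (ch in chs) {
      if (!(pre_all || marked[ch])) next
      prev <- vector("list", K)
      for (k in seq_len(K)) {
        acc <- A[[v]][[k]]
        for (s in chs) if (s != ch) acc <- acc * down$M[[s]][[k]]
        prev[[k]] <- acc
      }
      s <- .colmax4(prev[[1]])
      if (K > 1L) for (k in 2:K) s <- pmax(s, .colmax4(prev[[k]]))
      s[s <= 0] <- 1
      inv <- rep(1 / s, each = 4L)
      for (k in seq_len(K)) prev[[k]] <- prev[[k]] * inv
      if (pre_all) Pre[[ch]] <- prev
      if (ch > g$ntip && marked[ch]) {
        A[[ch]] <- lapply(seq_len(K), function(k)
          crossprod(pmats[[ch]][[k]], prev[[k]]))
      }
    }
  }
  list(A = A, Pre = Pre)
}

# Marginal posterior state probabilities at internal node v given down/up
# passes: normalize sum over categories of A_v * D_v.
.node_posterior <- function(ctx, A_v, D_v) {
  E <- A_v[[1]] * D_v[[1]]
  if (ctx$K > 1L) for (k in 2:ctx$K) E <- E + A_v[[k]] * D_v[[k]]
  tot <- colSums(E)
  tot[tot <= 0] <- 1
  t(E) / tot        # P x 4
}

# Log-likelihood of the whole alignment as a function of one branch length,
# all other branches fixed (up to a per-pattern constant).
.branch_loglik_fun <- function(g, ctx, Pre_v, D_v, weights) {
  K <- ctx$K
  function(t) {
    lik <- 0
    for (k in seq_len(K)) {
      Pm <- .ptrans(ctx$eigen, t * ctx$cat_rates[k])
      lik <- lik + colSums(Pre_v[[k]] * (Pm %*% D_v[[k]]))
    }
    sum(weights * log(pmax(lik / K, 1e-300)))
  }
}
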