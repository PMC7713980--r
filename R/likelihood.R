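# Likelihood evaluation on a fixed rooted topology, and estimation of branch
# lengths and substitution-model parameters.
#
# The topology is always taken as given (it typically comes from an external
# source such as a dated species tree); only branch lengths and, optionally,
# model parameters are estimated.  Branch lengths are optimized one at a time
# by Brent line search on [1e-8, 20], cycling branches in postorder, with
# cached "inside" and "outside" partial likelihoods so each line search costs
# O(patterns) per evaluation.  A damping step guarantees the total
# log-likelihood never decreases between rounds.

.as_patterns <- function(columns, species = NULL) {
  if (is.list(columns) && !is.null(columns$patterns))
    return(columns)
  if (is.matrix(columns) && is.character(columns)) {
    if (is.null(rownames(columns))) stop("character matrix must have species rownames")
    states <- matrix(NA_integer_, nrow(columns), ncol(columns),
                     dimnames = dimnames(columns))
    for (i in seq_len(nrow(columns)))
      states[i, ] <- .STATE_LOOKUP[as.integer(charToRaw(paste(columns[i, ], collapse = "")))]
    cp <- .collapse_patterns(states)
    return(list(patterns = cp$patterns, weights = cp$weights))
  }
  stop("columns must be a species x columns character matrix or a site-pattern list")
}

.check_usable <- function(pat) {
  usable <- colSums(!is.na(pat$patterns)) > 0
  if (!any(usable)) stop("alignment has zero usable columns (all data missing)")
  invisible(TRUE)
}

#' Log-likelihood of a single alignment column
#'
#' Felsenstein pruning under the given model on the fixed rooted topology.
#' Gaps and N are missing data (all-ones partial likelihood); the Gamma
#' mixture is averaged over categories with equal weights 1/K.
#'
#' @param tree rooted ape `phylo` with branch lengths
#' @param model a `substitution_model`
#' @param column named character vector, species -> state in
#'   \{A,C,G,T,N,-\}.  Tips absent from `column` are treated as missing;
#'   names absent from the tree raise an error.
#' @return the column log-likelihood (finite, <= 0)
#' @export
column_log_likelihood <- function(tree, model, column) {
  g <- .tree_graph(tree)
  extra <- setdiff(names(column), g$labels[seq_len(g$ntip)])
  if (length(extra))
    stop("column references species absent from tree: ", paste(extra, collapse = ", "))
  tips <- g$labels[seq_len(g$ntip)]
  states <- matrix(NA_integer_, length(tips), 1L, dimnames = list(tips, NULL))
  got <- intersect(tips, names(column))
  states[got, 1L] <- .STATE_LOOKUP[utf8ToInt(paste(column[got], collapse = ""))]
  ctx <- .model_context(model)
  down <- .peel_down(g, ctx, states)
  .down_loglik(g, ctx, down, 1)
}

#' Total log-likelihood of an alignment
#'
#' @inheritParams column_log_likelihood
#' @param columns a species x columns character matrix, or a site-pattern list
#'   from [site_patterns_from_blocks()]
#' @return total log-likelihood
#' @export
phylo_log_likelihood <- function(tree, model, columns) {
  pat <- .as_patterns(columns)
  g <- .tree_graph(tree)
  ctx <- .model_context(model)
  down <- .peel_down(g, ctx, pat$patterns)
  .down_loglik(g, ctx, down, pat$weights)
}

#' Estimate branch lengths on a fixed topology
#'
#' @inheritParams phylo_log_likelihood
#' @param min_len,max_len branch-length search bounds (defaults 1e-8 and 20)
#' @param max_rounds maximum optimization rounds over all branches (default 50)
#' @param tol convergence threshold on the largest branch-length change
#'   between rounds (default 1e-6)
#' @return the tree with estimated branch lengths; attributes `loglik` and
#'   `rounds` record the fit
#' @export
optimize_branch_lengths <- function(tree, model, columns,
                                    min_len = 1e-8, max_len = 20,
                                    max_rounds = 50L, tol = 1e-6) {
  pat <- .as_patterns(columns)
  .check_usable(pat)
  g0 <- .tree_graph(ensure_node_labels(tree))
  if (g0$ntip < 2L) stop("need at least 2 species")
  ctx <- .model_context(model)
  phy <- g0$phy
  blen <- pmin(pmax(g0$blen, min_len), max_len)
  blen[g0$root] <- NA_real_
  branch_nodes <- setdiff(g0$postorder, g0$root)

  ll_old <- -Inf
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    g <- .tree_graph(.set_blen(phy, blen))
    pmats <- .branch_pmats(g, ctx)
    down <- .peel_down(g, ctx, pat$patterns, pmats)
    ll_cur <- .down_loglik(g, ctx, down, pat$weights)
    up <- .peel_up(g, ctx, down, pre_all = TRUE, pmats = pmats)
    prop <- blen
    for (v in branch_nodes) {
      f <- .branch_loglik_fun(g, ctx, up$Pre[[v]], down$D[[v]], pat$weights)
      opt <- optimize(f, c(min_len, max_len), maximum = TRUE, tol = 1e-8)
      # keep the current value if the line search did not improve it there
      prop[v] <- if (opt$objective >= f(blen[v])) opt$maximum else blen[v]
    }
    # damping: the branch updates used partials from the round start, so
    # back off toward the previous lengths if the joint step overshoots
    step <- 1
    repeat {
      cand <- blen + step * (prop - blen)
      gc2 <- .tree_graph(.set_blen(phy, cand))
      dn2 <- .peel_down(gc2, ctx, pat$patterns)
      ll_new <- .down_loglik(gc2, ctx, dn2, pat$weights)
      if (ll_new >= ll_cur - 1e-9 || step < 1 / 1024) break
      step <- step / 2
    }
    delta <- max(abs(cand - blen), na.rm = TRUE)
    if (ll_new >= ll_cur) { blen <- cand; ll_cur <- ll_new }
    if (delta < tol || rounds >= max_rounds) break
    ll_old <- ll_cur
  }
  out <- .set_blen(phy, blen)
  attr(out, "loglik") <- ll_cur
  attr(out, "rounds") <- rounds
  out
}

#' Estimate substitution-model parameters on a fixed tree
#'
#' Base frequencies are fixed to the empirical counts of the alignment.
#' Exchangeabilities (normalized with GT = 1; under HKY85 only kappa is free)
#' and the Gamma shape alpha (on the interval 0.02 to 100) are optimized by coordinate
#' ascent with per-parameter Brent line searches.
#'
#' @inheritParams optimize_branch_lengths
#' @param family `"GTR"` or `"HKY85"`
#' @param k number of discrete Gamma categories (default 4)
#' @param estimate_alpha optimize the Gamma shape? (default TRUE; FALSE fits a
#'   rate-homogeneous model)
#' @param max_rounds maximum coordinate-ascent rounds (default 50)
#' @param tol convergence threshold on the largest relative parameter change
#' @param init optional named vector of starting values (subset of AC, AG,
#'   AT, CG, CT, kappa, alpha)
#' @return a `substitution_model` with attribute `loglik`
#' @export
estimate_model_params <- function(tree, columns, family = c("GTR", "HKY85"),
                                  k = 4L, estimate_alpha = TRUE,
                                  max_rounds = 50L, tol = 1e-6, init = NULL) {
  family <- match.arg(family)
  pat <- .as_patterns(columns)
  .check_usable(pat)
  g <- .tree_graph(ensure_node_labels(tree))

  counts <- vapply(1:4, function(b)
    sum(pat$weights * colSums(pat$patterns == b, na.rm = TRUE)), numeric(1))
  if (sum(counts) == 0) stop("alignment has zero usable columns")
  pi_hat <- pmax(counts, 1) / sum(pmax(counts, 1))

  make_model <- function(par) {
    if (family == "HKY85")
      substitution_model("HKY85", kappa = par[["kappa"]], base_freqs = pi_hat,
                         alpha = if (estimate_alpha) par[["alpha"]] else NULL, k = k)
    else
      substitution_model("GTR",
                         rates = c(AC = par[["AC"]], AG = par[["AG"]], AT = par[["AT"]],
                                   CG = par[["CG"]], CT = par[["CT"]], GT = 1),
                         base_freqs = pi_hat,
                         alpha = if (estimate_alpha) par[["alpha"]] else NULL, k = k)
  }
  ll <- function(par) {
    ctx <- .model_context(make_model(par))
    down <- .peel_down(g, ctx, pat$patterns)
    .down_loglik(g, ctx, down, pat$weights)
  }

  par <- if (family == "HKY85") c(kappa = 2) else
    c(AC = 1, AG = 1, AT = 1, CG = 1, CT = 1)
  if (estimate_alpha) par <- c(par, alpha = 1)
  if (!is.null(init)) {
    known <- intersect(names(init), names(par))
    par[known] <- init[known]
  }
  ll_cur <- ll(par)
  for (round in seq_len(max_rounds)) {
    par_old <- par; ll_old <- ll_cur
    for (p in names(par)) {
      bounds <- if (p == "alpha") log(c(0.02, 100)) else log(c(1e-3, 1e3))
      f <- function(lx) { pp <- par; pp[[p]] <- exp(lx); ll(pp) }
      opt <- optimize(f, bounds, maximum = TRUE, tol = 1e-7)
      if (opt$objective > ll_cur) {
        par[[p]] <- exp(opt$maximum); ll_cur <- opt$objective
      }
    }
    if (max(abs(par - par_old) / pmax(par_old, 1e-8)) < tol ||
        ll_cur - ll_old < 1e-8) break
  }
  out <- make_model(par)
  attr(out, "loglik") <- ll_cur
  out
}
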