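# Nucleotide substitution models: GTR and HKY85, with optional
# discrete-Gamma among-site rate heterogeneity.
#
# The rate matrix uses the standard reversible parameterization
# Q_ij = s_ij * pi_j (i != j), rows summing to zero, normalized so the mean
# rate at stationarity is one: -sum_i pi_i Q_ii = 1.  Branch lengths are then
# expected substitutions per site.

.RATE_NAMES <- c("AC", "AG", "AT", "CG", "CT", "GT")

#' Construct a substitution model
#'
#' @param family `"GTR"` or `"HKY85"`.  Under HKY85 the six exchangeabilities
#'   reduce to transition/transversion structure: AG = CT = kappa, the four
#'   transversions equal 1.
#' @param rates named vector of the six GTR exchangeabilities
#'   (AC, AG, AT, CG, CT, GT); ignored for HKY85
#' @param kappa transition/transversion ratio (HKY85 only, default 2)
#' @param base_freqs stationary base frequencies over A, C, G, T (must be
#'   positive and sum to 1)
#' @param alpha shape of the Gamma distribution of among-site rates; `NULL`
#'   means rate-homogeneous
#' @param k number of discrete Gamma categories (default 4; ignored when
#'   `alpha` is `NULL`)
#' @return an object of class `substitution_model`
#' @export
substitution_model <- function(family = c("GTR", "HKY85"),
                               rates = c(AC = 1, AG = 1, AT = 1, CG = 1, CT = 1, GT = 1),
                               kappa = 2,
                               base_freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                               alpha = NULL, k = 4L) {
  family <- match.arg(family)
  base_freqs <- unname(base_freqs)
  if (length(base_freqs) != 4L || any(base_freqs <= 0))
    stop("base_freqs must be 4 positive values")
  if (abs(sum(base_freqs) - 1) > 1e-12)
    base_freqs <- base_freqs / sum(base_freqs)
  if (family == "HKY85") {
    if (kappa <= 0) stop("kappa must be positive")
    rates <- c(AC = 1, AG = kappa, AT = 1, CG = 1, CT = kappa, GT = 1)
  } else {
    if (is.null(names(rates))) names(rates) <- .RATE_NAMES
    rates <- rates[.RATE_NAMES]
    if (anyNA(rates) || any(rates <= 0))
      stop("rates must be positive and named ", paste(.RATE_NAMES, collapse = ", "))
  }
  if (!is.null(alpha)) {
    if (alpha <= 0) stop("alpha must be positive")
    k <- as.integer(k)
    if (k < 1L) stop("k must be >= 1")
  } else k <- 1L
  structure(list(family = family, rates = rates,
                 base_freqs = setNames(base_freqs, BASES),
                 alpha = alpha, k = k),
            class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat(x$family, "model; pi = (", paste(signif(x$base_freqs, 4), collapse = ", "),
      ")\n  exchangeabilities:", paste(names(x$rates), signif(x$rates, 4),
                                      sep = "=", collapse = " "), "\n")
  if (is.null(x$alpha)) cat("  rate-homogeneous\n")
  else cat("  Gamma rates: alpha =", signif(x$alpha, 4), "with", x$k, "categories\n")
  invisible(x)
}

#' Build the normalized instantaneous rate matrix Q
#'
#' @param model a `substitution_model`
#' @return a 4x4 matrix with rows summing to zero, detailed balance
#'   `pi_i Q_ij = pi_j Q_ji`, and unit mean rate
#' @export
build_rate_matrix <- function(model) {
  pi <- model$base_freqs
  if (any(pi <= 0)) stop("base frequencies must be positive")
  s <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  s["A", "C"] <- model$rates["AC"]; s["A", "G"] <- model$rates["AG"]
  s["A", "T"] <- model$rates["AT"]; s["C", "G"] <- model$rates["CG"]
  s["C", "T"] <- model$rates["CT"]; s["G", "T"] <- model$rates["GT"]
  s <- s + t(s)
  Q <- s * rep(pi, each = 4)          # Q_ij = s_ij * pi_j
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))            # mean rate at stationarity
  Q / mu
}

# Spectral decomposition of a reversible Q via the symmetrized matrix
# B = diag(sqrt(pi)) Q diag(1/sqrt(pi)).  P(t) = R1 diag(exp(lambda t)) R2.
.model_eigen <- function(Q, pi) {
  sp <- sqrt(pi)
  B <- Q * (sp %o% (1 / sp))
  B <- (B + t(B)) / 2               # enforce symmetry against rounding
  e <- eigen(B, symmetric = TRUE)
  list(R1 = e$vectors / sp, R2 = t(e$vectors) * rep(sp, each = 4),
       lambda = e$values)
}

# Build the cached evaluation context for a model: Q, eigen system, category
# rates.  Everything downstream (likelihood, simulation, ASR) goes through
# this.
.model_context <- function(model) {
  Q <- build_rate_matrix(model)
  eg <- .model_eigen(Q, model$base_freqs)
  rates <- if (is.null(model$alpha)) 1 else gamma_category_rates(model$alpha, model$k)
  list(model = model, Q = Q, eigen = eg, pi = unname(model$base_freqs),
       cat_rates = rates, K = length(rates))
}

.ptrans <- function(eg, t) {
  P <- (eg$R1 * rep(exp(eg$lambda * t), each = 4)) %*% eg$R2
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Transition probability matrix P(t) = exp(Q t r)
#'
#' @param Q a 4x4 rate matrix from [build_rate_matrix()], or a
#'   `substitution_model`
#' @param t branch length (expected substitutions per site), must be >= 0
#' @param rate rate-category multiplier (default 1), must be > 0
#' @return 4x4 row-stochastic matrix
#' @export
transition_matrix <- function(Q, t, rate = 1) {
  if (t < 0) stop("branch length must be non-negative")
  if (rate <= 0) stop("rate multiplier must be positive")
  if (inherits(Q, "substitution_model")) {
    ctx <- .model_context(Q)
    P <- .ptrans(ctx$eigen, t * rate)
  } else {
    pi <- .q_stationary(Q)
    P <- .ptrans(.model_eigen(Q, pi), t * rate)
  }
  dimnames(P) <- list(BASES, BASES)
  P
}

# Stationary distribution of a reversible normalized Q (left null vector).
.q_stationary <- function(Q) {
  ns <- eigen(t(Q))
  i <- which.min(abs(ns$values))
  v <- Re(ns$vectors[, i])
  v / sum(v)
}

#' Discrete-Gamma rate categories (equal-probability, category means)
#'
#' K equal-probability categories of a Gamma(alpha, alpha) distribution
#' (mean 1); each category is represented by its conditional mean and the set
#' is renormalized to mean exactly 1.
#'
#' @param alpha Gamma shape (> 0)
#' @param k number of categories (>= 1)
#' @return non-decreasing positive rates of length `k`, mean 1
#' @export
gamma_category_rates <- function(alpha, k) {
  stopifnot(alpha > 0, k >= 1)
  k <- as.integer(k)
  if (k == 1L) return(1)
  qb <- qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
  # E[X | a < X < b] for Gamma(alpha, alpha) via the shape+1 CDF identity
  pg <- pgamma(qb, shape = alpha + 1, rate = alpha)
  rates <- k * diff(pg)
  rates / mean(rates)
}
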