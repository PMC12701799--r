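NUC <- c("A", "C", "G", "T")
EXCH_NAMES <- c("AC", "AG", "AT", "CG", "CT", "GT")

## IUPAC ambiguity -> compatible state sets (gap and ? fully undetermined)
iupac_sets <- local({
  m <- list(
    A = "A", C = "C", G = "G", T = "T", U = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"),
    N = NUC, "-" = NUC, "?" = NUC, X = NUC
  )
  lapply(m, function(s) NUC %in% s)
})

#' Construct a GTR+Gamma(+I) substitution model
#'
#' General time-reversible DNA model with discrete Gamma rate heterogeneity
#' (mean-of-quantile categories) and an optional proportion of invariant
#' sites. The rate matrix is normalized so the expected substitution rate at
#' stationarity is 1, i.e. branch lengths are in expected substitutions per
#' site.
#'
#' @param pi stationary frequencies (A, C, G, T), positive, summing to 1
#'   (renormalized if off by < 1e-6).
#' @param exch the six exchangeabilities (AC, AG, AT, CG, CT, GT), positive;
#'   only relative values matter.
#' @param alpha Gamma shape (> 0); large values approach rate homogeneity.
#' @param k number of discrete rate categories (>= 1).
#' @param p_inv proportion of invariant sites in [0, 1).
#' @return an object of class `gtr_model` holding `pi`, `exch`, `alpha`, `k`,
#'   `p_inv`, the normalized rate matrix `Q`, its symmetric eigensystem and
#'   the category `rates`.
#' @export
#' @examples
#' jc <- gtr_model()                     # Jukes-Cantor special case
#' round(jc$Q, 3)
gtr_model <- function(pi = rep(0.25, 4), exch = rep(1, 6),
                      alpha = 1, k = 4L, p_inv = 0) {
  stopifnot(length(pi) == 4L, all(pi > 0),
            length(exch) == 6L, all(exch > 0),
            alpha > 0, k >= 1L, p_inv >= 0, p_inv < 1)
  if (abs(sum(pi) - 1) > 1e-6)
    stop("stationary frequencies must sum to 1 (got ", sum(pi), ")")
  pi <- pi / sum(pi)
  names(pi) <- NUC
  names(exch) <- EXCH_NAMES
  Q <- matrix(0, 4, 4, dimnames = list(NUC, NUC))
  Q["A", "C"] <- Q["C", "A"] <- exch["AC"]
  Q["A", "G"] <- Q["G", "A"] <- exch["AG"]
  Q["A", "T"] <- Q["T", "A"] <- exch["AT"]
  Q["C", "G"] <- Q["G", "C"] <- exch["CG"]
  Q["C", "T"] <- Q["T", "C"] <- exch["CT"]
  Q["G", "T"] <- Q["T", "G"] <- exch["GT"]
  Q <- Q * rep(pi, each = 4)           # q_ij = exch_ij * pi_j
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))          # expected rate at stationarity
  Q <- Q / scale
  ## symmetrized eigendecomposition for stable matrix exponentials
  sp <- sqrt(pi)
  S <- Q * outer(sp, 1 / sp)
  S <- (S + t(S)) / 2
  eig <- eigen(S, symmetric = TRUE)
  structure(list(
    pi = pi, exch = exch, alpha = alpha, k = as.integer(k), p_inv = p_inv,
    Q = Q,
    eig = list(values = eig$values,
               left = eig$vectors * (1 / sp),    # D^{-1/2} V (rows scaled)
               right = t(eig$vectors) * rep(sp, each = 4)), # V' D^{1/2}
    rates = discrete_gamma_rates(alpha, k)
  ), class = "gtr_model")
}

#' @export
print.gtr_model <- function(x, ...) {
  cat("GTR+Gamma model: alpha =", signif(x$alpha, 4),
      "k =", x$k, if (x$p_inv > 0) paste("p_inv =", signif(x$p_inv, 4)), "\n")
  cat("  pi:  ", paste(sprintf("%s=%.4f", NUC, x$pi), collapse = " "), "\n")
  cat("  exch:", paste(sprintf("%s=%.3f", EXCH_NAMES, x$exch),
                       collapse = " "), "\n")
  invisible(x)
}

#' Discrete Gamma rate categories (mean-of-bin discretization)
#'
#' Splits the Gamma(alpha, rate = alpha) distribution (mean 1) into k
#' equal-probability bins and returns each bin's conditional mean, so the
#' category rates are strictly increasing and average exactly to 1.
#'
#' @param alpha Gamma shape (> 0).
#' @param k number of categories (>= 1).
#' @return numeric vector of k rates.
#' @export
discrete_gamma_rates <- function(alpha, k) {
  stopifnot(alpha > 0, k >= 1L)
  k <- as.integer(k)
  if (k == 1L) return(1)
  ## E[X | q_{i} < X <= q_{i+1}] * 1/k-probability bins, Gamma(a, rate a):
  ## integral of x f(x) over a bin equals the Gamma(a+1, rate a) cdf increment
  q <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = alpha,
                     rate = alpha)
  cdf1 <- stats::pgamma(q, shape = alpha + 1, rate = alpha)
  k * diff(cdf1)
}

#' Normalized GTR rate matrix
#'
#' @param model a `gtr_model`.
#' @return 4x4 rate matrix with rows summing to 0, scaled to one expected
#'   substitution per unit branch length.
#' @export
gtr_rate_matrix <- function(model) {
  stopifnot(inherits(model, "gtr_model"))
  model$Q
}

#' Transition probability matrix exp(Q t r)
#'
#' @param model a `gtr_model`.
#' @param t branch length (>= 0).
#' @param rate rate-category multiplier (>= 0).
#' @return 4x4 row-stochastic matrix.
#' @export
transition_matrix <- function(model, t, rate = 1) {
  stopifnot(inherits(model, "gtr_model"), t >= 0, rate >= 0)
  e <- model$eig
  P <- e$left %*% (exp(e$values * t * rate) * e$right)
  P[P < 0] <- 0
  P[P > 1] <- 1
  dimnames(P) <- list(NUC, NUC)
  P
}
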