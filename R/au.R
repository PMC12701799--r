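#' RELL bootstrap proportions across scales
#'
#' Resampling-estimated-log-likelihood bootstrap: for each scale r, draws B
#' replicates of round(r * n) site indices with replacement, totals each
#' tree's resampled log-likelihood, and records the fraction of replicates in
#' which the tree is maximal (exact ties share the credit equally), so the
#' proportions over trees sum to 1 at every scale.
#'
#' @param site_lnl numeric matrix, trees x sites, of per-site
#'   log-likelihoods computed on the same alignment.
#' @param scales replicate-size multipliers (> 0).
#' @param B bootstrap replicates per scale.
#' @param seed optional integer seed.
#' @return matrix of proportions, trees x scales.
#' @export
rell_bootstrap_proportions <- function(site_lnl,
                                       scales = seq(0.5, 1.4, by = 0.1),
                                       B = 1000L, seed = NULL) {
  stopifnot(is.matrix(site_lnl), all(scales > 0), B >= 1L)
  if (nrow(site_lnl) < 2L)
    stop("the test needs at least 2 trees")
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(site_lnl)
  ntree <- nrow(site_lnl)
  bp <- matrix(0, ntree, length(scales),
               dimnames = list(rownames(site_lnl), paste0("r", scales)))
  for (si in seq_along(scales)) {
    np <- max(1L, round(scales[si] * n))
    ## all B replicates at once: one flat index draw, block-wise tabulation
    idx <- sample.int(n, np * B, replace = TRUE)
    cnt <- matrix(tabulate(idx + rep(seq_len(B) - 1L, each = np) * n,
                           nbins = n * B), nrow = n)
    tot <- site_lnl %*% cnt                       # trees x B
    mx <- tot[1L, ]
    for (r in 2:ntree) mx <- pmax(mx, tot[r, ])
    is_top <- tot >= rep(mx - 1e-12 * pmax(1, abs(mx)), each = ntree)
    wins <- is_top / rep(colSums(is_top), each = ntree)  # ties share credit
    bp[, si] <- rowSums(wins) / B
  }
  bp
}

#' AU p-value from multiscale bootstrap proportions
#'
#' Fits the signed distance d and curvature c of Shimodaira's multiscale
#' bootstrap model by weighted least squares of
#' qnorm(1 - bp_r) = d * sqrt(r) + c / sqrt(r) over scales (weights from the
#' binomial variance of each proportion via the delta method), and returns
#' p_au = 1 - pnorm(d - c). Proportions are clamped to [1/(B+1), B/(B+1)]
#' before the probit transform.
#'
#' @param bp numeric vector of bootstrap proportions, one per scale.
#' @param scales the scales used.
#' @param B replicates per scale (for clamping and weights).
#' @return list with `d`, `c`, `p_au`, and `rss` (weighted residual sum).
#' @export
au_pvalue <- function(bp, scales = seq(0.5, 1.4, by = 0.1), B = 1000L) {
  if (length(unique(scales)) < 2L)
    stop("AU fit needs at least 2 distinct scales")
  stopifnot(length(bp) == length(scales))
  ## degenerate cases carry no usable slope information for the multiscale
  ## fit: a tree that wins at most one replicate per scale is maximally
  ## implausible, one that loses at most one is maximally plausible
  if (all(bp * B <= 1)) return(list(d = Inf, c = 0, p_au = 0, rss = 0))
  if (all(bp * B >= B - 1)) return(list(d = -Inf, c = 0, p_au = 1, rss = 0))
  bp <- pmin(pmax(bp, 1 / (B + 1)), B / (B + 1))
  z <- stats::qnorm(1 - bp)
  w <- (B * stats::dnorm(z)^2) / (bp * (1 - bp))
  X <- cbind(sqrt(scales), 1 / sqrt(scales))
  fit <- stats::lm.wfit(X, z, w)
  d <- unname(fit$coefficients[1L])
  cc <- unname(fit$coefficients[2L])
  list(d = d, c = cc, p_au = 1 - stats::pnorm(d - cc),
       rss = sum(w * fit$residuals^2))
}

#' Plausible tree set via the approximately unbiased test
#'
#' Runs the multiscale RELL bootstrap jointly over all candidate trees,
#' computes each tree's AU p-value, and flags trees with p_au >= alpha as
#' plausible. The maximum-likelihood tree is always flagged plausible, so the
#' plausible set is never empty.
#'
#' @inheritParams rell_bootstrap_proportions
#' @param alpha significance level (default 0.05).
#' @return data.frame with one row per tree: `tree`, `lnl`, `d`, `c`, `p_au`,
#'   `plausible`; the bootstrap proportion matrix is attached as attribute
#'   `"bp"`.
#' @export
plausible_set <- function(site_lnl, alpha = 0.05,
                          scales = seq(0.5, 1.4, by = 0.1),
                          B = 1000L, seed = NULL) {
  bp <- rell_bootstrap_proportions(site_lnl, scales, B, seed)
  fits <- apply(bp, 1L, au_pvalue, scales = scales, B = B)
  p <- vapply(fits, `[[`, numeric(1L), "p_au")
  lnl <- rowSums(site_lnl)
  plausible <- p >= alpha
  plausible[which.max(lnl)] <- TRUE
  out <- data.frame(
    tree = if (is.null(rownames(site_lnl))) paste0("tree", seq_len(nrow(site_lnl)))
           else rownames(site_lnl),
    lnl = lnl,
    d = vapply(fits, `[[`, numeric(1L), "d"),
    c = vapply(fits, `[[`, numeric(1L), "c"),
    p_au = p,
    plausible = plausible,
    row.names = NULL
  )
  attr(out, "bp") <- bp
  out
}
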