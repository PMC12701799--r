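## Pattern compression: unique columns with weights plus the map back to
## sites.  Leaf partial likelihoods are 4 x n_patterns matrices.
compress_patterns <- function(msa) {
  key <- do.call(paste0, lapply(seq_len(nrow(msa)), function(i) msa[i, ]))
  uniq <- !duplicated(key)
  idx <- match(key, key[uniq])
  list(msa = msa[, uniq, drop = FALSE],
       weights = as.vector(table(idx)[as.character(seq_len(sum(uniq)))]),
       site_index = idx)
}

leaf_partials <- function(msa) {
  lapply(seq_len(nrow(msa)), function(i) {
    sets <- iupac_sets[msa[i, ]]
    bad <- vapply(sets, is.null, logical(1L))
    if (any(bad))
      stop("unknown character(s) in sequence ", rownames(msa)[i], ": ",
           paste(unique(msa[i, bad]), collapse = " "))
    matrix(as.numeric(unlist(sets)), nrow = 4L)
  })
}

## Cached per-alignment likelihood data: compressed patterns, leaf partials
## (in tree tip order) and the branch-length-free invariant-class site
## likelihoods.
lik_data <- function(tree, msa, model) {
  msa <- as_msa(msa)
  if (!setequal(tree$tip.label, rownames(msa)))
    stop("tree leaves and MSA taxa differ")
  if (ncol(msa) == 0L) stop("alignment has zero columns")
  msa <- msa[tree$tip.label, , drop = FALSE]
  cmp <- compress_patterns(msa)
  cmp$pl <- leaf_partials(cmp$msa)
  cmp$inv_lik <- if (model$p_inv > 0)
    invariant_site_lik(cmp$msa, model$pi) else NULL
  cmp
}

## exp(Q t) via the cached eigensystem, without input checks (hot path)
transition_matrix_fast <- function(model, tt) {
  e <- model$eig
  P <- e$left %*% (exp(e$values * tt) * e$right)
  P[P < 0] <- 0
  P
}

col_maxs4 <- function(m) pmax(m[1L, ], m[2L, ], m[3L, ], m[4L, ])

## mix per-category per-pattern log-likelihoods (k x npat) into site
## log-likelihoods, with optional invariant-class mixing
mix_site_ll <- function(cat_ll, model, inv_lik) {
  mx <- cat_ll[1L, ]
  if (nrow(cat_ll) > 1L)
    for (i in 2L:nrow(cat_ll)) mx <- pmax(mx, cat_ll[i, ])
  s <- exp(cat_ll[1L, ] - mx)
  if (nrow(cat_ll) > 1L)
    for (i in 2L:nrow(cat_ll)) s <- s + exp(cat_ll[i, ] - mx)
  ll <- mx + log(s / nrow(cat_ll))
  if (model$p_inv > 0)
    ll <- log((1 - model$p_inv) * exp(ll) + model$p_inv * inv_lik)
  ll
}

## Lower (tip-side) conditional likelihoods for one rate category, with
## per-node rescaling.  Returns per-node partials and log-scalers plus the
## per-edge child contributions P_e %*% L_child needed by the upper pass.
lower_pass <- function(e, elen, nt, nnode, pl, model, rate) {
  nn <- nt + nnode
  L <- vector("list", nn)
  ls <- vector("list", nn)
  contrib <- vector("list", nrow(e))
  zero <- rep(0, ncol(pl[[1L]]))
  rescale <- function(v) {        # internal node complete: pull out scaler
    mx <- col_maxs4(L[[v]])
    mx[mx <= 0] <- 1
    L[[v]] <<- L[[v]] / rep(mx, each = 4L)
    ls[[v]] <<- ls[[v]] + log(mx)
  }
  for (i in seq_len(nrow(e))) {
    par <- e[i, 1L]; ch <- e[i, 2L]
    if (ch > nt) rescale(ch)      # postorder: ch's subtree is complete
    childL <- if (ch <= nt) pl[[ch]] else L[[ch]]
    child_ls <- if (ch <= nt) zero else ls[[ch]]
    P <- transition_matrix_fast(model, elen[i] * rate)
    contrib[[i]] <- P %*% childL
    if (is.null(L[[par]])) {
      L[[par]] <- contrib[[i]]
      ls[[par]] <- child_ls
    } else {
      L[[par]] <- L[[par]] * contrib[[i]]
      ls[[par]] <- ls[[par]] + child_ls
    }
  }
  list(L = L, ls = ls, contrib = contrib)
}

## Per-pattern log-likelihoods for one category from a completed lower pass
category_loglik <- function(low, root, model) {
  log(colSums(model$pi * low$L[[root]])) + low$ls[[root]]
}

## Internal engine: per-pattern site log-likelihoods.
pattern_loglik <- function(tree, ld, model) {
  nt <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  e <- tr$edge
  root <- e[nrow(e), 1L]
  k <- model$k
  cat_ll <- matrix(0, k, ncol(ld$msa))
  for (ci in seq_len(k)) {
    low <- lower_pass(e, tr$edge.length, nt, tr$Nnode, ld$pl, model,
                      model$rates[ci])
    cat_ll[ci, ] <- category_loglik(low, root, model)
  }
  mix_site_ll(cat_ll, model, ld$inv_lik)
}

## likelihood of each pattern under rate 0: sum_x pi_x * prod_leaves 1{x ok}
invariant_site_lik <- function(msa, pi) {
  ok <- matrix(TRUE, 4L, ncol(msa))
  for (i in seq_len(nrow(msa))) {
    sets <- iupac_sets[msa[i, ]]
    ok <- ok & matrix(as.logical(unlist(sets)), nrow = 4L)
  }
  colSums(pi * ok)
}

#' Per-site log-likelihoods under GTR+Gamma(+I)
#'
#' Felsenstein pruning with discrete Gamma rate mixing and numerical
#' rescaling. Gap and ambiguity characters contribute a partial likelihood of
#' 1 for every compatible state (gaps are fully undetermined). The sum of the
#' returned vector is the tree log-likelihood; internally the computation is
#' pattern-compressed.
#'
#' @param tree `phylo` whose tips match the MSA's taxa.
#' @param msa character matrix.
#' @param model a `gtr_model`.
#' @return numeric vector, one natural-log likelihood per site.
#' @export
site_log_likelihoods <- function(tree, msa, model) {
  ld <- lik_data(tree, msa, model)
  pattern_loglik(tree, ld, model)[ld$site_index]
}

#' Tree log-likelihood
#'
#' @inheritParams site_log_likelihoods
#' @return total natural-log likelihood.
#' @export
tree_log_likelihood <- function(tree, msa, model) {
  ld <- lik_data(tree, msa, model)
  sum(pattern_loglik(tree, ld, model) * ld$weights)
}

BL_MIN <- 1e-9
BL_MAX <- 100

## One sweep of edge-local branch-length optimization.  Lower and upper
## partials are computed once at the sweep's current lengths; each edge's
## one-dimensional problem is then exact in its own length given the others
## (a Jacobi-style sweep).  Returns proposed lengths.
brlen_sweep <- function(tr, ld, model) {
  nt <- length(tr$tip.label)
  e <- tr$edge
  ne <- nrow(e)
  root <- e[ne, 1L]
  npat <- ncol(ld$msa)
  k <- model$k
  zero <- rep(0, npat)
  lows <- vector("list", k)
  Us <- vector("list", k)        # per category: per-edge upper partials
  Uls <- vector("list", k)       # and their log-scalers
  for (ci in seq_len(k)) {
    low <- lower_pass(e, tr$edge.length, nt, tr$Nnode, ld$pl, model,
                      model$rates[ci])
    ## upper pass, preorder (reverse postorder): Uhat per node, U per edge
    Uhat <- vector("list", nt + tr$Nnode)
    Uhat_ls <- vector("list", nt + tr$Nnode)
    Uhat[[root]] <- matrix(model$pi, 4L, npat)
    Uhat_ls[[root]] <- zero
    U <- vector("list", ne)
    U_ls <- vector("list", ne)
    kids <- split(seq_len(ne), e[, 1L])
    for (i in rev(seq_len(ne))) {
      par <- e[i, 1L]; ch <- e[i, 2L]
      sib <- setdiff(kids[[as.character(par)]], i)
      u <- Uhat[[par]]
      uls <- Uhat_ls[[par]]
      for (j in sib) {
        u <- u * low$contrib[[j]]
        cls <- if (e[j, 2L] <= nt) zero else low$ls[[e[j, 2L]]]
        uls <- uls + cls
      }
      mx <- col_maxs4(u)
      mx[mx <= 0] <- 1
      u <- u / rep(mx, each = 4L)
      uls <- uls + log(mx)
      U[[i]] <- u
      U_ls[[i]] <- uls
      if (ch > nt) {
        P <- transition_matrix_fast(model, tr$edge.length[i] * model$rates[ci])
        Uhat[[ch]] <- crossprod(P, u)
        Uhat_ls[[ch]] <- uls
      }
    }
    lows[[ci]] <- low
    Us[[ci]] <- U
    Uls[[ci]] <- U_ls
  }
  w <- ld$weights
  lens <- tr$edge.length
  for (i in seq_len(ne)) {
    ch <- e[i, 2L]
    Lch <- lapply(seq_len(k), function(ci)
      if (ch <= nt) ld$pl[[ch]] else lows[[ci]]$L[[ch]])
    Lls <- lapply(seq_len(k), function(ci)
      if (ch <= nt) zero else lows[[ci]]$ls[[ch]])
    f <- function(logt) {
      tt <- exp(logt)
      cat_ll <- matrix(0, k, npat)
      for (ci in seq_len(k)) {
        P <- transition_matrix_fast(model, tt * model$rates[ci])
        lik <- colSums(Us[[ci]][[i]] * (P %*% Lch[[ci]]))
        lik[lik <= 0] <- 1e-300
        cat_ll[ci, ] <- log(lik) + Uls[[ci]][[i]] + Lls[[ci]]
      }
      -sum(mix_site_ll(cat_ll, model, ld$inv_lik) * w)
    }
    cur <- -f(log(max(lens[i], BL_MIN)))
    opt <- stats::optimize(f, lower = log(BL_MIN), upper = log(BL_MAX),
                           tol = 1e-4)
    if (-opt$objective > cur) lens[i] <- exp(opt$minimum)
  }
  lens
}

#' Optimize branch lengths by sweeps of edge-local line search
#'
#' Each sweep computes the tree's lower and upper conditional likelihoods
#' once and then solves every branch's one-dimensional problem (bracketed
#' line search on the log scale, bounds [1e-9, 100]); a sweep whose joint
#' update fails to improve the log-likelihood is rejected, so the returned
#' log-likelihood never decreases. Sweeps repeat until the gain drops below
#' `tol` or `max_rounds` is reached.
#'
#' @inheritParams site_log_likelihoods
#' @param tol stop when a sweep improves lnL by less than this.
#' @param max_rounds maximum number of sweeps.
#' @return list with `tree` (optimized lengths) and `lnl`.
#' @export
optimize_branch_lengths <- function(tree, msa, model, tol = 1e-3,
                                    max_rounds = 5L) {
  optimize_branch_lengths_ld(tree, lik_data(tree, msa, model), model,
                             tol, max_rounds)
}

## Same, with the per-alignment cache precomputed (internal hot path)
optimize_branch_lengths_ld <- function(tree, ld, model, tol = 1e-3,
                                       max_rounds = 5L) {
  tr <- ape::reorder.phylo(tree, "postorder")
  tr$edge.length[tr$edge.length < BL_MIN] <- BL_MIN
  cur <- sum(pattern_loglik(tr, ld, model) * ld$weights)
  for (round in seq_len(max_rounds)) {
    lens <- brlen_sweep(tr, ld, model)
    ## a joint (Jacobi-style) update can overshoot along near-degenerate
    ## directions; damp by log-space halving toward the current lengths
    accepted <- FALSE
    for (damp in 0:4) {
      cand <- tr
      cand$edge.length <- exp((log(pmax(lens, BL_MIN)) +
                               (2^damp - 1) * log(pmax(tr$edge.length,
                                                       BL_MIN))) / 2^damp)
      lnl <- sum(pattern_loglik(cand, ld, model) * ld$weights)
      if (lnl > cur) {
        improve <- lnl - cur
        tr <- cand
        cur <- lnl
        accepted <- TRUE
        break
      }
    }
    if (!accepted || improve < tol) break
  }
  list(tree = ape::reorder.phylo(tr, "cladewise"), lnl = cur)
}

#' Evaluate a tree: log-likelihood with optional parameter optimization
#'
#' Coordinate descent over the enabled parameter blocks, in the order branch
#' lengths, Gamma shape, exchangeabilities, stationary frequencies, repeated
#' until the outer improvement drops below `tol`. Evaluating several
#' topologies on the same alignment with identical flags yields comparable
#' log-likelihood scores.
#'
#' @inheritParams site_log_likelihoods
#' @param optimize character subset of `c("brlens", "alpha", "exch", "pi")`;
#'   empty means plain evaluation.
#' @param tol outer convergence tolerance in lnL units.
#' @param max_rounds maximum outer rounds.
#' @return list with `lnl`, `tree`, `model`, and `site_lnl` (per-site
#'   log-likelihood vector at the returned parameters).
#' @export
evaluate_tree <- function(tree, msa, model, optimize = character(0),
                          tol = 1e-3, max_rounds = 3L) {
  stopifnot(all(optimize %in% c("brlens", "alpha", "exch", "pi")))
  ld <- lik_data(tree, msa, model)
  lnl_of <- function(tr, mod) sum(pattern_loglik(tr, ld, mod) * ld$weights)
  cur <- lnl_of(tree, model)
  remake <- function(pi = model$pi, exch = model$exch, alpha = model$alpha)
    gtr_model(pi, exch, alpha, model$k, model$p_inv)
  if (length(optimize)) for (round in seq_len(max_rounds)) {
    before <- cur
    if ("brlens" %in% optimize) {
      ob <- optimize_branch_lengths(tree, msa, model, tol = tol,
                                    max_rounds = 3L)
      tree <- ob$tree; cur <- ob$lnl
    }
    if ("alpha" %in% optimize) {
      f <- function(la) -lnl_of(tree, remake(alpha = exp(la)))
      opt <- stats::optimize(f, lower = log(0.02), upper = log(100),
                             tol = 1e-3)
      if (-opt$objective > cur) {
        model <- remake(alpha = exp(opt$minimum))
        cur <- -opt$objective
      }
    }
    if ("exch" %in% optimize) {
      for (j in 1:5) {           # GT fixed at 1 as the reference rate
        f <- function(lx) {
          ex <- model$exch; ex[j] <- exp(lx); ex <- ex / ex[6L]
          -lnl_of(tree, remake(exch = ex))
        }
        cv <- log(model$exch[j] / model$exch[6L])
        opt <- stats::optimize(f, lower = cv - 3, upper = cv + 3, tol = 1e-3)
        if (-opt$objective > cur) {
          ex <- model$exch; ex[j] <- exp(opt$minimum); ex <- ex / ex[6L]
          model <- remake(exch = ex)
          cur <- -opt$objective
        }
      }
    }
    if ("pi" %in% optimize) {
      for (j in 1:3) {           # T is the softmax reference
        f <- function(lx) {
          lp <- log(model$pi / model$pi[4L]); lp[j] <- lx
          -lnl_of(tree, remake(pi = exp(lp) / sum(exp(lp))))
        }
        cv <- log(model$pi[j] / model$pi[4L])
        opt <- stats::optimize(f, lower = cv - 2, upper = cv + 2, tol = 1e-3)
        if (-opt$objective > cur) {
          lp <- log(model$pi / model$pi[4L]); lp[j] <- opt$minimum
          model <- remake(pi = exp(lp) / sum(exp(lp)))
          cur <- -opt$objective
        }
      }
    }
    if (cur - before < tol) break
  }
  list(lnl = cur, tree = tree, model = model,
       site_lnl = pattern_loglik(tree, ld, model)[ld$site_index])
}
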