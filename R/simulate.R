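#' Zipfian indel model
#'
#' Insertion/deletion process with Poisson event counts per branch (expected
#' events = rate x branch length x current sequence length) and event lengths
#' drawn from a truncated Zipf (power-law) distribution
#' P(L = l) proportional to l^(-s), l = 1..max_len.
#'
#' @param ins_rate insertion events per site per unit branch length (>= 0).
#' @param del_rate deletion analogue (>= 0).
#' @param zipf_s Zipf exponent (> 0; > 1 is the realistic regime).
#' @param max_len truncation length (>= 1).
#' @return object of class `indel_model`.
#' @export
indel_model <- function(ins_rate = 0, del_rate = 0, zipf_s = 1.5,
                        max_len = 10L) {
  stopifnot(ins_rate >= 0, del_rate >= 0, zipf_s > 0, max_len >= 1L)
  pmf <- seq_len(max_len)^(-zipf_s)
  structure(list(ins_rate = ins_rate, del_rate = del_rate,
                 zipf_s = zipf_s, max_len = as.integer(max_len),
                 pmf = pmf / sum(pmf)),
            class = "indel_model")
}

#' Draw indel lengths from the truncated Zipf distribution
#'
#' @param indel an `indel_model`.
#' @param n number of draws.
#' @return integer vector in [1, max_len].
#' @export
sample_zipf <- function(indel, n = 1L) {
  stopifnot(inherits(indel, "indel_model"))
  if (indel$max_len == 1L) return(rep(1L, n))
  sample.int(indel$max_len, n, replace = TRUE, prob = indel$pmf)
}

## Draw child states given parent states for one edge, by rate category.
## states: integer 1..4; cat: integer category per column; Plist: per-category
## transition matrices.
evolve_states <- function(states, cat, Plist) {
  out <- states
  for (ci in seq_along(Plist)) {
    P <- Plist[[ci]]
    for (s in 1:4) {
      idx <- which(cat == ci & states == s)
      if (length(idx))
        out[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[s, ])
    }
  }
  out
}

#' Simulate an alignment along a tree under GTR+Gamma with optional indels
#'
#' Substitutions evolve down the tree by drawing each site's state from the
#' transition probabilities of its rate category; with an indel model,
#' insertion and deletion events are placed on each branch (Poisson counts
#' with mean rate x branch length x current length, uniform positions,
#' Zipf lengths). Insertions create fresh alignment columns, reported as gaps
#' in every lineage that never carried them, so the output is a gapped
#' alignment whose columns are globally consistent. Inserted residues start
#' from the stationary distribution and receive their own rate category.
#' Columns carried by no surviving leaf are dropped.
#'
#' With `indel = NULL` (or both rates 0) the process reduces exactly to
#' gapless simulation: no indel random draws are made, so the substitution
#' random stream is untouched.
#'
#' @param tree `phylo` with branch lengths (expected substitutions/site).
#' @param model a `gtr_model`.
#' @param n_sites root sequence length (>= 1).
#' @param indel optional `indel_model`.
#' @param seed optional integer seed.
#' @return character matrix (leaves x alignment columns).
#' @export
simulate_msa <- function(tree, model, n_sites, indel = NULL, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "gtr_model"),
            n_sites >= 1L)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tree$edge.length))
    stop("tree needs branch lengths")
  nt <- ape::Ntip(tree)
  tr <- ape::reorder.phylo(tree, "cladewise")
  root <- tr$edge[1L, 1L]
  no_indel <- is.null(indel) ||
    (indel$ins_rate == 0 && indel$del_rate == 0)

  ## rate category per column: 0 = invariant (rate 0), else 1..k
  draw_cats <- function(n) {
    cats <- sample.int(model$k, n, replace = TRUE)
    if (model$p_inv > 0)
      cats[stats::runif(n) < model$p_inv] <- 0L
    cats
  }
  rates0 <- c(0, model$rates)          # index by cat + 1

  ## global column registry
  col_order <- seq_len(n_sites)        # ids in alignment order
  col_cat <- draw_cats(n_sites)        # by id
  next_id <- n_sites + 1L

  seqs <- vector("list", nt + tr$Nnode)     # per node: list(ids, states)
  root_states <- sample.int(4L, n_sites, replace = TRUE, prob = model$pi)
  seqs[[root]] <- list(ids = seq_len(n_sites), states = root_states)

  ## cladewise order guarantees parents are visited before children
  for (i in seq_len(nrow(tr$edge))) {
    par <- tr$edge[i, 1L]; child <- tr$edge[i, 2L]
    t_e <- tr$edge.length[i]
    ids <- seqs[[par]]$ids
    states <- seqs[[par]]$states
    cat <- col_cat[ids]
    ## substitutions (invariant category never changes)
    if (t_e > 0 && length(ids)) {
      Plist <- lapply(model$rates, function(r) transition_matrix(model, t_e, r))
      states <- evolve_states(states, cat, Plist)
    }
    if (!no_indel) {
      L <- length(ids)
      ## deletions
      lam_del <- indel$del_rate * t_e * L
      n_del <- if (lam_del > 0) stats::rpois(1L, lam_del) else 0L
      if (n_del > 0) for (ev in seq_len(n_del)) {
        L <- length(ids)
        if (L == 0L) break
        len <- sample_zipf(indel, 1L)
        start <- sample.int(L, 1L)
        drop <- start:min(L, start + len - 1L)
        ids <- ids[-drop]; states <- states[-drop]
      }
      ## insertions
      lam_ins <- indel$ins_rate * t_e * max(length(ids), 1L)
      n_ins <- if (lam_ins > 0) stats::rpois(1L, lam_ins) else 0L
      if (n_ins > 0) for (ev in seq_len(n_ins)) {
        L <- length(ids)
        len <- sample_zipf(indel, 1L)
        pos <- sample.int(L + 1L, 1L) - 1L    # insert after local pos
        new_ids <- next_id:(next_id + len - 1L)
        next_id <- next_id + len
        new_cats <- draw_cats(len)
        col_cat[new_ids] <- new_cats
        new_states <- sample.int(4L, len, replace = TRUE, prob = model$pi)
        ## register in global order: after the global slot of the local
        ## column at `pos` (or before this lineage's first column)
        gpos <- if (pos == 0L) {
          if (L == 0L) length(col_order) else match(ids[1L], col_order) - 1L
        } else match(ids[pos], col_order)
        col_order <- append(col_order, new_ids, after = gpos)
        ids <- append(ids, new_ids, after = pos)
        states <- append(states, new_states, after = pos)
      }
    }
    seqs[[child]] <- list(ids = ids, states = states)
  }

  ## assemble leaf rows over the union of leaf-carried columns
  leaf_ids <- sort(unique(unlist(lapply(seq_len(nt), function(i) seqs[[i]]$ids))))
  if (!length(leaf_ids))
    stop("all alignment columns were deleted; lower del_rate")
  keep <- col_order[col_order %in% leaf_ids]
  out <- matrix("-", nt, length(keep),
                dimnames = list(tr$tip.label, NULL))
  pos_of <- integer(max(keep))
  pos_of[keep] <- seq_along(keep)
  for (i in seq_len(nt)) {
    s <- seqs[[i]]
    if (length(s$ids))
      out[i, pos_of[s$ids]] <- NUC[s$states]
  }
  out
}

#' Simulate a gapless alignment
#'
#' Convenience wrapper over [simulate_msa()] with the indel process disabled.
#'
#' @inheritParams simulate_msa
#' @return character matrix (leaves x `n_sites`).
#' @export
simulate_gapless <- function(tree, model, n_sites, seed = NULL) {
  simulate_msa(tree, model, n_sites, indel = NULL, seed = seed)
}
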