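# Independent oracles and small fixture builders used across the suite.

# Quartet topology oracle via the four-point condition on path lengths with
# unit edge lengths: the pairing with the strictly smallest distance sum is
# the induced topology; ties mean the quartet is unresolved.
quartet_distance_oracle <- function(t1, t2) {
  labs <- sort(t1$tip.label)
  unit <- function(tr) {
    tr$edge.length <- rep(1, nrow(tr$edge))
    stats::cophenetic(tr)[labs, labs]
  }
  D1 <- unit(t1); D2 <- unit(t2)
  resolve <- function(D, q) {
    s <- c(D[q[1], q[2]] + D[q[3], q[4]],
           D[q[1], q[3]] + D[q[2], q[4]],
           D[q[1], q[4]] + D[q[2], q[3]])
    m <- which(s == min(s))
    if (length(m) > 1L) 0L else m
  }
  quads <- utils::combn(length(labs), 4L)
  diffs <- vapply(seq_len(ncol(quads)), function(i) {
    q <- quads[, i]
    resolve(D1, q) != resolve(D2, q)
  }, logical(1L))
  mean(diffs)
}

# Exhaustive likelihood oracle: sum over all internal-node state assignments,
# mixing rate categories (and the invariant class) exactly as the model does.
exhaustive_loglik_oracle <- function(tree, msa, model) {
  tr <- ape::reorder.phylo(tree, "postorder")
  nt <- ape::Ntip(tr)
  nn <- tr$Nnode
  msa <- msa[tr$tip.label, , drop = FALSE]
  states_of <- function(ch) which(phybench:::iupac_sets[[ch]])
  total <- 0
  root <- tr$edge[nrow(tr$edge), 1L]
  rates <- c(if (model$p_inv > 0) 0, model$rates)
  rate_w <- c(if (model$p_inv > 0) model$p_inv,
              rep((1 - model$p_inv) / model$k, model$k))
  for (site in seq_len(ncol(msa))) {
    site_lik <- 0
    for (ri in seq_along(rates)) {
      Ps <- lapply(seq_len(nrow(tr$edge)), function(i)
        transition_matrix(model, tr$edge.length[i], rates[ri]))
      assign_grid <- as.matrix(expand.grid(rep(list(1:4), nn)))
      lik <- 0
      for (g in seq_len(nrow(assign_grid))) {
        node_state <- c(rep(NA_integer_, nt), assign_grid[g, ])
        p <- unname(model$pi[node_state[root]])
        for (i in seq_len(nrow(tr$edge))) {
          par <- tr$edge[i, 1L]; ch <- tr$edge[i, 2L]
          if (ch <= nt) {
            ok <- states_of(msa[ch, site])
            p <- p * sum(Ps[[i]][node_state[par], ok])
          } else {
            p <- p * Ps[[i]][node_state[par], node_state[ch]]
          }
        }
        lik <- lik + p
      }
      site_lik <- site_lik + rate_w[ri] * lik
    }
    total <- total + log(site_lik)
  }
  total
}

# Brute-force Fitch oracle: minimum changes over all internal labelings.
fitch_oracle <- function(tree, msa) {
  tr <- ape::reorder.phylo(tree, "postorder")
  nt <- ape::Ntip(tr)
  nn <- tr$Nnode
  msa <- msa[tr$tip.label, , drop = FALSE]
  total <- 0L
  for (site in seq_len(ncol(msa))) {
    grid <- as.matrix(expand.grid(rep(list(1:4), nn)))
    best <- Inf
    for (g in seq_len(nrow(grid))) {
      node_state <- c(rep(NA_integer_, nt), grid[g, ])
      changes <- 0L
      for (i in seq_len(nrow(tr$edge))) {
        par <- tr$edge[i, 1L]; ch <- tr$edge[i, 2L]
        if (ch <= nt) {
          ok <- which(phybench:::iupac_sets[[msa[ch, site]]])
          if (!(node_state[par] %in% ok)) changes <- changes + 1L
        } else if (node_state[par] != node_state[ch]) {
          changes <- changes + 1L
        }
      }
      best <- min(best, changes)
    }
    total <- total + best
  }
  total
}

# A 2-taxon rooted-representation tree (degree-2 root), for closed-form
# likelihood checks.
two_taxon_tree <- function(t_total) {
  structure(list(
    edge = matrix(c(3L, 1L, 3L, 2L), 2L, 2L, byrow = TRUE),
    tip.label = c("a", "b"), Nnode = 1L,
    edge.length = c(t_total / 2, t_total / 2)
  ), class = "phylo")
}

random_msa <- function(n_taxa, n_sites, chars = c("A", "C", "G", "T")) {
  matrix(sample(chars, n_taxa * n_sites, replace = TRUE), n_taxa, n_sites,
         dimnames = list(paste0("t", seq_len(n_taxa)), NULL))
}
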