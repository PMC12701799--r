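JC_DMAX <- 10

#' Jukes-Cantor pairwise distance matrix
#'
#' For each pair, sites where either sequence carries a gap or ambiguity code
#' are dropped and the mismatch fraction p over the remaining sites is
#' transformed with d = -(3/4) log(1 - 4p/3). Saturated pairs (p >= 3/4) and
#' distances beyond the cap are clamped to 10.
#'
#' @param msa character matrix.
#' @return symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
jc_distance_matrix <- function(msa) {
  msa <- as_msa(msa)
  nt <- nrow(msa)
  plain <- msa %in% NUC
  dim(plain) <- dim(msa)
  d <- matrix(0, nt, nt, dimnames = list(rownames(msa), rownames(msa)))
  for (i in seq_len(nt - 1L)) for (j in (i + 1L):nt) {
    ok <- plain[i, ] & plain[j, ]
    if (!any(ok))
      stop("no comparable sites between ", rownames(msa)[i], " and ",
           rownames(msa)[j])
    p <- mean(msa[i, ok] != msa[j, ok])
    dij <- if (p >= 0.75) JC_DMAX else min(-0.75 * log(1 - 4 * p / 3), JC_DMAX)
    d[i, j] <- d[j, i] <- dij
  }
  d
}

#' BIONJ tree from a distance matrix
#'
#' Variance-weighted neighbor joining (Gascuel's BIONJ). On an additive
#' distance matrix the generating topology and edge lengths are recovered
#' exactly. Negative estimated branch lengths are clamped to 0.
#'
#' @param dm symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return unrooted `phylo`.
#' @export
bionj_tree <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) >= 3L)
  if (max(abs(dm - t(dm))) > 1e-12)
    stop("distance matrix is not symmetric")
  tr <- ape::bionj(dm)
  tr$edge.length[tr$edge.length < 0] <- 0
  ape::reorder.phylo(ape::unroot(tr), "cladewise")
}

#' Fitch small-parsimony score
#'
#' Minimum number of character changes needed on the fixed topology, summed
#' over sites; gaps and ambiguity codes contribute their full compatible
#' state set. Invariant to the (arbitrary) rooting used for the pass.
#'
#' @param tree `phylo`.
#' @param msa character matrix whose taxa match the tree's leaves.
#' @return integer parsimony score.
#' @export
fitch_score <- function(tree, msa) {
  msa <- as_msa(msa)
  if (!setequal(tree$tip.label, rownames(msa)))
    stop("tree leaves and MSA taxa differ")
  pd <- msa_phyDat(msa)
  as.integer(phangorn::fitch(tree, pd))
}

msa_phyDat <- function(msa) {
  phangorn::phyDat(msa, type = "DNA")
}

## The two NNI rearrangements around an internal edge, branch lengths kept
## attached to the moved subtrees.  `edge_row` must point at an edge whose
## child is internal; the tree must be binary (apart from the basal
## trifurcation of the unrooted representation).
nni_neighbors_at <- function(tree, edge_row) {
  e <- tree$edge
  u <- e[edge_row, 1L]; v <- e[edge_row, 2L]
  vkids <- which(e[, 1L] == v)
  ukids <- setdiff(which(e[, 1L] == u), edge_row)
  if (length(vkids) != 2L || length(ukids) < 1L)
    stop("NNI requires a binary tree")
  w_row <- ukids[1L]
  lapply(vkids, function(c_row) {
    t2 <- tree
    t2$edge[c_row, 1L] <- u
    t2$edge[w_row, 1L] <- v
    attr(t2, "order") <- NULL
    ape::reorder.phylo(t2, "cladewise")
  })
}

#' All NNI neighbors of a binary tree
#'
#' Two rearrangements per internal edge, with branch lengths preserved.
#'
#' @param tree binary `phylo` (unrooted representation).
#' @return list of `phylo` objects.
#' @export
nni_neighbors <- function(tree) {
  nt <- ape::Ntip(tree)
  rows <- which(tree$edge[, 2L] > nt)
  unlist(lapply(rows, function(r) nni_neighbors_at(tree, r)),
         recursive = FALSE)
}

#' Parsimony tree by random stepwise addition plus NNI
#'
#' Leaves are added in random order, each at the placement minimizing the
#' Fitch score, followed by rounds of first-improvement NNI hill climbing on
#' the parsimony score. Branch lengths are set to the per-edge parsimony
#' change counts divided by the number of sites (floored at 1e-6).
#'
#' @param msa character matrix (>= 3 taxa).
#' @param seed integer seed controlling the addition order.
#' @param nni_rounds rounds of NNI refinement (>= 0).
#' @return unrooted `phylo` with branch lengths; the final parsimony score is
#'   attached as attribute `"pscore"`.
#' @export
parsimony_tree <- function(msa, seed = NULL, nni_rounds = 2L) {
  msa <- as_msa(msa)
  stopifnot(nrow(msa) >= 3L, nni_rounds >= 0L)
  if (!is.null(seed)) set.seed(seed)
  pd <- msa_phyDat(msa)
  tr <- phangorn::random.addition(pd)
  score <- as.integer(phangorn::fitch(tr, pd))
  if (nni_rounds > 0L && ape::Ntip(tr) >= 4L) {
    for (round in seq_len(nni_rounds)) {
      improved <- FALSE
      ## one round = one sweep over internal edges, taking the first
      ## improving rearrangement at each edge and continuing the sweep
      nt <- ape::Ntip(tr)
      for (k in seq_along(which(tr$edge[, 2L] > nt))) {
        rows <- which(tr$edge[, 2L] > ape::Ntip(tr))
        if (k > length(rows)) break
        for (nb in nni_neighbors_at(tr, rows[k])) {
          s <- as.integer(phangorn::fitch(nb, pd))
          if (s < score) {
            tr <- nb; score <- s; improved <- TRUE
            break
          }
        }
      }
      if (!improved) break
    }
  }
  tr <- phangorn::acctran(tr, pd)
  tr$edge.length <- pmax(tr$edge.length / ncol(msa), 1e-6)
  tr <- ape::reorder.phylo(ape::unroot(tr), "cladewise")
  attr(tr, "pscore") <- score
  tr
}

#' NNI hill-climbing maximum-likelihood search
#'
#' Starting from `start`, alternates branch-length optimization with a sweep
#' over all NNI neighbors (evaluated at the current branch lengths, with the
#' most promising candidates re-optimized) and accepts the best strict
#' improvement, until no neighbor improves the log-likelihood by more than
#' `tol` or `max_rounds` is reached.
#'
#' @param msa character matrix.
#' @param model a `gtr_model`.
#' @param start starting `phylo` on the MSA's taxa (binary).
#' @param tol minimum lnL improvement to accept a rearrangement.
#' @param max_rounds maximum NNI rounds.
#' @param n_candidates how many top-ranked neighbors get a branch-length
#'   re-optimization before deciding.
#' @return list with `tree` and `lnl`.
#' @export
nni_ml_search <- function(msa, model, start, tol = 0.1, max_rounds = 10L,
                          n_candidates = 3L) {
  msa <- as_msa(msa)
  ld <- lik_data(start, msa, model)    # shared by all rearrangements
  ob <- optimize_branch_lengths_ld(start, ld, model, tol = tol,
                                   max_rounds = 3L)
  tree <- ob$tree; lnl <- ob$lnl
  if (ape::Ntip(tree) < 4L) return(list(tree = tree, lnl = lnl))
  for (round in seq_len(max_rounds)) {
    nbs <- nni_neighbors(tree)
    quick <- vapply(nbs, function(nb)
      sum(pattern_loglik(nb, ld, model) * ld$weights), numeric(1L))
    ord <- order(quick, decreasing = TRUE)[seq_len(min(n_candidates,
                                                       length(nbs)))]
    best_lnl <- lnl; best_tree <- NULL
    for (i in ord) {
      cand <- optimize_branch_lengths_ld(nbs[[i]], ld, model, tol = tol,
                                         max_rounds = 2L)
      if (cand$lnl > best_lnl + tol) {
        best_lnl <- cand$lnl; best_tree <- cand$tree
      }
    }
    if (is.null(best_tree)) break
    tree <- best_tree; lnl <- best_lnl
  }
  list(tree = tree, lnl = lnl)
}

BUILTIN_INFERRERS <- c("bionj", "parsimony", "nni-ml")

#' Run a registered inference tool on an alignment
#'
#' Built-in names (`"bionj"`, `"parsimony"`, `"nni-ml"`) dispatch to the
#' package's own inferrers. Any other name must be registered in
#' `config$tools` with an executable and an argument template; a registered
#' tool whose executable cannot be found yields status `"skipped"`, and a
#' failing invocation yields status `"failed"`, never an error.
#'
#' The template is a character vector of arguments in which `{msa}` is
#' replaced by the alignment path; the tool must print a Newick tree on
#' stdout or to the file named by the `best_tree` entry (with `{msa}`
#' substitution).
#'
#' @param name tool name.
#' @param msa character matrix (built-ins) - external tools additionally need
#'   `msa_path`.
#' @param config list with `tools` (registry), `model`, `seed`.
#' @param msa_path alignment file for external tools.
#' @return list with `tree` (`phylo` or NULL), `status`
#'   (`"ok" | "skipped" | "failed"`), `elapsed` (seconds), `log`.
#' @export
run_inference_tool <- function(name, msa, config = list(), msa_path = NULL) {
  t0 <- proc.time()[["elapsed"]]
  if (name %in% BUILTIN_INFERRERS) {
    model <- config$model %||% gtr_model()
    seed <- config$seed %||% 1L
    tree <- switch(name,
      "bionj" = bionj_tree(jc_distance_matrix(msa)),
      "parsimony" = parsimony_tree(msa, seed = seed,
                                   nni_rounds = config$nni_rounds %||% 2L),
      "nni-ml" = nni_ml_search(msa, model,
                               start = parsimony_tree(msa, seed = seed),
                               tol = config$ml_tol %||% 0.1,
                               max_rounds = config$ml_rounds %||% 10L)$tree
    )
    return(list(tree = tree, status = "ok",
                elapsed = proc.time()[["elapsed"]] - t0, log = ""))
  }
  reg <- config$tools[[name]]
  if (is.null(reg))
    stop("tool ", dQuote(name), " is not registered; known tools: ",
         paste(c(BUILTIN_INFERRERS, names(config$tools)), collapse = ", "))
  exe <- reg$cmd[[1L]]
  if (!nzchar(Sys.which(exe)))
    return(list(tree = NULL, status = "skipped",
                elapsed = proc.time()[["elapsed"]] - t0,
                log = paste0("executable not found: ", exe)))
  args <- vapply(reg$cmd[-1L], function(a)
    gsub("{msa}", msa_path, a, fixed = TRUE), character(1L))
  out <- tryCatch(
    suppressWarnings(system2(exe, args, stdout = TRUE, stderr = TRUE)),
    error = function(e) structure(conditionMessage(e), status = 1L)
  )
  status_code <- attr(out, "status") %||% 0L
  tree_text <- if (!is.null(reg$best_tree)) {
    f <- gsub("{msa}", msa_path, reg$best_tree, fixed = TRUE)
    if (file.exists(f)) paste(readLines(f), collapse = "") else NA_character_
  } else {
    nl <- grep("^\\s*\\(.*;\\s*$", out, value = TRUE)
    if (length(nl)) nl[[length(nl)]] else NA_character_
  }
  tree <- if (status_code == 0L && !is.na(tree_text))
    tryCatch(parse_newick(tree_text), error = function(e) NULL) else NULL
  list(tree = tree,
       status = if (is.null(tree)) "failed" else "ok",
       elapsed = proc.time()[["elapsed"]] - t0,
       log = paste(out, collapse = "\n"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
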