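CORPUS_COLS <- c("id", "n_taxa", "n_sites", "n_patterns", "gap_fraction",
                 "pi_A", "pi_C", "pi_G", "pi_T",
                 "exch_AC", "exch_AG", "exch_AT", "exch_CG", "exch_CT",
                 "exch_GT", "alpha", "tree_path", "source")

#' Assemble a corpus object
#'
#' A corpus is a table of dataset descriptors (taxa, sites, patterns, gap
#' fraction, GTR parameters, Gamma shape) plus the reference trees.
#'
#' @param table data.frame with the corpus columns (see
#'   [generate_synthetic_corpus()] for the schema).
#' @param trees named list of `phylo` objects, names matching `table$id`
#'   (entries may be missing when `tree_path` points at files).
#' @return object of class `corpus`.
#' @export
corpus <- function(table, trees = list()) {
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(CORPUS_COLS, names(table))
  if (length(missing_cols))
    stop("corpus table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(table$id)) stop("duplicate corpus ids")
  with(table, stopifnot(all(n_taxa >= 3), all(n_sites >= 1),
                        all(n_patterns >= 1), all(n_patterns <= n_sites),
                        all(gap_fraction >= 0), all(gap_fraction <= 1)))
  structure(list(table = table, trees = trees), class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  cat("corpus of", nrow(x$table), "datasets;",
      "taxa", paste(range(x$table$n_taxa), collapse = "-"),
      "| sites", paste(range(x$table$n_sites), collapse = "-"), "\n")
  invisible(x)
}

#' Model and tree of one corpus entry
#'
#' @param corp a `corpus`.
#' @param id entry id.
#' @param k,p_inv passed to [gtr_model()].
#' @return list with `row` (1-row data.frame), `model` and `tree`.
#' @export
corpus_entry <- function(corp, id, k = 4L, p_inv = 0) {
  stopifnot(inherits(corp, "corpus"))
  i <- match(id, corp$table$id)
  if (is.na(i)) stop("unknown corpus id: ", id)
  row <- corp$table[i, , drop = FALSE]
  tree <- corp$trees[[as.character(id)]]
  if (is.null(tree) && !is.na(row$tree_path) && nzchar(row$tree_path))
    tree <- parse_newick(paste(readLines(row$tree_path), collapse = ""))
  list(
    row = row,
    model = gtr_model(
      pi = unlist(row[paste0("pi_", NUC)], use.names = FALSE),
      exch = unlist(row[paste0("exch_", EXCH_NAMES)], use.names = FALSE),
      alpha = row$alpha, k = k, p_inv = p_inv
    ),
    tree = tree
  )
}

#' Filter a corpus at field quantiles
#'
#' Computes the q-quantile (linear interpolation) of each named field over
#' the corpus and keeps the entries strictly below every threshold - the
#' "95th percentile" outlier cut used to discard excessively large datasets.
#' Thresholds are attached as attribute `"thresholds"`.
#'
#' @param corp a `corpus`.
#' @param q quantile in (0, 1].
#' @param fields subset of `c("n_taxa", "n_patterns")`.
#' @return the filtered `corpus` (possibly empty, with a warning).
#' @export
percentile_filter <- function(corp, q = 0.95,
                              fields = c("n_taxa", "n_patterns")) {
  stopifnot(inherits(corp, "corpus"), q > 0, q <= 1,
            all(fields %in% c("n_taxa", "n_patterns")), length(fields) >= 1L)
  if (!nrow(corp$table)) stop("empty corpus")
  thr <- vapply(fields, function(f)
    unname(stats::quantile(corp$table[[f]], q, type = 7)), numeric(1L))
  keep <- rep(TRUE, nrow(corp$table))
  for (f in fields) keep <- keep & corp$table[[f]] < thr[[f]]
  if (!any(keep)) warning("percentile filter removed every entry")
  out <- corpus(corp$table[keep, , drop = FALSE],
                corp$trees[as.character(corp$table$id[keep])])
  attr(out, "thresholds") <- thr
  out
}

#' Bucketed representative selection
#'
#' Sorts the corpus by the site patterns-to-taxa ratio (ties broken by id),
#' splits it into `n_buckets` contiguous rank-based groups whose sizes differ
#' by at most one (earlier buckets take the remainder), and draws one entry
#' per bucket with the seeded RNG. The selection is returned sorted by ratio.
#'
#' @param corp a `corpus`.
#' @param n_buckets number of buckets (1 <= n_buckets <= corpus size).
#' @param seed integer seed.
#' @return a `corpus` of exactly `n_buckets` representatives.
#' @export
select_representatives <- function(corp, n_buckets, seed = 1L) {
  stopifnot(inherits(corp, "corpus"), n_buckets >= 1L)
  n <- nrow(corp$table)
  if (n < n_buckets)
    stop("corpus has ", n, " entries < ", n_buckets,
         " buckets; use a smaller n_buckets")
  set.seed(seed)
  ratio <- corp$table$n_patterns / corp$table$n_taxa
  ord <- order(ratio, corp$table$id)
  sizes <- rep(n %/% n_buckets, n_buckets)
  extra <- n %% n_buckets
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  stops <- cumsum(sizes)
  starts <- c(1L, utils::head(stops, -1L) + 1L)
  picks <- vapply(seq_len(n_buckets), function(b) {
    idx <- ord[starts[b]:stops[b]]
    idx[sample.int(length(idx), 1L)]
  }, integer(1L))
  picks <- picks[order(ratio[picks], corp$table$id[picks])]
  corpus(corp$table[picks, , drop = FALSE],
         corp$trees[as.character(corp$table$id[picks])])
}

#' Generate a synthetic benchmark corpus
#'
#' Emulates a database of dataset descriptors: each entry gets a random
#' binary reference tree (sequential leaf attachment, exponential branch
#' lengths), GTR parameters drawn from documented priors (Dirichlet-style
#' frequencies, log-uniform exchangeabilities relative to GT = 1, log-uniform
#' Gamma shape in [0.05, 5]), a gap-fraction target, and the pattern count
#' measured on a gapless simulation along the tree - so `n_patterns` always
#' reflects the entry's actual signal.
#'
#' @param n number of entries.
#' @param seed integer seed.
#' @param ranges list of sampling ranges: `n_taxa` (integer range), `n_sites`
#'   (integer range), `alpha` (log-uniform range), `bl_mean` (log-uniform
#'   range of the mean branch length), `gaps` (uniform range of the gap
#'   target).
#' @param dir optional directory: when given, writes `corpus.tsv` plus one
#'   Newick file per entry and records the paths in the table.
#' @return a `corpus` with in-memory trees (and files written when `dir` is
#'   set).
#' @export
generate_synthetic_corpus <- function(n, seed = 1L,
                                      ranges = list(), dir = NULL) {
  stopifnot(n >= 1L)
  r <- utils::modifyList(list(
    n_taxa = c(10L, 20L), n_sites = c(200L, 800L),
    alpha = c(0.05, 5), bl_mean = c(0.005, 0.3), gaps = c(0.05, 0.4)
  ), ranges)
  set.seed(seed)
  rows <- vector("list", n)
  trees <- vector("list", n)
  for (i in seq_len(n)) {
    nt <- sample(r$n_taxa[1L]:r$n_taxa[2L], 1L)
    ns <- sample(r$n_sites[1L]:r$n_sites[2L], 1L)
    alpha <- exp(stats::runif(1, log(r$alpha[1L]), log(r$alpha[2L])))
    blm <- exp(stats::runif(1, log(r$bl_mean[1L]), log(r$bl_mean[2L])))
    pi <- stats::rgamma(4, shape = 10); pi <- pi / sum(pi)
    exch <- exp(stats::runif(6, log(0.25), log(4))); exch <- exch / exch[6L]
    gaps <- stats::runif(1, r$gaps[1L], r$gaps[2L])
    tree <- random_tree(nt, bl_mean = blm,
                        seed = sample.int(2^31 - 1L, 1L))
    model <- gtr_model(pi, exch, alpha, k = 4L)
    sim <- simulate_gapless(tree, model, ns,
                            seed = sample.int(2^31 - 1L, 1L))
    id <- sprintf("syn%03d", i)
    trees[[i]] <- tree
    rows[[i]] <- data.frame(
      id = id, n_taxa = nt, n_sites = ns,
      n_patterns = count_patterns(sim), gap_fraction = gaps,
      pi_A = pi[1L], pi_C = pi[2L], pi_G = pi[3L], pi_T = pi[4L],
      exch_AC = exch[1L], exch_AG = exch[2L], exch_AT = exch[3L],
      exch_CG = exch[4L], exch_CT = exch[5L], exch_GT = exch[6L],
      alpha = alpha, tree_path = NA_character_, source = "synthetic"
    )
  }
  tab <- do.call(rbind, rows)
  names(trees) <- tab$id
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    tab$tree_path <- file.path(dir, paste0(tab$id, ".nwk"))
    for (i in seq_len(n))
      writeLines(write_newick(trees[[i]]), tab$tree_path[i])
    utils::write.table(tab, file.path(dir, "corpus.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  corpus(tab, trees)
}

#' Read a corpus TSV written by [generate_synthetic_corpus()]
#'
#' @param path `corpus.tsv` file; `tree_path` entries are resolved relative
#'   to the working directory as written.
#' @return a `corpus` (trees loaded lazily via [corpus_entry()]).
#' @export
read_corpus <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  corpus(tab)
}
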