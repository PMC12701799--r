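#' Benchmark run configuration
#'
#' Validates and assembles the configuration driving [run_pipeline()]. Modes:
#' `"simulated-truth"` (the generating tree is the reference),
#' `"gap-superimposed"` (gapless simulation with a gap mask taken from an
#' indel simulation superimposed), `"empirical-bestknown"` (the reference is
#' the highest-likelihood tree among replicate searches and tool trees).
#'
#' @param corpus a `corpus`, or NULL to generate a synthetic one.
#' @param synthetic_n size of the generated corpus when `corpus` is NULL.
#' @param synthetic_ranges passed to [generate_synthetic_corpus()].
#' @param mode one of the three modes above.
#' @param tools inferrer names; built-ins are `"bionj"`, `"parsimony"`,
#'   `"nni-ml"`, anything else must be registered in `external_tools`.
#' @param external_tools registry for [run_inference_tool()].
#' @param seed master seed; every stochastic stage derives its own stream
#'   from it.
#' @param au list with `alpha`, `scales`, `B` for the plausibility test.
#' @param difficulty_searches replicate parsimony searches per dataset that
#'   feed the ground-truth difficulty (the definitional count is 100; the
#'   default is scaled down for routine runs and is configurable).
#' @param eval_opt parameter blocks optimized when scoring trees (see
#'   [evaluate_tree()]).
#' @param indel NULL (gapless), an `indel_model`, or `"calibrate"` to fit one
#'   per dataset against the corpus entry's target statistics.
#' @param calibrate list with `budget`, `replicates` for per-dataset
#'   calibration.
#' @param out_dir output directory (required by [run_pipeline()]).
#' @return object of class `run_config`.
#' @export
run_config <- function(corpus = NULL, synthetic_n = 20L,
                       synthetic_ranges = list(),
                       mode = c("simulated-truth", "gap-superimposed",
                                "empirical-bestknown"),
                       tools = BUILTIN_INFERRERS, external_tools = list(),
                       seed = 1L,
                       au = list(alpha = 0.05,
                                 scales = seq(0.5, 1.4, by = 0.1), B = 1000L),
                       difficulty_searches = 20L,
                       eval_opt = "brlens",
                       indel = NULL, calibrate = list(budget = 20L,
                                                      replicates = 2L),
                       out_dir = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(tools) >= 1L, difficulty_searches >= 2L)
  external <- setdiff(tools, BUILTIN_INFERRERS)
  unknown <- setdiff(external, names(external_tools))
  if (length(unknown))
    stop("tool(s) not registered in external_tools: ",
         paste(unknown, collapse = ", "))
  if (!is.null(indel) && !identical(indel, "calibrate") &&
      !inherits(indel, "indel_model"))
    stop("indel must be NULL, \"calibrate\", or an indel_model")
  if (mode == "gap-superimposed" && !inherits(indel, "indel_model"))
    stop("gap-superimposed mode needs an explicit indel_model as the gap",
         " template source")
  structure(list(
    corpus = corpus, synthetic_n = synthetic_n,
    synthetic_ranges = synthetic_ranges, mode = mode, tools = tools,
    external_tools = external_tools, seed = as.integer(seed), au = au,
    difficulty_searches = as.integer(difficulty_searches),
    eval_opt = eval_opt, indel = indel, calibrate = calibrate,
    out_dir = out_dir
  ), class = "run_config")
}

dataset_seed <- function(cfg_seed, id) {
  (cfg_seed * 10007L + sum(utf8ToInt(id)) * 97L) %% (2^31 - 1L)
}

#' Best-known reference tree
#'
#' Evaluates every candidate under identical settings and returns the
#' strictly highest-likelihood tree; exact ties are broken by a fixed
#' precedence (thorough-search trees first, then tool registration order).
#'
#' @param candidates named list of `phylo` (tool trees).
#' @param thorough list of `phylo` from the thorough replicate search.
#' @param msa character matrix.
#' @param model `gtr_model`.
#' @param eval_opt optimization flags used for all evaluations.
#' @return list with `tree`, `provenance` (name or `"thorough<i>"`), `lnl`.
#' @export
best_known_reference <- function(candidates, thorough, msa, model,
                                 eval_opt = "brlens") {
  thorough_named <- if (length(thorough))
    stats::setNames(thorough, paste0("thorough", seq_along(thorough)))
  else list()
  all_trees <- c(thorough_named, candidates)
  if (!length(all_trees)) stop("no candidate trees")
  lnls <- vapply(all_trees, function(tr)
    evaluate_tree(tr, msa, model, optimize = eval_opt)$lnl, numeric(1L))
  best <- which.max(lnls)            # first maximum = precedence order
  list(tree = all_trees[[best]], provenance = names(all_trees)[best],
       lnl = lnls[[best]])
}

## difficulty of one dataset from replicate parsimony searches whose unique
## topologies are AU-tested jointly
dataset_difficulty <- function(msa, model, cfg, seed) {
  n_search <- cfg$difficulty_searches
  searches <- lapply(seq_len(n_search), function(i)
    parsimony_tree(msa, seed = (seed + 1000L + i) %% (2^31 - 1L)))
  keys <- vapply(searches, topology_key, character(1L))
  uniq <- which(!duplicated(keys))
  if (length(uniq) == 1L) {
    plausible <- rep(TRUE, n_search)
  } else {
    site_lnl <- t(vapply(uniq, function(i) {
      evaluate_tree(searches[[i]], msa, model, optimize = cfg$eval_opt,
                    tol = 0.05, max_rounds = 2L)$site_lnl
    }, numeric(ncol(msa))))
    rownames(site_lnl) <- keys[uniq]
    ps <- plausible_set(site_lnl, alpha = cfg$au$alpha,
                        scales = cfg$au$scales, B = cfg$au$B,
                        seed = (seed + 77L) %% (2^31 - 1L))
    plausible <- ps$plausible[match(keys, keys[uniq])]
  }
  difficulty_from_searches(searches, plausible)
}

simulate_dataset_msa <- function(entry, cfg, seed) {
  tree <- entry$tree; model <- entry$model
  n_sites <- entry$row$n_sites
  if (cfg$mode == "gap-superimposed") {
    gapped <- simulate_msa(tree, model, n_sites, cfg$indel,
                           seed = (seed + 13L) %% (2^31 - 1L))
    gapless <- simulate_gapless(tree, model, ncol(gapped), seed = seed)
    return(superimpose_gaps(gapless, gap_mask(gapped)))
  }
  indel <- cfg$indel
  root_len <- n_sites
  if (identical(indel, "calibrate")) {
    target <- list(sites = n_sites, patterns = entry$row$n_patterns,
                   gaps = entry$row$gap_fraction)
    cal <- calibrate_indels(tree, model, target,
                            budget = cfg$calibrate$budget,
                            replicates = cfg$calibrate$replicates,
                            seed = (seed + 31L) %% (2^31 - 1L))
    indel <- cal$indel
    root_len <- cal$root_len
  }
  simulate_msa(tree, model, root_len, indel, seed = seed)
}

blank_record <- function(id, tool, status, difficulty = NA_real_,
                         bucket = NA_integer_) {
  data.frame(dataset = id, tool = tool, status = status,
             rf_raw = NA_integer_, rf_norm = NA_real_, ntd = NA_real_,
             quartet = NA_real_, lnl = NA_real_, delta_lnl = NA_real_,
             rel_delta_lnl = NA_real_, au_p = NA_real_, plausible = NA,
             difficulty = difficulty, bucket = bucket)
}

#' Run the benchmark on a single dataset
#'
#' Simulates (or masks) the alignment, runs every configured inferrer,
#' evaluates all trees plus the reference under identical settings, runs the
#' AU test jointly over the reference and the inferred trees, computes the
#' dataset difficulty from replicate searches, and emits one
#' benchmark record per tool plus one for the reference. A failing stage
#' yields a `"failed"` record for that cell, never an error.
#'
#' @param entry output of [corpus_entry()] (needs a tree for the simulated
#'   modes).
#' @param cfg a [run_config()].
#' @param cache_dir optional dataset directory for resumable artifacts
#'   (`msa.fasta`, `trees/<tool>.nwk`, `difficulty.tsv`).
#' @return data.frame of benchmark records; the number of fresh tree
#'   inferences is attached as attribute `"inferences_run"`.
#' @export
run_dataset <- function(entry, cfg, cache_dir = NULL) {
  id <- entry$row$id
  model <- entry$model
  seed <- dataset_seed(cfg$seed, id)
  inferences_run <- 0L
  if (is.null(entry$tree)) stop("dataset ", id, " has no reference tree")

  ## --- alignment (cached) ---
  msa_file <- if (!is.null(cache_dir)) file.path(cache_dir, "msa.fasta")
  if (!is.null(msa_file) && file.exists(msa_file)) {
    msa <- read_fasta_msa(msa_file)
  } else {
    msa <- simulate_dataset_msa(entry, cfg, seed)
    if (!is.null(msa_file)) {
      dir.create(dirname(msa_file), recursive = TRUE, showWarnings = FALSE)
      write_fasta_msa(msa, msa_file)
    }
  }

  ## --- inference (cached per tool) ---
  trees_dir <- if (!is.null(cache_dir)) file.path(cache_dir, "trees")
  if (!is.null(trees_dir))
    dir.create(trees_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  for (ti in seq_along(cfg$tools)) {
    tool <- cfg$tools[ti]
    safe <- gsub("[^A-Za-z0-9_-]", "_", tool)
    nwk <- if (!is.null(trees_dir)) file.path(trees_dir, paste0(safe, ".nwk"))
    marker <- if (!is.null(trees_dir))
      file.path(trees_dir, paste0(safe, ".status"))
    if (!is.null(nwk) && file.exists(nwk)) {
      results[[tool]] <- list(tree = parse_newick(
        paste(readLines(nwk), collapse = "")), status = "ok")
      next
    }
    if (!is.null(marker) && file.exists(marker)) {
      results[[tool]] <- list(tree = NULL, status = readLines(marker)[1L])
      next
    }
    res <- tryCatch(
      run_inference_tool(tool, msa,
                         config = list(model = model,
                                       seed = (seed + ti) %% (2^31 - 1L),
                                       tools = cfg$external_tools),
                         msa_path = msa_file),
      error = function(e) list(tree = NULL, status = "failed",
                               log = conditionMessage(e)))
    inferences_run <- inferences_run + 1L
    if (!is.null(trees_dir)) {
      if (res$status == "ok") writeLines(write_newick(res$tree), nwk)
      else writeLines(res$status, marker)
    }
    results[[tool]] <- res
  }

  ## --- difficulty (cached) ---
  diff_file <- if (!is.null(cache_dir)) file.path(cache_dir, "difficulty.tsv")
  if (!is.null(diff_file) && file.exists(diff_file)) {
    difficulty <- utils::read.table(diff_file, header = TRUE)$difficulty[1L]
  } else {
    difficulty <- dataset_difficulty(msa, model, cfg, seed)$difficulty
    if (!is.null(diff_file))
      utils::write.table(data.frame(difficulty = difficulty), diff_file,
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }
  bucket <- difficulty_bucket(difficulty)

  ## --- reference tree ---
  ok_tools <- names(results)[vapply(results, function(r)
    r$status == "ok", logical(1L))]
  if (cfg$mode == "empirical-bestknown") {
    searches <- lapply(seq_len(min(cfg$difficulty_searches, 10L)),
                       function(i) parsimony_tree(msa,
                         seed = (seed + 5000L + i) %% (2^31 - 1L)))
    ref <- best_known_reference(
      lapply(results[ok_tools], `[[`, "tree"), searches, msa, model,
      cfg$eval_opt)
    reference <- ref$tree
  } else {
    reference <- entry$tree
  }

  ## --- evaluation of reference + inferred trees ---
  evals <- list(reference = evaluate_tree(reference, msa, model,
                                          optimize = cfg$eval_opt))
  for (tool in ok_tools)
    evals[[tool]] <- evaluate_tree(results[[tool]]$tree, msa, model,
                                   optimize = cfg$eval_opt)

  ## --- AU test over reference + inferred trees ---
  au <- NULL
  if (length(evals) >= 2L) {
    site_lnl <- do.call(rbind, lapply(evals, `[[`, "site_lnl"))
    rownames(site_lnl) <- names(evals)
    au <- plausible_set(site_lnl, alpha = cfg$au$alpha,
                        scales = cfg$au$scales, B = cfg$au$B,
                        seed = (seed + 99L) %% (2^31 - 1L))
  }

  ## --- records ---
  lnl_ref <- evals$reference$lnl
  rec_of <- function(tool) {
    r <- results[[tool]]
    if (is.null(r) || r$status != "ok")
      return(blank_record(id, tool, r$status %||% "failed",
                          difficulty, bucket))
    tr <- evals[[tool]]$tree
    rf <- rf_distance(reference, tr)
    row <- blank_record(id, tool, "ok", difficulty, bucket)
    row$rf_raw <- rf$raw
    row$rf_norm <- rf$normalized
    row$ntd <- ntd_distance(reference, tr)
    row$quartet <- quartet_distance(reference, tr)
    row$lnl <- evals[[tool]]$lnl
    row$delta_lnl <- lnl_ref - evals[[tool]]$lnl
    row$rel_delta_lnl <- row$delta_lnl / abs(lnl_ref)
    if (!is.null(au)) {
      i <- match(tool, au$tree)
      row$au_p <- au$p_au[i]
      row$plausible <- au$plausible[i]
    }
    row
  }
  ref_row <- blank_record(id, "reference", "ok", difficulty, bucket)
  ref_row$rf_raw <- 0L; ref_row$rf_norm <- 0; ref_row$ntd <- 0
  ref_row$quartet <- 0; ref_row$lnl <- lnl_ref
  ref_row$delta_lnl <- 0; ref_row$rel_delta_lnl <- 0
  if (!is.null(au)) {
    i <- match("reference", au$tree)
    ref_row$au_p <- au$p_au[i]; ref_row$plausible <- au$plausible[i]
  } else {
    ref_row$au_p <- 1; ref_row$plausible <- TRUE
  }
  out <- rbind(ref_row, do.call(rbind, lapply(cfg$tools, rec_of)))
  attr(out, "inferences_run") <- inferences_run
  out
}

#' Aggregate benchmark records into the per-bucket report
#'
#' Per (difficulty bucket, tool): count, mean and median of each distance and
#' of the log-likelihood difference, and the fraction of plausible trees.
#' Additionally computes, per tool, the Spearman rank correlation between
#' dataset difficulty and normalized RF distance across datasets.
#'
#' @param records data.frame of [run_dataset()] rows.
#' @return list with `by_bucket` (data.frame) and `spearman` (data.frame of
#'   `tool`, `rho`, `n`).
#' @export
aggregate_records <- function(records) {
  ok <- records[records$status == "ok", , drop = FALSE]
  if (!nrow(ok)) stop("no ok records to aggregate")
  grp <- interaction(ok$bucket, ok$tool, drop = TRUE)
  agg_one <- function(rows) {
    data.frame(
      bucket = rows$bucket[1L], tool = rows$tool[1L], n = nrow(rows),
      rf_norm_mean = mean(rows$rf_norm), rf_norm_median = stats::median(rows$rf_norm),
      ntd_mean = mean(rows$ntd), ntd_median = stats::median(rows$ntd),
      quartet_mean = mean(rows$quartet),
      quartet_median = stats::median(rows$quartet),
      delta_lnl_mean = mean(rows$delta_lnl),
      delta_lnl_median = stats::median(rows$delta_lnl),
      rel_delta_lnl_mean = mean(rows$rel_delta_lnl),
      plausible_fraction = mean(rows$plausible)
    )
  }
  by_bucket <- do.call(rbind, lapply(split(ok, grp), agg_one))
  by_bucket <- by_bucket[order(by_bucket$bucket, by_bucket$tool), ]
  rownames(by_bucket) <- NULL
  sp <- do.call(rbind, lapply(split(ok, ok$tool), function(rows) {
    rho <- if (nrow(rows) >= 3L && stats::sd(rows$rf_norm) > 0 &&
               stats::sd(rows$difficulty) > 0)
      stats::cor(rows$difficulty, rows$rf_norm, method = "spearman")
    else NA_real_
    data.frame(tool = rows$tool[1L], rho = rho, n = nrow(rows))
  }))
  rownames(sp) <- NULL
  list(by_bucket = by_bucket, spearman = sp)
}

#' Run the full benchmark pipeline
#'
#' Prepares the corpus (generating a synthetic one when none is supplied),
#' runs every dataset through simulation, inference, evaluation, the AU test
#' and difficulty scoring, and writes `records.tsv`, `aggregate.tsv`,
#' `spearman.tsv`, `summary.json` and `run.log` to the output directory.
#' The run is resumable: per-dataset artifacts (alignment, per-tool trees,
#' difficulty) are kept under `datasets/<id>/` and reused, so re-running an
#' untouched directory performs no new inference and adding a tool to the
#' configuration only infers that tool's trees.
#'
#' @param cfg a [run_config()] with `out_dir` set.
#' @return (invisibly) list with `records`, `aggregate`, `spearman`,
#'   `inferences_run`, `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$out_dir)) stop("cfg$out_dir is required")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  corp <- cfg$corpus
  if (is.null(corp))
    corp <- generate_synthetic_corpus(cfg$synthetic_n, seed = cfg$seed,
                                      ranges = cfg$synthetic_ranges)
  log_lines <- c(
    sprintf("phybench run: %d datasets, mode=%s, seed=%d",
            nrow(corp$table), cfg$mode, cfg$seed),
    sprintf("tools: %s", paste(cfg$tools, collapse = ", ")),
    sprintf("difficulty searches per dataset: %d (definitional count: 100)",
            cfg$difficulty_searches),
    sprintf("AU: alpha=%g B=%d scales=%s", cfg$au$alpha, cfg$au$B,
            paste(cfg$au$scales, collapse = ","))
  )
  records <- list()
  inferences_run <- 0L
  for (id in corp$table$id) {
    ds_dir <- file.path(cfg$out_dir, "datasets", id)
    rec_file <- file.path(ds_dir, "records.tsv")
    need <- c("reference", cfg$tools)
    if (file.exists(rec_file)) {
      cached <- utils::read.table(rec_file, sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE)
      if (all(need %in% cached$tool)) {
        records[[id]] <- cached[match(need, cached$tool), , drop = FALSE]
        log_lines <- c(log_lines, sprintf("%s: cached", id))
        next
      }
    }
    entry <- corpus_entry(corp, id)
    rec <- run_dataset(entry, cfg, cache_dir = ds_dir)
    inferences_run <- inferences_run + attr(rec, "inferences_run")
    utils::write.table(rec, rec_file, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    records[[id]] <- rec
    log_lines <- c(log_lines,
                   sprintf("%s: %d fresh inference(s), difficulty %.3f", id,
                           attr(rec, "inferences_run"), rec$difficulty[1L]))
  }
  records <- do.call(rbind, c(records, make.row.names = FALSE))
  agg <- aggregate_records(records)
  utils::write.table(records, file.path(cfg$out_dir, "records.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(agg$by_bucket, file.path(cfg$out_dir, "aggregate.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(agg$spearman, file.path(cfg$out_dir, "spearman.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  summary <- list(
    n_datasets = nrow(corp$table), mode = cfg$mode, seed = cfg$seed,
    tools = cfg$tools, difficulty_searches = cfg$difficulty_searches,
    au = cfg$au, inferences_run = inferences_run,
    spearman = stats::setNames(as.list(agg$spearman$rho), agg$spearman$tool)
  )
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(cfg$out_dir, "run.log"))
  invisible(list(records = records, aggregate = agg$by_bucket,
                 spearman = agg$spearman, inferences_run = inferences_run,
                 out_dir = cfg$out_dir))
}
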