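#' Components of the ground-truth difficulty score
#'
#' Bundles the statistics of a replicate-search experiment: how many search
#' trees there are (N_all), how many are statistically plausible (N_pl), how
#' many unique topologies each set contains, and the mean pairwise normalized
#' RF distance within each set.
#'
#' @param n_all number of search trees (>= 1).
#' @param n_pl number of plausible trees (1 <= n_pl <= n_all).
#' @param n_star_all unique topologies among all trees (<= n_all).
#' @param n_star_pl unique topologies among plausible trees (<= n_pl).
#' @param rf_all mean pairwise normalized RF among all trees, in [0, 1].
#' @param rf_pl same among plausible trees; must be 0 when n_pl = 1.
#' @return object of class `difficulty_components`.
#' @export
difficulty_components <- function(n_all, n_pl, n_star_all, n_star_pl,
                                  rf_all, rf_pl) {
  stopifnot(n_all >= 1, n_pl >= 1, n_pl <= n_all,
            n_star_all >= 1, n_star_all <= n_all,
            n_star_pl >= 1, n_star_pl <= n_pl,
            rf_all >= 0, rf_all <= 1, rf_pl >= 0, rf_pl <= 1)
  if (n_pl == 1 && rf_pl != 0)
    stop("rf_pl must be 0 when only one tree is plausible")
  structure(list(n_all = n_all, n_pl = n_pl, n_star_all = n_star_all,
                 n_star_pl = n_star_pl, rf_all = rf_all, rf_pl = rf_pl),
            class = "difficulty_components")
}

#' Ground-truth difficulty score
#'
#' The tree-space ruggedness score
#' \deqn{d = \frac{1}{5}\left[RF_{all} + RF_{pl} + \frac{N^*_{all}}{N_{all}}
#'   + \frac{N^*_{pl}}{N_{pl}} + \left(1 - \frac{N_{pl}}{N_{all}}\right)\right]}
#' computed from replicate tree searches: 0 means a single easy likelihood
#' peak, values near 1 mean many statistically indistinguishable yet
#' topologically distinct optima.
#'
#' @param comp a [difficulty_components()] object.
#' @return numeric in [0, 1].
#' @export
#' @examples
#' ground_truth_difficulty(difficulty_components(100, 100, 1, 1, 0, 0))
ground_truth_difficulty <- function(comp) {
  stopifnot(inherits(comp, "difficulty_components"))
  (comp$rf_all + comp$rf_pl +
     comp$n_star_all / comp$n_all +
     comp$n_star_pl / comp$n_pl +
     (1 - comp$n_pl / comp$n_all)) / 5
}

#' Difficulty from a set of search trees and plausibility flags
#'
#' Assembles the [difficulty_components()] from the trees (unique-topology
#' counts and mean pairwise normalized RF, over the full set and the
#' plausible subset) and evaluates [ground_truth_difficulty()].
#'
#' @param trees list of `phylo` objects on a common leaf set.
#' @param plausible logical vector, one flag per tree; at least one TRUE.
#' @return list with `components` and `difficulty`.
#' @export
difficulty_from_searches <- function(trees, plausible) {
  stopifnot(length(trees) >= 1L, length(plausible) == length(trees))
  if (!any(plausible))
    stop("at least one tree must be plausible")
  pl <- trees[plausible]
  comp <- difficulty_components(
    n_all = length(trees), n_pl = length(pl),
    n_star_all = unique_topology_count(trees),
    n_star_pl = unique_topology_count(pl),
    rf_all = mean_pairwise_rf(trees),
    rf_pl = mean_pairwise_rf(pl)
  )
  list(components = comp, difficulty = ground_truth_difficulty(comp))
}

#' Difficulty bucket
#'
#' Partitions the difficulty scale [0, 1] into five buckets of width 0.2
#' (0 = easy through 4 = hopeless); intervals are half-open with 1.0 mapped
#' into the last bucket.
#'
#' @param d difficulty in [0, 1] (vectorized).
#' @return integer bucket(s) in 0..4.
#' @export
difficulty_bucket <- function(d) {
  if (any(d < 0 | d > 1)) stop("difficulty outside [0, 1]")
  ## the tiny epsilon absorbs floating-point representation error at the
  ## nominal bucket boundaries (0.2, 0.4, ...)
  pmin(as.integer(floor(d / 0.2 + 1e-9)), 4L)
}
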