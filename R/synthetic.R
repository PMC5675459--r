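# Generator of fully factorial single-dose screens with known ground truth.
# Used for property tests, parameter recovery, and ranking benchmarks.

#' Configuration of a synthetic fully factorial screen
#'
#' The generator emulates a single-dose combination screen: true single-drug
#' viabilities are drawn uniformly from `single_range` (the default 0.6-0.9
#' mirrors a design that doses every drug near 80% survival so that even
#' six-drug cocktails stay measurable); true pairs deviate from the Bliss
#' product by log-normal pair interactions,
#' \eqn{g_{ij} = g_i g_j e^{\delta_{ij}}} with
#' \eqn{\delta_{ij} \sim N(0, \code{pair_interaction_sd}^2)}; true
#' higher-order cocktails follow the log-linear family at exponent
#' `true_alpha` (so parameter recovery has a well-defined truth), plus
#' optional third-order log-deviations for triplets
#' (`triplet_interaction_sd`). Every measurement is observed through
#' `n_repeats` independent multiplicative noise draws
#' \eqn{e^{\sigma Z}}, \eqn{Z \sim N(0,1)}, with
#' \eqn{\sigma = } `noise_sigma`.
#'
#' @param n_drugs Number of drugs (>= 3).
#' @param max_order Largest cocktail order generated (default: full
#'   factorial, all `2^n - 1` subsets).
#' @param true_alpha Generative log-linear exponent for orders >= 3
#'   (0 = Bliss world, `1/(M-1)` = pairs world, 1 = regression world).
#' @param single_range Interval in (0, 1\] for true single viabilities.
#' @param pair_interaction_sd Log-scale sd of pair deviations from Bliss.
#' @param noise_sigma Log-scale sd of per-repeat measurement noise.
#' @param n_repeats Biological repeats per measurement (>= 2).
#' @param triplet_interaction_sd Log-scale sd of third-order deviations
#'   injected into triplet truths (default 0: pure pairwise structure).
#' @param seed Integer seed: identical configs generate bit-identical
#'   screens.
#' @param cell_line Label of the simulated cell line.
#' @return Object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_drugs = 6, max_order = n_drugs,
                             true_alpha = 0.5,
                             single_range = c(0.6, 0.9),
                             pair_interaction_sd = 0.1,
                             noise_sigma = 0.05, n_repeats = 6,
                             triplet_interaction_sd = 0,
                             seed = 1, cell_line = "SIM") {
  stopifnot(n_drugs >= 3, n_drugs == round(n_drugs),
            max_order >= 1, max_order <= n_drugs,
            is.numeric(true_alpha), length(true_alpha) == 1L,
            length(single_range) == 2L,
            single_range[1L] > 0, single_range[2L] <= 1,
            single_range[1L] <= single_range[2L],
            pair_interaction_sd >= 0, noise_sigma >= 0,
            triplet_interaction_sd >= 0,
            n_repeats >= 2, n_repeats == round(n_repeats))
  structure(list(n_drugs = as.integer(n_drugs),
                 max_order = as.integer(max_order),
                 true_alpha = true_alpha,
                 single_range = as.numeric(single_range),
                 pair_interaction_sd = pair_interaction_sd,
                 noise_sigma = noise_sigma,
                 n_repeats = as.integer(n_repeats),
                 triplet_interaction_sd = triplet_interaction_sd,
                 seed = as.integer(seed), cell_line = cell_line),
            class = "synthetic_config")
}

#' Generate a synthetic fully factorial screen
#'
#' Draws a screen according to a [synthetic_config()] and packages it as a
#' [combination_dataset()] with per-record repeats, means, and standard
#' errors. The ground truth is stored in the `"truth"` attribute (named
#' vector of true viabilities by canonical cocktail label) for parameter-
#' recovery tests.
#'
#' @param config A `synthetic_config`.
#' @return A `combination_dataset`; `attr(, "truth")` holds the true
#'   noise-free viabilities, `attr(, "config")` the configuration.
#' @examples
#' scr <- generate_screen(synthetic_config(n_drugs = 4, max_order = 3,
#'                                         noise_sigma = 0))
#' @export
generate_screen <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  drugs <- sprintf("D%02d", seq_len(config$n_drugs))
  s_true <- stats::setNames(
    stats::runif(config$n_drugs, config$single_range[1L],
                 config$single_range[2L]), drugs)

  truth <- s_true
  if (config$max_order >= 2L) {
    pair_idx <- utils::combn(drugs, 2L)
    p_lab <- apply(pair_idx, 2L, paste, collapse = "+")
    delta <- stats::rnorm(length(p_lab), 0, config$pair_interaction_sd)
    p_true <- stats::setNames(
      apply(pair_idx, 2L, function(d) prod(s_true[d])) * exp(delta), p_lab)
    truth <- c(truth, p_true)
  }
  if (config$max_order >= 3L) {
    for (k in seq(3L, config$max_order)) {
      sets <- utils::combn(drugs, k, simplify = FALSE)
      a <- config$true_alpha
      b <- 1 - (k - 1) * a
      vals <- vapply(sets, function(d) {
        pk <- apply(utils::combn(d, 2L), 2L, paste, collapse = "+")
        prod(p_true[pk])^a * prod(s_true[d])^b
      }, 0)
      if (k == 3L && config$triplet_interaction_sd > 0) {
        vals <- vals * exp(stats::rnorm(length(vals), 0,
                                        config$triplet_interaction_sd))
      }
      truth <- c(truth,
                 stats::setNames(vals, vapply(sets, paste, "",
                                              collapse = "+")))
    }
  }

  n_rep <- config$n_repeats
  repeats <- lapply(truth, function(g) {
    g * exp(config$noise_sigma * stats::rnorm(n_rep))
  })
  rec <- data.frame(cell_line = config$cell_line, drugs = names(truth),
                    viability = vapply(repeats, mean, 0),
                    ste = vapply(repeats, function(r) {
                      stats::sd(r) / sqrt(length(r))
                    }, 0),
                    stringsAsFactors = FALSE)
  rec$repeats <- unname(repeats)
  ds <- combination_dataset(
    rec, name = sprintf("synthetic_screen(alpha=%g, sigma=%g, seed=%d)",
                        config$true_alpha, config$noise_sigma,
                        config$seed))
  attr(ds, "truth") <- truth
  attr(ds, "config") <- config
  ds
}

#' Recover the generative log-linear exponent from a screen
#'
#' Runs [alpha_scan()] on a dataset whose high-order cocktails all share
#' one order M and returns the alpha maximizing R-squared -- the
#' parameter-recovery harness for the synthetic generator. With mixed
#' orders the scan target is ambiguous, so an explicit
#' `order_restriction` is required.
#'
#' @param x A `combination_dataset`.
#' @param alpha_grid Scan grid (default step 0.025 over \[0, 1\]).
#' @param order_restriction Cocktail order to scan; required when the
#'   dataset mixes orders >= 3.
#' @return The recovered alpha (a grid point).
#' @export
recover_alpha <- function(x, alpha_grid = seq(0, 1, by = 0.025),
                          order_restriction = NULL) {
  stopifnot(inherits(x, "combination_dataset"))
  orders <- unique(x$records$order[x$records$order >= 3L])
  if (is.null(order_restriction)) {
    if (length(orders) != 1L) {
      stop("dataset mixes cocktail orders (",
           paste(sort(orders), collapse = ", "),
           "); give order_restriction", call. = FALSE)
    }
    order_restriction <- orders
  }
  alpha_scan(x, alpha_grid = alpha_grid,
             order_restriction = order_restriction)$best_alpha
}
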