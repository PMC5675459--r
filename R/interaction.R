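# Bliss-referenced interaction scoring and significance calls.

#' Bliss-log interaction score
#'
#' \deqn{I = \ln(1 + g_{1..k} - g^{Bliss}_{1..k}),}
#' the logarithmic deviation of the measured cocktail viability from the
#' product of its single-drug viabilities. `I < 0` means the cocktail kills
#' more than independent action predicts (synergy); `I > 0` means
#' antagonism; `I = 0` is exact Bliss independence. The log argument must be
#' positive (it fails only when the cocktail underperforms Bliss by almost
#' the entire scale).
#'
#' @param g_combo Measured cocktail viability.
#' @param singles Numeric vector of the constituent single-drug viabilities
#'   (names optional).
#' @return The interaction score, natural-log units.
#' @examples
#' interaction_score(0.67, c(0.77, 0.82)) # 0.038: mild antagonism
#' @export
interaction_score <- function(g_combo, singles) {
  stopifnot(is.numeric(g_combo), length(g_combo) == 1L, is.numeric(singles))
  arg <- 1 + g_combo - prod(singles)
  if (!is.finite(arg) || arg <= 0) {
    stop("interaction score undefined: 1 + ", format(g_combo), " - ",
         format(prod(singles)), " = ", format(arg), " is not positive",
         call. = FALSE)
  }
  log(arg)
}

#' Classify an interaction as synergistic, additive, or antagonistic
#'
#' A cocktail is called antagonistic when I > 0 and the 5th bootstrap
#' percentile of I is above 0, synergistic when I < 0 and the 95th
#' percentile is below 0, and additive otherwise (I = 0 lies inside the
#' 90% central interval, or the point estimate disagrees with the bound).
#'
#' @param I Interaction point estimate.
#' @param ci_low,ci_high 5th and 95th bootstrap percentiles of I.
#' @return One of `"synergistic"`, `"additive"`, `"antagonistic"`.
#' @examples
#' classify_interaction(0.04, 0.01, 0.08)    # antagonistic
#' classify_interaction(-0.01, -0.05, 0.02)  # additive
#' @export
classify_interaction <- function(I, ci_low, ci_high) {
  if (any(is.na(c(I, ci_low, ci_high)))) return("additive")
  stopifnot(ci_low <= ci_high)
  if (I > 0 && ci_low > 0) "antagonistic"
  else if (I < 0 && ci_high < 0) "synergistic"
  else "additive"
}

#' Bootstrap confidence interval for an interaction score
#'
#' Computes the per-repeat scores
#' \eqn{I_r = \ln(1 + g_r - \prod_i \bar g_i)} from the biological repeats
#' of the cocktail measurement and the mean single-drug viabilities, then
#' resamples the \eqn{I_r} with replacement `n_boot` times. The reported
#' point estimate is the mean of the bootstrap resample means and the
#' confidence bounds are their 5th and 95th percentiles; classification
#' follows [classify_interaction()]. Singles enter through their means by
#' default; supply `single_repeats` to resample them jointly as well.
#'
#' Any repeat with a non-positive log argument makes the score undefined
#' and raises an error before resampling -- repeats are never dropped
#' silently.
#'
#' @param combo_repeats Numeric vector (length >= 2) of per-repeat cocktail
#'   viabilities.
#' @param single_means Numeric vector of mean single-drug viabilities of the
#'   constituents.
#' @param n_boot Number of bootstrap resamples (>= 1000).
#' @param seed Integer seed; the result is bit-reproducible given the seed.
#'   The caller's RNG state is left untouched.
#' @param single_repeats Optional list of per-repeat viability vectors, one
#'   per single drug; when given, each bootstrap draw also resamples every
#'   drug's repeats and uses the resampled means in the Bliss product.
#' @param cell_line,drugs Optional labels carried into the result.
#' @return Object of class `"interaction_result"`: fields `I`, `ci_low`,
#'   `ci_high`, `label`, `n_repeats`, `n_boot`, `seed`, plus the labels.
#' @export
bootstrap_interaction <- function(combo_repeats, single_means,
                                  n_boot = 10000, seed = 17,
                                  single_repeats = NULL,
                                  cell_line = NA_character_,
                                  drugs = NA_character_) {
  stopifnot(is.numeric(combo_repeats), is.numeric(single_means))
  n <- length(combo_repeats)
  if (n < 2L) stop("need at least 2 repeats to bootstrap", call. = FALSE)
  if (n_boot < 1000L) stop("n_boot must be at least 1000", call. = FALSE)
  bliss <- prod(single_means)
  args <- 1 + combo_repeats - bliss
  if (any(args <= 0)) {
    stop("interaction score undefined for repeat(s) ",
         paste(which(args <= 0), collapse = ", "),
         ": log argument <= 0", call. = FALSE)
  }
  I_r <- log(args)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  if (is.null(single_repeats)) {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    boot_means <- colMeans(matrix(I_r[idx], nrow = n))
  } else {
    stopifnot(is.list(single_repeats))
    boot_means <- vapply(seq_len(n_boot), function(b) {
      s_b <- vapply(single_repeats, function(r) {
        mean(r[sample.int(length(r), replace = TRUE)])
      }, 0)
      g_b <- combo_repeats[sample.int(n, replace = TRUE)]
      a <- 1 + g_b - prod(s_b)
      if (any(a <= 0)) {
        stop("interaction score undefined in a bootstrap resample",
             call. = FALSE)
      }
      mean(log(a))
    }, 0)
  }

  I <- mean(boot_means)
  qs <- unname(stats::quantile(boot_means, c(0.05, 0.95), names = FALSE))
  structure(list(cell_line = cell_line,
                 drugs = if (is.na(drugs)) drugs else cocktail_label(drugs),
                 I = I, ci_low = qs[1L], ci_high = qs[2L],
                 label = classify_interaction(I, qs[1L], qs[2L]),
                 n_repeats = n, n_boot = as.integer(n_boot),
                 seed = as.integer(seed)),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat("<interaction",
      if (!is.na(x$drugs)) paste0(" ", x$drugs),
      if (!is.na(x$cell_line)) paste0(" [", x$cell_line, "]"),
      ": I = ", format(x$I, digits = 3),
      " (90% CI ", format(x$ci_low, digits = 3), " .. ",
      format(x$ci_high, digits = 3), "), ", x$label,
      ", n = ", x$n_repeats, ", n_boot = ", x$n_boot, ">\n", sep = "")
  invisible(x)
}

record_labels <- function(rec) {
  lab <- rec$label
  need <- !nzchar(lab)
  lab[need] <- mapply(classify_interaction, rec$interaction[need],
                      rec$ci_low[need], rec$ci_high[need])
  lab
}

#' Pair-consistency of higher-order interaction signs
#'
#' For every significantly synergistic or antagonistic cocktail of 3 or
#' more drugs in a cell line, checks whether at least one of its
#' constituent pairs is significant with the same sign. A significant
#' cocktail none of whose measured pairs shares its sign is an *exception*
#' -- a candidate for interactions beyond second order. Significance comes
#' from each record's stored label when present (e.g. the published calls
#' in [table2_fixture()]) and otherwise from [classify_interaction()] on
#' its `interaction`/`ci_low`/`ci_high` fields; records without either are
#' treated as additive.
#'
#' @param x A `combination_dataset` whose records carry interaction
#'   estimates (stored or bootstrap-derived).
#' @param cell_line Cell line to summarize.
#' @return Object of class `"consistency_summary"`: counts of significant
#'   cocktails per sign, how many contain a same-sign significant pair, the
#'   exceptions, and a per-cocktail detail table.
#' @export
pair_consistency_summary <- function(x, cell_line) {
  stopifnot(inherits(x, "combination_dataset"))
  if (!cell_line %in% x$records$cell_line) {
    stop("unknown cell line: ", cell_line, call. = FALSE)
  }
  rec <- x$records[x$records$cell_line == cell_line, ]
  lab <- stats::setNames(record_labels(rec), rec$drugs)
  hi <- rec[rec$order >= 3L, ]
  hi_lab <- lab[hi$drugs]
  detail <- data.frame(drugs = hi$drugs, order = hi$order,
                       label = unname(hi_lab),
                       has_same_sign_pair = NA,
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(detail))) {
    if (detail$label[i] == "additive") next
    pk <- pair_labels(detail$drugs[i])
    pl <- lab[pk]  # NA for unmeasured pairs
    detail$has_same_sign_pair[i] <-
      any(!is.na(pl) & pl == detail$label[i])
  }
  ant <- detail$label == "antagonistic"
  syn <- detail$label == "synergistic"
  exceptions <- detail$drugs[!is.na(detail$has_same_sign_pair) &
                               !detail$has_same_sign_pair]
  structure(list(cell_line = cell_line,
                 n_antagonistic = sum(ant),
                 n_antagonistic_with_antagonistic_pair =
                   sum(ant & detail$has_same_sign_pair %in% TRUE),
                 n_synergistic = sum(syn),
                 n_synergistic_with_synergistic_pair =
                   sum(syn & detail$has_same_sign_pair %in% TRUE),
                 exceptions = exceptions,
                 detail = detail),
            class = "consistency_summary")
}

#' @export
print.consistency_summary <- function(x, ...) {
  cat("Pair-consistency summary for", x$cell_line, "\n")
  cat("  antagonistic cocktails (order >= 3):", x$n_antagonistic,
      "| with an antagonistic pair:",
      x$n_antagonistic_with_antagonistic_pair, "\n")
  cat("  synergistic cocktails  (order >= 3):", x$n_synergistic,
      "| with a synergistic pair:",
      x$n_synergistic_with_synergistic_pair, "\n")
  if (length(x$exceptions)) {
    cat("  exceptions (no same-sign pair):",
        paste(x$exceptions, collapse = ", "), "\n")
  } else {
    cat("  no exceptions\n")
  }
  invisible(x)
}
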