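# Model-fit metrics, the alpha scan over the log-linear family, ranking
# accuracy, and noise-amplification analysis.

#' Coefficient of determination
#'
#' \deqn{R^2 = 1 - \sum_i (y_i - f_i)^2 / \sum_i (y_i - \bar y)^2}
#' for observations \eqn{y} and predictions \eqn{f}. Not clipped at zero:
#' a negative value means the model predicts worse than the observed mean,
#' and can be arbitrarily negative.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return R-squared (<= 1).
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(is.numeric(observed), is.numeric(predicted))
  if (length(observed) != length(predicted)) {
    stop("observed and predicted lengths differ (", length(observed),
         " vs ", length(predicted), ")", call. = FALSE)
  }
  if (length(observed) == 0L) stop("empty input", call. = FALSE)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop("R-squared undefined: observations have zero variance",
         call. = FALSE)
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Benchmark prediction models on a measured screen
#'
#' Pools every measured cocktail of order `min_order`..`max_order` across
#' the given cell lines, predicts each one with each model from that cell
#' line's measured singles/pairs, and reports one R-squared per model over
#' the points the model can predict. Cocktails with missing inputs (or an
#' order the model does not support) are skipped and listed per report, so
#' the evaluated point sets are identical across models except for those
#' recorded restrictions.
#'
#' @param x A `combination_dataset`.
#' @param models List of `model_spec`s or family-name strings.
#' @param cells Cell lines to pool; default all in the dataset.
#' @param min_order,max_order Cocktail-order range (defaults 3..Inf keep
#'   the model inputs out of the evaluation).
#' @return List of `"evaluation_report"` objects: `model`, `alpha`,
#'   `cell_lines`, `n_points`, `r2`, `per_order` (data frame of n and r2 by
#'   cocktail order), `points`, and `skipped`.
#' @examples
#' \donttest{
#' reports <- evaluate_models(table2_fixture(),
#'                            models = list("pairs", "bliss"))
#' sapply(reports, `[[`, "r2")
#' }
#' @export
evaluate_models <- function(x, models, cells = NULL, min_order = 3,
                            max_order = Inf) {
  stopifnot(inherits(x, "combination_dataset"))
  if (is.null(cells)) cells <- cell_lines(x)
  models <- lapply(models, function(m) {
    if (is.character(m)) model_spec(m) else m
  })
  lapply(models, function(spec) {
    per_cell <- lapply(cells, function(cl) {
      p <- predict_dataset(x, cl, spec, min_order, max_order)
      sk <- attr(p, "skipped")
      sk <- cbind(data.frame(cell_line = rep(cl, nrow(sk)),
                             stringsAsFactors = FALSE), sk)
      list(preds = p, skipped = sk)
    })
    preds <- do.call(rbind, lapply(per_cell, `[[`, "preds"))
    skipped <- do.call(rbind, lapply(per_cell, `[[`, "skipped"))
    pts <- preds[!is.na(preds$observed), , drop = FALSE]
    per_order <- do.call(rbind, lapply(sort(unique(pts$order)), function(m) {
      sub <- pts[pts$order == m, ]
      data.frame(order = m, n = nrow(sub),
                 r2 = if (nrow(sub) >= 2L &&
                            stats::var(sub$observed) > 0)
                   r_squared(sub$observed, sub$predicted) else NA_real_)
    }))
    structure(list(model = spec$family, alpha = spec$alpha,
                   cell_lines = cells, n_points = nrow(pts),
                   r2 = r_squared(pts$observed, pts$predicted),
                   per_order = per_order, points = pts, skipped = skipped),
              class = "evaluation_report")
  })
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation ", x$model,
      if (!is.null(x$alpha)) paste0("(alpha=", x$alpha, ")"),
      ": R2 = ", format(x$r2, digits = 4), " on ", x$n_points,
      " cocktails (", paste(x$cell_lines, collapse = ", "), ")>\n",
      sep = "")
  invisible(x)
}

#' Scan the log-linear family over alpha
#'
#' Evaluates `predict_loglinear` at every grid value of \eqn{\alpha} (with
#' \eqn{\beta = 1 - (M-1)\alpha}) against the measured cocktails and
#' reports the R-squared profile. On exactly Bliss-consistent data the
#' profile is flat; otherwise its maximum locates the best family member
#' (the pairs model sits at \eqn{\alpha = 1/(M-1)}). Ties resolve to the
#' smallest alpha, the lower-variance model.
#'
#' @inheritParams evaluate_models
#' @param alpha_grid Numeric grid; default `seq(0, 1, by = 0.05)`.
#' @param order_restriction `"pooled"` (all orders >= `min_order`) or a
#'   single integer cocktail order M.
#' @param min_order Lower order bound when pooling.
#' @return Object of class `"alpha_scan_result"`: `alphas`, `r2_values`,
#'   `best_alpha`, `best_r2`, `order_restriction`, `n_points`.
#' @export
alpha_scan <- function(x, alpha_grid = seq(0, 1, by = 0.05), cells = NULL,
                       order_restriction = "pooled", min_order = 3) {
  stopifnot(length(alpha_grid) >= 1L, is.numeric(alpha_grid))
  alpha_grid <- sort(alpha_grid)
  if (identical(order_restriction, "pooled")) {
    lo <- min_order; hi <- Inf
  } else {
    stopifnot(is.numeric(order_restriction),
              length(order_restriction) == 1L, order_restriction >= 2)
    lo <- hi <- order_restriction
  }
  reports <- evaluate_models(
    x, models = lapply(alpha_grid, function(a) model_spec("loglinear", a)),
    cells = cells, min_order = lo, max_order = hi)
  r2 <- vapply(reports, `[[`, 0, "r2")
  best <- which.max(r2)  # first maximum = smallest alpha on ties
  structure(list(alphas = alpha_grid, r2_values = r2,
                 best_alpha = alpha_grid[best], best_r2 = r2[best],
                 order_restriction = order_restriction,
                 n_points = reports[[best]]$n_points),
            class = "alpha_scan_result")
}

#' @export
print.alpha_scan_result <- function(x, ...) {
  cat("<alpha_scan over ", length(x$alphas), " points, orders = ",
      if (identical(x$order_restriction, "pooled")) "pooled" else
        x$order_restriction,
      ": best alpha = ", x$best_alpha,
      " (R2 = ", format(x$best_r2, digits = 4), ")>\n", sep = "")
  invisible(x)
}

#' Top-k ranking accuracy
#'
#' How well a model prioritizes the most effective cocktails: the overlap
#' between the top `k = floor(top_fraction * n)` cocktails by observed
#' effectiveness and the top k by predicted effectiveness, divided by k.
#' "Most effective" means *lowest* viability. Ties are broken by the
#' cocktail labels (or by position when no labels are given) so the result
#' is deterministic. A random predictor scores `k/n` on average; a
#' prediction that is any strictly increasing transform of another scores
#' identically.
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 10).
#' @param top_fraction Fraction of the list regarded as "top" (0 < f <= 1).
#' @param labels Optional cocktail labels used for deterministic
#'   tie-breaking.
#' @return Fraction in \[0, 1\] of the observed top-k recovered.
#' @export
ranking_accuracy <- function(observed, predicted, top_fraction = 0.1,
                             labels = NULL) {
  n <- length(observed)
  stopifnot(length(predicted) == n,
            top_fraction > 0, top_fraction <= 1)
  if (n < 10L) {
    stop("ranking needs at least 10 cocktails (got ", n, ")",
         call. = FALSE)
  }
  k <- floor(top_fraction * n)
  if (k < 1L) {
    stop("top_fraction * n is below 1; no top set to compare",
         call. = FALSE)
  }
  if (is.null(labels)) labels <- sprintf("%09d", seq_len(n))
  top <- function(v) order(v, labels, method = "radix")[seq_len(k)]
  length(intersect(top(observed), top(predicted))) / k
}

# -- noise amplification -----------------------------------------------------

loglinear_noise_factor <- function(alpha, M) {
  beta <- 1 - (M - 1) * alpha
  sqrt(alpha^2 * M * (M - 1) / 2 + beta^2 * M)
}

#' Analytic noise-amplification factor of a prediction formula
#'
#' Assume every measured single and pair viability carries independent
#' multiplicative noise with log-scale standard deviation \eqn{\sigma}.
#' First-order propagation through the log-linear family gives a log-scale
#' prediction noise of \eqn{\sigma \sqrt{\alpha^2 M(M-1)/2 + \beta^2 M}}:
#' \eqn{\sqrt M} for Bliss, \eqn{\sqrt{M(M-1)/2 + M(M-2)^2}} for
#' regression, and only \eqn{\sqrt{M/(2(M-1))}} for the pairs model --
#' below one \eqn{\sigma} for every order, because the pairs model touches
#' few inputs with small exponents. For triplets the three factors are
#' 1.7, 2.5, and 0.9.
#'
#' @param family `"bliss"`, `"pairs"`, `"regression"`, or `"loglinear"`.
#' @param M Cocktail order (>= 2; >= 3 for regression).
#' @param alpha Required iff `family = "loglinear"`.
#' @return Object of class `"noise_factor"` with fields `family`, `M`,
#'   `alpha`, `factor` (multiples of sigma).
#' @examples
#' noise_amplification_analytic("pairs", 3)$factor # sqrt(3/4)
#' @export
noise_amplification_analytic <- function(family, M, alpha = NULL) {
  stopifnot(is.numeric(M), length(M) == 1L, M == round(M))
  if (M < 2 || (family == "regression" && M < 3)) {
    stop("unsupported order M = ", M, " for family '", family, "'",
         call. = FALSE)
  }
  a <- switch(family,
              bliss = 0,
              pairs = 1 / (M - 1),
              regression = 1,
              loglinear = {
                if (is.null(alpha)) {
                  stop("loglinear needs alpha", call. = FALSE)
                }
                alpha
              },
              stop("no analytic noise factor for family '", family, "'",
                   call. = FALSE))
  structure(list(family = family, M = as.integer(M), alpha = a,
                 factor = loglinear_noise_factor(a, M)),
            class = "noise_factor")
}

#' @export
print.noise_factor <- function(x, ...) {
  cat("<noise_factor ", x$family, " M=", x$M, ": ",
      format(x$factor, digits = 4), " sigma>\n", sep = "")
  invisible(x)
}

#' Monte-Carlo noise-amplification factor
#'
#' Simulates a Bliss-consistent ground truth (singles drawn once, pairs
#' their products), perturbs every single and pair input with independent
#' multiplicative noise \eqn{e^{\sigma Z}}, recomputes the model prediction
#' in each simulation, and returns the standard deviation of the log
#' prediction divided by \eqn{\sigma}. Converges to the analytic factor as
#' \eqn{\sigma \to 0}; agreement at small sigma is a check of the
#' closed-form propagation.
#'
#' @inheritParams noise_amplification_analytic
#' @param sigma Log-scale noise sd of one measurement (0 < sigma <= 0.2).
#' @param n_sims Number of simulations (>= 1e4).
#' @param seed Integer seed (RNG state is restored on exit).
#' @return Empirical factor (multiples of sigma), with attribute `"mc_se"`,
#'   the approximate Monte-Carlo standard error of the factor.
#' @export
noise_amplification_mc <- function(family, M, sigma = 0.05, n_sims = 1e5,
                                   seed = 1, alpha = NULL) {
  stopifnot(sigma > 0, sigma <= 0.2, n_sims >= 1e4)
  a <- noise_amplification_analytic(family, M, alpha)$alpha
  beta <- 1 - (M - 1) * a
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  s_true <- stats::runif(M, 0.6, 0.9)
  p_true <- apply(utils::combn(M, 2L), 2L, function(ij) prod(s_true[ij]))
  P <- length(p_true)
  noisy_s <- matrix(rep(s_true, each = n_sims) *
                      exp(sigma * stats::rnorm(n_sims * M)),
                    nrow = n_sims)
  noisy_p <- matrix(rep(p_true, each = n_sims) *
                      exp(sigma * stats::rnorm(n_sims * P)),
                    nrow = n_sims)
  pred <- apply(noisy_p, 1L, prod)^a * apply(noisy_s, 1L, prod)^beta
  fac <- stats::sd(log(pred)) / sigma
  # se of a sd estimate from ~normal draws: sd / sqrt(2 (n - 1))
  attr(fac, "mc_se") <- fac / sqrt(2 * (n_sims - 1))
  fac
}
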