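# Cocktail-effect predictors. All formulas consume single-drug and/or
# drug-pair viabilities measured at one fixed dose per drug and predict the
# viability of the full cocktail at those same doses.

.EPS_SINGLE <- 1e-9  # singles below this make the beta != 0 powers blow up

#' Prediction model specification
#'
#' The log-linear family predicts an M-drug cocktail as
#' \deqn{g_{1..M} = (\prod g_{ij})^\alpha (\prod g_i)^\beta,
#'       \quad \beta = 1 - (M-1)\alpha,}
#' the constraint on \eqn{\beta} guaranteeing Bliss conservation (if every
#' pair satisfies \eqn{g_{ij} = g_i g_j}, the prediction collapses to the
#' Bliss product). Named members: `bliss` (\eqn{\alpha = 0}), `regression`
#' (\eqn{\alpha = 1}), and `pairs` (\eqn{\alpha = 1/(M-1)}, \eqn{\beta = 0}),
#' the last using pair data only. `isserlis` is the separate maximum-entropy
#' pairing formula, defined for M = 3 and 4 only.
#'
#' @param family One of `"bliss"`, `"pairs"`, `"regression"`, `"isserlis"`,
#'   `"loglinear"`.
#' @param alpha Exponent on the pair product; required iff
#'   `family = "loglinear"`.
#' @return Object of class `"model_spec"`.
#' @export
model_spec <- function(family = c("bliss", "pairs", "regression",
                                  "isserlis", "loglinear"),
                       alpha = NULL) {
  family <- match.arg(family)
  if (family == "loglinear") {
    if (is.null(alpha) || !is.finite(alpha)) {
      stop("loglinear model needs a finite alpha", call. = FALSE)
    }
  } else if (!is.null(alpha)) {
    stop("alpha is only meaningful for family = 'loglinear'", call. = FALSE)
  }
  structure(list(family = family, alpha = alpha), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec ", x$family,
      if (!is.null(x$alpha)) paste0(" alpha=", x$alpha), ">\n", sep = "")
  invisible(x)
}

# alpha of the log-linear member a named family corresponds to, at order M
model_alpha <- function(spec, M) {
  switch(spec$family,
         bliss = 0,
         pairs = 1 / (M - 1),
         regression = 1,
         loglinear = spec$alpha,
         stop("no log-linear alpha for family '", spec$family, "'",
              call. = FALSE))
}

new_prediction <- function(value, ck, family, alpha, beta, inputs_used,
                           cell_line = NA_character_, clamped = FALSE) {
  structure(list(cell_line = cell_line, cocktail = as.character(ck),
                 order = ck$order, value = value, model = family,
                 alpha = alpha, beta = beta, inputs_used = inputs_used,
                 clamped = clamped),
            class = "cocktail_prediction")
}

#' @export
print.cocktail_prediction <- function(x, ...) {
  cat("<prediction ", x$model, " ", x$cocktail, " = ",
      format(x$value, digits = 6),
      if (x$clamped) " (clamped to 0)", ">\n", sep = "")
  invisible(x)
}

# -- input lookup helpers ----------------------------------------------------

lookup_singles <- function(singles, ck) {
  names(singles) <- toupper(trimws(names(singles)))
  v <- singles[ck$drugs]
  miss <- ck$drugs[is.na(v)]
  if (length(miss)) {
    stop("missing single-drug viability for: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(v < 0)) stop("negative single-drug viability", call. = FALSE)
  stats::setNames(as.numeric(v), ck$drugs)
}

lookup_pairs <- function(pairs, ck) {
  names(pairs) <- vapply(names(pairs), cocktail_label, "")
  keys <- pair_labels(ck)
  v <- pairs[keys]
  miss <- keys[is.na(v)]
  if (length(miss)) {
    stop("missing pair viability for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(v < 0)) stop("negative pair viability", call. = FALSE)
  stats::setNames(as.numeric(v), keys)
}

check_singles_floor <- function(s) {
  bad <- names(s)[s <= .EPS_SINGLE]
  if (length(bad)) {
    stop("degenerate single-drug viability (<= ", .EPS_SINGLE,
         ") would blow up the prediction: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
}

# -- predictors --------------------------------------------------------------

#' Bliss independence prediction
#'
#' Predicts the cocktail viability as the product of its single-drug
#' viabilities: independent action, no interactions.
#'
#' @param singles Named numeric vector of single-drug viabilities (names are
#'   drug identifiers, canonicalized on lookup).
#' @param drugs Target cocktail (any representation accepted by
#'   [cocktail()]).
#' @return A `cocktail_prediction`.
#' @examples
#' predict_bliss(c(CPT = 0.77, CisPt = 0.82), "CPT+CisPt")$value
#' @export
predict_bliss <- function(singles, drugs) {
  ck <- cocktail(drugs)
  s <- lookup_singles(singles, ck)
  new_prediction(prod(s), ck, "bliss", 0, 1, names(s))
}

#' Pairs-model prediction
#'
#' Predicts an M-drug cocktail (M >= 2) as the product of all its
#' M(M-1)/2 pair viabilities raised to the power 1/(M-1):
#' \deqn{g^{pairs}_{1..M} = \left(\prod_{i<j} g_{ij}\right)^{1/(M-1)}.}
#' Uses pair data only, which makes it the least noise-sensitive member of
#' the log-linear family (see [noise_amplification_analytic()]).
#'
#' @param pairs Named numeric vector of pair viabilities, names like
#'   `"A+B"` (canonicalized on lookup).
#' @inheritParams predict_bliss
#' @return A `cocktail_prediction`.
#' @examples
#' p <- c("CPT+CisPt" = 0.67, "CPT+CbPt" = 0.58, "CisPt+CbPt" = 0.73)
#' predict_pairs(p, "CPT+CisPt+CbPt")$value # sqrt of the product
#' @export
predict_pairs <- function(pairs, drugs) {
  ck <- cocktail(drugs)
  if (ck$order < 2L) {
    stop("pairs model needs a cocktail of order >= 2", call. = FALSE)
  }
  p <- lookup_pairs(pairs, ck)
  a <- 1 / (ck$order - 1)
  new_prediction(prod(p)^a, ck, "pairs", a, 0, names(p))
}

#' Regression prediction
#'
#' The \eqn{\alpha = 1} member of the log-linear family:
#' \eqn{(\prod g_{ij}) (\prod g_i)^{-(M-2)}}; for triplets
#' \eqn{g_{12}g_{23}g_{13}/(g_1 g_2 g_3)}. Dividing by singles makes it the
#' most noise-amplifying member; singles at or below `1e-9` raise a
#' degenerate-input error rather than being clamped.
#'
#' @inheritParams predict_bliss
#' @inheritParams predict_pairs
#' @return A `cocktail_prediction`.
#' @export
predict_regression <- function(singles, pairs, drugs) {
  ck <- cocktail(drugs)
  if (ck$order < 3L) {
    stop("regression model needs a cocktail of order >= 3", call. = FALSE)
  }
  pr <- predict_loglinear(singles, pairs, drugs, alpha = 1)
  pr$model <- "regression"
  pr
}

#' Isserlis maximum-entropy prediction
#'
#' Pairing-sum formulas for triplets and quadruplets:
#' \deqn{g^{Iss}_{123} = g_1 g_{23} + g_2 g_{13} + g_3 g_{12}
#'   - 2 g_1 g_2 g_3,}
#' \deqn{g^{Iss}_{1234} = g_{12} g_{34} + g_{13} g_{24} + g_{14} g_{23}
#'   - 2 g_1 g_2 g_3 g_4.}
#' Not defined for other orders. The formula is not positivity-preserving;
#' negative outputs are clamped to 0 and flagged (`$clamped`).
#'
#' @inheritParams predict_regression
#' @return A `cocktail_prediction`.
#' @export
predict_isserlis <- function(singles, pairs, drugs) {
  ck <- cocktail(drugs)
  if (!ck$order %in% c(3L, 4L)) {
    stop("Isserlis formula is defined for cocktails of 3 or 4 drugs only ",
         "(got order ", ck$order, ")", call. = FALSE)
  }
  s <- lookup_singles(singles, ck)
  p <- lookup_pairs(pairs, ck)
  pair_of <- function(i, j) p[[paste(sort(c(ck$drugs[i], ck$drugs[j])),
                                     collapse = "+")]]
  value <- if (ck$order == 3L) {
    s[[1L]] * pair_of(2, 3) + s[[2L]] * pair_of(1, 3) +
      s[[3L]] * pair_of(1, 2) - 2 * prod(s)
  } else {
    pair_of(1, 2) * pair_of(3, 4) + pair_of(1, 3) * pair_of(2, 4) +
      pair_of(1, 4) * pair_of(2, 3) - 2 * prod(s)
  }
  clamped <- value < 0
  new_prediction(max(value, 0), ck, "isserlis", NA_real_, NA_real_,
                 c(names(s), names(p)), clamped = clamped)
}

#' Log-linear family prediction
#'
#' \eqn{(\prod g_{ij})^\alpha (\prod g_i)^\beta} with
#' \eqn{\beta = 1 - (M-1)\alpha} derived from the cocktail order, which
#' enforces Bliss conservation. \eqn{\alpha = 0} is Bliss independence,
#' \eqn{\alpha = 1/(M-1)} the pairs model, \eqn{\alpha = 1} regression.
#'
#' @inheritParams predict_regression
#' @param alpha Pair-product exponent.
#' @return A `cocktail_prediction`.
#' @export
predict_loglinear <- function(singles, pairs, drugs, alpha) {
  ck <- cocktail(drugs)
  if (ck$order < 2L) {
    stop("log-linear family needs a cocktail of order >= 2", call. = FALSE)
  }
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  beta <- 1 - (ck$order - 1) * alpha
  p <- lookup_pairs(pairs, ck)
  if (alpha < 0 && any(p == 0)) {
    stop("zero pair viability with negative alpha", call. = FALSE)
  }
  inputs <- names(p)
  if (beta != 0) {
    s <- lookup_singles(singles, ck)
    if (beta < 0) check_singles_floor(s)
    inputs <- c(names(s), inputs)
    value <- prod(p)^alpha * prod(s)^beta
  } else {
    value <- prod(p)^alpha
  }
  new_prediction(value, ck, "loglinear", alpha, beta, inputs)
}

# single numeric prediction used by the dataset/evaluation layer
predict_value <- function(spec, singles, pairs, ck) {
  switch(spec$family,
         bliss = predict_bliss(singles, ck),
         pairs = predict_pairs(pairs, ck),
         regression = predict_regression(singles, pairs, ck),
         isserlis = predict_isserlis(singles, pairs, ck),
         loglinear = predict_loglinear(singles, pairs, ck, spec$alpha))
}

#' Predict every cocktail of a dataset for one cell line
#'
#' Enumerates the distinct cocktails of the dataset (pooled over cell
#' lines, so combinations measured only in another cell line are still
#' predicted where inputs allow) with order between `min_order` and
#' `max_order`, and predicts each one from the given cell line's measured
#' singles and pairs. Cocktails whose required inputs are missing for that
#' cell line -- or whose order the model does not support -- are skipped and
#' reported, with reasons, in the `"skipped"` attribute.
#'
#' The default `min_order = 3` keeps the model inputs (singles and pairs)
#' out of the evaluated set: pairs predict themselves trivially.
#'
#' @param x A `combination_dataset`.
#' @param cell_line Cell line whose measurements feed the model.
#' @param model A `model_spec`, or a family name string.
#' @param min_order,max_order Cocktail-order range to predict.
#' @return Data frame with columns `cell_line`, `drugs`, `order`,
#'   `predicted`, `observed` (`NA` when the cocktail was not measured in
#'   this cell line), `model`, `alpha`, `beta`; attribute `"skipped"` is a
#'   data frame of `drugs` and `reason`.
#' @export
predict_dataset <- function(x, cell_line, model, min_order = 3,
                            max_order = Inf) {
  stopifnot(inherits(x, "combination_dataset"))
  if (!cell_line %in% x$records$cell_line) {
    stop("unknown cell line: ", cell_line, call. = FALSE)
  }
  if (is.character(model)) model <- model_spec(model)
  rec <- x$records
  targets <- unique(rec$drugs[rec$order >= min_order &
                                rec$order <= max_order])
  singles <- singles_map(x, cell_line)
  prs <- pairs_map(x, cell_line)
  obs <- stats::setNames(rec$viability[rec$cell_line == cell_line],
                         rec$drugs[rec$cell_line == cell_line])
  rows <- list()
  skipped <- list()
  for (d in targets) {
    pr <- tryCatch(predict_value(model, singles, prs, cocktail(d)),
                   error = function(e) conditionMessage(e))
    if (is.character(pr)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        drugs = d, reason = pr, stringsAsFactors = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      cell_line = cell_line, drugs = d, order = cocktail_order(d),
      predicted = pr$value,
      observed = if (d %in% names(obs)) obs[[d]] else NA_real_,
      model = model$family,
      alpha = if (is.null(pr$alpha)) NA_real_ else pr$alpha,
      beta = if (is.null(pr$beta)) NA_real_ else pr$beta,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_line = character(), drugs = character(),
               order = integer(), predicted = numeric(),
               observed = numeric(), model = character(),
               alpha = numeric(), beta = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(drugs = character(), reason = character(),
               stringsAsFactors = FALSE)
  out
}
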