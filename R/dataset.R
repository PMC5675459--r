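#' Combination screen dataset
#'
#' The unit of I/O and evaluation: a validated collection of viability
#' records, one per (cell line, cocktail). Each record carries the mean
#' viability as a fraction of untreated control, an optional standard error,
#' an optional Bliss-log interaction score with its 5th/95th bootstrap
#' percentile bounds as carried from the input table, an optional
#' significance label, and optional per-repeat viabilities.
#'
#' Validation enforces: unique (cell_line, drugs) keys; finite viabilities in
#' \[0, 2\] (values slightly above 1 are measurement noise; beyond 2 indicates
#' a unit error); and, for every drug appearing in a multi-drug cocktail of a
#' cell line, the presence of that cell line's single-drug record. Missing
#' pairs are permitted and can be listed with [missing_pairs()].
#'
#' @param records Data frame with columns `cell_line`, `drugs` (any drug
#'   order; canonicalized), `viability`, and optionally `ste`, `interaction`,
#'   `ci_low`, `ci_high`, `label`, `repeats` (list column of numeric
#'   vectors).
#' @param name Dataset name.
#' @param validate Run validation (default `TRUE`).
#' @return Object of class `"combination_dataset"` with fields `records`
#'   (canonicalized data frame, plus an `order` column) and `name`.
#' @seealso [read_dataset()], [write_dataset()], [table2_fixture()]
#' @export
combination_dataset <- function(records, name = "", validate = TRUE) {
  stopifnot(is.data.frame(records))
  required <- c("cell_line", "drugs", "viability")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("records lack required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rec <- as.data.frame(records, stringsAsFactors = FALSE)
  rec$cell_line <- as.character(rec$cell_line)
  rec$drugs <- vapply(rec$drugs, cocktail_label, "")
  rec$order <- vapply(rec$drugs, cocktail_order, 0L)
  rec$viability <- as.numeric(rec$viability)
  for (col in c("ste", "interaction", "ci_low", "ci_high")) {
    rec[[col]] <- if (col %in% names(records)) as.numeric(rec[[col]]) else
      rep(NA_real_, nrow(rec))
  }
  rec$label <- if ("label" %in% names(records)) {
    lab <- as.character(rec$label)
    lab[is.na(lab)] <- ""
    lab
  } else {
    rep("", nrow(rec))
  }
  if (!"repeats" %in% names(records)) {
    rec$repeats <- replicate(nrow(rec), NULL, simplify = FALSE)
  }
  rec <- rec[c("cell_line", "drugs", "order", "viability", "ste",
               "interaction", "ci_low", "ci_high", "label", "repeats")]
  rownames(rec) <- NULL
  x <- structure(list(records = rec, name = name),
                 class = "combination_dataset")
  if (validate) validate_dataset(x)
  x
}

#' Validate a combination dataset
#'
#' @param x A `combination_dataset`.
#' @return `x`, invisibly; errors describe every offending record.
#' @export
validate_dataset <- function(x) {
  stopifnot(inherits(x, "combination_dataset"))
  rec <- x$records
  key <- paste(rec$cell_line, rec$drugs, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (cell_line, cocktail) records: ",
         paste(gsub("\r", " / ", dup), collapse = "; "), call. = FALSE)
  }
  bad <- !is.finite(rec$viability) | rec$viability < 0
  if (any(bad)) {
    stop("non-finite or negative viability for: ",
         paste(rec$cell_line[bad], rec$drugs[bad], collapse = "; "),
         call. = FALSE)
  }
  high <- rec$viability > 2
  if (any(high)) {
    stop("viability above 2 (fraction-of-control expected, ",
         "check units) for: ",
         paste(rec$cell_line[high], rec$drugs[high], collapse = "; "),
         call. = FALSE)
  }
  if (any(!is.na(rec$ste) & rec$ste < 0)) {
    stop("negative standard error", call. = FALSE)
  }
  for (i in which(!vapply(rec$repeats, is.null, TRUE))) {
    r <- rec$repeats[[i]]
    if (!is.numeric(r) || length(r) < 1L || any(!is.finite(r) | r < 0)) {
      stop("invalid repeats for ", rec$cell_line[i], " ", rec$drugs[i],
           call. = FALSE)
    }
  }
  # every drug used in a multi-drug cocktail needs its single-drug anchor
  offenders <- character()
  for (cl in unique(rec$cell_line)) {
    sub <- rec[rec$cell_line == cl, ]
    singles <- sub$drugs[sub$order == 1L]
    used <- unique(unlist(strsplit(sub$drugs[sub$order > 1L], "+",
                                   fixed = TRUE)))
    miss <- setdiff(used, singles)
    if (length(miss)) {
      offenders <- c(offenders,
                     paste0(cl, ": ", paste(miss, collapse = ", ")))
    }
  }
  if (length(offenders)) {
    stop("single-drug records missing for drugs used in combinations -- ",
         paste(offenders, collapse = "; "), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.combination_dataset <- function(x, ...) {
  rec <- x$records
  cat("<combination_dataset",
      if (nzchar(x$name)) paste0(" '", x$name, "'"), ">\n", sep = "")
  cat("  ", nrow(rec), " records, ", length(unique(rec$cell_line)),
      " cell line(s): ",
      paste(unique(rec$cell_line), collapse = ", "), "\n", sep = "")
  tab <- table(rec$cell_line, rec$order)
  print(tab)
  invisible(x)
}

dataset_key <- function(x) paste(x$records$cell_line, x$records$drugs,
                                 sep = "\r")

#' Look up measured viability
#'
#' @param x A `combination_dataset`.
#' @param cell_line Cell-line label.
#' @param drugs Cocktail (any representation).
#' @return Measured mean viability, or `NA` if the record is absent.
#' @export
get_viability <- function(x, cell_line, drugs) {
  stopifnot(inherits(x, "combination_dataset"))
  lbl <- cocktail_label(drugs)
  i <- x$records$cell_line == cell_line & x$records$drugs == lbl
  if (!any(i)) NA_real_ else x$records$viability[which(i)[1L]]
}

#' Named single-drug viability map for one cell line
#'
#' @inheritParams get_viability
#' @return Named numeric vector keyed by canonical drug identifier.
#' @export
singles_map <- function(x, cell_line) {
  rec <- x$records
  i <- rec$cell_line == cell_line & rec$order == 1L
  stats::setNames(rec$viability[i], rec$drugs[i])
}

#' Named pair viability map for one cell line
#'
#' @inheritParams get_viability
#' @return Named numeric vector keyed by canonical pair label (`"A+B"`).
#' @export
pairs_map <- function(x, cell_line) {
  rec <- x$records
  i <- rec$cell_line == cell_line & rec$order == 2L
  stats::setNames(rec$viability[i], rec$drugs[i])
}

#' Pairs of the measured drug panel that were not measured
#'
#' Lists every pair of the cell line's single-drug panel with no measured
#' pair record (e.g. the HeLa carboplatin + nocodazole pair in the built-in
#' screen).
#'
#' @inheritParams get_viability
#' @return Character vector of missing canonical pair labels.
#' @export
missing_pairs <- function(x, cell_line) {
  stopifnot(inherits(x, "combination_dataset"))
  if (!cell_line %in% x$records$cell_line) {
    stop("unknown cell line: ", cell_line, call. = FALSE)
  }
  drugs <- sort(names(singles_map(x, cell_line)), method = "radix")
  if (length(drugs) < 2L) return(character())
  all_pairs <- apply(utils::combn(drugs, 2L), 2L, paste, collapse = "+")
  setdiff(all_pairs, names(pairs_map(x, cell_line)))
}

#' Distinct cell lines of a dataset
#' @param x A `combination_dataset`.
#' @return Character vector.
#' @export
cell_lines <- function(x) unique(x$records$cell_line)
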