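#' Canonicalize a set of drug identifiers
#'
#' Drug identifiers are case-insensitive tokens. The canonical form trims
#' whitespace, uppercases, and sorts; duplicate identifiers are an error
#' (a drug cannot appear twice in one cocktail).
#'
#' @param drugs Character vector of drug identifiers, or a single string with
#'   identifiers joined by `"+"` (e.g. `"CPT+CisPt"`).
#' @return Character vector of canonical identifiers, sorted.
#' @examples
#' canonical_drugs("CisPt+CPT")
#' canonical_drugs(c(" cpt", "CisPt"))
#' @export
canonical_drugs <- function(drugs) {
  if (!is.character(drugs)) {
    stop("drug identifiers must be character strings", call. = FALSE)
  }
  if (length(drugs) == 1L && grepl("+", drugs, fixed = TRUE)) {
    drugs <- strsplit(drugs, "+", fixed = TRUE)[[1L]]
  }
  d <- toupper(trimws(drugs))
  d <- d[nzchar(d)]
  if (length(d) == 0L) {
    stop("a cocktail needs at least one drug identifier", call. = FALSE)
  }
  if (anyDuplicated(d)) {
    stop("duplicate drug identifiers in cocktail: ",
         paste(unique(d[duplicated(d)]), collapse = ", "), call. = FALSE)
  }
  # radix sort: locale-independent ordering of the canonical label
  sort(d, method = "radix")
}

#' Drug cocktail
#'
#' A cocktail is a set of one or more distinct drugs; its order `M` is the
#' number of drugs. Two cocktails with the same drug set are identical
#' regardless of the order the drugs were supplied in, because the
#' constructor canonicalizes (see [canonical_drugs()]).
#'
#' @param drugs Character vector of drug identifiers or a `"+"`-joined string.
#' @return An object of class `"cocktail"` with fields `drugs` (canonical,
#'   sorted) and `order`.
#' @examples
#' cocktail("CPT+CisPt")
#' cocktail(c("NCZ", "Etopo", "MG132"))
#' @export
cocktail <- function(drugs) {
  if (inherits(drugs, "cocktail")) return(drugs)
  d <- canonical_drugs(drugs)
  structure(list(drugs = d, order = length(d)), class = "cocktail")
}

#' @export
as.character.cocktail <- function(x, ...) paste(x$drugs, collapse = "+")

#' @export
print.cocktail <- function(x, ...) {
  cat("<cocktail [", x$order, "] ", as.character(x), ">\n", sep = "")
  invisible(x)
}

#' Canonical label of a cocktail
#'
#' @param drugs A cocktail, a character vector of drugs, or a joined string.
#' @return Single string: sorted canonical identifiers joined by `"+"`.
#' @examples
#' cocktail_label("CisPt+CPT") # "CISPT+CPT"
#' @export
cocktail_label <- function(drugs) as.character(cocktail(drugs))

#' Number of drugs in a cocktail
#'
#' @inheritParams cocktail_label
#' @return Integer order M.
#' @export
cocktail_order <- function(drugs) cocktail(drugs)$order

#' Constituent pair labels of a cocktail
#'
#' Returns the canonical labels of all M(M-1)/2 drug pairs contained in a
#' cocktail of order M >= 2.
#'
#' @inheritParams cocktail_label
#' @return Character vector of pair labels.
#' @examples
#' pair_labels("CPT+CisPt+NCZ")
#' @export
pair_labels <- function(drugs) {
  ck <- cocktail(drugs)
  if (ck$order < 2L) {
    stop("cocktail of order ", ck$order, " has no pairs", call. = FALSE)
  }
  apply(utils::combn(ck$drugs, 2L), 2L, paste, collapse = "+")
}
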