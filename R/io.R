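#' Read a combination screen from a delimited text file
#'
#' The file must be UTF-8 delimited text (tab or comma, autodetected from
#' the header unless `sep` is given) with a header row and columns
#' `cell_line`, `drugs`, `viability`; optional columns `ste`, `interaction`,
#' `ci_low`, `ci_high`, `label`, and per-repeat viabilities either wide
#' (`repeat_1` .. `repeat_n`) or long (`repeat_index`, `repeat_value`, one
#' row per repeat). Lines starting with `#` are comments. Empty cells and
#' `"-"` both mean "not measured": rows with a missing viability are skipped
#' with a warning (the corresponding pair is then reported by
#' [missing_pairs()]).
#'
#' @param path Path to the file.
#' @param sep Field separator; `NULL` (default) autodetects `"\t"` vs `","`.
#' @param name Dataset name; defaults to the file name.
#' @param quiet Suppress the skipped-row warning.
#' @return A validated [combination_dataset()].
#' @export
read_dataset <- function(path, sep = NULL, name = basename(path),
                         quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  }
  raw <- utils::read.table(text = lines, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE, strip.white = TRUE)
  required <- c("cell_line", "drugs", "viability")
  miss <- setdiff(required, names(raw))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }

  is_blank <- function(v) is.na(v) | v == "" | v == "-"
  parse_num <- function(v, what) {
    out <- rep(NA_real_, length(v))
    fill <- !is_blank(v)
    val <- suppressWarnings(as.numeric(gsub("−", "-", v[fill])))
    if (anyNA(val)) {
      rows <- which(fill)[is.na(val)] + 1L  # +1 for the header line
      stop("malformed number in column '", what, "', file row(s) ",
           paste(rows, collapse = ", "), call. = FALSE)
    }
    out[fill] <- val
    out
  }

  viability <- parse_num(raw$viability, "viability")
  long <- all(c("repeat_index", "repeat_value") %in% names(raw))
  wide_cols <- grep("^repeat_[0-9]+$", names(raw), value = TRUE)

  if (long) {
    rep_val <- parse_num(raw$repeat_value, "repeat_value")
    rep_idx <- parse_num(raw$repeat_index, "repeat_index")
    grp <- paste(raw$cell_line, vapply(raw$drugs, cocktail_label, ""),
                 sep = "\r")
    first <- !duplicated(grp)
    out <- raw[first, setdiff(names(raw), c("repeat_index", "repeat_value")),
               drop = FALSE]
    out$viability <- viability[first]
    reps <- lapply(unique(grp), function(g) {
      i <- which(grp == g & !is.na(rep_val))
      if (!length(i)) return(NULL)
      rep_val[i][order(rep_idx[i])]
    })
    # a group may state the mean once; otherwise take the mean of repeats
    need <- is.na(out$viability) & !vapply(reps, is.null, TRUE)
    out$viability[need] <- vapply(reps[need], mean, 0)
    raw <- out
    viability <- raw$viability
    repeats <- reps
  } else if (length(wide_cols)) {
    mats <- lapply(wide_cols, function(cn) parse_num(raw[[cn]], cn))
    mat <- do.call(cbind, mats)
    repeats <- lapply(seq_len(nrow(raw)), function(i) {
      r <- mat[i, ]
      r <- r[!is.na(r)]
      if (length(r)) unname(r) else NULL
    })
  } else {
    repeats <- replicate(nrow(raw), NULL, simplify = FALSE)
  }

  skip <- is.na(viability)
  if (any(skip) && !quiet) {
    warning("skipping ", sum(skip), " record(s) with missing viability: ",
            paste(raw$cell_line[skip], raw$drugs[skip], collapse = "; "),
            call. = FALSE)
  }

  get_col <- function(cn) {
    if (cn %in% names(raw)) parse_num(raw[[cn]], cn) else NA_real_
  }
  rec <- data.frame(cell_line = raw$cell_line, drugs = raw$drugs,
                    viability = viability, stringsAsFactors = FALSE)
  rec$ste <- get_col("ste")
  rec$interaction <- get_col("interaction")
  rec$ci_low <- get_col("ci_low")
  rec$ci_high <- get_col("ci_high")
  rec$label <- if ("label" %in% names(raw)) raw$label else ""
  rec$repeats <- repeats
  rec <- rec[!skip, , drop = FALSE]
  combination_dataset(rec, name = name)
}

#' Write a combination screen to a delimited text file
#'
#' Writes all record fields (repeats as wide `repeat_1..repeat_n` columns)
#' with enough digits that `read_dataset(write_dataset(x))` round-trips
#' every value exactly at double precision. Absent values are written as
#' empty cells.
#'
#' @param x A `combination_dataset`.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @param header Optional comment line(s) written before the table, each
#'   prefixed with `"# "`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(x, path, sep = "\t", header = NULL) {
  stopifnot(inherits(x, "combination_dataset"))
  rec <- x$records
  fmt <- function(v) ifelse(is.na(v), "", formatC(v, format = "g",
                                                  digits = 15))
  out <- data.frame(cell_line = rec$cell_line, drugs = rec$drugs,
                    viability = fmt(rec$viability), ste = fmt(rec$ste),
                    interaction = fmt(rec$interaction),
                    ci_low = fmt(rec$ci_low), ci_high = fmt(rec$ci_high),
                    label = rec$label, stringsAsFactors = FALSE,
                    check.names = FALSE)
  n_rep <- max(c(0L, lengths(rec$repeats)))
  for (k in seq_len(n_rep)) {
    out[[paste0("repeat_", k)]] <- vapply(rec$repeats, function(r) {
      if (is.null(r) || length(r) < k) "" else fmt(r[k])
    }, "")
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste("#", header), con)
  utils::write.table(out, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The built-in six-drug chemotherapy screen
#'
#' A fully factorial viability screen of all 63 combinations of six
#' cytotoxic drugs (camptothecin CPT, cisplatin CISPT, carboplatin CBPT,
#' nocodazole NCZ, etoposide ETOPO, and the proteasome inhibitor MG132),
#' each at a fixed dose of about 80% single-drug survival, on two human
#' cancer cell lines (H1299 lung carcinoma and HeLa cervical carcinoma).
#' Viability is the 48-h survival fraction relative to untreated control
#' (neutral red assay); records carry the published means, standard errors,
#' Bliss-log interaction scores with 5th/95th bootstrap percentile bounds,
#' and the published significance calls. H1299 has all 63 combinations;
#' 17 HeLa combinations (all but one involving both CBPT and NCZ) were too
#' variable between repeats and are absent -- query them with
#' [missing_pairs()] or by the absent records.
#'
#' @return A [combination_dataset()] named `"table2"` (63 H1299 + 46 HeLa
#'   records). Per-repeat viabilities are not part of the published table,
#'   so `repeats` are `NULL` throughout.
#' @examples
#' scr <- table2_fixture()
#' get_viability(scr, "H1299", "CPT")
#' missing_pairs(scr, "HeLa")
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "table2_viability.tsv",
                      package = "pairscreen", mustWork = TRUE)
  ds <- read_dataset(path, sep = "\t", name = "table2", quiet = TRUE)
  ds
}
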