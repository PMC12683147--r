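#' Construct a Napping dataset
#'
#' A Napping (projective mapping) dataset holds the 2-D sheet placements of
#' `n` products by `m` raters, optional free-text descriptors attached to each
#' (rater, product) placement, and optional product metadata (design factors
#' such as breed or feeding group).
#'
#' @param products Character vector of product identifiers (length `n >= 2`),
#'   in display order.
#' @param raters Character vector of rater identifiers (length `m >= 1`).
#' @param sheets Named list (one entry per rater) of numeric matrices with two
#'   columns (`x`, `y`, nominally in cm) and row names giving the products the
#'   rater placed.  Partial sheets (a rater omitting products) are allowed;
#'   every sheet must place at least two products.
#' @param descriptors Named list (by rater) of named lists (by product) of
#'   character vectors: the free-text descriptors a rater attached to a
#'   product.  May be empty.
#' @param metadata Optional data frame of design factors, one row per product,
#'   with row names equal to the product identifiers.
#'
#' @return An object of class `napping_dataset`.
#' @export
napping_dataset <- function(products, raters, sheets,
                            descriptors = list(), metadata = NULL) {
  products <- as.character(products)
  raters <- as.character(raters)
  if (length(products) < 2L) abort_validation("need at least 2 products")
  if (anyDuplicated(products)) abort_validation("duplicate product identifiers")
  if (length(raters) < 1L) abort_validation("need at least 1 rater")
  if (anyDuplicated(raters)) abort_validation("duplicate rater identifiers")
  if (!all(names(sheets) %in% raters)) {
    abort_validation(sprintf(
      "sheet given for unknown rater(s): %s",
      paste(setdiff(names(sheets), raters), collapse = ", ")))
  }
  sheets <- lapply(sheets, function(s) {
    s <- as.matrix(s)
    storage.mode(s) <- "double"
    if (ncol(s) != 2L) abort_validation("each sheet needs exactly 2 coordinate columns")
    colnames(s) <- c("x", "y")
    if (is.null(rownames(s))) abort_validation("sheet rows must be named by product")
    if (!all(rownames(s) %in% products)) {
      abort_validation(sprintf("sheet places unknown product(s): %s",
                               paste(setdiff(rownames(s), products), collapse = ", ")))
    }
    if (anyDuplicated(rownames(s))) abort_validation("a sheet places a product twice")
    if (nrow(s) < 2L) abort_insufficient("a sheet must place at least 2 products")
    if (!all(is.finite(s))) abort_validation("non-finite coordinate on a sheet")
    s
  })
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (!setequal(rownames(metadata), products)) {
      abort_validation("metadata row names must match the product identifiers")
    }
    metadata <- metadata[products, , drop = FALSE]
    for (cn in colnames(metadata)) {
      lv <- as.character(metadata[[cn]])
      if (any(is.na(lv) | !nzchar(lv))) {
        abort_validation(sprintf("empty level in metadata factor '%s'", cn))
      }
      metadata[[cn]] <- lv
    }
  }
  structure(list(products = products, raters = raters, sheets = sheets,
                 descriptors = descriptors, metadata = metadata),
            class = "napping_dataset")
}

#' @export
print.napping_dataset <- function(x, ...) {
  cat(sprintf("Napping dataset: %d products, %d raters\n",
              length(x$products), length(x$raters)))
  placed <- vapply(x$sheets, nrow, integer(1))
  if (length(placed) && any(placed < length(x$products))) {
    cat(sprintf("  partial sheets: %d rater(s) omitted products\n",
                sum(placed < length(x$products))))
  }
  ndesc <- sum(lengths(unlist(x$descriptors, recursive = FALSE)))
  cat(sprintf("  descriptors: %d tokens; metadata factors: %s\n", ndesc,
              if (is.null(x$metadata)) "none"
              else paste(colnames(x$metadata), collapse = ", ")))
  invisible(x)
}

# parse a character vector to double, erroring with row context
parse_numeric_column <- function(v, column, rows) {
  out <- suppressWarnings(as.numeric(v))
  bad <- which(is.na(out) & !is.na(v))
  if (length(bad)) {
    val <- v[bad[1L]]
    hint <- if (grepl("^-?[0-9]+,[0-9]+$", val))
      " (comma decimal separator is not accepted; use '.')" else ""
    abort_parse(sprintf("non-numeric value '%s' in column '%s' at data row %d%s",
                        val, column, rows[bad[1L]], hint))
  }
  out
}

require_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort_format(sprintf("'%s' is missing required column(s): %s",
                         path, paste(miss, collapse = ", ")))
  }
}

tokenize_descriptors <- function(s, delim) {
  toks <- trimws(tolower(unlist(strsplit(s, delim))))
  toks[nzchar(toks)]
}

#' Read a Napping dataset from long-format CSV
#'
#' The canonical on-disk layout is tidy/long: one row per (rater, product)
#' placement with columns `rater`, `product`, `x`, `y` and an optional
#' descriptor column holding delimiter-separated free-text tokens.
#'
#' @param path Path to the placements CSV.
#' @param metadata_path Optional path to a product metadata CSV with a
#'   `product` column and one column per design factor.
#' @param descriptor_col Name of the optional descriptor column.
#' @param descriptor_delim Regular expression splitting descriptor strings
#'   into tokens (default: comma or semicolon).  Tokens are lower-cased and
#'   whitespace-trimmed at load; further processing is left to
#'   [descriptor_profile()].
#'
#' @return A [napping_dataset()].
#' @export
load_napping <- function(path, metadata_path = NULL,
                         descriptor_col = "descriptors",
                         descriptor_delim = "[,;]") {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  require_columns(df, c("rater", "product", "x", "y"), path)
  if (nrow(df) == 0L) abort_format(sprintf("'%s' contains no records", path))
  rows <- seq_len(nrow(df))
  x <- parse_numeric_column(df$x, "x", rows)
  y <- parse_numeric_column(df$y, "y", rows)
  key <- paste(df$rater, df$product, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    abort_validation(sprintf("duplicate placement of product '%s' by rater '%s'",
                             d$product, d$rater))
  }
  products <- unique(df$product)
  raters <- unique(df$rater)
  sheets <- lapply(split(data.frame(product = df$product, x = x, y = y,
                                    stringsAsFactors = FALSE),
                         factor(df$rater, levels = raters)),
                   function(g) {
                     g <- g[order(g$product), , drop = FALSE]  # row-order insensitivity
                     m <- cbind(x = g$x, y = g$y)
                     rownames(m) <- g$product
                     m
                   })
  descriptors <- list()
  if (descriptor_col %in% names(df)) {
    for (i in rows) {
      toks <- tokenize_descriptors(df[[descriptor_col]][i], descriptor_delim)
      if (length(toks)) descriptors[[df$rater[i]]][[df$product[i]]] <- toks
    }
  }
  metadata <- NULL
  if (!is.null(metadata_path)) {
    md <- utils::read.csv(metadata_path, colClasses = "character",
                          check.names = FALSE, fileEncoding = "UTF-8")
    require_columns(md, "product", metadata_path)
    if (anyDuplicated(md$product)) abort_validation("duplicate product in metadata")
    metadata <- md[, setdiff(names(md), "product"), drop = FALSE]
    rownames(metadata) <- md$product
  }
  # products sorted for row-order insensitivity; raters likewise
  ord <- order(products)
  napping_dataset(products[ord], raters[order(raters)], sheets,
                  descriptors = descriptors, metadata = metadata)
}

#' Write a Napping dataset to long-format CSV
#'
#' Inverse of [load_napping()]: `load_napping(write_napping(x))` recovers `x`.
#'
#' @param dataset A [napping_dataset()].
#' @param path Output CSV path for the placements.
#' @param metadata_path Optional output path for the product metadata table.
#' @return Invisibly, `path`.
#' @export
write_napping <- function(dataset, path, metadata_path = NULL) {
  rows <- do.call(rbind, lapply(names(dataset$sheets), function(r) {
    s <- dataset$sheets[[r]]
    desc <- vapply(rownames(s), function(p) {
      d <- dataset$descriptors[[r]][[p]]
      if (is.null(d)) "" else paste(d, collapse = "; ")
    }, character(1))
    data.frame(rater = r, product = rownames(s), x = s[, "x"], y = s[, "y"],
               descriptors = desc, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(metadata_path) && !is.null(dataset$metadata)) {
    md <- cbind(product = rownames(dataset$metadata), dataset$metadata)
    utils::write.csv(md, metadata_path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Construct a QDA dataset
#'
#' Holds trained-panel line-scale scores in long format: one record per
#' (rater, serving, attribute).  Servings are the physical samples served;
#' each serving belongs to one product.
#'
#' @param records Data frame with columns `rater`, `product`, `serving`,
#'   `attribute`, `score`.
#' @param factors Optional data frame of design factors, one row per product
#'   (row names are products).
#' @param scale_max Upper bound of the unstructured line scale in scale units
#'   (default 15, the conventional 15 cm line anchored 0-100).
#' @return An object of class `qda_dataset`.
#' @export
qda_dataset <- function(records, factors = NULL, scale_max = 15) {
  records <- as.data.frame(records)
  need <- c("rater", "product", "serving", "attribute", "score")
  require_columns(records, need, "records")
  if (nrow(records) == 0L) abort_format("no records")
  records$score <- as.numeric(records$score)
  for (cn in c("rater", "product", "serving", "attribute"))
    records[[cn]] <- as.character(records[[cn]])
  bad <- which(!is.finite(records$score) |
                 records$score < 0 | records$score > scale_max)
  if (length(bad)) {
    abort_validation(sprintf(
      "score %s outside [0, %g] at data row %d", records$score[bad[1L]],
      scale_max, bad[1L]))
  }
  key <- paste(records$rater, records$serving, records$attribute, sep = "\r")
  if (anyDuplicated(key)) {
    d <- records[duplicated(key), ][1L, ]
    abort_validation(sprintf(
      "duplicate record for rater '%s', serving '%s', attribute '%s'",
      d$rater, d$serving, d$attribute))
  }
  if (!is.null(factors)) {
    factors <- as.data.frame(factors)
    if (!all(unique(records$product) %in% rownames(factors))) {
      abort_validation("factors table does not cover every product")
    }
  }
  structure(list(records = records[order(records$rater, records$serving,
                                         records$attribute), ],
                 factors = factors, scale_max = scale_max),
            class = "qda_dataset")
}

#' @export
print.qda_dataset <- function(x, ...) {
  cat(sprintf("QDA dataset: %d records; %d raters, %d products, %d attributes; scale [0, %g]\n",
              nrow(x$records), length(unique(x$records$rater)),
              length(unique(x$records$product)),
              length(unique(x$records$attribute)), x$scale_max))
  invisible(x)
}

#' Read a QDA dataset from long-format CSV
#'
#' @param path CSV with columns `rater`, `product`, `serving`, `attribute`,
#'   `score`.
#' @param metadata_path Optional product metadata CSV (`product` column plus
#'   factor columns).
#' @inheritParams qda_dataset
#' @return A [qda_dataset()].
#' @export
load_qda <- function(path, scale_max = 15, metadata_path = NULL) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  require_columns(df, c("rater", "product", "serving", "attribute", "score"), path)
  if (nrow(df) == 0L) abort_format(sprintf("'%s' contains no records", path))
  df$score <- parse_numeric_column(df$score, "score", seq_len(nrow(df)))
  factors <- NULL
  if (!is.null(metadata_path)) {
    md <- utils::read.csv(metadata_path, colClasses = "character",
                          check.names = FALSE, fileEncoding = "UTF-8")
    require_columns(md, "product", metadata_path)
    factors <- md[, setdiff(names(md), "product"), drop = FALSE]
    rownames(factors) <- md$product
  }
  qda_dataset(df, factors = factors, scale_max = scale_max)
}

#' Write a QDA dataset to CSV
#' @param dataset A [qda_dataset()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_qda <- function(dataset, path) {
  utils::write.csv(dataset$records, path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a distance matrix as a square labelled CSV
#'
#' Full double precision is preserved, so `read_distance_matrix()` recovers
#' the matrix to better than 1e-12.
#'
#' @param matrix A [distance_matrix()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_distance_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "distance_matrix"))
  v <- matrix$values
  df <- data.frame(product = matrix$labels,
                   apply(v, 2L, function(col) sprintf("%.17g", col)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("product", matrix$labels)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort_io(sprintf("cannot write to '%s'", path))
  invisible(path)
}

#' Read a distance matrix written by [write_distance_matrix()]
#' @param path CSV path.
#' @param provenance Provenance tag to attach (`"per-rater"`,
#'   `"panel-averaged"` or `"concatenated"`).
#' @return A [distance_matrix()].
#' @export
read_distance_matrix <- function(path, provenance = "panel-averaged") {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                        colClasses = "character")
  labels <- df[[1L]]
  v <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(v) <- "double"
  dimnames(v) <- list(labels, names(df)[-1L])
  distance_matrix(v, provenance = provenance)
}

#' Read a key=value configuration file
#'
#' Minimal INI-style parser: one `key = value` pair per line, `#` comments,
#' blank lines ignored.  Values that parse as numbers are returned numeric.
#'
#' @param path Path to the configuration file.
#' @return Named list of settings.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      abort_format(sprintf("config line is not 'key = value': '%s'", ln))
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    val <- gsub('^"|"$', "", val)
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
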