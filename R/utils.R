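#' @keywords internal
"_PACKAGE"

#' @importFrom stats qnorm pbinom quantile median runif rnorm sd setNames
#' @importFrom utils head tail modifyList
NULL

# Items are strings: value items are "<col>.<symbol>" (e.g. "y2.-1"), annotation
# items are "T:<term>", and raw tokens (e.g. "a") are allowed for databases read
# from plain transaction files with an explicit cost table.
ANNOT_PREFIX <- "T:"

is_annotation_item <- function(items) startsWith(items, ANNOT_PREFIX)

#' Split value items into column and symbol parts
#'
#' Value items concatenate a column identifier and a symbol with a dot
#' (`"y2.-1"`). Raw tokens without a dot have no column part.
#'
#' @param items character vector of items.
#' @return list with character vectors `col` and `symbol` (NA where absent).
#' @keywords internal
split_items <- function(items) {
  col <- rep(NA_character_, length(items))
  symbol <- rep(NA_character_, length(items))
  ann <- is_annotation_item(items)
  pos <- regexpr("\\.[^.]*$", items)
  has_dot <- pos > 1L & !ann
  col[has_dot] <- substr(items[has_dot], 1L, pos[has_dot] - 1L)
  symbol[has_dot] <- substr(items[has_dot], pos[has_dot] + 1L, nchar(items[has_dot]))
  symbol[!has_dot & !ann] <- items[!has_dot & !ann]
  list(col = col, symbol = symbol)
}

make_item <- function(col, symbol) paste0(col, ".", symbol)

# Numeric formatting used by writers: full precision, no scientific notation.
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else format(v, digits = 15, scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_counter <- function() {
  env <- new.env(parent = emptyenv())
  env$visited <- 0L
  env$removed_transactions <- 0L
  env$removed_items <- 0L
  env
}

counter_state <- function(counter) {
  list(
    visited = counter$visited,
    removed_transactions = counter$removed_transactions,
    removed_items = counter$removed_items
  )
}

# Cell-set Jaccard between two biclusters given as list(rows=, cols=).
cell_jaccard <- function(a, b) {
  ri <- length(intersect(a$rows, b$rows))
  ci <- length(intersect(a$cols, b$cols))
  inter <- ri * ci
  union <- length(a$rows) * length(a$cols) + length(b$rows) * length(b$cols) - inter
  if (union == 0) return(0)
  inter / union
}

row_jaccard <- function(a, b) {
  inter <- length(intersect(a$rows, b$rows))
  union <- length(a$rows) + length(b$rows) - inter
  if (union == 0) return(0)
  inter / union
}

bic_log <- function(level, ..., verbose = getOption("bic2pam.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[", level, "] ", ...)
  invisible(NULL)
}
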