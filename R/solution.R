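#' Construct a bicluster
#'
#' A bicluster is a row subset `I` and a column subset `J` whose values follow
#' a coherency model: `a_ij = k_j + gamma_i + noise` (constant when all
#' `gamma_i = 0`, additive otherwise), with optional row signs for symmetric
#' models, or a shared linear ordering of columns (order-preserving).
#'
#' @param rows character vector of row identifiers (`I`), at least 1.
#' @param cols character vector of column identifiers (`J`), at least 2.
#' @param pattern expected values `k_j` aligned to `cols`; for order-preserving
#'   coherency, the ordering relation over `cols` (a character string).
#' @param coherency one of `"constant"`, `"additive"`, `"symmetric"`,
#'   `"order-preserving"`.
#' @param row_factors named numeric `gamma_i` per row (additive only).
#' @param signs named vector of +1/-1 per row (symmetric only).
#' @param p_value significance in `[0,1]`, or `NA` when not yet computed.
#' @return object of class `bicluster`.
#' @export
bicluster <- function(rows, cols, pattern, coherency = "constant",
                      row_factors = NULL, signs = NULL, p_value = NA_real_) {
  stopifnot(length(rows) >= 1L, length(cols) >= 2L)
  coherency <- match.arg(coherency, c("constant", "additive", "symmetric", "order-preserving"))
  if (coherency != "order-preserving" && length(pattern) != length(cols)) {
    stop("pattern length must equal the number of columns")
  }
  structure(
    list(rows = as.character(rows), cols = as.character(cols), pattern = pattern,
         coherency = coherency, row_factors = row_factors, signs = signs,
         p_value = p_value),
    class = "bicluster"
  )
}

#' @export
print.bicluster <- function(x, ...) {
  cat(sprintf("<bicluster> %d x %d (%s), pattern: %s\n",
              length(x$rows), length(x$cols), x$coherency,
              paste(x$pattern, collapse = " ")))
  invisible(x)
}

n_cells <- function(b) length(b$rows) * length(b$cols)

#' Construct a biclustering solution
#'
#' @param biclusters list of [bicluster()] objects.
#' @param params list of parameters and constraint expressions used (provenance).
#' @param matrix optional source matrix, used to compute the covered fraction of
#'   non-missing cells.
#' @return object of class `biclustering_solution` with `biclusters`, `params`
#'   and `coverage`.
#' @export
biclustering_solution <- function(biclusters, params = list(), matrix = NULL) {
  coverage <- NA_real_
  if (!is.null(matrix)) coverage <- solution_coverage(biclusters, matrix)
  structure(list(biclusters = biclusters, params = params, coverage = coverage),
            class = "biclustering_solution")
}

solution_coverage <- function(biclusters, m) {
  covered <- matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m))
  for (b in biclusters) covered[b$rows, b$cols] <- TRUE
  denom <- sum(!is.na(m))
  if (denom == 0) return(0)
  sum(covered & !is.na(m)) / denom
}

#' @export
print.biclustering_solution <- function(x, ...) {
  cat(sprintf("<biclustering_solution> %d biclusters, coverage %.3f\n",
              length(x$biclusters), x$coverage))
  invisible(x)
}

#' Serialize a biclustering solution to JSON
#'
#' The document captures, per bicluster, rows, cols, pattern, coherency, row
#' factors, signs and p-value, plus the run parameters and coverage, so that
#' `read_solution(write_solution(s))` round-trips.
#'
#' @param solution a `biclustering_solution`.
#' @param path output path.
#' @export
write_solution <- function(solution, path) {
  doc <- list(
    biclusters = lapply(solution$biclusters, function(b) {
      list(rows = b$rows, cols = b$cols, pattern = b$pattern,
           coherency = b$coherency,
           row_factors = if (!is.null(b$row_factors)) as.list(b$row_factors),
           signs = if (!is.null(b$signs)) as.list(b$signs),
           p_value = b$p_value)
    }),
    params = solution$params,
    coverage = solution$coverage
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a biclustering solution from JSON
#' @param path path written by [write_solution()].
#' @return a `biclustering_solution`.
#' @export
read_solution <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  bics <- lapply(doc$biclusters, function(b) {
    bicluster(rows = unlist(b$rows), cols = unlist(b$cols),
              pattern = unlist(b$pattern), coherency = b$coherency,
              row_factors = if (length(b$row_factors)) unlist(b$row_factors) else NULL,
              signs = if (length(b$signs)) unlist(b$signs) else NULL,
              p_value = b$p_value %||% NA_real_)
  })
  structure(list(biclusters = bics, params = doc$params,
                 coverage = doc$coverage %||% NA_real_),
            class = "biclustering_solution")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a biclustering solution
#'
#' One row per bicluster: sizes, coherency, p-value and the pattern as a
#' printed string.
#'
#' @param x a `biclustering_solution`.
#' @param ... unused.
#' @return a tibble.
#' @exportS3Method generics::tidy
tidy.biclustering_solution <- function(x, ...) {
  tibble::tibble(
    bicluster = seq_along(x$biclusters),
    n_rows = vapply(x$biclusters, function(b) length(b$rows), integer(1)),
    n_cols = vapply(x$biclusters, function(b) length(b$cols), integer(1)),
    coherency = vapply(x$biclusters, function(b) b$coherency, character(1)),
    pattern = vapply(x$biclusters, function(b) paste(b$pattern, collapse = " "), character(1)),
    p_value = vapply(x$biclusters, function(b) as.numeric(b$p_value), numeric(1))
  )
}

#' Glance at a biclustering solution
#' @param x a `biclustering_solution`.
#' @param ... unused.
#' @return one-row tibble with counts and coverage.
#' @exportS3Method generics::glance
glance.biclustering_solution <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    n_biclusters = nrow(td),
    coverage = x$coverage,
    median_rows = stats::median(td$n_rows),
    median_cols = stats::median(td$n_cols),
    min_p_value = if (nrow(td)) suppressWarnings(min(td$p_value, na.rm = TRUE)) else NA_real_
  )
}

#' Plot bicluster sizes of a solution
#'
#' Rows-by-columns scatter of the returned biclusters, coloured by coherency
#' and sized by -log10 p-value.
#'
#' @param object a `biclustering_solution`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.biclustering_solution <- function(object, ...) {
  td <- tidy(object)
  td$neglog_p <- -log10(pmax(td$p_value, 1e-300))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$n_cols, y = .data$n_rows,
                                   colour = .data$coherency, size = .data$neglog_p)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "columns", y = "rows", size = "-log10 p") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
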