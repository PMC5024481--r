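#' Read a real-valued matrix from delimited text
#'
#' The first row holds column identifiers and the first field of each
#' subsequent line the row identifier. Cells are parsed as reals; configurable
#' missing tokens become `NA`. Missing cells are first-class: they are excluded
#' from discretization and mining (important for sparse adjacency matrices,
#' where zeros would fabricate interactions).
#'
#' @param path file path.
#' @param sep field delimiter (default tab).
#' @param missing_tokens character vector of tokens parsed as missing.
#' @return numeric matrix with unique `rownames`/`colnames`.
#' @export
read_matrix <- function(path, sep = "\t", missing_tokens = c("", "NA", "NaN")) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("matrix file needs a header row and at least one data row")
  header <- strsplit(lines[1L], sep, fixed = TRUE)[[1L]]
  col_ids <- header[-1L]
  if (anyDuplicated(col_ids)) stop("duplicate column identifiers in ", path)
  rows <- strsplit(lines[-1L], sep, fixed = TRUE)
  row_ids <- vapply(rows, `[[`, character(1), 1L)
  if (anyDuplicated(row_ids)) stop("duplicate row identifiers in ", path)
  m <- matrix(NA_real_, nrow = length(row_ids), ncol = length(col_ids),
              dimnames = list(row_ids, col_ids))
  for (i in seq_along(rows)) {
    cells <- rows[[i]][-1L]
    if (length(cells) != length(col_ids)) {
      stop("row '", row_ids[i], "' has ", length(cells), " cells, expected ", length(col_ids))
    }
    miss <- cells %in% missing_tokens
    vals <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(vals) & !miss)
    if (length(bad)) {
      stop("non-numeric cell at row '", row_ids[i], "', column '", col_ids[bad[1L]], "'")
    }
    vals[miss] <- NA_real_
    m[i, ] <- vals
  }
  m
}

#' Write a matrix as delimited text
#'
#' Inverse of [read_matrix()]: header row of column ids, row id as first field.
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param sep field delimiter.
#' @export
write_matrix <- function(m, path, sep = "\t") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(m)), collapse = sep), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i], fmt_num(m[i, ])), collapse = sep), con)
  }
  invisible(path)
}

#' Amplitude of a matrix
#'
#' Range (max minus min) over the observed (non-missing) values.
#'
#' @param m numeric matrix.
#' @return non-negative scalar.
#' @export
amplitude <- function(m) {
  v <- m[!is.na(m)]
  if (!length(v)) stop("matrix has no observed values")
  max(v) - min(v)
}

#' Read a weighted network from a 3-column edge list
#'
#' @param path file with lines `node<sep>node<sep>weight`.
#' @param directed logical flag.
#' @param sep field delimiter.
#' @return object of class `bic_network`: list with `nodes`, `edges`
#'   (data.frame from/to/weight) and `directed`.
#' @export
read_network <- function(path, directed = FALSE, sep = "\t") {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty edge list")
  parts <- strsplit(lines, sep, fixed = TRUE)
  if (any(lengths(parts) != 3L)) stop("edge lines must have 3 fields: node, node, weight")
  edges <- data.frame(
    from = vapply(parts, `[[`, character(1), 1L),
    to = vapply(parts, `[[`, character(1), 2L),
    weight = as.numeric(vapply(parts, `[[`, character(1), 3L)),
    stringsAsFactors = FALSE
  )
  if (anyNA(edges$weight)) stop("non-numeric edge weight")
  network(edges, directed = directed)
}

#' Construct a network from an edge data frame
#'
#' @param edges data.frame with columns `from`, `to`, `weight`.
#' @param directed logical flag.
#' @export
network <- function(edges, directed = FALSE) {
  stopifnot(all(c("from", "to", "weight") %in% names(edges)))
  if (!nrow(edges)) stop("empty edge set")
  key <- if (directed) paste(edges$from, edges$to) else
    paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  if (anyDuplicated(key)) stop("duplicate edges in network")
  structure(
    list(nodes = sort(unique(c(edges$from, edges$to))), edges = edges, directed = directed),
    class = "bic_network"
  )
}

#' Map a network to a (sparse) adjacency matrix
#'
#' Rows are source nodes and columns target nodes; for undirected networks both
#' equal the node set and the matrix is symmetric. Absent edges become missing
#' cells, not zeros, so non-interactions are never mined as values.
#'
#' @param net a `bic_network`.
#' @return numeric matrix with `NA` for absent edges.
#' @export
network_to_matrix <- function(net) {
  stopifnot(inherits(net, "bic_network"))
  nodes <- net$nodes
  m <- matrix(NA_real_, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  e <- net$edges
  for (i in seq_len(nrow(e))) {
    m[e$from[i], e$to[i]] <- e$weight[i]
    if (!net$directed) m[e$to[i], e$from[i]] <- e$weight[i]
  }
  m
}

#' Read row annotations
#'
#' Lines are `row_id<TAB>term[,term...]`; a row with no terms keeps an empty
#' set. Terms are opaque strings (no ontology semantics).
#'
#' @param path annotation file.
#' @param sep delimiter between row id and term list.
#' @return named list mapping row id to character vector of terms.
#' @export
read_annotations <- function(path, sep = "\t") {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, sep, fixed = TRUE)[[1L]]
    id <- parts[1L]
    terms <- if (length(parts) < 2L || !nzchar(parts[2L])) character(0) else
      strsplit(parts[2L], ",", fixed = TRUE)[[1L]]
    out[[id]] <- unique(terms)
  }
  out
}

#' Write row annotations
#' @param ann named list of term vectors.
#' @param path output path.
#' @param sep delimiter.
#' @export
write_annotations <- function(ann, path, sep = "\t") {
  lines <- vapply(names(ann), function(id) {
    paste(id, paste(ann[[id]], collapse = ","), sep = sep)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a network edge list
#' @param net a `bic_network`.
#' @param path output path.
#' @param sep delimiter.
#' @export
write_network <- function(net, path, sep = "\t") {
  e <- net$edges
  writeLines(paste(e$from, e$to, fmt_num(e$weight), sep = sep), path)
  invisible(path)
}
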