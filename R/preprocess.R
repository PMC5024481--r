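#' Zero-mean row normalization
#'
#' Subtracts each row's mean over observed values; missing cells are untouched.
#' Idempotent.
#'
#' @param m numeric matrix.
#' @return matrix with every row's non-missing mean equal to 0.
#' @export
normalize_rows <- function(m) {
  all_missing <- rowSums(!is.na(m)) == 0L
  if (any(all_missing)) {
    stop("all-missing row(s): ", paste(rownames(m)[all_missing], collapse = ", "))
  }
  m - rowMeans(m, na.rm = TRUE)
}

alphabet_for <- function(n_items) {
  # integers centered at 0 for odd sizes ({-2,...,2}); even sizes skip 0
  if (n_items %% 2L == 1L) {
    seq.int(-(n_items %/% 2L), n_items %/% 2L)
  } else {
    setdiff(seq.int(-(n_items %/% 2L), n_items %/% 2L), 0L)
  }
}

#' Fit a discretization model
#'
#' `gaussian_quantile` places the `n_items - 1` cutpoints at the
#' `k/n_items` quantiles of a Normal fitted to all observed values, so symbols
#' are (approximately) equally populated under Gaussian-like expression data;
#' `equal_width` splits the observed `[min, max]` range evenly. The coherency
#' strength is `delta = amplitude / n_items`: finer alphabets mean stricter
#' coherency.
#'
#' @param m numeric matrix.
#' @param n_items alphabet size (>= 2).
#' @param method `"gaussian_quantile"` or `"equal_width"`.
#' @return object of class `disc_model`: alphabet (integer symbols), cutpoints,
#'   `delta`, observed range and the method used.
#' @export
fit_discretization <- function(m, n_items, method = c("gaussian_quantile", "equal_width")) {
  stopifnot(n_items >= 2L)
  method <- match.arg(method)
  v <- m[!is.na(m)]
  vmin <- min(v); vmax <- max(v)
  amp <- vmax - vmin
  if (method == "gaussian_quantile" && (length(v) < 2L || sd(v) == 0)) {
    warning("zero variance: falling back to equal_width discretization")
    method <- "equal_width"
  }
  probs <- seq_len(n_items - 1L) / n_items
  if (amp == 0) {
    # degenerate constant matrix: pick cutpoints so all cells land mid-alphabet
    cutpoints <- vmin + (seq_len(n_items - 1L) - n_items / 2)
  } else if (method == "gaussian_quantile") {
    cutpoints <- qnorm(probs, mean = mean(v), sd = sd(v))
  } else {
    cutpoints <- vmin + probs * amp
  }
  structure(
    list(alphabet = alphabet_for(n_items), n_items = as.integer(n_items),
         cutpoints = cutpoints, delta = amp / n_items, amplitude = amp,
         vmin = vmin, vmax = vmax, method = method),
    class = "disc_model"
  )
}

#' Discretize a matrix with multi-item assignments
#'
#' Each observed cell gets the symbol of its bin. Cells within
#' `alpha * (bin width)` of a cutpoint additionally receive the adjacent bin's
#' symbol (the multi-item assignment that makes pattern mining robust to
#' borderline discretizations); `alpha = 0` disables it.
#'
#' @param m numeric matrix.
#' @param model a `disc_model` from [fit_discretization()].
#' @param alpha multi-item boundary fraction in `[0, 0.5)` (default 0.25).
#' @return object of class `disc_matrix`: integer matrices `primary` and
#'   `secondary` (`NA` where only one symbol applies), plus the model.
#' @export
discretize <- function(m, model, alpha = 0.25) {
  stopifnot(inherits(model, "disc_model"), alpha >= 0, alpha < 0.5)
  cut <- model$cutpoints
  n <- model$n_items
  bounds <- c(min(model$vmin, min(m, na.rm = TRUE)), cut, max(model$vmax, max(m, na.rm = TRUE)))
  widths <- diff(bounds)
  bin <- matrix(findInterval(m, cut) + 1L, nrow(m), ncol(m), dimnames = dimnames(m))
  bin[bin > n] <- n
  primary <- matrix(model$alphabet[bin], nrow(m), ncol(m), dimnames = dimnames(m))
  primary[is.na(m)] <- NA_integer_
  secondary <- matrix(NA_integer_, nrow(m), ncol(m), dimnames = dimnames(m))
  if (alpha > 0) {
    for (k in seq_len(n)) {
      idx <- which(bin == k & !is.na(m))
      if (!length(idx)) next
      w <- alpha * widths[k]
      if (k > 1L) {
        lo <- idx[m[idx] - bounds[k] <= w]
        secondary[lo] <- model$alphabet[k - 1L]
      }
      if (k < n) {
        hi <- idx[bounds[k + 1L] - m[idx] <= w]
        secondary[hi] <- model$alphabet[k + 1L]
      }
    }
  }
  structure(list(primary = primary, secondary = secondary, model = model, alpha = alpha),
            class = "disc_matrix")
}

new_itemset_db <- function(tx, coherency = "constant", alphabet = integer(0),
                           row_factors = NULL, mirror_map = NULL) {
  structure(list(tx = tx, coherency = coherency, alphabet = alphabet,
                 row_factors = row_factors, mirror_map = mirror_map),
            class = "itemset_db")
}

#' @export
print.itemset_db <- function(x, ...) {
  cat(sprintf("<itemset_db> %d transactions (%s coherency)\n", length(x$tx), x$coherency))
  invisible(x)
}

#' Map a discretized matrix to a transactional itemset database
#'
#' Items concatenate the column id and the symbol (`"y2.-1"`). Under the
#' additive model each row is anchored at its minimum symbol (subtracted and
#' recorded as the row factor `gamma_i`); under the symmetric model each row
#' also emits a mirrored transaction with all symbols negated, so sign-flipped
#' profiles support the same patterns.
#'
#' @param disc a `disc_matrix` from [discretize()].
#' @param coherency `"constant"`, `"additive"` or `"symmetric"`.
#' @return an `itemset_db`; additive row factors in `$row_factors`, mirrored
#'   transaction ids mapped back to source rows in `$mirror_map`.
#' @export
to_itemset_db <- function(disc, coherency = c("constant", "additive", "symmetric")) {
  stopifnot(inherits(disc, "disc_matrix"))
  coherency <- match.arg(coherency)
  prim <- disc$primary
  sec <- disc$secondary
  cols <- colnames(prim)
  tx <- list()
  row_factors <- NULL
  mirror_map <- NULL
  row_items <- function(p, s) {
    obs <- which(!is.na(p))
    items <- make_item(cols[obs], p[obs])
    obs2 <- which(!is.na(s))
    if (length(obs2)) items <- c(items, make_item(cols[obs2], s[obs2]))
    unique(items)
  }
  for (i in seq_len(nrow(prim))) {
    id <- rownames(prim)[i]
    p <- prim[i, ]; s <- sec[i, ]
    if (!any(!is.na(p))) next
    if (coherency == "additive") {
      g <- min(p, na.rm = TRUE)
      p <- p - g
      s <- s - g
      row_factors <- c(row_factors, setNames(g, id))
    }
    if (coherency == "symmetric") {
      mid <- paste0(id, "::neg")
      tx[[id]] <- row_items(p, s)
      tx[[mid]] <- row_items(-p, -s)
      mirror_map <- c(mirror_map, setNames(id, mid))
    } else {
      tx[[id]] <- row_items(p, s)
    }
  }
  new_itemset_db(tx, coherency = coherency, alphabet = disc$model$alphabet,
                 row_factors = row_factors, mirror_map = mirror_map)
}

new_seq_db <- function(sequences) {
  structure(list(sequences = sequences), class = "seq_db")
}

#' @export
print.seq_db <- function(x, ...) {
  cat(sprintf("<seq_db> %d sequences\n", length(x$sequences)))
  invisible(x)
}

#' Map a matrix to a sequence database for order-preserving mining
#'
#' Per row, columns are sorted ascending by value; columns whose values tie
#' share one itemset (co-occurrence). Ties are decided after discretizing into
#' `n_items` symbols — by default `ceiling(ncol(m)/4)` (floored at 2), trading
#' precedences against co-occurrences — or by exact value equality when
#' `n_items = NULL`.
#'
#' @param m numeric matrix; rows need at least 2 observed cells.
#' @param n_items tie-deciding alphabet size, or `NULL` for exact-value ties.
#' @return a `seq_db`: per row, an ordered list of column-id itemsets, each
#'   itemset sorted by column id.
#' @export
to_sequence_db <- function(m, n_items = max(2L, ceiling(ncol(m) / 4))) {
  keys <- if (is.null(n_items)) m else {
    model <- suppressWarnings(fit_discretization(m, n_items, "gaussian_quantile"))
    discretize(m, model, alpha = 0)$primary
  }
  cols <- colnames(m)
  sequences <- list()
  for (i in seq_len(nrow(m))) {
    obs <- which(!is.na(m[i, ]))
    if (length(obs) < 2L) next
    k <- keys[i, obs]
    groups <- split(cols[obs], k)  # split sorts by key ascending
    sequences[[rownames(m)[i]]] <- unname(lapply(groups, function(g) sort(g)))
  }
  new_seq_db(sequences)
}

#' Append row annotations to a transactional database
#'
#' Annotation terms become namespaced items (`"T:term"`) appended to the row's
#' transaction (itemset databases) or as a trailing itemset (sequence
#' databases), so annotation-aware constraints can be mined like any other
#' item. Annotations for unknown rows are skipped with a warning.
#'
#' @param db an `itemset_db` or `seq_db`.
#' @param ann named list mapping row id to character vector of terms.
#' @return database of the same class with annotation items appended.
#' @export
append_annotations <- function(db, ann) UseMethod("append_annotations")

#' @export
append_annotations.itemset_db <- function(db, ann) {
  skipped <- 0L
  for (id in names(ann)) {
    terms <- ann[[id]]
    if (!length(terms)) next
    targets <- if (!is.null(db$mirror_map)) {
      c(id, names(db$mirror_map)[db$mirror_map == id])
    } else id
    targets <- targets[targets %in% names(db$tx)]
    if (!length(targets)) { skipped <- skipped + 1L; next }
    for (t in targets) db$tx[[t]] <- unique(c(db$tx[[t]], paste0(ANNOT_PREFIX, terms)))
  }
  if (skipped > 0L) warning(skipped, " annotated row(s) not present in database; skipped")
  db
}

#' @export
append_annotations.seq_db <- function(db, ann) {
  skipped <- 0L
  for (id in names(ann)) {
    terms <- ann[[id]]
    if (!length(terms)) next
    if (!id %in% names(db$sequences)) { skipped <- skipped + 1L; next }
    db$sequences[[id]] <- c(db$sequences[[id]], list(sort(paste0(ANNOT_PREFIX, terms))))
  }
  if (skipped > 0L) warning(skipped, " annotated row(s) not present in database; skipped")
  db
}

#' Remove uninformative symbols from an itemset database
#'
#' Deletes all value items whose symbol is in `symbols` (e.g. default
#' expression levels `{-1, 0, 1}`), then drops emptied transactions. This is
#' the pre-mining realization of a succinct exclusion constraint.
#'
#' @param db an `itemset_db`.
#' @param symbols symbols to remove (coerced to character).
#' @return reduced `itemset_db`; counts of removed items and transactions in
#'   attribute `"removed"`.
#' @export
remove_uninformative <- function(db, symbols) {
  stopifnot(inherits(db, "itemset_db"))
  symbols <- as.character(symbols)
  removed_items <- 0L
  for (id in names(db$tx)) {
    items <- db$tx[[id]]
    sym <- split_items(items)$symbol
    keep <- is.na(sym) | !(sym %in% symbols) | is_annotation_item(items)
    removed_items <- removed_items + sum(!keep)
    db$tx[[id]] <- items[keep]
  }
  value_count <- vapply(db$tx, function(it) sum(!is_annotation_item(it)), integer(1))
  drop <- value_count == 0L
  removed_tx <- sum(drop)
  db$tx <- db$tx[!drop]
  attr(db, "removed") <- list(items = removed_items, transactions = removed_tx)
  bic_log("info", "removed ", removed_items, " uninformative items, ",
          removed_tx, " emptied transactions")
  db
}
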