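SYNTH_SETTINGS <- list(
  "500x50"   = list(n_rows = 500L,  n_cols = 50L,  base_k = 6L,  rows = c(50, 70),   cols = c(5, 7)),
  "1000x100" = list(n_rows = 1000L, n_cols = 100L, base_k = 10L, rows = c(70, 100),  cols = c(7, 10)),
  "2000x200" = list(n_rows = 2000L, n_cols = 200L, base_k = 15L, rows = c(100, 200), cols = c(8, 12)),
  "4000x400" = list(n_rows = 4000L, n_cols = 400L, base_k = 20L, rows = c(200, 300), cols = c(10, 15))
)

#' Synthetic benchmark configuration
#'
#' Encodes the benchmark settings: matrix size, number of hidden biclusters
#' `K = base * (1/mu)` with `mu = 1` for constant and `mu = 2` for
#' order-preserving coherency, bicluster size ranges scaled by `mu`, coherency
#' strength via the alphabet size (`delta = amplitude/n_items`), noise
#' deviations and noisy/missing fractions, and overlap with plaid effects.
#'
#' @param setting one of `"500x50"`, `"1000x100"`, `"2000x200"`, `"4000x400"`.
#' @param coherency `"constant"` (mu = 1) or `"order-preserving"` (mu = 2).
#' @param n_items background alphabet size; `delta = amplitude/n_items`
#'   (default 5, i.e. 20% coherency strength).
#' @param noise_deviation deviation magnitude in units of `delta`
#'   (0, 0.5, 1 or 2; default 0.5).
#' @param noisy_fraction,missing_fraction fractions of cells perturbed /
#'   removed (default 0.02 each).
#' @param overlap overlapping degree `theta` (default 0.2; 0 plants disjoint
#'   biclusters).
#' @param plaid_f cumulative function on overlapping cells: `"sum"`,
#'   `"product"` or `"weighted"`.
#' @param plaid_nu cumulative-effect weight (default 1).
#' @param plaid_eps overlap noise scale (default 0.1).
#' @param kappa_frac average number of interacting biclusters, as a fraction
#'   of `K` (default 0.3).
#' @param phi distribution of overlapping areas: column-overlap scaling
#'   relative to the row overlap (default 0.8).
#' @param seed integer seed; all draws come from the seeded generator.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(setting = "500x50",
                             coherency = c("constant", "order-preserving"),
                             n_items = 5L, noise_deviation = 0.5,
                             noisy_fraction = 0.02, missing_fraction = 0.02,
                             overlap = 0.2, plaid_f = c("sum", "product", "weighted"),
                             plaid_nu = 1, plaid_eps = 0.1, kappa_frac = 0.3,
                             phi = 0.8, seed = NULL) {
  coherency <- match.arg(coherency)
  plaid_f <- match.arg(plaid_f)
  if (!setting %in% names(SYNTH_SETTINGS)) {
    stop("unknown setting '", setting, "'; use one of ",
         paste(names(SYNTH_SETTINGS), collapse = ", "))
  }
  s <- SYNTH_SETTINGS[[setting]]
  mu <- if (coherency == "constant") 1L else 2L
  cfg <- list(
    setting = setting, coherency = coherency, mu = mu,
    n_rows = s$n_rows, n_cols = s$n_cols,
    k = as.integer(round(s$base_k / mu)),
    row_range = as.integer(mu * s$rows), col_range = as.integer(mu * s$cols),
    n_items = as.integer(n_items), noise_deviation = noise_deviation,
    noisy_fraction = noisy_fraction, missing_fraction = missing_fraction,
    overlap = overlap, plaid_f = plaid_f, plaid_nu = plaid_nu,
    plaid_eps = plaid_eps, kappa_frac = kappa_frac, phi = phi, seed = seed
  )
  if (cfg$row_range[2L] > cfg$n_rows || cfg$col_range[2L] > cfg$n_cols) {
    stop("bicluster size range exceeds matrix dimensions")
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic matrix with planted biclusters
#'
#' Background cells are i.i.d. uniform on `[0, 1]`; `K` biclusters are
#' planted with sizes drawn uniformly from the configured ranges. Constant
#' biclusters share a per-column expected value; order-preserving biclusters
#' share a column ordering. With `overlap > 0`, `round(kappa_frac * K)`
#' bicluster pairs are forced to interact (sharing a `theta` fraction of rows
#' and `theta * phi` of columns) and their shared cells are combined with the
#' plaid function; noise deviations and missing values are then imputed on
#' the configured fractions of cells.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `matrix` (numeric, dimnames `x1..xn` / `y1..ym`) and
#'   `truth` (class `ground_truth`: planted biclusters with rows, cols,
#'   pattern and coherency).
#' @export
generate_synthetic <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_rows; m <- cfg$n_cols; K <- cfg$k
  row_ids <- paste0("x", seq_len(n)); col_ids <- paste0("y", seq_len(m))
  mat <- matrix(runif(n * m), n, m, dimnames = list(row_ids, col_ids))
  painted <- matrix(0L, n, m)

  sizes_r <- sample(seq.int(cfg$row_range[1L], cfg$row_range[2L]), K, replace = TRUE)
  sizes_c <- sample(seq.int(cfg$col_range[1L], cfg$col_range[2L]), K, replace = TRUE)

  # disjoint column blocks keep theta = 0 exactly non-overlapping; overlap is
  # then induced explicitly for the interacting pairs
  if (sum(sizes_c) <= m) {
    pool <- sample(col_ids)
    offsets <- cumsum(c(0L, sizes_c[-K]))
    col_sets <- lapply(seq_len(K), function(k) pool[offsets[k] + seq_len(sizes_c[k])])
    row_sets <- lapply(sizes_r, function(sz) sample(row_ids, sz))
  } else if (sum(sizes_r) <= n) {
    pool <- sample(row_ids)
    offsets <- cumsum(c(0L, sizes_r[-K]))
    row_sets <- lapply(seq_len(K), function(k) pool[offsets[k] + seq_len(sizes_r[k])])
    col_sets <- lapply(sizes_c, function(sz) sample(col_ids, sz))
  } else {
    stop("infeasible planting: biclusters cannot be made disjoint in either dimension")
  }

  if (cfg$overlap > 0 && K >= 2L) {
    n_pairs <- min(K - 1L, max(0L, as.integer(round(cfg$kappa_frac * K))))
    for (p in seq_len(n_pairs)) {
      a <- p; b <- p + 1L
      n_share_r <- max(1L, floor(cfg$overlap * length(row_sets[[b]])))
      n_share_c <- max(1L, floor(cfg$overlap * cfg$phi * length(col_sets[[b]])))
      row_sets[[b]][seq_len(n_share_r)] <- head(row_sets[[a]], n_share_r)
      col_sets[[b]][seq_len(n_share_c)] <- head(col_sets[[a]], n_share_c)
      row_sets[[b]] <- unique(row_sets[[b]])
      col_sets[[b]] <- unique(col_sets[[b]])
    }
  }

  truth <- vector("list", K)
  for (k in seq_len(K)) {
    rows <- row_sets[[k]]; cols <- col_sets[[k]]
    if (cfg$coherency == "constant") {
      kj <- runif(length(cols))
      contrib <- matrix(rep(kj, each = length(rows)), length(rows), length(cols))
      pattern <- kj
    } else {
      ord <- sample(cols)  # shared ordering, ascending
      contrib <- t(vapply(seq_along(rows), function(i) {
        v <- sort(runif(length(cols)))
        v[match(cols, ord)]
      }, numeric(length(cols))))
      pattern <- ord
    }
    old <- mat[rows, cols, drop = FALSE]
    layer <- painted[match(rows, row_ids), match(cols, col_ids), drop = FALSE]
    fresh <- layer == 0L
    combined <- contrib
    if (any(!fresh)) {
      combined[!fresh] <- switch(cfg$plaid_f,
        sum = old[!fresh] + cfg$plaid_nu * contrib[!fresh],
        product = old[!fresh] * (contrib[!fresh]^cfg$plaid_nu),
        weighted = (old[!fresh] + cfg$plaid_nu * contrib[!fresh]) / (1 + cfg$plaid_nu))
      combined[!fresh] <- combined[!fresh] +
        cfg$plaid_eps * rnorm(sum(!fresh), sd = 1 / cfg$n_items)
    }
    mat[rows, cols] <- combined
    painted[match(rows, row_ids), match(cols, col_ids)] <-
      layer + 1L
    col_ord <- order(cols)
    truth[[k]] <- list(rows = rows, cols = cols[col_ord],
                       pattern = if (cfg$coherency == "constant") pattern[col_ord] else pattern,
                       coherency = cfg$coherency)
  }

  amp <- max(mat) - min(mat)
  delta <- amp / cfg$n_items
  if (cfg$noisy_fraction > 0 && cfg$noise_deviation > 0) {
    idx <- sample(n * m, round(cfg$noisy_fraction * n * m))
    d <- cfg$noise_deviation * delta
    mat[idx] <- mat[idx] + runif(length(idx), -d, d)
  }
  if (cfg$missing_fraction > 0) {
    idx <- sample(n * m, round(cfg$missing_fraction * n * m))
    mat[idx] <- NA_real_
  }
  structure(
    list(matrix = mat,
         truth = structure(list(biclusters = truth, config = cfg, row_ids = row_ids),
                           class = "ground_truth")),
    class = "synthetic_instance"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d planted biclusters (%s)\n",
              length(x$biclusters), x$config$coherency))
  invisible(x)
}

#' Annotate a synthetic ground truth
#'
#' Every row receives a Normal number of background annotations (clipped at
#' zero); each planted bicluster additionally receives a dedicated term shared
#' by a Normal fraction of its rows (the functional-consistency parameter).
#' Background terms are drawn from a universe sized so each term lands on
#' about `per_term_rows` rows.
#'
#' @param gt a `ground_truth` from [generate_synthetic()].
#' @param per_row mean and sd of annotations per row (default `c(4, 2)`).
#' @param per_term_rows mean and sd of rows per background term
#'   (default `c(100, 10)`).
#' @param consistency mean and sd of the shared-annotation fraction per
#'   planted bicluster (default `c(0.85, 0.10)`, clipped to `[0, 1]`).
#' @param seed optional seed.
#' @return list with `annotations` (named list row -> terms) and
#'   `bicluster_terms` (dedicated term per planted bicluster).
#' @export
annotate_truth <- function(gt, per_row = c(4, 2), per_term_rows = c(100, 10),
                           consistency = c(0.85, 0.10), seed = NULL) {
  stopifnot(inherits(gt, "ground_truth"), per_row[1L] > 0, per_term_rows[1L] > 0)
  if (!is.null(seed)) set.seed(seed)
  rows <- gt$row_ids
  n_terms <- max(1L, as.integer(round(length(rows) * per_row[1L] / per_term_rows[1L])))
  terms <- paste0("BG", seq_len(n_terms))
  ann <- setNames(vector("list", length(rows)), rows)
  for (r in rows) {
    k <- max(0L, as.integer(round(rnorm(1, per_row[1L], per_row[2L]))))
    ann[[r]] <- if (k > 0L) sample(terms, min(k, n_terms)) else character(0)
  }
  bic_terms <- character(length(gt$biclusters))
  for (k in seq_along(gt$biclusters)) {
    term <- paste0("B", k)
    bic_terms[k] <- term
    share <- min(1, max(0, rnorm(1, consistency[1L], consistency[2L])))
    members <- gt$biclusters[[k]]$rows
    chosen <- sample(members, max(1L, round(share * length(members))))
    for (r in chosen) ann[[r]] <- c(ann[[r]], term)
  }
  list(annotations = ann, bicluster_terms = bic_terms)
}

#' Jaccard-based match scores between found and hidden biclusters
#'
#' `recoverability` is the mean over hidden biclusters of the best cell-set
#' Jaccard against the found solution (how well the planted structure was
#' recovered); `spuriousness_complement` is the mean over found biclusters of
#' the best Jaccard against the hidden set (1 means nothing spurious).
#'
#' @param found a [biclustering_solution()] or list of biclusters.
#' @param hidden a `ground_truth` or list of biclusters.
#' @return list with `recoverability` and `spuriousness_complement`, both in
#'   `[0, 1]`.
#' @export
match_score <- function(found, hidden) {
  if (inherits(found, "biclustering_solution")) found <- found$biclusters
  if (inherits(hidden, "ground_truth")) hidden <- hidden$biclusters
  if (!length(found) || !length(hidden)) {
    warning("empty bicluster set; match scores are 0")
    return(list(recoverability = 0, spuriousness_complement = 0))
  }
  jmat <- matrix(0, length(hidden), length(found))
  for (i in seq_along(hidden)) {
    for (j in seq_along(found)) {
      jmat[i, j] <- cell_jaccard(hidden[[i]], found[[j]])
    }
  }
  list(recoverability = mean(apply(jmat, 1L, max)),
       spuriousness_complement = mean(apply(jmat, 2L, max)))
}
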