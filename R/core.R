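#' Pipeline configuration
#'
#' Defaults follow the method's data-independent parameterization: zero-mean
#' row normalization, overall Gaussian discretization with a `{3,5,7}`-symbol
#' sweep (constant/additive/symmetric) or `ceiling(m/4)` symbols
#' (order-preserving), multi-item assignments, support starting at 0.8 and
#' decreasing by 10% (relative) per round until 50 dissimilar biclusters or
#' 10% matrix coverage, merging above 0.7 cell-Jaccard, filtering of
#' insignificant biclusters and of biclusters above 0.6 cell-Jaccard against
#' a larger one.
#'
#' @param coherency one of `"constant"`, `"additive"`, `"symmetric"`,
#'   `"order-preserving"`, `"all"`.
#' @param n_items alphabet sizes swept for non-order-preserving coherencies.
#' @param method discretization method.
#' @param alpha_multi multi-item boundary fraction (default 0.25: the dual
#'   band spans the bin, so a module whose expected value sits near a
#'   cutpoint is never split across symbols).
#' @param theta_start,theta_step initial support fraction and relative
#'   per-round decrease.
#' @param stop_biclusters,stop_coverage stop criteria (whichever first).
#' @param min_cols minimum pattern length (columns per bicluster); default 5.
#'   Narrow patterns in matrices with tens to hundreds of columns are
#'   dominated by spurious cross-module conjunctions, so they are excluded by
#'   default (configurable down to 2).
#' @param merge_overlap,filter_overlap cell-Jaccard thresholds.
#' @param significance_alpha level for the Bonferroni-corrected binomial-tail
#'   filter.
#' @param noise_tolerance tolerance used by extension/reduction.
#' @param removed_symbols symbols deleted as uninformative before mining.
#' @param normalize apply zero-mean row normalization.
#' @param costs cost table for constraint aggregates.
#' @param tau pruning periodicity forwarded to the miners.
#' @param max_rounds cap on support-decrease rounds (25 rounds from 0.8 ends
#'   near 6% support, below which module membership is indistinguishable from
#'   background co-occurrence).
#' @param mine_node_budget saturation guard: when one alphabet's mining round
#'   visits more pattern nodes than this, its pattern space has dissolved into
#'   background noise at that support level; the round is discarded and the
#'   support descent for that alphabet stops (coarse alphabets saturate before
#'   fine ones).
#' @param seed optional integer seed recorded in provenance and set before
#'   mining.
#' @return list of class `bic2pam_config`.
#' @export
bic2pam_config <- function(coherency = "constant", n_items = c(3L, 5L, 7L),
                           method = "gaussian_quantile", alpha_multi = 0.25,
                           theta_start = 0.80, theta_step = 0.10,
                           stop_biclusters = 50L, stop_coverage = 0.10,
                           min_cols = 5L, merge_overlap = 0.70,
                           filter_overlap = 0.60, significance_alpha = 0.01,
                           noise_tolerance = 0.1, removed_symbols = NULL,
                           normalize = TRUE, costs = NULL, tau = 1L,
                           max_rounds = 25L, mine_node_budget = 100000L,
                           seed = NULL) {
  stopifnot(theta_step > 0, theta_step < theta_start, theta_start <= 1,
            stop_coverage > 0, stop_coverage <= 1, merge_overlap > 0, merge_overlap <= 1,
            significance_alpha > 0, significance_alpha < 1,
            noise_tolerance >= 0, noise_tolerance <= 1)
  coherency <- match.arg(coherency,
                         c("constant", "additive", "symmetric", "order-preserving", "all"))
  structure(as.list(environment()), class = "bic2pam_config")
}

#' View a bicluster as a full-pattern (for constraint evaluation)
#' @param b a [bicluster()].
#' @return a [full_pattern()].
#' @export
as_full_pattern <- function(b) {
  stopifnot(inherits(b, "bicluster"))
  if (b$coherency == "order-preserving") {
    return(full_pattern(items = c(b$cols, attr(b, "annotations")), rows = b$rows,
                        cols = b$cols, symbols = b$pattern, groups = attr(b, "groups")))
  }
  full_pattern(items = c(make_item(b$cols, b$pattern), attr(b, "annotations")),
               rows = b$rows, cols = b$cols, symbols = as.character(b$pattern))
}

#' Map a full-pattern to a bicluster
#'
#' Rows are the coverage, columns the pattern's indexes and the bicluster
#' pattern the original symbols. Additive row factors are attached; mirrored
#' transaction ids from symmetric mining fold back to their source rows,
#' keeping the first-seen orientation per row.
#'
#' @param fp a [full_pattern()].
#' @param coherency coherency tag of the mined database.
#' @param factors named additive `gamma_i` (from the itemset database).
#' @param mirror_map named map mirrored-id -> source row id.
#' @return a [bicluster()], or `NULL` if fewer than 2 columns remain.
#' @export
pattern_to_bicluster <- function(fp, coherency = "constant", factors = NULL,
                                 mirror_map = NULL) {
  if (coherency == "order-preserving") {
    b <- bicluster(rows = fp$rows, cols = fp$cols, pattern = fp$symbols,
                   coherency = "order-preserving")
    attr(b, "groups") <- fp$groups
    return(b)
  }
  value_items <- fp$items[!is_annotation_item(fp$items)]
  parts <- split_items(value_items)
  ann_items <- fp$items[is_annotation_item(fp$items)]
  # multi-item patterns may carry two symbols for one column: keep the symbol
  # nearest zero (deterministic)
  sym_num <- suppressWarnings(as.numeric(parts$symbol))
  ord <- order(parts$col, abs(sym_num), sym_num)
  keep <- ord[!duplicated(parts$col[ord])]
  cols <- parts$col[keep]
  pattern <- sym_num[keep]
  o <- order(cols)
  cols <- cols[o]; pattern <- pattern[o]

  rows <- fp$rows
  signs <- NULL
  if (coherency == "symmetric" && !is.null(mirror_map)) {
    src <- ifelse(rows %in% names(mirror_map), mirror_map[rows], rows)
    sgn <- ifelse(rows %in% names(mirror_map), -1, 1)
    first <- !duplicated(src)
    rows <- src[first]
    signs <- setNames(sgn[first], rows)
  }
  row_factors <- if (coherency == "additive" && !is.null(factors)) {
    factors[intersect(rows, names(factors))]
  }
  if (length(cols) < 2L) return(NULL)
  b <- bicluster(rows = unique(rows), cols = cols, pattern = pattern,
                 coherency = if (coherency == "symmetric") "symmetric"
                             else if (coherency == "additive") "additive" else "constant",
                 row_factors = row_factors, signs = signs)
  if (length(ann_items)) attr(b, "annotations") <- ann_items
  b
}

#' Merge highly overlapping biclusters
#'
#' Pairs with cell-set Jaccard above `overlap` are merged (union of rows and
#' of columns), repeating to a fixpoint; the merged pattern is recomputed as
#' the per-column modal symbol over the merged rows (ties broken toward the
#' symbol nearest zero).
#'
#' @param bics list of biclusters.
#' @param overlap Jaccard threshold in `(0, 1]`.
#' @param disc optional `disc_matrix` (or named list of them, looked up by the
#'   biclusters' `"space"` attribute) for pattern recomputation.
#' @return list of biclusters.
#' @export
merge_biclusters <- function(bics, overlap = 0.70, disc = NULL) {
  stopifnot(overlap > 0, overlap <= 1)
  repeat {
    n <- length(bics)
    if (n < 2L) return(bics)
    # integer-coded row/col sets make the pairwise Jaccard sweep cheap
    row_ids <- unique(unlist(lapply(bics, `[[`, "rows")))
    col_ids <- unique(unlist(lapply(bics, `[[`, "cols")))
    rset <- lapply(bics, function(b) match(b$rows, row_ids))
    cset <- lapply(bics, function(b) match(b$cols, col_ids))
    alive <- rep(TRUE, n)
    merged_any <- FALSE
    for (i in seq_len(n - 1L)) {
      if (!alive[i]) next
      for (j in seq.int(i + 1L, n)) {
        if (!alive[j]) next
        if (bics[[i]]$coherency != bics[[j]]$coherency) next
        ri <- length(intersect(rset[[i]], rset[[j]]))
        if (ri == 0L) next
        ci <- length(intersect(cset[[i]], cset[[j]]))
        if (ci == 0L) next
        inter <- ri * ci
        union <- length(rset[[i]]) * length(cset[[i]]) +
          length(rset[[j]]) * length(cset[[j]]) - inter
        if (inter / union > overlap) {
          bics[[i]] <- merge_pair(bics[[i]], bics[[j]], disc_for(bics[[i]], disc))
          rset[[i]] <- union(rset[[i]], rset[[j]])
          cset[[i]] <- union(cset[[i]], cset[[j]])
          alive[j] <- FALSE
          merged_any <- TRUE
        }
      }
    }
    bics <- bics[alive]
    if (!merged_any) return(bics)
  }
}

disc_for <- function(b, disc) {
  if (is.null(disc) || inherits(disc, "disc_matrix")) return(disc)
  if (!length(disc)) return(NULL)
  disc[[attr(b, "space") %||% length(disc)]] %||% disc[[length(disc)]]
}

merge_pair <- function(a, b, disc = NULL) {
  rows <- union(a$rows, b$rows)
  cols <- sort(union(a$cols, b$cols))
  if (a$coherency == "order-preserving") {
    out <- bicluster(rows, a$cols, a$pattern, coherency = "order-preserving")
    attr(out, "groups") <- attr(a, "groups")
  } else {
    pattern <- if (!is.null(disc)) {
      vapply(cols, function(cl) modal_symbol(disc$primary[rows, cl]), numeric(1))
    } else {
      # fall back to a's pattern where defined, b's elsewhere
      p <- setNames(rep(NA_real_, length(cols)), cols)
      p[b$cols] <- b$pattern; p[a$cols] <- a$pattern
      unname(p)
    }
    out <- bicluster(rows, cols, unname(pattern), coherency = a$coherency,
                     row_factors = c(a$row_factors,
                                     b$row_factors[setdiff(names(b$row_factors),
                                                           names(a$row_factors))]),
                     signs = c(a$signs, b$signs[setdiff(names(b$signs), names(a$signs))]))
  }
  ann <- intersect(attr(a, "annotations") %||% character(0),
                   attr(b, "annotations") %||% character(0))
  if (length(ann)) attr(out, "annotations") <- ann
  attr(out, "space") <- attr(a, "space")
  out
}

modal_symbol <- function(v) {
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  tab <- table(v)
  best <- as.numeric(names(tab)[tab == max(tab)])
  best[order(abs(best), best)][1L]
}

# per-row fraction of pattern columns whose symbols include the expected one,
# vectorized for the constant model
match_fractions <- function(b, disc, rows = rownames(disc$primary), ann = NULL) {
  prim <- disc$primary[rows, b$cols, drop = FALSE]
  sec <- disc$secondary[rows, b$cols, drop = FALSE]
  target <- matrix(b$pattern, nrow(prim), ncol(prim), byrow = TRUE)
  frac_for <- function(tgt) {
    hit <- (!is.na(prim) & prim == tgt) | (!is.na(sec) & sec == tgt)
    rowMeans(hit)
  }
  fr <- switch(b$coherency,
    constant = frac_for(target),
    symmetric = pmax(frac_for(target), frac_for(-target)),
    additive = {
      vapply(seq_len(nrow(prim)), function(i) {
        d <- prim[i, ] - b$pattern
        g <- modal_symbol(d)
        if (is.na(g)) return(0)
        hit <- (!is.na(prim[i, ]) & prim[i, ] == b$pattern + g) |
          (!is.na(sec[i, ]) & sec[i, ] == b$pattern + g)
        mean(hit)
      }, numeric(1))
    },
    rep(0, nrow(prim)))
  names(fr) <- rows
  ann_items <- attr(b, "annotations")
  if (!is.null(ann_items) && length(ann_items)) {
    terms <- sub(paste0("^", ANNOT_PREFIX), "", ann_items)
    has <- vapply(rows, function(r) all(terms %in% (ann[[r]] %||% character(0))), logical(1))
    fr[!has] <- 0
  }
  fr
}

#' Extend a bicluster with compatible rows and columns
#'
#' Adds rows (then columns) whose cells match the pattern in at least
#' `1 - tolerance` of positions; with tolerance 0 only perfect matches are
#' added. Rows must also carry the bicluster's annotation terms, if any.
#'
#' @param b a bicluster (constant/additive/symmetric; order-preserving
#'   biclusters are returned unchanged).
#' @param disc the `disc_matrix` the bicluster was mined from.
#' @param tolerance noise tolerance in `[0, 1]`.
#' @param ann optional annotation map.
#' @return extended bicluster.
#' @export
extend_bicluster <- function(b, disc, tolerance = 0.1, ann = NULL) {
  stopifnot(tolerance >= 0, tolerance <= 1)
  if (b$coherency == "order-preserving") return(b)
  candidates <- setdiff(rownames(disc$primary), b$rows)
  if (length(candidates)) {
    fr <- match_fractions(b, disc, candidates, ann)
    add <- candidates[fr >= 1 - tolerance]
    if (length(add)) b$rows <- c(b$rows, add)
  }
  candidates <- setdiff(colnames(disc$primary), b$cols)
  for (cl in candidates) {
    sym <- modal_symbol(disc$primary[b$rows, cl])
    if (is.na(sym)) next
    if (col_match_share(disc, b$rows, cl, sym) >= 1 - tolerance) {
      ord <- order(c(b$cols, cl))
      b$pattern <- c(b$pattern, sym)[ord]
      b$cols <- c(b$cols, cl)[ord]
    }
  }
  b
}

# share of rows whose symbols (primary or multi-item secondary) include sym
col_match_share <- function(disc, rows, cl, sym) {
  p <- disc$primary[rows, cl]
  s <- disc$secondary[rows, cl]
  obs <- !is.na(p)
  if (!any(obs)) return(0)
  sum((obs & p == sym) | (!is.na(s) & s == sym)) / sum(obs)
}

#' Drop poorly matching rows and columns from a bicluster
#'
#' Removes rows whose cells match the pattern in fewer than `1 - tolerance`
#' of positions, then columns supported by fewer than `1 - tolerance` of the
#' remaining rows.
#'
#' @inheritParams extend_bicluster
#' @return reduced bicluster, or `NULL` if it degenerates.
#' @export
reduce_bicluster <- function(b, disc, tolerance = 0.1, ann = NULL) {
  stopifnot(tolerance >= 0, tolerance <= 1)
  if (b$coherency == "order-preserving") return(b)
  fr <- match_fractions(b, disc, b$rows, ann)
  b$rows <- b$rows[fr >= 1 - tolerance]
  if (!length(b$rows)) return(NULL)
  keep <- vapply(seq_along(b$cols), function(k) {
    col_match_share(disc, b$rows, b$cols[k], b$pattern[k]) >= 1 - tolerance
  }, logical(1))
  if (sum(keep) < 2L) return(NULL)
  b$cols <- b$cols[keep]; b$pattern <- b$pattern[keep]
  b
}

#' Binomial-tail significance of a bicluster
#'
#' Under a column-independence null, the probability that a random row
#' matches the pattern is `p = prod_j f_j(k_j)` with `f_j` the empirical
#' symbol frequency in column `j` (for additive/symmetric models, summed over
#' the allowed shifts/orientations; for order-preserving patterns
#' `p = 1/|J|!`, the probability of one ordering without ties). The p-value
#' is the upper binomial tail `P(Bin(n, p) >= |I|)`. Callers Bonferroni-adjust
#' by the number of candidate patterns.
#'
#' @param b a bicluster.
#' @param disc the `disc_matrix` of the mined matrix.
#' @return p-value in `[0, 1]`.
#' @export
bicluster_significance <- function(b, disc) {
  n <- nrow(disc$primary)
  p_phi <- pattern_probability(b, disc)
  p_phi <- min(1, max(0, p_phi))
  pbinom(length(b$rows) - 1L, n, p_phi, lower.tail = FALSE)
}

pattern_probability <- function(b, disc) {
  if (b$coherency == "order-preserving") {
    return(1 / factorial(min(length(b$cols), 170L)))
  }
  freq <- function(pattern) {
    p <- 1
    for (k in seq_along(b$cols)) {
      col <- disc$primary[, b$cols[k]]
      sec <- disc$secondary[, b$cols[k]]
      hit <- (!is.na(col) & col == pattern[k]) | (!is.na(sec) & sec == pattern[k])
      denom <- sum(!is.na(col))
      p <- p * if (denom) sum(hit) / denom else 0
    }
    p
  }
  if (b$coherency == "constant") return(freq(b$pattern))
  if (b$coherency == "symmetric") return(min(1, freq(b$pattern) + freq(-b$pattern)))
  # additive: any shift of the anchored pattern matches
  alpha_rng <- range(disc$model$alphabet)
  shifts <- seq.int(alpha_rng[1L] - min(b$pattern), alpha_rng[2L] - max(b$pattern))
  min(1, sum(vapply(shifts, function(g) freq(b$pattern + g), numeric(1))))
}

#' Filter biclusters by significance and dissimilarity
#'
#' Drops biclusters whose Bonferroni-corrected p-value is at or above `alpha`
#' and any bicluster too similar to a strictly larger retained one; the
#' output is sorted by corrected p-value, then size. Similarity against a
#' larger bicluster is the larger of the cell-set Jaccard and the row-set
#' Jaccard: the row-set term suppresses column fragments of a module (a
#' sub-pattern over fewer columns whose coverage is the module's rows plus
#' background), which the cell-set Jaccard alone never reaches.
#'
#' @param bics list of biclusters with `p_value` set to the uncorrected
#'   binomial tail.
#' @param filter_overlap Jaccard threshold.
#' @param alpha significance level.
#' @param n_tests Bonferroni correction factor (defaults to `length(bics)`).
#' @return filtered, sorted list of biclusters with corrected `p_value`.
#' @export
filter_biclusters <- function(bics, filter_overlap = 0.60, alpha = 0.01,
                              n_tests = length(bics)) {
  stopifnot(alpha > 0, alpha < 1)
  if (!length(bics)) return(bics)
  for (i in seq_along(bics)) {
    bics[[i]]$p_value <- min(1, bics[[i]]$p_value * max(1L, n_tests))
  }
  keep <- vapply(bics, function(b) b$p_value < alpha, logical(1))
  if (!any(keep)) {
    bic_log("info", "all ", length(bics), " biclusters filtered as insignificant")
    return(list())
  }
  bics <- bics[keep]
  sizes <- vapply(bics, n_cells, numeric(1))
  ord <- order(vapply(bics, function(b) b$p_value, numeric(1)), -sizes)
  bics <- bics[ord]
  sizes <- sizes[ord]
  retained <- list()
  retained_sizes <- numeric(0)
  for (k in seq_along(bics)) {
    dominated <- FALSE
    for (r in seq_along(retained)) {
      if (retained_sizes[r] > sizes[k] &&
          cell_jaccard(bics[[k]], retained[[r]]) > filter_overlap) {
        dominated <- TRUE
        break
      }
      # row-set redundancy: fragments and symbol variants of a retained
      # module share most of its rows (ties resolved by the p-value order)
      if (retained_sizes[r] >= sizes[k] &&
          row_jaccard(bics[[k]], retained[[r]]) > filter_overlap) {
        dominated <- TRUE
        break
      }
    }
    if (!dominated) {
      retained[[length(retained) + 1L]] <- bics[[k]]
      retained_sizes <- c(retained_sizes, sizes[k])
    }
  }
  retained
}

coherencies_in_scope <- function(coherency) {
  if (coherency == "all") c("constant", "symmetric", "additive", "order-preserving")
  else coherency
}

#' Run the full constraint-guided biclustering pipeline
#'
#' Preprocesses the input (normalization, discretization with multi-item
#' assignments, mapping to itemset/sequence databases, optional annotations
#' and uninformative-symbol removal), instantiates and soundness-checks the
#' constraints, mines closed full-patterns with a decreasing support
#' threshold until the stop criterion, maps patterns to biclusters and
#' postprocesses them (merge, extend, reduce, significance filter).
#'
#' Candidate biclusters whose uncorrected binomial-tail p-value already
#' exceeds the significance level are dropped on sight — they could never
#' survive the (stricter) Bonferroni-corrected filter, so this loses nothing
#' while keeping low-support rounds tractable.
#'
#' @param x numeric matrix (rows x columns) or a `bic_network`.
#' @param config a [bic2pam_config()].
#' @param constraints list of [parse_constraint()] objects, a single
#'   constraint, or a path to a constraints file.
#' @param annotations named list of row annotations or a path to an
#'   annotation file.
#' @return a [biclustering_solution()]; attribute `"report"` carries stage
#'   timings, miner counters and the constraint audit.
#' @export
run_bic2pam <- function(x, config = bic2pam_config(), constraints = NULL,
                        annotations = NULL) {
  t0 <- proc.time()[["elapsed"]]
  if (inherits(x, "bic_network")) x <- network_to_matrix(x)
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.character(constraints)) constraints <- read_constraints(constraints)
  if (inherits(constraints, "bic_constraint")) constraints <- list(constraints)
  constraints <- constraints %||% list()
  if (is.character(annotations)) annotations <- read_annotations(annotations)

  m <- if (isTRUE(config$normalize)) normalize_rows(x) else x
  report <- list(counters = list(), stages = list(), constraint_audit = list())
  all_bics <- list()
  seen_keys <- new.env(parent = emptyenv())
  n_candidates <- 0L
  discs <- list()
  pp_cache <- new.env(parent = emptyenv())

  for (coh in coherencies_in_scope(config$coherency)) {
    if (coh == "order-preserving") {
      m_op <- m
      if (!is.null(config$removed_symbols)) {
        model <- fit_discretization(m, max(config$n_items), config$method)
        sym <- discretize(m, model, alpha = 0)$primary
        m_op[sym %in% as.numeric(config$removed_symbols)] <- NA
      }
      db <- to_sequence_db(m_op)
      if (!is.null(annotations)) db <- append_annotations(db, annotations)
      dbs <- list(op = list(db = db, disc = NULL, space = "op"))
    } else {
      dbs <- lapply(config$n_items, function(ni) {
        model <- fit_discretization(m, ni, config$method)
        disc <- discretize(m, model, alpha = config$alpha_multi)
        db <- to_itemset_db(disc, coh)
        if (!is.null(annotations)) db <- append_annotations(db, annotations)
        if (!is.null(config$removed_symbols)) {
          db <- remove_uninformative(db, config$removed_symbols)
        }
        list(db = db, disc = disc, space = paste0("n", ni))
      })
      names(dbs) <- vapply(dbs, `[[`, character(1), "space")
      for (e in dbs) discs[[e$space]] <- e$disc
    }
    # soundness check + translation of pattern/col constraints into item space
    item_constraints <- list()
    seq_cs <- NULL
    if (length(constraints)) {
      if (coh == "order-preserving") {
        seq_cs <- constraints_to_seq_cs(constraints, dbs[[1L]]$db, m)
      } else {
        alphabet <- dbs[[1L]]$db$alphabet
        item_constraints <- lapply(constraints, function(cst) {
          tc <- translate_constraint(cst, alphabet, colnames(m))
          check_constraint_bound(tc, dbs[[length(dbs)]]$db)
          tc
        })
      }
    }

    theta <- config$theta_start
    round <- 0L
    active <- setNames(rep(TRUE, length(dbs)), names(dbs))
    solution_bics <- list()
    repeat {
      round <- round + 1L
      new_any <- FALSE
      for (sp in names(dbs)[active]) {
        entry <- dbs[[sp]]
        n_tx <- if (coh == "order-preserving") length(entry$db$sequences) else length(entry$db$tx)
        if (ceiling(theta * n_tx) < 2L) { active[sp] <- FALSE; next }
        if (coh == "order-preserving") {
          pats <- mine_sequential_closed(entry$db, theta1 = theta,
                                         theta2 = config$min_cols, cs = seq_cs,
                                         max_nodes = config$mine_node_budget)
        } else {
          params <- miner_params(theta1 = theta, theta2 = config$min_cols,
                                 constraints = item_constraints,
                                 costs = config$costs, tau = config$tau,
                                 max_nodes = config$mine_node_budget)
          pats <- mine_closed(entry$db, params)
        }
        report$counters[[length(report$counters) + 1L]] <-
          c(list(coherency = coh, space = sp, theta = theta,
                 n_patterns = length(pats)), attr(pats, "counters"))
        if (isTRUE(attr(pats, "truncated"))) {
          active[sp] <- FALSE
          bic_log("info", sp, " saturated at theta=", signif(theta, 3))
          next
        }
        for (fp in pats) {
          b <- pattern_to_bicluster(fp, coh, factors = entry$db$row_factors,
                                    mirror_map = entry$db$mirror_map)
          if (is.null(b)) next
          key <- paste(coh, paste(sort(b$rows), collapse = ","),
                       paste(b$cols, collapse = ","),
                       paste(b$pattern, collapse = ","), sep = "|")
          if (!is.null(seen_keys[[key]])) next
          seen_keys[[key]] <- TRUE
          n_candidates <- n_candidates + 1L
          attr(b, "space") <- sp
          if (!is.null(entry$disc)) {
            if (bicluster_significance(b, entry$disc) >= config$significance_alpha) next
          }
          all_bics[[length(all_bics) + 1L]] <- b
          new_any <- TRUE
        }
      }
      if (new_any || round == 1L) {
        solution_bics <- postprocess_biclusters(all_bics, config, discs, annotations,
                                                n_tests = n_candidates, cache = pp_cache)
      }
      enough <- length(solution_bics) >= config$stop_biclusters ||
        solution_coverage(solution_bics, m) >= config$stop_coverage
      theta <- theta * (1 - config$theta_step)
      if (enough || round >= config$max_rounds || !any(active)) break
    }
  }

  solution_bics <- postprocess_biclusters(all_bics, config, discs, annotations,
                                          n_tests = n_candidates, cache = pp_cache)
  # enforcement + audit: postprocessing (extension, merging, consensus) may
  # alter patterns, so every returned bicluster is re-checked with evaluate()
  # and offenders dropped
  if (length(constraints)) {
    alphabet <- if (length(discs)) discs[[length(discs)]]$model$alphabet else integer(0)
    translated <- lapply(constraints, function(cst) {
      tryCatch(translate_constraint(cst, alphabet, colnames(m)),
               error = function(e) cst)
    })
    ok <- vapply(solution_bics, function(b) {
      all(vapply(translated, function(tc) {
        !isFALSE(tryCatch(evaluate_constraint(tc, b, config$costs),
                          error = function(e) NA))
      }, logical(1)))
    }, logical(1))
    if (any(!ok)) {
      bic_log("info", sum(!ok), " postprocessed bicluster(s) dropped by constraint re-check")
      solution_bics <- solution_bics[ok]
    }
    report$constraint_audit <- lapply(translated, function(tc) {
      pass <- all(vapply(solution_bics, function(b) {
        isTRUE(tryCatch(evaluate_constraint(tc, b, config$costs), error = function(e) NA))
      }, logical(1)))
      list(constraint = tc$text, all_pass = pass)
    })
  }
  report$stages$total_seconds <- proc.time()[["elapsed"]] - t0
  report$n_candidates <- n_candidates
  params <- config[setdiff(names(config), "costs")]
  params$constraints <- vapply(constraints, `[[`, character(1), "text")
  sol <- biclustering_solution(solution_bics, params = params, matrix = x)
  attr(sol, "report") <- report
  sol
}

postprocess_biclusters <- function(bics, config, discs, ann = NULL,
                                   n_tests = length(bics), cache = NULL) {
  if (!length(bics)) return(list())
  bics <- merge_biclusters(bics, overlap = config$merge_overlap, disc = discs)
  refine <- function(b) {
    disc <- disc_for(b, discs)
    if (is.null(disc)) { b$p_value <- 0; return(b) }
    key <- paste(attr(b, "space"), b$coherency, paste(b$rows, collapse = ","),
                 paste(b$cols, collapse = ","), paste(b$pattern, collapse = ","), sep = "|")
    if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
    out <- extend_bicluster(b, disc, tolerance = config$noise_tolerance, ann = ann)
    out <- reduce_bicluster(out, disc, tolerance = config$noise_tolerance, ann = ann)
    if (!is.null(out)) out$p_value <- bicluster_significance(out, disc)
    if (!is.null(cache)) cache[[key]] <- out
    out
  }
  bics <- Filter(Negate(is.null), lapply(bics, refine))
  bics <- merge_biclusters(bics, overlap = config$merge_overlap, disc = discs)
  bics <- Filter(Negate(is.null),
                 lapply(bics, consensus_rows, discs = discs,
                        tol = config$noise_tolerance, ann = ann))
  for (i in seq_along(bics)) {
    disc <- disc_for(bics[[i]], discs)
    bics[[i]]$p_value <- if (is.null(disc)) 0 else bicluster_significance(bics[[i]], disc)
  }
  filter_biclusters(bics, filter_overlap = config$filter_overlap,
                    alpha = config$significance_alpha, n_tests = max(n_tests, length(bics)))
}

# Consensus row reduction across the swept coherency strengths: a row stays
# only if it matches the module's per-alphabet pattern (modal symbol per
# column over the current rows) in at least half of the swept alphabets.
# Rows admitted solely by the coarsest alphabet's wide symbol bands fail the
# finer alphabets and drop out; true member rows pass nearly all.
consensus_rows <- function(b, discs, tol, ann = NULL) {
  if (is.null(b) || b$coherency == "order-preserving") return(b)
  if (inherits(discs, "disc_matrix") || length(discs) < 2L) return(b)
  discs <- Filter(Negate(is.null), discs)
  if (length(discs) < 2L) return(b)
  votes <- rep(0L, length(b$rows))
  for (disc in discs) {
    patd <- vapply(b$cols, function(cl) modal_symbol(disc$primary[b$rows, cl]),
                   numeric(1))
    if (anyNA(patd)) next
    bd <- b
    bd$pattern <- patd
    fr <- match_fractions(bd, disc, b$rows, ann)
    votes <- votes + (fr >= 1 - tol)
  }
  keep <- votes >= ceiling(length(discs) / 2)
  if (!any(keep)) return(NULL)
  b$rows <- b$rows[keep]
  b
}

constraints_to_seq_cs <- function(constraints, db, m) {
  required <- character(0); forbidden <- character(0)
  superpattern <- list(); regex <- NULL
  value_constraint <- NULL
  min_prec <- NULL; max_prec <- NULL
  for (cst in constraints) {
    check_constraint_bound(cst, db)
    for (a in cst$atoms) {
      if (a$kind == "regex") {
        regex <- a$tokens
      } else if (a$kind == "set" && a$target == "cols") {
        if (a$rel %in% c("contains", "superset")) required <- union(required, a$set)
        if (a$rel == "excludes") forbidden <- union(forbidden, a$set)
      } else if (a$kind == "aggregate" && a$target == "cols" && a$agg == "length") {
        if (a$cmp == ">=") min_prec <- a$value - 1
        if (a$cmp == "<=") max_prec <- a$value - 1
      } else if (a$kind == "aggregate" && a$target == "pattern") {
        value_constraint <- structure(list(atoms = list(a), ops = character(0), text = a$text),
                                      class = "bic_constraint")
      }
    }
  }
  seq_constraints(required = required, forbidden = forbidden,
                  min_precedences = min_prec, max_precedences = max_prec,
                  superpattern = superpattern, regex = regex,
                  value_constraint = value_constraint, value_matrix = m)
}
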