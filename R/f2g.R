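#' Construct a full-pattern
#'
#' A full-pattern couples a pattern with its coverage (supporting transaction
#' ids), its column indexes and the original symbol pattern, so biclusters can
#' be mapped directly from mined patterns.
#'
#' @param items character items (column-symbol concatenations, annotation
#'   items, or raw tokens); for sequential patterns, the flattened column ids.
#' @param rows coverage: supporting transaction/row ids.
#' @param cols column identifiers used by the pattern.
#' @param symbols original pattern aligned to `cols` (symbols, or the ordering
#'   relation for sequential patterns).
#' @param groups for sequential patterns, the ordered list of column itemsets.
#' @return object of class `full_pattern` with `support` and `length` fields.
#' @export
full_pattern <- function(items, rows, cols, symbols, groups = NULL) {
  structure(
    list(items = items, rows = rows, cols = cols, symbols = symbols,
         groups = groups, support = length(rows), length = length(items)),
    class = "full_pattern"
  )
}

#' @export
print.full_pattern <- function(x, ...) {
  lhs <- if (is.null(x$groups)) paste(x$items, collapse = ",") else
    paste(vapply(x$groups, function(g) {
      if (length(g) > 1L) paste0("(", paste(g, collapse = " "), ")") else g
    }, character(1)), collapse = " ")
  cat(sprintf("<full_pattern> {%s} support=%d coverage={%s}\n",
              lhs, x$support, paste(x$rows, collapse = ",")))
  invisible(x)
}

#' Mining parameters
#'
#' @param theta1 minimum support: an absolute count (>= 1) or a fraction of
#'   transactions (converted with `ceiling(theta1 * |D|)`).
#' @param theta2 minimum pattern length.
#' @param constraints list of [parse_constraint()] objects (implicit
#'   conjunction between list elements).
#' @param costs cost table; default maps each symbol to its numeric value.
#' @param tau pruning periodicity: data reductions are re-applied on every
#'   `tau`-th conditional projection (`tau = 1` reapplies always).
#' @param max_nodes search budget: the mining run stops once this many pattern
#'   nodes have been visited and the (incomplete) result is flagged with
#'   attribute `"truncated"`. `Inf` disables the budget.
#' @return object of class `miner_params`.
#' @export
miner_params <- function(theta1, theta2 = 2L, constraints = list(), costs = NULL,
                         tau = 1L, max_nodes = Inf) {
  stopifnot(theta1 > 0, theta2 >= 1L, tau >= 1L, max_nodes > 0)
  if (inherits(constraints, "bic_constraint")) constraints <- list(constraints)
  structure(list(theta1 = theta1, theta2 = as.integer(theta2),
                 constraints = constraints, costs = costs, tau = as.integer(tau),
                 max_nodes = max_nodes),
            class = "miner_params")
}

tx_full_pattern <- function(id, items) {
  parts <- split_items(items)
  ok <- !is.na(parts$symbol)
  full_pattern(items, rows = id, cols = unique(parts$col[!is.na(parts$col)]),
               symbols = parts$symbol[ok])
}

constraint_is_monotone <- function(constraint, costs = NULL) {
  all(vapply(constraint$atoms, function(a) "monotone" %in% classify_atom(a, costs),
             logical(1)))
}

# succinct equality bounds (min= / max=) are mu-eligible in conjunctions:
# a transaction without an item of the required cost can never satisfy them
mu_equality_ok <- function(atoms, items, costs) {
  vals <- item_costs(items, costs)
  vals <- vals[!is.na(vals)]
  for (a in atoms) {
    if (a$kind == "aggregate" && a$cmp == "=" && a$agg %in% c("min", "max")) {
      if (!any(abs(vals - a$value) < 1e-12)) return(FALSE)
    }
  }
  TRUE
}

#' Delete transactions that cannot satisfy a monotone constraint
#'
#' A transaction whose full item set fails a monotone constraint cannot
#' contain any satisfying sub-pattern (if the superset fails, every subset
#' fails), so it can be removed without changing the constrained result.
#'
#' @param db an `itemset_db`.
#' @param constraint a `bic_constraint` classified monotone (or a succinct
#'   min/max equality bound).
#' @param costs cost table.
#' @return reduced `itemset_db` with removal counts in attribute `"removed"`.
#' @export
mu_reduce <- function(db, constraint, costs = NULL) {
  stopifnot(inherits(db, "itemset_db"))
  monotone <- constraint_is_monotone(constraint, costs)
  eq_atoms <- Filter(function(a) a$kind == "aggregate" && a$cmp == "=" &&
                       a$agg %in% c("min", "max"), constraint$atoms)
  if (!monotone && !(length(eq_atoms) && !any(constraint$ops == "or"))) {
    attr(db, "removed") <- list(transactions = 0L)
    return(db)
  }
  keep <- vapply(names(db$tx), function(id) {
    items <- db$tx[[id]]
    ok <- TRUE
    if (monotone) ok <- evaluate_constraint(constraint, tx_full_pattern(id, items), costs)
    if (ok && length(eq_atoms)) ok <- mu_equality_ok(eq_atoms, items, costs)
    ok
  }, logical(1))
  removed <- sum(!keep)
  db$tx <- db$tx[keep]
  attr(db, "removed") <- list(transactions = removed)
  db
}

forbidden_item_test <- function(atoms, costs) {
  # returns function(items) -> logical vector, TRUE where the item conflicts
  bounds <- Filter(function(a) a$kind == "aggregate" && a$target %in% c("pattern", "items") &&
                     ((a$agg == "min" && a$cmp %in% c(">=", "=")) ||
                      (a$agg == "max" && a$cmp %in% c("<=", "="))), atoms)
  excludes <- Filter(function(a) a$kind == "set" && a$rel == "excludes" &&
                       a$target %in% c("pattern", "items"), atoms)
  if (!length(bounds) && !length(excludes)) return(NULL)
  function(items) {
    bad <- rep(FALSE, length(items))
    ann <- is_annotation_item(items)
    vals <- item_costs(items, costs)
    sym <- split_items(items)$symbol
    for (a in bounds) {
      if (a$agg == "min") bad <- bad | (!ann & !is.na(vals) & vals < a$value)
      if (a$agg == "max") bad <- bad | (!ann & !is.na(vals) & vals > a$value)
    }
    for (a in excludes) {
      if (a$target == "items") bad <- bad | items %in% a$set
      if (a$target == "pattern") bad <- bad | (!is.na(sym) & sym %in% a$set)
    }
    bad
  }
}

#' Delete single items that conflict with a constraint
#'
#' Items that would make any containing pattern violate a succinct value bound
#' (`min >=`, `max <=`, their equality forms, or an excludes set) are removed
#' from all transactions; transactions left shorter than the minimum pattern
#' length are dropped.
#'
#' @param db an `itemset_db`.
#' @param constraint a `bic_constraint` (conjunctions only are pushed).
#' @param costs cost table.
#' @param theta2 minimum pattern length used to drop emptied transactions.
#' @return reduced `itemset_db` with removal counts in attribute `"removed"`.
#' @export
alpha_reduce <- function(db, constraint, costs = NULL, theta2 = 1L) {
  stopifnot(inherits(db, "itemset_db"))
  if (any(constraint$ops == "or")) {
    attr(db, "removed") <- list(items = 0L, transactions = 0L)
    return(db)
  }
  test <- forbidden_item_test(constraint$atoms, costs)
  if (is.null(test)) {
    attr(db, "removed") <- list(items = 0L, transactions = 0L)
    return(db)
  }
  removed_items <- 0L
  for (id in names(db$tx)) {
    items <- db$tx[[id]]
    bad <- test(items)
    removed_items <- removed_items + sum(bad)
    db$tx[[id]] <- items[!bad]
  }
  short <- lengths(db$tx) < theta2
  db$tx <- db$tx[!short]
  attr(db, "removed") <- list(items = removed_items, transactions = sum(short))
  db
}

# ---- FP-tree ---------------------------------------------------------------

item_order <- function(supports, costs_by_item = NULL, convertible_dir = NULL) {
  items <- names(supports)
  if (!is.null(convertible_dir)) {
    # cost-sorted enumeration for convertible constraints: descending cost for
    # avg >= v (extensions can only lower the average), ascending for avg <= v
    cost <- costs_by_item[items]
    ord <- order(if (convertible_dir == ">=") -cost else cost, -supports, items)
  } else {
    ord <- order(-supports, items)
  }
  items[ord]
}

#' Build an FP-tree with transaction identifiers
#'
#' Infrequent items are dropped, the header is ordered by descending support
#' (ascending cost when a convertible constraint is active), transactions are
#' inserted as root paths in header order, and each transaction's id is stored
#' at its path terminal, ready to rise through conditional projections.
#'
#' @param db an `itemset_db`.
#' @param params a [miner_params()].
#' @return object of class `fp_tree`: `root` (environment), `header` (item ->
#'   list of nodes), `order` (items in header order), `supports`.
#' @export
build_fp_tree <- function(db, params) {
  theta1 <- resolve_theta1(params$theta1, length(db$tx))
  db <- push_succinct(db, params)
  supports <- table(unlist(lapply(db$tx, unique)))
  supports <- supports[supports >= theta1]
  conv <- convertible_direction(params)
  costs_by_item <- if (!is.null(conv)) {
    all_items <- names(supports)
    setNames(item_costs(all_items, params$costs), all_items)
  }
  ord <- item_order(setNames(as.integer(supports), names(supports)), costs_by_item, conv)
  rank <- setNames(seq_along(ord), ord)
  root <- new.env(parent = emptyenv())
  root$item <- NA_character_; root$count <- 0L; root$children <- list(); root$tids <- character(0)
  header <- setNames(vector("list", length(ord)), ord)
  for (id in names(db$tx)) {
    items <- intersect(ord, db$tx[[id]])
    items <- items[order(rank[items])]
    node <- root
    for (it in items) {
      child <- node$children[[it]]
      if (is.null(child)) {
        child <- new.env(parent = emptyenv())
        child$item <- it; child$count <- 0L; child$children <- list(); child$tids <- character(0)
        node$children[[it]] <- child
        header[[it]] <- c(header[[it]], child)
      }
      child$count <- child$count + 1L
      node <- child
    }
    if (!identical(node, root)) node$tids <- c(node$tids, id)
  }
  structure(list(root = root, header = header, order = ord,
                 supports = supports, n_tx = length(db$tx), theta1 = theta1),
            class = "fp_tree")
}

# compressed path database: one entry per terminal-annotated path
fp_tree_paths <- function(tree) {
  entries_items <- list()
  entries_tids <- list()
  walk <- function(node, path) {
    if (!is.na(node$item)) path <- c(path, node$item)
    if (length(node$tids)) {
      entries_items[[length(entries_items) + 1L]] <<- path
      entries_tids[[length(entries_tids) + 1L]] <<- node$tids
    }
    for (child in node$children) walk(child, path)
  }
  walk(tree$root, character(0))
  list(items = entries_items, tids = entries_tids)
}

resolve_theta1 <- function(theta1, n_tx) {
  if (theta1 < 1) max(1L, as.integer(ceiling(theta1 * n_tx))) else as.integer(theta1)
}

convertible_direction <- function(params) {
  for (cst in params$constraints) {
    if (any(cst$ops == "or")) next
    for (a in cst$atoms) {
      if (a$kind == "aggregate" && a$agg == "avg" && a$cmp %in% c(">=", "<=") &&
          a$target %in% c("pattern", "items")) {
        return(a$cmp)
      }
    }
  }
  NULL
}

# succinct / mu / alpha reductions applied before tree construction
push_succinct <- function(db, params, pattern_items = character(0), counter = NULL) {
  for (cst in params$constraints) {
    before <- length(db$tx)
    db2 <- mu_reduce(db, cst, params$costs)
    if (!is.null(counter)) {
      counter$removed_transactions <- counter$removed_transactions +
        attr(db2, "removed")$transactions
    }
    db <- db2
    db2 <- alpha_reduce(db, cst, params$costs, theta2 = max(1L, params$theta2 - length(pattern_items)))
    if (!is.null(counter)) {
      counter$removed_items <- counter$removed_items + attr(db2, "removed")$items
      counter$removed_transactions <- counter$removed_transactions +
        attr(db2, "removed")$transactions
    }
    db <- db2
  }
  db
}

# ---- closed constrained mining --------------------------------------------

#' Mine closed full-patterns under constraints
#'
#' FP-growth-style search over the transaction database, carrying transaction
#' identifiers through every conditional projection so each pattern's coverage
#' is known exactly. Constraints are pushed by class: succinct bounds remove
#' items and transactions up front (and on every `tau`-th projection),
#' anti-monotone constraints prune subtrees, convertible average bounds stop
#' growth under a cost-sorted enumeration, and monotone constraints, once
#' satisfied by a prefix, are not re-checked on its extensions.
#'
#' Closure is computed within the constraint-satisfying pattern space: a
#' satisfying pattern is reported iff no satisfying superset has identical
#' coverage; the minimum-length filter is applied after closure.
#'
#' @param db an `itemset_db`.
#' @param params a [miner_params()].
#' @return list of [full_pattern()]s; attribute `"counters"` holds the
#'   visited-node count and reduction tallies.
#' @export
mine_closed <- function(db, params) {
  counter <- new_counter()
  theta1 <- resolve_theta1(params$theta1, length(db$tx))
  db <- push_succinct(db, params, counter = counter)
  if (!length(db$tx)) return(finish_patterns(list(), params, counter))

  supports <- table(unlist(lapply(db$tx, unique)))
  supports <- supports[supports >= theta1]
  if (!length(supports)) return(finish_patterns(list(), params, counter))
  conv <- convertible_direction(params)
  costs_by_item <- setNames(
    suppressWarnings(tryCatch(item_costs(names(supports), params$costs),
                              error = function(e) rep(NA_real_, length(supports)))),
    names(supports))
  vocab <- item_order(setNames(as.integer(supports), names(supports)),
                      if (!is.null(conv)) costs_by_item, conv)
  rank_of <- setNames(seq_along(vocab), vocab)
  vocab_costs <- costs_by_item[vocab]
  vocab_parts <- split_items(vocab)
  vocab_ann <- is_annotation_item(vocab)
  tids <- names(db$tx)

  # pushable atoms from conjunctive constraints
  am_atoms <- list(); conv_atoms <- list(); mono_idx <- list()
  conj <- list()
  post_constraints <- list()
  for (cst in params$constraints) {
    if (any(cst$ops == "or")) { post_constraints <- c(post_constraints, list(cst)); next }
    conj <- c(conj, list(cst))
    for (a in cst$atoms) {
      props <- classify_atom(a, params$costs)
      if ("anti_monotone" %in% props) am_atoms <- c(am_atoms, list(a))
      if ("convertible_am" %in% props && !is.null(conv) && a$cmp == conv) {
        conv_atoms <- c(conv_atoms, list(a))
      }
    }
  }
  conj_atoms <- unlist(lapply(conj, `[[`, "atoms"), recursive = FALSE) %||% list()
  conj_monotone <- vapply(conj_atoms, function(a) "monotone" %in% classify_atom(a, params$costs),
                          logical(1))
  has_constraints <- length(conj_atoms) > 0L || length(post_constraints) > 0L

  # transaction-by-item incidence; conditional databases are row subsets, so
  # candidate supports per projection come from one colSums call
  V <- length(vocab)
  M <- matrix(FALSE, length(db$tx), V)
  for (i in seq_along(db$tx)) {
    ranks <- unname(rank_of[intersect(names(rank_of), db$tx[[i]])])
    if (length(ranks)) M[i, ranks] <- TRUE
  }
  # numeric copy: candidate supports per projection come from one BLAS matvec
  Mnum <- M + 0

  # results accumulate in a hashed environment: one O(1) insert per node
  res <- new.env(parent = emptyenv(), hash = TRUE)
  state <- new.env(parent = emptyenv())
  state$n <- 0L
  state$truncated <- FALSE

  fp_of <- function(ranks, cov_idx) {
    items <- vocab[ranks]
    ok <- !vocab_ann[ranks]
    full_pattern(items, rows = tids[cov_idx],
                 cols = unique(vocab_parts$col[ranks][!is.na(vocab_parts$col[ranks])]),
                 symbols = vocab_parts$symbol[ranks][ok & !is.na(vocab_parts$symbol[ranks])])
  }

  satisfies_all <- function(fp, mono_done) {
    if (length(conj_atoms)) {
      for (k in seq_along(conj_atoms)) {
        if (mono_done[k]) next
        if (!evaluate_atom(conj_atoms[[k]], fp, params$costs)) return(FALSE)
      }
    }
    for (cst in post_constraints) {
      if (!evaluate_constraint(cst, fp, params$costs)) return(FALSE)
    }
    TRUE
  }

  recurse <- function(cov_idx, cand, pattern, mono_done, depth) {
    if (!length(cand) || !length(cov_idx)) return(invisible(NULL))
    # tau-periodic conditional data reductions (mu on covered transactions
    # w.r.t. the prefix: a transaction failing a monotone constraint on its
    # full remaining item set cannot support any satisfying extension)
    if (length(conj) && depth > 0L && depth %% params$tau == 0L) {
      keep <- rep(TRUE, length(cov_idx))
      for (ci in seq_along(conj)) {
        if (!constraint_is_monotone(conj[[ci]], params$costs)) next
        if (any(vapply(conj[[ci]]$atoms, function(a) identical(a$target, "rows"), logical(1)))) next
        for (j in which(keep)) {
          items_j <- c(pattern, cand[M[cov_idx[j], cand]])
          fpt <- fp_of(items_j, cov_idx)
          if (!evaluate_constraint(conj[[ci]], fpt, params$costs)) keep[j] <- FALSE
        }
      }
      if (!all(keep)) {
        counter$removed_transactions <- counter$removed_transactions + sum(!keep)
        cov_idx <- cov_idx[keep]
        if (!length(cov_idx)) return(invisible(NULL))
      }
    }
    covvec <- numeric(nrow(M))
    covvec[cov_idx] <- 1
    sup <- drop(crossprod(Mnum, covvec))
    frequent <- cand[sup[cand] >= theta1]
    if (!length(frequent)) return(invisible(NULL))
    for (r in frequent) {
      if (state$truncated) return(invisible(NULL))
      counter$visited <- counter$visited + 1L
      if (counter$visited > params$max_nodes) {
        state$truncated <- TRUE
        return(invisible(NULL))
      }
      new_pattern <- c(pattern, r)
      new_cov <- cov_idx[M[cov_idx, r]]
      new_mono <- mono_done
      sat <- TRUE
      if (has_constraints) {
        fp <- fp_of(new_pattern, new_cov)
        # anti-monotone pruning: a failing pattern has no satisfying superset
        pruned <- FALSE
        for (a in am_atoms) {
          if (!evaluate_atom(a, fp, params$costs)) { pruned <- TRUE; break }
        }
        # convertible stop: under the cost order, extensions only worsen avg
        if (!pruned) {
          for (a in conv_atoms) {
            if (!evaluate_atom(a, fp, params$costs)) { pruned <- TRUE; break }
          }
        }
        if (pruned) next
        if (length(conj_atoms)) {
          for (kk in which(conj_monotone & !mono_done)) {
            if (evaluate_atom(conj_atoms[[kk]], fp, params$costs)) new_mono[kk] <- TRUE
          }
        }
        sat <- satisfies_all(fp, new_mono)
      }
      state$n <- state$n + 1L
      res[[as.character(state$n)]] <- list(new_pattern, new_cov, sat)
      recurse(new_cov, frequent[frequent > r], new_pattern, new_mono, depth + 1L)
    }
    invisible(NULL)
  }

  mono_init <- if (length(conj_atoms)) rep(FALSE, length(conj_atoms)) else logical(0)
  recurse(seq_along(tids), seq_len(V), integer(0), mono_init, 0L)

  # closure within the satisfying space, then length filter (skipped when the
  # node budget truncated the search: partial results are not reported)
  out <- list()
  if (!state$truncated && state$n > 0L) {
    recs <- mget(as.character(seq_len(state$n)), envir = res)
    sat_idx <- which(vapply(recs, `[[`, logical(1), 3L))
    if (length(sat_idx)) {
      all_pat <- lapply(recs, `[[`, 1L)
      all_cov <- lapply(recs, `[[`, 2L)
      keys <- vapply(all_cov[sat_idx], paste, character(1), collapse = ",")
      for (grp in split(sat_idx, keys)) {
        pats <- all_pat[grp]
        lens <- lengths(pats)
        for (j in seq_along(grp)) {
          if (lens[j] < params$theta2) next
          is_sub <- any(vapply(seq_along(grp), function(k) {
            k != j && lens[k] > lens[j] && all(pats[[j]] %in% pats[[k]])
          }, logical(1)))
          if (!is_sub) out[[length(out) + 1L]] <- fp_of(pats[[j]], all_cov[[grp[j]]])
        }
      }
    }
  }
  finish_patterns(out, params, counter, truncated = state$truncated)
}

finish_patterns <- function(patterns, params, counter, truncated = FALSE) {
  attr(patterns, "counters") <- counter_state(counter)
  attr(patterns, "truncated") <- truncated
  patterns
}
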