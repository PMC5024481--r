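#' Sequential constraint set
#'
#' Constraints for order-preserving (sequential) pattern mining: item
#' constraints (required/forbidden columns), length bounds on precedences
#' (itemset-to-itemset steps) and co-occurrences (largest itemset size),
#' super-pattern constraints (required sub-orderings such as "y2 before y1"),
#' a regular expression over column-id tokens, and aggregate constraints
#' evaluated on the median of values from the supporting rows.
#'
#' @param required columns that must appear in the pattern.
#' @param forbidden columns that must not appear.
#' @param min_precedences,max_precedences bounds on `n_itemsets - 1`.
#' @param min_cooccurrences,max_cooccurrences bounds on the largest itemset.
#' @param superpattern list of character vectors; each is an ordering chain
#'   `c(a, b, ...)` required as a sub-ordering (a strictly before b, ...).
#' @param regex a sequence pattern string (`"y2 < (y1 y3) < *"`; `*` is a
#'   wildcard itemset) compiled to a deterministic token automaton.
#' @param value_constraint optional [parse_constraint()] aggregate over the
#'   pattern's expected values; requires `value_matrix`.
#' @param value_matrix numeric matrix the medians are recomputed from.
#' @return object of class `seq_constraints`.
#' @export
seq_constraints <- function(required = character(0), forbidden = character(0),
                            min_precedences = NULL, max_precedences = NULL,
                            min_cooccurrences = NULL, max_cooccurrences = NULL,
                            superpattern = list(), regex = NULL,
                            value_constraint = NULL, value_matrix = NULL) {
  tokens <- if (is.null(regex)) NULL else
    if (is.character(regex)) parse_seqpattern(regex) else regex
  stopifnot(is.null(min_precedences) || min_precedences >= 0,
            is.null(max_precedences) || max_precedences >= 0)
  structure(list(required = required, forbidden = forbidden,
                 min_precedences = min_precedences, max_precedences = max_precedences,
                 min_cooccurrences = min_cooccurrences, max_cooccurrences = max_cooccurrences,
                 superpattern = superpattern, regex = tokens,
                 value_constraint = value_constraint, value_matrix = value_matrix),
            class = "seq_constraints")
}

seq_pattern_cols <- function(groups) unlist(groups, use.names = FALSE)

n_precedences <- function(groups) length(groups) - 1L

max_cooc <- function(groups) if (length(groups)) max(lengths(groups)) else 0L

# token automaton over itemset tokens; '*' matches any run of itemsets.
# Reachable token positions after consuming the groups (epsilon-closure of
# '*' skips); `relax_last` treats the final group as still growable by
# larger-sorting column ids (safe over-approximation for prefix feasibility).
regex_states <- function(tokens, groups, relax_last = FALSE) {
  m <- length(tokens)
  closure <- function(states) {
    repeat {
      extra <- states[states <= m]
      extra <- extra[vapply(tokens[extra], identical, logical(1), "*")] + 1L
      new <- sort(unique(c(states, extra)))
      if (identical(new, states)) return(new)
      states <- new
    }
  }
  states <- closure(1L)
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    growable <- relax_last && gi == length(groups)
    nxt <- integer(0)
    for (s in states) {
      if (s > m) next
      tok <- tokens[[s]]
      if (identical(tok, "*")) {
        nxt <- c(nxt, s)  # wildcard absorbs the group
      } else {
        extra <- setdiff(tok, g)
        ok <- !length(extra) ||
          (growable && length(g) && all(extra > max(g)))
        if (ok) nxt <- c(nxt, s + 1L)
      }
    }
    states <- closure(sort(unique(nxt)))
    if (!length(states)) return(integer(0))
  }
  states
}

regex_full_match <- function(tokens, groups) {
  states <- regex_states(tokens, groups)
  (length(tokens) + 1L) %in% states
}

superpattern_satisfied <- function(chains, groups) {
  if (!length(chains)) return(TRUE)
  pos <- integer(0)
  for (gi in seq_along(groups)) pos[groups[[gi]]] <- gi
  all(vapply(chains, function(ch) {
    p <- pos[ch]
    !anyNA(p) && all(diff(p) > 0L)
  }, logical(1)))
}

seq_satisfies <- function(groups, rows, cs) {
  if (is.null(cs)) return(TRUE)
  cols <- seq_pattern_cols(groups)
  if (length(cs$required) && !all(cs$required %in% cols)) return(FALSE)
  if (length(cs$forbidden) && length(intersect(cs$forbidden, cols))) return(FALSE)
  np <- n_precedences(groups); mc <- max_cooc(groups)
  if (!is.null(cs$min_precedences) && np < cs$min_precedences) return(FALSE)
  if (!is.null(cs$max_precedences) && np > cs$max_precedences) return(FALSE)
  if (!is.null(cs$min_cooccurrences) && mc < cs$min_cooccurrences) return(FALSE)
  if (!is.null(cs$max_cooccurrences) && mc > cs$max_cooccurrences) return(FALSE)
  if (!superpattern_satisfied(cs$superpattern, groups)) return(FALSE)
  if (!is.null(cs$regex) && !regex_full_match(cs$regex, groups)) return(FALSE)
  if (!is.null(cs$value_constraint)) {
    m <- cs$value_matrix
    vcols <- intersect(cols, colnames(m))
    vrows <- intersect(rows, rownames(m))
    if (!length(vcols) || !length(vrows)) return(FALSE)
    med <- vapply(vcols, function(j) median(m[vrows, j], na.rm = TRUE), numeric(1))
    fp <- full_pattern(items = vcols, rows = rows, cols = vcols,
                       symbols = as.character(med), groups = groups)
    if (!evaluate_constraint(cs$value_constraint, fp)) return(FALSE)
  }
  TRUE
}

#' Check whether a prefix can still lead to satisfying patterns
#'
#' `"prune_prefix"` when an anti-monotone bound is already exceeded or the
#' regex automaton has no reachable state (no extension can satisfy);
#' `"prune_sequence"` when the supplied projected sequence cannot satisfy a
#' monotone item constraint; otherwise `"continue"`, with attribute
#' `recheck = FALSE` once every monotone constraint is already satisfied by
#' the prefix (satisfaction persists under extension).
#'
#' @param prefix list of column-id itemsets (the pattern so far).
#' @param cs a [seq_constraints()].
#' @param sequence optional: a full sequence (list of itemsets) to test for
#'   `prune_sequence`.
#' @return character verdict.
#' @export
prefix_check <- function(prefix, cs, sequence = NULL) {
  stopifnot(length(prefix) >= 1L)
  if (!is.null(cs$max_precedences) && n_precedences(prefix) > cs$max_precedences) {
    return("prune_prefix")
  }
  if (!is.null(cs$max_cooccurrences) && length(prefix) > 1L &&
      max(lengths(prefix[-length(prefix)])) > cs$max_cooccurrences) {
    return("prune_prefix")
  }
  if (length(cs$forbidden) && length(intersect(cs$forbidden, seq_pattern_cols(prefix)))) {
    return("prune_prefix")
  }
  if (!is.null(cs$regex) && !length(regex_states(cs$regex, prefix, relax_last = TRUE))) {
    return("prune_prefix")
  }
  if (!is.null(sequence) && length(cs$required)) {
    if (!all(cs$required %in% unlist(sequence))) return("prune_sequence")
  }
  out <- "continue"
  mono_ok <- superpattern_satisfied(cs$superpattern, prefix) &&
    (!length(cs$required) || all(cs$required %in% seq_pattern_cols(prefix))) &&
    (is.null(cs$min_precedences) || n_precedences(prefix) >= cs$min_precedences) &&
    (is.null(cs$min_cooccurrences) || max_cooc(prefix) >= cs$min_cooccurrences)
  attr(out, "recheck") <- !mono_ok
  out
}

seq_rank_maps <- function(db) {
  lapply(db$sequences, function(s) {
    ranks <- rep.int(seq_along(s), lengths(s))
    setNames(ranks, unlist(s, use.names = FALSE))
  })
}

#' Project a sequence database on a prefix
#'
#' Returns the suffix information of every sequence supporting the prefix:
#' the remainder of the itemset the prefix ends in (columns sorting after the
#' prefix's last column, available for co-occurrence extension) and all later
#' itemsets.
#'
#' @param db a `seq_db`.
#' @param prefix list of column-id itemsets.
#' @param theta1 minimum support; projecting an infrequent prefix errors.
#' @return named list per supporting sequence with `cooc` (co-occurrence
#'   candidates) and `suffix` (later itemsets).
#' @export
seq_project <- function(db, prefix, theta1 = 1L) {
  ranks <- seq_rank_maps(db)
  out <- list()
  for (id in names(db$sequences)) {
    r <- ranks[[id]]
    emb <- seq_embedding(prefix, r)
    if (is.null(emb)) next
    s <- db$sequences[[id]]
    last <- prefix[[length(prefix)]]
    in_last <- s[[emb]]
    cooc <- in_last[in_last > max(last)]
    suffix <- if (emb < length(s)) s[(emb + 1L):length(s)] else list()
    out[[id]] <- list(cooc = cooc, suffix = suffix)
  }
  if (length(out) < theta1) stop("prefix support ", length(out), " below theta1 = ", theta1)
  out
}

# forced embedding under item-indexability: each pattern itemset must sit in a
# single sequence itemset and ranks must strictly increase; returns the rank of
# the last itemset, or NULL
seq_embedding <- function(groups, rank_map) {
  prev <- 0L
  for (g in groups) {
    rg <- rank_map[g]
    if (anyNA(rg)) return(NULL)
    if (length(unique(rg)) != 1L) return(NULL)
    if (rg[1L] <= prev) return(NULL)
    prev <- rg[1L]
  }
  prev
}

#' Mine closed sequential full-patterns under constraints
#'
#' Prefix-projection search over an item-indexable sequence database (each
#' column occurs once per sequence, so embeddings are forced and projections
#' reduce to rank comparisons). Frequent prefixes are grown by co-occurrence
#' extension (adding a column to the last itemset) or precedence extension
#' (starting a new itemset); anti-monotone length bounds, forbidden columns
#' and the regex automaton's dead states prune prefixes, and monotone
#' constraints stop being re-checked once a prefix satisfies them.
#'
#' Closure is computed within the satisfying space on (pattern, coverage)
#' pairs: a satisfying pattern is reported iff no satisfying supersequence has
#' identical coverage.
#'
#' @param db a `seq_db`.
#' @param theta1 minimum support (count or fraction).
#' @param theta2 minimum number of columns in the pattern.
#' @param cs optional [seq_constraints()].
#' @param max_nodes search budget on visited projections; the run stops when
#'   exceeded and flags the result with attribute `"truncated"`.
#' @return list of [full_pattern()]s (with `groups` and the ordering relation
#'   as `symbols`); attribute `"counters"` holds the visited-projection count.
#' @export
mine_sequential_closed <- function(db, theta1, theta2 = 2L, cs = NULL, max_nodes = Inf) {
  counter <- new_counter()
  n <- length(db$sequences)
  out <- list()
  if (n == 0L) {
    attr(out, "counters") <- counter_state(counter)
    attr(out, "truncated") <- FALSE
    return(out)
  }
  theta1 <- resolve_theta1(theta1, n)
  ranks <- seq_rank_maps(db)
  ids <- names(db$sequences)

  # prune_sequence: sequences that cannot satisfy monotone item constraints
  active <- seq_len(n)
  if (!is.null(cs) && length(cs$required)) {
    has_req <- vapply(ranks, function(r) all(cs$required %in% names(r)), logical(1))
    counter$removed_transactions <- sum(!has_req)
    active <- active[has_req[active]]
  }
  universe <- sort(unique(unlist(lapply(db$sequences, unlist))))
  if (!is.null(cs)) universe <- setdiff(universe, cs$forbidden)

  res <- new.env(parent = emptyenv(), hash = TRUE)
  state <- new.env(parent = emptyenv())
  state$n <- 0L
  state$truncated <- FALSE

  recurse <- function(groups, supp, last_rank, recheck) {
    if (state$truncated) return(invisible(NULL))
    if (counter$visited > max_nodes) {
      state$truncated <- TRUE
      return(invisible(NULL))
    }
    # supp: indices of supporting sequences; last_rank aligned to supp
    verdict <- prefix_check(groups, cs %||% seq_constraints())
    if (verdict == "prune_prefix") return(invisible(NULL))
    recheck <- recheck && isTRUE(attr(verdict, "recheck"))
    cov <- sort(ids[supp])
    sat <- seq_satisfies(groups, cov, cs)
    state$n <- state$n + 1L
    res[[as.character(state$n)]] <- list(groups, cov, sat)

    last <- groups[[length(groups)]]
    used <- seq_pattern_cols(groups)
    # co-occurrence extensions
    for (col in universe[universe > max(last)]) {
      if (col %in% used) next
      sel <- vapply(seq_along(supp), function(k) {
        r <- ranks[[supp[k]]][col]
        !is.na(r) && r == last_rank[k]
      }, logical(1))
      if (sum(sel) < theta1) next
      counter$visited <- counter$visited + 1L
      recurse(c(groups[-length(groups)], list(c(last, col))),
              supp[sel], last_rank[sel], recheck)
    }
    # precedence extensions
    allow_seq <- is.null(cs) || is.null(cs$max_precedences) ||
      n_precedences(groups) < cs$max_precedences
    if (allow_seq) {
      for (col in universe) {
        if (col %in% used) next
        r_new <- vapply(seq_along(supp), function(k) {
          r <- ranks[[supp[k]]][col]
          if (!is.na(r) && r > last_rank[k]) r else NA_integer_
        }, integer(1))
        sel <- !is.na(r_new)
        if (sum(sel) < theta1) next
        counter$visited <- counter$visited + 1L
        recurse(c(groups, list(col)), supp[sel], r_new[sel], recheck)
      }
    }
    invisible(NULL)
  }

  for (col in universe) {
    r0 <- vapply(active, function(k) {
      r <- ranks[[k]][col]
      if (is.na(r)) NA_integer_ else r
    }, integer(1))
    sel <- !is.na(r0)
    if (sum(sel) < theta1) next
    counter$visited <- counter$visited + 1L
    recurse(list(col), active[sel], r0[sel], TRUE)
  }

  if (!state$truncated && state$n > 0L) {
    recs <- mget(as.character(seq_len(state$n)), envir = res)
    all_pat <- lapply(recs, `[[`, 1L)
    all_cov <- lapply(recs, `[[`, 2L)
    sat_idx <- which(vapply(recs, `[[`, logical(1), 3L))
    sizes <- vapply(all_pat[sat_idx], function(g) length(unlist(g)), integer(1))
    keys <- vapply(all_cov[sat_idx], paste, character(1), collapse = ",")
    for (grp_pos in split(seq_along(sat_idx), keys)) {
      grp <- sat_idx[grp_pos]
      sz <- sizes[grp_pos]
      for (j in seq_along(grp)) {
        if (sz[j] < theta2) next
        contained <- any(vapply(seq_along(grp), function(k) {
          k != j && sz[k] > sz[j] && is_subsequence(all_pat[[grp[j]]], all_pat[[grp[k]]])
        }, logical(1)))
        if (!contained) {
          groups <- all_pat[[grp[j]]]
          cols <- seq_pattern_cols(groups)
          out[[length(out) + 1L]] <- full_pattern(
            items = cols, rows = all_cov[[grp[j]]], cols = cols,
            symbols = ordering_relation(groups), groups = groups)
        }
      }
    }
  }
  attr(out, "counters") <- counter_state(counter)
  attr(out, "truncated") <- state$truncated
  out
}

# subsequence containment for sequences of itemsets (greedy earliest match)
is_subsequence <- function(a, b) {
  j <- 1L
  for (g in a) {
    repeat {
      if (j > length(b)) return(FALSE)
      if (all(g %in% b[[j]])) break
      j <- j + 1L
    }
    j <- j + 1L
  }
  TRUE
}

ordering_relation <- function(groups) {
  paste(vapply(groups, function(g) {
    if (length(g) > 1L) paste0("(", paste(g, collapse = " "), ")") else g
  }, character(1)), collapse = " < ")
}
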