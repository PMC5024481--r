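# Independent brute-force oracles and random-instance generators.
# These deliberately re-implement support counting, constraint aggregates and
# closure by direct enumeration, without calling the package's miners.

worked_db <- function() {
  bic2pam:::new_itemset_db(list(x1 = c("a", "b", "c"),
                                x2 = c("a", "b", "c", "d"),
                                x3 = c("a", "d")))
}

worked_costs <- c(a = 0, b = 1, c = 2, d = 3)

# constraint specs for the oracle are plain lists, independent of the grammar:
#   list(type, v, set); eval_spec computes aggregates with base R directly
eval_spec <- function(spec, items, costs) {
  if (is.null(spec)) return(TRUE)
  vals <- unname(costs[items])
  switch(spec$type,
    range_ge = (max(vals) - min(vals)) >= spec$v,
    range_le = (max(vals) - min(vals)) <= spec$v,
    sum_le = sum(vals) <= spec$v,
    sum_ge = sum(vals) >= spec$v,
    max_le = max(vals) <= spec$v,
    min_ge = min(vals) >= spec$v,
    avg_ge = mean(vals) >= spec$v,
    avg_le = mean(vals) <= spec$v,
    countval_ge = length(unique(vals)) >= spec$v,
    superset = all(spec$set %in% items),
    excludes = !any(spec$set %in% items),
    contains = any(spec$set %in% items),
    stop("unknown oracle spec ", spec$type))
}

# grammar text equivalent for the package miner
spec_to_text <- function(spec) {
  switch(spec$type,
    range_ge = paste0("range(items) >= ", spec$v),
    range_le = paste0("range(items) <= ", spec$v),
    sum_le = paste0("sum(items) <= ", spec$v),
    sum_ge = paste0("sum(items) >= ", spec$v),
    max_le = paste0("max(items) <= ", spec$v),
    min_ge = paste0("min(items) >= ", spec$v),
    avg_ge = paste0("avg(items) >= ", spec$v),
    avg_le = paste0("avg(items) <= ", spec$v),
    countval_ge = paste0("countVal(items) >= ", spec$v),
    superset = paste0("items superset {", paste(spec$set, collapse = ","), "}"),
    excludes = paste0("items excludes {", paste(spec$set, collapse = ","), "}"),
    contains = paste0("items contains {", paste(spec$set, collapse = ","), "}"))
}

# brute-force constrained closed full-pattern mining by powerset enumeration
oracle_mine_closed <- function(tx, theta1, theta2, spec = NULL, costs = NULL) {
  universe <- sort(unique(unlist(tx)))
  if (is.null(costs)) costs <- setNames(suppressWarnings(as.numeric(universe)), universe)
  subsets <- list()
  for (k in seq_along(universe)) {
    cmb <- utils::combn(universe, k, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  cover <- function(s) sort(names(tx)[vapply(tx, function(t) all(s %in% t), logical(1))])
  covs <- lapply(subsets, cover)
  sup <- lengths(covs)
  sat <- vapply(seq_along(subsets), function(i) {
    sup[i] >= theta1 && eval_spec(spec, subsets[[i]], costs)
  }, logical(1))
  keep <- logical(length(subsets))
  for (i in which(sat)) {
    if (length(subsets[[i]]) < theta2) next
    closed <- TRUE
    for (j in which(sat)) {
      if (j == i) next
      if (length(subsets[[j]]) > length(subsets[[i]]) &&
          all(subsets[[i]] %in% subsets[[j]]) &&
          identical(covs[[i]], covs[[j]])) {
        closed <- FALSE
        break
      }
    }
    keep[i] <- closed
  }
  canon_set(lapply(which(keep), function(i) {
    list(items = subsets[[i]], cov = covs[[i]])
  }))
}

canon_set <- function(pats) {
  out <- vapply(pats, function(p) {
    paste0("{", paste(sort(p$items), collapse = ","), "}@{",
           paste(sort(p$cov), collapse = ","), "}")
  }, character(1))
  sort(out)
}

canon_mined <- function(pats) {
  canon_set(lapply(pats, function(fp) list(items = fp$items, cov = fp$rows)))
}

rand_itemset_db <- function(n_tx = 6L, n_items = 6L, density = 0.45) {
  universe <- letters[seq_len(n_items)]
  tx <- list()
  for (i in seq_len(n_tx)) {
    items <- universe[stats::runif(n_items) < density]
    if (!length(items)) items <- sample(universe, 1L)
    tx[[paste0("t", i)]] <- items
  }
  bic2pam:::new_itemset_db(tx)
}

# ---- sequential oracle -----------------------------------------------------

# all ordered set partitions of a character vector
ordered_partitions <- function(set) {
  if (!length(set)) return(list(list()))
  out <- list()
  n <- length(set)
  for (k in seq_len(n)) {
    for (block in utils::combn(set, k, simplify = FALSE)) {
      rest <- setdiff(set, block)
      for (tail_part in ordered_partitions(rest)) {
        out[[length(out) + 1L]] <- c(list(sort(block)), tail_part)
      }
    }
  }
  out
}

seq_supports <- function(groups, sequences) {
  ok <- vapply(sequences, function(s) {
    j <- 1L
    for (g in groups) {
      found <- FALSE
      while (j <= length(s)) {
        if (all(g %in% s[[j]])) { found <- TRUE; j <- j + 1L; break }
        j <- j + 1L
      }
      if (!found) return(FALSE)
    }
    TRUE
  }, logical(1))
  sort(names(sequences)[ok])
}

# spec: list(pred = function(groups) TRUE/FALSE) -- independent predicate
oracle_mine_seq <- function(sequences, theta1, theta2, pred = NULL) {
  universe <- sort(unique(unlist(sequences)))
  pats <- list()
  for (k in seq_along(universe)) {
    for (cols in utils::combn(universe, k, simplify = FALSE)) {
      pats <- c(pats, ordered_partitions(cols))
    }
  }
  covs <- lapply(pats, seq_supports, sequences = sequences)
  sat <- vapply(seq_along(pats), function(i) {
    length(covs[[i]]) >= theta1 && (is.null(pred) || pred(pats[[i]]))
  }, logical(1))
  contains_seq <- function(a, b) {
    # is a a subsequence of b
    j <- 1L
    for (g in a) {
      found <- FALSE
      while (j <= length(b)) {
        if (all(g %in% b[[j]])) { found <- TRUE; j <- j + 1L; break }
        j <- j + 1L
      }
      if (!found) return(FALSE)
    }
    TRUE
  }
  keep <- logical(length(pats))
  for (i in which(sat)) {
    if (length(unlist(pats[[i]])) < theta2) next
    closed <- TRUE
    for (j in which(sat)) {
      if (j == i) next
      if (length(unlist(pats[[j]])) > length(unlist(pats[[i]])) &&
          identical(covs[[i]], covs[[j]]) && contains_seq(pats[[i]], pats[[j]])) {
        closed <- FALSE
        break
      }
    }
    keep[i] <- closed
  }
  canon_seq_set(lapply(which(keep), function(i) list(groups = pats[[i]], cov = covs[[i]])))
}

canon_seq_set <- function(pats) {
  out <- vapply(pats, function(p) {
    g <- paste(vapply(p$groups, function(x) paste(sort(x), collapse = " "), character(1)),
               collapse = "|")
    paste0("<", g, ">@{", paste(sort(p$cov), collapse = ","), "}")
  }, character(1))
  sort(out)
}

canon_seq_mined <- function(pats) {
  canon_seq_set(lapply(pats, function(fp) list(groups = fp$groups, cov = fp$rows)))
}

rand_seq_db <- function(n_seq = 6L, n_cols = 4L, p_drop = 0.15) {
  universe <- paste0("y", seq_len(n_cols))
  sequences <- list()
  for (i in seq_len(n_seq)) {
    cols <- universe[stats::runif(n_cols) >= p_drop]
    if (length(cols) < 2L) cols <- sample(universe, 2L)
    perm <- sample(cols)
    # random grouping into itemsets
    breaks <- c(TRUE, stats::runif(length(perm) - 1L) < 0.6)
    groups <- split(perm, cumsum(breaks))
    sequences[[paste0("s", i)]] <- unname(lapply(groups, sort))
  }
  bic2pam:::new_seq_db(sequences)
}

make_tiny_matrix <- function() {
  m <- matrix(c(1, 2, 3,
                5, 5, 5,
                1, NA, 3), nrow = 3, byrow = TRUE,
              dimnames = list(c("x1", "x2", "x3"), c("y1", "y2", "y3")))
  m
}
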