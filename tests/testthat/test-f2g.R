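test_that("the FP-tree compresses shared prefixes and stores transaction ids", {
  db <- worked_db()
  tree <- build_fp_tree(db, miner_params(1, 2))
  # support order: a(3) first, then b,c,d (2 each, lexicographic ties)
  expect_equal(tree$order, c("a", "b", "c", "d"))
  root_children <- tree$root$children
  expect_length(root_children, 1L)           # every transaction starts with a
  a_node <- root_children[["a"]]
  expect_equal(a_node$count, 3L)
  expect_setequal(names(a_node$children), c("b", "d"))  # two branches under a
  # terminal ids: x1 ends at c, x2 at the deep d, x3 at the shallow d
  paths <- bic2pam:::fp_tree_paths(tree)
  keys <- vapply(paths$items, paste, character(1), collapse = ",")
  expect_setequal(unlist(paths$tids[keys == "a,b,c"]), "x1")
  expect_setequal(unlist(paths$tids[keys == "a,b,c,d"]), "x2")
  expect_setequal(unlist(paths$tids[keys == "a,d"]), "x3")
  # the terminal id sets partition the database
  expect_equal(sum(lengths(paths$tids)), 3L)

  single <- build_fp_tree(bic2pam:::new_itemset_db(list(t1 = c("a", "b"))),
                          miner_params(1, 2))
  p1 <- bic2pam:::fp_tree_paths(single)
  expect_length(p1$items, 1L)
  expect_equal(p1$tids[[1]], "t1")

  high <- build_fp_tree(db, miner_params(3, 1))
  expect_equal(high$order, "a")  # supports: a 3, b/c/d 2
})

test_that("mu-reduction removes transactions that cannot satisfy the constraint", {
  # symbolic transactions with a min(pattern)=0 succinct bound
  db <- bic2pam:::new_itemset_db(list(
    x1 = c("y1.-1", "y2.3", "y3.1"),
    x2 = c("y1.0", "y2.2", "y3.1"),
    x3 = c("y1.2", "y2.0", "y3.0"),
    x4 = c("y1.1", "y2.-1", "y3.2")
  ))
  out <- mu_reduce(db, parse_constraint("min(pattern) = 0"))
  expect_setequal(names(out$tx), c("x2", "x3"))
  expect_equal(attr(out, "removed")$transactions, 2L)

  # a constraint satisfied by every transaction leaves the database unchanged
  all_ok <- mu_reduce(db, parse_constraint("range(pattern) >= 1"))
  expect_equal(names(all_ok$tx), names(db$tx))

  # monotone range bound no transaction can meet empties the database
  none <- mu_reduce(db, parse_constraint("range(pattern) >= 40"))
  expect_length(none$tx, 0L)
})

test_that("alpha-reduction removes conflicting items and short transactions", {
  db <- bic2pam:::new_itemset_db(list(
    x1 = c("y1.-1", "y2.3", "y3.1"),
    x4 = c("y1.1", "y2.-1", "y3.2"),
    x5 = c("y1.-1", "y2.-2")
  ))
  out <- alpha_reduce(db, parse_constraint("min(pattern) = 0"), theta2 = 2)
  expect_setequal(out$tx$x1, c("y2.3", "y3.1"))
  expect_setequal(out$tx$x4, c("y1.1", "y3.2"))
  expect_false("x5" %in% names(out$tx))  # emptied below theta2
  expect_equal(attr(out, "removed")$items, 4L)

  ident <- alpha_reduce(db, parse_constraint("range(pattern) >= 1"))
  expect_equal(ident$tx, db$tx)
})

test_that("the worked three-transaction example yields the printed results", {
  db <- worked_db()
  base <- function(spec = list()) miner_params(1, 2, spec, worked_costs)
  # monotone range >= 2: three closed satisfying patterns
  r <- mine_closed(db, base(list(parse_constraint("range(items) >= 2"))))
  expect_length(r, 3L)
  expect_setequal(canon_mined(r),
                  c("{a,b,c}@{x1,x2}", "{a,b,c,d}@{x2}", "{a,d}@{x2,x3}"))
  # anti-monotone sum <= 1: exactly {a,b} covering two transactions
  s <- mine_closed(db, base(list(parse_constraint("sum(items) <= 1"))))
  expect_equal(canon_mined(s), "{a,b}@{x1,x2}")
  # succinct superset {c,d}: exactly {a,b,c,d}
  u <- mine_closed(db, base(list(parse_constraint("items superset {c,d}"))))
  expect_equal(canon_mined(u), "{a,b,c,d}@{x2}")
  # convertible avg >= 2: exactly {b,c,d}
  v <- mine_closed(db, base(list(parse_constraint("avg(items) >= 2"))))
  expect_equal(canon_mined(v), "{b,c,d}@{x2}")
  # unconstrained run restricted to length >= 2: three closed patterns
  n <- mine_closed(db, base())
  expect_length(n, 3L)
})

test_that("reported supports equal recomputed coverage sizes", {
  set.seed(33)
  for (trial in 1:20) {
    db <- rand_itemset_db(8, 7, 0.5)
    pats <- mine_closed(db, miner_params(2, 2))
    for (fp in pats) {
      cov <- names(db$tx)[vapply(db$tx, function(t) all(fp$items %in% t), logical(1))]
      expect_setequal(fp$rows, cov)
      expect_equal(fp$support, length(cov))
    }
  }
})

test_that("the miner equals the brute-force oracle on random databases", {
  set.seed(404)
  specs <- list(
    NULL,
    list(type = "range_ge", v = 2),
    list(type = "sum_le", v = 4),
    list(type = "max_le", v = 4),
    list(type = "superset", set = c("a", "b")),
    list(type = "excludes", set = "c"),
    list(type = "avg_ge", v = 2.5),
    list(type = "avg_le", v = 2),
    list(type = "countval_ge", v = 2)
  )
  for (trial in 1:40) {
    db <- rand_itemset_db(sample(4:8, 1), sample(4:7, 1), runif(1, 0.35, 0.6))
    universe <- sort(unique(unlist(db$tx)))
    costs <- setNames(sample(0:7, length(universe)), universe)
    theta1 <- sample(1:3, 1)
    for (spec in specs) {
      constraints <- if (is.null(spec)) list() else list(parse_constraint(spec_to_text(spec)))
      mined <- mine_closed(db, miner_params(theta1, 2, constraints, costs))
      expected <- oracle_mine_closed(db$tx, theta1, 2, spec, costs)
      expect_identical(canon_mined(mined), expected,
                       label = paste("trial", trial, spec$type %||% "none"))
    }
  }
})

test_that("constraint pushing never changes results and only shrinks the search", {
  set.seed(505)
  specs <- list(
    list(type = "sum_le", v = 5),
    list(type = "superset", set = "a"),
    list(type = "avg_ge", v = 3),
    list(type = "range_ge", v = 3)
  )
  for (trial in 1:25) {
    db <- rand_itemset_db(6, 6, 0.5)
    universe <- sort(unique(unlist(db$tx)))
    costs <- setNames(sample(0:6, length(universe)), universe)
    for (spec in specs) {
      cst <- parse_constraint(spec_to_text(spec))
      for (tau in c(1L, 2L, 5L)) {
        pushed <- mine_closed(db, miner_params(1, 2, list(cst), costs, tau = tau))
        # post-filter route: unconstrained enumeration + oracle-side filtering
        expected <- oracle_mine_closed(db$tx, 1, 2, spec, costs)
        expect_identical(canon_mined(pushed), expected)
        unpruned <- mine_closed(db, miner_params(1, 2, list(), costs))
        expect_lte(attr(pushed, "counters")$visited,
                   attr(unpruned, "counters")$visited)
      }
    }
  }
})

test_that("fractional support thresholds convert to ceiling counts", {
  db <- worked_db()
  # 0.5 of 3 transactions -> ceiling = 2
  pats <- mine_closed(db, miner_params(0.5, 2))
  expect_true(all(vapply(pats, function(p) p$support >= 2, logical(1))))
  expect_setequal(canon_mined(pats), c("{a,b,c}@{x1,x2}", "{a,d}@{x2,x3}"))
})

test_that("the node budget truncates deep searches and flags the result", {
  set.seed(9)
  db <- rand_itemset_db(10, 8, 0.8)
  full <- mine_closed(db, miner_params(1, 2))
  expect_false(attr(full, "truncated"))
  cut <- mine_closed(db, miner_params(1, 2, max_nodes = 5))
  expect_true(attr(cut, "truncated"))
  expect_lte(attr(cut, "counters")$visited, 6L)
})
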