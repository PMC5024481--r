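test_that("the grammar parses aggregate, set and regex atoms", {
  c1 <- parse_constraint("min(pattern) <= -3")
  expect_equal(c1$atoms[[1]]$kind, "aggregate")
  expect_equal(c1$atoms[[1]]$target, "pattern")
  expect_equal(c1$atoms[[1]]$value, -3)

  c2 <- parse_constraint("countVal(pattern) >= 2")
  expect_equal(c2$atoms[[1]]$agg, "countVal")

  c3 <- parse_constraint("rows superset {x2, x3}")
  expect_equal(c3$atoms[[1]]$rel, "superset")
  expect_setequal(c3$atoms[[1]]$set, c("x2", "x3"))

  c4 <- parse_constraint("min(pattern) <= -2 and max(pattern) >= 2")
  expect_length(c4$atoms, 2)
  expect_equal(c4$ops, "and")

  c5 <- parse_constraint("regex(y2 < (y1 y3) < *)")
  expect_equal(c5$atoms[[1]]$kind, "regex")
  expect_equal(c5$atoms[[1]]$tokens[[2]], c("y1", "y3"))

  expect_error(parse_constraint("foo(pattern) >= 1"), "unknown aggregate")
  expect_error(parse_constraint("min(banana) >= 1"), "unknown target")
  expect_error(parse_constraint("min pattern >= "), "syntax error")
})

test_that("classification follows the standard constraint taxonomy", {
  cl <- function(s, costs = NULL) classify_constraint(parse_constraint(s), costs)
  expect_true("monotone" %in% cl("range(items) >= 2"))
  expect_true("anti_monotone" %in% cl("max(items) <= 1"))
  expect_true("anti_monotone" %in% cl("min(items) >= 0"))
  expect_true("anti_monotone" %in% cl("sum(items) <= 1", costs = c(a = 0, b = 1)))
  expect_equal(cl("sum(items) <= 1", costs = c(a = -1, b = 1)), "none")
  expect_true("succinct" %in% cl("min(items) <= -3"))
  expect_true("succinct" %in% cl("items contains {a}"))
  expect_true("convertible_am" %in% cl("avg(items) >= 2"))
  expect_true("monotone" %in% cl("countVal(pattern) >= 2"))
  expect_equal(cl("regex(y1 < *)"), "prefix_monotone")
  # rows-target containment is enforced as a coverage check: anti-monotone
  expect_equal(cl("rows superset {x1}"), "anti_monotone")
  # disjunctions stay succinct only when every atom is succinct
  expect_equal(cl("items contains {a} or items contains {b}"), "succinct")
  expect_equal(cl("items contains {a} or range(items) >= 2"), "none")
})

test_that("evaluation computes aggregates over the cost table", {
  costs <- worked_costs
  fp_ab <- full_pattern(c("a", "b"), rows = c("x1", "x2"), cols = character(0),
                        symbols = c("a", "b"))
  fp_bcd <- full_pattern(c("b", "c", "d"), rows = "x2", cols = character(0),
                         symbols = c("b", "c", "d"))
  expect_true(evaluate_constraint(parse_constraint("sum(items) <= 1"), fp_ab, costs))
  expect_true(evaluate_constraint(parse_constraint("avg(items) >= 2"), fp_bcd, costs))
  expect_false(evaluate_constraint(parse_constraint("avg(items) >= 2"), fp_ab, costs))

  # countVal over a constant pattern (0,0,0) has one distinct value
  fp0 <- full_pattern(c("y1.0", "y2.0", "y3.0"), rows = "x1",
                      cols = c("y1", "y2", "y3"), symbols = c("0", "0", "0"))
  expect_false(evaluate_constraint(parse_constraint("countVal(pattern) >= 2"), fp0))

  # annotation items are excluded from aggregates but visible to set atoms
  fp_ann <- full_pattern(c("y1.2", "T:T1"), rows = "x1", cols = "y1", symbols = "2")
  expect_true(evaluate_constraint(parse_constraint("avg(pattern) >= 2"), fp_ann))
  expect_true(evaluate_constraint(parse_constraint("items contains {T:T1}"), fp_ann))

  expect_error(evaluate_constraint(parse_constraint("sum(items) <= 1"),
                                   full_pattern("zz", "x1", character(0), "zz")),
               "no cost")
})

test_that("pattern- and column-space constraints translate to item space", {
  tc <- translate_constraint(parse_constraint("pattern contains {a}"),
                             alphabet = 0:2, columns = c("y1", "y2", "y3"))
  expect_setequal(tc$atoms[[1]]$set, c("y1.a", "y2.a", "y3.a"))
  expect_equal(tc$atoms[[1]]$target, "items")

  tc2 <- translate_constraint(parse_constraint("cols contains {y2}"),
                              alphabet = c(-1L, 0L, 1L), columns = c("y1", "y2"))
  expect_setequal(tc2$atoms[[1]]$set, c("y2.-1", "y2.0", "y2.1"))

  expect_error(translate_constraint(parse_constraint("pattern contains {a}"),
                                    alphabet = integer(0), columns = "y1"),
               "empty alphabet")
})

test_that("a superset-of-columns constraint requires a symbol per column", {
  tc <- translate_constraint(parse_constraint("cols superset {y1, y2}"),
                             alphabet = 0:1, columns = c("y1", "y2", "y3"))
  fp_both <- full_pattern(c("y1.0", "y2.1"), "x", c("y1", "y2"), c("0", "1"))
  fp_one <- full_pattern(c("y1.0", "y3.1"), "x", c("y1", "y3"), c("0", "1"))
  expect_true(evaluate_constraint(tc, fp_both))
  expect_false(evaluate_constraint(tc, fp_one))
})

test_that("monotone/anti-monotone classifications are stable on nested patterns", {
  set.seed(101)
  universe <- letters[1:8]
  specs <- list(
    list(text = "range(items) >= 2", dir = "monotone"),
    list(text = "countVal(items) >= 2", dir = "monotone"),
    list(text = "items superset {a,b}", dir = "monotone"),
    list(text = "max(items) <= 4", dir = "anti_monotone"),
    list(text = "sum(items) <= 6", dir = "anti_monotone"),
    list(text = "items excludes {c}", dir = "anti_monotone")
  )
  for (trial in 1:200) {
    costs <- setNames(sample(0:7), universe)
    small <- sample(universe, sample(2:5, 1))
    big <- unique(c(small, sample(universe, sample(1:3, 1))))
    for (sp in specs) {
      cst <- parse_constraint(sp$text)
      expect_true(sp$dir %in% classify_constraint(cst, costs))
      v_small <- evaluate_constraint(cst, full_pattern(small, "t", character(0), small), costs)
      v_big <- evaluate_constraint(cst, full_pattern(big, "t", character(0), big), costs)
      if (sp$dir == "monotone") {
        expect_false(v_small && !v_big)  # true never flips to false on supersets
      } else {
        expect_false(!v_small && v_big)  # false never flips to true on supersets
      }
    }
  }
})

test_that("aggregate evaluation agrees with direct recomputation on random draws", {
  set.seed(202)
  universe <- letters[1:8]
  for (trial in 1:1000) {
    costs <- setNames(round(runif(8, -3, 5), 2), universe)
    items <- sample(universe, sample(1:6, 1))
    vals <- unname(costs[items])
    fp <- full_pattern(items, "t", character(0), items)
    v <- runif(1, -2, 4)
    checks <- c(
      evaluate_constraint(parse_constraint(paste0("min(items) >= ", v)), fp, costs) == (min(vals) >= v),
      evaluate_constraint(parse_constraint(paste0("max(items) <= ", v)), fp, costs) == (max(vals) <= v),
      evaluate_constraint(parse_constraint(paste0("sum(items) <= ", v)), fp, costs) == (sum(vals) <= v),
      evaluate_constraint(parse_constraint(paste0("avg(items) >= ", v)), fp, costs) == (mean(vals) >= v),
      evaluate_constraint(parse_constraint(paste0("range(items) >= ", v)), fp, costs) ==
        (max(vals) - min(vals) >= v),
      evaluate_constraint(parse_constraint(paste0("countVal(items) >= 2")), fp, costs) ==
        (length(unique(vals)) >= 2)
    )
    expect_true(all(checks))
  }
})

test_that("soundness checking rejects unbound operands", {
  db <- worked_db()
  expect_silent(check_constraint_bound(parse_constraint("items superset {a,b}"), db))
  expect_error(check_constraint_bound(parse_constraint("items superset {zz}"), db),
               "not present")
  sdb <- bic2pam:::new_seq_db(list(s1 = list("y1", "y2")))
  expect_error(check_constraint_bound(parse_constraint("regex(y9 < *)"), sdb),
               "not present")
})
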