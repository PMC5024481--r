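test_that("full-patterns map to biclusters with rows, cols and pattern", {
  fp <- full_pattern(c("y1.6", "y2.5", "y4.3"), rows = c("t1", "t3"),
                     cols = c("y1", "y2", "y4"), symbols = c("6", "5", "3"))
  b <- pattern_to_bicluster(fp, "constant")
  expect_setequal(b$rows, c("t1", "t3"))
  expect_equal(b$cols, c("y1", "y2", "y4"))
  expect_equal(b$pattern, c(6, 5, 3))

  fp2 <- full_pattern(c("y1.0", "y2.2"), rows = "x1", cols = c("y1", "y2"),
                      symbols = c("0", "2"))
  b2 <- pattern_to_bicluster(fp2, "additive", factors = c(x1 = 1))
  expect_equal(b2$row_factors, c(x1 = 1))
  expect_equal(b2$coherency, "additive")

  # mirrored rows fold back with the original orientation first
  fp3 <- full_pattern(c("y1.1", "y2.-1"), rows = c("x2", "x2::neg"),
                      cols = c("y1", "y2"), symbols = c("1", "-1"))
  b3 <- pattern_to_bicluster(fp3, "symmetric", mirror_map = c("x2::neg" = "x2"))
  expect_equal(b3$rows, "x2")
  expect_equal(unname(b3$signs["x2"]), 1)
})

test_that("merging unions overlapping biclusters and respects the threshold", {
  a <- bicluster(paste0("r", 1:4), paste0("c", 1:4), rep(1, 4))
  dup <- bicluster(paste0("r", 1:4), paste0("c", 1:4), rep(1, 4))
  out <- merge_biclusters(list(a, dup), overlap = 0.7)
  expect_length(out, 1L)

  # two 4x4 biclusters sharing a 4x3 block: Jaccard 12/20 = 0.6, not merged
  b <- bicluster(paste0("r", 1:4), paste0("c", 2:5), rep(1, 4))
  out2 <- merge_biclusters(list(a, b), overlap = 0.7)
  expect_length(out2, 2L)
  expect_length(merge_biclusters(list(a, b), overlap = 0.55), 1L)

  disjoint <- bicluster(paste0("q", 1:3), paste0("d", 1:3), rep(1, 3))
  expect_length(merge_biclusters(list(a, disjoint), overlap = 0.7), 2L)

  # merging is idempotent at the fixpoint
  once <- merge_biclusters(list(a, b, dup), overlap = 0.7)
  expect_equal(merge_biclusters(once, overlap = 0.7), once)
})

make_block_disc <- function() {
  # 10 x 6 symbolic matrix with a 4-row constant block on cols c1..c3
  set.seed(5)
  prim <- matrix(sample(-1:1, 60, replace = TRUE), 10, 6,
                 dimnames = list(paste0("r", 1:10), paste0("c", 1:6)))
  prim[1:4, 1:3] <- rep(c(1L, -1L, 0L), each = 4)
  prim[5, 1:3] <- c(1L, -1L, 99L)  # matches 2 of 3 positions
  prim[5, 4:6] <- 7L
  structure(list(primary = prim,
                 secondary = matrix(NA_integer_, 10, 6, dimnames = dimnames(prim)),
                 model = list(alphabet = -1:1, n_items = 3L), alpha = 0),
            class = "disc_matrix")
}

test_that("extension adds rows by match fraction; tolerance 0 means exact", {
  disc <- make_block_disc()
  b <- bicluster(paste0("r", 1:4), paste0("c", 1:3), c(1, -1, 0))
  ext0 <- extend_bicluster(b, disc, tolerance = 0)
  expect_false("r5" %in% ext0$rows)
  # r5 matches 2 of 3 pattern columns: added once tolerance admits 2/3
  ext <- extend_bicluster(b, disc, tolerance = 0.4)
  expect_true("r5" %in% ext$rows)
})

test_that("reduction drops poorly matching rows and is identity on clean blocks", {
  disc <- make_block_disc()
  clean <- bicluster(paste0("r", 1:4), paste0("c", 1:3), c(1, -1, 0))
  expect_equal(reduce_bicluster(clean, disc, tolerance = 0)[1:3], clean[1:3])
  noisy <- bicluster(paste0("r", c(1:4, 5)), paste0("c", 1:3), c(1, -1, 0))
  red <- reduce_bicluster(noisy, disc, tolerance = 0)
  expect_false("r5" %in% red$rows)
})

test_that("significance is the upper binomial tail of the pattern probability", {
  # a pattern spanning every row of a constant column has probability 1
  prim <- matrix(0L, 20, 2, dimnames = list(paste0("r", 1:20), c("c1", "c2")))
  disc <- structure(list(primary = prim,
                         secondary = matrix(NA_integer_, 20, 2, dimnames = dimnames(prim)),
                         model = list(alphabet = -1:1, n_items = 3L), alpha = 0),
                    class = "disc_matrix")
  b <- bicluster(paste0("r", 1:20), c("c1", "c2"), c(0, 0))
  expect_equal(bicluster_significance(b, disc), 1)

  # |I| = 5, n = 100, p_phi = 0.01 -> P(Bin(100, 0.01) >= 5)
  prim2 <- matrix(1L, 100, 2, dimnames = list(paste0("r", 1:100), c("c1", "c2")))
  prim2[11:100, 1] <- 0L  # f(c1 = 1) = 0.1
  prim2[11:100, 2] <- 2L  # f(c2 = 1) = 0.1
  disc2 <- structure(list(primary = prim2,
                          secondary = matrix(NA_integer_, 100, 2, dimnames = dimnames(prim2)),
                          model = list(alphabet = 0:2, n_items = 3L), alpha = 0),
                     class = "disc_matrix")
  b2 <- bicluster(paste0("r", 1:5), c("c1", "c2"), c(1, 1))
  expect_equal(bicluster_significance(b2, disc2),
               pbinom(4, 100, 0.01, lower.tail = FALSE), tolerance = 1e-12)

  # the tail is non-increasing in |I| at fixed p_phi
  b3 <- bicluster(paste0("r", 1:8), c("c1", "c2"), c(1, 1))
  expect_lte(bicluster_significance(b3, disc2), bicluster_significance(b2, disc2))
})

test_that("filtering drops insignificant and dominated biclusters", {
  big <- bicluster(paste0("r", 1:10), paste0("c", 1:5), rep(1, 5), p_value = 1e-10)
  inside <- bicluster(paste0("r", 1:8), paste0("c", 1:4), rep(1, 4), p_value = 1e-6)
  weak <- bicluster(paste0("q", 1:3), paste0("d", 1:3), rep(1, 3), p_value = 0.5)
  other <- bicluster(paste0("s", 1:6), paste0("e", 1:4), rep(1, 4), p_value = 1e-8)
  out <- filter_biclusters(list(big, inside, weak, other), filter_overlap = 0.6,
                           alpha = 0.01, n_tests = 4)
  labs <- vapply(out, function(b) b$rows[1], character(1))
  expect_true("r1" %in% labs)   # the big one is retained
  expect_true("s1" %in% labs)   # dissimilar significant one retained
  expect_equal(sum(labs == "r1"), 1L)  # the nested one is dominated
  expect_false(any(vapply(out, function(b) b$p_value >= 0.01, logical(1))))
  # p-values are Bonferroni-corrected
  expect_equal(out[[1]]$p_value, 1e-10 * 4)

  expect_length(filter_biclusters(list(weak), alpha = 0.01), 0L)
})

test_that("the pipeline recovers a planted block in a small random matrix", {
  set.seed(21)
  m <- matrix(runif(50 * 20), 50, 20,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:20)))
  rows <- paste0("g", 1:10)
  cols <- paste0("s", c(2, 5, 9, 14, 18))
  kj <- c(0.95, 0.1, 0.5, 0.8, 0.05)
  m[rows, cols] <- rep(kj, each = 10)
  sol <- run_bic2pam(m, bic2pam_config(n_items = 5, seed = 3))
  expect_gte(length(sol$biclusters), 1L)
  planted <- list(rows = rows, cols = cols)
  best <- max(vapply(sol$biclusters, function(b) bic2pam:::cell_jaccard(b, planted),
                     numeric(1)))
  expect_gte(best, 0.9)
})

test_that("a stop target of one bicluster halts after the first productive round", {
  set.seed(22)
  m <- matrix(runif(40 * 12), 40, 12,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:12)))
  m[paste0("g", 1:12), paste0("s", 1:5)] <- rep(c(0.9, 0.1, 0.5, 0.75, 0.2), each = 12)
  sol <- run_bic2pam(m, bic2pam_config(n_items = 5, stop_biclusters = 1L, seed = 3))
  expect_gte(length(sol$biclusters), 1L)
})

test_that("solutions are deterministic given the same inputs and seed", {
  set.seed(23)
  m <- matrix(runif(40 * 12), 40, 12,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:12)))
  m[paste0("g", 1:12), paste0("s", 1:5)] <- rep(c(0.9, 0.1, 0.5, 0.75, 0.2), each = 12)
  s1 <- run_bic2pam(m, bic2pam_config(n_items = 5, seed = 7))
  s2 <- run_bic2pam(m, bic2pam_config(n_items = 5, seed = 7))
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_solution(s1, f1); write_solution(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("returned biclusters satisfy inputted constraints post hoc", {
  set.seed(24)
  m <- matrix(runif(60 * 15), 60, 15,
              dimnames = list(paste0("g", 1:60), paste0("s", 1:15)))
  m[paste0("g", 1:15), paste0("s", 1:5)] <- rep(c(0.97, 0.9, 0.95, 0.92, 0.99), each = 15)
  m[paste0("g", 30:45), paste0("s", 8:12)] <- rep(c(0.03, 0.1, 0.05, 0.02, 0.08), each = 16)
  cst <- parse_constraint("max(pattern) <= 0")
  sol <- run_bic2pam(m, bic2pam_config(n_items = 5, seed = 3), constraints = list(cst))
  expect_gte(length(sol$biclusters), 1L)
  for (b in sol$biclusters) expect_lte(max(b$pattern), 0)
  audit <- attr(sol, "report")$constraint_audit
  expect_true(audit[[1]]$all_pass)
})

test_that("unbound constraint symbols fail before mining", {
  m <- matrix(runif(20 * 6), 20, 6,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:6)))
  expect_error(
    run_bic2pam(m, bic2pam_config(n_items = 3, seed = 1),
                constraints = parse_constraint("items superset {zz.9}")),
    "not present")
})

test_that("uninformative-symbol removal keeps removed symbols out of patterns", {
  set.seed(26)
  m <- matrix(runif(60 * 15), 60, 15,
              dimnames = list(paste0("g", 1:60), paste0("s", 1:15)))
  m[paste0("g", 1:15), paste0("s", 1:5)] <- rep(c(0.97, 0.9, 0.95, 0.92, 0.99), each = 15)
  sol <- run_bic2pam(m, bic2pam_config(n_items = 5, removed_symbols = 0, seed = 3))
  for (b in sol$biclusters) expect_false(0 %in% b$pattern)
})

test_that("order-preserving runs return shared column orderings", {
  set.seed(27)
  m <- matrix(runif(40 * 8), 40, 8,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:8)))
  ord <- c("s3", "s1", "s6", "s2", "s8")
  for (g in paste0("g", 1:14)) m[g, ord] <- sort(runif(5)) + seq(0, 4) * 2
  sol <- run_bic2pam(m, bic2pam_config(coherency = "order-preserving",
                                       min_cols = 4L, seed = 3))
  expect_gte(length(sol$biclusters), 1L)
  b <- sol$biclusters[[1]]
  expect_equal(b$coherency, "order-preserving")
  expect_true(all(paste0("g", 1:14) %in% b$rows) ||
                length(intersect(b$rows, paste0("g", 1:14))) >= 10)
})
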