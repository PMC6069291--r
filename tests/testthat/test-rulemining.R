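make_abc_db <- function() {
  # "d" is in the universe but occurs in no transaction
  transaction_db(list(p1 = c("a", "b"), p2 = c("a", "b", "c"),
                      p3 = c("b", "c"), p4 = "a"),
                 items = c("a", "b", "c", "d"))
}

test_that("support and confidence match direct enumeration", {
  db <- make_abc_db()
  expect_equal(rule_support(db, "a", "b"), 0.5)
  expect_equal(rule_confidence(db, "a", "b"), 2 / 3)
  expect_equal(rule_support(db, "b", character(0)), 0.75)
  expect_equal(rule_support(db, "a", c("b", "c")), 0.25)
  expect_equal(rule_confidence(db, "b", "a"), 2 / 3)
  # boundary values
  expect_equal(rule_confidence(db, c("a", "c"), "b"), 1)
  expect_equal(rule_support(db, "c", "d"), 0)
  expect_error(rule_confidence(db, "d", "a"), "no transaction")
  empty <- transaction_db(list(), c("a"))
  expect_error(rule_support(empty, "a"), "empty")
  expect_error(mine_top_k(empty), "empty")
})

test_that("rule sets enforce non-empty disjoint itemsets and unique identity", {
  expect_error(rule_set(list(c("a")), list(c("a", "b")), 1, 1, 2),
               "disjoint")
  expect_error(rule_set(list(character(0)), list("b"), 1, 1, 2),
               "non-empty")
  expect_error(rule_set(list("a", "a"), list("b", "b"), c(1, 1), c(1, 1),
                        c(2, 2)), "duplicate")
  rs <- rule_set(list(c("b", "a")), list("c"), 1L, 2L, 4L)
  expect_equal(rs$antecedent, "a|b")  # items stored sorted
  expect_equal(rs$support, 0.25)
  expect_equal(rs$confidence, 0.5)
})

test_that("exhaustive rule enumeration matches hand-computed examples", {
  db2 <- transaction_db(list(t1 = c("a", "b"), t2 = c("a", "b")),
                        items = c("a", "b"))
  r <- enumerate_valid_rules(db2, miner_params(k = 10, minconf = 0.6,
                                               max_rule_size = 2))
  expect_equal(nrow(r), 2)
  expect_setequal(rule_keys(r), c("a => b", "b => a"))
  expect_true(all(r$support == 1 & r$confidence == 1))

  db3 <- transaction_db(list(t1 = c("a", "b"), t2 = "a"),
                        items = c("a", "b"))
  r3 <- enumerate_valid_rules(db3, miner_params(k = 10, minconf = 1,
                                                max_rule_size = 2))
  expect_equal(rule_keys(r3), "b => a")

  empty_universe <- transaction_db(list(t1 = character(0)), character(0))
  expect_equal(nrow(enumerate_valid_rules(empty_universe)), 0)
})

test_that("redundancy needs equal metrics plus the subset structure", {
  r_a <- rule_set(list(c("a", "d")), list("b"), 4L, 5L, 10L)
  r_b <- rule_set(list("a"), list(c("b", "c")), 4L, 5L, 10L)
  expect_true(is_redundant(r_a, r_b))
  expect_false(is_redundant(r_b, r_a))  # direction matters
  r_c <- rule_set(list(c("a", "d")), list("b"), 3L, 5L, 10L)
  expect_false(is_redundant(r_c, r_b))  # support differs
  expect_false(is_redundant(r_a, r_a))  # never self-redundant
  # equal ratios but different counts over the same cohort differ exactly
  r_d <- rule_set(list("a"), list(c("b", "c")), 8L, 10L, 10L)
  expect_false(is_redundant(r_a, r_d))  # 4/10 vs 8/10 support
})

test_that("top-k mining prefers support and respects k", {
  db <- transaction_db(
    setNames(c(rep(list(c("a", "b", "c")), 5), rep(list(c("a", "b")), 5)),
             paste0("p", 1:10)),
    items = c("a", "b", "c"))
  top <- mine_top_k(db, miner_params(k = 2, minconf = 0.6,
                                     max_rule_size = 3))
  expect_equal(nrow(top), 2)
  expect_setequal(rule_keys(top), c("a => b", "b => a"))
  expect_true(all(top$support == 1))
  # k larger than available returns everything valid and non-redundant
  all_rules <- mine_top_k(db, miner_params(k = 1000, minconf = 0.6,
                                           max_rule_size = 3))
  expect_lt(nrow(all_rules), 1000)
  expect_gt(nrow(all_rules), 2)
  # no rule reaches the confidence floor
  db_lo <- transaction_db(list(t1 = c("a", "b"), t2 = "a", t3 = "b",
                               t4 = character(0)),
                          items = c("a", "b"))
  expect_equal(nrow(mine_top_k(db_lo, miner_params(k = 5, minconf = 0.9,
                                                   max_rule_size = 2))), 0)
})

test_that("rule sorting is support, then confidence, then lexicographic", {
  rs <- rule_set(list("a", "b", "c", "d"), list("x", "x", "x", "x"),
                 c(5L, 7L, 5L, 5L), c(10L, 11L, 6L, 6L),
                 rep(10L, 4))
  s <- sort_rules(rs)
  expect_equal(s$antecedent, c("b", "c", "d", "a"))
  # b first (support .7); c and d tie on support and confidence, broken
  # lexicographically; a last (conf .5)
  expect_equal(s$support[1], 0.7)
})

test_that("stored metrics equal recomputation from the database", {
  db <- random_db(101)
  rules <- mine_top_k(db, miner_params(k = 50, minconf = 0.5,
                                       max_rule_size = 4))
  for (i in seq_len(nrow(rules))) {
    X <- strsplit(rules$antecedent[i], "|", fixed = TRUE)[[1]]
    Y <- strsplit(rules$consequent[i], "|", fixed = TRUE)[[1]]
    expect_equal(rules$support[i], rule_support(db, X, Y))
    expect_equal(rules$confidence[i], rule_confidence(db, X, Y))
  }
  expect_true(all(rules$support <= rules$confidence))
  expect_true(all(rules$confidence <= 1))
  expect_true(all(rules$support > 0))
})

test_that("support is anti-monotone in the antecedent", {
  db <- random_db(202)
  p <- miner_params(k = 200, minconf = 0.5, max_rule_size = 4)
  rules <- enumerate_valid_rules(db, p)
  for (i in seq_len(min(nrow(rules), 40))) {
    X <- strsplit(rules$antecedent[i], "|", fixed = TRUE)[[1]]
    Y <- strsplit(rules$consequent[i], "|", fixed = TRUE)[[1]]
    extra <- setdiff(db$items, c(X, Y))
    if (length(extra) == 0) next
    expect_lte(rule_support(db, c(X, extra[1]), Y),
               rule_support(db, X, Y))
  }
})

test_that("mined output contains no redundant pair", {
  for (seed in c(11, 12, 13)) {
    db <- random_db(seed)
    rules <- mine_top_k(db, miner_params(k = 30, minconf = 0.5,
                                         max_rule_size = 4))
    if (nrow(rules) < 2) next
    any_redundant <- FALSE
    for (a in seq_len(nrow(rules))) {
      for (b in seq_len(nrow(rules))) {
        if (a != b && is_redundant(rules[a, ], rules[b, ])) {
          any_redundant <- TRUE
        }
      }
    }
    expect_false(any_redundant)
  }
})

test_that("large-universe fallback engine agrees with the compiled path", {
  # padding the universe with never-occurring items pushes the miner
  # onto the pure-R engine; results must match the compact universe
  db <- random_db(55, n_items = 10, n_trans = 40)
  pad <- sprintf("pad%02d", 1:60)
  db_wide <- transaction_db(db$transactions, c(db$items, pad))
  p <- miner_params(k = 25, minconf = 0.5, max_rule_size = 4)
  for (mode in c("exact", "tnr_search")) {
    p$mode <- mode
    expect_identical(
      as.data.frame(mine_top_k(db_wide, p)),
      as.data.frame(mine_top_k(db, p)))
  }
})

test_that("rule sets round-trip through CSV", {
  db <- random_db(33)
  rules <- mine_top_k(db, miner_params(k = 20, minconf = 0.5,
                                       max_rule_size = 3))
  f <- withr::local_tempfile(fileext = ".csv")
  write_rules(rules, f)
  back <- read_rules(f)
  expect_identical(as.data.frame(back), as.data.frame(rules))
})
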