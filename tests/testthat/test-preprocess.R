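test_that("variable selection keeps yes/no clinical variables only", {
  d <- make_tiny_dictionary()
  sel <- select_variables(d)
  expect_setequal(sel$name, c("stroke15", "prev_hx_stroke", "htn2"))
  # age is numerical, fstk_type multi-valued: both excluded
  expect_false(any(c("age", "fstk_type") %in% sel$name))
  expect_equal(nrow(select_variables(d[0, ])), 0)
  # yes/no variable of category "other" is excluded
  d2 <- data_dictionary(data.frame(
    name = "consent", label = "gave consent", var_type = "categorical",
    domain_raw = "yes|no", category = "other", stringsAsFactors = FALSE))
  expect_equal(nrow(select_variables(d2)), 0)
  # an extra unknown token in the domain does not disqualify
  d3 <- data_dictionary(data.frame(
    name = "x", label = "x", var_type = "categorical",
    domain_raw = "no|yes|unknown", category = "medication",
    stringsAsFactors = FALSE))
  expect_equal(select_variables(d3)$name, "x")
})

test_that("visit combination takes yes over no over unknown", {
  tb <- patient_table(data.frame(
    patient_id = rep(c("p1", "p2", "p3"), each = 2),
    visit_id = rep(c("baseline", "followup"), 3),
    med1c1 = c("yes", "no", "no", "no", "unknown", "unknown"),
    stringsAsFactors = FALSE))
  cmb <- combine_visits(tb)
  expect_equal(nrow(cmb), 3)
  expect_equal(cmb$med1c1, c("yes", "no", "unknown"))
  # partial missingness resolves to the observed answer
  tb2 <- patient_table(data.frame(
    patient_id = c("p1", "p1"), visit_id = c("v1", "v2"),
    v = c("unknown", "no"), stringsAsFactors = FALSE))
  expect_equal(combine_visits(tb2)$v, "no")
})

test_that("variable merging ORs siblings into the canonical variable", {
  tb <- patient_table(data.frame(
    patient_id = c("p1", "p2", "p3"), visit_id = "combined",
    stroke15 = c("no", "no", "unknown"),
    prev_hx_stroke = c("yes", "no", "unknown"),
    htn2 = c("yes", "no", "no"),
    stringsAsFactors = FALSE))
  merged <- merge_variables(tb, make_tiny_mapping())
  expect_setequal(table_variables(merged), c("strokehist", "htn"))
  expect_equal(merged$strokehist, c("yes", "no", "unknown"))
  expect_equal(merged$htn, c("yes", "no", "no"))
})

test_that("unknown is the identity of the merge operator", {
  for (x in c("yes", "no")) {
    tb <- patient_table(data.frame(
      patient_id = "p1", visit_id = "v1",
      stroke15 = x, prev_hx_stroke = "unknown",
      stringsAsFactors = FALSE))
    expect_equal(merge_variables(tb, make_tiny_mapping())$strokehist, x)
  }
})

test_that("preprocessing commutes with patient-row permutation", {
  set.seed(7)
  tb <- patient_table(data.frame(
    patient_id = rep(paste0("p", 1:6), each = 2),
    visit_id = rep(c("v1", "v2"), 6),
    stroke15 = sample(c("yes", "no", "unknown"), 12, TRUE),
    prev_hx_stroke = sample(c("yes", "no", "unknown"), 12, TRUE),
    htn2 = sample(c("yes", "no", "unknown"), 12, TRUE),
    stringsAsFactors = FALSE))
  perm <- sample(nrow(tb))
  tbp <- patient_table(as.data.frame(tb)[perm, ])
  a <- merge_variables(combine_visits(tb), make_tiny_mapping())
  b <- merge_variables(combine_visits(tbp), make_tiny_mapping())
  da <- as.data.frame(a)
  db <- as.data.frame(b)[match(a$patient_id, b$patient_id), ]
  rownames(db) <- NULL
  expect_identical(da, db)
})

test_that("constrained transactions keep satisfying patients minus the constraint item", {
  tb <- make_tiny_table()  # strokehist yes,yes,no; htn yes,no,yes
  db <- build_transactions(tb, query_constraint("strokehist"), "merged")
  expect_equal(n_transactions(db), 2)
  expect_equal(db$items, "htn")
  expect_equal(db$transactions, list(p1 = "htn", p2 = character(0)))
  # no constraint: everything retained
  db0 <- build_transactions(tb, NULL, "merged")
  expect_equal(n_transactions(db0), 3)
  expect_setequal(db0$items, c("strokehist", "htn"))
  expect_error(build_transactions(tb, query_constraint("nope"), "merged"),
               "no column")
})

test_that("complement transactions partition the cohort with the same universe", {
  tb <- make_tiny_table()
  q <- query_constraint("strokehist")
  db_o <- build_transactions(tb, q, "merged")
  db_n <- complement_transactions(tb, q, "merged")
  expect_equal(db_n$transactions, list(p3 = "htn"))
  expect_length(intersect(names(db_o$transactions),
                          names(db_n$transactions)), 0)
  expect_setequal(c(names(db_o$transactions), names(db_n$transactions)),
                  tb$patient_id)
  expect_false("strokehist" %in% c(db_o$items, db_n$items,
                                   unlist(db_o$transactions),
                                   unlist(db_n$transactions)))
})

test_that("unmerged constraints are evaluated at the canonical level", {
  tb <- combine_visits(make_tiny_raw_table())
  q <- query_constraint("strokehist")
  mp <- make_tiny_mapping()
  db <- build_transactions(tb, q, "unmerged", mapping = mp)
  # p1 (stroke15 yes) and p2 (prev_hx_stroke yes) satisfy; both mapped
  # columns leave the universe
  expect_setequal(names(db$transactions), c("p1", "p2"))
  expect_equal(db$items, "htn2")
  dbn <- complement_transactions(tb, q, "unmerged", mapping = mp)
  expect_setequal(names(dbn$transactions), c("p3", "p4"))
  # patients with unknown constraint status fall in the complement
  expect_true("p4" %in% names(dbn$transactions))
})

test_that("cohort-size gate is a simple threshold", {
  tr <- setNames(rep(list(character(0)), 20), paste0("p", 1:20))
  db <- transaction_db(tr, character(0))
  expect_true(check_cohort_size(db, 20))
  db19 <- transaction_db(tr[1:19], character(0))
  expect_false(check_cohort_size(db19, 20))
  expect_false(check_cohort_size(transaction_db(list(), character(0)), 20))
})

test_that("transaction databases round-trip through text and matrix forms", {
  db <- transaction_db(list(p1 = c("a", "c"), p2 = character(0), p3 = "b"),
                       items = c("a", "b", "c", "d"))
  f <- withr::local_tempfile()
  write_transactions(db, f)
  db2 <- read_transactions(f)
  expect_identical(db2$transactions, db$transactions)
  expect_identical(db2$items, db$items)
  m <- as_incidence_matrix(db)
  expect_equal(dim(m), c(3, 4))
  db3 <- from_incidence_matrix(m)
  expect_identical(db3$transactions, db$transactions)
})
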