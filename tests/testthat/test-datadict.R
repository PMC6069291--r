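test_that("patient tables read from CSV with token normalization", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,visit_id,stroke,htn",
               "p1,v1,yes,1",
               "p2,v1,no,0",
               "p3,v1,NA,"), f)
  tb <- read_patient_table(f)
  expect_s3_class(tb, "patient_table")
  expect_equal(nrow(tb), 3)
  expect_equal(tb$stroke, c("yes", "no", "unknown"))
  expect_equal(tb$htn, c("yes", "no", "unknown"))
})

test_that("a file without a visit column is one visit; missing id column errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,stroke", "p1,Y", "p2,N"), f)
  tb <- read_patient_table(f)
  expect_equal(unique(tb$visit_id), "v1")
  expect_equal(tb$stroke, c("yes", "no"))
  expect_error(read_patient_table(f, id_col = "subject"), "patient-id column")
})

test_that("unmappable tokens are reported and duplicate rows rejected", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,visit_id,stroke", "p1,v1,maybe"), f)
  expect_error(read_patient_table(f), "maybe")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,visit_id,stroke", "p1,v1,yes", "p1,v1,no"), f2)
  expect_error(read_patient_table(f2), "duplicate")
})

test_that("dictionaries parse domains and enforce invariants", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,label,type,domain,category",
               "stroke15,MD reported stroke,categorical,yes|no,medical_history",
               "age,age,numerical,,other"), f)
  d <- read_dictionary(f)
  expect_equal(d$domain[[1]], c("yes", "no"))
  expect_equal(d$var_type[2], "numerical")
  expect_length(d$domain[[2]], 0)

  writeLines(c("name,label,type,domain,category",
               "stroke15,a,categorical,yes|no,medical_history",
               "stroke15,b,categorical,yes|no,medical_history"), f)
  expect_error(read_dictionary(f), "duplicate")
  writeLines(c("name,label,type,domain,category",
               "x,a,fancy,yes|no,medical_history"), f)
  expect_error(read_dictionary(f), "unknown variable type")
})

test_that("mappings allow many dataset variables per canonical but not the converse", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("canonical_name,canonical_label,dataset_name",
               "strokehist,stroke - history,stroke15",
               "strokehist,stroke - history,prev_hx_stroke"), f)
  mp <- read_mapping(f)
  expect_equal(length(unique(mp$canonical_name)), 1)
  expect_setequal(mapped_variables(mp, "strokehist"),
                  c("stroke15", "prev_hx_stroke"))

  writeLines("canonical_name,canonical_label,dataset_name", f)
  expect_equal(nrow(read_mapping(f)), 0)

  writeLines(c("canonical_name,canonical_label,dataset_name",
               "a,a,x", "b,b,x"), f)
  expect_error(read_mapping(f), "more than one canonical")
})

test_that("loaded structures round-trip through their writers", {
  tb <- make_tiny_raw_table()
  d <- make_tiny_dictionary()
  mp <- make_tiny_mapping()
  ft <- withr::local_tempfile(fileext = ".csv")
  fd <- withr::local_tempfile(fileext = ".csv")
  fm <- withr::local_tempfile(fileext = ".csv")
  write_patient_table(tb, ft)
  write_dictionary(d, fd)
  write_mapping(mp, fm)
  expect_identical(as.data.frame(read_patient_table(ft)), as.data.frame(tb))
  expect_identical(as.data.frame(read_dictionary(fd)), as.data.frame(d))
  expect_identical(as.data.frame(read_mapping(fm)), as.data.frame(mp))
})

test_that("imbalance rate is the yes proportion among yes/no answers", {
  tb <- patient_table(data.frame(
    patient_id = paste0("p", 1:1000), visit_id = "v1",
    stroke = c(rep("yes", 33), rep("no", 967)),
    mixed = c(rep("yes", 5), rep("no", 5), rep("unknown", 990)),
    zero = c(rep("no", 10), rep("unknown", 990)),
    blank = rep("unknown", 1000),
    stringsAsFactors = FALSE))
  expect_equal(imbalance_rate(tb, "stroke"), 3.3)
  expect_equal(imbalance_rate(tb, "mixed"), 50)
  expect_equal(imbalance_rate(tb, "zero"), 0)
  expect_error(imbalance_rate(tb, "blank"), "undefined")
  expect_equal(mean_imbalance_rate(tb, c("stroke", "mixed", "zero")),
               mean(c(3.3, 50, 0)))
})

test_that("imbalance rates stay within [0, 100] on random tables", {
  set.seed(42)
  for (i in 1:20) {
    vals <- sample(c("yes", "no", "unknown"), 50, replace = TRUE,
                   prob = c(.1, .8, .1))
    if (sum(vals != "unknown") == 0) next
    tb <- patient_table(data.frame(patient_id = paste0("p", 1:50),
                                   visit_id = "v1", v = vals,
                                   stringsAsFactors = FALSE))
    r <- imbalance_rate(tb, "v")
    expect_gte(r, 0)
    expect_lte(r, 100)
  }
})
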