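# Shared miniature fixtures, built in code.

make_tiny_table <- function() {
  patient_table(data.frame(
    patient_id = c("p1", "p2", "p3"),
    visit_id = "v1",
    strokehist = c("yes", "yes", "no"),
    htn = c("yes", "no", "yes"),
    stringsAsFactors = FALSE))
}

make_tiny_dictionary <- function() {
  data_dictionary(data.frame(
    name = c("stroke15", "prev_hx_stroke", "htn2", "age", "fstk_type"),
    label = c("MD reported stroke", "previous history of stroke",
              "hypertension", "age at visit", "type of fatal stroke"),
    var_type = c("categorical", "categorical", "categorical", "numerical",
                 "categorical"),
    domain_raw = c("yes|no", "yes|no", "yes|no", "",
                   "hemorrhagic|ischemic|unknown"),
    category = c("medical_history", "medical_history", "medical_history",
                 "other", "medical_history"),
    stringsAsFactors = FALSE))
}

make_tiny_mapping <- function() {
  canonical_mapping(data.frame(
    canonical_name = c("strokehist", "strokehist", "htn"),
    canonical_label = c("stroke - history", "stroke - history",
                        "hypertension - history"),
    dataset_name = c("stroke15", "prev_hx_stroke", "htn2"),
    stringsAsFactors = FALSE))
}

# raw two-visit table over the tiny dictionary's selected variables
make_tiny_raw_table <- function() {
  patient_table(data.frame(
    patient_id = rep(c("p1", "p2", "p3", "p4"), each = 2),
    visit_id = rep(c("v1", "v2"), 4),
    stroke15       = c("no", "yes",  "no", "no",  "no", "no",  "unknown", "unknown"),
    prev_hx_stroke = c("no", "no",   "yes", "no", "no", "no",  "unknown", "unknown"),
    htn2           = c("yes", "no",  "no", "no",  "no", "yes", "yes", "no"),
    stringsAsFactors = FALSE))
}

expect_rule_in <- function(rules, ant, con) {
  key <- paste(paste(sort(ant), collapse = "|"),
               paste(sort(con), collapse = "|"), sep = " => ")
  expect_true(key %in% rule_keys(rules),
              label = sprintf("rule %s present", key))
}
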