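# Independent brute-force oracle for top-k non-redundant rule mining.
# Deliberately written with combn() enumeration and per-rule recounting,
# sharing no code with the package's miner.

oracle_count <- function(trans, Z) {
  sum(vapply(trans, function(t) all(Z %in% t), TRUE))
}

# every rule X -> Y with |X|+|Y| <= max_size, support > 0, conf >= minconf
oracle_all_rules <- function(trans, minconf, max_size) {
  items <- sort(unique(unlist(trans)))
  out <- list()
  sizes <- 2:min(max_size, length(items))
  if (length(items) < 2) sizes <- integer(0)
  for (size in sizes) {
    for (Z in utils::combn(items, size, simplify = FALSE)) {
      cz <- oracle_count(trans, Z)
      if (cz == 0) next
      for (xs in seq_len(size - 1)) {
        for (X in utils::combn(Z, xs, simplify = FALSE)) {
          cx <- oracle_count(trans, X)
          if (cz + 1e-9 >= minconf * cx) {
            out[[length(out) + 1L]] <- list(
              ant = X, con = setdiff(Z, X), sc = cz, ac = cx)
          }
        }
      }
    }
  }
  out
}

oracle_rule_df <- function(rules, n) {
  if (length(rules) == 0) {
    return(data.frame(antecedent = character(0), consequent = character(0),
                      support_count = integer(0),
                      antecedent_count = integer(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    antecedent = vapply(rules, function(r) paste(sort(r$ant), collapse = "|"), ""),
    consequent = vapply(rules, function(r) paste(sort(r$con), collapse = "|"), ""),
    support_count = vapply(rules, function(r) r$sc, 0L),
    antecedent_count = vapply(rules, function(r) r$ac, 0L),
    stringsAsFactors = FALSE)
}

# redundancy per definition: equal support and confidence (as exact
# fractions over a shared cohort), smaller antecedent, larger consequent
oracle_nonredundant <- function(df) {
  if (nrow(df) < 2) return(df)
  ants <- strsplit(df$antecedent, "|", fixed = TRUE)
  cons <- strsplit(df$consequent, "|", fixed = TRUE)
  drop <- rep(FALSE, nrow(df))
  for (a in seq_len(nrow(df))) {
    for (b in seq_len(nrow(df))) {
      if (a == b) next
      same <- df$antecedent[a] == df$antecedent[b] &&
        df$consequent[a] == df$consequent[b]
      if (same) next
      if (df$support_count[a] == df$support_count[b] &&
          df$support_count[a] * df$antecedent_count[b] ==
            df$support_count[b] * df$antecedent_count[a] &&
          all(ants[[b]] %in% ants[[a]]) &&
          all(cons[[a]] %in% cons[[b]])) {
        drop[a] <- TRUE
        break
      }
    }
  }
  df[!drop, , drop = FALSE]
}

oracle_top_k <- function(trans, k, minconf, max_size, n = length(trans)) {
  df <- oracle_rule_df(oracle_all_rules(trans, minconf, max_size), n)
  df <- oracle_nonredundant(df)
  df$support <- df$support_count / n
  df$confidence <- df$support_count / df$antecedent_count
  o <- order(-df$support, -df$confidence, df$antecedent, df$consequent,
             method = "radix")
  df <- df[o, , drop = FALSE]
  df <- utils::head(df, k)
  rownames(df) <- NULL
  df
}

# random sparse transaction database over a small universe
random_db <- function(seed, n_items = NULL, n_trans = NULL) {
  set.seed(seed)
  if (is.null(n_items)) n_items <- sample(4:12, 1)
  if (is.null(n_trans)) n_trans <- sample(8:50, 1)
  items <- letters[seq_len(n_items)]
  p <- stats::runif(n_items, 0.05, 0.5)
  tr <- lapply(seq_len(n_trans), function(i) items[stats::runif(n_items) < p])
  names(tr) <- paste0("t", seq_len(n_trans))
  transaction_db(tr, items)
}
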