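#' Construct a rule set
#'
#' A rule set is an ordered collection of association rules X -> Y.
#' Antecedent and consequent itemsets are stored as \code{"|"}-joined,
#' lexicographically sorted item strings; metrics are kept both as exact
#' integer counts (\code{support_count}, \code{antecedent_count},
#' \code{cohort_size}) and as the derived proportions \code{support} and
#' \code{confidence}.  Rule identity — used by all set operations — is the
#' pair (antecedent, consequent) only; metrics are excluded from identity.
#'
#' @param antecedent list of character vectors (or pre-joined strings).
#' @param consequent list of character vectors (or pre-joined strings).
#' @param support_count integer, transactions containing X and Y.
#' @param antecedent_count integer, transactions containing X.
#' @param cohort_size integer, total transactions in the mined database.
#' @return A data frame of class \code{rule_set} with one row per rule.
#' @export
rule_set <- function(antecedent = list(), consequent = list(),
                     support_count = integer(0),
                     antecedent_count = integer(0),
                     cohort_size = integer(0)) {
  ant <- .join_items(antecedent)
  con <- .join_items(consequent)
  if (length(ant) > 0) {
    ai <- .split_items(ant)
    ci <- .split_items(con)
    if (any(lengths(ai) == 0) || any(lengths(ci) == 0)) {
      stop("antecedent and consequent must be non-empty", call. = FALSE)
    }
    overlap <- mapply(function(a, b) length(intersect(a, b)) > 0, ai, ci)
    if (any(overlap)) {
      stop("antecedent and consequent must be disjoint", call. = FALSE)
    }
  }
  df <- data.frame(
    antecedent = ant, consequent = con,
    support_count = as.integer(support_count),
    antecedent_count = as.integer(antecedent_count),
    cohort_size = as.integer(cohort_size),
    stringsAsFactors = FALSE)
  df$support <- ifelse(df$cohort_size > 0,
                       df$support_count / df$cohort_size, NA_real_)
  df$confidence <- ifelse(df$antecedent_count > 0,
                          df$support_count / df$antecedent_count, NA_real_)
  if (anyDuplicated(rule_keys(df))) {
    stop("duplicate rules (same antecedent and consequent)", call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("rule_set", "data.frame")
  df
}

#' @keywords internal
.join_items <- function(x) {
  if (is.character(x)) x <- as.list(x)
  vapply(x, function(it) {
    paste(sort(unique(strsplit(paste(it, collapse = "|"), "|",
                               fixed = TRUE)[[1]])), collapse = "|")
  }, "")
}

#' @keywords internal
.split_items <- function(x) strsplit(x, "|", fixed = TRUE)

#' Identity keys of a rule set
#'
#' One string per rule, determined by (antecedent, consequent) only.
#' @param rules a \code{rule_set}.
#' @return Character vector of keys.
#' @export
rule_keys <- function(rules) {
  paste(rules$antecedent, rules$consequent, sep = " => ")
}

#' @export
print.rule_set <- function(x, n = 10, ...) {
  cat("Rule set: ", nrow(x), " rule(s)\n", sep = "")
  if (nrow(x) > 0) {
    shown <- utils::head(x, n)
    lines <- sprintf("  {%s} => {%s}  supp=%.3f conf=%.3f (%d/%d)",
                     gsub("|", ", ", shown$antecedent, fixed = TRUE),
                     gsub("|", ", ", shown$consequent, fixed = TRUE),
                     shown$support, shown$confidence,
                     shown$support_count, shown$cohort_size)
    cat(lines, sep = "\n")
    if (nrow(x) > n) cat("  ... and", nrow(x) - n, "more\n")
    cat("\n")
  }
  invisible(x)
}

#' Support of a rule in a transaction database
#'
#' The proportion of transactions containing every item of X and Y.
#'
#' @param db a \code{transaction_db}.
#' @param X,Y character vectors of item names (disjoint, within the item
#'   universe).
#' @return Proportion in \code{[0, 1]}.
#' @export
#' @examples
#' db <- transaction_db(list(p1 = c("a", "b"), p2 = c("a", "b", "c"),
#'                           p3 = c("b", "c"), p4 = "a"),
#'                      items = c("a", "b", "c"))
#' rule_support(db, "a", "b")     # 0.5
#' rule_confidence(db, "a", "b")  # 2/3
rule_support <- function(db, X, Y = character(0)) {
  n <- n_transactions(db)
  if (n == 0) stop("support undefined on an empty database", call. = FALSE)
  Z <- union(X, Y)
  extra <- setdiff(Z, db$items)
  if (length(extra) > 0) {
    stop("items outside universe: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  sum(vapply(db$transactions, function(t) all(Z %in% t), TRUE)) / n
}

#' Confidence of a rule in a transaction database
#'
#' The proportion of X-containing transactions that also contain Y.
#' Undefined (an error) when X occurs in no transaction.
#'
#' @inheritParams rule_support
#' @return Proportion in \code{[0, 1]}.
#' @export
rule_confidence <- function(db, X, Y) {
  n <- n_transactions(db)
  if (n == 0) stop("confidence undefined on an empty database", call. = FALSE)
  n_x <- sum(vapply(db$transactions, function(t) all(X %in% t), TRUE))
  if (n_x == 0) {
    stop("confidence undefined: antecedent occurs in no transaction",
         call. = FALSE)
  }
  n_xy <- sum(vapply(db$transactions, function(t) all(c(X, Y) %in% t), TRUE))
  n_xy / n_x
}

#' Sort rules by support, then confidence
#'
#' Descending support, then descending confidence, then lexicographically
#' on (antecedent, consequent) so that fully tied rules have a stable,
#' reproducible order.
#'
#' @param rules a \code{rule_set}.
#' @return The sorted \code{rule_set}.
#' @export
sort_rules <- function(rules) {
  if (nrow(rules) == 0) return(rules)
  o <- order(-rules$support, -rules$confidence,
             rules$antecedent, rules$consequent, method = "radix")
  out <- rules[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Test the miner's redundancy relation between two rules
#'
#' Rule \code{r_a} is redundant with respect to \code{r_b} when both hold:
#' (1) the two rules have exactly equal support and equal confidence, and
#' (2) the antecedent of \code{r_b} is a subset of the antecedent of
#' \code{r_a} while the consequent of \code{r_a} is a subset of the
#' consequent of \code{r_b} (minimum-condition / maximum-consequent
#' direction).  A rule is never redundant with itself.  Metric equality is
#' decided on the integer counts (cross-multiplication), not on floating
#' point values.
#'
#' @param r_a,r_b single-row \code{rule_set} data frames (or one-row
#'   subsets of a larger set).
#' @return \code{TRUE} or \code{FALSE}.
#' @export
is_redundant <- function(r_a, r_b) {
  stopifnot(nrow(r_a) == 1, nrow(r_b) == 1)
  if (r_a$antecedent == r_b$antecedent && r_a$consequent == r_b$consequent) {
    return(FALSE)
  }
  supp_eq <- r_a$support_count * r_b$cohort_size ==
    r_b$support_count * r_a$cohort_size
  conf_eq <- r_a$support_count * r_b$antecedent_count ==
    r_b$support_count * r_a$antecedent_count
  if (!supp_eq || !conf_eq) return(FALSE)
  ant_a <- .split_items(r_a$antecedent)[[1]]
  ant_b <- .split_items(r_b$antecedent)[[1]]
  con_a <- .split_items(r_a$consequent)[[1]]
  con_b <- .split_items(r_b$consequent)[[1]]
  all(ant_b %in% ant_a) && all(con_a %in% con_b)
}

#' @keywords internal
#' Drop every rule redundant w.r.t. another rule of the input set.
#' Redundancy needs exact metric equality, so candidates are grouped by
#' (support_count, reduced confidence fraction) and compared pairwise
#' within groups.  Scanning against the full input equals scanning against
#' retained rules only, because redundancy is transitive.
.remove_redundant <- function(rules) {
  if (nrow(rules) < 2) return(rules)
  g <- vapply(seq_len(nrow(rules)), function(i) {
    d <- .gcd(rules$support_count[i], rules$antecedent_count[i])
    paste(rules$support_count[i], rules$cohort_size[i],
          rules$support_count[i] %/% d, rules$antecedent_count[i] %/% d)
  }, "")
  drop <- rep(FALSE, nrow(rules))
  for (idx in split(seq_len(nrow(rules)), g)) {
    if (length(idx) < 2) next
    drop[idx] <- .structurally_dominated(
      .split_items(rules$antecedent[idx]),
      .split_items(rules$consequent[idx]))
  }
  out <- rules[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @keywords internal
#' For each rule i, whether some other rule j has ant_j a subset of ant_i
#' and con_i a subset of con_j.  Subset relations are computed for all
#' pairs at once from item-membership matrices: with A the antecedent
#' membership matrix, (A tcrossprod A)[j, i] equals |ant_j| exactly when
#' ant_j is a subset of ant_i.  Rules are assumed pairwise distinct in
#' (antecedent, consequent), so only the diagonal must be excluded.
.structurally_dominated <- function(ants, cons) {
  g <- length(ants)
  items <- unique(c(unlist(ants), unlist(cons)))
  A <- matrix(0, g, length(items))
  C <- matrix(0, g, length(items))
  A[cbind(rep(seq_len(g), lengths(ants)),
          match(unlist(ants), items))] <- 1
  C[cbind(rep(seq_len(g), lengths(cons)),
          match(unlist(cons), items))] <- 1
  ant_sub <- tcrossprod(A) == lengths(ants)        # [j,i]: ant_j subset of ant_i
  con_sub <- tcrossprod(C) == lengths(cons)        # [i,j]: con_i subset of con_j
  D <- ant_sub & t(con_sub)                        # [j,i]: j dominates i
  diag(D) <- FALSE
  colSums(D) > 0
}

#' @keywords internal
.gcd <- function(a, b) {
  while (b != 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  max(a, 1L)
}

#' Write / read a rule set as CSV
#'
#' Columns: antecedent and consequent (sorted, \code{"|"}-joined),
#' \code{support_count}, \code{antecedent_count}, \code{cohort_size},
#' \code{support}, \code{confidence}.
#'
#' @param rules a \code{rule_set}.
#' @param path output path.
#' @export
write_rules <- function(rules, path) {
  utils::write.csv(as.data.frame(rules), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    antecedent = "character", consequent = "character",
    support_count = "integer", antecedent_count = "integer",
    cohort_size = "integer", support = "numeric", confidence = "numeric"))
  rule_set(df$antecedent, df$consequent, df$support_count,
           df$antecedent_count, df$cohort_size)
}
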