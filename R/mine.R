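#' Miner parameters
#'
#' Bundles the knobs of the top-k non-redundant rule miner.  Top-k mining
#' replaces a user-chosen minimum-support threshold: the miner returns the
#' k highest-support rules whose confidence reaches \code{minconf}, after
#' discarding redundant rules.
#'
#' @param k number of rules to return (default 100).
#' @param minconf confidence floor in (0, 1] (default 0.6).
#' @param delta non-negative integer; in \code{tnr_search} mode the
#'   internal candidate buffer holds \code{k + delta} rules before final
#'   truncation, trading work for exactness.  Ignored in exact mode.
#' @param max_rule_size cap on \code{|antecedent| + |consequent|}
#'   (default 5).
#' @param mode \code{"tnr_search"} (the default: pruned search with a
#'   delta-inflated candidate buffer, the algorithm the pipeline is
#'   built around) or \code{"exact"} (full enumeration; the correctness
#'   reference, intended for desk-scale instances).
#' @return An object of class \code{miner_params}.
#' @export
miner_params <- function(k = 100, minconf = 0.6, delta = 10,
                         max_rule_size = 5,
                         mode = c("tnr_search", "exact")) {
  mode <- match.arg(mode)
  stopifnot(k >= 1, minconf > 0, minconf <= 1, delta >= 0,
            max_rule_size >= 2)
  structure(list(k = as.integer(k), minconf = minconf,
                 delta = as.integer(delta),
                 max_rule_size = as.integer(max_rule_size), mode = mode),
            class = "miner_params")
}

#' @export
print.miner_params <- function(x, ...) {
  cat(sprintf("Miner parameters: k=%d, minconf=%.2f, delta=%d, ",
              x$k, x$minconf, x$delta),
      sprintf("max rule size=%d, mode=%s\n", x$max_rule_size, x$mode),
      sep = "")
  invisible(x)
}

# Depth-first enumeration of itemsets present in the database (count > 0),
# up to `max_size` items, generating every rule X -> Y with
# X u Y = itemset, X, Y non-empty and confidence >= minconf.  Transaction
# id lists are carried as logical vectors; counts of every enumerated
# itemset are memoised so antecedent counts are O(1) lookups (a subset
# always has a count at least as large as its superset, hence is never
# pruned before it is needed).  When `buffer` is finite the minimum
# support count of interest rises once `buffer` candidate rules exist
# (top-k pruning by anti-monotonicity); ties with the boundary are kept.
.mine_rules_engine <- function(db, minconf, max_size, buffer = Inf) {
  n <- n_transactions(db)
  items <- db$items
  m <- length(items)
  acc <- new.env(parent = emptyenv())
  acc$ant <- vector("list", 256)
  acc$con <- vector("list", 256)
  acc$sc <- integer(256)
  acc$ac <- integer(256)
  acc$nr <- 0L
  acc$threshold <- 1L
  if (m == 0 || n == 0) {
    return(list(ant = list(), con = list(), sc = integer(0),
                ac = integer(0)))
  }
  if (m <= 62) {  # compiled search; itemsets as 62-bit masks
    idx <- lapply(db$transactions, function(t) match(t, items))
    res <- mine_rules_cpp(idx, m, minconf, max_size,
                          if (is.finite(buffer)) as.integer(buffer) else 0L)
    return(list(ant = lapply(res$ant, function(i) items[i]),
                con = lapply(res$con, function(i) items[i]),
                sc = res$sc, ac = res$ac))
  }
  inc <- as_incidence_matrix(db) == 1L
  counts <- new.env(hash = TRUE, parent = emptyenv())
  acc$next_check <- if (is.finite(buffer)) buffer else Inf
  # Buffer compaction: drop buffered rules redundant w.r.t. another
  # buffered rule (safe by transitivity of the redundancy relation), then
  # raise the support threshold to the support of the (k + delta)-th best
  # surviving candidate.  Thresholding on non-redundant candidates is
  # what keeps the search both fast and close to the exact result.
  compact <- function() {
    idx <- seq_len(acc$nr)
    idx <- idx[acc$sc[idx] >= acc$threshold]
    df <- rule_set(acc$ant[idx], acc$con[idx],
                   acc$sc[idx], acc$ac[idx], rep(n, length(idx)))
    df <- .remove_redundant(df)
    if (nrow(df) >= buffer) {
      s <- sort(df$support_count, decreasing = TRUE)
      acc$threshold <- max(acc$threshold, s[buffer])
    }
    df <- df[df$support_count >= acc$threshold, , drop = FALSE]
    pad <- vector("list", 256)
    acc$ant <- c(as.list(df$antecedent), pad)
    acc$con <- c(as.list(df$consequent), pad)
    acc$sc <- c(df$support_count, integer(256))
    acc$ac <- c(df$antecedent_count, integer(256))
    acc$nr <- nrow(df)
    acc$next_check <- acc$nr + max(buffer, 2048L)
  }
  push_rule <- function(X, Y, sc, ac) {
    i <- acc$nr + 1L
    if (i > length(acc$sc)) {
      grow <- length(acc$sc) * 2L
      length(acc$ant) <- grow
      length(acc$con) <- grow
      length(acc$sc) <- grow
      length(acc$ac) <- grow
    }
    acc$ant[[i]] <- X
    acc$con[[i]] <- Y
    acc$sc[i] <- sc
    acc$ac[i] <- ac
    acc$nr <- i
    if (i >= acc$next_check) compact()
  }
  single_counts <- colSums(inc)
  get_count <- function(zi) {
    if (length(zi) == 1L) return(single_counts[zi])
    key <- paste(zi, collapse = " ")
    v <- counts[[key]]
    if (is.null(v)) {
      v <- sum(rowSums(inc[, zi, drop = FALSE]) == length(zi))
      counts[[key]] <- v
    }
    v
  }
  # all non-trivial antecedent/consequent splits of an itemset of each
  # size, as logical membership rows, computed once
  split_masks <- lapply(seq_len(max_size), function(len) {
    if (len < 2L) return(NULL)
    do.call(rbind, lapply(seq_len(bitwShiftL(1L, len) - 2L), function(mask) {
      bitwAnd(bitwShiftR(mask, seq_len(len) - 1L), 1L) == 1L
    }))
  })
  gen_rules <- function(zi, cz) {
    mm <- split_masks[[length(zi)]]
    acs <- apply(mm, 1L, function(in_x) get_count(zi[in_x]))
    ok <- which(cz + 1e-9 >= minconf * acs)
    for (r in ok) {
      push_rule(items[zi[mm[r, ]]], items[zi[!mm[r, ]]], cz, acs[r])
    }
  }
  # transaction-id lists shrink along each DFS branch, so intersection
  # cost tracks the (sparse) co-occurrence counts, not the cohort size
  rec <- function(prefixi, ptid, start) {
    for (j in start:m) {
      t2 <- ptid[inc[ptid, j]]
      cz <- length(t2)
      if (cz == 0L || cz < acc$threshold) next
      zi <- c(prefixi, j)
      if (length(zi) >= 2L) {
        counts[[paste(zi, collapse = " ")]] <- cz
        gen_rules(zi, cz)
      }
      if (length(zi) < max_size && j < m) rec(zi, t2, j + 1L)
    }
  }
  rec(integer(0), seq_len(n), 1L)
  keep <- seq_len(acc$nr)
  if (is.finite(buffer)) keep <- keep[acc$sc[keep] >= acc$threshold]
  list(ant = acc$ant[keep], con = acc$con[keep],
       sc = acc$sc[keep], ac = acc$ac[keep])
}

#' Enumerate every valid rule of a transaction database
#'
#' The brute-force reference: all rules X -> Y with non-empty disjoint
#' itemsets, \code{|X| + |Y| <= max_rule_size}, support > 0 and
#' confidence at least \code{minconf}, with exact metrics attached.
#' Intended for desk-scale item universes; the result is sorted with
#' [sort_rules()].
#'
#' @param db a \code{transaction_db}.
#' @param params a [miner_params()].
#' @return A \code{rule_set}.
#' @export
enumerate_valid_rules <- function(db, params = miner_params()) {
  r <- .mine_rules_engine(db, params$minconf, params$max_rule_size)
  sort_rules(rule_set(r$ant, r$con, r$sc, r$ac,
                      rep(n_transactions(db), length(r$sc))))
}

#' Mine the top-k non-redundant association rules
#'
#' Returns at most \code{k} rules with confidence at least
#' \code{minconf}, none of which is redundant with respect to another
#' rule of the input rule space (see [is_redundant()]), chosen to
#' maximise support under the deterministic ordering of [sort_rules()].
#'
#' In \code{"tnr_search"} mode (the default) the search prunes itemsets
#' whose support falls below a rising threshold: the support of the
#' \code{(k + delta)}-th best candidate after periodic redundancy-aware
#' compaction of the buffer.  Rules tied with the boundary are retained.
#' In \code{"exact"} mode the miner enumerates every valid rule before
#' removing redundant ones and truncating — the correctness reference
#' the search is validated against; the two modes agree unless more than
#' \code{delta} top-stratum candidates are invalidated by late-found
#' dominating rules.  Rules tied at the k-th position are resolved by
#' the deterministic ordering, not all included.
#'
#' @inheritParams enumerate_valid_rules
#' @return A \code{rule_set} with at most \code{params$k} rows.
#' @export
#' @examples
#' db <- transaction_db(stats::setNames(
#'   c(rep(list(c("a", "b", "c")), 5), rep(list(c("a", "b")), 5)),
#'   paste0("p", 1:10)), items = c("a", "b", "c"))
#' mine_top_k(db, miner_params(k = 2, minconf = 0.6, max_rule_size = 3))
mine_top_k <- function(db, params = miner_params()) {
  if (n_transactions(db) == 0) {
    stop("cannot mine an empty transaction database", call. = FALSE)
  }
  buffer <- if (params$mode == "tnr_search") params$k + params$delta else Inf
  r <- .mine_rules_engine(db, params$minconf, params$max_rule_size, buffer)
  rules <- rule_set(r$ant, r$con, r$sc, r$ac,
                    rep(n_transactions(db), length(r$sc)))
  rules <- .remove_redundant(rules)
  out <- utils::head(sort_rules(rules), params$k)
  rownames(out) <- NULL
  out
}
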