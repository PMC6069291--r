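#' Remove general rules
#'
#' A rule mined in the constrained cohort is "general" when it also
#' belongs to the top-k set mined on the complement cohort (the patients
#' not satisfying the query constraint): it describes the population at
#' large, not the queried sub-cohort.  This operation computes
#' O - (O intersect N) under rule identity (antecedent, consequent),
#' preserving the order of O and the metrics measured on the constrained
#' cohort.
#'
#' @param O \code{rule_set} mined on the constrained cohort.
#' @param N \code{rule_set} mined on the complement cohort with the same
#'   miner parameters.
#' @return The surviving subset of \code{O}.
#' @export
remove_general <- function(O, N) {
  if (nrow(O) == 0 || nrow(N) == 0) return(O)
  out <- O[!(rule_keys(O) %in% rule_keys(N)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove structurally subsumed rules
#'
#' A rule r_a is subsumed by another rule r_b when the antecedent of r_b
#' is a subset of the antecedent of r_a and the consequent of r_a is a
#' subset of the consequent of r_b — r_b says at least as much from
#' weaker premises — regardless of whether their metrics agree (metric
#' equality is the extra condition of the miner's redundancy relation;
#' here only the structural condition applies).  Every subsumed rule is
#' removed, scanning against the full input set: a rule that is itself
#' removed can still subsume others, which by transitivity gives the same
#' survivors as scanning against maximal rules only.  Order is preserved
#' among survivors, and the operation is idempotent.
#'
#' @param rules a \code{rule_set}.
#' @return The non-subsumed subset.
#' @export
remove_subsumed <- function(rules) {
  if (nrow(rules) < 2) return(rules)
  drop <- .structurally_dominated(.split_items(rules$antecedent),
                                  .split_items(rules$consequent))
  out <- rules[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Jaccard similarity of two rule sets
#'
#' \code{|A intersect B| / |A union B|} under rule identity; 0 when both
#' sets are empty.
#'
#' @param A,B \code{rule_set}s.
#' @return Proportion in \code{[0, 1]}.
#' @export
jaccard_rules <- function(A, B) {
  ka <- unique(rule_keys(A))
  kb <- unique(rule_keys(B))
  u <- length(union(ka, kb))
  if (u == 0) return(0)
  length(intersect(ka, kb)) / u
}

#' @keywords internal
#' Rewrite rule items through the canonical mapping, collapsing sibling
#' dataset variables into one canonical item.  Items shared between the
#' canonicalized antecedent and consequent are kept on the antecedent
#' side and dropped from the consequent; rules whose consequent empties
#' out (they related a variable to its own sibling) are dropped, as are
#' duplicates created by the collapse.
.canonicalize_rules <- function(rules, mapping) {
  if (nrow(rules) == 0) return(rules)
  to_canonical <- function(items) {
    hit <- match(items, mapping$dataset_name)
    items[!is.na(hit)] <- mapping$canonical_name[hit[!is.na(hit)]]
    sort(unique(items))
  }
  ants <- lapply(.split_items(rules$antecedent), to_canonical)
  cons <- lapply(.split_items(rules$consequent), to_canonical)
  cons <- mapply(function(a, b) setdiff(b, a), ants, cons, SIMPLIFY = FALSE)
  keep <- lengths(cons) > 0
  ants <- ants[keep]
  cons <- cons[keep]
  sub <- rules[keep, , drop = FALSE]
  key <- paste(vapply(ants, paste, "", collapse = "|"),
               vapply(cons, paste, "", collapse = "|"), sep = " => ")
  first <- !duplicated(key)
  rule_set(ants[first], cons[first], sub$support_count[first],
           sub$antecedent_count[first], sub$cohort_size[first])
}

#' Compare merged-mode and unmerged-mode rule sets
#'
#' Quantifies how much the two preprocessing modes agree for one query.
#' Unmerged rules are first canonicalized — their dataset-variable items
#' are rewritten to canonical variables through the mapping, collapsing
#' sibling items — so that structurally equivalent rules are recognised.
#' Counts of common and mode-specific rules and the Jaccard similarity
#' are returned.
#'
#' @param O_merged final \code{rule_set} from a merged-mode run.
#' @param O_unmerged final \code{rule_set} from an unmerged-mode run of
#'   the same query.
#' @param mapping the \code{canonical_mapping} used by the merged run.
#' @return A list with components \code{n_common},
#'   \code{n_distinct_merged}, \code{n_distinct_unmerged} and
#'   \code{jaccard}.
#' @export
compare_methods <- function(O_merged, O_unmerged, mapping) {
  canon <- .canonicalize_rules(O_unmerged, mapping)
  km <- unique(rule_keys(O_merged))
  ku <- unique(rule_keys(canon))
  common <- intersect(km, ku)
  list(n_common = length(common),
       n_distinct_merged = length(setdiff(km, ku)),
       n_distinct_unmerged = length(setdiff(ku, km)),
       jaccard = jaccard_rules(O_merged, canon))
}
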