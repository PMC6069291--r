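#' Prepare a patient table for mining
#'
#' Applies the fixed preprocessing order: restrict to the dictionary's
#' selected yes/no variables, combine visits into one record per patient,
#' and (merged mode only) merge sibling dataset variables into canonical
#' variables.
#'
#' @param table a \code{patient_table} (possibly multi-visit).
#' @param dictionary a \code{data_dictionary}.
#' @param mapping a \code{canonical_mapping}.
#' @param mode \code{"merged"} or \code{"unmerged"}.
#' @return A one-row-per-patient \code{patient_table} whose columns are
#'   canonical variables (merged) or dataset variables (unmerged).
#' @export
prepare_table <- function(table, dictionary, mapping,
                          mode = c("merged", "unmerged")) {
  mode <- match.arg(mode)
  selected <- select_variables(dictionary)$name
  keep <- intersect(table_variables(table), selected)
  tab <- patient_table(as.data.frame(table)[, c("patient_id", "visit_id",
                                                keep), drop = FALSE])
  tab <- combine_visits(tab)
  if (mode == "merged") tab <- merge_variables(tab, mapping)
  tab
}

#' Enumerate eligible query constraints
#'
#' A canonical variable is an eligible query when it maps to at least one
#' selected dataset variable present in the table and at least
#' \code{min_patients} patients satisfy it (any mapped variable yes,
#' after visit combination).
#'
#' @param table a \code{patient_table}.
#' @param mapping a \code{canonical_mapping}.
#' @param dictionary a \code{data_dictionary}.
#' @param min_patients cohort-size gate (default 20).
#' @return Character vector of eligible canonical variable names.
#' @export
eligible_queries <- function(table, mapping, dictionary, min_patients = 20) {
  tab <- prepare_table(table, dictionary, mapping, mode = "unmerged")
  vars <- table_variables(tab)
  df <- as.data.frame(tab)
  out <- character(0)
  for (cn in unique(mapping$canonical_name)) {
    cols <- intersect(mapped_variables(mapping, cn), vars)
    if (length(cols) == 0) next
    n_yes <- sum(rowSums(df[, cols, drop = FALSE] == "yes") > 0)
    if (n_yes >= min_patients) out <- c(out, cn)
  }
  out
}

#' Run the full constraint-based mining pipeline for one query
#'
#' Executes, in order: variable selection, visit combination, (merged
#' mode) variable merging, constraint filtering and yes-item projection,
#' top-k non-redundant mining on the constrained cohort (rule set O),
#' the same mining on the complement cohort (rule set N), removal of
#' general rules (O - N), removal of subsumed rules, and the final
#' support/confidence sort.  Queries whose cohort is smaller than
#' \code{min_patients} yield a structured skip record rather than an
#' error.  The run is deterministic given its inputs.
#'
#' @param table a \code{patient_table} (raw, multi-visit allowed).
#' @param dictionary a \code{data_dictionary}.
#' @param mapping a \code{canonical_mapping}.
#' @param query canonical variable name, or a [query_constraint()].
#' @param params a [miner_params()].
#' @param min_patients minimum constrained-cohort size (default 20); the
#'   gate applies to the query cohort only — a small complement still
#'   participates in general-rule removal, with a warning.
#' @param mode \code{"merged"} (default) or \code{"unmerged"}.
#' @param dataset_label free-text label carried into outputs.
#' @param prepared set to \code{TRUE} when \code{table} is already the
#'   output of [prepare_table()] for this \code{mode} (skips
#'   re-preprocessing, e.g. inside [qarm_all()]).
#' @return An object of class \code{qarm_result}: the final
#'   \code{rule_set} plus per-stage counts (\code{n_top_k},
#'   \code{n_general_removed}, \code{n_subsumed_removed},
#'   \code{cohort_size}, \code{complement_size}) and a \code{skipped}
#'   flag.  The identity \code{n_top_k = nrow(rules) +
#'   n_general_removed + n_subsumed_removed} always holds.
#' @export
qarm <- function(table, dictionary, mapping, query,
                 params = miner_params(), min_patients = 20,
                 mode = c("merged", "unmerged"), dataset_label = "dataset",
                 prepared = FALSE) {
  mode <- match.arg(mode)
  if (!inherits(query, "query_constraint")) query <- query_constraint(query)
  tab <- if (prepared) table else prepare_table(table, dictionary, mapping, mode)
  db_o <- build_transactions(tab, query, mode = mode, mapping = mapping)
  empty_rules <- rule_set()
  res <- list(query = query$canonical_name, dataset_label = dataset_label,
              mode = mode, params = params,
              cohort_size = n_transactions(db_o),
              complement_size = NA_integer_,
              rules = empty_rules, n_top_k = 0L,
              n_general_removed = 0L, n_subsumed_removed = 0L,
              skipped = FALSE, reason = NA_character_)
  if (!check_cohort_size(db_o, min_patients)) {
    res$skipped <- TRUE
    res$reason <- sprintf("cohort size %d below the %d-patient gate",
                          n_transactions(db_o), min_patients)
    class(res) <- "qarm_result"
    return(res)
  }
  O <- mine_top_k(db_o, params)
  db_n <- complement_transactions(tab, query, mode = mode, mapping = mapping)
  res$complement_size <- n_transactions(db_n)
  if (n_transactions(db_n) == 0) {
    N <- empty_rules
  } else {
    if (n_transactions(db_n) < min_patients) {
      warning("complement cohort for ", query$canonical_name, " has only ",
              n_transactions(db_n), " patients; general-rule removal is ",
              "still performed", call. = FALSE)
    }
    N <- mine_top_k(db_n, params)
  }
  kept <- remove_general(O, N)
  final <- remove_subsumed(kept)
  res$rules <- sort_rules(final)
  res$n_top_k <- nrow(O)
  res$n_general_removed <- nrow(O) - nrow(kept)
  res$n_subsumed_removed <- nrow(kept) - nrow(final)
  class(res) <- "qarm_result"
  res
}

#' @export
print.qarm_result <- function(x, ...) {
  cat("QARM result for query '", x$query, "' (", x$mode, " mode, ",
      x$dataset_label, ")\n", sep = "")
  if (x$skipped) {
    cat("  skipped: ", x$reason, "\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("  cohort: %d patients (complement %d)\n",
              x$cohort_size, x$complement_size))
  cat(sprintf("  top-k rules mined: %d; general removed: %d; subsumed removed: %d\n",
              x$n_top_k, x$n_general_removed, x$n_subsumed_removed))
  cat(sprintf("  final rules: %d\n", nrow(x$rules)))
  invisible(x)
}

#' @export
summary.qarm_result <- function(object, ...) {
  print(object)
  if (!object$skipped && nrow(object$rules) > 0) print(object$rules)
  invisible(object)
}

#' Run the pipeline over every eligible query
#'
#' Applies [qarm()] to each requested query constraint (or to all
#' eligible ones), optionally writing one rules CSV per query plus a
#' summary CSV of per-query stage counts.  Per-query skips are carried
#' as records, never raised.
#'
#' @inheritParams qarm
#' @param queries character vector of canonical names, or \code{"all"}
#'   (default) for every eligible query.
#' @param out_dir if non-NULL, directory to write
#'   \code{rules_<query>.csv} files and \code{summary.csv}.
#' @return An object of class \code{qarm_run}: list with
#'   \code{results} (list of \code{qarm_result}), \code{summary}
#'   (data frame) and \code{total_rules}.
#' @export
qarm_all <- function(table, dictionary, mapping, queries = "all",
                     params = miner_params(), min_patients = 20,
                     mode = c("merged", "unmerged"),
                     dataset_label = "dataset", out_dir = NULL) {
  mode <- match.arg(mode)
  if (identical(queries, "all")) {
    queries <- eligible_queries(table, mapping, dictionary, min_patients)
  }
  tab <- prepare_table(table, dictionary, mapping, mode)
  results <- lapply(queries, function(q) {
    tryCatch(
      qarm(tab, dictionary, mapping, q, params = params,
           min_patients = min_patients, mode = mode,
           dataset_label = dataset_label, prepared = TRUE),
      error = function(e) {
        structure(list(query = q, dataset_label = dataset_label,
                       mode = mode, params = params,
                       cohort_size = NA_integer_,
                       complement_size = NA_integer_,
                       rules = rule_set(), n_top_k = 0L,
                       n_general_removed = 0L, n_subsumed_removed = 0L,
                       skipped = TRUE, reason = conditionMessage(e)),
                  class = "qarm_result")
      })
  })
  summary_df <- do.call(rbind, lapply(results, function(r) {
    data.frame(query = r$query, dataset = r$dataset_label, mode = r$mode,
               cohort_size = r$cohort_size,
               n_top_k = r$n_top_k,
               n_general_removed = r$n_general_removed,
               n_subsumed_removed = r$n_subsumed_removed,
               n_rules = nrow(r$rules),
               skipped = r$skipped, stringsAsFactors = FALSE)
  }))
  if (is.null(summary_df)) {
    summary_df <- data.frame(query = character(0), dataset = character(0),
                             mode = character(0), cohort_size = integer(0),
                             n_top_k = integer(0),
                             n_general_removed = integer(0),
                             n_subsumed_removed = integer(0),
                             n_rules = integer(0), skipped = logical(0))
  }
  run <- structure(list(results = results, summary = summary_df,
                        total_rules = sum(summary_df$n_rules)),
                   class = "qarm_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (r in results) {
      if (!r$skipped) {
        write_rules(r$rules, file.path(out_dir,
                                       paste0("rules_", r$query, ".csv")))
      }
    }
    utils::write.csv(summary_df, file.path(out_dir, "summary.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  run
}

#' @export
print.qarm_run <- function(x, ...) {
  ran <- x$summary[!x$summary$skipped, , drop = FALSE]
  cat("QARM run: ", nrow(x$summary), " query(ies), ",
      sum(x$summary$skipped), " skipped\n", sep = "")
  cat("Total final rules: ", x$total_rules, sep = "")
  if (nrow(ran) > 0) {
    cat(sprintf(" (mean %.1f per analysed query)", mean(ran$n_rules)))
  }
  cat("\n")
  invisible(x)
}

#' Read or write a pipeline configuration as YAML
#'
#' The configuration bundles data paths, miner parameters, gate, mode and
#' query list so a run can be reproduced from one file; it round-trips
#' through YAML.
#'
#' @param config named list as produced by [qarm_config()].
#' @param path YAML file path.
#' @return \code{read_config} returns the configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(qarm_config, cfg)
}

#' @rdname write_config
#' @param table,dictionary,mapping input CSV paths.
#' @param k,minconf,delta,max_rule_size,mode_miner miner settings, see
#'   [miner_params()].
#' @param min_patients cohort gate.
#' @param mode merged or unmerged preprocessing.
#' @param queries canonical names or \code{"all"}.
#' @param seed integer seed for any stochastic component (synthetic-data
#'   generation; mining itself is deterministic).
#' @param output_dir where run outputs are written.
#' @export
qarm_config <- function(table = NULL, dictionary = NULL, mapping = NULL,
                        k = 100, minconf = 0.6, delta = 10,
                        max_rule_size = 5, mode_miner = "exact",
                        min_patients = 20, mode = "merged",
                        queries = "all", seed = 1L, output_dir = NULL) {
  structure(list(table = table, dictionary = dictionary, mapping = mapping,
                 k = k, minconf = minconf, delta = delta,
                 max_rule_size = max_rule_size, mode_miner = mode_miner,
                 min_patients = min_patients, mode = mode,
                 queries = queries, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "qarm_config")
}
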