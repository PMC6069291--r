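#' Select eligible yes/no variables from a dictionary
#'
#' Keeps exactly the variables usable for rule mining: categorical type,
#' a yes/no domain (order-insensitive, an optional \code{unknown} token is
#' ignored) and a clinically relevant category (\code{medical_history},
#' \code{medication}, \code{sleep_symptom} or \code{other_symptom}).
#' Multi-valued categorical variables (e.g. a six-valued stroke-type
#' variable), numerical variables and variables of category \code{other}
#' are excluded.
#'
#' @param dictionary a \code{data_dictionary}.
#' @return The \code{data_dictionary} subset of selected variables (may be
#'   empty).
#' @export
select_variables <- function(dictionary) {
  keep <- vapply(seq_len(nrow(dictionary)), function(i) {
    if (dictionary$var_type[i] != "categorical") return(FALSE)
    dom <- setdiff(tolower(dictionary$domain[[i]]), "unknown")
    if (!setequal(dom, c("yes", "no"))) return(FALSE)
    dictionary$category[i] %in% c("medical_history", "medication",
                                  "sleep_symptom", "other_symptom")
  }, TRUE)
  out <- dictionary[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @keywords internal
#' Three-valued vote: yes dominates, then no, all-unknown stays unknown.
.vote <- function(any_yes, any_no) {
  ifelse(any_yes, "yes", ifelse(any_no, "no", "unknown"))
}

#' Combine multiple visits into one record per patient
#'
#' Repeated measurements of the same yes/no variable across visits are
#' collapsed: the combined value is \code{"yes"} if any visit is yes,
#' otherwise \code{"no"} if any visit is no, otherwise \code{"unknown"}.
#' A patient whose answers are all missing therefore stays
#' \code{"unknown"} rather than being fabricated into a "no".
#'
#' @param table a \code{patient_table}, possibly with several visits per
#'   patient.
#' @return A \code{patient_table} with one row per patient
#'   (\code{visit_id} set to \code{"combined"}).
#' @export
combine_visits <- function(table) {
  vars <- table_variables(table)
  pid <- factor(table$patient_id, levels = unique(table$patient_id))
  out <- data.frame(patient_id = levels(pid), visit_id = "combined",
                    stringsAsFactors = FALSE)
  for (v in vars) {
    any_yes <- rowsum((table[[v]] == "yes") + 0L, pid, reorder = FALSE) > 0
    any_no  <- rowsum((table[[v]] == "no") + 0L, pid, reorder = FALSE) > 0
    out[[v]] <- .vote(drop(any_yes), drop(any_no))
  }
  patient_table(out)
}

#' Merge similar dataset variables into canonical variables
#'
#' Dataset variables that map to the same canonical variable measure the
#' same clinical fact (e.g. a physician-reported and a self-reported
#' stroke history).  Left unmerged they generate uninteresting rules that
#' merely relate a variable to its sibling.  This operation replaces each
#' group of sibling columns by a single column named after the canonical
#' variable, valued \code{"yes"} if any sibling is yes, else \code{"no"}
#' if any sibling is no, else \code{"unknown"}.  Columns not covered by
#' the mapping pass through under their own names.
#'
#' @param table a \code{patient_table} with one row per patient.
#' @param mapping a \code{canonical_mapping}.
#' @return A \code{patient_table} with canonical-variable columns.
#' @export
merge_variables <- function(table, mapping) {
  vars <- table_variables(table)
  out <- table[, c("patient_id", "visit_id"), drop = FALSE]
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  mapped <- character(0)
  for (cn in unique(mapping$canonical_name)) {
    group <- intersect(mapped_variables(mapping, cn), vars)
    if (length(group) == 0) next
    sub <- as.data.frame(table)[, group, drop = FALSE]
    any_yes <- rowSums(sub == "yes") > 0
    any_no  <- rowSums(sub == "no") > 0
    out[[cn]] <- .vote(any_yes, any_no)
    mapped <- c(mapped, group)
  }
  for (v in setdiff(vars, mapped)) out[[v]] <- table[[v]]
  patient_table(out)
}

#' Define a query constraint
#'
#' A query constraint selects the sub-cohort of patients answering
#' \code{"yes"} to one canonical variable; rules are then mined within
#' that sub-cohort only.  The constrained value is always \code{"yes"}.
#'
#' @param canonical_name name of the canonical variable.
#' @return An object of class \code{query_constraint}.
#' @export
query_constraint <- function(canonical_name) {
  stopifnot(is.character(canonical_name), length(canonical_name) == 1,
            nzchar(canonical_name))
  structure(list(canonical_name = canonical_name, value = "yes"),
            class = "query_constraint")
}

#' @export
print.query_constraint <- function(x, ...) {
  cat("Query constraint: ", x$canonical_name, " = yes\n", sep = "")
  invisible(x)
}

#' @keywords internal
#' Which columns realize the constraint, and which patients satisfy it.
.constraint_info <- function(table, constraint, mode, mapping) {
  vars <- table_variables(table)
  if (mode == "merged") {
    cols <- intersect(constraint$canonical_name, vars)
  } else {
    if (is.null(mapping)) {
      stop("unmerged mode needs the canonical mapping to evaluate the ",
           "constraint", call. = FALSE)
    }
    cols <- intersect(mapped_variables(mapping, constraint$canonical_name), vars)
  }
  if (length(cols) == 0) {
    stop("constraint variable ", sQuote(constraint$canonical_name),
         " has no column in the table", call. = FALSE)
  }
  sub <- as.data.frame(table)[, cols, drop = FALSE]
  list(cols = cols, satisfied = rowSums(sub == "yes") > 0)
}

#' Transform a patient table into a transaction database
#'
#' Each patient becomes a transaction holding the variables answered
#' \code{"yes"} ("no" and "unknown" answers carry no item: imbalanced
#' clinical variables would otherwise flood the miner with uninteresting
#' negative rules).  When a query constraint is given, only patients
#' satisfying it are retained, and the constraint's own column(s) are
#' removed from every transaction and from the item universe, since the
#' constraint is satisfied by the whole sub-cohort by construction.  In
#' unmerged mode the constraint is still evaluated at the canonical level
#' (a patient qualifies if any mapped dataset variable is yes) and all
#' mapped dataset columns are excluded from the universe.
#'
#' @param table a \code{patient_table} with one row per patient, already
#'   visit-combined (and variable-merged when \code{mode = "merged"}).
#' @param constraint a [query_constraint()], or \code{NULL} to keep the
#'   whole cohort.
#' @param mode \code{"merged"} (columns are canonical variables) or
#'   \code{"unmerged"} (columns are dataset variables).
#' @param mapping the \code{canonical_mapping}; required in unmerged mode
#'   when a constraint is given.
#' @return A [transaction_db()].
#' @export
build_transactions <- function(table, constraint = NULL,
                               mode = c("merged", "unmerged"),
                               mapping = NULL) {
  mode <- match.arg(mode)
  if (anyDuplicated(table$patient_id)) {
    stop("table must have one row per patient (combine visits first)",
         call. = FALSE)
  }
  vars <- table_variables(table)
  if (is.null(constraint)) {
    keep <- rep(TRUE, nrow(table))
    universe <- vars
  } else {
    info <- .constraint_info(table, constraint, mode, mapping)
    keep <- info$satisfied
    universe <- setdiff(vars, info$cols)
  }
  .project_yes(table[keep, , drop = FALSE], universe)
}

#' @rdname build_transactions
#' @description \code{complement_transactions} applies the same yes-item
#'   projection to the patients that do \emph{not} satisfy the constraint
#'   (patients with an unknown constraint status fall in the complement);
#'   the constraint column(s) are likewise excluded from the universe.
#'   The two databases partition the patient set.
#' @export
complement_transactions <- function(table, constraint,
                                    mode = c("merged", "unmerged"),
                                    mapping = NULL) {
  mode <- match.arg(mode)
  if (anyDuplicated(table$patient_id)) {
    stop("table must have one row per patient (combine visits first)",
         call. = FALSE)
  }
  info <- .constraint_info(table, constraint, mode, mapping)
  universe <- setdiff(table_variables(table), info$cols)
  .project_yes(table[!info$satisfied, , drop = FALSE], universe)
}

#' @keywords internal
.project_yes <- function(rows, universe) {
  df <- as.data.frame(rows)
  if (nrow(df) == 0 || length(universe) == 0) {
    tr <- rep(list(character(0)), nrow(df))
    names(tr) <- df$patient_id
    return(transaction_db(tr, universe))
  }
  m <- as.matrix(df[, universe, drop = FALSE]) == "yes"
  tr <- lapply(seq_len(nrow(m)), function(i) universe[m[i, ]])
  names(tr) <- df$patient_id
  transaction_db(tr, universe)
}

#' Check the minimum-cohort-size gate
#'
#' A query is only analysed when enough patients exhibit the constrained
#' characteristic; by default at least 20.
#'
#' @param db a \code{transaction_db}.
#' @param min_patients minimum number of transactions (default 20).
#' @return \code{TRUE} if the cohort is large enough.
#' @export
check_cohort_size <- function(db, min_patients = 20) {
  n_transactions(db) >= min_patients
}
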