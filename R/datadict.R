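#' Default token normalization map
#'
#' Raw clinical CSV exports encode yes/no answers in many dialects
#' (\code{"1"}/\code{"0"}, \code{"Y"}/\code{"N"}, \code{"TRUE"}/...).  All
#' readers in this package normalize cell values to the three canonical
#' tokens \code{"yes"}, \code{"no"} and \code{"unknown"} through a token
#' map: a named list with components \code{yes}, \code{no} and
#' \code{unknown}, each a character vector of accepted spellings.  Matching
#' is case-insensitive; a literal \code{NA} cell is always mapped to
#' \code{"unknown"}.
#'
#' @return A token map (named list of character vectors).
#' @export
#' @examples
#' default_token_map()
default_token_map <- function() {
  list(
    yes     = c("yes", "y", "1", "true"),
    no      = c("no", "n", "0", "false"),
    unknown = c("", "na", "unknown")
  )
}

#' @keywords internal
.normalize_tokens <- function(x, token_map) {
  raw <- as.character(x)
  low <- tolower(trimws(raw))
  out <- rep(NA_character_, length(low))
  out[is.na(raw)] <- "unknown"
  for (tok in c("yes", "no", "unknown")) {
    out[!is.na(low) & low %in% tolower(token_map[[tok]])] <- tok
  }
  bad <- unique(raw[is.na(out)])
  if (length(bad) > 0) {
    stop("unmappable cell tokens: ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Construct a patient table
#'
#' A patient table holds one record per (patient, visit), with one column
#' per dataset variable and every cell equal to \code{"yes"}, \code{"no"}
#' or \code{"unknown"}.  The first two columns are always
#' \code{patient_id} and \code{visit_id}.
#'
#' @param df data frame with columns \code{patient_id}, \code{visit_id}
#'   and one character column per variable.
#' @return An object of class \code{patient_table}.
#' @export
patient_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (!all(c("patient_id", "visit_id") %in% names(df))) {
    stop("patient table needs patient_id and visit_id columns", call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df <- df[, c("patient_id", "visit_id",
               setdiff(names(df), c("patient_id", "visit_id"))), drop = FALSE]
  key <- paste(df$patient_id, df$visit_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), c("patient_id", "visit_id"), drop = FALSE]
    stop("duplicate (patient_id, visit_id) rows: ",
         paste(paste(dup$patient_id, dup$visit_id, sep = "/"), collapse = ", "),
         call. = FALSE)
  }
  vars <- setdiff(names(df), c("patient_id", "visit_id"))
  for (v in vars) {
    bad <- setdiff(unique(df[[v]]), c("yes", "no", "unknown"))
    if (length(bad) > 0) {
      stop("column ", sQuote(v), " holds non-normalized values: ",
           paste(sQuote(bad), collapse = ", "), call. = FALSE)
    }
  }
  rownames(df) <- NULL
  class(df) <- c("patient_table", "data.frame")
  df
}

#' Variable columns of a patient table
#' @param table a \code{patient_table}.
#' @return Character vector of dataset-variable column names.
#' @export
table_variables <- function(table) {
  setdiff(names(table), c("patient_id", "visit_id"))
}

#' Read a patient-level CSV file
#'
#' Reads a CSV with a header row and one row per (patient, visit).  Cell
#' values of all non-identifier columns are normalized to
#' \code{yes}/\code{no}/\code{unknown} through \code{token_map};
#' unrecognised tokens are a hard error that lists the offending values.
#'
#' @param path path to the CSV file.
#' @param id_col name of the patient-identifier column (default
#'   \code{"patient_id"}).  Missing id column is an error.
#' @param visit_col name of the visit-identifier column.  If the column is
#'   absent the whole file is treated as a single visit.
#' @param token_map see [default_token_map()].
#' @return A [patient_table()].
#' @export
read_patient_table <- function(path, id_col = "patient_id",
                               visit_col = "visit_id",
                               token_map = default_token_map()) {
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, na.strings = NULL)
  if (!id_col %in% names(df)) {
    stop("patient-id column ", sQuote(id_col), " not found in ", path,
         call. = FALSE)
  }
  names(df)[names(df) == id_col] <- "patient_id"
  if (visit_col %in% names(df)) {
    names(df)[names(df) == visit_col] <- "visit_id"
  } else {
    df$visit_id <- "v1"
  }
  for (v in setdiff(names(df), c("patient_id", "visit_id"))) {
    df[[v]] <- .normalize_tokens(df[[v]], token_map)
  }
  patient_table(df)
}

#' Write a patient table back to CSV
#'
#' Inverse of [read_patient_table()]: the written file re-reads to an
#' identical in-memory table.
#'
#' @param table a \code{patient_table}.
#' @param path output path.
#' @export
write_patient_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.patient_table <- function(x, ...) {
  cat("Patient table: ", length(unique(x$patient_id)), " patients, ",
      length(unique(x$visit_id)), " visit(s), ",
      length(table_variables(x)), " variables\n", sep = "")
  NextMethod()
}

# ---- data dictionary --------------------------------------------------------

.valid_categories <- c("medical_history", "medication", "sleep_symptom",
                       "other_symptom", "other")

#' Read a data dictionary CSV
#'
#' The dictionary describes each dataset variable: \code{name},
#' \code{label}, \code{type} (\code{categorical}, \code{numerical} or
#' \code{other}), \code{domain} (permitted values, \code{"|"}-delimited)
#' and \code{category} (\code{medical_history}, \code{medication},
#' \code{sleep_symptom}, \code{other_symptom} or \code{other}; anything
#' else is retained but later excluded by variable selection).
#'
#' @param path path to the dictionary CSV.
#' @return A data frame of class \code{data_dictionary} with columns
#'   \code{name}, \code{label}, \code{var_type}, \code{domain} (list of
#'   character vectors) and \code{category}.
#' @export
read_dictionary <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, na.strings = NULL)
  need <- c("name", "type", "domain", "category")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("dictionary is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"label" %in% names(df)) df$label <- df$name
  data_dictionary(data.frame(
    name = df$name, label = df$label, var_type = df$type,
    domain_raw = df$domain, category = df$category,
    stringsAsFactors = FALSE))
}

#' @rdname read_dictionary
#' @param df data frame with columns \code{name}, \code{label},
#'   \code{var_type}, \code{domain_raw} (pipe-delimited) and
#'   \code{category}.
#' @export
data_dictionary <- function(df) {
  if (anyDuplicated(df$name)) {
    stop("duplicate variable names in dictionary: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "),
         call. = FALSE)
  }
  bad_type <- setdiff(unique(df$var_type), c("categorical", "numerical", "other"))
  if (length(bad_type) > 0) {
    stop("unknown variable type(s): ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  }
  df$domain <- lapply(df$domain_raw, function(d) {
    d <- trimws(strsplit(d, "|", fixed = TRUE)[[1]])
    d[nzchar(d)]
  })
  empty_cat <- df$var_type == "categorical" & lengths(df$domain) == 0
  if (any(empty_cat)) {
    stop("categorical variable(s) with empty domain: ",
         paste(df$name[empty_cat], collapse = ", "), call. = FALSE)
  }
  df <- df[, c("name", "label", "var_type", "domain", "category")]
  rownames(df) <- NULL
  class(df) <- c("data_dictionary", "data.frame")
  df
}

#' Write a data dictionary to CSV
#' @param dictionary a \code{data_dictionary}.
#' @param path output path.
#' @export
write_dictionary <- function(dictionary, path) {
  out <- data.frame(
    name = dictionary$name, label = dictionary$label,
    type = dictionary$var_type,
    domain = vapply(dictionary$domain, paste, "", collapse = "|"),
    category = dictionary$category, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- canonical mapping ------------------------------------------------------

#' Read a canonical-variable mapping CSV
#'
#' Links canonical (study-harmonized) variables to the study-specific
#' dataset variables that measure them.  One canonical variable may map to
#' several dataset variables; a dataset variable belongs to at most one
#' canonical variable (violations are an error).
#'
#' @param path CSV with columns \code{canonical_name},
#'   \code{canonical_label} (optional) and \code{dataset_name}.
#' @return A data frame of class \code{canonical_mapping}.
#' @export
read_mapping <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, na.strings = NULL)
  need <- c("canonical_name", "dataset_name")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("mapping is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"canonical_label" %in% names(df)) df$canonical_label <- df$canonical_name
  canonical_mapping(df[, c("canonical_name", "canonical_label", "dataset_name")])
}

#' @rdname read_mapping
#' @param df data frame with the mapping columns.
#' @export
canonical_mapping <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(df$dataset_name)) {
    dup <- unique(df$dataset_name[duplicated(df$dataset_name)])
    stop("dataset variable(s) mapped to more than one canonical variable: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("canonical_mapping", "data.frame")
  df
}

#' Dataset variables mapped to a canonical variable
#' @param mapping a \code{canonical_mapping}.
#' @param canonical_name canonical variable name.
#' @return Character vector of dataset variable names (possibly empty).
#' @export
mapped_variables <- function(mapping, canonical_name) {
  mapping$dataset_name[mapping$canonical_name == canonical_name]
}

#' Write a canonical mapping to CSV
#' @param mapping a \code{canonical_mapping}.
#' @param path output path.
#' @export
write_mapping <- function(mapping, path) {
  utils::write.csv(as.data.frame(mapping), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# ---- summary statistics -----------------------------------------------------

#' Imbalance rate of a yes/no variable
#'
#' The percentage of observed yes answers among the yes/no answers of a
#' variable, \code{100 * n_yes / (n_yes + n_no)}; \code{"unknown"} cells
#' are excluded from the denominator.  Clinical yes/no variables are
#' typically heavily imbalanced towards "no" (single-digit rates).
#'
#' @param table a \code{patient_table}.
#' @param var name of a yes/no variable column.
#' @return Percentage in \code{[0, 100]}.  A variable with no yes/no
#'   observations has an undefined rate and raises an error.
#' @export
#' @examples
#' tb <- patient_table(data.frame(
#'   patient_id = paste0("p", 1:4), visit_id = "v1",
#'   stroke = c("yes", "no", "no", "unknown")))
#' imbalance_rate(tb, "stroke")  # 100 * 1 / 3
imbalance_rate <- function(table, var) {
  if (!var %in% table_variables(table)) {
    stop("variable ", sQuote(var), " not in table", call. = FALSE)
  }
  x <- table[[var]]
  n_yes <- sum(x == "yes")
  n_no <- sum(x == "no")
  if (n_yes + n_no == 0) {
    stop("imbalance rate undefined for ", sQuote(var),
         ": no yes/no observations", call. = FALSE)
  }
  100 * n_yes / (n_yes + n_no)
}

#' Mean imbalance rate over a set of variables
#'
#' Arithmetic mean of [imbalance_rate()] over the given variables, the
#' per-dataset summary statistic usually reported alongside a dictionary.
#'
#' @inheritParams imbalance_rate
#' @param vars variable names; defaults to all variable columns.
#' @return Mean percentage.
#' @export
mean_imbalance_rate <- function(table, vars = table_variables(table)) {
  mean(vapply(vars, function(v) imbalance_rate(table, v), 0))
}
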