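#' Construct a transaction database
#'
#' A transaction database is the input format of the rule miner: one
#' itemset per patient, each itemset a subset of a fixed item universe.
#' Patients whose itemset is empty are retained — they count in the
#' denominator of support.
#'
#' @param transactions named list; one character vector of item names per
#'   patient, names are patient ids (unique).
#' @param items the item universe (ordered character vector).
#' @return An object of class \code{transaction_db}.
#' @export
transaction_db <- function(transactions, items) {
  stopifnot(is.list(transactions), is.character(items))
  if (anyDuplicated(items)) stop("duplicate items in universe", call. = FALSE)
  if (is.null(names(transactions)) && length(transactions) > 0) {
    stop("transactions must be named by patient id", call. = FALSE)
  }
  if (anyDuplicated(names(transactions))) {
    stop("duplicate patient ids in transactions", call. = FALSE)
  }
  transactions <- lapply(transactions, function(t) {
    t <- sort(unique(as.character(t)))
    extra <- setdiff(t, items)
    if (length(extra) > 0) {
      stop("transaction items outside universe: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    t
  })
  structure(list(transactions = transactions, items = items),
            class = "transaction_db")
}

#' Number of transactions in a database
#' @param db a \code{transaction_db}.
#' @return Integer count of transactions (patients).
#' @export
n_transactions <- function(db) length(db$transactions)

#' @export
print.transaction_db <- function(x, ...) {
  cat("Transaction database: ", n_transactions(x), " transactions over ",
      length(x$items), " items\n", sep = "")
  cat("Mean itemset size: ",
      if (n_transactions(x) > 0)
        round(mean(lengths(x$transactions)), 2) else 0, "\n", sep = "")
  invisible(x)
}

#' Convert a transaction database to a dense 0/1 matrix
#' @param db a \code{transaction_db}.
#' @return Integer matrix, patients in rows, items in columns.
#' @export
as_incidence_matrix <- function(db) {
  m <- matrix(0L, nrow = n_transactions(db), ncol = length(db$items),
              dimnames = list(names(db$transactions), db$items))
  for (i in seq_along(db$transactions)) {
    m[i, db$transactions[[i]]] <- 1L
  }
  m
}

#' Build a transaction database from a dense 0/1 matrix or data frame
#' @param m 0/1 matrix or data frame with patient ids as row names and
#'   items as column names.
#' @return A [transaction_db()].
#' @export
from_incidence_matrix <- function(m) {
  m <- as.matrix(m)
  items <- colnames(m)
  tr <- lapply(seq_len(nrow(m)), function(i) items[m[i, ] == 1])
  names(tr) <- rownames(m)
  transaction_db(tr, items)
}

#' Write / read a transaction database as plain text
#'
#' One line per transaction: the patient id, a tab, then tab-separated
#' item names.  The item universe goes to a sidecar file (one item per
#' line) so that items absent from every transaction survive the round
#' trip.
#'
#' @param db a \code{transaction_db}.
#' @param path output path for the transaction lines; the universe is
#'   written to \code{paste0(path, ".items")}.
#' @export
write_transactions <- function(db, path) {
  lines <- vapply(seq_along(db$transactions), function(i) {
    paste(c(names(db$transactions)[i], db$transactions[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  writeLines(db$items, paste0(path, ".items"))
  invisible(path)
}

#' @rdname write_transactions
#' @export
read_transactions <- function(path) {
  items <- readLines(paste0(path, ".items"))
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tr <- lapply(parts, function(p) p[-1][nzchar(p[-1])])
  names(tr) <- vapply(parts, `[[`, "", 1)
  transaction_db(tr, items)
}
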