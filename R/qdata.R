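#' Construct a sorting-grid specification
#'
#' @param columnValues ordered integer grid values (e.g. `-3:3`).
#' @param columnCapacities positive integers, one per column; must sum to the
#'   number of statements in the Q-sample the grid is used with. Symmetric
#'   anchors (min = -max) are conventional but not required.
#' @return a [GridSpec-class].
#' @examples
#' gridSpec(-2:2, c(1, 2, 3, 2, 1))
#' @export
gridSpec <- function(columnValues, columnCapacities) {
  new("GridSpec",
      columnValues = as.integer(columnValues),
      columnCapacities = as.integer(columnCapacities))
}

#' Construct a Q-sort matrix
#'
#' @param values integer matrix, statements in rows and participants in
#'   columns.
#' @param grid a [GridSpec-class]; inferred via [inferGrid()] when omitted.
#' @param participantIds optional column labels (defaults to existing
#'   colnames, then `P1..Pp`).
#' @param statementIds optional integer row labels, unique and contiguous
#'   from 1 (defaults to existing rownames, then `1..S`).
#' @param forced enforce the forced-distribution constraint (every column's
#'   value histogram equals the grid capacities). Default `TRUE`; with
#'   `FALSE` only the value range is checked (free-distribution data).
#' @return a validated [QSortMatrix-class].
#' @examples
#' m <- cbind(a = c(-1, 0, 1), b = c(1, 0, -1))
#' qSortMatrix(m)
#' @export
qSortMatrix <- function(values, grid = NULL, participantIds = NULL,
                        statementIds = NULL, forced = TRUE) {
  values <- as.matrix(values)
  if (is.null(participantIds)) {
    participantIds <- colnames(values)
    if (is.null(participantIds)) {
      participantIds <- paste0("P", seq_len(ncol(values)))
    }
  }
  if (is.null(statementIds)) {
    statementIds <- rownames(values)
    if (is.null(statementIds)) statementIds <- seq_len(nrow(values))
    statementIds <- as.integer(statementIds)
  }
  if (is.null(grid)) grid <- inferGrid(values)
  storage.mode(values) <- "integer"
  dimnames(values) <- NULL
  new("QSortMatrix", values = values, grid = grid,
      participantIds = as.character(participantIds),
      statementIds = as.integer(statementIds), forced = isTRUE(forced))
}

#' Infer the sorting grid from a Q-sort matrix
#'
#' The grid values are the sorted distinct entries of the first column and
#' the capacities are that column's value histogram. Every other column must
#' produce the same histogram; a mismatch signals free-distribution data and
#' inference fails, naming the deviating participants.
#'
#' @param values integer matrix (statements x participants) with at least one
#'   column.
#' @return a [GridSpec-class].
#' @examples
#' inferGrid(cbind(c(-1, 0, 1), c(1, -1, 0)))
#' @export
inferGrid <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) < 1L) stop("need at least one column to infer a grid")
  ref <- sort(unique(values[, 1]))
  cap <- as.integer(table(factor(values[, 1], levels = ref)))
  hists <- apply(values, 2, function(col) {
    if (!all(col %in% ref)) return(NULL)
    as.integer(table(factor(col, levels = ref)))
  }, simplify = FALSE)
  ok <- vapply(hists, function(h) !is.null(h) && identical(h, cap), logical(1))
  if (!all(ok)) {
    who <- colnames(values)[!ok]
    if (is.null(who)) who <- which(!ok)
    stop("grid inference failed: participants with deviating value histograms: ",
         paste(who, collapse = ", "),
         " (free-distribution data? pass an explicit grid with forced = FALSE)")
  }
  gridSpec(ref, cap)
}

#' Read a Q-sort matrix from delimited text
#'
#' Expects a comma- or tab-delimited file with a header row of participant
#' ids and a first column of statement ids; all remaining cells integers.
#' The canonical orientation is statements in rows; `layout =
#' "participants_by_statements"` transposes on read (then the header holds
#' statement ids and the first column participant ids).
#'
#' @param path file path; the delimiter is taken from the extension
#'   (`.tsv`/`.txt` tab, otherwise comma).
#' @param layout `"statements_by_participants"` (default) or
#'   `"participants_by_statements"`.
#' @param grid a [GridSpec-class], or `NULL` to infer it from the data.
#' @param forced see [qSortMatrix()].
#' @param sep overrides the delimiter guessed from the extension.
#' @return a validated [QSortMatrix-class].
#' @seealso [writeQSorts()]
#' @examples
#' f <- system.file("extdata", "example_qsorts.csv", package = "qrotate")
#' readQSorts(f)
#' @export
readQSorts <- function(path,
                       layout = c("statements_by_participants",
                                  "participants_by_statements"),
                       grid = NULL, forced = TRUE, sep = NULL) {
  layout <- match.arg(layout)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE)
  if (ncol(raw) < 2L) stop("expected an id column plus at least one data column")
  ids <- raw[[1]]
  cells <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(cells), nrow(cells)))
  bad <- which(is.na(num) | num != round(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-integer cell '%s' at row id '%s', column '%s'",
                 cells[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 colnames(cells)[bad[1, 2]]))
  }
  if (layout == "participants_by_statements") {
    qSortMatrix(t(num), grid = grid, participantIds = ids,
                statementIds = as.integer(colnames(cells)), forced = forced)
  } else {
    qSortMatrix(num, grid = grid, participantIds = colnames(cells),
                statementIds = as.integer(ids), forced = forced)
  }
}

#' Write a Q-sort matrix to delimited text
#'
#' Writes the canonical statements-in-rows layout with a header of
#' participant ids and a leading `statement` column, so that
#' `readQSorts(writeQSorts(q, f))` round-trips the numeric content exactly.
#'
#' @param q a [QSortMatrix-class].
#' @param path output file; extension chooses the delimiter as in
#'   [readQSorts()].
#' @param sep delimiter override.
#' @return `path`, invisibly.
#' @export
writeQSorts <- function(q, path, sep = NULL) {
  stopifnot(is(q, "QSortMatrix"))
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- data.frame(statement = q@statementIds, q@values,
                   check.names = FALSE)
  colnames(df)[-1] <- q@participantIds
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a grid specification from JSON
#'
#' Expects `{"values": [-3, ..., 3], "capacities": [...]}`.
#'
#' @param path JSON file path.
#' @return a [GridSpec-class].
#' @export
readGridSpec <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(spec$values) || is.null(spec$capacities)) {
    stop("grid JSON must contain 'values' and 'capacities'")
  }
  gridSpec(spec$values, spec$capacities)
}

#' Write a grid specification to JSON
#'
#' @param grid a [GridSpec-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGridSpec <- function(grid, path) {
  stopifnot(is(grid, "GridSpec"))
  jsonlite::write_json(list(values = grid@columnValues,
                            capacities = grid@columnCapacities), path)
  invisible(path)
}

#' Read a Q-sample statement list
#'
#' Plain text, one statement per line: `id<TAB>text`. Ids must be unique and
#' contiguous from 1.
#'
#' @param path file path.
#' @return a data.frame with columns `id` (integer) and `text` (character).
#' @export
readStatements <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                          col.names = c("id", "text"),
                          colClasses = c("integer", "character"))
  if (nrow(df) == 0L) stop("statement list is empty")
  if (!identical(sort(df$id), seq_len(nrow(df)))) {
    stop("statement ids must be unique and contiguous from 1")
  }
  df[order(df$id), , drop = FALSE]
}
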