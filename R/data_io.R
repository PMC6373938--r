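#' Read a response matrix from delimited text
#'
#' Expects persons as rows and a header of item identifiers.  Optional
#' `person_id` and `group` columns are recognised by name.  Any cell whose
#' token is in `missing_codes` (after trimming) becomes an explicit missing
#' value; any other non-integer token is an error naming the offending cell.
#'
#' @param path path to a CSV/TSV file (delimiter sniffed from the header).
#' @param missing_codes tokens to treat as missing.
#' @param max_cat declared maximum category (scalar or per item); defaults to
#'   the observed maximum.
#' @return A [response_matrix()].
#' @export
read_response_matrix <- function(path, missing_codes = c("", "NA", "NaN"),
                                 max_cat = NULL) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE,
                          na.strings = character(0))  # tokens stay literal
  person_ids <- NULL; group <- NULL
  if ("person_id" %in% names(df)) {
    person_ids <- df[["person_id"]]; df[["person_id"]] <- NULL
  }
  if ("group" %in% names(df)) {
    group <- trimws(df[["group"]]); df[["group"]] <- NULL
    group[group %in% missing_codes] <- NA_character_
  }
  item_ids <- names(df)
  x <- matrix(NA_integer_, nrow(df), length(item_ids))
  for (j in seq_along(item_ids)) {
    tok <- trimws(df[[j]])
    is_miss <- tok %in% missing_codes
    val <- suppressWarnings(as.integer(tok))
    bad <- which(!is_miss & (is.na(val) | val != suppressWarnings(as.numeric(tok))))
    if (length(bad))
      stop(sprintf("cannot parse response token '%s' at row %d, column '%s'",
                   tok[bad[1]], bad[1], item_ids[j]))
    val[is_miss] <- NA_integer_
    x[, j] <- val
  }
  response_matrix(x, person_ids = person_ids, item_ids = item_ids,
                  group = group, max_cat = max_cat)
}

#' Write a response matrix as CSV
#'
#' @param matrix a [response_matrix()].
#' @param path output path.
#' @param na token used for missing cells.
#' @export
write_response_matrix <- function(matrix, path, na = "NA") {
  stopifnot(inherits(matrix, "response_matrix"))
  df <- as.data.frame(matrix$responses)
  df <- cbind(person_id = matrix$person_ids, df)
  if (!is.null(matrix$group)) df$group <- matrix$group
  utils::write.table(df, path, sep = ",", na = na, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an item bank from its JSON serialization
#'
#' @param path path to a JSON bank written by [write_item_bank()] (an array
#'   of objects with `item_id`, `label`, `deltas`, `scoring_map`).
#' @return An [item_bank()].
#' @export
read_item_bank <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (length(obj) == 0) stop("empty bank")
  need <- c("item_id", "deltas")
  for (it in obj) {
    if (!all(need %in% names(it)))
      stop("bank entry missing required field(s): ",
           paste(setdiff(need, names(it)), collapse = ", "))
  }
  item_bank(
    item_ids = vapply(obj, function(it) as.character(it$item_id), ""),
    deltas = lapply(obj, function(it) unlist(it$deltas)),
    labels = vapply(obj, function(it)
      if (is.null(it$label)) as.character(it$item_id) else as.character(it$label), ""),
    scoring_maps = lapply(obj, function(it)
      if (is.null(it$scoring_map)) NULL else as.integer(unlist(it$scoring_map))) |>
      (function(l) if (all(vapply(l, is.null, TRUE))) NULL else {
        # mixed explicit/default maps: fill defaults from threshold counts
        for (i in seq_along(l)) if (is.null(l[[i]]))
          l[[i]] <- 0:length(unlist(obj[[i]]$deltas))
        l
      })())
}

#' Write an item bank to JSON
#'
#' @param bank an [item_bank()].
#' @param path output path.
#' @export
write_item_bank <- function(bank, path) {
  stopifnot(inherits(bank, "item_bank"))
  obj <- lapply(seq_len(n_items(bank)), function(i) list(
    item_id = bank$item_ids[i],
    label = bank$labels[[i]],
    deltas = as.numeric(bank$deltas[[i]]),
    scoring_map = as.integer(bank$scoring_maps[[i]])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export an item bank as a delimited table
#'
#' Mirrors the published presentation: one row per item with its number,
#' wording, threshold parameters and scoring map.
#'
#' @param bank an [item_bank()].
#' @param path output CSV path.
#' @export
export_bank_csv <- function(bank, path) {
  stopifnot(inherits(bank, "item_bank"))
  nd <- max(vapply(bank$deltas, length, 1L))
  dm <- t(vapply(bank$deltas, function(d) c(d, rep(NA_real_, nd - length(d))),
                 numeric(nd)))
  colnames(dm) <- paste0("delta", seq_len(nd))
  df <- data.frame(item_number = seq_len(n_items(bank)),
                   item_id = bank$item_ids,
                   wording = unlist(bank$labels), dm,
                   scoring = vapply(bank$scoring_maps,
                                    function(s) paste(s, collapse = "-"), ""),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Create an empty purification ledger
#'
#' The ledger is the ordered audit trail of the item-reduction pipeline: one
#' entry per action with the stage, item id(s), the action taken and the
#' statistic that motivated it.
#'
#' @return An object of class `purification_ledger`.
#' @export
new_ledger <- function() {
  structure(list(entries = list()), class = "purification_ledger")
}

#' Append an entry to a purification ledger
#'
#' @param ledger a [new_ledger()].
#' @param stage one of `"mokken"`, `"dimensionality"`, `"rescore"`,
#'   `"local_dependency"`, `"dif"`, `"misfit"`, `"fit"`.
#' @param item_id item id(s) the action concerns (may be empty for
#'   scale-level entries).
#' @param action one of `"flag"`, `"rescore"`, `"remove"`, `"keep"`,
#'   `"note"`.
#' @param statistic named list/vector of supporting statistics.
#' @param rationale free-text justification.
#' @return The ledger with the entry appended.
#' @export
ledger_add <- function(ledger, stage, item_id = character(), action = "note",
                       statistic = NULL, rationale = "") {
  stopifnot(inherits(ledger, "purification_ledger"))
  stage <- match.arg(stage, c("mokken", "dimensionality", "rescore",
                              "local_dependency", "dif", "misfit", "fit"))
  action <- match.arg(action, c("flag", "rescore", "remove", "keep", "note"))
  if (action == "remove") {
    prev <- ledger_removed(ledger)
    dup <- intersect(as.character(item_id), prev)
    if (length(dup)) stop("item(s) already removed: ", paste(dup, collapse = ", "))
  }
  e <- list(stage = stage, item_id = as.character(item_id), action = action,
            statistic = statistic, rationale = rationale)
  ledger$entries[[length(ledger$entries) + 1L]] <- e
  ledger
}

#' Item ids with a `remove` entry in a ledger
#' @param ledger a [new_ledger()].
#' @export
ledger_removed <- function(ledger) {
  unique(unlist(lapply(ledger$entries, function(e)
    if (e$action == "remove") e$item_id else character())))
}

#' @export
print.purification_ledger <- function(x, ...) {
  cat(sprintf("<purification_ledger> %d entries, %d removals\n",
              length(x$entries), length(ledger_removed(x))))
  for (e in x$entries)
    cat(sprintf("  [%s] %s %s\n", e$stage, e$action,
                paste(e$item_id, collapse = ",")))
  invisible(x)
}

#' Write a purification ledger as JSON lines
#'
#' One JSON object per line, in pipeline order; re-readable losslessly with
#' [read_ledger()].
#'
#' @param ledger a [new_ledger()].
#' @param path output path.
#' @export
write_ledger <- function(ledger, path) {
  stopifnot(inherits(ledger, "purification_ledger"))
  lines <- vapply(ledger$entries, function(e)
    as.character(jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA,
                                  null = "null")), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a purification ledger from JSON lines
#' @param path path written by [write_ledger()].
#' @return A `purification_ledger`.
#' @export
read_ledger <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  led <- new_ledger()
  led$entries <- lapply(lines, function(l) {
    e <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    e$item_id <- as.character(unlist(e$item_id))
    e
  })
  led
}
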