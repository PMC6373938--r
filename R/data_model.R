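#' Construct a polytomous response matrix
#'
#' The central data container: an integer persons x items matrix of 0-based
#' category codes with explicit missingness (`NA`), optional per-person group
#' labels, and a declared maximum category per item.
#'
#' @param responses integer matrix (or data frame) of category codes, persons
#'   in rows, items in columns.  `NA` marks a missing response; sentinel codes
#'   are not allowed.
#' @param person_ids character vector of unique person identifiers; defaults
#'   to row names or `p1..pn`.
#' @param item_ids character vector of unique item identifiers; defaults to
#'   column names or `i1..iJ`.
#' @param group optional per-person labels (e.g. `"service_user"`, `"carer"`,
#'   `"both"`, `"unreported"`).
#' @param max_cat integer maximum category per item (scalar recycled);
#'   defaults to the observed column maximum.
#' @return An object of class `response_matrix`.
#' @examples
#' m <- response_matrix(matrix(c(0, 1, 2, NA, 4, 3), 3, 2))
#' missing_fraction(m)
#' @export
response_matrix <- function(responses, person_ids = NULL, item_ids = NULL,
                            group = NULL, max_cat = NULL) {
  x <- as.matrix(responses)
  storage.mode(x) <- "integer"
  n <- nrow(x); J <- ncol(x)
  if (is.null(person_ids)) {
    person_ids <- if (!is.null(rownames(x))) rownames(x) else paste0("p", seq_len(n))
  }
  if (is.null(item_ids)) {
    item_ids <- if (!is.null(colnames(x))) colnames(x) else paste0("i", seq_len(J))
  }
  person_ids <- as.character(person_ids); item_ids <- as.character(item_ids)
  if (anyDuplicated(person_ids)) stop("duplicate person ids: ",
    paste(unique(person_ids[duplicated(person_ids)]), collapse = ", "))
  if (anyDuplicated(item_ids)) stop("duplicate item ids: ",
    paste(unique(item_ids[duplicated(item_ids)]), collapse = ", "))
  if (length(person_ids) != n || length(item_ids) != J)
    stop("id lengths do not match matrix dimensions")
  if (is.null(max_cat)) {
    max_cat <- suppressWarnings(apply(x, 2, max, na.rm = TRUE))
    max_cat[!is.finite(max_cat)] <- 1L
  }
  max_cat <- as.integer(rep_len(max_cat, J))
  if (any(max_cat < 1L)) stop("max_cat must be >= 1 for every item")
  bad <- which(!is.na(x) & (x < 0L | x > rep(max_cat, each = n)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(x))
    stop(sprintf("response %d out of range [0, %d] at person '%s', item '%s'",
                 x[bad[1]], max_cat[rc[2]], person_ids[rc[1]], item_ids[rc[2]]))
  }
  if (!is.null(group)) {
    group <- as.character(rep_len(group, n))
  }
  dimnames(x) <- list(person_ids, item_ids)
  structure(list(responses = x, person_ids = person_ids, item_ids = item_ids,
                 group = group, max_cat = stats::setNames(max_cat, item_ids)),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d persons x %d items, %.1f%% missing\n",
              nrow(x$responses), ncol(x$responses), 100 * missing_fraction(x)))
  if (!is.null(x$group))
    cat("  groups:", paste(names(table(x$group)), table(x$group),
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$responses)

#' Fraction of missing cells in a response matrix
#' @param matrix a [response_matrix()].
#' @return Proportion of person-by-item cells that are `NA`.
#' @export
missing_fraction <- function(matrix) {
  stopifnot(inherits(matrix, "response_matrix"))
  mean(is.na(matrix$responses))
}

#' Subset a response matrix by items and/or persons
#'
#' @param matrix a [response_matrix()].
#' @param items item ids (or logical/integer index) to keep.
#' @param persons person ids (or index) to keep.
#' @return A `response_matrix` restricted to the selection.
#' @export
subset_items <- function(matrix, items = NULL, persons = NULL) {
  stopifnot(inherits(matrix, "response_matrix"))
  ii <- if (is.null(items)) seq_along(matrix$item_ids) else items
  if (is.character(ii)) {
    miss <- setdiff(ii, matrix$item_ids)
    if (length(miss)) stop("unknown item id(s): ", paste(miss, collapse = ", "))
    ii <- match(ii, matrix$item_ids)
  }
  pp <- if (is.null(persons)) seq_along(matrix$person_ids) else persons
  if (is.character(pp)) pp <- match(pp, matrix$person_ids)
  response_matrix(matrix$responses[pp, ii, drop = FALSE],
                  person_ids = matrix$person_ids[pp],
                  item_ids = matrix$item_ids[ii],
                  group = if (is.null(matrix$group)) NULL else matrix$group[pp],
                  max_cat = matrix$max_cat[ii])
}

#' Construct a calibrated item bank
#'
#' An item bank stores, for each item, the ordered category threshold
#' parameters (delta) of the partial credit model on the theta metric, a
#' scoring map from raw to scored categories, and a human-readable label.
#'
#' @param item_ids character vector of unique item identifiers.
#' @param deltas list of numeric threshold vectors, one per item; item `i`
#'   with `m` thresholds has `m + 1` scored categories.
#' @param labels optional character item wordings.
#' @param scoring_maps optional list of integer vectors mapping raw category
#'   `k` (0-based; position `k + 1`) to its scored category.  Must start at 0
#'   and be non-decreasing with unit steps (adjacent categories only may be
#'   merged).  Default is the identity map.
#' @return An object of class `item_bank`.
#' @examples
#' b <- item_bank(c("a", "b"), list(c(-1, 0.5), c(0, 1)))
#' n_items(b)
#' @export
item_bank <- function(item_ids, deltas, labels = NULL, scoring_maps = NULL) {
  item_ids <- as.character(item_ids)
  if (length(item_ids) == 0) stop("empty bank")
  if (anyDuplicated(item_ids)) stop("duplicate item ids in bank")
  if (!is.list(deltas) || length(deltas) != length(item_ids))
    stop("deltas must be a list with one threshold vector per item")
  deltas <- lapply(deltas, as.numeric)
  if (any(vapply(deltas, length, 1L) < 1L))
    stop("every item needs at least one threshold")
  if (any(!vapply(deltas, function(d) all(is.finite(d)), TRUE)))
    stop("thresholds must be finite")
  if (is.null(labels)) labels <- item_ids
  labels <- as.character(rep_len(labels, length(item_ids)))
  if (is.null(scoring_maps)) {
    scoring_maps <- lapply(deltas, function(d) 0:length(d))
  }
  scoring_maps <- lapply(scoring_maps, as.integer)
  for (i in seq_along(item_ids)) {
    sm <- scoring_maps[[i]]
    if (sm[1] != 0L) stop("scoring map must start at 0 (item ", item_ids[i], ")")
    st <- diff(sm)
    if (any(st < 0L) || any(st > 1L))
      stop("scoring map must be non-decreasing in unit steps (item ",
           item_ids[i], ")")
    if (max(sm) != length(deltas[[i]]))
      stop(sprintf(
        "item '%s': %d thresholds but scoring map tops out at category %d",
        item_ids[i], length(deltas[[i]]), max(sm)))
  }
  names(deltas) <- names(labels) <- names(scoring_maps) <- item_ids
  structure(list(item_ids = item_ids, deltas = deltas, labels = labels,
                 scoring_maps = scoring_maps),
            class = "item_bank")
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("<item_bank> %d items, %s thresholds per item\n", n_items(x),
              paste(sort(unique(vapply(x$deltas, length, 1L))), collapse = "/")))
  invisible(x)
}

#' Number of items in a bank
#' @param bank an [item_bank()].
#' @export
n_items <- function(bank) length(bank$item_ids)

#' Subset an item bank
#' @param bank an [item_bank()].
#' @param items item ids or index to keep (order preserved as given).
#' @return An `item_bank` with the selected items.
#' @export
subset_bank <- function(bank, items) {
  if (is.character(items)) {
    miss <- setdiff(items, bank$item_ids)
    if (length(miss)) stop("unknown item id(s): ", paste(miss, collapse = ", "))
    idx <- match(items, bank$item_ids)
  } else idx <- items
  item_bank(bank$item_ids[idx], bank$deltas[idx], bank$labels[idx],
            bank$scoring_maps[idx])
}

#' The published 19-item physical-health care-planning experience bank
#'
#' The calibrated partial-credit item bank of the EQUIP physical-health
#' patient-reported experience measure: 19 items, each originally answered on
#' a 5-point Likert scale and rescored 0-1-1-2-2, leaving three scored
#' categories and two threshold parameters per item.
#'
#' @return An [item_bank()] with 19 items; `original_number` attribute keeps
#'   each item's number in the 67-item candidate pool.
#' @examples
#' bank <- equip_ph_bank()
#' range(unlist(bank$deltas))
#' @export
equip_ph_bank <- function() {
  wording <- c(
    "My care planning team ask about my existing physical health conditions.",
    "The physical health information in my care plan is personalised.",
    "My care planning team encourage me to take responsibility for my physical health care planning.",
    "My opinion on my physical health is valued by my care planning team.",
    "I know who reads the physical health information contained within my care plan",
    "My care planning team offer practical advice about my physical health.",
    "My care plan gives details of my physical health history.",
    "My thoughts about my physical health are included in my care plan.",
    "I experience continuity of care for the treatment of both my physical health conditions and mental health conditions.",
    "The physical health information in my care plan is helpful.",
    "Physical health reviews are carried out in a timely manner.",
    "My care planning team have a good understanding of my fears about future physical health conditions.",
    "My care planning team have the time they need to talk to me about physical health concerns.",
    "The content of my physical health care plan is responsive to changes in my circumstances.",
    "Information in my care plan has helped me to maintain my physical health.",
    "I was asked what I wanted in the physical health information in my care plan.",
    "The care plan adequately addresses any side effects I experience from my medication.",
    "I have had the opportunity to invite all the relevant people to care planning meetings related to my physical health.",
    "My care planning team makes sure my mental health is not prioritised over my physical health.")
  d1 <- c(-1.20, -1.92, -2.01, -2.03, -1.02, -1.42, -1.16, -0.62, -0.68,
          -1.61, -0.53, -0.77, -1.18, -1.14, -0.63, -0.25, -1.22, -0.55, -1.15)
  d2 <- c(0.12, 0.20, 0.27, 0.38, 0.43, 0.51, 0.52, 0.76, 0.77, 0.83, 0.86,
          0.92, 0.94, 1.06, 1.08, 1.13, 1.13, 1.27, 1.51)
  orig <- c(50, 24, 53, 37, 4, 55, 13, 15, 52, 22, 16, 62, 56, 44, 27, 41,
            60, 46, 51)
  bank <- item_bank(paste0("item", seq_len(19)),
                    deltas = Map(c, d1, d2),
                    labels = wording,
                    scoring_maps = rep(list(c(0L, 1L, 1L, 2L, 2L)), 19))
  attr(bank, "original_number") <- orig
  bank
}
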