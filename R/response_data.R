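#' Multi-cohort item-response dataset
#'
#' Bundles a persons-by-items matrix of ordinal response codes with the
#' person-level metadata the harmonization model needs: a cohort (group)
#' label per person, an optional family identifier (for twin designs), and a
#' group-by-item administration mask recording which items each cohort was
#' actually given. Items never administered to a group are missing *by
#' design* and are distinguished from ordinary missing responses: the former
#' are encoded in the mask, the latter as `NA` on an administered item.
#'
#' @param data A data frame with one row per person containing the item
#'   columns, the group column, and optionally a family column.
#' @param items Character vector of item column names, in scale order.
#' @param group Name of the group (cohort) column. Coerced to factor; its
#'   levels define the group indexing `1..J`.
#' @param family Optional name of the family-identifier column.
#' @param C Highest category code; responses must lie in `0..C`. Both
#'   questionnaires supported here are 3-point scales, so the default is 2.
#' @param admin_mask Optional logical groups-by-items matrix (rows named by
#'   group level, columns by item). When `NULL` it is inferred: item `k`
#'   counts as administered in group `j` iff any group-`j` person has a
#'   non-missing code on `k`.
#' @param groups Optional character vector fixing the group levels (useful
#'   for empty datasets or to impose an ordering); default the sorted
#'   observed labels.
#'
#' @return An object of class `response_dataset`: a list with elements
#'   `persons` (tibble of person id, group, family), `responses` (integer
#'   matrix), `admin` (logical matrix), and `C`.
#' @export
#' @examples
#' df <- tibble::tibble(group = c("A", "A", "B"),
#'                      i1 = c(0, 1, 2), i2 = c(2, 1, 0))
#' response_dataset(df, items = c("i1", "i2"))
response_dataset <- function(data, items, group = "group", family = NULL,
                             C = 2, admin_mask = NULL, groups = NULL) {
  stopifnot(is.data.frame(data), length(items) >= 1)
  missing_cols <- setdiff(c(items, group, family), names(data))
  if (length(missing_cols) > 0) {
    stop("columns not found in data: ", paste(missing_cols, collapse = ", "))
  }
  grp <- if (is.null(groups)) factor(data[[group]])
         else factor(data[[group]], levels = groups)
  if (nlevels(grp) < 1 || anyNA(grp)) {
    stop("unknown or missing group label in column '", group, "'")
  }

  Y <- matrix(NA_integer_, nrow(data), length(items),
              dimnames = list(NULL, items))
  for (k in seq_along(items)) {
    v <- data[[items[k]]]
    ok <- is.na(v) | (is.finite(v) & v == round(v) & v >= 0 & v <= C)
    if (!all(ok)) {
      bad <- which(!ok)[1]
      stop("non-integer or out-of-range response code in row ", bad,
           ", column '", items[k], "': ", v[bad], " (allowed 0..", C, ")")
    }
    Y[, k] <- as.integer(v)
  }

  counts <- rowsum((!is.na(Y)) + 0L, grp)
  inferred <- matrix(FALSE, nlevels(grp), length(items),
                     dimnames = list(levels(grp), items))
  if (nrow(counts) > 0) inferred[rownames(counts), ] <- counts > 0
  if (is.null(admin_mask)) {
    admin <- inferred
  } else {
    admin <- as.matrix(admin_mask)
    storage.mode(admin) <- "logical"
    if (!setequal(rownames(admin), levels(grp)) ||
        !setequal(colnames(admin), items)) {
      stop("admin_mask dimnames must match group levels and item names")
    }
    admin <- admin[levels(grp), items, drop = FALSE]
    if (any(inferred & !admin)) {
      bad <- which(inferred & !admin, arr.ind = TRUE)[1, ]
      stop("observed responses on item '", items[bad[2]],
           "' in group '", levels(grp)[bad[1]],
           "' contradict admin_mask = FALSE")
    }
  }

  persons <- tibble::tibble(
    person = seq_len(nrow(data)),
    group = grp,
    family = if (is.null(family)) NA_character_ else as.character(data[[family]])
  )
  structure(list(persons = persons, responses = Y, admin = admin,
                 C = as.integer(C)),
            class = "response_dataset")
}

#' @export
print.response_dataset <- function(x, ...) {
  cat("<response_dataset>\n")
  cat("  persons: ", nrow(x$responses), "  items: ", ncol(x$responses),
      "  categories: 0..", x$C, "\n", sep = "")
  tab <- table(x$persons$group)
  cat("  groups:  ", paste(sprintf("%s (n=%d, %d items)", names(tab), tab,
                                   rowSums(x$admin)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
#' @importFrom tibble as_tibble
as_tibble.response_dataset <- function(x, ...) {
  out <- tibble::as_tibble(x$responses)
  dplyr::bind_cols(x$persons[c("group", "family")], out)
}

n_groups <- function(ds) nrow(ds$admin)
group_levels <- function(ds) rownames(ds$admin)
item_names <- function(ds) colnames(ds$responses)

#' Read a multi-cohort responses table from CSV
#'
#' Reads a comma-separated, UTF-8, headered table with one row per person
#' and builds a validated [response_dataset()]. Unless an explicit
#' administration mask is given, design missingness is inferred from
#' all-missing group/item cells.
#'
#' @param path Path to the responses CSV.
#' @param items Item column names; default everything except `group`/`family`.
#' @param group,family,C,admin_mask As in [response_dataset()]; `admin_mask`
#'   may also be a path to a CSV of 0/1 with a `group` column and one column
#'   per item.
#' @param na Token representing a missing response (default `"NA"`).
#' @return A validated [response_dataset()].
#' @export
read_responses <- function(path, items = NULL, group = "group", family = NULL,
                           C = 2, na = "NA", admin_mask = NULL) {
  df <- readr::read_csv(path, na = na, show_col_types = FALSE,
                        progress = FALSE)
  if (is.null(items)) {
    items <- setdiff(names(df), c(group, family))
  }
  if (is.character(admin_mask) && length(admin_mask) == 1) {
    m <- readr::read_csv(admin_mask, show_col_types = FALSE, progress = FALSE)
    mask <- as.matrix(m[items])
    rownames(mask) <- as.character(m[[group]])
    admin_mask <- mask > 0
  }
  response_dataset(df, items = items, group = group, family = family,
                   C = C, admin_mask = admin_mask)
}

#' Write a responses table to CSV
#'
#' Inverse of [read_responses()] on the canonical dialect (comma-separated,
#' header row, `NA` missing token); reading the file back reproduces the
#' dataset exactly.
#'
#' @param ds A [response_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(ds, path) {
  df <- dplyr::bind_cols(
    ds$persons["group"],
    if (!all(is.na(ds$persons$family))) ds$persons["family"],
    tibble::as_tibble(ds$responses)
  )
  readr::write_csv(df, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Keep only persons with complete data on a set of items
#'
#' Completeness is judged per person against the items *administered to that
#' person's group*: an item a cohort was never given cannot make its members
#' incomplete. This is the complete-case rule used to construct per-scale
#' analysis samples.
#'
#' @param ds A [response_dataset()].
#' @param items Item subset defining the scale; default all items.
#' @return The filtered `response_dataset`, with the number of removed
#'   persons in attribute `"n_removed"`.
#' @export
complete_case_filter <- function(ds, items = NULL) {
  items <- items %||% item_names(ds)
  stopifnot(all(items %in% item_names(ds)))
  adm <- ds$admin[as.integer(ds$persons$group), items, drop = FALSE]
  miss <- is.na(ds$responses[, items, drop = FALSE]) & adm
  keep <- rowSums(miss) == 0
  if (!any(keep)) stop("no complete cases on the requested items")
  out <- subset_persons(ds, keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Randomly keep one person per family
#'
#' For twin cohorts, avoids within-family dependence by selecting one member
#' of each family uniformly at random. Persons without a family ID are an
#' error unless `singletons = "keep"` treats them as one-person families.
#'
#' @param ds A [response_dataset()].
#' @param seed Integer seed making the selection reproducible.
#' @param singletons `"error"` (default) or `"keep"` for persons with
#'   missing family IDs.
#' @return The thinned `response_dataset`.
#' @export
select_one_per_family <- function(ds, seed = NULL,
                                  singletons = c("error", "keep")) {
  singletons <- match.arg(singletons)
  fam <- ds$persons$family
  if (anyNA(fam)) {
    if (singletons == "error") {
      stop("missing family IDs; use singletons = \"keep\" to retain them")
    }
    fam[is.na(fam)] <- paste0(".singleton.", which(is.na(fam)))
  }
  if (!is.null(seed)) set.seed(seed)
  pick <- unsplit(lapply(split(seq_along(fam), fam), function(idx) {
    chosen <- if (length(idx) == 1) idx else idx[sample.int(length(idx), 1)]
    idx == chosen
  }), fam)
  subset_persons(ds, pick)
}

subset_persons <- function(ds, keep) {
  out <- ds
  out$persons <- ds$persons[keep, , drop = FALSE]
  out$persons$person <- seq_len(sum(keep))
  out$responses <- ds$responses[keep, , drop = FALSE]
  out$persons$group <- factor(out$persons$group, levels = group_levels(ds))
  out
}

#' Observed sum-score statistics for one group
#'
#' Mean and standard deviation (denominator `n - 1`) of the raw sum score
#' over a set of items, within one group — the `M` and `SD` columns of the
#' scale-level DTF tables.
#'
#' @param ds A [response_dataset()] (complete cases on `items` assumed).
#' @param group Group level to summarize.
#' @param items Item subset; default all items administered to `group`.
#' @return A one-row tibble: `group`, `n`, `mean`, `sd`, `ts` (maximum
#'   possible score, `C * length(items)`).
#' @export
observed_sum_stats <- function(ds, group, items = NULL) {
  stopifnot(group %in% group_levels(ds))
  items <- items %||% item_names(ds)[ds$admin[group, ]]
  if (!all(ds$admin[group, items])) {
    stop("some requested items are not administered in group '", group, "'")
  }
  rows <- ds$persons$group == group
  scores <- rowSums(ds$responses[rows, items, drop = FALSE])
  if (anyNA(scores)) stop("missing responses present; filter complete cases first")
  if (length(scores) < 2) stop("need at least 2 persons for an SD")
  tibble::tibble(group = group, n = length(scores),
                 mean = mean(scores), sd = stats::sd(scores),
                 ts = ds$C * length(items))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
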