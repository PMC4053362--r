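#' Multi-label case tables
#'
#' An `ml_dataset` is a tibble with one row per case: a `case_id` column, a
#' `labels` list-column holding each case's non-empty label set, and one 0/1
#' column per binary feature (symptom present/absent). The ordered label
#' alphabet is carried as an attribute and fixes ranking tie-break order for
#' the whole lifetime of the dataset.
#'
#' @param features a numeric 0/1 matrix or data frame, one row per case.
#' @param labelsets a list of character vectors, one non-empty label set per
#'   case; every label must belong to `alphabet`.
#' @param alphabet ordered character vector of unique label names (length
#'   >= 2). Defaults to the sorted union of the observed labels.
#' @param case_ids optional character identifiers, one per case.
#'
#' @return A tibble of class `ml_dataset` with columns `case_id`, `labels`
#'   and the feature columns, plus attributes `alphabet` and `feature_cols`.
#' @examples
#' d <- ml_dataset(matrix(c(1, 0, 0, 1), 2, 2), list("A", c("A", "B")))
#' ml_alphabet(d)
#' @export
ml_dataset <- function(features, labelsets, alphabet = NULL, case_ids = NULL) {
  features <- as.matrix(features)
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  }
  n <- nrow(features)
  if (n < 1L || ncol(features) < 1L) {
    abort("need at least one case and one feature", class = "mlcp_empty_input")
  }
  if (!is.list(labelsets) || length(labelsets) != n) {
    abort("`labelsets` must be a list with one entry per case")
  }
  labelsets <- lapply(labelsets, as.character)
  empty <- which(lengths(labelsets) == 0L)
  if (length(empty)) {
    abort(sprintf("empty label set in row %d", empty[1L]),
          class = "mlcp_empty_labelset")
  }
  if (is.null(alphabet)) alphabet <- sort(unique(unlist(labelsets)))
  validate_alphabet(alphabet)
  if (is.null(case_ids)) case_ids <- as.character(seq_len(n))
  bad <- which(!stats::complete.cases(features) |
                 apply(features, 1L, function(r) any(!r %in% c(0, 1))))
  if (length(bad)) {
    abort(sprintf("non-binary or missing feature value in row %d", bad[1L]),
          class = "mlcp_parse_error")
  }
  unknown <- setdiff(unique(unlist(labelsets)), alphabet)
  if (length(unknown)) {
    abort(paste0("label not in alphabet: ", unknown[1L]),
          class = "mlcp_alphabet_error")
  }
  out <- tibble::tibble(case_id = as.character(case_ids),
                        labels = lapply(labelsets, function(l) {
                          alphabet[alphabet %in% l]
                        }))
  out <- dplyr::bind_cols(out, tibble::as_tibble(features))
  new_ml_dataset(out, alphabet, colnames(features))
}

new_ml_dataset <- function(tbl, alphabet, feature_cols) {
  structure(tbl,
            alphabet = alphabet,
            feature_cols = feature_cols,
            class = c("ml_dataset", class(tibble::tibble())))
}

validate_alphabet <- function(alphabet) {
  if (length(alphabet) < 2L || anyDuplicated(alphabet) ||
      any(!nzchar(alphabet))) {
    abort("alphabet must hold >= 2 unique non-empty label names",
          class = "mlcp_alphabet_error")
  }
  invisible(alphabet)
}

#' Accessors for multi-label datasets
#'
#' @param data an `ml_dataset` (or PT5-transformed table).
#' @return `ml_alphabet()` the ordered label alphabet; `ml_features()` the
#'   numeric feature matrix; `ml_labelsets()` the list of label sets.
#' @export
ml_alphabet <- function(data) attr(data, "alphabet")

#' @rdname ml_alphabet
#' @export
ml_features <- function(data) {
  cols <- attr(data, "feature_cols")
  as.matrix(data[, cols, drop = FALSE])
}

#' @rdname ml_alphabet
#' @export
ml_labelsets <- function(data) data$labels

# row subset that keeps the ml_dataset attributes (dplyr verbs drop them)
ml_subset <- function(data, idx) {
  out <- as.data.frame(data)[idx, , drop = FALSE]
  out <- tibble::as_tibble(out)
  new_ml_dataset(out, ml_alphabet(data), attr(data, "feature_cols"))
}

#' Read and write multi-label case tables
#'
#' Two on-disk dialects are supported, both plain delimited text with a
#' header. In the `"set"` dialect a single column holds each case's label
#' set as delimiter-separated names (`"spleen deficiency;qi deficiency"`).
#' In the `"indicator"` dialect each label has its own 0/1 column. All other
#' non-id columns are taken as binary features unless `feature_cols` names
#' them explicitly. An ordered alphabet can be pinned via `alphabet` or a
#' JSON sidecar file (an array of label names) so that ranking tie-breaks
#' are reproducible across machines.
#'
#' @param path file to read or write.
#' @param dialect `"set"` or `"indicator"`.
#' @param label_col name of the label-set column (`"set"` dialect).
#' @param label_cols names of the 0/1 label columns (`"indicator"` dialect);
#'   their order defines the alphabet unless `alphabet` overrides it.
#' @param feature_cols feature column names; default: everything that is not
#'   an id or label column.
#' @param alphabet ordered label names, or the path of a JSON sidecar.
#' @param id_col optional case-id column name.
#' @param sep field delimiter (`","`; use `"\t"` for TSV).
#' @param label_sep within-cell separator of the `"set"` dialect.
#' @param drop_empty if `TRUE`, rows with empty label sets are dropped with
#'   a warning instead of raising an error.
#' @return `read_ml_dataset()` an [ml_dataset()]; `write_ml_dataset()` the
#'   path, invisibly.
#' @export
read_ml_dataset <- function(path, dialect = c("set", "indicator"),
                            label_col = "labels", label_cols = NULL,
                            feature_cols = NULL, alphabet = NULL,
                            id_col = NULL, sep = ",", label_sep = ";",
                            drop_empty = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) abort("empty input file", class = "mlcp_empty_input")
  if (is.character(alphabet) && length(alphabet) == 1L &&
      file.exists(alphabet)) {
    alphabet <- as.character(jsonlite::read_json(alphabet, simplifyVector = TRUE))
  }
  case_ids <- if (!is.null(id_col)) as.character(raw[[id_col]]) else NULL
  if (dialect == "set") {
    if (!label_col %in% names(raw)) {
      abort(paste0("label column not found: ", label_col),
            class = "mlcp_parse_error")
    }
    labelsets <- strsplit(as.character(raw[[label_col]]), label_sep,
                          fixed = TRUE)
    labelsets <- lapply(labelsets, function(l) trimws(l[nzchar(trimws(l))]))
    drop_cols <- c(label_col, id_col)
  } else {
    if (is.null(label_cols)) {
      abort("`label_cols` is required for the indicator dialect")
    }
    if (!all(label_cols %in% names(raw))) {
      abort("missing indicator label columns", class = "mlcp_parse_error")
    }
    ind <- as.matrix(raw[, label_cols, drop = FALSE])
    labelsets <- apply(ind, 1L, function(r) label_cols[r == 1], simplify = FALSE)
    if (is.null(alphabet)) alphabet <- label_cols
    drop_cols <- c(label_cols, id_col)
  }
  if (is.null(feature_cols)) feature_cols <- setdiff(names(raw), drop_cols)
  feats <- raw[, feature_cols, drop = FALSE]
  for (j in seq_along(feats)) {
    v <- feats[[j]]
    bad <- which(is.na(v) | !(v %in% c(0, 1)))
    if (length(bad)) {
      abort(sprintf("non-binary feature value in row %d, column '%s'",
                    bad[1L], feature_cols[j]),
            class = "mlcp_parse_error")
    }
  }
  if (drop_empty) {
    empty <- lengths(labelsets) == 0L
    if (any(empty)) {
      warn(sprintf("dropping %d case(s) with empty label sets", sum(empty)))
      feats <- feats[!empty, , drop = FALSE]
      labelsets <- labelsets[!empty]
      case_ids <- case_ids[!empty]
    }
  }
  ml_dataset(feats, labelsets, alphabet = alphabet, case_ids = case_ids)
}

#' @rdname read_ml_dataset
#' @param data an [ml_dataset()] to write.
#' @export
write_ml_dataset <- function(data, path, dialect = c("set", "indicator"),
                             sep = ",", label_sep = ";") {
  dialect <- match.arg(dialect)
  stopifnot(inherits(data, "ml_dataset"))
  alpha <- ml_alphabet(data)
  out <- data.frame(case_id = data$case_id, check.names = FALSE)
  if (dialect == "set") {
    out$labels <- vapply(ml_labelsets(data), paste, "", collapse = label_sep)
  } else {
    for (a in alpha) {
      out[[a]] <- vapply(ml_labelsets(data), function(l) as.integer(a %in% l),
                         integer(1L))
    }
  }
  out <- cbind(out, as.data.frame(ml_features(data), check.names = FALSE))
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Expand multi-label cases into single-label examples (PT5)
#'
#' The PT5 problem transformation replicates every case once per label it
#' carries: a case with label set of size l contributes l rows with the
#' feature vector copied verbatim and one label each. Rows keep the source
#' order; within a case, labels follow alphabet order. The `origin` column
#' records which source row each example came from, which downstream scorers
#' use to exclude a case's own replicates from nonconformity pools.
#'
#' @param data an [ml_dataset()].
#' @return A tibble of class `pt5_df` with columns `origin`, `case_id`,
#'   `label` and the feature columns; `alphabet` and `feature_cols` travel
#'   as attributes. The number of rows equals the total label count.
#' @examples
#' d <- ml_dataset(matrix(c(1, 0), 1, 2), list(c("A", "B")))
#' pt5_transform(d) # two rows, labels A then B
#' @export
pt5_transform <- function(data) {
  stopifnot(inherits(data, "ml_dataset"))
  sets <- ml_labelsets(data)
  l <- lengths(sets)
  origin <- rep(seq_len(nrow(data)), l)
  new_pt5_df(ml_features(data)[origin, , drop = FALSE],
             labels = unlist(sets),
             origin = origin,
             alphabet = ml_alphabet(data),
             case_id = data$case_id[origin])
}

new_pt5_df <- function(features, labels, origin, alphabet, case_id = NULL) {
  features <- as.matrix(features)
  if (is.null(case_id)) case_id <- as.character(origin)
  out <- tibble::tibble(origin = as.integer(origin),
                        case_id = as.character(case_id),
                        label = as.character(labels))
  out <- dplyr::bind_cols(out, tibble::as_tibble(features))
  structure(out,
            alphabet = alphabet,
            feature_cols = colnames(features),
            class = c("pt5_df", class(tibble::tibble())))
}

#' Collapse a PT5 table back to multi-label cases
#'
#' Inverse of [pt5_transform()]: groups rows by `origin` and collects the
#' labels back into sets.
#'
#' @param data a `pt5_df`.
#' @return An [ml_dataset()].
#' @export
pt5_collapse <- function(data) {
  stopifnot(inherits(data, "pt5_df"))
  ord <- order(unique(data$origin))
  origins <- unique(data$origin)[ord]
  first <- match(origins, data$origin)
  feats <- ml_features(data)[first, , drop = FALSE]
  sets <- split(data$label, factor(data$origin, levels = origins))
  ml_dataset(feats, unname(sets), alphabet = ml_alphabet(data),
             case_ids = data$case_id[first])
}
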