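#' Construct an annotation table
#'
#' An annotation table maps each compound to a binary label vector over the
#' eleven pathway classes of [pathway_classes()].  Every retained compound
#' must carry at least one class: compounds without any pathway information
#' are excluded from benchmarks by construction.
#'
#' @param labels A numeric or logical matrix with 11 columns (registry order)
#'   and one row per compound; row names are the compound identifiers
#'   (opaque, case-sensitive strings, e.g. KEGG ligand ids).  Entries must be
#'   0/1.  A 0-row matrix yields an empty table.
#' @return An object of class `annotation_table`.
#' @seealso [read_annotations()], [average_label_count()]
#' @export
annotation_table <- function(labels) {
  if (is.data.frame(labels)) labels <- as.matrix(labels)
  if (!is.matrix(labels)) stop("`labels` must be a matrix", call. = FALSE)
  mode(labels) <- "integer"
  if (ncol(labels) != .N_CLASSES) {
    stop("`labels` must have exactly ", .N_CLASSES, " columns", call. = FALSE)
  }
  if (nrow(labels) > 0L) {
    ids <- rownames(labels)
    if (is.null(ids) || anyNA(ids) || any(ids == "")) {
      stop("`labels` must have non-empty row names (compound ids)",
        call. = FALSE
      )
    }
    if (anyDuplicated(ids)) {
      stop("duplicate compound ids in `labels`", call. = FALSE)
    }
    if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
      stop("label entries must be 0 or 1", call. = FALSE)
    }
    if (any(rowSums(labels) == 0L)) {
      stop("every compound must carry at least one pathway class",
        call. = FALSE
      )
    }
  }
  colnames(labels) <- as.character(1:.N_CLASSES)
  structure(list(labels = labels), class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat(
    "Annotation table:", nrow(x$labels), "compounds,",
    sum(x$labels), "class memberships\n"
  )
  invisible(x)
}

#' Compound identifiers of an annotation table
#' @param annotations An `annotation_table`.
#' @return Character vector of compound ids, in table order.
#' @export
compounds <- function(annotations) {
  stopifnot(inherits(annotations, "annotation_table"))
  rownames(annotations$labels) %||% character(0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Label matrix of an annotation table
#' @param annotations An `annotation_table`.
#' @return Integer 0/1 matrix, compounds x 11 classes.
#' @export
labels_matrix <- function(annotations) {
  stopifnot(inherits(annotations, "annotation_table"))
  annotations$labels
}

#' Per-class compound counts
#'
#' Number of compounds annotated to each pathway class.  Because compounds
#' may belong to several classes the counts sum to the total number of
#' (compound, class) memberships, not the number of compounds.
#'
#' @param annotations An `annotation_table`.
#' @return Named integer vector of length 11.
#' @export
class_counts <- function(annotations) {
  stopifnot(inherits(annotations, "annotation_table"))
  counts <- colSums(labels_matrix(annotations))
  stats::setNames(as.integer(counts), as.character(1:.N_CLASSES))
}

#' Label-multiplicity histogram
#'
#' Counts of compounds by number of pathway classes they belong to.
#'
#' @param annotations An `annotation_table`.
#' @return Named integer vector; names are label counts ("1", "2", ...).
#' @export
label_multiplicity <- function(annotations) {
  stopifnot(inherits(annotations, "annotation_table"))
  m <- rowSums(labels_matrix(annotations))
  tab <- table(factor(m, levels = seq_len(max(m, 1))))
  stats::setNames(as.integer(tab), names(tab))
}

#' Average number of pathway classes per compound
#'
#' The mean label count lambda: the total number of (compound, class)
#' memberships divided by the number of compounds.  Lambda is also, exactly,
#' the sum of the eleven per-order accuracies of any full ranking evaluation,
#' since each true class occupies exactly one rank.
#'
#' @param annotations A non-empty `annotation_table`.
#' @return A single number >= 1.
#' @export
average_label_count <- function(annotations) {
  stopifnot(inherits(annotations, "annotation_table"))
  n <- nrow(labels_matrix(annotations))
  if (n == 0L) stop("annotation table is empty", call. = FALSE)
  sum(labels_matrix(annotations)) / n
}

#' Expected first-order accuracy of a random guess
#'
#' Under a uniformly random permutation of the eleven classes, the chance
#' that any given rank hits a true class of a compound with `m` labels is
#' `m/11`; averaged over compounds this is lambda/11.
#'
#' @param annotations A non-empty `annotation_table`.
#' @return A fraction in (0, 1].
#' @export
random_baseline <- function(annotations) {
  average_label_count(annotations) / .N_CLASSES
}

#' Recommended prediction-order cutoff k
#'
#' The smallest integer greater than or equal to the average label count:
#' the number of top-ranked classes a user should inspect.
#'
#' @param annotations A non-empty `annotation_table`.
#' @return An integer in 1..11.
#' @export
order_cutoff_k <- function(annotations) {
  as.integer(ceiling(average_label_count(annotations)))
}

#' Read an annotation table from a tab-separated file
#'
#' Two dialects are accepted.  In the `"delimited-codes"` dialect each row is
#' `compound_id<TAB>codes` with codes packed as e.g. `4;6;8` or `4, 6, 8`.
#' In the `"one-row-per-pair"` dialect each row is
#' `compound_id<TAB>single_code` and a compound's classes accumulate over
#' rows.  Duplicate (compound, code) pairs collapse to a single indicator.
#' '#' comment lines and blank lines are skipped; a single header line is
#' detected and skipped when its second field does not parse as class codes.
#' Columns beyond the second (e.g. compound names) are ignored.
#'
#' @param path Path to the file.
#' @param dialect `"delimited-codes"` (default) or `"one-row-per-pair"`.
#' @return An `annotation_table`; empty input yields an empty table.
#' @export
read_annotations <- function(path,
                             dialect = c("delimited-codes", "one-row-per-pair")) {
  dialect <- match.arg(dialect)
  dat <- .read_data_lines(path)
  if (length(dat$lines) == 0L) {
    return(annotation_table(matrix(integer(0), 0, .N_CLASSES)))
  }
  fields <- strsplit(dat$lines, "\t", fixed = TRUE)

  parse_codes <- function(s) {
    toks <- strsplit(trimws(s), "[,;[:space:]]+")[[1]]
    toks[nzchar(toks)]
  }
  # Header detection: a first line whose code field is a recognizable column
  # name (anything else with unparseable codes is an error, not a header).
  header_names <- c(
    "class_codes", "class_code", "codes", "code", "classes",
    "pathway_class", "pathway_classes"
  )
  start <- 1L
  if (length(fields[[1]]) >= 2L &&
    tolower(trimws(fields[[1]][2])) %in% header_names) {
    start <- 2L
  }
  if (start > length(fields)) {
    return(annotation_table(matrix(integer(0), 0, .N_CLASSES)))
  }

  lab <- new.env(parent = emptyenv())
  order_seen <- character(0)
  for (i in seq(start, length(fields))) {
    f <- fields[[i]]
    ln <- dat$lineno[i]
    if (length(f) < 2L || !nzchar(trimws(f[1]))) {
      stop("malformed annotation row at line ", ln,
        ": expected at least 2 tab-separated fields",
        call. = FALSE
      )
    }
    id <- trimws(f[1])
    toks <- parse_codes(f[2])
    if (length(toks) == 0L) {
      stop("compound with zero class codes at line ", ln, call. = FALSE)
    }
    if (dialect == "one-row-per-pair" && length(toks) != 1L) {
      stop("expected a single class code at line ", ln,
        " (one-row-per-pair dialect)",
        call. = FALSE
      )
    }
    codes <- suppressWarnings(as.integer(toks))
    if (anyNA(codes)) {
      stop("unparseable class code at line ", ln, ": '", f[2], "'",
        call. = FALSE
      )
    }
    if (any(codes < 1L | codes > .N_CLASSES)) {
      stop("class code outside 1..", .N_CLASSES, " at line ", ln,
        call. = FALSE
      )
    }
    if (!exists(id, envir = lab, inherits = FALSE)) {
      order_seen <- c(order_seen, id)
      assign(id, integer(0), envir = lab)
    }
    assign(id, union(get(id, envir = lab), codes), envir = lab)
  }

  m <- matrix(0L, length(order_seen), .N_CLASSES,
    dimnames = list(order_seen, as.character(1:.N_CLASSES))
  )
  for (id in order_seen) m[id, get(id, envir = lab)] <- 1L
  annotation_table(m)
}

#' Write an annotation table to a tab-separated file
#'
#' Writes the delimited-codes dialect (`compound_id<TAB>codes`, codes joined
#' by `;`), readable back with [read_annotations()].
#'
#' @param annotations An `annotation_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_table"))
  m <- labels_matrix(annotations)
  codes <- apply(m, 1L, function(r) paste(which(r == 1L), collapse = ";"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("compound_id\tclass_codes", con)
  if (nrow(m) > 0L) {
    writeLines(paste(rownames(m), codes, sep = "\t"), con)
  }
  invisible(path)
}

#' Build an annotation table realizing a label-multiplicity distribution
#'
#' Constructs a table with `counts[m]` compounds carrying exactly `m` class
#' labels, for deriving arithmetic identities (lambda, baseline, cutoff k)
#' from a stated multiplicity distribution.  Class identities are irrelevant
#' to those quantities and are assigned deterministically by cycling through
#' the registry.
#'
#' @param counts Integer vector; `counts[m]` is the number of compounds with
#'   `m` labels.  `length(counts)` must be at most 11.
#' @return An `annotation_table` with `sum(counts)` compounds.
#' @examples
#' # the benchmark's multiplicity distribution over 3,137 compounds
#' at <- annotations_from_multiplicity(c(2820, 226, 53, 23, 9, 4, 2))
#' average_label_count(at)
#' @export
annotations_from_multiplicity <- function(counts) {
  counts <- as.integer(counts)
  if (length(counts) < 1L || length(counts) > .N_CLASSES ||
    anyNA(counts) || any(counts < 0L)) {
    stop("`counts` must be non-negative counts for multiplicities 1..11",
      call. = FALSE
    )
  }
  n <- sum(counts)
  if (n == 0L) stop("`counts` sums to zero compounds", call. = FALSE)
  mult <- rep(seq_along(counts), counts)
  m <- matrix(0L, n, .N_CLASSES)
  rownames(m) <- sprintf("M%05d", seq_len(n))
  for (i in seq_len(n)) {
    cls <- ((i - 1L + seq_len(mult[i]) - 1L) %% .N_CLASSES) + 1L
    m[i, cls] <- 1L
  }
  annotation_table(m)
}

#' Build a single-label annotation table from per-class counts
#'
#' One compound per (class, index): `counts[j]` compounds annotated to class
#' `j` only.  Useful for realizing a printed per-class census as an
#' annotation multiset.
#'
#' @param counts Integer vector of length 11 (registry order).
#' @return An `annotation_table` with `sum(counts)` single-label compounds.
#' @export
annotations_from_class_counts <- function(counts) {
  counts <- as.integer(counts)
  if (length(counts) != .N_CLASSES || anyNA(counts) || any(counts < 0L)) {
    stop("`counts` must be 11 non-negative integers", call. = FALSE)
  }
  n <- sum(counts)
  if (n == 0L) stop("`counts` sums to zero compounds", call. = FALSE)
  cls <- rep(1:.N_CLASSES, counts)
  m <- matrix(0L, n, .N_CLASSES)
  rownames(m) <- sprintf("K%02d_%04d", cls, unlist(lapply(counts, seq_len)))
  m[cbind(seq_len(n), cls)] <- 1L
  annotation_table(m)
}
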