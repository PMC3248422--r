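#' Construct an interaction network
#'
#' An undirected, weighted chemical-chemical interaction network.  Edges are
#' stored on unordered compound pairs; weights are interaction confidence
#' scores in (0, 1] (the probability-like STITCH combined score).  Absence of
#' an edge means weight 0, and self-interactions are never represented.
#'
#' Rows listing the same unordered pair more than once (including opposite
#' directions) collapse to a single edge carrying the maximum weight; a
#' warning is emitted when the duplicates disagree.
#'
#' @param edges A data frame with columns `a`, `b` (character compound ids)
#'   and `weight` (numeric in (0, 1]).  May have zero rows.
#' @return An object of class `interaction_network`.
#' @seealso [read_interactions()], [restrict_to_annotated()]
#' @export
interaction_network <- function(edges = data.frame(
                                  a = character(0), b = character(0),
                                  weight = numeric(0)
                                )) {
  stopifnot(
    is.data.frame(edges),
    all(c("a", "b", "weight") %in% names(edges))
  )
  a <- as.character(edges$a)
  b <- as.character(edges$b)
  w <- as.numeric(edges$weight)
  if (any(a == b)) {
    stop("self-interactions are not representable (w(c,c) = 0 always)",
      call. = FALSE
    )
  }
  if (anyNA(w) || any(w <= 0) || any(w > 1)) {
    stop("edge weights must lie in (0, 1]", call. = FALSE)
  }
  # canonical unordered representation
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- tapply(w, key, max)
    nconf <- sum(tapply(w, key, function(x) length(unique(x)) > 1L))
    if (nconf > 0L) {
      warning(nconf, " duplicated pair(s) with conflicting scores; ",
        "keeping the maximum",
        call. = FALSE
      )
    }
    keys <- names(agg)
    parts <- strsplit(keys, "\r", fixed = TRUE)
    lo <- vapply(parts, `[`, character(1), 1L)
    hi <- vapply(parts, `[`, character(1), 2L)
    w <- as.numeric(agg)
  }
  ord <- order(lo, hi)
  structure(
    list(edges = data.frame(
      a = lo[ord], b = hi[ord], weight = w[ord],
      stringsAsFactors = FALSE
    )),
    class = "interaction_network"
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(
    "Interaction network:", nrow(x$edges), "edges over",
    length(network_compounds(x)), "compounds\n"
  )
  invisible(x)
}

#' Edges of an interaction network
#' @param network An `interaction_network`.
#' @return Data frame with columns `a`, `b`, `weight`; `a < b` lexically.
#' @export
network_edges <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  network$edges
}

#' Number of edges
#' @param network An `interaction_network`.
#' @return Integer edge count.
#' @export
n_edges <- function(network) {
  nrow(network_edges(network))
}

#' Compounds incident to at least one edge
#' @param network An `interaction_network`.
#' @return Sorted character vector of compound ids.
#' @export
network_compounds <- function(network) {
  e <- network_edges(network)
  sort(unique(c(e$a, e$b)))
}

#' Confidence score of one compound pair
#'
#' @param network An `interaction_network`.
#' @param a,b Compound ids.
#' @return The edge weight, or 0 when no edge exists or `a == b`.
#' @export
edge_weight <- function(network, a, b) {
  e <- network_edges(network)
  if (a == b) {
    return(0)
  }
  hit <- which(e$a == min(a, b) & e$b == max(a, b))
  if (length(hit) == 0L) 0 else e$weight[hit]
}

#' Read an interaction network from a tab-separated file
#'
#' Expected layout is STITCH-like: two compound-id columns followed by a
#' score.  With a header line, a column named `score` or `combined_score` is
#' used; without one, column 3 of a 3-column file, else the last column
#' (STITCH's `chemical_chemical.links.detailed` puts the combined score
#' last).  Other columns (per-evidence-channel scores and the like) are
#' ignored with a log line.  '#' comments and blank lines are skipped.
#'
#' Scores on the `"unit"` scale must lie in \[0, 1\]; on the `"stitch999"`
#' scale they must be integers 0--999 and are divided by 1000.  Zero-score
#' rows are dropped silently; self-pair rows are dropped with a warning;
#' repeated or bidirectional listings of a pair collapse to the maximum
#' weight with a warning when they disagree.
#'
#' @param path Path to the file.
#' @param score_scale `"unit"` (default) or `"stitch999"`.
#' @return An `interaction_network`.
#' @export
read_interactions <- function(path, score_scale = c("unit", "stitch999")) {
  score_scale <- match.arg(score_scale)
  dat <- .read_data_lines(path)
  if (length(dat$lines) == 0L) {
    return(interaction_network())
  }
  fields <- strsplit(dat$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed interaction row at line ",
      dat$lineno[which(nf < 3L)[1]],
      ": expected at least 3 tab-separated fields",
      call. = FALSE
    )
  }

  score_col <- if (nf[1] == 3L) 3L else nf[1]
  start <- 1L
  first_score <- suppressWarnings(as.numeric(fields[[1]][score_col]))
  if (is.na(first_score)) { # header line
    header <- tolower(fields[[1]])
    named <- which(header %in% c("score", "combined_score"))
    if (length(named) > 0L) score_col <- named[1]
    start <- 2L
  }
  if (any(nf[seq(start, length(fields))] > 3L)) {
    message(
      "read_interactions: ignoring extra columns; using column ",
      score_col, " as the score"
    )
  }
  if (start > length(fields)) {
    return(interaction_network())
  }

  idx <- seq(start, length(fields))
  a <- vapply(fields[idx], `[`, character(1), 1L)
  b <- vapply(fields[idx], `[`, character(1), 2L)
  s_raw <- vapply(fields[idx], `[`, character(1), score_col)
  s <- suppressWarnings(as.numeric(s_raw))
  if (anyNA(s)) {
    stop("unparseable score at line ", dat$lineno[idx[which(is.na(s))[1]]],
      call. = FALSE
    )
  }
  if (any(s < 0)) {
    stop("negative score at line ", dat$lineno[idx[which(s < 0)[1]]],
      call. = FALSE
    )
  }
  if (score_scale == "unit") {
    if (any(s > 1)) {
      stop("unit-scale score > 1 at line ",
        dat$lineno[idx[which(s > 1)[1]]],
        "; use score_scale = \"stitch999\" for integer scores",
        call. = FALSE
      )
    }
    w <- s
  } else {
    if (any(s != floor(s) | s > 999)) {
      stop("stitch999 scores must be integers 0..999 (line ",
        dat$lineno[idx[which(s != floor(s) | s > 999)[1]]], ")",
        call. = FALSE
      )
    }
    w <- s / 1000
  }

  self <- a == b
  if (any(self)) {
    warning("dropping ", sum(self), " self-pair row(s)", call. = FALSE)
  }
  keep <- !self & w > 0
  interaction_network(data.frame(
    a = a[keep], b = b[keep], weight = w[keep],
    stringsAsFactors = FALSE
  ))
}

#' Write an interaction network to a tab-separated file
#'
#' Columns `chemical_a`, `chemical_b`, `score` on the unit scale, readable
#' back with [read_interactions()].
#'
#' @param network An `interaction_network`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_interactions <- function(network, path) {
  e <- network_edges(network)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("chemical_a\tchemical_b\tscore", con)
  if (nrow(e) > 0L) {
    writeLines(paste(e$a, e$b, format(e$weight, digits = 15, trim = TRUE,
      scientific = FALSE
    ), sep = "\t"), con)
  }
  invisible(path)
}

#' Restrict a network to annotated compounds
#'
#' Keeps exactly the edges whose both endpoints appear in the annotation
#' table — the benchmark-assembly rule that interactions are only usable
#' when both partners carry pathway annotations.  Idempotent.
#'
#' @param network An `interaction_network`.
#' @param annotations An `annotation_table`.
#' @return The filtered `interaction_network`, with attributes
#'   `n_surviving_edges` and `n_connected_compounds` (compounds retaining at
#'   least one edge); the counts are also logged.
#' @export
restrict_to_annotated <- function(network, annotations) {
  stopifnot(
    inherits(network, "interaction_network"),
    inherits(annotations, "annotation_table")
  )
  e <- network_edges(network)
  ids <- compounds(annotations)
  keep <- e$a %in% ids & e$b %in% ids
  out <- interaction_network(e[keep, , drop = FALSE])
  n_edge <- n_edges(out)
  n_comp <- length(network_compounds(out))
  message(
    "restrict_to_annotated: ", n_edge, " of ", nrow(e),
    " edges survive; ", n_comp, " compounds keep >= 1 edge"
  )
  attr(out, "n_surviving_edges") <- n_edge
  attr(out, "n_connected_compounds") <- n_comp
  out
}

# Sparse symmetric adjacency over the given id universe (weights of pairs
# with an endpoint outside `ids` are dropped).  Rows/cols named by `ids`.
.sparse_adjacency <- function(network, ids) {
  e <- network_edges(network)
  i <- match(e$a, ids)
  j <- match(e$b, ids)
  keep <- !is.na(i) & !is.na(j)
  Matrix::sparseMatrix(
    i = c(i[keep], j[keep]), j = c(j[keep], i[keep]),
    x = rep(e$weight[keep], 2L),
    dims = c(length(ids), length(ids)),
    dimnames = list(ids, ids)
  )
}
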