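#' Tie-breaking policy for class rankings
#'
#' Tied class scores are ordered randomly; the `"random"` mode implements
#' that reproducibly by seeding a dedicated RNG stream from `seed` and the
#' query id, so equal (seed, query, scores) always give the identical
#' permutation while distinct queries receive independent tie orders.  The
#' `"code"` mode breaks ties by lowest class code first — fully
#' deterministic, convenient for regression tests.
#'
#' @param mode `"random"` (seeded random order among ties, default) or
#'   `"code"` (lowest code first).
#' @param seed Integer seed; used only in `"random"` mode.
#' @return An object of class `tie_policy`.
#' @export
tie_policy <- function(mode = c("random", "code"), seed = 0L) {
  mode <- match.arg(mode)
  stopifnot(.is_count(seed))
  structure(list(mode = mode, seed = as.integer(seed)), class = "tie_policy")
}

# Tie-break keys for one query: smaller key wins within a tied score block.
.tie_keys <- function(policy, query_id) {
  if (policy$mode == "code") {
    seq_len(.N_CLASSES)
  } else {
    qseed <- (as.numeric(policy$seed) + .str_hash(query_id)) %% 2147483647
    .with_seed(qseed, stats::runif(.N_CLASSES))
  }
}

#' Interaction profile of a query against a training set
#'
#' Entry `i` is the confidence score of the query's interaction with the
#' `i`-th training compound, 0 where no interaction is recorded.  The
#' self-interaction is excluded: if the query itself occurs among
#' `training_ids` its entry is forced to 0.
#'
#' @param query_id Compound id of the query.
#' @param network An `interaction_network`.
#' @param training_ids Character vector of training compound ids, no
#'   duplicates.
#' @return Named numeric vector along `training_ids`.  A query absent from
#'   the network yields the all-zero vector.
#' @export
neighbor_vector <- function(query_id, network, training_ids) {
  stopifnot(
    inherits(network, "interaction_network"),
    is.character(training_ids)
  )
  if (anyDuplicated(training_ids)) {
    stop("`training_ids` must not contain duplicates", call. = FALSE)
  }
  v <- stats::setNames(numeric(length(training_ids)), training_ids)
  e <- network_edges(network)
  inc_a <- e$a == query_id
  inc_b <- e$b == query_id
  partner <- c(e$b[inc_a], e$a[inc_b])
  w <- c(e$weight[inc_a], e$weight[inc_b])
  hit <- match(partner, training_ids)
  ok <- !is.na(hit)
  v[hit[ok]] <- w[ok]
  v[training_ids == query_id] <- 0
  v
}

#' Class scores of a query compound
#'
#' For each of the eleven pathway classes, the sum of the query's interaction
#' confidence scores with the annotated training compounds belonging to that
#' class: `Q_j = sum_i w(query, c_i) * p_ij`.  High-confidence neighbours and
#' many neighbours in a class both raise its score.  Summation runs in
#' ascending training-id order for reproducible floating-point results.
#'
#' @param query_id Compound id of the query.
#' @param network An `interaction_network`.
#' @param annotations A non-empty `annotation_table` (the training set).
#' @return An object of class `score_vector`: list with `query_id`, `scores`
#'   (named numeric, length 11, registry order) and `no_evidence` (`TRUE`
#'   when all scores are zero, i.e. the query has no annotated neighbour).
#' @export
class_scores <- function(query_id, network, annotations) {
  stopifnot(inherits(annotations, "annotation_table"))
  ids <- sort(compounds(annotations))
  if (length(ids) == 0L) stop("annotation table is empty", call. = FALSE)
  v <- neighbor_vector(query_id, network, ids)
  P <- labels_matrix(annotations)[ids, , drop = FALSE]
  q <- as.numeric(v %*% P)
  structure(
    list(
      query_id = query_id,
      scores = stats::setNames(q, as.character(1:.N_CLASSES)),
      no_evidence = all(q == 0)
    ),
    class = "score_vector"
  )
}

#' @export
print.score_vector <- function(x, ...) {
  cat("Class scores for", x$query_id,
    if (x$no_evidence) "(no interaction evidence)", "\n"
  )
  print(round(x$scores, 3))
  invisible(x)
}

#' Rank the eleven pathway classes for a query
#'
#' Sorts the class scores in descending order; the class at rank `r` is the
#' r-th order prediction for the query.  Ties are ordered according to
#' `policy` (random order among ties by default, reproducible under the
#' policy seed).
#'
#' @param scores A `score_vector` (see [class_scores()]).
#' @param policy A `tie_policy`.
#' @return An object of class `ranked_prediction`: list with `query_id`,
#'   `order` (integer permutation of 1..11; `order[r]` is the class code
#'   predicted at rank `r`), `scores` (the scores in ranked order,
#'   non-increasing) and `no_evidence`.
#' @export
rank_classes <- function(scores, policy = tie_policy()) {
  stopifnot(inherits(scores, "score_vector"), inherits(policy, "tie_policy"))
  keys <- .tie_keys(policy, scores$query_id)
  ord <- order(-scores$scores, keys)
  structure(
    list(
      query_id = scores$query_id,
      order = as.integer(ord),
      scores = as.numeric(scores$scores[ord]),
      no_evidence = scores$no_evidence
    ),
    class = "ranked_prediction"
  )
}

#' @export
print.ranked_prediction <- function(x, ...) {
  cat(
    "Ranked prediction for", x$query_id,
    if (x$no_evidence) "(no interaction evidence)", "\n"
  )
  print(data.frame(
    rank = seq_len(.N_CLASSES), class = x$order,
    score = round(x$scores, 3)
  ), row.names = FALSE)
  invisible(x)
}

#' Most likely pathway class of a query
#'
#' The class code with the highest score — the first-order prediction,
#' identical to `rank_classes(scores, policy)$order[1]`.
#'
#' @inheritParams rank_classes
#' @return A single class code in 1..11.
#' @export
predict_top <- function(scores, policy = tie_policy()) {
  rank_classes(scores, policy)$order[1L]
}

#' Write ranked predictions to a tab-separated file
#'
#' One row per (query, rank): `query_id`, `rank` (1--11), `class_code`,
#' `score` (3 decimals, the precision at which confidence sums are
#' reported).  Rows are ordered by query id, then rank.
#'
#' @param predictions A list of `ranked_prediction` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_predictions <- function(predictions, path) {
  stopifnot(all(vapply(predictions, inherits, logical(1), "ranked_prediction")))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("query_id\trank\tclass_code\tscore", con)
  if (length(predictions) > 0L) {
    qids <- vapply(predictions, `[[`, character(1), "query_id")
    for (p in predictions[order(qids)]) {
      writeLines(sprintf(
        "%s\t%d\t%d\t%.3f",
        p$query_id, seq_len(.N_CLASSES), p$order, p$scores
      ), con)
    }
  }
  invisible(path)
}

#' Read back a prediction file
#'
#' Inverse of [write_predictions()] to printed precision.
#'
#' @param path Path to a prediction file.
#' @return A list of `ranked_prediction` objects (no-evidence flags are
#'   recovered as all-zero score rows).
#' @export
read_predictions <- function(path) {
  df <- utils::read.delim(path,
    colClasses = c("character", "integer", "integer", "numeric")
  )
  lapply(split(df, df$query_id), function(d) {
    d <- d[order(d$rank), ]
    structure(
      list(
        query_id = d$query_id[1], order = d$class_code,
        scores = d$score, no_evidence = all(d$score == 0)
      ),
      class = "ranked_prediction"
    )
  })
}
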