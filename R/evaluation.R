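#' Stratified fold assignment for cross-validation
#'
#' Splits the annotated compounds into `folds` approximately equal groups by
#' splitting each pathway class across folds: classes are visited from
#' smallest to largest membership, each class's not-yet-assigned compounds
#' are shuffled with the seeded generator and dealt round-robin across
#' folds.  Multi-label compounds are assigned when their smallest class is
#' visited, so rare classes spread evenly over folds.
#'
#' @param annotations A non-empty `annotation_table`.
#' @param folds Number of folds, >= 2 and <= number of compounds.
#' @param seed Integer seed for the shuffles.
#' @return An object of class `fold_assignment`: a named integer vector
#'   mapping compound id to fold index 1..`folds`, with attributes `folds`
#'   and `seed`.
#' @export
make_folds <- function(annotations, folds = 5L, seed = 1L) {
  stopifnot(inherits(annotations, "annotation_table"), .is_count(seed))
  if (!.is_count(folds) || folds < 2L) {
    stop("`folds` must be an integer >= 2", call. = FALSE)
  }
  ids <- compounds(annotations)
  if (folds > length(ids)) {
    stop("`folds` exceeds the number of annotated compounds", call. = FALSE)
  }
  P <- labels_matrix(annotations)
  sizes <- colSums(P)
  assigned <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  ptr <- 0L
  .with_seed(seed, {
    for (j in order(sizes, seq_len(.N_CLASSES))) {
      members <- ids[P[, j] == 1L & is.na(assigned)]
      if (length(members) == 0L) next
      for (id in .shuffle(members)) {
        ptr <- ptr %% as.integer(folds) + 1L
        assigned[id] <- ptr
      }
    }
  })
  structure(assigned,
    folds = as.integer(folds), seed = as.integer(seed),
    class = "fold_assignment"
  )
}

# True class codes of one compound.
.true_classes <- function(annotations, id) {
  P <- labels_matrix(annotations)
  if (!id %in% rownames(P)) {
    stop("no truth annotation for compound ", id, call. = FALSE)
  }
  which(P[id, ] == 1L)
}

#' Accuracy of the j-th order prediction
#'
#' The fraction of evaluated compounds whose j-th ranked class is among
#' their true pathway classes: `ACC_j = N_j / N`.
#'
#' @param predictions A list of `ranked_prediction` objects.
#' @param truths An `annotation_table` containing every predicted query.
#' @param j Prediction order, 1..11.
#' @return A fraction in \[0, 1\].
#' @export
order_accuracy <- function(predictions, truths, j) {
  stopifnot(.is_count(j), j >= 1L, j <= .N_CLASSES)
  if (length(predictions) == 0L) stop("no predictions", call. = FALSE)
  hits <- vapply(predictions, function(p) {
    p$order[j] %in% .true_classes(truths, p$query_id)
  }, logical(1))
  mean(hits)
}

# All 11 order accuracies at once.
.accuracy_vector <- function(predictions, truths) {
  P <- labels_matrix(truths)
  acc <- numeric(.N_CLASSES)
  for (p in predictions) {
    truth <- P[p$query_id, ]
    acc <- acc + (truth[p$order] == 1L)
  }
  stats::setNames(acc / length(predictions), paste0("order", 1:.N_CLASSES))
}

#' Coverage of the true classes within the top k orders
#'
#' Pair semantics (default): the fraction of true (compound, class)
#' memberships whose class is ranked within the first `k` orders; equal to
#' `sum_{j<=k} ACC_j / lambda`.  Subset semantics: the fraction of compounds
#' whose entire true class set lies within the top `k`.  For single-label
#' compounds the two coincide.
#'
#' @param predictions A list of `ranked_prediction` objects.
#' @param truths An `annotation_table` containing every predicted query.
#' @param k Number of top orders, 1..11.
#' @param semantics `"pair"` (default) or `"subset"`.
#' @return A fraction in \[0, 1\]; 1 at `k = 11` under both semantics.
#' @export
coverage <- function(predictions, truths, k, semantics = c("pair", "subset")) {
  semantics <- match.arg(semantics)
  if (!.is_count(k) || k < 1L || k > .N_CLASSES) {
    stop("`k` must be an integer in 1..", .N_CLASSES, call. = FALSE)
  }
  if (length(predictions) == 0L) stop("no predictions", call. = FALSE)
  covered <- vapply(predictions, function(p) {
    truth <- .true_classes(truths, p$query_id)
    c(sum(truth %in% p$order[seq_len(k)]), length(truth))
  }, numeric(2))
  if (semantics == "pair") {
    sum(covered[1, ]) / sum(covered[2, ])
  } else {
    mean(covered[1, ] == covered[2, ])
  }
}

#' Pair coverage from printed order accuracies
#'
#' The arithmetic identity `L(k) = sum_{j<=k} ACC_j / lambda`, for computing
#' coverage from a reported accuracy row without per-compound data.
#'
#' @param acc Numeric vector of the 11 order accuracies (fractions or
#'   percentages; `lambda` must be on the same scale times 100 when
#'   percentages are used — pass fractions and a plain lambda for clarity).
#' @param lambda Average label count on the matching scale.
#' @param k Number of top orders.
#' @return The pair coverage at `k`.
#' @export
coverage_from_accuracies <- function(acc, lambda, k) {
  stopifnot(length(acc) == .N_CLASSES, .is_count(k), k >= 1, k <= .N_CLASSES)
  sum(acc[seq_len(k)]) / lambda
}

#' Rank pathway classes for independent query compounds
#'
#' Scores each query against the full annotation table (the query's own
#' annotation, if present, contributes nothing since self-interactions are
#' excluded) and returns the descending class ranking.  Queries with no
#' annotated interaction partner carry `no_evidence = TRUE` and receive an
#' all-tie permutation under the policy.
#'
#' @param network An `interaction_network`.
#' @param annotations A non-empty `annotation_table` (the reference set).
#' @param query_ids Character vector of query compound ids.
#' @param policy A `tie_policy`.
#' @return A list of `ranked_prediction` objects, one per query.
#' @export
predict_independent <- function(network, annotations, query_ids,
                                policy = tie_policy()) {
  stopifnot(is.character(query_ids))
  lapply(query_ids, function(q) {
    rank_classes(class_scores(q, network, annotations), policy)
  })
}

#' Cross-validated evaluation of the interaction-based predictor
#'
#' Runs F-fold cross-validation: the annotated compounds are split with
#' [make_folds()]; each fold in turn is the test set, and every test
#' compound is scored using only the training-fold annotations (an
#' interaction contributes only when the partner lies in the training fold),
#' ranked, and pooled.  Test compounds with zero training-fold evidence are
#' kept and ranked by the tie rule, so the identity `sum_j ACC_j = lambda`
#' holds exactly; their count is reported.
#'
#' @param network An `interaction_network`.
#' @param annotations A non-empty `annotation_table`.
#' @param folds Number of folds (default 5).
#' @param seed Integer seed driving the fold split (and, via `policy`'s
#'   default, the tie-breaks).
#' @param policy A `tie_policy`; defaults to seeded-random ties with `seed`.
#' @param coverage_semantics `"pair"` (default) or `"subset"` for the
#'   reported L(k) curve.
#' @return An object of class `cv_report`: list with
#'   \describe{
#'     \item{acc}{the 11 overall order accuracies ACC_1..ACC_11;}
#'     \item{per_class_acc}{11 x 11 matrix, class x order: the fraction of
#'       test compounds annotated to the row class whose ranking places that
#'       class at the column order (rows sum to 1);}
#'     \item{lambda}{average label count of the truth table;}
#'     \item{coverage}{L(k) for k = 1..11;}
#'     \item{baseline}{lambda / 11, the random-guess first-order accuracy;}
#'     \item{k}{the order cutoff ceil(lambda);}
#'     \item{n_evaluated, n_no_evidence}{compound counts;}
#'     \item{predictions}{the pooled `ranked_prediction` list (query-id
#'       sorted).}
#'   }
#' @export
cross_validate <- function(network, annotations, folds = 5L, seed = 1L,
                           policy = tie_policy("random", seed),
                           coverage_semantics = c("pair", "subset")) {
  coverage_semantics <- match.arg(coverage_semantics)
  stopifnot(
    inherits(network, "interaction_network"),
    inherits(annotations, "annotation_table"),
    inherits(policy, "tie_policy")
  )
  fold <- make_folds(annotations, folds, seed)
  ids <- sort(compounds(annotations))
  W <- .sparse_adjacency(network, ids)
  P <- labels_matrix(annotations)[ids, , drop = FALSE]

  predictions <- vector("list", length(ids))
  names(predictions) <- ids
  for (f in seq_len(attr(fold, "folds"))) {
    test_ids <- ids[fold[ids] == f]
    train_ids <- ids[fold[ids] != f]
    Q <- as.matrix(W[test_ids, train_ids, drop = FALSE] %*%
      P[train_ids, , drop = FALSE])
    for (q in test_ids) {
      sv <- structure(
        list(
          query_id = q,
          scores = stats::setNames(Q[q, ], as.character(1:.N_CLASSES)),
          no_evidence = all(Q[q, ] == 0)
        ),
        class = "score_vector"
      )
      predictions[[q]] <- rank_classes(sv, policy)
    }
  }

  acc <- .accuracy_vector(predictions, annotations)
  lambda <- average_label_count(annotations)

  # class x order hit matrix: each true (compound, class) membership falls at
  # exactly one order of that compound's permutation.
  per_class <- matrix(0, .N_CLASSES, .N_CLASSES,
    dimnames = list(
      class = as.character(1:.N_CLASSES),
      order = as.character(1:.N_CLASSES)
    )
  )
  denom <- numeric(.N_CLASSES)
  for (p in predictions) {
    truth <- .true_classes(annotations, p$query_id)
    denom[truth] <- denom[truth] + 1
    r <- match(truth, p$order)
    per_class[cbind(truth, r)] <- per_class[cbind(truth, r)] + 1
  }
  per_class <- sweep(per_class, 1L, pmax(denom, 1), "/")

  cov <- vapply(
    1:.N_CLASSES,
    function(k) coverage(predictions, annotations, k, coverage_semantics),
    numeric(1)
  )
  structure(
    list(
      acc = acc,
      per_class_acc = per_class,
      class_n = stats::setNames(as.integer(denom), as.character(1:.N_CLASSES)),
      lambda = lambda,
      coverage = stats::setNames(cov, paste0("k", 1:.N_CLASSES)),
      coverage_semantics = coverage_semantics,
      baseline = lambda / .N_CLASSES,
      k = as.integer(ceiling(lambda)),
      n_evaluated = length(predictions),
      n_no_evidence = sum(vapply(predictions, `[[`, logical(1), "no_evidence")),
      folds = attr(fold, "folds"),
      seed = as.integer(seed),
      predictions = predictions
    ),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, digits = 2, ...) {
  cat(
    x$folds, "-fold cross-validation over ", x$n_evaluated,
    " compounds (", x$n_no_evidence, " without interaction evidence)\n",
    sep = ""
  )
  cat(sprintf(
    "ACC_1 = %.2f%%   lambda = %.4f   baseline = %.2f%%   L(%d) = %.2f%%\n",
    100 * x$acc[1], x$lambda, 100 * x$baseline,
    x$k, 100 * x$coverage[x$k]
  ))
  invisible(x)
}

#' Write a cross-validation report
#'
#' `path` receives the class-by-order accuracy table: one row per pathway
#' class plus an overall row, eleven order columns, percentages to 2
#' decimals.  `metrics_path` (optional) receives the scalar metrics and
#' curves as JSON.
#'
#' @param report A `cv_report`.
#' @param path Output path for the tab-separated table.
#' @param metrics_path Optional output path for the JSON metrics.
#' @return Invisibly, `path`.
#' @export
write_cv_report <- function(report, path, metrics_path = NULL) {
  stopifnot(inherits(report, "cv_report"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  writeLines(paste(
    c("class_code", paste0("order", 1:.N_CLASSES)),
    collapse = "\t"
  ), con)
  for (j in 1:.N_CLASSES) {
    writeLines(paste(
      c(j, sprintf("%.2f", 100 * report$per_class_acc[j, ])),
      collapse = "\t"
    ), con)
  }
  writeLines(paste(c("Overall", sprintf("%.2f", 100 * report$acc)),
    collapse = "\t"
  ), con)
  close(con)
  if (!is.null(metrics_path)) {
    jsonlite::write_json(
      list(
        acc = unname(report$acc),
        lambda = report$lambda,
        baseline = report$baseline,
        k = report$k,
        coverage = unname(report$coverage),
        coverage_semantics = report$coverage_semantics,
        n_evaluated = report$n_evaluated,
        n_no_evidence = report$n_no_evidence,
        folds = report$folds,
        seed = report$seed
      ),
      metrics_path,
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}
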