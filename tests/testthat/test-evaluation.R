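test_that("label-count statistics reproduce the printed benchmark arithmetic", {
  at <- annotations_from_multiplicity(group2_multiplicity)
  expect_identical(length(compounds(at)), 3137L)
  expect_equal(average_label_count(at), 3606 / 3137, tolerance = 1e-12)
  expect_equal(round(average_label_count(at), 2), 1.15)
  expect_equal(round(random_baseline(at), 4), 0.1045)
  expect_identical(order_cutoff_k(at), 2L)

  single <- annotations_from_multiplicity(c(40))
  expect_equal(average_label_count(single), 1.0)
  expect_equal(random_baseline(single), 1 / 11)

  two_three <- annotations_from_multiplicity(c(0, 1, 1))
  expect_equal(average_label_count(two_three), 2.5)

  # "equal or greater": integer lambda is its own cutoff
  expect_identical(order_cutoff_k(annotations_from_multiplicity(c(0, 5))), 2L)
  expect_identical(
    order_cutoff_k(annotations_from_multiplicity(c(0, 99, 0, 0, 0, 1))),
    3L
  )

  expect_error(
    average_label_count(annotation_table(matrix(integer(0), 0, 11))),
    "empty"
  )
})

test_that("order accuracy counts j-th rank hits against the truth table", {
  m <- matrix(0L, 4, 11, dimnames = list(paste0("T", 1:4), NULL))
  m[1, 3] <- 1L
  m[2, c(1, 5)] <- 1L
  m[3, 7] <- 1L
  m[4, 2] <- 1L
  truths <- annotation_table(m)
  mk <- function(id, ord) {
    structure(
      list(
        query_id = id, order = as.integer(ord),
        scores = rev(sort(stats::runif(11))), no_evidence = FALSE
      ),
      class = "ranked_prediction"
    )
  }
  preds <- list(
    mk("T1", c(3, 1, 2, 4:11)), # hit at order 1
    mk("T2", c(5, 1, 2, 3, 4, 6:11)), # hit at orders 1 and 2
    mk("T3", c(1, 2, 3, 4, 5, 6, 7, 8:11)), # first hit at order 7
    mk("T4", c(2, 1, 3:11)) # hit at order 1
  )
  expect_equal(order_accuracy(preds, truths, 1), 0.75)
  expect_equal(order_accuracy(preds, truths, 2), 0.25)
  expect_equal(order_accuracy(preds, truths, 7), 0.25)

  # every true class occupies exactly one rank: accuracies sum to lambda
  acc <- vapply(1:11, function(j) order_accuracy(preds, truths, j), numeric(1))
  expect_equal(sum(acc), average_label_count(truths), tolerance = 1e-12)

  expect_error(order_accuracy(list(mk("T9", 1:11)), truths, 1), "no truth")
})

test_that("coverage follows pair and subset semantics", {
  m <- matrix(0L, 3, 11, dimnames = list(paste0("U", 1:3), NULL))
  m[1, c(1, 2)] <- 1L
  m[2, 4] <- 1L
  m[3, c(5, 9)] <- 1L
  truths <- annotation_table(m)
  mk <- function(id, ord) {
    structure(
      list(
        query_id = id, order = as.integer(ord),
        scores = numeric(11), no_evidence = FALSE
      ),
      class = "ranked_prediction"
    )
  }
  preds <- list(
    mk("U1", c(1, 3, 2, 4:11)), # classes {1,2} at orders {1,3}
    mk("U2", c(4, 1:3, 5:11)), # class 4 at order 1
    mk("U3", c(5, 9, 1:4, 6:8, 10, 11)) # classes {5,9} at orders {1,2}
  )
  # pairs covered at k=2: U1 -> 1 of 2, U2 -> 1, U3 -> 2 => 4/5
  expect_equal(coverage(preds, truths, 2, "pair"), 4 / 5)
  # whole sets within top 2: only U2 and U3
  expect_equal(coverage(preds, truths, 2, "subset"), 2 / 3)
  expect_equal(coverage(preds, truths, 11, "pair"), 1)
  expect_equal(coverage(preds, truths, 11, "subset"), 1)
  expect_error(coverage(preds, truths, 0), "1..11")
  expect_error(coverage(preds, truths, 12), "1..11")

  # pair coverage is the accuracy identity sum_{j<=k} ACC_j / lambda
  acc <- vapply(1:11, function(j) order_accuracy(preds, truths, j), numeric(1))
  lambda <- average_label_count(truths)
  for (k in c(1, 2, 3, 11)) {
    expect_equal(
      coverage(preds, truths, k, "pair"),
      coverage_from_accuracies(acc, lambda, k),
      tolerance = 1e-12
    )
  }

  # single-label truths: both semantics coincide at every k
  single <- annotation_table(
    labels_matrix(truths)["U2", , drop = FALSE]
  )
  for (k in 1:11) {
    expect_equal(
      coverage(preds[2], single, k, "pair"),
      coverage(preds[2], single, k, "subset")
    )
  }
})

test_that("fold assignment is stratified, balanced and seed-deterministic", {
  one_class <- annotation_table(
    matrix(c(rep(1L, 100), rep(0L, 1000)), 100, 11,
      dimnames = list(sprintf("F%03d", 1:100), NULL)
    )
  )
  f <- make_folds(one_class, folds = 5, seed = 4)
  expect_identical(as.vector(table(unclass(f))), rep(20L, 5))

  expect_identical(
    unclass(make_folds(one_class, 5, seed = 4)),
    unclass(make_folds(one_class, 5, seed = 4))
  )
  expect_false(identical(
    unclass(make_folds(one_class, 5, seed = 4)),
    unclass(make_folds(one_class, 5, seed = 5))
  ))

  # a 7-member class deals round-robin into per-fold sizes of 1 or 2
  seven <- annotation_table(
    matrix(c(rep(1L, 7), rep(0L, 70)), 7, 11,
      dimnames = list(paste0("S", 1:7), NULL)
    )
  )
  sizes <- table(factor(unclass(make_folds(seven, 5, seed = 1)), levels = 1:5))
  expect_true(all(sizes %in% 1:2))

  expect_error(make_folds(seven, folds = 8, seed = 1), "exceeds")
  expect_error(make_folds(seven, folds = 1, seed = 1), ">= 2")
})

test_that("cross-validation is perfect on assortative cliques and deterministic", {
  world <- assortative_cliques(per_class = 6)
  rep1 <- cross_validate(world$network, world$annotations,
    folds = 2, seed = 5
  )
  expect_equal(unname(rep1$acc[1]), 1.0)
  expect_equal(unname(rep1$coverage[1]), 1.0)
  expect_identical(rep1$n_no_evidence, 0L)

  # identical seeds give bit-identical reports
  rep2 <- cross_validate(world$network, world$annotations,
    folds = 2, seed = 5
  )
  expect_identical(rep1, rep2)

  # structural identities surfaced end-to-end
  expect_equal(sum(rep1$acc), rep1$lambda, tolerance = 1e-12)
  expect_equal(unname(rep1$coverage[11]), 1, tolerance = 1e-12)
  expect_equal(unname(rowSums(rep1$per_class_acc)), rep(1, 11),
    tolerance = 1e-12
  )
})

test_that("cross-validation reports hold their identities on noisy data", {
  cfg <- synthetic_config(n_compounds = 250, seed = 31)
  ann <- generate_annotations(cfg)
  net <- generate_network(ann, cfg)
  rep <- cross_validate(net, ann, folds = 5, seed = 31)
  expect_equal(sum(rep$acc), rep$lambda, tolerance = 1e-12)
  expect_true(all(diff(rep$coverage) >= -1e-12)) # L(k) non-decreasing
  expect_equal(unname(rep$coverage[11]), 1, tolerance = 1e-12)
  present <- rep$class_n > 0
  expect_equal(
    unname(rowSums(rep$per_class_acc))[present],
    rep(1, sum(present)),
    tolerance = 1e-12
  )
  expect_identical(rep$n_evaluated, 250L)
  # pair coverage at the cutoff equals the accuracy identity
  expect_equal(
    unname(rep$coverage[rep$k]),
    coverage_from_accuracies(rep$acc, rep$lambda, rep$k),
    tolerance = 1e-12
  )
})

test_that("independent prediction ranks the worked-example queries correctly", {
  preds <- predict_independent(
    independent_queries_network(), independent_queries_annotations(),
    c("C16265", "C14150", "C99999"),
    tie_policy("code")
  )
  expect_identical(preds[[1]]$order[1:2], c(1L, 2L))
  expect_identical(preds[[2]]$order[1], 11L)
  expect_true(preds[[3]]$no_evidence)
  expect_setequal(preds[[3]]$order, 1:11)
  expect_false(preds[[1]]$no_evidence)
})

test_that("report serialization writes the class-by-order table and metrics", {
  world <- assortative_cliques(per_class = 4)
  rep <- cross_validate(world$network, world$annotations, folds = 2, seed = 2)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_cv_report(rep, tsv, js)
  tab <- utils::read.delim(tsv)
  expect_identical(dim(tab), c(12L, 12L)) # 11 classes + overall x code + 11 orders
  expect_identical(tab$class_code[12], "Overall")
  expect_equal(as.numeric(tab[12, 2]), round(100 * unname(rep$acc[1]), 2))
  met <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(met$lambda, rep$lambda)
  expect_length(met$acc, 11L)
})
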