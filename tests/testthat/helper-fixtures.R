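# Shared fixtures and independent oracles for the test suite.

extdata <- function(f) {
  path <- system.file("extdata", f, package = "cciRank")
  if (!nzchar(path)) stop("missing packaged fixture: ", f)
  path
}

dihydrouracil_annotations <- function() read_annotations(extdata("dihydrouracil_annotations.tsv"))
dihydrouracil_network <- function() read_interactions(extdata("dihydrouracil_interactions.tsv"))
independent_queries_annotations <- function() read_annotations(extdata("independent_queries_annotations.tsv"))
independent_queries_network <- function() read_interactions(extdata("independent_queries_interactions.tsv"))

# The benchmark's label-multiplicity census: compounds with 1..7 classes.
group2_multiplicity <- c(2820, 226, 53, 23, 9, 4, 2)

# Independent oracle for the class scores: a naive double loop over
# (edge, class) pairs, sharing no code with class_scores().
oracle_class_scores <- function(query_id, network, annotations) {
  e <- network_edges(network)
  P <- labels_matrix(annotations)
  q <- numeric(11)
  for (r in seq_len(nrow(e))) {
    partner <- if (e$a[r] == query_id) {
      e$b[r]
    } else if (e$b[r] == query_id) {
      e$a[r]
    } else {
      next
    }
    if (!partner %in% rownames(P)) next
    for (j in 1:11) {
      if (P[partner, j] == 1L) q[j] <- q[j] + e$weight[r]
    }
  }
  q
}

# Random small instance (annotations + network) for property tests.
random_instance <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("R%03d", seq_len(n))
  m <- matrix(0L, n, 11, dimnames = list(ids, NULL))
  for (i in seq_len(n)) {
    m[i, sample.int(11, sample(1:3, 1))] <- 1L
  }
  npair <- n * (n - 1) / 2
  pairs <- which(upper.tri(diag(n)))
  sel <- pairs[stats::runif(npair) < 0.3]
  ij <- arrayInd(sel, c(n, n))
  edges <- data.frame(
    a = ids[ij[, 1]], b = ids[ij[, 2]],
    weight = round(stats::runif(length(sel), 0.05, 1), 3),
    stringsAsFactors = FALSE
  )
  list(
    annotations = annotation_table(m),
    network = interaction_network(edges)
  )
}

# A world where every compound's neighbours all share its single class:
# `per_class` compounds per class, full intra-class cliques, no cross edges.
assortative_cliques <- function(per_class = 10L, weight = 0.8) {
  n <- 11L * per_class
  cls <- rep(1:11, each = per_class)
  ids <- sprintf("Q%02d_%02d", cls, sequence(rep(per_class, 11)))
  m <- matrix(0L, n, 11, dimnames = list(ids, NULL))
  m[cbind(seq_len(n), cls)] <- 1L
  edges <- do.call(rbind, lapply(1:11, function(j) {
    members <- ids[cls == j]
    idx <- utils::combn(members, 2)
    data.frame(
      a = idx[1, ], b = idx[2, ], weight = weight,
      stringsAsFactors = FALSE
    )
  }))
  list(
    annotations = annotation_table(m),
    network = interaction_network(edges)
  )
}

write_tmp_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
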