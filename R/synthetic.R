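#' Configuration for the synthetic benchmark generator
#'
#' Describes a synthetic world mirroring the benchmark statistics of the
#' KEGG/STITCH dataset the method was developed on: class sizes proportional
#' to the Group-II census, label multiplicities proportional to its printed
#' distribution (about 90% single-label, lambda near 1.15), and a
#' planted-assortativity network in which compound pairs sharing at least
#' one pathway class interact more often (`p_in`) and more strongly
#' (`weight_in`) than pairs with disjoint label sets (`p_out`,
#' `weight_out`).
#'
#' @param n_compounds Number of compounds (default 1000).
#' @param class_weights 11 positive reals, relative class sizes; default
#'   proportional to the benchmark census (394, 120, 383, 132, 483, 154, 43,
#'   309, 499, 519, 570).
#' @param multiplicity_dist Probabilities of carrying 1..m classes; default
#'   proportional to 2820:226:53:23:9:4:2.
#' @param p_in Edge probability for pairs sharing a class (default 0.05).
#' @param p_out Edge probability for label-disjoint pairs (default 0.002);
#'   must satisfy `0 <= p_out <= p_in <= 1`.
#' @param weight_in,weight_out Length-2 ranges within (0, 1] for uniform
#'   weight draws on intra/inter-class edges (defaults (0.4, 1.0) and
#'   (0.15, 0.5)).
#' @param seed Integer seed; equal configurations generate bit-identical
#'   data.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_compounds = 1000L,
                             class_weights = c(
                               394, 120, 383, 132, 483, 154,
                               43, 309, 499, 519, 570
                             ),
                             multiplicity_dist =
                               c(2820, 226, 53, 23, 9, 4, 2) / 3137,
                             p_in = 0.05,
                             p_out = 0.002,
                             weight_in = c(0.4, 1.0),
                             weight_out = c(0.15, 0.5),
                             seed = 1L) {
  if (!.is_count(n_compounds) || n_compounds < 1) {
    stop("`n_compounds` must be a positive integer", call. = FALSE)
  }
  if (length(class_weights) != .N_CLASSES || any(class_weights <= 0)) {
    stop("`class_weights` must be 11 positive numbers", call. = FALSE)
  }
  if (length(multiplicity_dist) < 1L ||
    length(multiplicity_dist) > .N_CLASSES ||
    any(multiplicity_dist < 0) || sum(multiplicity_dist) <= 0) {
    stop("`multiplicity_dist` must be non-negative weights for 1..11 labels",
      call. = FALSE
    )
  }
  multiplicity_dist <- multiplicity_dist / sum(multiplicity_dist)
  if (!(p_out >= 0 && p_out <= p_in && p_in <= 1)) {
    stop("need 0 <= p_out <= p_in <= 1", call. = FALSE)
  }
  check_range <- function(r, what) {
    if (length(r) != 2L || r[1] <= 0 || r[2] > 1 || r[1] > r[2]) {
      stop("`", what, "` must be a range within (0, 1]", call. = FALSE)
    }
  }
  check_range(weight_in, "weight_in")
  check_range(weight_out, "weight_out")
  stopifnot(.is_count(seed))
  structure(
    list(
      n_compounds = as.integer(n_compounds),
      class_weights = as.numeric(class_weights),
      multiplicity_dist = as.numeric(multiplicity_dist),
      p_in = p_in, p_out = p_out,
      weight_in = as.numeric(weight_in),
      weight_out = as.numeric(weight_out),
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Generate a synthetic annotation table
#'
#' Each compound draws its label count from `multiplicity_dist`, then that
#' many distinct classes weighted by `class_weights`.  Deterministic under
#' the configuration seed.
#'
#' @param config A `synthetic_config`.
#' @return An `annotation_table` with `config$n_compounds` compounds.
#' @export
generate_annotations <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_compounds
  m <- matrix(0L, n, .N_CLASSES)
  rownames(m) <- sprintf("S%05d", seq_len(n))
  .with_seed(config$seed, {
    mult <- sample.int(length(config$multiplicity_dist), n,
      replace = TRUE, prob = config$multiplicity_dist
    )
    for (i in seq_len(n)) {
      cls <- sample.int(.N_CLASSES, mult[i], prob = config$class_weights)
      m[i, cls] <- 1L
    }
  })
  annotation_table(m)
}

#' Generate a class-assortative synthetic interaction network
#'
#' For every unordered compound pair an edge is drawn with probability
#' `p_in` when the two label sets share at least one class and `p_out`
#' otherwise; the weight is uniform on `weight_in` or `weight_out`
#' accordingly.  No self-edges.  Deterministic under the configuration seed
#' (a stream independent of the annotation draw).
#'
#' @param annotations An `annotation_table` (typically from
#'   [generate_annotations()]).
#' @param config A `synthetic_config`.
#' @return An `interaction_network`.
#' @export
generate_network <- function(annotations, config) {
  stopifnot(
    inherits(annotations, "annotation_table"),
    inherits(config, "synthetic_config")
  )
  P <- labels_matrix(annotations)
  ids <- rownames(P)
  n <- nrow(P)
  if (n < 2L) {
    return(interaction_network())
  }
  shared <- tcrossprod(P) > 0
  ut <- which(upper.tri(shared))
  is_in <- shared[ut]
  edges <- .with_seed(config$seed + 104729, { # offset decouples from labels
    p <- ifelse(is_in, config$p_in, config$p_out)
    present <- stats::runif(length(ut)) < p
    sel <- ut[present]
    sel_in <- is_in[present]
    w <- numeric(length(sel))
    w[sel_in] <- stats::runif(
      sum(sel_in),
      config$weight_in[1], config$weight_in[2]
    )
    w[!sel_in] <- stats::runif(
      sum(!sel_in),
      config$weight_out[1], config$weight_out[2]
    )
    ij <- arrayInd(sel, dim(shared))
    data.frame(
      a = ids[ij[, 1]], b = ids[ij[, 2]], weight = w,
      stringsAsFactors = FALSE
    )
  })
  # runif can in principle hit the open lower bound exactly; clamp away 0
  edges$weight[edges$weight <= 0] <- min(
    config$weight_out[1],
    config$weight_in[1]
  )
  interaction_network(edges)
}
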