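#' L1 distance between two subjects' occupation patterns
#'
#' Sum over windows and states of the absolute difference of the occupation
#' indices.
#'
#' @param ua,ub W x K occupation matrices with identical dimensions
#' @return nonnegative scalar
#' @export
occupation_distance <- function(ua, ub) {
  ua <- as.matrix(ua); ub <- as.matrix(ub)
  if (!identical(dim(ua), dim(ub)))
    stop("occupation matrices must share window count and state set")
  sum(abs(ua - ub))
}

#' Subject-by-subject similarity from occupation patterns
#'
#' Pairwise L1 occupation distances, mapped to similarities by the affine
#' transform s = max(d) - d (order preserving; self-similarity maximal).
#'
#' @param u_list list of W x K occupation matrices, one per subject
#' @return S x S symmetric nonnegative similarity matrix with zero diagonal
#'   distance mapped to the maximum; attribute `distance` holds the distance
#'   matrix
#' @export
occupation_similarity <- function(u_list) {
  S <- length(u_list)
  d <- matrix(0, S, S)
  for (i in seq_len(S)) {
    for (j in seq_len(S)) {
      if (j > i) d[i, j] <- d[j, i] <- occupation_distance(u_list[[i]], u_list[[j]])
    }
  }
  sim <- max(d) - d
  attr(sim, "distance") <- d
  sim
}

#' Subtype individuals by modularity optimisation
#'
#' Newman leading-eigenvector modularity maximisation on the weighted
#' similarity graph (self-loops removed). Modules smaller than `min_module`
#' are retained in the labelling but flagged excluded. Labels are relabelled
#' canonically (decreasing module size, ties by first member) so the result
#' is invariant to subject ordering up to the consistent permutation.
#'
#' @param sim S x S symmetric nonnegative similarity matrix
#' @param min_module smallest module size retained for downstream analysis
#' @return object of class `statedcm_subtypes`: `labels` (integer per
#'   subject), `Q` (modularity), `excluded` (subject indices in minor
#'   modules), `module_sizes`
#' @export
cluster_subtypes <- function(sim, min_module = 4) {
  sim <- as.matrix(sim)
  if (max(abs(sim - t(sim))) > 1e-12) stop("similarity matrix must be symmetric")
  if (any(sim < 0)) stop("similarity matrix must be nonnegative")
  diag(sim) <- 0
  if (max(sim) == 0) {
    return(structure(list(labels = rep(1L, nrow(sim)), Q = 0,
                          excluded = integer(0), module_sizes = nrow(sim)),
                     class = "statedcm_subtypes"))
  }
  g <- igraph::graph_from_adjacency_matrix(sim, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  cl <- igraph::cluster_leading_eigen(g, weights = igraph::E(g)$weight)
  memb <- as.integer(igraph::membership(cl))
  Q <- igraph::modularity(g, memb, weights = igraph::E(g)$weight)
  sizes <- table(memb)
  first <- vapply(as.integer(names(sizes)), function(m) min(which(memb == m)), integer(1))
  ord <- order(-as.integer(sizes), first)
  relab <- integer(length(sizes))
  relab[as.integer(names(sizes))[ord]] <- seq_along(ord)
  labels <- relab[memb]
  module_sizes <- as.integer(table(labels))
  excluded <- which(labels %in% which(module_sizes < min_module))
  structure(list(labels = labels, Q = Q, excluded = excluded,
                 module_sizes = module_sizes),
            class = "statedcm_subtypes")
}

#' @export
print.statedcm_subtypes <- function(x, ...) {
  cat(sprintf("%d subtypes (sizes %s), Q = %.3f; %d subject(s) in minor modules\n",
              length(x$module_sizes), paste(x$module_sizes, collapse = "/"),
              x$Q, length(x$excluded)))
  invisible(x)
}
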