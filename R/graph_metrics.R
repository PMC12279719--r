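# Weighted efficiency metrics on structural connectomes.
#
# All metrics follow the weighted, undirected conventions of the Brain
# Connectivity Toolbox: connection weights w are converted to traversal
# lengths 1/w (stronger connections are shorter), absent edges have
# infinite length, and disconnected pairs contribute 0 (= 1/Inf) to
# efficiency sums rather than raising an error.

# Accept a connectome or a bare symmetric nonnegative matrix.
as_weight_matrix <- function(x) {
  if (inherits(x, "connectome")) return(x$weights)
  if (is.matrix(x) && is.numeric(x)) {
    if (nrow(x) != ncol(x)) stop("matrix must be square")
    if (any(x < 0)) stop("negative weight in connectivity matrix")
    if (max(abs(x - t(x))) > 1e-8 * max(abs(x), 1e-300)) {
      stop("matrix must be symmetric")
    }
    x <- (x + t(x)) / 2
    diag(x) <- 0
    return(x)
  }
  stop("expected a connectome or a numeric matrix")
}

#' Connection-length transform of a connectome
#'
#' Converts weights to traversal lengths \code{1/w}; absent edges (zero
#' weight) become \code{Inf}, and the diagonal is 0.
#'
#' @param c A \code{\link{connectome}} or square symmetric matrix.
#' @return An n x n matrix of lengths (class \code{length_graph}).
#' @examples
#' length_matrix(matrix(c(0, 2, 2, 0), 2))[1, 2]  # 0.5
#' @export
length_matrix <- function(c) {
  w <- as_weight_matrix(c)
  len <- ifelse(w > 0, 1 / w, Inf)
  diag(len) <- 0
  structure(len, class = c("length_graph", class(len)))
}

# All-pairs shortest paths on a finite-length adjacency built from a
# length matrix (Inf = no edge). Dijkstra via igraph.
dist_on_lengths <- function(len) {
  n <- nrow(len)
  adj <- len
  diag(adj) <- 0
  adj[!is.finite(adj)] <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  d <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(d) <- dimnames(len)
  d
}

#' All-pairs shortest path lengths
#'
#' @param g A length matrix from \code{\link{length_matrix}} (entries are
#'   positive lengths or \code{Inf}).
#' @return Symmetric matrix of shortest-path lengths; 0 on the diagonal,
#'   \code{Inf} between different components.
#' @export
shortest_paths <- function(g) {
  if (!is.matrix(g)) stop("expected a length matrix")
  dist_on_lengths(unclass(g))
}

#' Weighted global efficiency
#'
#' Mean inverse shortest-path length over all ordered node pairs:
#' \deqn{E_{glob} = \frac{1}{n} \sum_i \frac{\sum_{j \ne i} d_{ij}^{-1}}{n - 1}}
#' with path lengths computed on the \code{1/w} length transform.
#' An index of network integration; disconnected pairs contribute 0.
#'
#' @param c A \code{\link{connectome}} or square symmetric matrix.
#' @return Nonnegative scalar.
#' @examples
#' w <- matrix(1, 4, 4); diag(w) <- 0
#' global_efficiency(w)  # complete binary graph: 1
#' @export
global_efficiency <- function(c) {
  w <- as_weight_matrix(c)
  n <- nrow(w)
  if (n < 2) stop("global efficiency needs at least 2 nodes")
  d <- dist_on_lengths(length_matrix(w))
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Weighted regional (nodal local) efficiency
#'
#' For each node i with neighbours N_i (k_i = |N_i| strictly positive
#' weights), the efficiency of communication among the neighbours once i is
#' removed, in the weighted "true generalization" of the binary formula:
#' \deqn{E_{reg}(i) = \frac{\sum_{j \ne h \in N_i} (w_{ij} w_{ih})^{1/3}
#'   \, [d^{1/3}_{jh}(N_i)]^{-1}}{k_i (k_i - 1)}}
#' where \eqn{d^{1/3}_{jh}(N_i)} is the shortest path between j and h in the
#' subgraph induced by N_i, computed on cube-root lengths \eqn{(1/w)^{1/3}}.
#' The cube root is applied to edge lengths \emph{before} the path search,
#' so that on a binary matrix the value equals the binary local-efficiency
#' formula exactly. Nodes with fewer than two neighbours score 0.
#'
#' @param c A \code{\link{connectome}} or square symmetric matrix.
#' @return Numeric vector of per-node efficiencies, named by node when the
#'   input carries node names.
#' @examples
#' k3 <- matrix(1, 3, 3); diag(k3) <- 0
#' regional_efficiency(k3)  # triangle: 1 for every node
#' @export
regional_efficiency <- function(c) {
  w <- as_weight_matrix(c)
  n <- nrow(w)
  adj <- w > 0
  wc <- w^(1 / 3)
  len3 <- ifelse(adj, (1 / w)^(1 / 3), Inf)
  diag(len3) <- 0
  ereg <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ])
    k <- length(nb)
    if (k < 2) next
    dsub <- dist_on_lengths(len3[nb, nb, drop = FALSE])
    dinv <- 1 / dsub
    diag(dinv) <- 0
    sw <- wc[i, nb]
    ereg[i] <- sum(tcrossprod(sw) * dinv) / (k * (k - 1))
  }
  names(ereg) <- rownames(w)
  ereg
}

#' Weighted local efficiency
#'
#' The arithmetic mean of \code{\link{regional_efficiency}} across all
#' nodes; an index of network segregation.
#'
#' @param c A \code{\link{connectome}} or square symmetric matrix.
#' @return Nonnegative scalar.
#' @export
local_efficiency <- function(c) {
  mean(regional_efficiency(c))
}

# Run expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Supplementary global network metrics
#'
#' Density (fraction of possible edges present), mean weighted clustering
#' coefficient (geometric-mean-of-triangles variant, weights normalized by
#' the maximum weight), modularity (best Q over seeded Louvain restarts on
#' the weights), and mean node strength.
#'
#' @param c A \code{\link{connectome}} or square symmetric matrix.
#' @param seed Seed for the community-search restarts.
#' @param restarts Number of Louvain restarts (default 20).
#' @return Named list \code{density}, \code{clustering}, \code{modularity},
#'   \code{strength}.
#' @export
supplementary_global_metrics <- function(c, seed = 1L, restarts = 20L) {
  w <- as_weight_matrix(c)
  n <- nrow(w)
  m_edges <- sum(w[upper.tri(w)] > 0)
  density <- if (n > 1) m_edges / (n * (n - 1) / 2) else 0
  strength <- mean(rowSums(w))

  clustering <- 0
  if (max(w) > 0) {
    b <- (w / max(w))^(1 / 3)
    cyc <- diag(b %*% b %*% b)
    k <- rowSums(w > 0)
    ci <- ifelse(k >= 2, cyc / (k * (k - 1)), 0)
    clustering <- mean(ci)
  }

  modularity <- 0
  if (m_edges > 0) {
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE)
    qs <- with_seed(seed, vapply(seq_len(restarts), function(r) {
      cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
      igraph::modularity(cl)
    }, numeric(1)))
    modularity <- max(qs)
  }

  list(density = density, clustering = clustering,
       modularity = modularity, strength = strength)
}

#' Per-subject efficiency profile
#'
#' @param c A \code{\link{connectome}}.
#' @param seed Seed for the modularity restarts.
#' @return One-row data.frame: \code{subject_id}, \code{e_glob},
#'   \code{e_loc}, \code{density}, \code{clustering}, \code{modularity},
#'   \code{strength}, then one \code{e_reg} column per node (named by
#'   atlas label and hemisphere).
#' @export
efficiency_profile <- function(c, seed = 1L) {
  stopifnot(inherits(c, "connectome"))
  ereg <- regional_efficiency(c)
  supp <- supplementary_global_metrics(c, seed = seed)
  out <- data.frame(subject_id = c$subject_id,
                    e_glob = global_efficiency(c),
                    e_loc = mean(ereg),
                    density = supp$density,
                    clustering = supp$clustering,
                    modularity = supp$modularity,
                    strength = supp$strength,
                    stringsAsFactors = FALSE, check.names = FALSE)
  ereg_df <- as.data.frame(as.list(ereg), check.names = FALSE)
  cbind(out, ereg_df)
}

#' Efficiency profiles for a whole cohort
#'
#' @param cohort A \code{\link{cohort_dataset}} with connectomes.
#' @param seed Seed for the modularity restarts (shared by all subjects,
#'   so repeated runs are identical).
#' @return data.frame with one row per subject, columns as in
#'   \code{\link{efficiency_profile}}.
#' @export
cohort_profiles <- function(cohort, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  if (is.null(cohort$connectomes)) stop("cohort has no connectomes")
  rows <- lapply(cohort$connectomes, efficiency_profile, seed = seed)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a cohort profile table to TSV
#' @param profiles Output of \code{\link{cohort_profiles}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.table(profiles, path, sep = "\t", row.names = FALSE,
                     quote = TRUE)
  invisible(path)
}
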