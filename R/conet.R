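#' CoNetwork: a thresholded correlation co-occurrence network
#'
#' An undirected, signed, weighted graph over ASVs. Edges are Spearman
#' correlations that pass both the magnitude threshold (|rho| >
#' \code{rThreshold}) and the adjusted-p threshold (p_adj <
#' \code{pThreshold}); nodes with no surviving edge are excluded. An
#' optional module partition (integer labels, 1 = largest module) is
#' attached by [detectModules()].
#'
#' @slot graph The underlying \code{igraph} object (edge attributes
#'   \code{weight} = signed rho and \code{p_adj}).
#' @slot edges data.frame with \code{source}, \code{target}, \code{rho},
#'   \code{p_adj}.
#' @slot rThreshold,pThreshold The thresholds the edges satisfy.
#' @slot modules Named integer vector (node -> module label), possibly
#'   empty before module detection.
#' @export
setClass("CoNetwork",
  representation(graph = "ANY", edges = "data.frame",
                 rThreshold = "numeric", pThreshold = "numeric",
                 modules = "integer"),
  validity = function(object) {
    e <- object@edges
    msg <- character(0)
    if (nrow(e)) {
      if (any(abs(e$rho) > 1)) msg <- c(msg, "edge weights outside [-1, 1]")
      if (any(abs(e$rho) <= object@rThreshold))
        msg <- c(msg, "edge below the correlation threshold")
      if (any(e$p_adj >= object@pThreshold))
        msg <- c(msg, "edge above the adjusted-p threshold")
    }
    if (length(object@modules) &&
        !setequal(names(object@modules), networkNodes(object)))
      msg <- c(msg, "module partition must cover exactly the network nodes")
    if (length(msg)) msg else TRUE
  })

#' @describeIn CoNetwork Node identifiers.
#' @param x,object A \code{CoNetwork}.
#' @export
networkNodes <- function(x) igraph::V(x@graph)$name

#' @describeIn CoNetwork Edge table (source, target, rho, p_adj).
#' @export
networkEdges <- function(x) x@edges

#' @describeIn CoNetwork Module membership (named integer), or an error if
#'   [detectModules()] has not been run.
#' @export
moduleMembership <- function(x) {
  if (!length(x@modules)) stop("no module partition; run detectModules()")
  x@modules
}

setMethod("show", "CoNetwork", function(object) {
  cat("CoNetwork:", length(networkNodes(object)), "nodes,",
      nrow(object@edges), "edges",
      sprintf("(|rho| > %g, p_adj < %g)\n",
              object@rThreshold, object@pThreshold))
  if (nrow(object@edges))
    cat("  negative edges:", sum(object@edges$rho < 0), "\n")
  if (length(object@modules))
    cat("  modules:", max(object@modules), "(sizes",
        paste(tabulate(object@modules), collapse = ", "), ")\n")
})

#' Prevalence filter
#'
#' Retains ASVs present (count > 0) in at least \code{min_samples} samples,
#' removing rare taxa before correlation analysis.
#'
#' @param x SummarizedExperiment or ASVs x samples matrix.
#' @param min_samples Minimum number of occupied samples (default 5).
#' @return Filtered object of the same class.
#' @export
prevalenceFilter <- function(x, min_samples = 5) {
  if (min_samples < 1) stop("min_samples must be >= 1")
  m <- if (methods::is(x, "SummarizedExperiment")) asvCounts(x) else as.matrix(x)
  keep <- rowSums(m > 0) >= min_samples
  x[keep, ]
}

#' Pairwise Spearman correlations among ASVs
#'
#' Rank-transforms each ASV's abundance profile across samples and computes
#' all pairwise correlations (average ranks for ties). Two-sided p-values
#' come from the t-distribution approximation
#' \code{t = rho * sqrt((n - 2) / (1 - rho^2))}; with \code{exact = TRUE}
#' and n <= 10 samples the exact null distribution is used instead (via
#' \code{cor.test}). Constant ASVs have undefined correlations, recorded as
#' \code{NA} and never promoted to edges.
#'
#' @param x SummarizedExperiment or ASVs x samples matrix with >= 4 samples.
#' @param exact Use the exact Spearman null distribution (n <= 10 only).
#' @return List with matrices \code{rho} and \code{p} (unit/zero diagonal),
#'   both ASVs x ASVs.
#' @export
spearmanMatrix <- function(x, exact = FALSE) {
  m <- if (methods::is(x, "SummarizedExperiment")) asvCounts(x) else as.matrix(x)
  n <- ncol(m)
  if (n < 4) stop("need >= 4 samples for correlation analysis")
  rk <- t(apply(m, 1, rank))
  const <- apply(rk, 1, function(v) max(v) == min(v))
  rho <- suppressWarnings(stats::cor(t(rk), method = "pearson"))
  rho[const, ] <- NA_real_
  rho[, const] <- NA_real_
  rho <- pmin(pmax(rho, -1), 1)
  if (exact && n <= 10) {
    p <- matrix(NA_real_, nrow(m), nrow(m))
    for (i in seq_len(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
      if (const[i] || const[j]) next
      p[i, j] <- p[j, i] <- suppressWarnings(
        stats::cor.test(m[i, ], m[j, ], method = "spearman",
                        exact = TRUE)$p.value)
    }
  } else {
    tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    p[abs(rho) >= 1 - 1e-15] <- 0
  }
  diag(rho) <- 1
  diag(p) <- 0
  dimnames(rho) <- dimnames(p) <- list(rownames(m), rownames(m))
  list(rho = rho, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control:
#' \code{q_(i) = min_(j >= i) p_(j) * m / j}, capped at 1 and mapped back
#' to the input order.
#'
#' @param p Vector of raw p-values in [0, 1] (NA allowed, passed through).
#' @return Adjusted p-values in the input order.
#' @export
bhAdjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Build the thresholded co-occurrence network
#'
#' Keeps the edge (i, j) iff |rho_ij| > \code{r_threshold} and the
#' BH-adjusted p is below \code{p_threshold}. Edge weights are the signed
#' correlations (negative edges mark exclusion patterns). Nodes with no
#' surviving edge are excluded from the network.
#'
#' @param rho Symmetric Spearman correlation matrix (from
#'   [spearmanMatrix()]).
#' @param p_adj Matrix of BH-adjusted p-values, conformable with \code{rho}
#'   (adjust the upper triangle of the raw p matrix with [bhAdjust()]).
#' @param r_threshold Correlation magnitude threshold, in (0, 1).
#' @param p_threshold Adjusted-p threshold, in (0, 1).
#' @return A \linkS4class{CoNetwork}.
#' @export
buildNetwork <- function(rho, p_adj, r_threshold = 0.75, p_threshold = 0.001) {
  if (!all(dim(rho) == dim(p_adj))) stop("rho and p_adj must be conformable")
  if (r_threshold <= 0 || r_threshold >= 1 || p_threshold <= 0 ||
      p_threshold >= 1) stop("thresholds must lie in (0, 1)")
  nodes <- rownames(rho)
  if (is.null(nodes)) nodes <- as.character(seq_len(nrow(rho)))
  idx <- which(upper.tri(rho) & !is.na(rho) & !is.na(p_adj) &
               abs(rho) > r_threshold & p_adj < p_threshold, arr.ind = TRUE)
  edges <- data.frame(source = nodes[idx[, 1]], target = nodes[idx[, 2]],
                      rho = rho[idx], p_adj = p_adj[idx],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$source, to = edges$target,
               weight = edges$rho, p_adj = edges$p_adj),
    directed = FALSE)
  methods::new("CoNetwork", graph = g, edges = edges,
               rThreshold = r_threshold, pThreshold = p_threshold,
               modules = integer(0))
}

#' Detect network modules
#'
#' Partitions the unweighted, undirected graph by seeded greedy modularity
#' maximization with local move refinement (multilevel algorithm). Module
#' labels are assigned in decreasing size order, so module 1 is always the
#' largest.
#'
#' @param net A \linkS4class{CoNetwork}.
#' @param seed Integer seed; the same seed on the same graph gives an
#'   identical partition.
#' @return The network with its \code{modules} slot filled (retrieve with
#'   [moduleMembership()]).
#' @export
detectModules <- function(net, seed = 1L) {
  g <- net@graph
  if (igraph::vcount(g) == 0) stop("empty network")
  gu <- igraph::delete_edge_attr(g, "weight")   # unweighted partition
  cl <- withr::with_seed(seed, igraph::cluster_louvain(gu))
  memb <- igraph::membership(cl)
  sizes <- table(memb)
  relabel <- stats::setNames(seq_along(sizes),
                             names(sort(sizes, decreasing = TRUE)))
  out <- as.integer(relabel[as.character(memb)])
  names(out) <- names(memb)
  net@modules <- out
  methods::validObject(net)
  net
}

asIgraph <- function(net) {
  if (methods::is(net, "CoNetwork")) net@graph else net
}

#' Newman-Girvan modularity of a partition
#'
#' \code{Q = sum_c (e_c / m - (d_c / 2m)^2)} on the unweighted graph, where
#' \code{e_c} counts intra-module edges, \code{d_c} is the module degree
#' sum and \code{m} the total edge count.
#'
#' @param net A \linkS4class{CoNetwork} (or igraph).
#' @param membership Module labels per node; defaults to the stored
#'   partition.
#' @return Modularity Q in [-0.5, 1].
#' @export
graphModularity <- function(net, membership = NULL) {
  g <- asIgraph(net)
  if (igraph::ecount(g) == 0) stop("modularity undefined on an empty graph")
  if (is.null(membership)) membership <- moduleMembership(net)
  m <- membership[igraph::V(g)$name]
  # force unit weights: igraph would otherwise pick up the signed rho
  igraph::modularity(g, as.integer(factor(m)),
                     weights = rep(1, igraph::ecount(g)))
}

#' Average local clustering coefficient
#'
#' Mean over nodes of triangles / possible wedges, with degree < 2 nodes
#' contributing 0; unweighted.
#'
#' @param net A \linkS4class{CoNetwork} (or igraph).
#' @return C in [0, 1].
#' @export
avgClustering <- function(net) {
  g <- asIgraph(net)
  if (igraph::vcount(g) == 0) stop("empty network")
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

#' Average shortest-path length
#'
#' Mean unweighted shortest-path length over all connected ordered pairs;
#' pairs in different components are excluded.
#'
#' @param net A \linkS4class{CoNetwork} (or igraph).
#' @return L >= 1.
#' @export
avgPathLength <- function(net) {
  g <- asIgraph(net)
  if (igraph::ecount(g) == 0) stop("path length undefined without edges")
  igraph::mean_distance(g, weights = NA, unconnected = TRUE)
}

#' Freeman degree centralization
#'
#' \code{sum_i (k_max - k_i) / ((n - 1)(n - 2))}: 1 for a star, 0 for any
#' regular graph.
#'
#' @param net A \linkS4class{CoNetwork} (or igraph).
#' @return Centralization in [0, 1].
#' @export
degreeCentralization <- function(net) {
  g <- asIgraph(net)
  n <- igraph::vcount(g)
  if (n < 3) stop("degree centralization needs >= 3 nodes")
  k <- igraph::degree(g, loops = FALSE)
  sum(max(k) - k) / ((n - 1) * (n - 2))
}

#' Network topology report
#'
#' The summary statistics used to compare seasonal networks: node and edge
#' counts, modularity of the stored (or given) partition, average
#' clustering coefficient, average path length, average degree
#' (2 * edges / nodes) and Freeman degree centralization.
#'
#' @param net A \linkS4class{CoNetwork} with modules detected (or a
#'   membership passed explicitly).
#' @param membership Optional module labels per node.
#' @return Named list of the seven statistics.
#' @export
topologyReport <- function(net, membership = NULL) {
  g <- asIgraph(net)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  list(n_nodes = n, n_edges = m,
       modularity = graphModularity(net, membership),
       avg_clustering = avgClustering(net),
       avg_path_length = avgPathLength(net),
       avg_degree = 2 * m / n,
       degree_centralization = if (n >= 3) degreeCentralization(net)
                               else NA_real_)
}

zScore <- function(v, denominator = c("population", "sample")) {
  denominator <- match.arg(denominator)
  mu <- mean(v)
  s <- if (denominator == "population") sqrt(mean((v - mu)^2)) else stats::sd(v)
  if (!is.finite(s) || s == 0) return(rep(0, length(v)))
  (v - mu) / s
}

#' Per-sample module abundance (mean z-score)
#'
#' Each member ASV's relative abundance across samples is standardized to a
#' z-score (population SD by default; all-zero series for zero-variance
#' ASVs); a module's abundance in a sample is the mean z over its members.
#'
#' @param x SummarizedExperiment or ASVs x samples count matrix (use the
#'   rarefied, lineage-filtered table).
#' @param membership Named integer vector, ASV -> module; every named ASV
#'   must be present in the table.
#' @param denominator \code{"population"} (n) or \code{"sample"} (n - 1)
#'   SD.
#' @return Matrix, samples x modules (columns \code{Module_1}, ...).
#' @export
moduleAbundance <- function(x, membership,
                            denominator = c("population", "sample")) {
  denominator <- match.arg(denominator)
  m <- if (methods::is(x, "SummarizedExperiment")) asvCounts(x) else as.matrix(x)
  missing <- setdiff(names(membership), rownames(m))
  if (length(missing))
    stop("module members absent from the table: ",
         paste(utils::head(missing, 5), collapse = ", "))
  rel <- t(t(m) / colSums(m))                     # relative abundance
  mods <- sort(unique(membership))
  out <- sapply(mods, function(k) {
    members <- names(membership)[membership == k]
    if (!length(members)) stop("module ", k, " has no ASVs in the table")
    z <- t(apply(rel[members, , drop = FALSE], 1, zScore,
                 denominator = denominator))
    colMeans(z)
  })
  out <- matrix(out, ncol = length(mods),
                dimnames = list(colnames(m), paste0("Module_", mods)))
  out
}

#' Export a network as an edge-list TSV
#'
#' @param net A \linkS4class{CoNetwork}.
#' @param path Output path (columns \code{source target rho p_adj}, plus
#'   \code{module_source}/\code{module_target} when modules are present).
#' @return \code{path}, invisibly.
#' @export
exportEdgeList <- function(net, path) {
  e <- networkEdges(net)
  if (length(net@modules)) {
    e$module_source <- net@modules[e$source]
    e$module_target <- net@modules[e$target]
  }
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network as GraphML
#'
#' Nodes carry a \code{module} attribute when a partition is present; edges
#' carry \code{weight} (signed rho) and \code{p_adj}.
#'
#' @param net A \linkS4class{CoNetwork}.
#' @param path Output .graphml path.
#' @return \code{path}, invisibly.
#' @export
exportGraphML <- function(net, path) {
  g <- net@graph
  if (length(net@modules))
    igraph::V(g)$module <- as.integer(net@modules[igraph::V(g)$name])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
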