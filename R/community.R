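TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Assemble an ASV experiment
#'
#' Builds a \linkS4class{SummarizedExperiment} holding an ASV count table
#' (ASVs as rows, samples as columns, assay \code{"counts"}), ranked
#' taxonomy in \code{rowData} and sample metadata in \code{colData}.
#'
#' @param counts Non-negative integer matrix, ASVs x samples (a samples x
#'   ASVs matrix is accepted and transposed when its dimnames make the
#'   orientation unambiguous via \code{asv_ids}).
#' @param taxonomy Optional data.frame with column \code{asv_id} and rank
#'   columns (domain...genus), or a \code{lineage} column of
#'   semicolon-delimited strings.
#' @param metadata Optional data.frame with column \code{sample_id}.
#' @return A \code{SummarizedExperiment}.
#' @export
makeAsvExperiment <- function(counts, taxonomy = NULL, metadata = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("ASV_%04d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("S%03d", seq_len(ncol(counts)))
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be finite non-negative integers")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("duplicate ASV or sample identifiers")
  storage.mode(counts) <- "integer"

  rd <- S4Vectors::DataFrame(row.names = rownames(counts))
  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy)
    if (!is.null(taxonomy$lineage)) taxonomy <- cbind(
      taxonomy["asv_id"], splitLineage(taxonomy$lineage))
    idx <- match(rownames(counts), taxonomy$asv_id)
    for (rk in intersect(TAX_RANKS, names(taxonomy)))
      rd[[rk]] <- as.character(taxonomy[[rk]][idx])
  }
  cd <- S4Vectors::DataFrame(row.names = colnames(counts))
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    idx <- match(colnames(counts), metadata$sample_id)
    for (nm in setdiff(names(metadata), "sample_id"))
      cd[[nm]] <- metadata[[nm]][idx]
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rd, colData = cd)
}

splitLineage <- function(lineage) {
  parts <- strsplit(as.character(lineage), ";", fixed = TRUE)
  out <- t(vapply(parts, function(p) {
    p <- trimws(p)
    length(p) <- length(TAX_RANKS)
    p
  }, character(length(TAX_RANKS))))
  colnames(out) <- TAX_RANKS
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' @rdname makeAsvExperiment
#' @param x A SummarizedExperiment built by [makeAsvExperiment()].
#' @export
asvCounts <- function(x) {
  SummarizedExperiment::assay(x, "counts")
}

#' Read an ASV count table from TSV
#'
#' The table may be oriented either way; orientation is detected from the
#' header sentinel: a first column named \code{asv_id} means ASVs are rows,
#' \code{sample_id} means samples are rows.
#'
#' @param path TSV path.
#' @return Integer matrix, ASVs x samples.
#' @export
readAsvTable <- function(path) {
  x <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  sentinel <- names(x)[1]
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- as.character(x[[1]])
  if (identical(sentinel, "sample_id")) m <- t(m)
  else if (!identical(sentinel, "asv_id"))
    stop("first column must be 'asv_id' or 'sample_id', got '", sentinel, "'")
  storage.mode(m) <- "integer"
  m
}

#' Read a taxonomy table from TSV
#'
#' @param path TSV with columns \code{asv_id} and \code{lineage}
#'   (semicolon-delimited domain;phylum;class;order;family;genus).
#' @return data.frame with \code{asv_id} plus one column per rank.
#' @export
readTaxonomy <- function(path) {
  x <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (!all(c("asv_id", "lineage") %in% names(x)))
    stop("taxonomy file needs 'asv_id' and 'lineage' columns")
  cbind(x["asv_id"], splitLineage(x$lineage))
}

#' Remove ASVs whose lineage matches banned labels
#'
#' Drops ASVs (such as chloroplast and mitochondrial reads) whose lineage
#' contains any banned label, matched case-insensitively as a substring over
#' all taxonomic ranks. ASVs absent from the taxonomy are retained and
#' listed in the \code{"unannotated"} attribute.
#'
#' @param x SummarizedExperiment from [makeAsvExperiment()].
#' @param banned Character vector of labels, e.g.
#'   \code{c("Chloroplast", "Mitochondria")}.
#' @return The filtered SummarizedExperiment; samples unchanged.
#' @export
removeLineages <- function(x, banned = c("Chloroplast", "Mitochondria")) {
  stopifnot(length(banned) > 0)
  rd <- SummarizedExperiment::rowData(x)
  ranks <- intersect(TAX_RANKS, colnames(rd))
  if (!length(ranks)) stop("no taxonomy attached; cannot filter lineages")
  lin <- do.call(paste, c(lapply(ranks, function(r) {
    v <- rd[[r]]
    v[is.na(v)] <- ""
    v
  }), sep = ";"))
  annotated <- nchar(gsub(";", "", lin)) > 0
  hit <- rep(FALSE, nrow(x))
  for (b in banned)
    hit <- hit | grepl(b, lin, ignore.case = TRUE, fixed = FALSE)
  out <- x[!hit, ]
  attr(out, "unannotated") <- rownames(x)[!annotated]
  out
}

#' Rarefy an ASV table to a fixed depth
#'
#' Subsamples each sample's reads uniformly without replacement to exactly
#' \code{depth} reads. Samples whose total is below \code{depth} are dropped
#' and listed in the \code{"dropped"} attribute. The draw is seeded and
#' bit-reproducible.
#'
#' @param x SummarizedExperiment (counts assay) or ASVs x samples matrix.
#' @param depth Target depth, >= 1.
#' @param seed Integer seed.
#' @return Object of the same class with rarefied counts.
#' @export
rarefyAsvTable <- function(x, depth, seed = 1L) {
  if (depth < 1) stop("rarefaction depth must be >= 1")
  m <- if (methods::is(x, "SummarizedExperiment")) asvCounts(x) else as.matrix(x)
  totals <- colSums(m)
  keep <- totals >= depth
  dropped <- colnames(m)[!keep]
  m <- m[, keep, drop = FALSE]
  rar <- withr::with_seed(seed, withCallingHandlers(
    t(vegan::rrarefy(t(m), sample = depth)),
    # rrarefy heuristically warns when the smallest nonzero count is > 1;
    # shallow samples are already dropped above, so this is never actionable
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  storage.mode(rar) <- "integer"
  out <- if (methods::is(x, "SummarizedExperiment")) {
    y <- x[, keep]
    SummarizedExperiment::assay(y, "counts") <- rar
    y
  } else rar
  attr(out, "dropped") <- dropped
  out
}

#' ASV richness of one sample
#'
#' @param counts Non-negative count vector.
#' @return Number of ASVs with at least one read.
#' @export
richness <- function(counts) {
  if (!length(counts)) stop("empty count vector")
  sum(counts > 0)
}

#' Shannon diversity of one sample
#'
#' H = -sum p_i log(p_i) over taxa with p_i > 0; natural log by default.
#'
#' @param counts Non-negative count vector with positive total.
#' @param base Logarithm base (default e, i.e. nats).
#' @return Shannon index.
#' @export
shannonIndex <- function(counts, base = exp(1)) {
  tot <- sum(counts)
  if (!is.finite(tot) || tot <= 0) stop("total count must be > 0")
  p <- counts[counts > 0] / tot
  -sum(p * log(p, base = base))
}

#' Per-sample alpha diversity
#'
#' @param x SummarizedExperiment or ASVs x samples matrix.
#' @return data.frame with \code{sample_id}, \code{richness},
#'   \code{shannon}.
#' @export
alphaDiversity <- function(x) {
  m <- if (methods::is(x, "SummarizedExperiment")) asvCounts(x) else as.matrix(x)
  data.frame(sample_id = colnames(m),
             richness = apply(m, 2, richness),
             shannon = apply(m, 2, shannonIndex),
             row.names = NULL)
}

#' Bray-Curtis dissimilarity between two samples
#'
#' \code{sum(|x - y|) / sum(x + y)}: 0 for identical compositions, 1 for
#' disjoint supports.
#'
#' @param x,y Non-negative count vectors of equal length, positive totals.
#' @return Dissimilarity in [0, 1].
#' @export
brayCurtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (sum(x) <= 0 || sum(y) <= 0) stop("totals must be > 0")
  sum(abs(x - y)) / sum(x + y)
}

#' Bray-Curtis distance matrix over all samples
#'
#' @param x SummarizedExperiment or ASVs x samples matrix.
#' @return A symmetric samples x samples matrix with zero diagonal.
#' @export
brayCurtisMatrix <- function(x) {
  m <- if (methods::is(x, "SummarizedExperiment")) asvCounts(x) else as.matrix(x)
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- brayCurtis(m[, i], m[, j])
  d
}

#' Principal coordinate analysis (classical scaling)
#'
#' Double-centers \code{-D^2/2} and eigendecomposes it. Axes with positive
#' eigenvalues carry the coordinates; negative eigenvalues (possible for
#' semi-metric dissimilarities such as Bray-Curtis) are reported but their
#' axes omitted, with no Lingoes/Cailliez correction.
#'
#' @param d Square symmetric non-negative matrix with zero diagonal (or a
#'   \code{dist}).
#' @param tol Symmetry tolerance.
#' @return List with \code{coordinates} (samples x positive axes),
#'   \code{eigenvalues} (all, decreasing), \code{prop_explained} (share of
#'   the positive eigenvalue total per retained axis) and
#'   \code{n_negative}.
#' @export
pcoa <- function(d, tol = 1e-8) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > tol)
    stop("distance matrix must be square and symmetric")
  if (any(abs(diag(d)) > tol) || any(d < 0))
    stop("distance matrix must be non-negative with zero diagonal")
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- e$values > max(e$values, 0) * 1e-12 & e$values > tol
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords,
       eigenvalues = e$values,
       prop_explained = e$values[pos] / sum(e$values[pos]),
       n_negative = sum(e$values < -tol))
}

permanovaF <- function(d2, groups) {
  # one-way pseudo-F from squared distances; SS identities of classical
  # multivariate partitioning: SS = sum_{i<j} d2_ij / n within each stratum
  n <- nrow(d2)
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ssw <- ssw + sum(sub[upper.tri(sub)]) / length(idx)
  }
  a <- length(unique(groups))
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Pseudo-F from the among/within partition of squared inter-sample
#' distances, with a permutation p-value
#' \code{p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm)}.
#'
#' @param d Distance matrix (or \code{dist}) over samples.
#' @param groups Group labels, one per sample; >= 2 groups with >= 2
#'   members each.
#' @param n_perm Number of label permutations (>= 99).
#' @param seed Integer seed for the permutations.
#' @return List with \code{f}, \code{p}, \code{n_perm}, \code{df}.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L) {
  d <- as.matrix(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(d)) stop("one group label per sample required")
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 groups with >= 2 members each")
  if (n_perm < 99) stop("n_perm must be >= 99")
  d2 <- d^2
  f_obs <- permanovaF(d2, groups)
  count <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i)
      permanovaF(d2, sample(groups)), numeric(1)) >= f_obs)
  })
  list(f = f_obs, p = (1 + count) / (1 + n_perm),
       n_perm = n_perm,
       df = c(among = length(tab) - 1, within = nrow(d) - length(tab)))
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Rank-sum statistic with average ranks for ties. The p-value is exact by
#' enumeration when both samples have at most 8 values and there are no
#' ties, otherwise from the normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y Numeric samples, each non-empty.
#' @return List with \code{w} (rank sum of \code{x}), \code{u}
#'   (Mann-Whitney U), \code{p}, \code{exact}.
#' @export
wilcoxonRankSum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  w <- sum(r[seq_along(x)])
  u <- w - length(x) * (length(x) + 1) / 2
  ties <- any(duplicated(c(x, y)))
  exact <- length(x) <= 8 && length(y) <= 8 && !ties
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                       alternative = "two.sided")$p.value)
  list(w = w, u = u, p = p, exact = exact)
}

#' Aggregate ASV counts to a taxonomic rank
#'
#' Sums counts per rank label and converts to relative abundance; ASVs with
#' no annotation at that rank are pooled into \code{"Unassigned"}.
#'
#' @param x SummarizedExperiment with taxonomy in \code{rowData}.
#' @param rank One of domain, phylum, class, order, family, genus.
#' @return Relative-abundance matrix, samples x taxa; rows sum to 1.
#' @export
aggregateTaxa <- function(x, rank = "class") {
  if (!rank %in% TAX_RANKS)
    stop("unknown rank '", rank, "'; expected one of: ",
         paste(TAX_RANKS, collapse = ", "))
  rd <- SummarizedExperiment::rowData(x)
  if (!rank %in% colnames(rd)) stop("taxonomy lacks rank '", rank, "'")
  lab <- as.character(rd[[rank]])
  lab[is.na(lab) | lab == ""] <- "Unassigned"
  m <- asvCounts(x)
  agg <- rowsum(m, lab)                      # taxa x samples
  rel <- t(agg) / colSums(m)                 # samples x taxa
  rel[, order(colMeans(rel), decreasing = TRUE), drop = FALSE]
}
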