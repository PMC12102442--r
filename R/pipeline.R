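#' BH-adjust a symmetric p-value matrix
#'
#' Adjusts the upper-triangle p-values (one test per unordered pair) with
#' [bhAdjust()] and mirrors the result, leaving the diagonal untouched.
#'
#' @param p Symmetric matrix of raw p-values.
#' @return Matrix of adjusted p-values, same shape.
#' @export
bhAdjustMatrix <- function(p) {
  q <- p
  up <- upper.tri(p)
  q[up] <- bhAdjust(p[up])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  q
}

#' Validate a pipeline input directory
#'
#' Schema checks for the four input tables (metadata.tsv, rates.tsv,
#' asv.tsv, taxonomy.tsv): required columns, duplicate identifiers, count
#' integrity, size-fraction consistency, and sample-set agreement across
#' files. Errors fail validation; warnings do not.
#'
#' @param dir Directory holding the input TSVs.
#' @return List with \code{pass} (logical) and \code{issues} (data.frame
#'   with \code{file}, \code{level}, \code{message}).
#' @export
validateInputs <- function(dir) {
  issues <- data.frame(file = character(0), level = character(0),
                       message = character(0), stringsAsFactors = FALSE)
  note <- function(file, level, message) {
    issues[nrow(issues) + 1, ] <<- list(file, level, message)
  }
  paths <- file.path(dir, c("metadata.tsv", "rates.tsv", "asv.tsv",
                            "taxonomy.tsv"))
  names(paths) <- basename(paths)
  for (f in names(paths)) if (!file.exists(paths[f]))
    note(f, "error", "file missing")
  if (any(issues$level == "error"))
    return(list(pass = FALSE, issues = issues))

  md <- utils::read.delim(paths["metadata.tsv"], stringsAsFactors = FALSE)
  if (!all(c("sample_id", "season") %in% names(md)))
    note("metadata.tsv", "error", "needs sample_id and season columns")
  else if (anyDuplicated(md$sample_id))
    note("metadata.tsv", "error", paste("duplicated sample_id:",
         paste(unique(md$sample_id[duplicated(md$sample_id)]),
               collapse = ", ")))

  rt <- try(readRateInputs(paths["rates.tsv"]), silent = TRUE)
  if (inherits(rt, "try-error"))
    note("rates.tsv", "error", "unreadable or lacks sample_id")
  else {
    if (anyDuplicated(rt$sample_id))
      note("rates.tsv", "error", "duplicated sample_id")
    both <- !is.na(rt$int_total_umol_L_d) & !is.na(rt$int_02_08_umol_L_d)
    if (any(rt$int_02_08_umol_L_d[both] > rt$int_total_umol_L_d[both]))
      note("rates.tsv", "error", "size-fraction INT exceeds total INT")
  }

  cn <- try(readAsvTable(paths["asv.tsv"]), silent = TRUE)
  if (inherits(cn, "try-error"))
    note("asv.tsv", "error", "unreadable or unrecognized orientation")
  else {
    if (any(cn < 0) || anyNA(cn))
      note("asv.tsv", "error", "counts must be non-negative integers")
    if (anyDuplicated(rownames(cn)))
      note("asv.tsv", "error", "duplicated asv_id")
    if (!inherits(md, "try-error") && "sample_id" %in% names(md)) {
      extra <- setdiff(colnames(cn), md$sample_id)
      if (length(extra))
        note("asv.tsv", "warning", paste("samples absent from metadata:",
             paste(utils::head(extra, 5), collapse = ", ")))
    }
  }

  tx <- try(readTaxonomy(paths["taxonomy.tsv"]), silent = TRUE)
  if (inherits(tx, "try-error"))
    note("taxonomy.tsv", "error", "unreadable or lacks asv_id/lineage")
  else if (!inherits(cn, "try-error")) {
    miss <- setdiff(rownames(cn), tx$asv_id)
    if (length(miss))
      note("taxonomy.tsv", "warning", paste("ASVs without taxonomy:",
           paste(utils::head(miss, 5), collapse = ", ")))
  }
  list(pass = !any(issues$level == "error"), issues = issues)
}

analyzeSeasonNetwork <- function(se_season, min_prevalence, r_threshold,
                                 p_threshold, seed) {
  filt <- prevalenceFilter(se_season, min_prevalence)
  sp <- spearmanMatrix(filt)
  q <- bhAdjustMatrix(sp$p)
  net <- buildNetwork(sp$rho, q, r_threshold, p_threshold)
  if (nrow(networkEdges(net)) == 0)
    return(list(network = net, topology = NULL, module_abundance = NULL))
  net <- detectModules(net, seed)
  list(network = net,
       topology = topologyReport(net),
       module_abundance = moduleAbundance(filt, moduleMembership(net)))
}

#' Run the full analysis pipeline on an input directory
#'
#' Orchestrates the stages end to end: input validation; rate panel
#' conversion; lineage filtering and rarefaction of the ASV table; alpha
#' diversity, Bray-Curtis/PCoA/PERMANOVA and seasonal Wilcoxon contrasts;
#' per-season co-occurrence networks (prevalence filter, Spearman, BH,
#' thresholding, module detection, topology, module z-score abundance);
#' and the coupling/decoupling report linking respiration to module
#' abundance. Seasons are analyzed as independent strata. All randomness
#' flows from \code{seed}; two runs with the same inputs and seed produce
#' byte-identical outputs.
#'
#' @param input_dir Directory with metadata.tsv, rates.tsv, asv.tsv,
#'   taxonomy.tsv (as written by [writeDataset()]).
#' @param out_dir Optional output directory; when given, all result tables
#'   plus a JSON run manifest are written there.
#' @param rarefy_depth Rarefaction depth (reads per sample).
#' @param min_prevalence Minimum occupied samples per ASV for the network
#'   stage.
#' @param r_threshold,p_threshold Network edge thresholds (|rho| and
#'   BH-adjusted p).
#' @param method Correlation method for the linkage stage.
#' @param n_perm PERMANOVA permutation count.
#' @param seed Master seed; per-stage seeds are derived from it and
#'   recorded in the manifest.
#' @return List with \code{manifest}, \code{rate_panel},
#'   \code{diversity}, \code{pcoa}, \code{permanova},
#'   \code{season_contrasts}, \code{networks} (per season),
#'   \code{decoupling} (per season plus a pooled rate panel).
#' @export
runPipeline <- function(input_dir, out_dir = NULL,
                        rarefy_depth = 49920, min_prevalence = 5,
                        r_threshold = 0.75, p_threshold = 0.001,
                        method = c("spearman", "pearson"),
                        n_perm = 999, seed = 1L) {
  method <- match.arg(method)
  seed <- as.integer(seed)
  val <- validateInputs(input_dir)
  if (!val$pass)
    stop("input validation failed:\n", paste(
      sprintf("  [%s] %s: %s", val$issues$level, val$issues$file,
              val$issues$message), collapse = "\n"))

  md <- utils::read.delim(file.path(input_dir, "metadata.tsv"),
                          stringsAsFactors = FALSE)
  inputs <- readRateInputs(file.path(input_dir, "rates.tsv"))
  counts <- readAsvTable(file.path(input_dir, "asv.tsv"))
  tax <- readTaxonomy(file.path(input_dir, "taxonomy.tsv"))

  panel <- computeRatePanel(inputs)

  se <- makeAsvExperiment(counts, taxonomy = tax, metadata = md)
  se <- removeLineages(se)
  rar <- rarefyAsvTable(se, depth = rarefy_depth, seed = seed + 10L)
  season <- as.character(SummarizedExperiment::colData(rar)$season)

  diversity <- alphaDiversity(rar)
  bc <- brayCurtisMatrix(rar)
  ord <- pcoa(bc)
  pmv <- if (length(unique(season)) >= 2)
    permanova(bc, season, n_perm = n_perm, seed = seed + 20L) else NULL

  # seasonal Wilcoxon contrasts on environment, rates and diversity
  merged <- merge(merge(md, panel, by = "sample_id", all.x = TRUE),
                  diversity, by = "sample_id", all.x = TRUE)
  merged <- merged[order(merged$sample_id), , drop = FALSE]
  merged$ba_cells_mL <- inputs$ba_cells_mL[match(merged$sample_id,
                                                 inputs$sample_id)]
  contrasts <- NULL
  if (length(unique(merged$season)) == 2) {
    ss <- split(merged, merged$season)
    vars <- intersect(c("temperature_C", "salinity", "chl_ug_L",
                        "ba_cells_mL", "bp_mgC_m3_d", "br_mgC_m3_d",
                        "richness", "shannon"),
                      names(merged))
    contrasts <- do.call(rbind, lapply(vars, function(v) {
      x <- ss[[1]][[v]]; y <- ss[[2]][[v]]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (!length(x) || !length(y)) return(NULL)
      wt <- wilcoxonRankSum(x, y)
      data.frame(variable = v, group1 = names(ss)[1], group2 = names(ss)[2],
                 median1 = stats::median(x), median2 = stats::median(y),
                 w = wt$w, p = wt$p, stringsAsFactors = FALSE)
    }))
  }

  networks <- lapply(stats::setNames(unique(season), unique(season)),
    function(s) analyzeSeasonNetwork(rar[, season == s], min_prevalence,
                                     r_threshold, p_threshold,
                                     seed + 30L))

  link_panel <- data.frame(
    sample_id = merged$sample_id,
    chl = merged$chl_ug_L,
    ba = merged$ba_cells_mL,
    bp = merged$bp_mgC_m3_d,
    br = merged$br_mgC_m3_d, stringsAsFactors = FALSE)
  pooled <- decouplingReport(link_panel, method = method)
  per_season <- lapply(stats::setNames(unique(season), unique(season)),
    function(s) {
      ma <- networks[[s]]$module_abundance
      sel <- link_panel$sample_id %in% colnames(rar)[season == s]
      sub <- link_panel[sel, , drop = FALSE]
      if (is.null(ma) || sum(stats::complete.cases(sub[c("ba","bp","br")])) < 3)
        return(NULL)
      decouplingReport(sub, module_abund = ma, method = method)
    })

  manifest <- list(
    config = list(rarefy_depth = rarefy_depth,
                  min_prevalence = min_prevalence,
                  r_threshold = r_threshold, p_threshold = p_threshold,
                  method = method, n_perm = n_perm),
    seeds = list(master = seed, rarefaction = seed + 10L,
                 permanova = seed + 20L, modules = seed + 30L),
    input_checksums = as.list(tools::md5sum(
      file.path(input_dir, c("metadata.tsv", "rates.tsv", "asv.tsv",
                             "taxonomy.tsv")))),
    n_samples = ncol(counts), n_asv = nrow(counts),
    n_samples_rarefied = ncol(rar),
    rate_errors = attr(panel, "errors"),
    samples_dropped = attr(rar, "dropped"))

  result <- list(manifest = manifest, rate_panel = panel,
                 diversity = diversity, pcoa = ord, permanova = pmv,
                 season_contrasts = contrasts, networks = networks,
                 decoupling = list(pooled = pooled, per_season = per_season))
  if (!is.null(out_dir)) writePipelineOutputs(result, out_dir)
  result
}

writePipelineOutputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  writeRatePanel(result$rate_panel, file.path(out_dir, "rate_panel.tsv"))
  wt(result$diversity, "diversity.tsv")
  co <- result$pcoa$coordinates
  wt(data.frame(sample_id = rownames(co), co, check.names = FALSE),
     "pcoa_coordinates.tsv")
  if (!is.null(result$season_contrasts))
    wt(result$season_contrasts, "season_contrasts.tsv")
  for (s in names(result$networks)) {
    nw <- result$networks[[s]]
    if (is.null(nw$topology)) next
    exportEdgeList(nw$network, file.path(out_dir,
                                         paste0("network_", s, ".tsv")))
    exportGraphML(nw$network, file.path(out_dir,
                                        paste0("network_", s, ".graphml")))
    jsonlite::write_json(nw$topology,
                         file.path(out_dir, paste0("topology_", s, ".json")),
                         auto_unbox = TRUE, digits = NA)
    ma <- nw$module_abundance
    wt(data.frame(sample_id = rownames(ma), ma, check.names = FALSE),
       paste0("module_abundance_", s, ".tsv"))
  }
  verd <- result$decoupling$pooled$verdicts
  jsonlite::write_json(verd, file.path(out_dir, "decoupling_verdicts.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  regs <- do.call(rbind, lapply(names(result$decoupling$per_season),
    function(s) result$decoupling$per_season[[s]]$regressions))
  if (!is.null(regs) && nrow(regs)) wt(regs, "module_regressions.tsv")
  if (!is.null(result$permanova))
    jsonlite::write_json(result$permanova,
                         file.path(out_dir, "permanova.json"),
                         auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
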