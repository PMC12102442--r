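#' Generator configuration for synthetic survey data
#'
#' Defines the study conditions the generator emulates: a two-season
#' oligotrophic surface survey (40 summer and 48 winter stations) with
#' seasonal environmental contrasts, a bacterial abundance-production
#' coupling, a respiration rate driven by one community module, and an ASV
#' table with planted intra-correlated modules plus chloroplast and
#' mitochondrial contaminant lineages.
#'
#' Environmental and rate means/SDs default to the survey values:
#' summer temperature 29.8 +/- 0.6 C, salinity 34.7 +/- 0.4, Chl a
#' 0.05 +/- 0.02 ug/L; winter 26.9 +/- 1.4, 34.8 +/- 0.5, 0.10 +/- 0.04.
#' Bacterial abundance follows BA = ba_intercept + ba_chl_slope * Chl +
#' noise (so the seasonal means 6.95e5 / 8.45e5 cells/mL arise from the
#' seasonal Chl contrast); production is csBP x BA with lognormal noise;
#' respiration is BR0 + beta * (module-1 z-abundance) + noise,
#' independent of production by construction.
#'
#' @param n_summer,n_winter Station counts per season.
#' @param env Per-season mean/SD for temperature, salinity and Chl a.
#' @param ba_intercept,ba_chl_slope,ba_noise_sd BA model (cells/mL; slope
#'   per ug Chl/L).
#' @param csbp Cell-specific production level, fg C/cell/d.
#' @param csbp_sdlog Lognormal noise SD (log scale) on csBP.
#' @param br0 Baseline bacterial respiration, mg C m-3 d-1.
#' @param beta_module Effect of module-1 z-abundance on BR (mg C m-3 d-1
#'   per z unit).
#' @param br_noise_sd BR residual SD, mg C m-3 d-1.
#' @param br_frac_range Range of the bacterial share of community
#'   respiration (INT_0.2-0.8 / INT_T), drawn uniformly.
#' @param n_asv Total number of ASVs, contaminants included.
#' @param module_sizes Planted module sizes (module 1 first and largest).
#' @param intra_rho Target intra-module Spearman correlation of member
#'   abundances. The latent Pearson correlation is derived via the
#'   bivariate-normal identity \code{rho_P = 2 sin(pi rho_S / 6)} and the
#'   factor loading set to \code{eps_sd * sqrt(rho_P / (1 - rho_P))}.
#' @param module_base_shift Baseline log-abundance shift for module
#'   members. The negative default keeps the co-varying modules a modest
#'   share of each sample, limiting the compositional attenuation that
#'   closure (normalization to relative abundance) would otherwise impose
#'   on the realized intra-module correlations.
#' @param base_sd SD of per-ASV baseline log-abundance.
#' @param eps_sd Residual log-abundance SD.
#' @param depth_range Sequencing depth range, drawn uniformly per sample.
#' @param contaminant_fraction Fraction of ASVs given chloroplast or
#'   mitochondrial lineages.
#' @param constants [conversionConstants()] used when back-computing raw
#'   tracer inputs.
#' @return A named list of class \code{"GeneratorConfig"}.
#' @export
generatorConfig <- function(
    n_summer = 40L, n_winter = 48L,
    env = list(
      summer = list(temp = c(29.8, 0.6), sal = c(34.7, 0.4),
                    chl = c(0.05, 0.02)),
      winter = list(temp = c(26.9, 1.4), sal = c(34.8, 0.5),
                    chl = c(0.10, 0.04))),
    ba_intercept = 5.45e5, ba_chl_slope = 3e6, ba_noise_sd = 1.1e5,
    csbp = 0.085, csbp_sdlog = 0.4,
    br0 = 4.7, beta_module = 1.0, br_noise_sd = 1.4,
    br_frac_range = c(0.4, 0.9),
    n_asv = 120L, module_sizes = c(20L, 15L, 10L), intra_rho = 0.85,
    module_base_shift = -1.0,
    base_sd = 1.2, eps_sd = 1.0, depth_range = c(50000L, 120000L),
    contaminant_fraction = 0.1,
    constants = conversionConstants()) {
  cfg <- as.list(environment())
  if (sum(cfg$module_sizes) > cfg$n_asv)
    stop("module sizes must sum to <= n_asv")
  if (any(cfg$module_sizes < 2)) stop("each module needs >= 2 ASVs")
  if (cfg$intra_rho <= 0 || cfg$intra_rho >= 1)
    stop("intra_rho must lie in (0, 1)")
  if (any(cfg$depth_range < 1) || diff(cfg$depth_range) < 0)
    stop("invalid depth range")
  structure(cfg, class = "GeneratorConfig")
}

TAXON_POOL <- data.frame(
  phylum = c("Proteobacteria", "Proteobacteria", "Proteobacteria",
             "Proteobacteria", "Proteobacteria", "Proteobacteria",
             "Bacteroidota", "Cyanobacteria", "Actinobacteriota",
             "Planctomycetota", "Marinimicrobia_SAR406_clade",
             "Proteobacteria"),
  class = c("Alphaproteobacteria", "Alphaproteobacteria",
            "Alphaproteobacteria", "Gammaproteobacteria",
            "Gammaproteobacteria", "Gammaproteobacteria",
            "Bacteroidia", "Cyanobacteriia", "Acidimicrobiia",
            "Planctomycetes", "Marinimicrobia", "Alphaproteobacteria"),
  order = c("SAR11_clade", "Rhodobacterales", "Rhodospirillales",
            "SAR86_clade", "Thiotrichales", "Pseudomonadales",
            "Flavobacteriales", "Synechococcales", "Microtrichales",
            "Pirellulales", "Marinimicrobia_SAR406_clade",
            "Puniceispirillales"),
  stringsAsFactors = FALSE)

#' Generate per-station environmental metadata
#'
#' @param config A [generatorConfig()].
#' @param seed Integer seed.
#' @return data.frame with \code{sample_id}, \code{season},
#'   \code{temperature_C}, \code{salinity}, \code{chl_ug_L}; normal draws
#'   truncated at 0.
#' @export
genEnvironment <- function(config = generatorConfig(), seed = 1L) {
  withr::with_seed(seed, {
    one <- function(n, season, pars, prefix) {
      if (n == 0) return(NULL)
      data.frame(
        sample_id = sprintf("%s%03d", prefix, seq_len(n)),
        season = season,
        temperature_C = pmax(stats::rnorm(n, pars$temp[1], pars$temp[2]), 0),
        salinity = pmax(stats::rnorm(n, pars$sal[1], pars$sal[2]), 0),
        chl_ug_L = pmax(stats::rnorm(n, pars$chl[1], pars$chl[2]), 0),
        stringsAsFactors = FALSE)
    }
    rbind(one(config$n_summer, "summer", config$env$summer, "SU"),
          one(config$n_winter, "winter", config$env$winter, "WI"))
  })
}

#' Generate metabolic rates and back-computed tracer inputs
#'
#' Plants the coupling structure: BA increases with Chl a, BP is csBP x BA
#' with lognormal noise (so BA and BP are coupled), and BR is driven only
#' by the module-1 z-score abundance plus noise (so BR is independent of
#' BP given the module). Raw leucine and INT inputs are back-computed by
#' inverting the exact rate-conversion formulas, so [computeRatePanel()]
#' applied to the inputs reproduces the true panel.
#'
#' @param metadata Output of [genEnvironment()].
#' @param config A [generatorConfig()].
#' @param module_z Per-sample module-1 z-abundance (aligned with
#'   \code{metadata}); when NULL a latent standard-normal series is drawn
#'   in its place.
#' @param seed Integer seed.
#' @return List with \code{inputs} (raw tracer table for
#'   [computeRatePanel()]), \code{truth} (true BA/BP/BR/CR_O2 and the
#'   bacterial fraction), and \code{n_truncated}.
#' @export
genRates <- function(metadata, config = generatorConfig(), module_z = NULL,
                     seed = 1L) {
  n <- nrow(metadata)
  cc <- config$constants
  withr::with_seed(seed, {
    ba <- config$ba_intercept + config$ba_chl_slope * metadata$chl_ug_L +
      stats::rnorm(n, 0, config$ba_noise_sd)
    n_trunc <- sum(ba < 1e4)
    ba <- pmax(ba, 1e4)
    csbp <- config$csbp *
      stats::rlnorm(n, meanlog = -config$csbp_sdlog^2 / 2,
                    sdlog = config$csbp_sdlog)
    bp <- csbp * ba * 1e-6                       # fg/cell/d * cells/mL -> mg C m-3 d-1
    if (is.null(module_z)) module_z <- stats::rnorm(n)
    br <- config$br0 + config$beta_module * module_z +
      stats::rnorm(n, 0, config$br_noise_sd)
    n_trunc <- n_trunc + sum(br < 0.05)
    br <- pmax(br, 0.05)
    frac <- stats::runif(n, config$br_frac_range[1], config$br_frac_range[2])
  })
  br_o2 <- br / (cc$rq * cc$c_atomic_mass)
  cr_o2 <- br_o2 / frac
  int_total <- 10^((log10(cr_o2) - cc$cal_intercept) / cc$cal_slope)
  list(
    inputs = data.frame(
      sample_id = metadata$sample_id,
      leu_nmol_L_d = bp / cc$leu_to_c,
      int_total_umol_L_d = int_total,
      int_02_08_umol_L_d = frac * int_total,
      abs_sample = NA_real_, abs_blank = NA_real_,
      ba_cells_mL = ba, stringsAsFactors = FALSE),
    truth = data.frame(
      sample_id = metadata$sample_id, ba = ba, bp = bp, br = br,
      cr_o2 = cr_o2, bacterial_fraction = frac, module_z = module_z,
      stringsAsFactors = FALSE),
    n_truncated = n_trunc)
}

#' Generate an ASV community with planted correlated modules
#'
#' Log-abundance of ASV i in sample s is \code{base_i + lambda *
#' F_(m(i),s) + eps}, where members of a module share the latent factor
#' F_m drawn per sample; the loading is set from \code{intra_rho} so
#' intra-module latent correlations hit the target. Abundances are
#' normalized and sampled multinomially at a per-sample depth drawn from
#' \code{depth_range}. A fixed fraction of ASVs (never module members)
#' carries chloroplast or mitochondrial lineages; the rest draw lineages
#' from a pool of common marine classes and orders.
#'
#' @param metadata Output of [genEnvironment()].
#' @param config A [generatorConfig()].
#' @param seed Integer seed.
#' @return List with \code{counts} (ASVs x samples integer matrix),
#'   \code{taxonomy} (asv_id + rank columns), and \code{truth} (module
#'   membership with 0 = background, the factor matrix, and the loading).
#' @export
genCommunity <- function(metadata, config = generatorConfig(), seed = 1L) {
  n_s <- nrow(metadata)
  n_a <- config$n_asv
  asv_ids <- sprintf("ASV_%04d", seq_len(n_a))
  n_contam <- round(config$contaminant_fraction * n_a)
  rho_p <- min(2 * sin(pi * config$intra_rho / 6), 1 - 1e-9)
  lambda <- config$eps_sd * sqrt(rho_p / (1 - rho_p))

  withr::with_seed(seed, {
    contam <- sort(sample.int(n_a, n_contam))
    clean <- setdiff(seq_len(n_a), contam)
    membership <- stats::setNames(integer(n_a), asv_ids)
    pos <- 0
    for (k in seq_along(config$module_sizes)) {
      take <- clean[(pos + 1):(pos + config$module_sizes[k])]
      membership[take] <- k
      pos <- pos + config$module_sizes[k]
    }
    base <- stats::rnorm(n_a, 0, config$base_sd)
    base[membership > 0] <- base[membership > 0] + config$module_base_shift
    Fm <- matrix(stats::rnorm(length(config$module_sizes) * n_s), ncol = n_s)
    eps <- matrix(stats::rnorm(n_a * n_s, 0, config$eps_sd), nrow = n_a)
    logab <- base + eps
    for (k in seq_along(config$module_sizes)) {
      rows <- which(membership == k)
      logab[rows, ] <- logab[rows, ] + lambda * rep(Fm[k, ], each = length(rows))
    }
    w <- exp(logab)
    depths <- round(stats::runif(n_s, config$depth_range[1],
                                 config$depth_range[2]))
    counts <- vapply(seq_len(n_s), function(s)
      as.integer(stats::rmultinom(1, depths[s], w[, s])), integer(n_a))
    dimnames(counts) <- list(asv_ids, metadata$sample_id)

    pool_idx <- sample.int(nrow(TAXON_POOL), n_a, replace = TRUE)
    tax <- data.frame(
      asv_id = asv_ids, domain = "Bacteria",
      phylum = TAXON_POOL$phylum[pool_idx],
      class = TAXON_POOL$class[pool_idx],
      order = TAXON_POOL$order[pool_idx],
      family = paste0("Family_", pool_idx),
      genus = paste0("Genus_", pool_idx), stringsAsFactors = FALSE)
    is_chloro <- contam[seq_len(ceiling(n_contam / 2))]
    is_mito <- setdiff(contam, is_chloro)
    tax[is_chloro, c("phylum", "class", "order", "family", "genus")] <-
      list("Cyanobacteria", "Cyanobacteriia", "Chloroplast", "", "")
    tax[is_mito, c("phylum", "class", "order", "family", "genus")] <-
      list("Proteobacteria", "Alphaproteobacteria", "Rickettsiales",
           "Mitochondria", "")
  })
  list(counts = counts, taxonomy = tax,
       truth = list(membership = membership, factors = Fm, lambda = lambda,
                    contaminants = asv_ids[contam]))
}

#' Generate a complete synthetic survey bundle
#'
#' Wires the three generators on a shared station list: environment first,
#' then the community, then rates whose respiration is driven by the
#' realized module-1 z-score abundance of the generated (lineage-clean)
#' count table. Deterministic per seed.
#'
#' @param config A [generatorConfig()].
#' @param seed Integer seed; stage seeds are derived as seed, seed + 1,
#'   seed + 2.
#' @return List with \code{metadata}, \code{rate_inputs},
#'   \code{rate_truth}, \code{counts}, \code{taxonomy}, \code{truth}
#'   (module membership, coupling coefficients, module-1 z series).
#' @export
genDataset <- function(config = generatorConfig(), seed = 1L) {
  seed <- as.integer(seed)
  md <- genEnvironment(config, seed)
  comm <- genCommunity(md, config, seed + 1L)
  memb <- comm$truth$membership
  planted <- memb[memb > 0]
  mz <- moduleAbundance(comm$counts, planted)[md$sample_id, "Module_1"]
  rates <- genRates(md, config, module_z = mz, seed = seed + 2L)
  list(metadata = md,
       rate_inputs = rates$inputs,
       rate_truth = rates$truth,
       counts = comm$counts,
       taxonomy = comm$taxonomy,
       truth = list(membership = memb,
                    contaminants = comm$truth$contaminants,
                    lambda = comm$truth$lambda,
                    ba_chl_slope = config$ba_chl_slope,
                    csbp = config$csbp,
                    beta_module = config$beta_module,
                    module1_z = mz,
                    seed = seed))
}

#' Write a synthetic bundle to disk in the pipeline's input formats
#'
#' Writes \code{metadata.tsv}, \code{rates.tsv}, \code{asv.tsv},
#' \code{taxonomy.tsv} and \code{truth.json} into \code{dir}.
#'
#' @param bundle Output of [genDataset()].
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeDataset <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(bundle$metadata, "metadata.tsv")
  wt(bundle$rate_inputs, "rates.tsv")
  asv <- data.frame(asv_id = rownames(bundle$counts), bundle$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  wt(asv, "asv.tsv")
  tx <- bundle$taxonomy
  lineage <- do.call(paste, c(tx[TAX_RANKS], sep = ";"))
  wt(data.frame(asv_id = tx$asv_id, lineage = lineage,
                stringsAsFactors = FALSE), "taxonomy.tsv")
  jsonlite::write_json(
    list(membership = as.list(bundle$truth$membership),
         contaminants = bundle$truth$contaminants,
         lambda = bundle$truth$lambda,
         ba_chl_slope = bundle$truth$ba_chl_slope,
         csbp = bundle$truth$csbp,
         beta_module = bundle$truth$beta_module,
         module1_z = as.list(stats::setNames(bundle$truth$module1_z,
                                             bundle$metadata$sample_id)),
         seed = bundle$truth$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
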