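#' Scale a vector by its maximum
#'
#' Divides every value by the overall maximum so the largest value maps to
#' 1; used to put respiration rates from different surveys on a common
#' axis before regression.
#'
#' @param values Numeric vector with a positive maximum.
#' @return Scaled vector.
#' @export
scaleToMax <- function(values) {
  mx <- max(values, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) stop("maximum must be positive")
  values / mx
}

#' Ordinary least-squares regression of y on x
#'
#' @param x,y Numeric vectors, n >= 3 complete pairs, x non-constant.
#' @return List with \code{slope}, \code{intercept}, \code{r2}, \code{p}
#'   (two-sided t-test on the slope) and \code{n}.
#' @export
linReg <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 complete pairs")
  if (max(x) == min(x)) stop("x is constant; slope undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  p <- if (nrow(sm$coefficients) > 1) sm$coefficients[2, 4] else NA_real_
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else sm$r.squared   # constant y: define R^2 = 0
  slope <- unname(stats::coef(fit)[2])
  if (sst == 0) slope <- 0
  list(slope = slope,
       intercept = unname(stats::coef(fit)[1]),
       r2 = r2, p = p, n = length(x))
}

starsFor <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Pairwise correlation panel with significance stars
#'
#' Correlates every pair of variables (pairwise-complete observations) and
#' marks p < 0.05 with * and p < 0.01 with **. Spearman by default,
#' matching the network methodology; an optional BH adjustment across the
#' panel is off by default because the survey-style heatmap reports raw
#' stars.
#'
#' @param vars Named list (or data.frame) of numeric vectors of equal
#'   length.
#' @param method \code{"spearman"} or \code{"pearson"}.
#' @param bh Apply BH adjustment across the upper triangle before starring.
#' @return List with matrices \code{r}, \code{p}, \code{stars}, and
#'   \code{n} (complete pairs per cell).
#' @export
correlationPanel <- function(vars, method = c("spearman", "pearson"),
                             bh = FALSE) {
  method <- match.arg(method)
  df <- as.data.frame(vars)
  k <- ncol(df)
  nm <- names(df)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(r) <- 1; diag(p) <- 0; diag(n) <- colSums(!is.na(df))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- stats::complete.cases(df[[i]], df[[j]])
    n[i, j] <- n[j, i] <- sum(ok)
    if (sum(ok) < 3) next
    ct <- suppressWarnings(
      stats::cor.test(df[[i]][ok], df[[j]][ok], method = method))
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  pstar <- p
  if (bh) {
    up <- upper.tri(p)
    pstar[up] <- bhAdjust(p[up])
    pstar[lower.tri(pstar)] <- t(pstar)[lower.tri(pstar)]
  }
  stars <- matrix(starsFor(pstar), k, k, dimnames = list(nm, nm))
  diag(stars) <- ""
  list(r = r, p = p, stars = stars, n = n, method = method)
}

#' Principal component analysis on standardized variables
#'
#' Columns are z-scored (so the decomposition is of the correlation
#' matrix), zero-variance columns are dropped with a warning, axes are
#' ordered by variance, and each axis's sign is fixed so its
#' largest-magnitude loading is positive.
#'
#' @param m Numeric matrix or data.frame, samples x variables (>= 3
#'   samples, >= 2 variables).
#' @return List with \code{loadings} (variables x axes), \code{scores}
#'   (samples x axes), \code{percent_variance}.
#' @export
pcaPanel <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 3 || ncol(m) < 2) stop("need >= 3 samples and >= 2 variables")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance columns: ",
            paste(colnames(m)[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  z <- scale(m)
  e <- eigen(stats::cor(m), symmetric = TRUE)
  ev <- pmax(e$values, 0)
  load <- e$vectors
  for (j in seq_len(ncol(load))) {
    top <- which.max(abs(load[, j]))
    if (load[top, j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(colnames(m), paste0("PC", seq_len(ncol(load))))
  scores <- z %*% load
  list(loadings = load, scores = scores,
       percent_variance = 100 * ev / sum(ev))
}

#' Coupling/decoupling report for rates and community modules
#'
#' Assembles the descriptive linkage analysis: (i) a correlation panel over
#' chlorophyll a, bacterial abundance, production and respiration; (ii)
#' per-season OLS regressions of max-scaled BR on each network module's
#' z-score abundance; (iii) a verdict table flagging each rate pair as
#' coupled (p < alpha) or decoupled (p >= alpha). The verdicts are
#' descriptive labels for observed correlation, not causal claims.
#'
#' @param panel data.frame with columns \code{sample_id}, \code{ba},
#'   \code{bp}, \code{br} and optionally \code{chl}.
#' @param module_abund Samples x modules matrix from [moduleAbundance()]
#'   (rownames = sample ids), or NULL to skip the module regressions.
#' @param season Optional factor of season labels per panel row; module
#'   regressions are run within each season.
#' @param method Correlation method for the panel.
#' @param alpha Significance level for the coupled/decoupled verdict.
#' @return List with \code{correlations}, \code{regressions} (data.frame),
#'   \code{verdicts} (data.frame with pair, rho, p, verdict).
#' @export
decouplingReport <- function(panel, module_abund = NULL, season = NULL,
                             method = c("spearman", "pearson"),
                             alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(is.data.frame(panel),
            all(c("sample_id", "ba", "bp", "br") %in% names(panel)))
  if (sum(stats::complete.cases(panel[c("ba", "bp", "br")])) < 3)
    stop("need >= 3 matched samples")
  if (!is.null(season) && length(season) != nrow(panel))
    stop("season must have one label per panel row")

  vars <- panel[intersect(c("chl", "ba", "bp", "br"), names(panel))]
  corr <- correlationPanel(vars, method = method)

  pairs <- utils::combn(names(vars), 2)
  verdicts <- data.frame(
    var1 = pairs[1, ], var2 = pairs[2, ],
    r = corr$r[t(pairs)], p = corr$p[t(pairs)],
    stringsAsFactors = FALSE)
  verdicts$verdict <- ifelse(is.na(verdicts$p), "undetermined",
                             ifelse(verdicts$p < alpha, "coupled",
                                    "decoupled"))

  regressions <- NULL
  if (!is.null(module_abund)) {
    module_abund <- as.matrix(module_abund)
    idx <- match(panel$sample_id, rownames(module_abund))
    if (anyNA(idx)) stop("module abundance lacks samples: ",
                         paste(panel$sample_id[is.na(idx)][1:3], collapse = ", "))
    ma <- module_abund[idx, , drop = FALSE]
    seas <- if (is.null(season)) rep("all", nrow(panel))
            else as.character(season)
    rows <- list()
    for (s in unique(seas)) {
      sel <- seas == s & !is.na(panel$br)
      if (sum(sel) < 3) next
      br_scaled <- scaleToMax(panel$br[sel])
      for (mod in colnames(ma)) {
        fit <- try(linReg(ma[sel, mod], br_scaled), silent = TRUE)
        if (inherits(fit, "try-error")) next
        rows[[length(rows) + 1]] <- data.frame(
          season = s, module = mod, slope = fit$slope,
          intercept = fit$intercept, r2 = fit$r2, p = fit$p, n = fit$n,
          stringsAsFactors = FALSE)
      }
    }
    regressions <- if (length(rows)) do.call(rbind, rows) else
      data.frame(season = character(0), module = character(0),
                 slope = numeric(0), intercept = numeric(0),
                 r2 = numeric(0), p = numeric(0), n = integer(0))
    rownames(regressions) <- NULL
  }
  list(correlations = corr, regressions = regressions, verdicts = verdicts,
       alpha = alpha, method = method)
}
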