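#' Conversion constants for bacterial metabolic rates
#'
#' Bundles the empirical constants used to convert raw tracer measurements
#' into carbon-unit rates: the leucine-to-carbon factor for bacterial
#' production, the log-log calibration relating total INT reduction to
#' community respiration in oxygen units, the respiratory quotient, and the
#' atomic mass of carbon used for the O2-to-carbon step.
#'
#' @param leu_to_c Leucine-to-carbon conversion factor, kg C mol^-1 leucine.
#'   With leucine incorporation in nmol L^-1 d^-1 this yields bacterial
#'   production in mg C m^-3 d^-1 (equivalently ug C L^-1 d^-1).
#' @param cal_slope Slope of the log10-log10 calibration
#'   \code{log10(CR_O2) = cal_slope * log10(INT_T) + cal_intercept},
#'   with INT_T in umol INT L^-1 d^-1 and CR_O2 in umol O2 L^-1 d^-1.
#' @param cal_intercept Intercept of the same calibration.
#' @param rq Respiratory quotient, mol C respired per mol O2 consumed.
#' @param c_atomic_mass Atomic mass of carbon, ug C umol^-1.
#' @return A named list of class \code{"ConversionConstants"}.
#' @examples
#' cc <- conversionConstants()
#' leucineToBP(1, cc)   # 0.37 mg C m^-3 d^-1
#' @export
conversionConstants <- function(leu_to_c = 0.37, cal_slope = 0.72,
                                cal_intercept = 0.44, rq = 1.0,
                                c_atomic_mass = 12.011) {
  vals <- c(leu_to_c = leu_to_c, cal_slope = cal_slope, rq = rq,
            c_atomic_mass = c_atomic_mass)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("conversion constants must be finite and strictly positive")
  if (!is.finite(cal_intercept))
    stop("cal_intercept must be finite")
  structure(list(leu_to_c = leu_to_c, cal_slope = cal_slope,
                 cal_intercept = cal_intercept, rq = rq,
                 c_atomic_mass = c_atomic_mass),
            class = "ConversionConstants")
}

#' Blank-correct an absorbance reading
#'
#' Subtracts the killed-control absorbance from the live-sample absorbance.
#' Negative differences (blank exceeding sample, as happens by noise in the
#' field) are clamped to zero with a warning rather than treated as errors.
#'
#' @param abs_sample,abs_blank Absorbance at 485 nm, both finite and >= 0.
#' @return Corrected absorbance, >= 0.
#' @export
blankCorrect <- function(abs_sample, abs_blank) {
  if (any(!is.finite(abs_sample)) || any(!is.finite(abs_blank)) ||
      any(abs_sample < 0) || any(abs_blank < 0))
    stop("absorbances must be finite and non-negative")
  d <- abs_sample - abs_blank
  if (any(d < 0)) {
    warning("blank absorbance exceeds sample absorbance; clamping to 0")
    d[d < 0] <- 0
  }
  d
}

#' Convert absorbance to INT-formazan concentration via a standard curve
#'
#' Inverts the linear standard curve \code{absorbance = slope * conc +
#' intercept}; concentrations below zero are clamped to zero.
#'
#' @param absorbance Absorbance at 485 nm.
#' @param slope Standard-curve slope (absorbance per uM), > 0.
#' @param intercept Standard-curve intercept (absorbance).
#' @return INT-formazan concentration, uM.
#' @export
applyStandardCurve <- function(absorbance, slope, intercept = 0) {
  if (!is.finite(slope) || slope <= 0)
    stop("standard curve slope must be finite and > 0")
  pmax((absorbance - intercept) / slope, 0)
}

#' Leucine incorporation to bacterial production
#'
#' BP = leucine incorporation x leucine-to-carbon factor. With incorporation
#' in nmol Leu L^-1 d^-1 and the factor in kg C mol^-1 Leu the product is
#' ug C L^-1 d^-1 = mg C m^-3 d^-1.
#'
#' @param leu Leucine incorporation rate, nmol Leu L^-1 d^-1, >= 0.
#' @param constants A [conversionConstants()] list.
#' @return Bacterial production, mg C m^-3 d^-1.
#' @export
leucineToBP <- function(leu, constants = conversionConstants()) {
  if (any(leu < 0, na.rm = TRUE)) stop("leucine incorporation must be >= 0")
  leu * constants$leu_to_c
}

#' Total INT reduction to community respiration in oxygen units
#'
#' Applies the empirical power-law calibration
#' \code{log10(CR_O2) = cal_slope * log10(INT_T) + cal_intercept}.
#' The logarithm requires INT_T > 0; a measured zero should be mapped to
#' CR_O2 = 0 by the caller explicitly (as [computeRatePanel()] does), so the
#' log-domain restriction is never silent.
#'
#' @param int_total Total INT reduction rate INT_T, umol INT L^-1 d^-1, > 0.
#' @param constants A [conversionConstants()] list.
#' @return Community respiration CR_O2, umol O2 L^-1 d^-1.
#' @export
intToCR <- function(int_total, constants = conversionConstants()) {
  if (any(!is.finite(int_total)) || any(int_total <= 0))
    stop("int_total must be finite and > 0 (log-log calibration)")
  10^(constants$cal_slope * log10(int_total) + constants$cal_intercept)
}

#' Partition community respiration into its bacterial fraction
#'
#' Bacterial respiration in oxygen units is community respiration scaled by
#' the share of INT reduced in the 0.2-0.8 um size fraction:
#' \code{BR_O2 = CR_O2 * INT_0.2-0.8 / INT_T}.
#'
#' @param cr_o2 Community respiration, umol O2 L^-1 d^-1.
#' @param int_02_08 INT reduced in the 0.2-0.8 um fraction, umol L^-1 d^-1.
#' @param int_total Total INT reduction INT_T, umol L^-1 d^-1, > 0.
#' @param sample_id Optional identifier(s) used in error messages.
#' @return Bacterial respiration, umol O2 L^-1 d^-1, in [0, cr_o2].
#' @export
partitionBR <- function(cr_o2, int_02_08, int_total, sample_id = NULL) {
  if (any(int_total <= 0, na.rm = TRUE)) stop("int_total must be > 0")
  frac <- int_02_08 / int_total
  bad <- which(frac > 1 | frac < 0)
  if (length(bad)) {
    who <- if (is.null(sample_id)) paste(bad, collapse = ", ")
           else paste(sample_id[bad], collapse = ", ")
    stop("size-fraction INT exceeds total INT (or is negative) for: ", who)
  }
  cr_o2 * frac
}

#' Oxygen-unit respiration to carbon units
#'
#' Converts umol O2 L^-1 d^-1 to mg C m^-3 d^-1 using the respiratory
#' quotient (mol C per mol O2) and the atomic mass of carbon:
#' 1 umol C L^-1 d^-1 x 12.011 ug C umol^-1 = 12.011 ug C L^-1 d^-1
#' = 12.011 mg C m^-3 d^-1.
#'
#' @param rate_o2 Respiration rate, umol O2 L^-1 d^-1, >= 0.
#' @param constants A [conversionConstants()] list.
#' @return Rate in mg C m^-3 d^-1.
#' @export
o2ToCarbon <- function(rate_o2, constants = conversionConstants()) {
  if (any(rate_o2 < 0, na.rm = TRUE)) stop("rate_o2 must be >= 0")
  rate_o2 * constants$rq * constants$c_atomic_mass
}

#' Cell-specific rate
#'
#' Divides a volumetric carbon rate by bacterial abundance:
#' 1 mg C m^-3 = 10^6 fg C mL^-1, so
#' \code{cs = rate * 1e6 / ba} with \code{ba} in cells mL^-1 gives
#' fg C cell^-1 d^-1.
#'
#' @param rate Rate, mg C m^-3 d^-1.
#' @param ba Bacterial abundance, cells mL^-1, > 0.
#' @return Cell-specific rate, fg C cell^-1 d^-1.
#' @export
cellSpecificRate <- function(rate, ba) {
  if (any(!is.finite(ba)) || any(ba <= 0))
    stop("bacterial abundance must be finite and > 0")
  rate * 1e6 / ba
}

#' Compute the full per-sample rate panel
#'
#' Composes the individual conversions into one panel: bacterial production
#' from leucine incorporation, community respiration from total INT
#' reduction, bacterial respiration from the size-fraction partition at the
#' respiratory quotient, and cell-specific rates. Raw absorbances, when
#' supplied instead of INT rates, are blank-corrected and put through the
#' standard curve first. Missing raw fields propagate as \code{NA} outputs,
#' never as zeros; a measured \code{int_total} of exactly zero maps to
#' \code{cr_o2 = 0} explicitly. Per-sample validation failures are collected
#' in the \code{errors} attribute rather than aborting the whole panel.
#'
#' @param inputs A data.frame with columns \code{sample_id},
#'   \code{leu_nmol_L_d}, \code{int_total_umol_L_d},
#'   \code{int_02_08_umol_L_d}, \code{ba_cells_mL} and optionally
#'   \code{abs_sample}, \code{abs_blank}, \code{curve_slope},
#'   \code{curve_intercept}.
#' @param constants A [conversionConstants()] list.
#' @return A data.frame with columns \code{sample_id}, \code{bp_mgC_m3_d},
#'   \code{cr_o2_umolO2_L_d}, \code{br_mgC_m3_d}, \code{csbp_fgC_cell_d},
#'   \code{csbr_fgC_cell_d}; rows with validation errors are dropped and
#'   reported in \code{attr(, "errors")} (a character vector, one message
#'   per offending sample).
#' @examples
#' x <- data.frame(sample_id = "st1", leu_nmol_L_d = 1,
#'                 int_total_umol_L_d = 1, int_02_08_umol_L_d = 1,
#'                 ba_cells_mL = 1e6)
#' computeRatePanel(x)
#' @export
computeRatePanel <- function(inputs, constants = conversionConstants()) {
  stopifnot(is.data.frame(inputs), "sample_id" %in% names(inputs))
  need <- c("leu_nmol_L_d", "int_total_umol_L_d", "int_02_08_umol_L_d",
            "ba_cells_mL")
  for (col in need) if (is.null(inputs[[col]])) inputs[[col]] <- NA_real_
  if (anyDuplicated(inputs$sample_id))
    stop("duplicate sample_id in rate inputs: ",
         paste(unique(inputs$sample_id[duplicated(inputs$sample_id)]),
               collapse = ", "))

  errors <- character(0)
  one <- function(row) {
    sid <- row$sample_id
    out <- data.frame(sample_id = sid, bp_mgC_m3_d = NA_real_,
                      cr_o2_umolO2_L_d = NA_real_, br_mgC_m3_d = NA_real_,
                      csbp_fgC_cell_d = NA_real_, csbr_fgC_cell_d = NA_real_)
    res <- try({
      int_t <- row$int_total_umol_L_d
      int_b <- row$int_02_08_umol_L_d
      # absorbance route: blank-correct and calibrate when rates are absent
      if (is.na(int_t) && !is.null(row$abs_sample) && !is.na(row$abs_sample)) {
        corr <- blankCorrect(row$abs_sample, row$abs_blank)
        slope <- if (!is.null(row$curve_slope)) row$curve_slope else 1
        icpt <- if (!is.null(row$curve_intercept)) row$curve_intercept else 0
        int_t <- applyStandardCurve(corr, slope, icpt)
      }
      if (!is.na(row$leu_nmol_L_d))
        out$bp_mgC_m3_d <- leucineToBP(row$leu_nmol_L_d, constants)
      if (!is.na(int_t)) {
        out$cr_o2_umolO2_L_d <- if (int_t == 0) 0 else intToCR(int_t, constants)
        if (!is.na(int_b)) {
          br_o2 <- if (int_t == 0) 0 else
            partitionBR(out$cr_o2_umolO2_L_d, int_b, int_t, sid)
          out$br_mgC_m3_d <- o2ToCarbon(br_o2, constants)
        }
      }
      if (!is.na(row$ba_cells_mL)) {
        if (!is.na(out$bp_mgC_m3_d))
          out$csbp_fgC_cell_d <- cellSpecificRate(out$bp_mgC_m3_d,
                                                  row$ba_cells_mL)
        if (!is.na(out$br_mgC_m3_d))
          out$csbr_fgC_cell_d <- cellSpecificRate(out$br_mgC_m3_d,
                                                  row$ba_cells_mL)
      }
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      errors <<- c(errors, paste0(sid, ": ",
                                  trimws(attr(res, "condition")$message)))
      return(NULL)
    }
    out
  }

  rows <- lapply(seq_len(nrow(inputs)), function(i) one(inputs[i, , drop = FALSE]))
  panel <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(panel))
    panel <- data.frame(sample_id = character(0), bp_mgC_m3_d = numeric(0),
                        cr_o2_umolO2_L_d = numeric(0), br_mgC_m3_d = numeric(0),
                        csbp_fgC_cell_d = numeric(0), csbr_fgC_cell_d = numeric(0))
  rownames(panel) <- NULL
  attr(panel, "errors") <- errors
  attr(panel, "units") <- c(bp = "mg C m-3 d-1", cr_o2 = "umol O2 L-1 d-1",
                            br = "mg C m-3 d-1", csbp = "fg C cell-1 d-1",
                            csbr = "fg C cell-1 d-1")
  panel
}

#' Read raw rate measurements from TSV
#'
#' @param path TSV with header \code{sample_id leu_nmol_L_d
#'   int_total_umol_L_d int_02_08_umol_L_d abs_sample abs_blank ba_cells_mL};
#'   missing values as empty fields or "NA".
#' @return data.frame suitable for [computeRatePanel()].
#' @export
readRateInputs <- function(path) {
  x <- utils::read.delim(path, sep = "\t", header = TRUE,
                         na.strings = c("", "NA"), check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(x)) stop("rate input lacks 'sample_id' column")
  x$sample_id <- as.character(x$sample_id)
  x
}

#' Write a rate panel (and its validation report) to disk
#'
#' @param panel Output of [computeRatePanel()].
#' @param path Output TSV path; a JSON validation report is written next to
#'   it as \code{<path>.report.json}.
#' @return \code{path}, invisibly.
#' @export
writeRatePanel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  report <- list(n_samples = nrow(panel),
                 n_errors = length(attr(panel, "errors")),
                 errors = as.list(attr(panel, "errors")))
  jsonlite::write_json(report, paste0(path, ".report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
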