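#' @import methods
NULL

.VALID_BASES <- c("A", "C", "G", "T")

## Canonical column set of the per-variant association table held by a
## StudyPanel. Positions are 1-based (GWAS convention). Betas are per copy of
## the effect allele: SD units for continuous traits, log-OR for binary ones.
.PANEL_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "pvalue", "n", "n_cases", "n_controls")

.empty_records <- function() {
  data.frame(snp_id = character(), chrom = character(), pos = integer(),
             effect_allele = character(), other_allele = character(),
             eaf = numeric(), beta = numeric(), se = numeric(),
             pvalue = numeric(), n = numeric(), n_cases = numeric(),
             n_controls = numeric(), stringsAsFactors = FALSE)
}

.validate_records <- function(df) {
  ## Returns a character vector of row-level problems ("" where the row is
  ## fine), so callers can reject rows with line numbers.
  msg <- character(nrow(df))
  bad <- function(cond, text) {
    cond[is.na(cond)] <- TRUE
    ifelse(cond & !nzchar(msg), text, "")
  }
  add <- function(cur, extra) ifelse(nzchar(cur), cur, extra)
  msg <- add(msg, bad(!(df$effect_allele %in% .VALID_BASES) |
                      !(df$other_allele %in% .VALID_BASES),
                      "alleles must be single bases A/C/G/T"))
  msg <- add(msg, bad(df$effect_allele == df$other_allele,
                      "effect and other allele identical"))
  msg <- add(msg, bad(!is.finite(df$se) | df$se <= 0, "se must be > 0"))
  msg <- add(msg, bad(!is.finite(df$beta), "beta must be finite"))
  msg <- add(msg, bad(!is.finite(df$eaf) | df$eaf < 0 | df$eaf > 1,
                      "eaf must lie in [0,1]"))
  msg <- add(msg, bad(!is.finite(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1,
                      "pvalue must lie in (0,1]"))
  msg <- add(msg, bad(!is.finite(df$n) | df$n <= 0, "n must be positive"))
  cc <- is.finite(df$n_cases) & is.finite(df$n_controls)
  msg <- add(msg, ifelse(cc & df$n_cases + df$n_controls != df$n,
                         "n_cases + n_controls != n", ""))
  msg <- add(msg, ifelse(cc & (df$n_cases < 0 | df$n_controls < 0),
                         "negative case/control count", ""))
  msg
}

#' StudyPanel: one trait's GWAS summary statistics
#'
#' Container for the per-variant association statistics of a single trait
#' (one GWAS source), together with trait-level metadata. `records` is a
#' data.frame with one row per variant and the canonical columns
#' `snp_id, chrom, pos, effect_allele, other_allele, eaf, beta, se, pvalue,
#' n, n_cases, n_controls` (the last two may be `NA` for continuous traits).
#'
#' @slot traitName character(1) trait label.
#' @slot traitType `"continuous"` or `"binary"`.
#' @slot sdUnits optional annotation of what 1 SD means on the measurement
#'   scale (e.g. `"1 SD ~ 17.6-21.5 umol/L"` for plasma vitamin C).
#' @slot nCases,nControls panel-level case/control counts for binary traits
#'   (`NA` when given per record or for continuous traits).
#' @slot records data.frame of per-variant associations (see above).
#'
#' @export
setClass("StudyPanel",
  representation(traitName = "character", traitType = "character",
                 sdUnits = "character", nCases = "numeric",
                 nControls = "numeric", records = "data.frame"),
  prototype(traitName = NA_character_, traitType = "continuous",
            sdUnits = NA_character_, nCases = NA_real_, nControls = NA_real_,
            records = .empty_records()))

setValidity("StudyPanel", function(object) {
  df <- object@records
  if (!all(.PANEL_COLS %in% names(df)))
    return(paste("records must contain columns:",
                 paste(setdiff(.PANEL_COLS, names(df)), collapse = ", ")))
  if (!object@traitType %in% c("continuous", "binary"))
    return("traitType must be 'continuous' or 'binary'")
  if (anyDuplicated(df$snp_id))
    return(paste("duplicate snp_id:",
                 paste(unique(df$snp_id[duplicated(df$snp_id)]),
                       collapse = ", ")))
  if (nrow(df)) {
    prob <- .validate_records(df)
    if (any(nzchar(prob)))
      return(paste0("invalid record ", df$snp_id[nzchar(prob)][1], ": ",
                    prob[nzchar(prob)][1]))
  }
  if (object@traitType == "binary") {
    panel_cc <- is.finite(object@nCases) && is.finite(object@nControls)
    rec_cc <- nrow(df) == 0 ||
      all(is.finite(df$n_cases) & is.finite(df$n_controls))
    if (!panel_cc && !rec_cc)
      return("binary trait requires case/control counts on the panel or per record")
  }
  TRUE
})

#' LDReference: pairwise signed LD correlations
#'
#' Sparse table of signed correlations r between nearby variants, as computed
#' from a phased reference panel (e.g. 503 European samples of 1000 Genomes
#' phase 3). Entries are stored symmetrically; `r(a,a) = 1` is implicit.
#' The sign of r carries the haplotype phase: a proxy "in phase" with its
#' index variant has r > 0 between the recorded effect alleles.
#'
#' @slot entries data.frame with columns `snp_a`, `snp_b`, `r`.
#' @slot sampleN integer(1) reference-panel size.
#'
#' @export
setClass("LDReference",
  representation(entries = "data.frame", sampleN = "integer"),
  prototype(entries = data.frame(snp_a = character(), snp_b = character(),
                                 r = numeric(), stringsAsFactors = FALSE),
            sampleN = NA_integer_))

setValidity("LDReference", function(object) {
  df <- object@entries
  if (!all(c("snp_a", "snp_b", "r") %in% names(df)))
    return("entries must have columns snp_a, snp_b, r")
  if (nrow(df) && any(!is.finite(df$r) | abs(df$r) > 1))
    return("r must lie in [-1, 1]")
  TRUE
})

## Columns of the harmonized-instrument table: gamma/se on the exposure side,
## Gamma/se on the outcome side, both expressed per copy of the same allele.
.HARM_COLS <- c("snp_id", "proxy_of", "beta_exp", "se_exp", "beta_out",
                "se_out", "eaf_exp", "eaf_out", "palindromic", "action")

#' HarmonizedSet: analysis-ready exposure-outcome instrument set
#'
#' Holds the instruments retained for one exposure-outcome pair after
#' selection, proxy substitution and allele alignment, plus an audit of the
#' variants dropped along the way. Both betas of every retained instrument
#' are expressed per copy of the same effect allele.
#'
#' @slot exposureName,outcomeName character(1) trait labels.
#' @slot instruments data.frame with columns `snp_id, proxy_of, beta_exp,
#'   se_exp, beta_out, se_out, eaf_exp, eaf_out, palindromic, action`;
#'   action is one of `kept`, `flipped`, `proxied`.
#' @slot audit data.frame (`snp_id`, `action`, `reason`) of dropped variants.
#'
#' @export
setClass("HarmonizedSet",
  representation(exposureName = "character", outcomeName = "character",
                 instruments = "data.frame", audit = "data.frame"),
  prototype(exposureName = NA_character_, outcomeName = NA_character_,
            instruments = data.frame(), audit = data.frame(
              snp_id = character(), action = character(),
              reason = character(), stringsAsFactors = FALSE)))

setValidity("HarmonizedSet", function(object) {
  df <- object@instruments
  if (!all(.HARM_COLS %in% names(df)))
    return(paste("instruments must contain columns:",
                 paste(setdiff(.HARM_COLS, names(df)), collapse = ", ")))
  if (anyDuplicated(df$snp_id)) return("duplicate snp_id among instruments")
  if (nrow(df)) {
    if (any(df$se_exp <= 0) || any(df$se_out <= 0))
      return("instrument SEs must be > 0")
    if (!all(df$action %in% c("kept", "flipped", "proxied")))
      return("retained instruments must have action kept/flipped/proxied")
  }
  TRUE
})

#' MREstimate: one method's causal estimate with diagnostics
#'
#' One MR method's causal estimate for an exposure-outcome pair. `beta` is on
#' the log-OR scale per 1-SD exposure for binary outcomes (exponentiate for
#' the OR) and on the SD scale per unit log-OR in reverse MR. Optional slots
#' are `NA` when the method does not produce them.
#'
#' @slot method one of `wald`, `ivw_re`, `egger`, `weighted_median`, `mbe`,
#'   `presso`, `robust`, `raps`, `mv_ivw`.
#' @slot beta,se,ciLow,ciHigh,pvalue point estimate, SE, normal 95% CI, and
#'   two-sided normal p-value.
#' @slot nSnps number of instruments used.
#' @slot q,qDf,qP Cochran's Q heterogeneity statistic, df, and p.
#' @slot eggerIntercept,eggerInterceptSE,eggerInterceptP MR-Egger intercept
#'   (average directional pleiotropy) and its test.
#' @slot pressoGlobalP MR-PRESSO global test p-value.
#' @slot outliers snp_ids flagged as pleiotropic outliers.
#' @slot distortionP MR-PRESSO distortion-test p-value.
#'
#' @export
setClass("MREstimate",
  representation(method = "character", beta = "numeric", se = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", pvalue = "numeric",
                 nSnps = "integer", q = "numeric", qDf = "numeric",
                 qP = "numeric", eggerIntercept = "numeric",
                 eggerInterceptSE = "numeric", eggerInterceptP = "numeric",
                 pressoGlobalP = "numeric", outliers = "character",
                 distortionP = "numeric"),
  prototype(q = NA_real_, qDf = NA_real_, qP = NA_real_,
            eggerIntercept = NA_real_, eggerInterceptSE = NA_real_,
            eggerInterceptP = NA_real_, pressoGlobalP = NA_real_,
            outliers = character(), distortionP = NA_real_))

setValidity("MREstimate", function(object) {
  if (length(object@beta) != 1 || !is.finite(object@beta))
    return("beta must be a finite scalar")
  if (!is.finite(object@se) || object@se <= 0) return("se must be > 0")
  if (object@ciLow > object@beta || object@beta > object@ciHigh)
    return("CI must bracket beta")
  TRUE
})

#' MetaResult: random-effects meta-analysis summary
#'
#' Result of DerSimonian-Laird random-effects pooling on the log scale.
#'
#' @slot pooled,se,ciLow,ciHigh pooled log effect, its SE and normal 95% CI.
#' @slot tau2 moment estimate of between-study variance (>= 0).
#' @slot q,qDf Cochran's Q about the fixed-effect mean and its df.
#' @slot i2 heterogeneity fraction `max(0, (Q - df)/Q)`.
#' @slot nStudies number of studies pooled.
#'
#' @export
setClass("MetaResult",
  representation(pooled = "numeric", se = "numeric", ciLow = "numeric",
                 ciHigh = "numeric", tau2 = "numeric", q = "numeric",
                 qDf = "integer", i2 = "numeric", nStudies = "integer"))

setValidity("MetaResult", function(object) {
  if (object@tau2 < 0) return("tau2 must be >= 0")
  if (object@se <= 0) return("se must be > 0")
  TRUE
})

#' MinDetectableOR: detectable odds-ratio bounds for a binary-outcome design
#'
#' The pair of odds ratios closest to 1 that a given two-sample MR design can
#' detect at the target power, found on a fixed OR grid.
#'
#' @slot orLower largest OR < 1 on the grid with power >= target.
#' @slot orUpper smallest OR > 1 on the grid with power >= target.
#' @slot gridStep grid resolution (default 0.01).
#' @slot powerLower,powerUpper achieved power at the two bounds.
#'
#' @export
setClass("MinDetectableOR",
  representation(orLower = "numeric", orUpper = "numeric",
                 gridStep = "numeric", powerLower = "numeric",
                 powerUpper = "numeric"))

setValidity("MinDetectableOR", function(object) {
  if (!(object@orLower < 1 && object@orUpper > 1))
    return("orLower must be < 1 and orUpper > 1")
  TRUE
})

#' SimTruth: generating parameters of a synthetic two-sample dataset
#'
#' Records the ground truth behind a synthetic summary-statistics pair so
#' estimator output can be compared against it.
#'
#' @slot betaCausal true causal effect (log-OR per SD for binary outcomes).
#' @slot gamma true per-variant SNP-exposure effects.
#' @slot alpha true per-variant direct (pleiotropic) SNP-outcome effects.
#' @slot realizedR2 exposure variance explained by the instruments.
#'
#' @export
setClass("SimTruth",
  representation(betaCausal = "numeric", gamma = "numeric",
                 alpha = "numeric", realizedR2 = "numeric"))
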