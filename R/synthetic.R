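## Synthetic two-sample GWAS summary statistics with known truth.
##
## Summary statistics are drawn directly from their asymptotic sampling
## distributions (no individual-level genotypes): for a standardized
## continuous exposure, gamma-hat_j ~ N(gamma_j, (1-R2)/(n_X 2 f_j (1-f_j)));
## for a binary outcome on the log-OR scale,
## Gamma-hat_j ~ N(beta * gamma_j + alpha_j, 1/(n_Y K (1-K) 2 f_j (1-f_j)))
## (logistic score approximation). Exposure and outcome draws are
## independent, matching the two-sample design.

.NONPALINDROMIC_PAIRS <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                                  "G", "A", "C", "A", "G", "T", "C", "T"),
                                ncol = 2, byrow = TRUE)

#' Configuration of the synthetic two-sample generator
#'
#' Defaults emulate the study conditions of a 10-instrument vitamin C style
#' design: 10 independent SNPs jointly explaining 1.87% of a standardized
#' exposure measured in 52,018 people, and a population-cohort binary
#' outcome of 456,348 people with a rare-disease case fraction (2,120
#' cases). All effects are oriented to the exposure-increasing allele
#' (true gamma_j > 0), the convention under which directional pleiotropy is
#' directional on the ratio scale.
#'
#' @param n_snps number of instruments J.
#' @param maf_range range the effect-allele frequencies are drawn from.
#' @param target_r2 exposure variance explained, met exactly by scaling.
#' @param n_exposure exposure GWAS sample size.
#' @param n_outcome outcome GWAS sample size.
#' @param case_fraction outcome case fraction K (binary outcome).
#' @param beta_causal true causal effect, log-OR per SD exposure.
#' @param pleiotropy list: `mode` (`"none"`, `"balanced"`, `"directional"`),
#'   `mean_alpha` (directional mean direct effect), `sd_alpha`, and
#'   `invalid_fraction` (share of SNPs receiving a nonzero direct effect).
#' @param ld_block list: `size` (variants per LD block including the index;
#'   1 disables proxy generation) and `rho` (pairwise correlation of block
#'   members with the index variant).
#' @param seed default RNG seed used by [simulateTwoSample()].
#' @return A named list.
#' @export
simConfig <- function(n_snps = 10, maf_range = c(0.1, 0.9),
                      target_r2 = 0.0187, n_exposure = 52018,
                      n_outcome = 456348, case_fraction = 2120 / 456348,
                      beta_causal = 0,
                      pleiotropy = list(mode = "none", mean_alpha = 0,
                                        sd_alpha = 0, invalid_fraction = 0),
                      ld_block = list(size = 1, rho = 0.9), seed = 1L) {
  stopifnot(n_snps >= 1, case_fraction > 0, case_fraction < 1,
            target_r2 > 0, target_r2 < 1,
            pleiotropy$invalid_fraction >= 0,
            pleiotropy$invalid_fraction <= 1)
  if (!pleiotropy$mode %in% c("none", "balanced", "directional"))
    stop("pleiotropy mode must be none, balanced or directional")
  list(n_snps = n_snps, maf_range = maf_range, target_r2 = target_r2,
       n_exposure = n_exposure, n_outcome = n_outcome,
       case_fraction = case_fraction, beta_causal = beta_causal,
       pleiotropy = pleiotropy, ld_block = ld_block, seed = as.integer(seed))
}

.draw_alleles <- function(n) {
  idx <- sample.int(nrow(.NONPALINDROMIC_PAIRS), n, replace = TRUE)
  list(ea = .NONPALINDROMIC_PAIRS[idx, 1], oa = .NONPALINDROMIC_PAIRS[idx, 2])
}

#' Simulate a two-sample GWAS summary-statistics pair with known truth
#'
#' Draws effect-allele frequencies, true SNP-exposure effects scaled so the
#' instruments explain exactly `target_r2` of the exposure, per-SNP direct
#' (pleiotropic) outcome effects per the configured mode, and then noisy
#' exposure/outcome estimates from the asymptotic sampling distributions.
#' When `ld_block$size > 1`, each instrument gets `size - 1` companion
#' variants at pairwise correlation `rho`, present in the outcome panel and
#' the LD reference (for proxy-substitution tests).
#'
#' @param config see [simConfig()].
#' @param seed RNG seed (defaults to `config$seed`); the same seed always
#'   reproduces identical panels.
#' @return `list(exposure = StudyPanel, outcome = StudyPanel,
#'   ld = LDReference or NULL, truth = SimTruth)`.
#' @export
simulateTwoSample <- function(config = simConfig(), seed = config$seed) {
  J <- config$n_snps
  .with_seed(seed, {
    f <- stats::runif(J, config$maf_range[1], config$maf_range[2])
    graw <- stats::runif(J, 0.5, 1.5)
    denom <- sum(2 * graw^2 * f * (1 - f))
    g <- graw * sqrt(config$target_r2 / denom)

    sx <- sqrt((1 - config$target_r2) / (config$n_exposure * 2 * f * (1 - f)))
    gh <- stats::rnorm(J, g, sx)

    alpha <- numeric(J)
    pl <- config$pleiotropy
    n_inv <- round(pl$invalid_fraction * J)
    if (pl$mode != "none" && n_inv > 0) {
      which_inv <- sample.int(J, n_inv)
      mu <- if (pl$mode == "directional") pl$mean_alpha else 0
      alpha[which_inv] <- stats::rnorm(n_inv, mu, pl$sd_alpha)
    }
    K <- config$case_fraction
    sy <- sqrt(1 / (config$n_outcome * K * (1 - K) * 2 * f * (1 - f)))
    Gamma <- config$beta_causal * g + alpha
    Gh <- stats::rnorm(J, Gamma, sy)

    al <- .draw_alleles(J)
    ids <- paste0("snp", seq_len(J))
    chrom <- as.character(sample.int(22, J, replace = TRUE))
    pos <- sample.int(1e8, J)

    exp_rec <- data.frame(snp_id = ids, chrom = chrom, pos = pos,
                          effect_allele = al$ea, other_allele = al$oa,
                          eaf = f, beta = gh, se = sx,
                          pvalue = pmax(2 * stats::pnorm(-abs(gh / sx)),
                                        .Machine$double.xmin),
                          n = config$n_exposure, stringsAsFactors = FALSE)
    out_rec <- data.frame(snp_id = ids, chrom = chrom, pos = pos,
                          effect_allele = al$ea, other_allele = al$oa,
                          eaf = f, beta = Gh, se = sy,
                          pvalue = pmax(2 * stats::pnorm(-abs(Gh / sy)),
                                        .Machine$double.xmin),
                          n = config$n_outcome, stringsAsFactors = FALSE)

    ld <- NULL
    if (config$ld_block$size > 1) {
      rho <- config$ld_block$rho
      extra <- list(); pairs <- list()
      for (j in seq_len(J)) {
        members <- paste0(ids[j], "_proxy", seq_len(config$ld_block$size - 1))
        Gp <- stats::rnorm(length(members), rho * Gamma[j], sy[j])
        extra[[j]] <- data.frame(snp_id = members, chrom = chrom[j],
                                 pos = pos[j] + seq_along(members),
                                 effect_allele = al$ea[j],
                                 other_allele = al$oa[j], eaf = f[j],
                                 beta = Gp, se = sy[j],
                                 pvalue = pmax(2 * stats::pnorm(-abs(Gp / sy[j])),
                                               .Machine$double.xmin),
                                 n = config$n_outcome,
                                 stringsAsFactors = FALSE)
        block <- c(ids[j], members)
        cmb <- utils::combn(block, 2)
        pairs[[j]] <- data.frame(snp_a = cmb[1, ], snp_b = cmb[2, ],
                                 r = rho, stringsAsFactors = FALSE)
      }
      out_rec <- rbind(out_rec, do.call(rbind, extra))
      ld <- LDReference(do.call(rbind, pairs), sampleN = 503L)
    }

    exposure <- StudyPanel(exp_rec, traitName = "exposure",
                           traitType = "continuous")
    n_cases <- round(K * config$n_outcome)
    outcome <- StudyPanel(out_rec, traitName = "outcome",
                          traitType = "binary", nCases = n_cases,
                          nControls = config$n_outcome - n_cases)
    truth <- new("SimTruth", betaCausal = config$beta_causal, gamma = g,
                 alpha = alpha, realizedR2 = sum(2 * g^2 * f * (1 - f)))
    list(exposure = exposure, outcome = outcome, ld = ld, truth = truth)
  })
}

## The 11 vitamin C instrument loci (rs identifiers as reported for the
## source exposure GWAS; effect sizes and frequencies here are synthetic,
## scaled so the 11 variants jointly explain exactly 1.87% of the exposure).
.VITC_SNPS <- data.frame(
  snp_id = c("rs33972313", "rs6693447", "rs13028225", "rs10051765",
             "rs7740812", "rs174547", "rs117885456", "rs2559850",
             "rs10136000", "rs56738967", "rs9895661"),
  gene = c("SLC23A1", "RER1", "SLC23A3", "RGS14", "GSTA5", "FADS1",
           "SNRPF", "CHPT1", "AKT1", "MAF", "BCAS3"),
  chrom = c("5", "1", "2", "5", "6", "11", "12", "12", "14", "16", "17"),
  pos = c(138715502L, 2444998L, 220072956L, 176801494L, 52668142L,
          61570783L, 96249111L, 118571065L, 105242966L, 79740541L,
          59286644L),
  eaf = c(0.03, 0.55, 0.86, 0.36, 0.48, 0.67, 0.02, 0.60, 0.26, 0.72,
          0.35),
  beta_raw = c(1.9, 0.7, 1.0, 0.8, 0.7, 0.9, 2.1, 0.8, 0.8, 0.9, 0.8),
  stringsAsFactors = FALSE)

#' Vitamin C style exposure fixture (synthetic effect sizes)
#'
#' An 11-SNP exposure panel using the rs identifiers of the known vitamin C
#' loci (SLC23A1 rs33972313 plus ten further loci), with synthetic per-SNP
#' effects and frequencies scaled so the panel explains exactly 1.87% of a
#' standardized exposure measured in 52,018 people. The FADS1 variant
#' rs174547 is returned as the blacklist entry (excluded a priori for its
#' broad lipid pleiotropy), so instrument selection yields the 10-SNP set.
#'
#' @return `list(panel = StudyPanel, blacklist = "rs174547")`.
#' @examples
#' fx <- makeVitaminCFixture()
#' length(selectInstruments(fx$panel, blacklist = fx$blacklist))  # 10
#' @export
makeVitaminCFixture <- function() {
  d <- .VITC_SNPS
  n <- 52018
  r2_target <- 0.0187
  scale <- sqrt(r2_target / sum(2 * d$beta_raw^2 * d$eaf * (1 - d$eaf)))
  beta <- d$beta_raw * scale
  se <- sqrt((1 - r2_target) / (n * 2 * d$eaf * (1 - d$eaf)))
  p <- 2 * stats::pnorm(-abs(beta / se))
  ## non-palindromic allele pairs, fixed for reproducibility
  ea <- c("T", "A", "C", "C", "A", "T", "G", "A", "C", "G", "C")
  oa <- c("C", "G", "T", "T", "G", "C", "A", "G", "T", "A", "T")
  rec <- data.frame(snp_id = d$snp_id, chrom = d$chrom, pos = d$pos,
                    effect_allele = ea, other_allele = oa, eaf = d$eaf,
                    beta = beta, se = se, pvalue = p, n = n,
                    stringsAsFactors = FALSE)
  panel <- StudyPanel(rec, traitName = "vitamin C",
                      traitType = "continuous",
                      sdUnits = "1 SD ~ 17.6-21.5 umol/L")
  list(panel = panel, blacklist = "rs174547")
}
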