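# Shared builders for the test suite.

# Harmonized set straight from a simulated panel pair (both panels share
# alleles and orientation by construction, so no allele bookkeeping needed;
# alignment itself is exercised in test-harmonize.R).
hset_from_sim <- function(sim) {
  e <- records(sim$exposure)
  o <- records(sim$outcome)
  o <- o[match(e$snp_id, o$snp_id), , drop = FALSE]
  HarmonizedSet(e$beta, e$se, o$beta, o$se, snp_id = e$snp_id,
                eaf_exp = e$eaf, eaf_out = o$eaf)
}

# A well-powered binary-outcome design (large balanced case/control panel)
# used by the simulation studies; small per-rep SEs keep Monte-Carlo bands
# tight.
big_case_control_config <- function(n_snps = 10, beta_causal = 0,
                                    pleiotropy = list(mode = "none",
                                                      mean_alpha = 0,
                                                      sd_alpha = 0,
                                                      invalid_fraction = 0),
                                    maf_range = c(0.1, 0.9), seed = 1L) {
  simConfig(n_snps = n_snps, maf_range = maf_range,
            n_outcome = 247173, case_fraction = 133384 / 247173,
            beta_causal = beta_causal, pleiotropy = pleiotropy, seed = seed)
}

# Independent oracles shared by the unit and acceptance tests.

# Weighted median by brute-force scan over the empirical weighted CDF
# (mid-point cumulative weights, manual bracketing -- no approx()).
wm_oracle <- function(b, w) {
  o <- order(b)
  b <- b[o]
  w <- w[o] / sum(w)
  cw <- cumsum(w) - w / 2
  if (0.5 <= cw[1]) return(b[1])
  if (0.5 >= cw[length(b)]) return(b[length(b)])
  i <- max(which(cw < 0.5))
  b[i] + (0.5 - cw[i]) / (cw[i + 1] - cw[i]) * (b[i + 1] - b[i])
}

# Weighted Gaussian KDE evaluated point by point (independent of the
# package's vectorized grid code).
kde_oracle <- function(x, b, w, h) {
  wn <- w / sum(w)
  vapply(x, function(xi) sum(wn * dnorm((b - xi) / h)) / h, numeric(1))
}

# Minimal well-formed per-variant records.
demo_records <- function(n = 3) {
  data.frame(snp_id = paste0("rs", seq_len(n)),
             chrom = as.character(rep_len(1:22, n)),
             pos = seq_len(n) * 1000L,
             effect_allele = rep_len(c("A", "C", "T", "G"), n),
             other_allele = rep_len(c("G", "T", "A", "C"), n),
             eaf = seq(0.1, 0.6, length.out = n),
             beta = seq(0.05, 0.1, length.out = n),
             se = rep(0.005, n),
             pvalue = rep(1e-20, n),
             n = rep(52018, n),
             stringsAsFactors = FALSE)
}

# Write records as a canonical TSV and return the path.
write_canonical_tsv <- function(rec, path = tempfile(fileext = ".tsv"),
                                sep = "\t") {
  out <- data.frame(SNP = rec$snp_id, CHR = rec$chrom, POS = rec$pos,
                    EA = rec$effect_allele, OA = rec$other_allele,
                    EAF = rec$eaf, BETA = rec$beta, SE = rec$se,
                    P = rec$pvalue, N = rec$n, stringsAsFactors = FALSE)
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}
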