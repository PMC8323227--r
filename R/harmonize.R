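## Instrument selection, LD-proxy substitution and allele alignment.

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Construct an LDReference from a pairwise correlation table
#'
#' @param entries data.frame with columns `snp_a`, `snp_b`, `r` (signed LD
#'   correlation between the recorded effect alleles of the two variants).
#'   Entries are symmetrized on construction.
#' @param sampleN reference-panel sample size (e.g. 503 for the European
#'   1000 Genomes phase 3 reference).
#' @return An [LDReference-class].
#' @export
LDReference <- function(entries, sampleN = NA_integer_) {
  entries <- data.frame(snp_a = as.character(entries$snp_a),
                        snp_b = as.character(entries$snp_b),
                        r = as.numeric(entries$r), stringsAsFactors = FALSE)
  mirror <- data.frame(snp_a = entries$snp_b, snp_b = entries$snp_a,
                       r = entries$r, stringsAsFactors = FALSE)
  both <- rbind(entries, mirror)
  both <- both[!duplicated(both[, c("snp_a", "snp_b")]), , drop = FALSE]
  rownames(both) <- NULL
  new("LDReference", entries = both, sampleN = as.integer(sampleN))
}

#' Read an LD reference table
#'
#' Expects a delimited table with columns `SNP_A`, `SNP_B`, `R`.
#'
#' @param path file path.
#' @param sep field separator.
#' @param sampleN reference-panel size annotation.
#' @return An [LDReference-class].
#' @export
readLDReference <- function(path, sep = "\t", sampleN = NA_integer_) {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("SNP_A", "SNP_B", "R")
  if (!all(need %in% names(raw)))
    stop("LD reference must have columns SNP_A, SNP_B, R")
  LDReference(data.frame(snp_a = raw$SNP_A, snp_b = raw$SNP_B, r = raw$R,
                         stringsAsFactors = FALSE), sampleN = sampleN)
}

#' Select genome-wide-significant instruments from an exposure panel
#'
#' Returns, in panel order, the snp_ids with `pvalue` strictly below
#' `p_threshold` (the genome-wide threshold 5e-8 by default; a variant at
#' exactly the threshold is excluded) and not on the blacklist. The blacklist
#' carries variants excluded a priori for known pleiotropy (e.g. a
#' lipid-associated locus).
#'
#' @param panel exposure [StudyPanel-class].
#' @param p_threshold significance threshold, strict `<`.
#' @param blacklist character vector of snp_ids to exclude.
#' @return Character vector of instrument snp_ids.
#' @export
selectInstruments <- function(panel, p_threshold = 5e-8,
                              blacklist = character()) {
  stopifnot(is(panel, "StudyPanel"),
            p_threshold > 0, p_threshold < 1)
  df <- panel@records
  keep <- df$pvalue < p_threshold & !(df$snp_id %in% blacklist)
  ids <- df$snp_id[keep]
  if (!length(ids))
    stop("no instruments survive p < ", format(p_threshold),
         " and the blacklist")
  ids
}

#' Find an LD proxy for an instrument absent from the outcome panel
#'
#' Among variants present in `candidates` (the outcome panel), returns the
#' one with maximal squared LD correlation with `target`, provided
#' `r^2 > r2_min` strictly; ties in r^2 are broken lexicographically by
#' snp_id. The signed r is returned so the proxy can be phased to the
#' original variant: the proxy's effect direction is multiplied by `sign(r)`
#' downstream. A target unknown to the LD reference, or with no qualifying
#' candidate, yields `NULL` (the instrument is then discarded).
#'
#' @param target snp_id missing from the outcome panel.
#' @param candidates outcome [StudyPanel-class].
#' @param ld an [LDReference-class].
#' @param r2_min minimum squared correlation, strict `>` (default 0.8).
#' @return `list(snp_id =, r =)` or `NULL`.
#' @export
findProxy <- function(target, candidates, ld, r2_min = 0.8) {
  stopifnot(is(candidates, "StudyPanel"), is(ld, "LDReference"),
            r2_min > 0, r2_min < 1)
  ent <- ld@entries
  hits <- ent[ent$snp_a == target & ent$snp_b != target, , drop = FALSE]
  if (!nrow(hits)) return(NULL)  # unknown variant => no proxy
  hits <- hits[hits$snp_b %in% candidates@records$snp_id, , drop = FALSE]
  if (!nrow(hits)) return(NULL)
  r2 <- hits$r^2
  ok <- r2 > r2_min
  if (!any(ok)) return(NULL)
  hits <- hits[ok, , drop = FALSE]
  r2 <- r2[ok]
  best <- which(r2 == max(r2))
  if (length(best) > 1) best <- best[order(hits$snp_b[best])][1]
  list(snp_id = hits$snp_b[best], r = hits$r[best])
}

.is_palindromic <- function(ea, oa) .COMPLEMENT[[ea]] == oa

.as_rec <- function(rec) as.list(rec)

#' Align one outcome record to an exposure record's effect allele
#'
#' Resolves the four allele orientations of a two-sample variant pair:
#' same orientation (kept), swapped alleles (outcome beta negated, eaf
#' complemented), and both again after strand complementation. Palindromic
#' variants (A/T or C/G) are un-resolvable by alleles alone: when either
#' panel's allele frequency lies within `palindromic_eaf_window` of 0.5 the
#' variant is dropped; otherwise it is oriented by frequency (frequencies on
#' the same side of 0.5 imply the same allele).
#'
#' @param exp_rec,out_rec one-row data.frames (or named lists) with fields
#'   `snp_id, effect_allele, other_allele, eaf, beta, se`; `out_rec` may be
#'   a proxy record already phased to the target.
#' @param palindromic_eaf_window half-width of the ambiguity window around
#'   eaf 0.5 (default 0.08, i.e. drop when eaf is in `[0.42, 0.58]`).
#' @param proxy_of snp_id of the original instrument when `out_rec` is a
#'   proxy, `NA` otherwise.
#' @return A one-row data.frame in the [HarmonizedSet-class] instrument
#'   schema; `action` is `kept`, `flipped`, `proxied`, or
#'   `dropped_palindromic`.
#' @export
alignAlleles <- function(exp_rec, out_rec, palindromic_eaf_window = 0.08,
                         proxy_of = NA_character_) {
  e <- .as_rec(exp_rec); o <- .as_rec(out_rec)
  ea_e <- e$effect_allele; oa_e <- e$other_allele
  ea_o <- o$effect_allele; oa_o <- o$other_allele
  pal <- .is_palindromic(ea_e, oa_e)

  out <- function(action, beta_out, eaf_out) {
    data.frame(snp_id = e$snp_id, proxy_of = proxy_of,
               beta_exp = e$beta, se_exp = e$se,
               beta_out = beta_out, se_out = o$se,
               eaf_exp = e$eaf, eaf_out = eaf_out,
               palindromic = pal, action = action,
               stringsAsFactors = FALSE)
  }

  if (pal) {
    w <- palindromic_eaf_window
    ambiguous <- abs(e$eaf - 0.5) <= w || abs(o$eaf - 0.5) <= w
    if (ambiguous) return(out("dropped_palindromic", o$beta, o$eaf))
    if (!((ea_o == ea_e && oa_o == oa_e) || (ea_o == oa_e && oa_o == ea_e)))
      stop("irreconcilable alleles for ", e$snp_id)
    same_side <- (e$eaf - 0.5) * (o$eaf - 0.5) > 0
    if (same_side) return(out("kept", o$beta, o$eaf))
    return(out("flipped", -o$beta, 1 - o$eaf))
  }

  if (ea_o == ea_e && oa_o == oa_e)
    return(out("kept", o$beta, o$eaf))
  if (ea_o == oa_e && oa_o == ea_e)
    return(out("flipped", -o$beta, 1 - o$eaf))
  cea <- .COMPLEMENT[[ea_o]]; coa <- .COMPLEMENT[[oa_o]]
  if (cea == ea_e && coa == oa_e)
    return(out("kept", o$beta, o$eaf))
  if (cea == oa_e && coa == ea_e)
    return(out("flipped", -o$beta, 1 - o$eaf))
  stop("irreconcilable alleles for ", e$snp_id, ": exposure ", ea_e, "/",
       oa_e, " vs outcome ", ea_o, "/", oa_o)
}

#' Harmonize an exposure and an outcome panel into an analysis-ready set
#'
#' Full harmonization pass: select instruments from the exposure panel
#' (`p < p_threshold`, blacklist applied), substitute an LD proxy (maximal
#' `r^2 > r2_min`, phased via the sign of r) for instruments absent from the
#' outcome panel, align effect alleles, and drop unresolvable palindromic
#' variants. Every dropped variant is recorded in the audit slot with its
#' reason.
#'
#' @param exposure,outcome [StudyPanel-class] objects.
#' @param ld optional [LDReference-class] for proxy lookup; without it,
#'   absent instruments are dropped.
#' @param p_threshold instrument significance threshold (strict `<`).
#' @param blacklist snp_ids excluded a priori.
#' @param r2_min proxy LD threshold (strict `>`).
#' @param palindromic_eaf_window see [alignAlleles()].
#' @return A [HarmonizedSet-class].
#' @export
harmonizePanels <- function(exposure, outcome, ld = NULL,
                            p_threshold = 5e-8, blacklist = character(),
                            r2_min = 0.8, palindromic_eaf_window = 0.08) {
  stopifnot(is(exposure, "StudyPanel"), is(outcome, "StudyPanel"))
  ids <- selectInstruments(exposure, p_threshold, blacklist)
  erec <- exposure@records
  orec <- outcome@records
  rows <- list(); audit <- list()
  for (id in ids) {
    e <- erec[erec$snp_id == id, , drop = FALSE]
    if (id %in% orec$snp_id) {
      o <- orec[orec$snp_id == id, , drop = FALSE]
      h <- alignAlleles(e, o, palindromic_eaf_window)
    } else {
      px <- if (is.null(ld)) NULL else findProxy(id, outcome, ld, r2_min)
      if (is.null(px)) {
        audit[[length(audit) + 1L]] <-
          data.frame(snp_id = id, action = "dropped_no_proxy",
                     reason = "absent from outcome panel and no proxy with sufficient LD",
                     stringsAsFactors = FALSE)
        next
      }
      o <- orec[orec$snp_id == px$snp_id, , drop = FALSE]
      ## phase the proxy to the original via the sign of r
      o$beta <- o$beta * sign(px$r)
      if (px$r < 0) o$eaf <- 1 - o$eaf
      h <- data.frame(snp_id = id, proxy_of = px$snp_id,
                      beta_exp = e$beta, se_exp = e$se,
                      beta_out = o$beta, se_out = o$se,
                      eaf_exp = e$eaf, eaf_out = o$eaf,
                      palindromic = .is_palindromic(e$effect_allele,
                                                    e$other_allele),
                      action = "proxied", stringsAsFactors = FALSE)
    }
    if (h$action == "dropped_palindromic") {
      audit[[length(audit) + 1L]] <-
        data.frame(snp_id = id, action = "dropped_palindromic",
                   reason = "palindromic with allele frequency near 0.5",
                   stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- h
    }
  }
  inst <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(.empty_harm(), .HARM_COLS)
  aud <- if (length(audit)) do.call(rbind, audit) else
    data.frame(snp_id = character(), action = character(),
               reason = character(), stringsAsFactors = FALSE)
  rownames(inst) <- NULL; rownames(aud) <- NULL
  new("HarmonizedSet", exposureName = exposure@traitName,
      outcomeName = outcome@traitName, instruments = inst, audit = aud)
}

.empty_harm <- function() {
  data.frame(snp_id = character(), proxy_of = character(),
             beta_exp = numeric(), se_exp = numeric(),
             beta_out = numeric(), se_out = numeric(),
             eaf_exp = numeric(), eaf_out = numeric(),
             palindromic = logical(), action = character(),
             stringsAsFactors = FALSE)
}

#' Build a HarmonizedSet directly from effect vectors
#'
#' Convenience constructor for simulation studies and tests where the
#' allele bookkeeping has already been done.
#'
#' @param beta_exp,se_exp SNP-exposure effects and SEs.
#' @param beta_out,se_out SNP-outcome effects and SEs.
#' @param snp_id instrument labels (default `snp1, snp2, ...`).
#' @param exposureName,outcomeName trait labels.
#' @param eaf_exp,eaf_out allele frequencies (optional).
#' @return A [HarmonizedSet-class] with all actions `kept`.
#' @export
HarmonizedSet <- function(beta_exp, se_exp, beta_out, se_out,
                          snp_id = paste0("snp", seq_along(beta_exp)),
                          exposureName = "exposure",
                          outcomeName = "outcome",
                          eaf_exp = rep(NA_real_, length(beta_exp)),
                          eaf_out = eaf_exp) {
  inst <- data.frame(snp_id = snp_id, proxy_of = NA_character_,
                     beta_exp = beta_exp, se_exp = se_exp,
                     beta_out = beta_out, se_out = se_out,
                     eaf_exp = eaf_exp, eaf_out = eaf_out,
                     palindromic = FALSE, action = "kept",
                     stringsAsFactors = FALSE)
  new("HarmonizedSet", exposureName = exposureName,
      outcomeName = outcomeName, instruments = inst,
      audit = data.frame(snp_id = character(), action = character(),
                         reason = character(), stringsAsFactors = FALSE))
}

#' Instrument variance explained on a standardized exposure
#'
#' For an exposure standardized to unit variance, the variance explained by
#' independent variants is `sum(2 * beta^2 * eaf * (1 - eaf))`.
#'
#' @param beta per-allele effects in SD units.
#' @param eaf effect-allele frequencies, strictly inside (0,1).
#' @return The variance explained (0 for an empty input).
#' @examples
#' varianceExplained(0.1, 0.5)  # 0.005
#' @export
varianceExplained <- function(beta, eaf) {
  if (length(beta) == 0) return(0)
  stopifnot(length(beta) == length(eaf))
  if (any(!is.finite(eaf) | eaf <= 0 | eaf >= 1))
    stop("eaf must lie strictly inside (0, 1)")
  sum(2 * beta^2 * eaf * (1 - eaf))
}

#' Greedy LD pruning of an instrument list
#'
#' Keeps instruments in input order, dropping any later variant whose squared
#' LD correlation with an already-kept variant exceeds `r2_max`. The source
#' GWAS instruments are assumed pre-pruned; this pass exists for synthetic
#' panels that include LD-block members.
#'
#' @param snp_ids candidate instruments, in priority order.
#' @param ld an [LDReference-class].
#' @param r2_max maximum tolerated squared correlation (default 0.01).
#' @return The pruned character vector, in input order.
#' @export
pruneInstruments <- function(snp_ids, ld, r2_max = 0.01) {
  stopifnot(is(ld, "LDReference"))
  ent <- ld@entries
  kept <- character()
  for (id in snp_ids) {
    hits <- ent[ent$snp_a == id & ent$snp_b %in% kept, , drop = FALSE]
    if (!nrow(hits) || max(hits$r^2) <= r2_max) kept <- c(kept, id)
  }
  kept
}
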