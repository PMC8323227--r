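## Summary-statistics I/O: the single place file dialects are handled.
## Canonical on-disk format: TSV with header
##   SNP CHR POS EA OA EAF BETA SE P N [N_CASES N_CONTROLS]
## Positions are 1-based; alleles are uppercased on read; indels rejected
## (the analyses use SNPs only).

.CANON_HEADER <- c(snp_id = "SNP", chrom = "CHR", pos = "POS",
                   effect_allele = "EA", other_allele = "OA", eaf = "EAF",
                   beta = "BETA", se = "SE", pvalue = "P", n = "N",
                   n_cases = "N_CASES", n_controls = "N_CONTROLS")
.OPTIONAL_COLS <- c("n_cases", "n_controls")

#' Construct a StudyPanel from a per-variant data.frame
#'
#' @param records data.frame with the canonical columns (`n_cases` and
#'   `n_controls` may be omitted; they default to `NA`).
#' @param traitName trait label.
#' @param traitType `"continuous"` (betas in SD units) or `"binary"`
#'   (betas on the log-OR scale).
#' @param sdUnits optional annotation of the SD scale.
#' @param nCases,nControls panel-level case/control counts for binary traits.
#' @return A validated [StudyPanel-class].
#' @examples
#' rec <- data.frame(snp_id = "rs1", chrom = "1", pos = 100L,
#'                   effect_allele = "A", other_allele = "G", eaf = 0.3,
#'                   beta = 0.1, se = 0.01, pvalue = 1e-20, n = 50000)
#' StudyPanel(rec, traitName = "vitamin C", traitType = "continuous")
#' @export
StudyPanel <- function(records, traitName = "trait",
                       traitType = c("continuous", "binary"),
                       sdUnits = NA_character_, nCases = NA_real_,
                       nControls = NA_real_) {
  traitType <- match.arg(traitType)
  for (col in .OPTIONAL_COLS)
    if (is.null(records[[col]])) records[[col]] <- rep(NA_real_, nrow(records))
  records <- records[, .PANEL_COLS, drop = FALSE]
  records$snp_id <- as.character(records$snp_id)
  records$chrom <- as.character(records$chrom)
  records$pos <- as.integer(records$pos)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("eaf", "beta", "se", "pvalue", "n", .OPTIONAL_COLS))
    records[[col]] <- as.numeric(records[[col]])
  rownames(records) <- NULL
  new("StudyPanel", traitName = traitName, traitType = traitType,
      sdUnits = sdUnits, nCases = nCases, nControls = nControls,
      records = records)
}

#' Read GWAS summary statistics into a StudyPanel
#'
#' Reads a delimited text table of per-variant association statistics,
#' validates every row, and returns a [StudyPanel-class]. Rows that violate
#' the record invariants (non-ACGT or identical alleles, `se <= 0`,
#' frequencies outside `[0,1]`, unparsable numerics, ...) are rejected, not
#' silently kept: each rejection is reported on standard error with its file
#' line number, and the full rejection table is attached as attribute
#' `"rejections"` on the returned panel's records.
#'
#' Structural problems are errors: a mapped column missing from the file, or
#' duplicated `snp_id` among accepted rows.
#'
#' @param path file path.
#' @param column_map named character vector mapping canonical names
#'   (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pvalue`, `n`, `n_cases`, `n_controls`) to the file's
#'   column names. Defaults to the canonical header
#'   `SNP CHR POS EA OA EAF BETA SE P N N_CASES N_CONTROLS`.
#' @param sep field separator; tab by default, set `","` for CSV. The dialect
#'   is always explicit, never guessed.
#' @inheritParams StudyPanel
#' @return A validated [StudyPanel-class]; row order of accepted rows is the
#'   file order.
#' @export
readSummaryStats <- function(path, column_map = .CANON_HEADER, sep = "\t",
                             traitName = "trait",
                             traitType = c("continuous", "binary"),
                             sdUnits = NA_character_, nCases = NA_real_,
                             nControls = NA_real_) {
  traitType <- match.arg(traitType)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE)
  full_map <- .CANON_HEADER
  full_map[names(column_map)] <- column_map
  required <- setdiff(names(full_map), .OPTIONAL_COLS)
  missing_cols <- required[!(full_map[required] %in% names(raw))]
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste0(full_map[missing_cols], " (", missing_cols, ")",
                collapse = ", "))

  df <- .empty_records()[rep(1, nrow(raw)), , drop = FALSE]
  df <- data.frame(snp_id = raw[[full_map["snp_id"]]],
                   chrom = raw[[full_map["chrom"]]],
                   stringsAsFactors = FALSE)
  df$pos <- suppressWarnings(as.integer(raw[[full_map["pos"]]]))
  df$effect_allele <- toupper(raw[[full_map["effect_allele"]]])
  df$other_allele <- toupper(raw[[full_map["other_allele"]]])
  for (col in c("eaf", "beta", "se", "pvalue", "n"))
    df[[col]] <- suppressWarnings(as.numeric(raw[[full_map[col]]]))
  for (col in .OPTIONAL_COLS)
    df[[col]] <- if (full_map[col] %in% names(raw))
      suppressWarnings(as.numeric(raw[[full_map[col]]])) else NA_real_

  problems <- .validate_records(df)
  numeric_na <- !is.finite(df$pos)
  problems <- ifelse(numeric_na & !nzchar(problems),
                     "unparsable numeric field", problems)
  rejected <- nzchar(problems)
  line <- seq_len(nrow(df)) + 1L  # +1 for the header line
  if (any(rejected)) {
    for (i in which(rejected))
      message("rejected line ", line[i], " (", df$snp_id[i], "): ",
              problems[i])
  }
  kept <- df[!rejected, , drop = FALSE]
  dups <- unique(kept$snp_id[duplicated(kept$snp_id)])
  if (length(dups))
    stop("duplicate snp_id in ", path, ": ", paste(dups, collapse = ", "))
  panel <- StudyPanel(kept, traitName = traitName, traitType = traitType,
                      sdUnits = sdUnits, nCases = nCases,
                      nControls = nControls)
  attr(panel@records, "rejections") <-
    data.frame(line = line[rejected], snp_id = df$snp_id[rejected],
               reason = problems[rejected], stringsAsFactors = FALSE)
  panel
}

#' Write a StudyPanel to the canonical TSV format
#'
#' Writes the canonical header
#' `SNP CHR POS EA OA EAF BETA SE P N N_CASES N_CONTROLS`; numeric fields are
#' printed with 17 significant digits so that `readSummaryStats()` of the
#' written file reproduces every field exactly (round-trip identity).
#'
#' @param panel a [StudyPanel-class].
#' @param path destination file path.
#' @param sep field separator (tab by default).
#' @return `path`, invisibly.
#' @export
writeSummaryStats <- function(panel, path, sep = "\t") {
  stopifnot(is(panel, "StudyPanel"))
  df <- panel@records
  out <- data.frame(SNP = df$snp_id, CHR = df$chrom, POS = df$pos,
                    EA = df$effect_allele, OA = df$other_allele,
                    stringsAsFactors = FALSE)
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  out$EAF <- fmt(df$eaf); out$BETA <- fmt(df$beta); out$SE <- fmt(df$se)
  out$P <- fmt(df$pvalue); out$N <- fmt(df$n)
  out$N_CASES <- fmt(df$n_cases); out$N_CONTROLS <- fmt(df$n_controls)
  ok <- tryCatch({
    utils::write.table(out, path, sep = sep, quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}
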