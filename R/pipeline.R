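## Orchestration of the bi-directional design: forward runs (exposure ->
## each outcome), reverse runs (each outcome's instruments -> the exposure),
## per-outcome variant exclusions, multivariable adjustment, and report
## files. Forward and reverse share one code path; direction only decides
## which panel supplies the instruments.

.as_panel <- function(x, ...) {
  if (is(x, "StudyPanel")) x else readSummaryStats(x, ...)
}

.as_ld <- function(x) {
  if (is.null(x) || is(x, "LDReference")) x else readLDReference(x)
}

.as_blacklist <- function(x) {
  if (is.null(x)) character()
  else if (length(x) == 1 && is.character(x) && file.exists(x))
    readLines(x, warn = FALSE)
  else as.character(x)
}

#' Assemble a bi-directional MR analysis configuration
#'
#' @param exposure exposure panel: a [StudyPanel-class] or a file path.
#' @param outcomes named list of outcome panels (objects or paths).
#' @param direction `"forward"` (exposure -> each outcome), `"reverse"`
#'   (each outcome's instruments -> the exposure), or `"both"`.
#' @param p_threshold instrument p-value threshold (strict `<`).
#' @param r2_min LD-proxy threshold (strict `>`).
#' @param blacklist snp_ids (or a newline-delimited file) excluded from the
#'   forward instrument set a priori.
#' @param snp_exclusions named list (by outcome) of snp_ids to drop from
#'   that pair's instruments (e.g. a nicotine-pathway variant dropped from a
#'   lung-cancer instrument set in a sensitivity re-run).
#' @param ld optional [LDReference-class] or path, for proxy substitution.
#' @param covariate optional second exposure panel (object or path) for
#'   multivariable adjustment of forward runs.
#' @param seed seed used by every stochastic estimator.
#' @param suite estimator settings, see [suiteConfig()] (`seed` is set from
#'   `seed`).
#' @param out_dir optional output directory for `results.tsv`, `audit.tsv`
#'   and `run.json`.
#' @return A named list (the configuration).
#' @export
mrAnalysisConfig <- function(exposure, outcomes,
                             direction = c("forward", "reverse", "both"),
                             p_threshold = 5e-8, r2_min = 0.8,
                             blacklist = character(),
                             snp_exclusions = list(), ld = NULL,
                             covariate = NULL, seed = 1L,
                             suite = suiteConfig(seed = seed),
                             out_dir = NULL) {
  direction <- match.arg(direction)
  if (is.null(names(outcomes)) || any(!nzchar(names(outcomes))))
    stop("outcomes must be a named list")
  suite$seed <- as.integer(seed)
  list(exposure = exposure, outcomes = outcomes, direction = direction,
       p_threshold = p_threshold, r2_min = r2_min, blacklist = blacklist,
       snp_exclusions = snp_exclusions, ld = ld, covariate = covariate,
       seed = as.integer(seed), suite = suite, out_dir = out_dir)
}

#' Read an analysis configuration from a YAML file
#'
#' Keys mirror the arguments of [mrAnalysisConfig()]; panel values are file
#' paths resolved relative to the YAML file's directory.
#'
#' @param path YAML file path.
#' @return A configuration list.
#' @export
readAnalysisConfig <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p)) NULL else file.path(base, p)
  mrAnalysisConfig(
    exposure = rel(y$exposure),
    outcomes = lapply(y$outcomes, rel),
    direction = if (is.null(y$direction)) "forward" else y$direction,
    p_threshold = if (is.null(y$p_threshold)) 5e-8 else y$p_threshold,
    r2_min = if (is.null(y$r2_min)) 0.8 else y$r2_min,
    blacklist = if (is.null(y$blacklist)) character() else rel(y$blacklist),
    snp_exclusions = if (is.null(y$snp_exclusions)) list()
                     else y$snp_exclusions,
    ld = rel(y$ld), covariate = rel(y$covariate),
    seed = if (is.null(y$seed)) 1L else y$seed,
    out_dir = y$out_dir)
}

.run_pair <- function(exp_panel, out_panel, cfg, exclusions, label,
                      direction) {
  hset <- harmonizePanels(exp_panel, out_panel, ld = .as_ld(cfg$ld),
                          p_threshold = cfg$p_threshold,
                          blacklist = c(.as_blacklist(cfg$blacklist),
                                        exclusions),
                          r2_min = cfg$r2_min)
  suite <- runEstimatorSuite(hset, config = cfg$suite)
  tab <- suite$table
  tab <- cbind(data.frame(pair = label, direction = direction,
                          exposure = exp_panel@traitName,
                          outcome = out_panel@traitName,
                          stringsAsFactors = FALSE), tab)
  aud <- auditLog(hset)
  if (nrow(aud))
    aud <- cbind(data.frame(pair = label, stringsAsFactors = FALSE), aud)
  else
    aud <- data.frame(pair = character(), snp_id = character(),
                      action = character(), reason = character(),
                      stringsAsFactors = FALSE)
  list(table = tab, audit = aud, hset = hset, suite = suite)
}

#' Run the configured bi-directional analysis
#'
#' For every exposure-outcome pair of the configured direction(s):
#' select instruments, substitute proxies, harmonize alleles, and run the
#' estimator battery. Failures are isolated per pair (recorded, the run
#' continues). Forward runs estimate the log-OR of each outcome per 1-SD
#' exposure increase; reverse runs estimate the SD change of the exposure
#' per 1-unit change in the log relative risk of the (binary) trait
#' supplying the instruments. When `out_dir` is set, writes `results.tsv`
#' (combined long table), `audit.tsv` (all dropped/proxied variants) and
#' `run.json` (configuration echo incl. seed and package version).
#'
#' @param config a configuration from [mrAnalysisConfig()] or
#'   [readAnalysisConfig()].
#' @return (invisibly) `list(results, audit, pairs, failures, mv)`:
#'   `results` and `audit` are long-format data.frames over all pairs,
#'   `pairs` holds each pair's harmonized set and suite, `failures` is a
#'   named character vector of per-pair error messages (empty on a clean
#'   run), `mv` the multivariable estimates when a covariate was supplied.
#' @export
runDirection <- function(config) {
  exp_panel <- .as_panel(config$exposure)
  out_panels <- lapply(config$outcomes, .as_panel)
  dirs <- switch(config$direction, forward = "forward",
                 reverse = "reverse", both = c("forward", "reverse"))
  results <- list(); audits <- list(); pairs <- list()
  failures <- character()

  for (dir in dirs) {
    for (nm in names(out_panels)) {
      excl <- config$snp_exclusions[[nm]]
      if (is.null(excl)) excl <- character()
      label <- paste0(dir, ":", nm)
      res <- tryCatch({
        if (dir == "forward")
          .run_pair(exp_panel, out_panels[[nm]], config, character(),
                    label, dir)
        else
          .run_pair(out_panels[[nm]], exp_panel, config, excl, label, dir)
      }, error = function(e) conditionMessage(e))
      if (is.character(res)) {
        failures[label] <- res
        message("pair ", label, " failed: ", res)
        next
      }
      results[[label]] <- res$table
      audits[[label]] <- res$audit
      pairs[[label]] <- list(hset = res$hset, suite = res$suite)
    }
  }

  mv <- NULL
  if (!is.null(config$covariate) && "forward" %in% dirs) {
    cov_panel <- .as_panel(config$covariate)
    mv <- lapply(names(out_panels), function(nm) {
      tryCatch(.run_multivariable(exp_panel, cov_panel, out_panels[[nm]],
                                  config),
               error = function(e) conditionMessage(e))
    })
    names(mv) <- names(out_panels)
  }

  results <- if (length(results)) do.call(rbind, c(results,
                                                   make.row.names = FALSE))
             else data.frame()
  audit <- if (length(audits)) do.call(rbind, c(audits,
                                                make.row.names = FALSE))
           else data.frame()

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(results, file.path(config$out_dir, "results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(audit, file.path(config$out_dir, "audit.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    meta <- list(seed = config$seed, direction = config$direction,
                 p_threshold = config$p_threshold, r2_min = config$r2_min,
                 outcomes = names(out_panels),
                 package_version = as.character(
                   utils::packageVersion("bimr")),
                 failures = as.list(failures))
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE),
               file.path(config$out_dir, "run.json"))
  }
  if (length(failures))
    warning(length(failures), " pair(s) failed; see $failures")
  invisible(list(results = results, audit = audit, pairs = pairs,
                 failures = failures, mv = mv))
}

## Multivariable IVW for one outcome: instruments = union of both exposures'
## genome-wide-significant variants that all three panels report.
.run_multivariable <- function(exp_panel, cov_panel, out_panel, cfg) {
  bl <- .as_blacklist(cfg$blacklist)
  ids <- union(selectInstruments(exp_panel, cfg$p_threshold, bl),
               selectInstruments(cov_panel, cfg$p_threshold, bl))
  e <- exp_panel@records; cv <- cov_panel@records; o <- out_panel@records
  ids <- ids[ids %in% e$snp_id & ids %in% cv$snp_id & ids %in% o$snp_id]
  if (length(ids) < 3)
    stop("multivariable run needs >= 3 shared instruments")
  ei <- e[match(ids, e$snp_id), ]; ci <- cv[match(ids, cv$snp_id), ]
  oi <- o[match(ids, o$snp_id), ]
  ## align covariate and outcome records to the exposure's effect allele
  a_cov <- do.call(rbind, lapply(seq_along(ids), function(i)
    alignAlleles(ei[i, ], ci[i, ], palindromic_eaf_window = 0)))
  a_out <- do.call(rbind, lapply(seq_along(ids), function(i)
    alignAlleles(ei[i, ], oi[i, ], palindromic_eaf_window = 0)))
  X <- cbind(ei$beta, a_cov$beta_out)
  colnames(X) <- c(exp_panel@traitName, cov_panel@traitName)
  multivariableIVW(X, a_out$beta_out, a_out$se_out)
}

#' Star-coding of p-values
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, empty
#' otherwise.
#'
#' @param p numeric vector of p-values.
#' @return Character vector of the same length.
#' @export
starCode <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out[is.na(p)] <- ""
  out
}

#' Reporting flags for an estimator-suite result
#'
#' Machine-readable highlighting rules: `prefer_outlier_corrected` when the
#' MR-PRESSO global test indicates horizontal pleiotropy
#' (p < `presso_alpha`, default 0.01) so the outlier-corrected and robust
#' estimates deserve emphasis, and `prefer_weighted_median` when Cochran's Q
#' indicates significant heterogeneity (p < `q_alpha`, default 0.05).
#' P-values get the conventional star coding.
#'
#' @param suite a result of [runEstimatorSuite()].
#' @param presso_alpha,q_alpha the two thresholds.
#' @return `list(flags = character(), table = data.frame)` where `table` is
#'   the suite table with a `stars` column appended.
#' @export
highlightRules <- function(suite, presso_alpha = 0.01, q_alpha = 0.05) {
  tab <- suite$table
  flags <- character()
  gp <- tab$presso_global_p[tab$method == "presso"]
  if (length(gp) && !is.na(gp) && gp < presso_alpha)
    flags <- c(flags, "prefer_outlier_corrected")
  qp <- tab$q_p[tab$method == "ivw_re"]
  if (length(qp) && !is.na(qp) && qp < q_alpha)
    flags <- c(flags, "prefer_weighted_median")
  tab$stars <- starCode(tab$p)
  list(flags = flags, table = tab)
}
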