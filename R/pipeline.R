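#' @include AllClasses.R
NULL

#' Pipeline analysis settings
#'
#' Thresholds and mode switches for the discovery pipeline. The principal
#' analysis uses all cis-pQTLs passing the source threshold without
#' clumping; LD clumping and sentinel-only modes are sensitivity switches.
#'
#' @param fdrQ FDR significance level per protein dataset.
#' @param smrP SMR significance level (raw; the Bonferroni-adjusted flag is
#'   also emitted).
#' @param heidiP HEIDI linkage-call threshold.
#' @param pph4Call PPH4 level for a "colocalized" call.
#' @param pph4Pass PPH4 level above which colocalization counts as passed
#'   for tiering (moderate colocalization counts).
#' @param clump logical; LD-clump instruments.
#' @param clumpR2,clumpKb clumping parameters.
#' @param sentinelOnly logical; keep only the lowest-p instrument.
#' @param steiger logical; apply the Steiger directionality filter.
#' @param palindromeWindow ambiguous-EAF half-width for harmonization.
#' @param secondOrderWald logical; second-order delta SE for Wald ratios.
#' @param smrCfg,colocCfg component settings.
#' @return list of settings.
#' @export
pipelineSettings <- function(fdrQ = 0.05, smrP = 0.05, heidiP = 0.01,
                             pph4Call = 0.8, pph4Pass = 0.5,
                             clump = FALSE, clumpR2 = 0.01, clumpKb = 10000,
                             sentinelOnly = FALSE, steiger = TRUE,
                             palindromeWindow = 0.08,
                             secondOrderWald = FALSE,
                             smrCfg = smrConfig(), colocCfg = colocConfig()) {
  stopifnot(fdrQ > 0, fdrQ < 1, heidiP > 0, heidiP < 1)
  smrCfg$heidiP <- heidiP
  list(fdrQ = fdrQ, smrP = smrP, heidiP = heidiP, pph4Call = pph4Call,
       pph4Pass = pph4Pass, clump = clump, clumpR2 = clumpR2,
       clumpKb = clumpKb, sentinelOnly = sentinelOnly, steiger = steiger,
       palindromeWindow = palindromeWindow,
       secondOrderWald = secondOrderWald, smrCfg = smrCfg,
       colocCfg = colocCfg)
}

## instrument pipeline for one (source table, outcome) pair
.instrument_mr <- function(pid, cis, outcome, ld, threshold, settings,
                           sourceLabel) {
  instr <- selectInstruments(cis, threshold)
  if (nrow(instr@records) && settings$clump)
    instr <- clumpVariants(instr, ld, settings$clumpR2, settings$clumpKb)
  if (nrow(instr@records) && settings$sentinelOnly) {
    best <- which.min(instr@records$pval)
    instr@records <- instr@records[best, , drop = FALSE]
  }
  if (nrow(instr@records) == 0L)
    return(list(primary = .mr_result(pid, outcome@traitId, "none", k = 0L,
                                     status = "no_instruments"),
                egger = NULL, status = "no_instruments"))
  h <- suppressWarnings(harmonize(instr, outcome, settings$palindromeWindow))
  if (settings$steiger) h <- steigerFilter(h)$kept
  iset <- InstrumentSet(pid, h, ld, sourceLabel)
  runProteinMR(iset, binary = outcome@traitType == "binary",
               outcomeId = outcome@traitId)
}

.mr_row <- function(pid, src, bundle) {
  pr <- bundle$primary
  data.frame(protein_id = pid, source = src, method = pr@method,
             beta = pr@beta, se = pr@se, pval = pr@pval,
             n_instruments = pr@nInstruments,
             q_stat = pr@qStat, q_pval = pr@qPval,
             egger_intercept = if (!is.null(bundle$egger))
               bundle$egger@eggerIntercept else NA_real_,
             egger_intercept_p = if (!is.null(bundle$egger))
               bundle$egger@eggerInterceptP else NA_real_,
             min_f = if (nrow(bundle$fStats)) min(bundle$fStats$f) else NA_real_,
             status = pr@status, stringsAsFactors = FALSE)
}

#' Run the discovery pipeline on an in-memory panel
#'
#' Executes the full evidence chain on a panel structure (as produced by
#' \code{\link{simulatePanel}} or by the file loader behind
#' \code{\link{runPipeline}}): per-source instrument selection and MR,
#' per-source FDR across proteins, fixed-effect meta-analysis of proteins
#' significant (q < fdrQ) in at least one source with estimates in at least
#' two, SMR + HEIDI per gene, colocalization of the best source's cis
#' region with the outcome, replication counting over the outcome panel,
#' direction consistency, and tier assignment.
#'
#' @param panel panel structure (see \code{\link{simulatePanel}}).
#' @param settings from \code{\link{pipelineSettings}}.
#' @return list(evidence, mrBySource, combined, smr, coloc, replication,
#'   settings).
#' @export
runPanelAnalysis <- function(panel, settings = pipelineSettings()) {
  thresholds <- setNames(panel$sources$p_threshold, panel$sources$source)
  pids <- names(panel$loci)
  n_genes <- length(pids)

  mr_rows <- list()
  for (pid in pids) {
    loc <- panel$loci[[pid]]
    for (src in names(loc$sources)) {
      cis <- suppressWarnings(cisWindow(loc$gene, loc$sources[[src]]))
      bundle <- .instrument_mr(pid, cis, loc$outcome, loc$ld,
                               thresholds[[src]], settings, src)
      mr_rows[[paste(pid, src)]] <- .mr_row(pid, src, bundle)
    }
  }
  mr <- do.call(rbind, mr_rows)
  rownames(mr) <- NULL
  ## FDR within each protein dataset separately
  mr$q <- NA_real_
  for (src in unique(mr$source)) {
    i <- mr$source == src & !is.na(mr$pval)
    mr$q[i] <- bhFDR(mr$pval[i])
  }

  combined <- NULL
  smr_tab <- NULL
  coloc_tab <- NULL
  repl_tab <- NULL
  dir_tab <- NULL
  repl_long <- NULL
  for (pid in pids) {
    loc <- panel$loci[[pid]]
    rows <- mr[mr$protein_id == pid & !is.na(mr$beta), , drop = FALSE]
    any_sig <- any(rows$q < settings$fdrQ, na.rm = TRUE)
    ## combined effect: meta when significant somewhere and >= 2 estimates,
    ## otherwise the best single-source estimate
    if (nrow(rows)) {
      if (any_sig && nrow(rows) >= 2L) {
        m <- fixedEffectMeta(rows$beta, rows$se)
        comb <- data.frame(protein_id = pid, beta = m$beta, se = m$se,
                           pval = m$pval, or = m$or, or_low = m$orLow,
                           or_high = m$orHigh, n_sources_used = m$k,
                           stringsAsFactors = FALSE)
      } else {
        b <- rows[which.min(rows$q), , drop = FALSE]
        comb <- data.frame(protein_id = pid, beta = b$beta, se = b$se,
                           pval = b$pval, or = exp(b$beta),
                           or_low = exp(b$beta - qnorm(0.975) * b$se),
                           or_high = exp(b$beta + qnorm(0.975) * b$se),
                           n_sources_used = 1L, stringsAsFactors = FALSE)
      }
      combined <- rbind(combined, comb)
    }

    ## SMR + HEIDI (blood expression)
    sr <- runGeneSMR(loc$gene, loc$eqtl, loc$outcome, loc$ld,
                     cfg = settings$smrCfg, tissueLabel = "blood")
    passed_raw <- sr@status == "ok" && !is.na(sr@pSmr) && sr@pSmr < settings$smrP
    passed_bonf <- sr@status == "ok" && !is.na(sr@pSmr) &&
      sr@pSmr < settings$smrP / max(1L, n_genes)
    smr_tab <- rbind(smr_tab, data.frame(
      protein_id = pid, gene_id = loc$gene$gene_id, tissue = "blood",
      top_variant = sr@topVariant, b_smr = sr@bSmr, se_smr = sr@seSmr,
      p_smr = sr@pSmr, heidi_p = sr@heidiP, heidi_n_snps = sr@heidiNSnps,
      smr_status = sr@status, passed_smr = passed_raw,
      passed_smr_bonferroni = passed_bonf, stringsAsFactors = FALSE))

    ## colocalization: best source's full cis region vs outcome
    best_src <- if (nrow(rows)) rows$source[which.min(rows$q)]
                else names(loc$sources)[1]
    cis_full <- suppressWarnings(cisWindow(loc$gene, loc$sources[[best_src]]))
    cr <- NULL
    if (nrow(cis_full@records) >= 2L) {
      hh <- suppressWarnings(harmonize(cis_full, loc$outcome,
                                       settings$palindromeWindow))
      kp <- keptPairs(hh)
      if (nrow(kp@pairs) >= 2L) {
        t1 <- .pairs_to_sumstats(kp, "exp", paste0(pid, "_", best_src),
                                 "quantitative")
        t2 <- .pairs_to_sumstats(kp, "out", loc$outcome@traitId,
                                 loc$outcome@traitType)
        cr <- colocalize(t1, t2, settings$colocCfg)
      }
    }
    coloc_tab <- rbind(coloc_tab, data.frame(
      protein_id = pid,
      pph0 = if (is.null(cr)) NA_real_ else cr@pph["pph0"],
      pph1 = if (is.null(cr)) NA_real_ else cr@pph["pph1"],
      pph2 = if (is.null(cr)) NA_real_ else cr@pph["pph2"],
      pph3 = if (is.null(cr)) NA_real_ else cr@pph["pph3"],
      pph4 = if (is.null(cr)) NA_real_ else cr@pph["pph4"],
      call = if (is.null(cr)) NA_character_ else cr@call,
      n_variants = if (is.null(cr)) 0L else cr@nVariants,
      passed_coloc = !is.null(cr) && cr@pph["pph4"] > settings$pph4Pass,
      coloc_source = best_src, stringsAsFactors = FALSE))

    ## replication panel
    principal_beta <- if (!is.null(combined) &&
                          pid %in% combined$protein_id)
      combined$beta[combined$protein_id == pid] else NA_real_
    count <- 0L
    if (is.finite(principal_beta) && length(loc$panel)) {
      prow <- lapply(names(loc$panel), function(oid) {
        outc <- loc$panel[[oid]]
        b <- .instrument_mr(pid, suppressWarnings(cisWindow(loc$gene,
                                                            loc$sources[[best_src]])),
                            outc, loc$ld, thresholds[[best_src]], settings,
                            best_src)$primary
        spec <- panel$outcomeSpec[panel$outcomeSpec$outcome_id == oid, ]
        data.frame(protein_id = pid, outcome_id = oid,
                   polarity = spec$polarity, beta = b@beta, pval = b@pval,
                   stringsAsFactors = FALSE)
      })
      prow <- do.call(rbind, prow)
      repl_long <- rbind(repl_long, prow)
      count <- countReplications(principal_beta, prow)
    }
    repl_tab <- rbind(repl_tab, data.frame(protein_id = pid,
                                           replication_count = count))

    gene_betas <- setNames(sr@bSmr, "blood")
    dc <- if (is.finite(principal_beta))
      directionConsistency(principal_beta, gene_betas)$summary
    else NA_character_
    dir_tab <- rbind(dir_tab, data.frame(protein_id = pid,
                                         direction_consistent = dc,
                                         stringsAsFactors = FALSE))
  }

  mr_by_source <- split(mr, mr$source)
  evidence <- buildEvidenceTable(mr_by_source,
                                 if (is.null(combined))
                                   data.frame(protein_id = character(0))
                                 else combined,
                                 smr_tab, coloc_tab, repl_tab, dir_tab)
  list(evidence = evidence, mrBySource = mr, combined = combined,
       smr = smr_tab, coloc = coloc_tab, replication = repl_long,
       settings = settings)
}

## Load a file-driven pipeline configuration (YAML) into the in-memory
## panel structure consumed by runPanelAnalysis.
.load_panel <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  need <- function(path, what) {
    if (is.null(path) || !file.exists(path))
      stop("pipeline config: missing ", what, " file: ",
           if (is.null(path)) "(unset)" else path)
    path
  }
  genes <- readGeneAnnotations(need(config$genes, "gene annotation"),
                               header = FALSE)
  spec <- read.delim(need(config$outcome_spec, "outcome spec"),
                     stringsAsFactors = FALSE)
  thresholds <- unlist(config$source_thresholds)
  loci <- list()
  for (entry in config$proteins) {
    pid <- entry$protein_id
    gene <- genes[genes$gene_id == entry$gene_id, , drop = FALSE]
    if (nrow(gene) != 1L)
      stop("pipeline config: gene '", entry$gene_id, "' not found for ", pid)
    ld <- readLDMatrix(need(entry$ld, paste0("LD (", pid, ")")))
    outcome <- readSumStats(need(entry$outcome, "outcome"),
                            traitType = "binary")
    eqtl <- readSumStats(need(entry$eqtl, "eQTL"), traitType = "quantitative")
    srcs <- lapply(names(entry$sources), function(s)
      readSumStats(need(entry$sources[[s]], paste0("pQTL ", s)),
                   traitType = "quantitative"))
    names(srcs) <- names(entry$sources)
    pan <- lapply(names(entry$panel), function(o) {
      fam <- spec$family[spec$outcome_id == o]
      readSumStats(need(entry$panel[[o]], paste0("panel ", o)),
                   traitType = if (grepl("binary", fam)) "binary"
                               else "quantitative")
    })
    names(pan) <- names(entry$panel)
    loci[[pid]] <- list(sources = srcs, eqtl = eqtl, outcome = outcome,
                        panel = pan, ld = ld, gene = gene)
  }
  list(loci = loci, genes = genes,
       outcomeSpec = spec,
       sources = data.frame(source = names(thresholds),
                            p_threshold = as.numeric(thresholds),
                            stringsAsFactors = FALSE),
       seed = if (is.null(config$seed)) NA_integer_ else config$seed)
}

#' Run the file-driven discovery pipeline
#'
#' Loads a declarative YAML configuration naming the pQTL source tables
#' (with their selection thresholds), eQTL and outcome tables, LD matrices
#' and gene annotations, validates every referenced path, executes
#' \code{\link{runPanelAnalysis}}, and writes per-stage TSVs, the evidence
#' table, a provenance record and a run log to the output directory.
#' Rerunning with unchanged inputs reproduces the evidence TSV
#' byte-identically.
#'
#' @param config path to a YAML config (or an equivalent list); see
#'   \code{\link{exportPanel}} for a generator of the expected layout.
#' @param outDir output directory.
#' @param settings from \code{\link{pipelineSettings}}.
#' @param verbose logical; log stage events to stderr.
#' @return the \code{\link{runPanelAnalysis}} result, invisibly; files are
#'   written to \code{outDir}.
#' @export
runPipeline <- function(config, outDir, settings = pipelineSettings(),
                        verbose = TRUE) {
  log_lines <- character(0)
  say <- function(stage, event) {
    line <- sprintf("%s\t%s\t%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                    stage, event)
    log_lines <<- c(log_lines, line)
    if (verbose) message(line)
  }
  say("config", "loading")
  panel <- .load_panel(config)
  say("config", sprintf("%d proteins, %d sources", length(panel$loci),
                        nrow(panel$sources)))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  say("analysis", "running")
  res <- runPanelAnalysis(panel, settings)
  stage_out <- function(tab, name) {
    if (!is.null(tab)) {
      writeEvidenceTable(tab, file.path(outDir, name))
      say("write", name)
    }
  }
  stage_out(res$mrBySource, "mr_per_source.tsv")
  stage_out(res$combined, "mr_combined.tsv")
  stage_out(res$smr, "smr.tsv")
  stage_out(res$coloc, "coloc.tsv")
  stage_out(res$replication, "replication.tsv")
  stage_out(res$evidence, "evidence.tsv")
  prov <- list(package = "omicsMR",
               version = as.character(utils::packageVersion("omicsMR")),
               config = if (is.character(config)) normalizePath(config)
                        else "in-memory",
               seed = panel$seed,
               settings = settings[c("fdrQ", "smrP", "heidiP", "pph4Call",
                                     "pph4Pass", "clump", "clumpR2",
                                     "clumpKb", "sentinelOnly", "steiger",
                                     "palindromeWindow")])
  jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, file.path(outDir, "run.log"))
  say("done", outDir)
  invisible(res)
}
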