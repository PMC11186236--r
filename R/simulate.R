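#' @include AllClasses.R
NULL

## cache of AR(1) LD matrices and their Cholesky factors keyed by (m, rho)
.sim_cache <- new.env(parent = emptyenv())

#' Construct a synthetic scenario
#'
#' Defaults encode a realistic cis locus for this design: 200 variants with
#' AR(1) LD decay rho = 0.9, a protein GWAS of 35,000 (deCODE-like), a
#' blood eQTL study of 31,000 (eQTLGen-like), a binary outcome GWAS of
#' 41,395 cases / 439,303 controls (CKDGen-like, effective n ~ 151,000), a
#' protein-outcome effect theta = 0.2 log-odds per SD, variant effects
#' a = e = 0.3 SD per allele on the molecular traits, and a direct
#' variant-outcome effect c = 0.15 for the linkage/pleiotropy
#' architectures. In the \code{reverse} architecture the causal variant
#' drives the outcome with effect \code{a} and the protein responds with
#' back-effect \code{theta * a}.
#'
#' @param name architecture: null, causal, mediated, linkage, pleiotropy,
#'   reverse.
#' @param m,rho locus size and AR(1) LD parameter.
#' @param nProt,nEqtl,nCase,nCtrl sample sizes.
#' @param theta,a,e,c effect sizes (see class docs).
#' @param causalIdx,secondIdx causal-variant positions (defaults: locus
#'   midpoint; secondIdx 3 variants away, r-squared ~ 0.53 with the causal
#'   variant).
#' @param aIdx indices of protein-effect variants (default causalIdx);
#'   several independent instruments can be requested for calibration runs.
#' @param palFrac fraction of palindromic (A/T) variants.
#' @param seed integer seed.
#' @return a \linkS4class{SimScenario}.
#' @export
simScenario <- function(name = c("null", "causal", "linkage", "pleiotropy",
                                 "reverse", "mediated"),
                        m = 200L, rho = 0.9,
                        nProt = 35000, nEqtl = 31000,
                        nCase = 41395, nCtrl = 439303,
                        theta = 0.2, a = 0.3, e = 0.3, c = 0.15,
                        causalIdx = NULL, secondIdx = NULL, aIdx = NULL,
                        palFrac = 0.15, seed = 1L) {
  name <- match.arg(name)
  m <- as.integer(m)
  if (is.null(causalIdx)) causalIdx <- max(1L, m %/% 2L)
  if (is.null(secondIdx)) secondIdx <- min(m, causalIdx + 3L)
  if (is.null(aIdx)) aIdx <- causalIdx
  new("SimScenario", name = name, m = m, rho = rho,
      nProt = nProt, nEqtl = nEqtl, nCase = nCase, nCtrl = nCtrl,
      theta = theta, a = a, e = e, c = c,
      causalIdx = as.integer(causalIdx), secondIdx = as.integer(secondIdx),
      aIdx = as.integer(aIdx), palFrac = palFrac, seed = as.integer(seed))
}

#' AR(1) regional LD matrix
#'
#' \code{R_ij = rho^|i-j|}, variant ids snp_1..snp_m, positions spaced
#' 10 kb apart. The matrix (with its Cholesky factor) is cached per
#' (m, rho).
#'
#' @param m number of variants.
#' @param rho AR(1) parameter, |rho| < 1.
#' @return an \linkS4class{LDMatrix}.
#' @export
makeLD <- function(m, rho) {
  stopifnot(m >= 1, abs(rho) < 1)
  key <- sprintf("%d_%.17g", m, rho)
  hit <- .sim_cache[[key]]
  if (!is.null(hit)) return(hit$ld)
  r <- rho^abs(outer(seq_len(m), seq_len(m), "-"))
  ld <- LDMatrix(r, paste0("snp_", seq_len(m)))
  .sim_cache[[key]] <- list(ld = ld, chol = chol(r))
  ld
}

.cached_chol <- function(m, rho) {
  makeLD(m, rho)
  .sim_cache[[sprintf("%d_%.17g", m, rho)]]$chol
}

.derive_seed <- function(seed, ...) {
  k <- c(...)
  as.integer((as.numeric(seed) + sum(k * 7919)) %% 2147483629 + 1)
}

## One trait's regional marginal summary statistics:
## bhat ~ MVN(R beta_joint, R / n_eff) on the standardized scale, with
## per-variant se = 1/sqrt(n_eff) and two-sided normal p.
.draw_trait <- function(bMarginal, U, nEff, seed, frame, traitId, traitType,
                        nTotal = nEff, nCase = NA, nCtrl = NA) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  m <- length(bMarginal)
  bhat <- bMarginal + drop(crossprod(U, rnorm(m))) / sqrt(nEff)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  se <- rep(1 / sqrt(nEff), m)
  rec <- data.frame(variant_id = frame$variant_id, chrom = frame$chrom,
                    pos = frame$pos, effect_allele = frame$effect_allele,
                    other_allele = frame$other_allele, eaf = frame$eaf,
                    beta = bhat, se = se,
                    pval = pmax(2 * pnorm(-abs(bhat) / se),
                                .Machine$double.xmin),
                    n = nTotal, ncase = nCase, nctrl = nCtrl,
                    stringsAsFactors = FALSE)
  SumStats(rec, traitId = traitId, traitType = traitType)
}

.joint_effects <- function(scn) {
  z <- numeric(scn@m)
  prot <- eqtl <- out <- z
  ci <- scn@causalIdx
  switch(scn@name,
         null = {
           prot[scn@aIdx] <- scn@a
           eqtl[ci] <- scn@e
         },
         causal = ,
         mediated = {
           prot[scn@aIdx] <- scn@a
           eqtl[ci] <- scn@e
           out <- scn@theta * prot
         },
         pleiotropy = {
           prot[scn@aIdx] <- scn@a
           eqtl[ci] <- scn@e
           out <- scn@theta * prot
           out[ci] <- out[ci] + scn@c
         },
         linkage = {
           prot[scn@aIdx] <- scn@a
           eqtl[ci] <- scn@e
           out[scn@secondIdx] <- scn@c
         },
         reverse = {
           out[ci] <- scn@a
           prot[ci] <- scn@theta * scn@a
         })
  list(prot = prot, eqtl = eqtl, out = out)
}

## shared variant frame (ids, positions, alleles, frequencies) for a locus
.locus_frame <- function(scn, chrom = "1", posStart = 1e6) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(.derive_seed(scn@seed, 11))
  m <- scn@m
  pal <- runif(m) < scn@palFrac
  eaf <- runif(m, 0.05, 0.5)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  data.frame(variant_id = paste0("snp_", seq_len(m)), chrom = chrom,
             pos = as.integer(posStart + (seq_len(m) - 1L) * 1e4),
             effect_allele = "A",
             other_allele = ifelse(pal, "T", "C"),
             eaf = eaf, stringsAsFactors = FALSE)
}

#' Effective sample size of a case-control GWAS
#'
#' \code{4 / (1/ncase + 1/nctrl)}; the variance scale of log-odds summary
#' statistics on the standardized scale.
#'
#' @param ncase,nctrl case and control counts.
#' @return numeric.
#' @export
effectiveN <- function(ncase, nctrl) 4 / (1 / ncase + 1 / nctrl)

#' Simulate regional summary statistics for one locus
#'
#' Draws marginal association estimates for three traits (protein,
#' expression, binary outcome) at one locus under the scenario's causal
#' architecture. Joint (causal) effect vectors are translated to expected
#' marginal effects via \code{b = R beta_joint}; sampled estimates follow
#' MVN(b, R/n_eff) on the standardized scale with per-variant
#' se = 1/sqrt(n_eff); the binary outcome uses the effective sample size
#' 4/(1/ncase + 1/nctrl) on the log-odds scale. Allele labels are A/C with
#' a fixed fraction of palindromic A/T variants, and effect-allele
#' frequencies are uniform(0.05, 0.5), so harmonization is exercised.
#' Identical scenarios (including seed) reproduce byte-identical tables.
#'
#' @param scn a \linkS4class{SimScenario}.
#' @param chrom chromosome label for the locus.
#' @param traitPrefix prefix for the trait ids.
#' @return list(prot, eqtl, outcome: \linkS4class{SumStats};
#'   ld: \linkS4class{LDMatrix}; gene: one-row annotation;
#'   truth: list(scenario, joint, marginal)).
#' @export
simulateRegion <- function(scn, chrom = "1", traitPrefix = "sim") {
  stopifnot(is(scn, "SimScenario"))
  validObject(scn)
  ld <- makeLD(scn@m, scn@rho)
  U <- .cached_chol(scn@m, scn@rho)
  frame <- .locus_frame(scn, chrom = chrom)
  joint <- .joint_effects(scn)
  marg <- lapply(joint, function(b) drop(ld@r %*% b))
  nEffOut <- effectiveN(scn@nCase, scn@nCtrl)
  prot <- .draw_trait(marg$prot, U, scn@nProt, .derive_seed(scn@seed, 1),
                      frame, paste0(traitPrefix, "_prot"), "quantitative")
  eqtl <- .draw_trait(marg$eqtl, U, scn@nEqtl, .derive_seed(scn@seed, 2),
                      frame, paste0(traitPrefix, "_eqtl"), "quantitative")
  outc <- .draw_trait(marg$out, U, nEffOut, .derive_seed(scn@seed, 3),
                      frame, paste0(traitPrefix, "_outcome"), "binary",
                      nTotal = scn@nCase + scn@nCtrl,
                      nCase = scn@nCase, nCtrl = scn@nCtrl)
  gene <- data.frame(gene_id = paste0(traitPrefix, "_gene"),
                     symbol = paste0(traitPrefix, "_gene"), chrom = chrom,
                     start = min(frame$pos), end = max(frame$pos),
                     stringsAsFactors = FALSE)
  list(prot = prot, eqtl = eqtl, outcome = outc, ld = ld, gene = gene,
       truth = list(scenario = scn, joint = joint, marginal = marg))
}

#' Default replication-outcome panel specification
#'
#' Seventeen outcomes mirroring a kidney-disease replication design: three
#' further disease GWAS (binary, polarity +1), four kidney-function
#' outcomes (two continuous filtration-rate traits with polarity -1, where
#' a negative beta means increased risk, and two binary rapid-decline
#' traits), four continuous annualized filtration-slope strata
#' (polarity -1), and six binary clinical disease types (+1).
#'
#' @return data.frame(outcome_id, family, polarity, ncase, nctrl, n).
#' @export
defaultOutcomePanel <- function() {
  rbind(
    data.frame(outcome_id = paste0("ckd", 2:4), family = "ckd_binary",
               polarity = 1, ncase = 10000, nctrl = 100000, n = NA),
    data.frame(outcome_id = c("egfr_crea", "egfr_cys"),
               family = "egfr_continuous", polarity = -1,
               ncase = NA, nctrl = NA, n = 100000),
    data.frame(outcome_id = c("rapid3", "ckdi25"), family = "decline_binary",
               polarity = 1, ncase = 10000, nctrl = 100000, n = NA),
    data.frame(outcome_id = paste0("slope_", 1:4), family = "slope_continuous",
               polarity = -1, ncase = NA, nctrl = NA, n = 50000),
    data.frame(outcome_id = paste0("clin_", 1:6), family = "clinical_binary",
               polarity = 1, ncase = 5000, nctrl = 200000, n = NA))
}

#' Default pseudo-source definitions for the protein GWAS
#'
#' Three independent re-drawings of each protein locus with the sample
#' sizes and instrument-selection thresholds of the three plasma-proteome
#' GWAS the design emulates.
#'
#' @return data.frame(source, n, p_threshold).
#' @export
defaultProteinSources <- function() {
  data.frame(source = c("iceland", "fenland", "ukb_ppp"),
             n = c(35359, 10708, 54219),
             p_threshold = c(1.8e-9, 1.004e-11, 1.7e-11),
             stringsAsFactors = FALSE)
}

#' Simulate a multi-locus discovery panel
#'
#' Generates k independent loci (one per protein), each with three
#' pseudo-source protein tables (independent noise, source-specific sample
#' sizes), one blood eQTL table, the principal binary outcome, and a
#' 17-outcome replication panel with declared polarities. Per-locus
#' scenarios are assigned from the supplied mixture; the ground-truth table
#' records each locus's architecture. Deterministic given (k, mix, seed).
#'
#' @param k number of loci / proteins.
#' @param mix named numeric of scenario proportions (must sum to 1), e.g.
#'   \code{c(null = 0.9, mediated = 0.1)}.
#' @param seed integer seed.
#' @param scenarioArgs list of overrides passed to \code{\link{simScenario}}
#'   for every locus (effect sizes, m, rho, ...).
#' @param sources data.frame as \code{\link{defaultProteinSources}}.
#' @param panelSpec data.frame as \code{\link{defaultOutcomePanel}}.
#' @return list(loci, genes, outcomeSpec, sources, truth, seed).
#' @export
simulatePanel <- function(k = 10L, mix = c(null = 1), seed = 1L,
                          scenarioArgs = list(),
                          sources = defaultProteinSources(),
                          panelSpec = defaultOutcomePanel()) {
  stopifnot(abs(sum(mix) - 1) < 1e-8, all(names(mix) != ""))
  k <- as.integer(k)
  ## largest-remainder apportionment, then a seeded shuffle
  exact <- mix * k
  counts <- floor(exact)
  rem <- k - sum(counts)
  if (rem > 0) {
    extra <- order(exact - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  scen_names <- rep(names(mix), counts)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(.derive_seed(seed, 97))
  scen_names <- sample(scen_names)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())

  loci <- vector("list", k)
  names(loci) <- paste0("protein_", seq_len(k))
  genes <- NULL
  truth <- NULL
  for (l in seq_len(k)) {
    scn_args <- c(list(name = scen_names[l],
                       seed = .derive_seed(seed, 211, l)), scenarioArgs)
    scn <- do.call(simScenario, scn_args)
    reg <- simulateRegion(scn, chrom = as.character(l),
                          traitPrefix = names(loci)[l])
    U <- .cached_chol(scn@m, scn@rho)
    frame <- .locus_frame(scn, chrom = as.character(l))
    marg <- reg$truth$marginal
    src_tabs <- lapply(seq_len(nrow(sources)), function(s)
      .draw_trait(marg$prot, U, sources$n[s],
                  .derive_seed(seed, 211, l, 5, s), frame,
                  paste0(names(loci)[l], "_", sources$source[s]),
                  "quantitative"))
    names(src_tabs) <- sources$source
    pan_tabs <- lapply(seq_len(nrow(panelSpec)), function(o) {
      spec <- panelSpec[o, ]
      binary <- !is.na(spec$ncase)
      nEff <- if (binary) effectiveN(spec$ncase, spec$nctrl) else spec$n
      .draw_trait(spec$polarity * marg$out, U, nEff,
                  .derive_seed(seed, 211, l, 31, o), frame,
                  paste0(names(loci)[l], "_", spec$outcome_id),
                  if (binary) "binary" else "quantitative",
                  nTotal = if (binary) spec$ncase + spec$nctrl else spec$n,
                  nCase = if (binary) spec$ncase else NA,
                  nCtrl = if (binary) spec$nctrl else NA)
    })
    names(pan_tabs) <- panelSpec$outcome_id
    gene <- reg$gene
    gene$gene_id <- paste0("gene_", l)
    gene$symbol <- gene$gene_id
    loci[[l]] <- list(sources = src_tabs, eqtl = reg$eqtl,
                      outcome = reg$outcome, panel = pan_tabs,
                      ld = reg$ld, gene = gene, truth = reg$truth)
    genes <- rbind(genes, gene)
    truth <- rbind(truth, data.frame(protein_id = names(loci)[l],
                                     gene_id = gene$gene_id,
                                     scenario = scn@name,
                                     theta = if (scn@name %in%
                                                 c("causal", "mediated",
                                                   "pleiotropy")) scn@theta
                                             else 0,
                                     stringsAsFactors = FALSE))
  }
  list(loci = loci, genes = genes,
       outcomeSpec = panelSpec[, c("outcome_id", "family", "polarity")],
       sources = sources, truth = truth, seed = as.integer(seed))
}

#' Export a simulated panel as plain-text files
#'
#' Writes every table of a \code{\link{simulatePanel}} result in the
#' package's canonical formats (summary-statistics TSVs, LD matrix text,
#' BED-like gene annotations, outcome-spec TSV, truth JSON) plus a ready
#' pipeline configuration, so the file-driven pipeline can be run on it.
#'
#' @param panel result of \code{\link{simulatePanel}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the path of the written pipeline config.
#' @export
exportPanel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genes_path <- file.path(dir, "genes.bed")
  g <- panel$genes
  write.table(data.frame(g$chrom, g$start, g$end, g$gene_id, g$symbol),
              genes_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  spec_path <- file.path(dir, "outcome_spec.tsv")
  write.table(panel$outcomeSpec, spec_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  cfg <- list(genes = genes_path, outcome_spec = spec_path,
              seed = panel$seed, pqtl_sources = list(), proteins = list())
  for (pid in names(panel$loci)) {
    loc <- panel$loci[[pid]]
    pdir <- file.path(dir, pid)
    dir.create(pdir, showWarnings = FALSE)
    entry <- list(protein_id = pid, gene_id = loc$gene$gene_id,
                  ld = file.path(pdir, "ld.txt"),
                  eqtl = file.path(pdir, "eqtl.tsv"),
                  outcome = file.path(pdir, "outcome.tsv"),
                  sources = list(), panel = list())
    writeLDMatrix(loc$ld, entry$ld, digits = 6)
    writeSumStats(loc$eqtl, entry$eqtl)
    writeSumStats(loc$outcome, entry$outcome)
    for (s in names(loc$sources)) {
      p <- file.path(pdir, paste0("pqtl_", s, ".tsv"))
      writeSumStats(loc$sources[[s]], p)
      entry$sources[[s]] <- p
    }
    for (o in names(loc$panel)) {
      p <- file.path(pdir, paste0("panel_", o, ".tsv"))
      writeSumStats(loc$panel[[o]], p)
      entry$panel[[o]] <- p
    }
    cfg$proteins[[pid]] <- entry
  }
  cfg$source_thresholds <- as.list(setNames(panel$sources$p_threshold,
                                            panel$sources$source))
  jsonlite::write_json(panel$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  cfg_path <- file.path(dir, "run.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}
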