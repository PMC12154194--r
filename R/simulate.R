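#' Specify a synthetic multi-tissue cohort
#'
#' Parameters of the synthetic-cohort generator. The generator emulates a
#' two-condition mouse study (e.g. thermoneutral vs cold housing) profiled by
#' label-free proteomics in several tissues: per-protein log2 baselines are
#' drawn once per tissue, a configurable fraction of proteins receives a
#' condition effect (a planted log2 fold change), and residual between-mouse
#' variation is Gaussian on the log2 scale, so emitted intensities are
#' log-normal — strictly positive and right-skewed like LFQ data.
#'
#' @param tissues character vector of tissue labels (>= 2 for cross-talk).
#' @param proteinsPerTissue number of proteins quantified per tissue.
#' @param nSubjectsPerCondition mice per condition (study range 5-8).
#' @param conditions two condition labels, reference first.
#' @param fracRegulated fraction of each tissue's proteins given a condition
#'   effect.
#' @param effectLog2fcMean,effectLog2fcSd normal distribution of planted log2
#'   fold changes for regulated proteins.
#' @param baseLog2Mean,baseLog2Sd distribution of per-protein baseline log2
#'   abundance.
#' @param noiseSd residual between-mouse standard deviation, log2 scale.
#' @param secretedFraction fraction of the protein universe annotated
#'   secreted.
#' @param missingRate missing-at-random masking rate applied to the emitted
#'   matrices (default 0).
#' @param driverVarMultiplier variance inflation applied to planted edge
#'   drivers so that endocrine couplings are detectable at small n.
#' @param seed integer seed; the generator is a pure function of
#'   (spec, edges).
#' @return a validated list of class `cohortSpec`.
#' @seealso [plantedEdge()], [simulateCohort()], [simulateNullCohort()]
#' @export
cohortSpec <- function(tissues = c("liver", "sWAT", "eWAT", "BAT",
                                   "quadriceps", "hypothalamus"),
                       proteinsPerTissue = 400L,
                       nSubjectsPerCondition = 8L,
                       conditions = c("thermoneutral_30C", "cold_5C"),
                       fracRegulated = 0.3,
                       effectLog2fcMean = 0, effectLog2fcSd = 1,
                       baseLog2Mean = 23, baseLog2Sd = 2,
                       noiseSd = 0.25,
                       secretedFraction = 0.15,
                       missingRate = 0,
                       driverVarMultiplier = 2,
                       seed = 1L) {
  spec <- list(tissues = as.character(tissues),
               proteinsPerTissue = as.integer(proteinsPerTissue),
               nSubjectsPerCondition = as.integer(nSubjectsPerCondition),
               conditions = as.character(conditions),
               fracRegulated = fracRegulated,
               effectLog2fcMean = effectLog2fcMean,
               effectLog2fcSd = effectLog2fcSd,
               baseLog2Mean = baseLog2Mean, baseLog2Sd = baseLog2Sd,
               noiseSd = noiseSd, secretedFraction = secretedFraction,
               missingRate = missingRate,
               driverVarMultiplier = driverVarMultiplier,
               seed = as.integer(seed))
  if (length(spec$tissues) < 2L || anyDuplicated(spec$tissues))
    .stopf("need >= 2 distinct tissue labels")
  if (spec$proteinsPerTissue < 2L || spec$nSubjectsPerCondition < 2L)
    .stopf("counts must be >= 2")
  if (length(spec$conditions) != 2L || anyDuplicated(spec$conditions))
    .stopf("exactly two distinct condition labels required")
  for (f in c("fracRegulated", "secretedFraction", "missingRate"))
    if (spec[[f]] < 0 || spec[[f]] > 1)
      .stopf("'%s' must lie in [0, 1]", f)
  if (spec$noiseSd <= 0 || spec$baseLog2Sd <= 0 || spec$effectLog2fcSd <= 0)
    .stopf("standard deviations must be > 0")
  if (spec$driverVarMultiplier < 1)
    .stopf("'driverVarMultiplier' must be >= 1")
  class(spec) <- "cohortSpec"
  spec
}

#' Plant a directed endocrine edge in a synthetic cohort
#'
#' Describes one secreted driver protein in an origin tissue whose
#' between-mouse abundance fluctuation is propagated, with slope
#' `couplingBeta`, into a module of target-tissue proteins. This is the
#' correlation structure that the cross-talk module is designed to recover:
#' a secreted protein in one tissue co-varying with many proteins of another.
#'
#' @param originTissue,targetTissue distinct tissue labels.
#' @param driverProtein identifier of the secreted driver, or `NULL` to let
#'   the generator pick one (recorded in the returned truth). Generated
#'   drivers are given a high baseline abundance (baseline mean + 2 baseline
#'   sd), emulating an abundantly expressed endocrine factor.
#' @param targetModule identifiers of the target module, or `NULL` with
#'   `moduleSize` to let the generator sample one.
#' @param moduleSize size of the sampled module when `targetModule` is
#'   `NULL`.
#' @param couplingBeta slope of target log2 abundance on the driver's
#'   residual log2 deviation.
#' @param moduleNoiseSd residual sd of module members around the transmitted
#'   signal (log2 scale); 0 gives |r| = 1 with the driver.
#' @param includeConditionEffect if `TRUE`, the driver's condition effect is
#'   transmitted too (a condition-coupled endocrine factor); by default only
#'   its between-mouse residual is.
#' @return a list of class `plantedEdge`.
#' @export
plantedEdge <- function(originTissue, targetTissue, driverProtein = NULL,
                        targetModule = NULL, moduleSize = 50L,
                        couplingBeta = 1, moduleNoiseSd = 0.25,
                        includeConditionEffect = FALSE) {
  if (identical(originTissue, targetTissue))
    .stopf("origin and target tissue must differ")
  edge <- list(originTissue = originTissue, targetTissue = targetTissue,
               driverProtein = driverProtein, targetModule = targetModule,
               moduleSize = as.integer(moduleSize),
               couplingBeta = couplingBeta, moduleNoiseSd = moduleNoiseSd,
               includeConditionEffect = isTRUE(includeConditionEffect))
  if (is.null(targetModule) && edge$moduleSize < 1L)
    .stopf("'moduleSize' must be >= 1")
  if (!is.null(targetModule) && !length(targetModule))
    .stopf("'targetModule' must be non-empty")
  if (moduleNoiseSd < 0) .stopf("'moduleNoiseSd' must be >= 0")
  class(edge) <- "plantedEdge"
  edge
}

#' Simulate a multi-tissue proteomic cohort with known truth
#'
#' Generates one abundance matrix per tissue (log-normal intensities),
#' sample metadata, a secreted-protein annotation and the ground truth
#' (planted log2 fold changes and resolved endocrine edges). Protein
#' identifiers form one shared universe across tissues (as gene products do),
#' and the secreted annotation is protein-level, like a UniProt secreted
#' flag. Identical `(spec, edges)` give bit-identical output.
#'
#' Per subject j of condition c and protein p of tissue T, log2 abundance is
#' `base[p] + log2fc[p] * [c == treatment] + eps`, `eps ~ N(0, noiseSd)`.
#' Planted drivers have their residual sd inflated to
#' `noiseSd * sqrt(driverVarMultiplier)`; each target-module member replaces
#' its own residual with `couplingBeta * driverResidual + N(0, moduleNoiseSd)`.
#'
#' @param spec a [cohortSpec()].
#' @param edges list of [plantedEdge()] objects (may be empty).
#' @return list with elements `proteomes` (named list of
#'   [TissueProteome-class]), `metadata` (data.frame), `secreted` (character
#'   vector) and `truth` (list: `regulated` per tissue data.frame
#'   (`protein_id`, `log2fc`), `edges` with resolved drivers and modules,
#'   `seed`).
#' @examples
#' sim <- simulateCohort(cohortSpec(tissues = c("liver", "sWAT"),
#'                                  proteinsPerTissue = 50,
#'                                  nSubjectsPerCondition = 4, seed = 7))
#' names(sim$proteomes)
#' @export
simulateCohort <- function(spec, edges = list()) {
  stopifnot(inherits(spec, "cohortSpec"))
  if (inherits(edges, "plantedEdge")) edges <- list(edges)
  for (e in edges) {
    stopifnot(inherits(e, "plantedEdge"))
    if (!all(c(e$originTissue, e$targetTissue) %in% spec$tissues))
      .stopf("planted edge references unknown tissue '%s'",
             setdiff(c(e$originTissue, e$targetTissue), spec$tissues)[1L])
  }
  withr::with_seed(spec$seed, .simulateCohortImpl(spec, edges))
}

.simulateCohortImpl <- function(spec, edges) {
  P <- spec$proteinsPerTissue
  proteins <- sprintf("P%04d", seq_len(P))
  nPer <- spec$nSubjectsPerCondition
  subjects <- sprintf("M%02d", seq_len(2L * nPer))
  condition <- rep(spec$conditions, each = nPer)
  isTreated <- condition == spec$conditions[2L]

  # Protein-level secreted annotation over the shared identifier universe.
  nSec <- max(1L, round(spec$secretedFraction * P))
  secreted <- sort(sample(proteins, nSec))

  # Resolve drivers/modules; generated drivers get a high baseline so that
  # abundance-based candidate ranking reflects the expressed-factor scenario.
  for (i in seq_along(edges)) {
    e <- edges[[i]]
    if (is.null(e$driverProtein)) {
      taken <- vapply(edges[seq_len(i - 1L)],
                      function(x) x$driverProtein %||% "", character(1L))
      pool <- setdiff(secreted, taken)
      if (!length(pool)) .stopf("no secreted proteins left to host a driver")
      e$driverProtein <- sample(pool, 1L)
    }
    if (!e$driverProtein %in% proteins)
      .stopf("driver '%s' not in the protein universe", e$driverProtein)
    secreted <- sort(union(secreted, e$driverProtein))
    if (is.null(e$targetModule)) {
      pool <- setdiff(proteins, e$driverProtein)
      if (e$moduleSize > length(pool))
        .stopf("module size %d exceeds available proteins", e$moduleSize)
      e$targetModule <- sort(sample(pool, e$moduleSize))
    } else {
      if (!all(e$targetModule %in% proteins))
        .stopf("target module references unknown proteins")
      e$targetModule <- unique(e$targetModule)
    }
    edges[[i]] <- e
  }

  # Pass 1: draw every tissue's baselines, condition effects and residuals
  # (with driver-variance inflation); pass 2 propagates edges, so edge
  # direction never depends on the order tissues are listed in.
  draws <- list()
  for (tis in spec$tissues) {
    base <- stats::rnorm(P, spec$baseLog2Mean, spec$baseLog2Sd)
    names(base) <- proteins
    nReg <- round(spec$fracRegulated * P)
    regIds <- if (nReg > 0) sort(sample(proteins, nReg)) else character()
    lfc <- stats::setNames(numeric(P), proteins)
    if (length(regIds))
      lfc[regIds] <- stats::rnorm(length(regIds), spec$effectLog2fcMean,
                                  spec$effectLog2fcSd)

    drivers <- vapply(Filter(function(e) e$originTissue == tis, edges),
                      `[[`, character(1L), "driverProtein")
    base[drivers] <- spec$baseLog2Mean + 2 * spec$baseLog2Sd

    resid <- matrix(stats::rnorm(P * 2L * nPer, 0, spec$noiseSd), P, 2L * nPer,
                    dimnames = list(proteins, NULL))
    if (length(drivers))
      resid[drivers, ] <- matrix(
        stats::rnorm(length(drivers) * 2L * nPer, 0,
                     spec$noiseSd * sqrt(spec$driverVarMultiplier)),
        length(drivers), 2L * nPer)
    draws[[tis]] <- list(base = base, lfc = lfc, regIds = regIds, resid = resid)
  }

  # Pass 2: replace each target-module member's residual with the
  # transmitted driver signal plus module noise, then assemble intensities.
  for (e in edges) {
    d <- draws[[e$originTissue]]$resid[e$driverProtein, ]
    transmitted <- e$couplingBeta * d
    if (e$includeConditionEffect)
      transmitted <- transmitted +
        e$couplingBeta * draws[[e$originTissue]]$lfc[[e$driverProtein]] *
          as.numeric(isTreated)
    mod <- e$targetModule
    draws[[e$targetTissue]]$resid[mod, ] <-
      matrix(rep(transmitted, each = length(mod)), length(mod), 2L * nPer) +
      matrix(stats::rnorm(length(mod) * 2L * nPer, 0, e$moduleNoiseSd),
             length(mod), 2L * nPer)
  }

  proteomes <- list()
  regulated <- list()
  for (tis in spec$tissues) {
    dw <- draws[[tis]]
    log2mat <- dw$base + outer(dw$lfc, as.numeric(isTreated)) + dw$resid
    sampleIds <- paste(tis, subjects, sep = "_")
    colnames(log2mat) <- sampleIds
    intens <- 2^log2mat
    if (spec$missingRate > 0) {
      mask <- matrix(stats::runif(length(intens)) < spec$missingRate,
                     nrow(intens), ncol(intens))
      intens[mask] <- NA_real_
    }
    proteomes[[tis]] <- TissueProteome(
      intens, tissue = tis,
      colData = DataFrame(subject_id = subjects, condition = condition,
                          row.names = sampleIds))
    regulated[[tis]] <- data.frame(protein_id = dw$regIds,
                                   log2fc = unname(dw$lfc[dw$regIds]),
                                   stringsAsFactors = FALSE)
  }

  metadata <- do.call(rbind, lapply(spec$tissues, function(tis)
    data.frame(sample_id = paste(tis, subjects, sep = "_"),
               subject_id = subjects, tissue = tis, condition = condition,
               stringsAsFactors = FALSE)))
  rownames(metadata) <- NULL

  list(proteomes = proteomes, metadata = metadata, secreted = secreted,
       truth = list(regulated = regulated, edges = edges, seed = spec$seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a global-null cohort
#'
#' Same generator as [simulateCohort()] with the condition-effect fraction
#' forced to zero and no planted edges: every protein is exchangeable between
#' conditions, so two-sample p-values are Uniform(0, 1) and any discovery is
#' false. Used for FDR and cross-talk calibration.
#'
#' @param spec a [cohortSpec()]; its `fracRegulated` is overridden to 0.
#' @return same structure as [simulateCohort()].
#' @export
simulateNullCohort <- function(spec) {
  stopifnot(inherits(spec, "cohortSpec"))
  spec$fracRegulated <- 0
  simulateCohort(spec, edges = list())
}

#' Write a simulated cohort to a directory of text tables
#'
#' Emits one abundance TSV per tissue (`<tissue>.tsv`), `metadata.tsv`,
#' `secreted.txt` and per-tissue truth tables, so the full pipeline can run
#' file-to-file from generated data.
#'
#' @param sim result of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tis in names(sim$proteomes))
    writeAbundanceTable(sim$proteomes[[tis]], file.path(dir, paste0(tis, ".tsv")))
  writeResultTable(sim$metadata, file.path(dir, "metadata.tsv"))
  writeProteinList(sim$secreted, file.path(dir, "secreted.txt"))
  for (tis in names(sim$truth$regulated)) {
    tb <- sim$truth$regulated[[tis]]
    if (nrow(tb))
      writeResultTable(tb, file.path(dir, paste0("truth_", tis, ".tsv")))
  }
  invisible(dir)
}
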