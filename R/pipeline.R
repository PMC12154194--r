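#' Principal component analysis of a tissue's samples
#'
#' Samples are projected onto principal components of the per-protein
#' centered log2 abundance matrix (complete-case proteins only). Used as a
#' cohort QC: condition and depot separation should be visible on the first
#' components.
#'
#' @param object a [TissueProteome-class] on the log2 scale.
#' @param nComponents number of components to return (default 2; at most
#'   `min(dim)`).
#' @return list with `coordinates` (samples x components matrix) and
#'   `varianceExplained` (fractions, non-increasing, summing to <= 1).
#' @export
pcaSamples <- function(object, nComponents = 2L) {
  stopifnot(is(object, "TissueProteome"))
  if (!identical(valueScale(object), "log2"))
    .stopf("pcaSamples expects a log2-scale matrix; apply logTransform() first")
  m <- abundances(object)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 2L)
    .stopf("fewer than 2 complete-case proteins; cannot run PCA")
  maxComp <- min(nrow(m), ncol(m))
  if (nComponents > maxComp)
    .stopf("nComponents = %d exceeds min(dim) = %d", nComponents, maxComp)
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- seq_len(nComponents)
  list(coordinates = pc$x[, k, drop = FALSE], varianceExplained = ve[k])
}

#' Run the full file-to-file analysis pipeline
#'
#' Orchestrates the whole workflow from a configuration (YAML path or list):
#' read the per-tissue abundance tables, metadata, secreted annotation and
#' optional gene sets; per-tissue differential tables; the directional
#' cross-talk network; candidate ranking for the strongest edge (or a
#' configured origin/target pair); target prediction for the top candidate,
#' with preranked enrichment of the signed-r ranking against the gene sets;
#' per-sample set scores; and, when a second perturbation is configured, the
#' cross-perturbation concordance summary. Every output table carries the
#' seed and a hash of the configuration in `#`-comment header lines; a
#' `run.log` records per-stage counts and exclusions. The run is a pure
#' function of (input files, config): identical reruns are byte-identical.
#'
#' Configuration fields (defaults in parentheses): `tissues` (named map
#' tissue -> TSV path), `metadata`, `secreted`, `gene_sets` (optional GMT),
#' `conditions` (reference, treatment), `output_dir`, `seed` (1), `alpha`
#' (0.05), `pseudo_count` (1), `min_per_group` (3), `min_pairs` (5),
#' `n_permutations` (200), `correlation: {method (pearson), scope (all),
#' alpha (0.05)}`, `crosstalk_origin`/`crosstalk_target` (optional),
#' `second_perturbation` (optional: `tissues`, `metadata`, `conditions`).
#'
#' @param config path to a YAML file or an equivalent named list.
#' @return the output directory, invisibly.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) .stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- .validateConfig(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(cfg$output_dir, "run.log")
  logCon <- file(logPath, open = "wt")
  on.exit(close(logCon))
  logf <- function(fmt, ...) writeLines(sprintf(fmt, ...), logCon)
  meta <- c(seed = as.character(cfg$seed), config_md5 = cfg$hash)
  logf("pipeline start; seed %d; config md5 %s", cfg$seed, cfg$hash)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("FAILED at stage '%s': %s", name,
                         conditionMessage(e)),
                 file.path(cfg$output_dir, "FAILED"))
      logf("stage %s FAILED: %s", name, conditionMessage(e))
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  ## inputs
  inp <- stage("read_inputs", {
    proteomes <- lapply(names(cfg$tissues), function(tis)
      readAbundanceTable(cfg$tissues[[tis]], tissue = tis))
    names(proteomes) <- names(cfg$tissues)
    md <- readSampleMetadata(cfg$metadata)
    sec <- readProteinList(cfg$secreted)
    sets <- if (!is.null(cfg$gene_sets)) readGMT(cfg$gene_sets) else NULL
    for (tis in names(proteomes))
      logf("input %s: %d proteins x %d samples", tis,
           nrow(proteomes[[tis]]), ncol(proteomes[[tis]]))
    logf("secreted annotation: %d proteins; gene sets: %d", length(sec),
         length(sets))
    list(proteomes = proteomes, metadata = md, secreted = sec, sets = sets)
  })

  ## differential per tissue
  diffs <- stage("differential", {
    out <- lapply(inp$proteomes, function(tp)
      differentialTable(tp, inp$metadata, conditions = cfg$conditions,
                        alpha = cfg$alpha, minPerGroup = cfg$min_per_group,
                        pseudo = cfg$pseudo_count))
    for (tis in names(out)) {
      d <- out[[tis]]
      writeResultTable(diffTable(d),
                       file.path(cfg$output_dir,
                                 sprintf("differential_%s.tsv", tis)),
                       meta = meta)
      logf("differential %s: %d tested, %d significant (%.1f%%), %d excluded",
           tis, nrow(diffTable(d)), length(significantProteins(d)),
           100 * significantFraction(d), nrow(excludedProteins(d)))
    }
    out
  })

  ## cross-talk network
  net <- stage("crosstalk", {
    net <- crosstalkNetwork(inp$proteomes, inp$metadata, inp$secreted,
                            method = cfg$correlation$method,
                            alpha = cfg$correlation$alpha,
                            minPairs = cfg$min_pairs,
                            pseudo = cfg$pseudo_count,
                            scope = cfg$correlation$scope,
                            nPermutations = cfg$n_permutations,
                            seed = cfg$seed)
    writeResultTable(net$edges, file.path(cfg$output_dir, "crosstalk_edges.tsv"),
                     meta = meta)
    writeResultTable(net$originTotals,
                     file.path(cfg$output_dir, "crosstalk_origin_totals.tsv"),
                     meta = meta)
    logf("crosstalk: %d edges scored, %d pairs failed", nrow(net$edges),
         nrow(net$failures))
    if (nrow(net$failures))
      for (i in seq_len(nrow(net$failures)))
        logf("  failed %s->%s: %s", net$failures$origin[i],
             net$failures$target[i], net$failures$reason[i])
    net
  })

  ## candidate ranking and target prediction on the strongest edge
  stage("candidates", if (!nrow(net$edges)) {
    logf("candidates: no edge available, skipped")
  } else {
    key <- if (!is.null(cfg$crosstalk_origin) && !is.null(cfg$crosstalk_target))
      paste0(cfg$crosstalk_origin, "->", cfg$crosstalk_target)
    else {
      i <- order(-net$edges$normalized_score, net$edges$origin,
                 net$edges$target)[1L]
      paste0(net$edges$origin[i], "->", net$edges$target[i])
    }
    edge <- net$edgeObjects[[key]]
    if (is.null(edge)) .stopf("edge %s was not scored", key)
    ranking <- rankCandidates(edge, inp$proteomes[[edge@origin]],
                              pseudo = cfg$pseudo_count)
    writeResultTable(ranking, file.path(cfg$output_dir, "candidates.tsv"),
                     meta = meta)
    logf("candidates on %s: %d ranked", key, nrow(ranking))
    if (nrow(ranking)) {
      top <- ranking$protein_id[1L]
      pairing <- alignSubjects(inp$proteomes[[edge@origin]],
                               inp$proteomes[[edge@target]], inp$metadata,
                               scope = cfg$correlation$scope,
                               minPairs = cfg$min_pairs)
      pred <- predictTargets(top, inp$proteomes[[edge@origin]],
                             inp$proteomes[[edge@target]], pairing,
                             method = cfg$correlation$method,
                             alpha = cfg$correlation$alpha,
                             minPairs = cfg$min_pairs,
                             pseudo = cfg$pseudo_count)
      writeResultTable(pred@table,
                       file.path(cfg$output_dir, "target_prediction.tsv"),
                       meta = meta)
      logf("target prediction for %s: %d of %d targets predicted", top,
           length(predictedTargets(pred)), nrow(pred@table))
      if (!is.null(inp$sets)) {
        r <- predictionRanking(pred)
        enr <- do.call(rbind, lapply(names(inp$sets), function(nm)
          tryCatch(prerankedGSEA(r, inp$sets[[nm]],
                                 nPermutations = cfg$n_permutations,
                                 seed = .deriveSeed(cfg$seed, 97L),
                                 setName = nm),
                   error = function(e) NULL)))
        if (!is.null(enr) && nrow(enr)) {
          writeResultTable(enr,
                           file.path(cfg$output_dir, "target_enrichment.tsv"),
                           meta = meta)
          logf("target enrichment: %d sets scored", nrow(enr))
        }
      }
    }
  })

  ## per-sample set scores
  stage("setscore", if (is.null(inp$sets)) {
    logf("setscore: no gene sets configured, skipped")
  } else {
    rows <- list()
    for (tis in names(inp$proteomes)) {
      m <- inp$proteomes[[tis]]
      cc <- stats::complete.cases(abundances(m))
      mcc <- m[cc, ]
      for (nm in names(inp$sets)) {
        sc <- tryCatch(sampleSetScore(mcc, inp$sets[[nm]], setName = nm),
                       error = function(e) NULL)
        if (!is.null(sc)) {
          sc$tissue <- tis
          rows[[paste(tis, nm)]] <- sc
        }
      }
      logf("setscore %s: %d complete-case proteins scored", tis, sum(cc))
    }
    if (length(rows))
      writeResultTable(do.call(rbind, unname(rows)),
                       file.path(cfg$output_dir, "sample_set_scores.tsv"),
                       meta = meta)
  })

  ## second perturbation: overlap and concordance
  stage("concordance", if (is.null(cfg$second_perturbation)) {
    logf("concordance: no second perturbation configured, skipped")
  } else {
    sp <- cfg$second_perturbation
    md2 <- readSampleMetadata(sp$metadata)
    rows <- list()
    for (tis in intersect(names(cfg$tissues), names(sp$tissues))) {
      tp2 <- readAbundanceTable(sp$tissues[[tis]], tissue = tis)
      d2 <- differentialTable(tp2, md2, conditions = sp$conditions,
                              alpha = cfg$alpha,
                              minPerGroup = cfg$min_per_group,
                              pseudo = cfg$pseudo_count)
      cc <- concordance(diffs[[tis]], d2)
      cc$tissue <- tis
      rows[[tis]] <- cc
      logf("concordance %s: overlap %d, opposite fraction %.3f", tis,
           cc$n_overlap, cc$frac_opposite)
    }
    writeResultTable(do.call(rbind, unname(rows)),
                     file.path(cfg$output_dir, "concordance.tsv"), meta = meta)
  })

  logf("pipeline complete")
  invisible(cfg$output_dir)
}

.validateConfig <- function(config) {
  cfg <- config
  need <- c("tissues", "metadata", "secreted", "conditions", "output_dir")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    .stopf("config lacks required fields: %s", paste(miss, collapse = ", "))
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$alpha <- cfg$alpha %||% 0.05
  cfg$pseudo_count <- cfg$pseudo_count %||% 1
  cfg$min_per_group <- cfg$min_per_group %||% 3L
  cfg$min_pairs <- cfg$min_pairs %||% 5L
  cfg$n_permutations <- cfg$n_permutations %||% 200L
  corr <- cfg$correlation %||% list()
  cfg$correlation <- list(method = corr$method %||% "pearson",
                          scope = corr$scope %||% "all",
                          alpha = corr$alpha %||% 0.05)
  if (!cfg$correlation$method %in% c("pearson", "spearman"))
    .stopf("correlation method must be 'pearson' or 'spearman'")
  if (length(cfg$conditions) != 2L)
    .stopf("config 'conditions' must list reference and treatment")
  paths <- c(unlist(cfg$tissues), cfg$metadata, cfg$secreted, cfg$gene_sets,
             if (!is.null(cfg$second_perturbation))
               c(unlist(cfg$second_perturbation$tissues),
                 cfg$second_perturbation$metadata))
  for (p in paths)
    if (!file.exists(p)) .stopf("config references a missing path: %s", p)
  # hash identifies the analysis (inputs and parameters), not the output path
  canon <- cfg[setdiff(names(cfg), c("hash", "output_dir"))]
  tmp <- tempfile()
  yaml::write_yaml(canon[order(names(canon))], tmp)
  cfg$hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  cfg
}
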