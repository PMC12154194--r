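# Small in-code fixtures shared across test files.

toyMatrix <- function(values = c(1, 2, 4, 8, 16, 32), nrow = 3,
                      proteins = sprintf("P%d", seq_len(nrow)),
                      samples = sprintf("s%d", length(values) / nrow)) {
  ncol <- length(values) / nrow
  matrix(values, nrow, ncol,
         dimnames = list(proteins, sprintf("s%d", seq_len(ncol))))
}

toyProteome <- function(values = c(1, 2, 4, 8, 16, 32), nrow = 3,
                        tissue = "liver", ...) {
  TissueProteome(toyMatrix(values, nrow), tissue = tissue, ...)
}

writeTempTSV <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# Two-tissue cohort with one planted liver -> sWAT edge at a chosen pairwise
# driver-target correlation (derived from the variance model).
recoveryCohort <- function(seed, nProteins = 400L, nPer = 8L, rTarget = 0.8,
                           moduleSize = 200L, noiseSd = 0.25,
                           driverVarMultiplier = 2) {
  sdDriver <- noiseSd * sqrt(driverVarMultiplier)
  moduleNoiseSd <- sdDriver * sqrt(1 / rTarget^2 - 1)
  spec <- cohortSpec(tissues = c("liver", "sWAT"),
                     proteinsPerTissue = nProteins,
                     nSubjectsPerCondition = nPer, fracRegulated = 0,
                     noiseSd = noiseSd,
                     driverVarMultiplier = driverVarMultiplier, seed = seed)
  edge <- plantedEdge("liver", "sWAT", moduleSize = moduleSize,
                      couplingBeta = 1, moduleNoiseSd = moduleNoiseSd)
  simulateCohort(spec, edge)
}

fixtureConfig <- function(outDir, seed = 7, nPermutations = 25) {
  ed <- system.file("extdata", package = "tissuetalk")
  list(tissues = list(liver = file.path(ed, "synthetic_liver.tsv"),
                      sWAT = file.path(ed, "synthetic_sWAT.tsv"),
                      eWAT = file.path(ed, "synthetic_eWAT.tsv")),
       metadata = file.path(ed, "synthetic_metadata.tsv"),
       secreted = file.path(ed, "synthetic_secreted.txt"),
       gene_sets = file.path(ed, "synthetic_gene_sets.gmt"),
       conditions = c("thermoneutral_30C", "cold_5C"),
       output_dir = outDir, seed = seed, n_permutations = nPermutations)
}
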