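#' Read a tissue abundance table
#'
#' Reads a tab-separated protein quantification table: first column
#' `protein_id`, remaining columns one sample each. Tokens listed in
#' `missingCodes` (and empty fields) become explicit missing values.
#' Duplicated protein identifiers, non-numeric cells and negative intensities
#' are rejected with the offending row/column named.
#'
#' @param path path to a TSV file with a header row.
#' @param tissue tissue label to attach.
#' @param missingCodes character tokens to interpret as missing
#'   (default `"NA"`).
#' @return a [TissueProteome-class] on the intensity scale.
#' @seealso [writeAbundanceTable()] for the inverse.
#' @export
readAbundanceTable <- function(path, tissue, missingCodes = "NA") {
  if (!file.exists(path)) .stopf("abundance table not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", comment.char = "#",
                          na.strings = NULL)
  if (ncol(df) < 2L)
    .stopf("malformed header in %s: need a protein_id column plus >= 1 sample", path)
  if (names(df)[1L] != "protein_id")
    .stopf("malformed header in %s: first column must be 'protein_id', got '%s'",
           path, names(df)[1L])
  ids <- df[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup))
    .stopf("duplicated protein IDs in %s: %s (first at row %d)", path,
           paste(unique(dup), collapse = ", "),
           which(duplicated(ids))[1L])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  vals[vals %in% missingCodes | vals == ""] <- NA
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(ids, colnames(vals))))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    .stopf("non-numeric value '%s' in %s at row '%s', column '%s'",
           vals[bad[1L, 1L], bad[1L, 2L]], path, ids[bad[1L, 1L]],
           colnames(vals)[bad[1L, 2L]])
  neg <- which(!is.na(num) & num < 0, arr.ind = TRUE)
  if (nrow(neg))
    .stopf("negative intensity in %s at row '%s', column '%s'",
           path, ids[neg[1L, 1L]], colnames(vals)[neg[1L, 2L]])
  TissueProteome(num, tissue = tissue)
}

#' Write a tissue abundance table
#'
#' Inverse of [readAbundanceTable()]: TSV with a `protein_id` first column,
#' doubles serialized at full precision, missing values as `NA`.
#'
#' @param object a [TissueProteome-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAbundanceTable <- function(object, path) {
  m <- abundances(object)
  df <- data.frame(protein_id = rownames(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- m[, j]
  writeResultTable(df, path)
}

#' Read a sample metadata table
#'
#' TSV with columns `sample_id`, `subject_id`, `tissue`, `condition`. Each
#' sample must appear once; a (subject, tissue) pair may occur at most once
#' per condition (one measurement per mouse and tissue).
#'
#' @param path path to the TSV file.
#' @return a data.frame with the four columns above.
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path)) .stopf("metadata table not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "subject_id", "tissue", "condition")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .stopf("metadata %s lacks columns: %s", path, paste(miss, collapse = ", "))
  validateMetadata(df)
  df[need]
}

#' @rdname readSampleMetadata
#' @param metadata a metadata data.frame to validate in place.
#' @export
validateMetadata <- function(metadata) {
  if (anyDuplicated(metadata$sample_id))
    .stopf("duplicated sample_id in metadata: %s",
           paste(unique(metadata$sample_id[duplicated(metadata$sample_id)]),
                 collapse = ", "))
  key <- paste(metadata$subject_id, metadata$tissue, metadata$condition, sep = "\r")
  if (anyDuplicated(key))
    .stopf("metadata has repeated (subject, tissue) measurements within a condition")
  invisible(metadata)
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one tab-separated line per set with fields
#' name, description, members... Members are deduplicated preserving first
#' occurrence. A line with fewer than three fields is a parse error reported
#' with its line number.
#'
#' @param path path to the GMT file.
#' @return named list of character member vectors; each element carries a
#'   `description` attribute.
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) .stopf("GMT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      .stopf("GMT parse error at line %d: expected >= 3 tab-separated fields, got %d",
             i, length(f))
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members))
      .stopf("GMT parse error at line %d: set '%s' has no members", i, f[1L])
    if (f[1L] %in% names(sets))
      .stopf("GMT parse error at line %d: duplicated set name '%s'", i, f[1L])
    attr(members, "description") <- f[2L]
    sets[[f[1L]]] <- members
  }
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors (optionally with a
#'   `description` attribute per element).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    d <- attr(sets[[nm]], "description")
    paste(c(nm, if (is.null(d)) "" else d, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read or write a plain protein identifier list
#'
#' One identifier per line (used for the secreted-protein annotation).
#' Identifiers are opaque case-sensitive strings; duplicates are dropped.
#'
#' @param path file path.
#' @return character vector of unique identifiers.
#' @export
readProteinList <- function(path) {
  if (!file.exists(path)) .stopf("protein list not found: %s", path)
  ids <- readLines(path)
  unique(ids[nzchar(ids)])
}

#' @rdname readProteinList
#' @param ids character vector to write.
#' @export
writeProteinList <- function(ids, path) {
  writeLines(unique(ids), path)
  invisible(path)
}

#' Merge the two plasma sample-preparation panels
#'
#' Combines a primary plasma panel (e.g. a small-protein enrichment assay)
#' with a secondary panel (e.g. undepleted plasma): every protein of the
#' primary panel keeps the primary values; proteins detected only in the
#' secondary panel are appended with secondary values. Samples are restricted
#' to the intersection of the two panels' sample sets. The originating panel
#' of each protein is recorded in `rowData(..)$panel`.
#'
#' @param primary,secondary [TissueProteome-class] objects sharing the same
#'   tissue label and (at least partially) the same samples.
#' @return merged [TissueProteome-class].
#' @export
mergePlasmaPanels <- function(primary, secondary) {
  stopifnot(is(primary, "TissueProteome"), is(secondary, "TissueProteome"))
  if (!identical(tissueName(primary), tissueName(secondary)))
    .stopf("panels must share one tissue label ('%s' vs '%s')",
           tissueName(primary), tissueName(secondary))
  common <- intersect(sampleIds(primary), sampleIds(secondary))
  if (length(common) == 0L && length(proteinIds(secondary)) > 0L)
    .stopf("plasma panels share no samples; cannot merge")
  if (length(proteinIds(secondary)) == 0L)
    common <- sampleIds(primary)
  pm <- abundances(primary)[, common, drop = FALSE]
  extra <- setdiff(proteinIds(secondary), proteinIds(primary))
  sm <- abundances(secondary)[extra, common, drop = FALSE]
  merged <- rbind(pm, sm)
  TissueProteome(
    merged, tissue = tissueName(primary),
    rowData = DataFrame(panel = rep(c("primary", "secondary"),
                                    c(nrow(pm), nrow(sm))),
                        row.names = rownames(merged)),
    valueScale = valueScale(primary)
  )
}

#' Write a result table at full precision
#'
#' Generic TSV writer for the package's tabular outputs. Doubles are
#' serialized with 17 significant digits so that [readResultTable()]
#' reproduces them bit-comparably. Optional header metadata (e.g. seed,
#' configuration hash) is written as `# key: value` comment lines.
#'
#' @param table a non-empty-schema data.frame.
#' @param path output path.
#' @param meta optional named character vector written as comment lines.
#' @return `path`, invisibly.
#' @export
writeResultTable <- function(table, path, meta = NULL) {
  if (!is.data.frame(table) || ncol(table) == 0L)
    .stopf("result table must be a data.frame with at least one column")
  out <- as.data.frame(lapply(table, .formatFull), check.names = FALSE,
                        stringsAsFactors = FALSE, optional = TRUE)
  names(out) <- names(table)
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) .stopf("cannot write '%s': %s", path,
                                             conditionMessage(e)))
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(sprintf("# %s: %s", names(meta), unname(meta)), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname writeResultTable
#' @export
readResultTable <- function(path) {
  if (!file.exists(path)) .stopf("result table not found: %s", path)
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    comment.char = "#", check.names = FALSE)
}
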