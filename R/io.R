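#' Read a beta-value matrix with its sample sheet
#'
#' Reads a TSV of methylation beta values (first column = probe ids, header
#' row = sample ids) and a CSV sample sheet mapping `sample_id` to `group`
#' (and optionally `activity`). Cells that cannot be parsed as numbers
#' (e.g. `NA`) are kept as missing values, never zero-filled; resolve them
#' with [impute_missing()].
#'
#' @param path Path to the TSV matrix.
#' @param sample_sheet_path Path to the sample sheet CSV.
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(path, sample_sheet_path) {
  tab <- readr::read_tsv(path,
                         col_types = readr::cols(.default = readr::col_character()))
  probe_ids <- tab[[1]]
  if (anyDuplicated(probe_ids)) {
    abort(paste0("Duplicate probe id in ", path, ": ",
                 probe_ids[duplicated(probe_ids)][1]))
  }
  values <- vapply(tab[-1], function(col) suppressWarnings(as.numeric(col)),
                   numeric(nrow(tab)))
  values <- matrix(values, nrow = nrow(tab),
                   dimnames = list(probe_ids, names(tab)[-1]))
  samples <- readr::read_csv(sample_sheet_path, col_types = readr::cols())
  beta_matrix(values, samples)
}

#' Write a beta-value matrix to TSV (with sample sheet)
#'
#' Values are written with 6 significant digits; [read_beta_matrix()] on the
#' output round-trips within that formatting precision.
#'
#' @param x A [beta_matrix()].
#' @param path Output TSV path.
#' @param sample_sheet_path Optional output CSV path for the sample sheet.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(x, path, sample_sheet_path = NULL) {
  tab <- tibble::as_tibble(signif(x$values, 6), rownames = "probe_id")
  readr::write_tsv(tab, path)
  if (!is.null(sample_sheet_path)) {
    readr::write_csv(x$samples, sample_sheet_path)
  }
  invisible(path)
}

#' Read a Bismark coverage file
#'
#' Parses the 6-column Bismark coverage dialect (chrom, 1-based start, end,
#' percent methylation, count methylated, count unmethylated) into a
#' [cpg_counts()] table with `n_total = count_meth + count_unmeth` and
#' `pos = start`. Unsorted input is sorted on load (with a message);
#' duplicate positions and negative counts are errors; an empty file yields
#' an empty table with a warning.
#'
#' @param path Path to the `.cov` file.
#' @param sample_id Sample identifier to attach.
#' @param group `"control"` or `"case"`.
#' @param activity Optional activity score to attach.
#' @return A [cpg_counts()] object.
#' @export
read_bismark_cov <- function(path, sample_id, group, activity = NA_real_) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  if (file.size(path) == 0) {
    warn(paste0("Empty coverage file: ", path))
    return(cpg_counts(tibble::tibble(chrom = character(), pos = integer(),
                                     n_total = integer(), n_meth = integer()),
                      sample_id, group, activity))
  }
  tab <- readr::read_tsv(path, col_names = c("chrom", "start", "end",
                                             "pct_meth", "n_meth", "n_unmeth"),
                         col_types = "ciidii")
  if (any(tab$n_meth < 0) || any(tab$n_unmeth < 0)) {
    abort(paste0("Negative count in ", path, "."))
  }
  sites <- tibble::tibble(chrom = tab$chrom, pos = tab$start,
                          n_total = tab$n_meth + tab$n_unmeth,
                          n_meth = tab$n_meth)
  cpg_counts(sites, sample_id, group, activity)
}

#' Write a CpG count table as a Bismark coverage file
#'
#' @param x A [cpg_counts()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bismark_cov <- function(x, path) {
  pct <- ifelse(x$sites$n_total > 0,
                100 * x$sites$n_meth / x$sites$n_total, 0)
  tab <- tibble::tibble(chrom = x$sites$chrom, start = x$sites$pos,
                        end = x$sites$pos, pct = signif(pct, 6),
                        n_meth = x$sites$n_meth,
                        n_unmeth = x$sites$n_total - x$sites$n_meth)
  readr::write_tsv(tab, path, col_names = FALSE)
  invisible(path)
}

#' Write DMRs as a BED6 file
#'
#' Internal 1-based inclusive region coordinates are converted to BED's
#' 0-based half-open convention. The score column is
#' `-log10(region_p)` capped at 300 (a p of exactly zero maps to 300);
#' strand is always `"."` since CpG methylation is strand-collapsed here.
#'
#' @param dmrs A DMR tibble as returned by [call_dmrs()] (columns `chrom`,
#'   `start`, `end`, `region_p`; `direction` used in the name if present).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  if (nrow(dmrs) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  name <- paste0(dmrs$chrom, ":", dmrs$start, "-", dmrs$end,
                 if ("direction" %in% names(dmrs)) paste0("_", dmrs$direction)
                 else "")
  score <- pmin(-log10(dmrs$region_p), 300)
  bed <- tibble::tibble(chrom = dmrs$chrom, start = dmrs$start - 1L,
                        end = dmrs$end, name = name,
                        score = signif(score, 6), strand = ".")
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read a BED file into a 1-based interval tibble
#'
#' The inverse coordinate convention of [write_dmr_bed()]: BED's 0-based
#' half-open `[start, end)` becomes internal 1-based inclusive
#' `[start + 1, end]`.
#'
#' @param path Path to a BED3+ file.
#' @return A tibble with `chrom`, `start`, `end` (1-based inclusive) and any
#'   further BED columns (`name`, `score`, `strand`).
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  tab <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols())
  names(tab)[1:3] <- c("chrom", "start", "end")
  extra <- c("name", "score", "strand")
  if (ncol(tab) > 3) {
    names(tab)[4:min(6, ncol(tab))] <- extra[seq_len(min(3, ncol(tab) - 3))]
  }
  tab$start <- as.integer(tab$start) + 1L
  tab$end <- as.integer(tab$end)
  tab
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene symbols. Duplicate genes within a set are collapsed; empty
#' sets are skipped with a warning; duplicate set names are an error.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors (gene sets).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, 1L) < 2)
  if (length(short)) {
    abort(paste0("GMT line ", short[1],
                 " lacks the description column (fewer than 2 fields)."))
  }
  nm <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(nm)) {
    abort(paste0("Duplicate gene-set name: ", nm[duplicated(nm)][1]))
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- nm
  empty <- vapply(sets, length, 1L) == 0
  if (any(empty)) {
    warn(paste0("Skipping ", sum(empty), " empty gene set(s): ",
                paste(nm[empty], collapse = ", ")))
    sets <- sets[!empty]
  }
  sets
}

#' Read a probe annotation table
#'
#' CSV with columns `probe_id`, `chrom`, `pos` (1-based), `gene`
#' (may be empty) and `region_class` (e.g. promoter, TSS200, TSS1500,
#' body, intergenic).
#'
#' @param path Path to the CSV.
#' @return A tibble with one row per probe.
#' @export
read_probe_annotation <- function(path) {
  ann <- readr::read_csv(path, col_types = readr::cols(
    probe_id = readr::col_character(), chrom = readr::col_character(),
    pos = readr::col_integer(), gene = readr::col_character(),
    region_class = readr::col_character()))
  if (anyDuplicated(ann$probe_id)) {
    abort("Probe ids in annotation must be unique.")
  }
  if (any(ann$pos < 1)) abort("Annotation positions must be >= 1.")
  ann$gene[is.na(ann$gene)] <- ""
  ann
}

#' Read a methylation signature matrix
#'
#' CSV schema: first column `marker_id`, one further column per cell type,
#' values = reference methylation fractions in \[0,1\].
#'
#' @param path Path to the CSV.
#' @return A [signature_matrix()].
#' @export
read_signature_matrix <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols())
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab[[1]]
  signature_matrix(values)
}
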