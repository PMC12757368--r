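#' All overlapping pairs between two interval sets
#'
#' Intervals use BED-style 0-based half-open coordinates; a pair is
#' reported when the overlap is at least 1 bp. Matching is per chromosome
#' (strand is ignored throughout).
#'
#' @param a,b Data frames with columns `chrom`, `start` (0-based),
#'   `end` (exclusive).
#' @return A tibble `a_index`, `b_index` (row numbers into `a` and `b`),
#'   sorted by (`a_index`, `b_index`).
#' @export
intersect_intervals <- function(a, b) {
  a <- tibble::as_tibble(a); b <- tibble::as_tibble(b)
  stopifnot(all(a$start < a$end), all(b$start < b$end))
  out <- purrr::map_dfr(intersect(unique(a$chrom), unique(b$chrom)),
                        function(ch) {
    ia <- which(a$chrom == ch); ib <- which(b$chrom == ch)
    # to 1-based closed for IRanges
    ra <- IRanges::IRanges(start = a$start[ia] + 1L, end = a$end[ia])
    rb <- IRanges::IRanges(start = b$start[ib] + 1L, end = b$end[ib])
    hits <- IRanges::findOverlaps(ra, rb, minoverlap = 1L)
    tibble::tibble(a_index = ia[S4Vectors::queryHits(hits)],
                   b_index = ib[S4Vectors::subjectHits(hits)])
  })
  if (!nrow(out)) return(tibble::tibble(a_index = integer(),
                                        b_index = integer()))
  dplyr::arrange(out, .data$a_index, .data$b_index)
}

# internal 1-based inclusive -> 0-based half-open
to_bed0 <- function(x) {
  tibble::tibble(chrom = x$chrom, start = x$start - 1L, end = x$end)
}

#' Screen model DMRs by cross-platform gene evidence
#'
#' Disease-specific genes are the intersection of consensus DEGs and DMGs.
#' Each such gene's locus is the interval spanning its annotated probes
#' (minimum to maximum probe position) padded by `padding_bp` on both
#' sides; WGBS DMRs overlapping at least one locus are retained, in
#' deterministic (chrom, start) order.
#'
#' @param deg_genes,dmg_genes Character vectors of consensus gene symbols.
#' @param dmrs DMR tibble from [call_dmrs()].
#' @param ann Probe annotation tibble.
#' @param padding_bp Locus padding in bp (default 2000).
#' @return The retained rows of `dmrs`, with a `gene` column naming the
#'   (first) overlapping locus gene.
#' @export
screen_model_regions <- function(deg_genes, dmg_genes, dmrs, ann,
                                 padding_bp = 2000) {
  genes <- intersect(deg_genes, dmg_genes)
  if (!length(genes)) {
    warn("DEG/DMG gene intersection is empty; no model regions.")
    return(dplyr::mutate(dmrs[0, ], gene = character(0)))
  }
  hit <- ann[ann$gene %in% genes, ]
  loci <- dplyr::summarise(dplyr::group_by(hit, .data$gene),
                           chrom = dplyr::first(.data$chrom),
                           start = max(0L, min(.data$pos) - 1L - padding_bp),
                           end = max(.data$pos) + padding_bp,
                           .groups = "drop")
  if (!nrow(dmrs)) return(dplyr::mutate(dmrs, gene = character(0)))
  ov <- intersect_intervals(to_bed0(dmrs), loci)
  if (!nrow(ov)) {
    return(dplyr::mutate(dmrs[0, ], gene = character(0)))
  }
  first_hit <- dplyr::summarise(dplyr::group_by(ov, .data$a_index),
                                b_index = min(.data$b_index),
                                .groups = "drop")
  out <- dmrs[first_hit$a_index, ]
  out$gene <- loci$gene[first_hit$b_index]
  dplyr::arrange(out, .data$chrom, .data$start)
}

region_ids_of <- function(regions) {
  paste0(regions$chrom, ":", regions$start, "-", regions$end)
}

#' Build a WGBS feature matrix of region mean methylation
#'
#' The value of region r in sample s is the coverage-weighted pooled ratio
#' `sum(n_meth) / sum(n_total)` over the CpGs inside the region (1-based
#' inclusive bounds). Regions with zero coverage in a sample are missing
#' and then mean-imputed within the sample's group.
#'
#' @param regions DMR tibble (`chrom`, `start`, `end`).
#' @param tables List of [cpg_counts()] tables.
#' @return A [feature_matrix()] (samples x regions).
#' @export
build_feature_matrix_wgbs <- function(regions, tables) {
  ids <- region_ids_of(regions)
  vals <- purrr::map(tables, function(t) {
    s <- t$sites
    vapply(seq_len(nrow(regions)), function(j) {
      in_r <- s$chrom == regions$chrom[j] & s$pos >= regions$start[j] &
        s$pos <= regions$end[j]
      tot <- sum(s$n_total[in_r])
      if (tot > 0) sum(s$n_meth[in_r]) / tot else NA_real_
    }, numeric(1))
  })
  values <- do.call(rbind, vals)
  dimnames(values) <- list(purrr::map_chr(tables, "sample_id"), ids)
  samples <- tibble::tibble(
    sample_id = rownames(values),
    group = purrr::map_chr(tables, "group"),
    activity = purrr::map_dbl(tables, function(t) t$activity %||% NA_real_))
  # group-mean imputation of uncovered regions
  for (g in unique(samples$group)) {
    rows <- which(samples$group == g)
    sub <- values[rows, , drop = FALSE]
    cm <- colMeans(sub, na.rm = TRUE)
    na_idx <- which(is.na(sub), arr.ind = TRUE)
    if (nrow(na_idx)) sub[na_idx] <- cm[na_idx[, 2]]
    values[rows, ] <- sub
  }
  feature_matrix(values, samples)
}

#' Project model regions onto an array cohort
#'
#' The value of region r in sample s is the unweighted mean beta of the
#' probes whose annotated position lies inside the region. Regions covered
#' by no probe are dropped from the matrix (message) — drop them from any
#' companion matrix too, to keep feature spaces aligned.
#'
#' @param regions DMR tibble (`chrom`, `start`, `end`).
#' @param beta A [beta_matrix()].
#' @param ann Probe annotation tibble.
#' @return A [feature_matrix()] (samples x surviving regions).
#' @export
project_features_array <- function(regions, beta, ann) {
  ids <- region_ids_of(regions)
  ann <- ann[ann$probe_id %in% rownames(beta$values), ]
  probe_rows <- purrr::map(seq_len(nrow(regions)), function(j) {
    ann$probe_id[ann$chrom == regions$chrom[j] &
                   ann$pos >= regions$start[j] & ann$pos <= regions$end[j]]
  })
  covered <- lengths(probe_rows) > 0
  if (any(!covered)) {
    inform(paste0("Dropping ", sum(!covered),
                  " region(s) covered by no probe."))
  }
  values <- vapply(which(covered), function(j) {
    colMeans(beta$values[probe_rows[[j]], , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(beta$values)))
  values <- matrix(values, nrow = ncol(beta$values),
                   dimnames = list(colnames(beta$values), ids[covered]))
  feature_matrix(values, beta$samples)
}

#' Annotate DMRs with TSS distance and regulatory context
#'
#' For each DMR: the distance to the nearest transcription start site
#' (0 when a TSS falls inside the region) and a regulatory-element class —
#' the most common `region_class` among probes inside the region, or
#' `"intergenic"` when no probe falls inside.
#'
#' @param dmrs DMR tibble (`chrom`, `start`, `end`).
#' @param ann Probe annotation tibble.
#' @param tss_table Tibble with `gene`, `chrom`, `tss` (1-based position).
#' @return The input rows plus `tss_distance`, `nearest_gene` and
#'   `region_class`; ready for histogramming.
#' @export
annotate_dmr_context <- function(dmrs, ann, tss_table) {
  if (is.null(tss_table) || !nrow(tss_table)) {
    abort("`tss_table` must contain at least one TSS.")
  }
  res <- purrr::map_dfr(seq_len(nrow(dmrs)), function(j) {
    same <- tss_table[tss_table$chrom == dmrs$chrom[j], ]
    if (nrow(same)) {
      d <- pmax(0, pmax(dmrs$start[j] - same$tss, same$tss - dmrs$end[j]))
      k <- which.min(d)
      dist <- d[k]; gene <- same$gene[k]
    } else {
      dist <- NA_real_; gene <- NA_character_
    }
    inside <- ann$chrom == dmrs$chrom[j] & ann$pos >= dmrs$start[j] &
      ann$pos <= dmrs$end[j]
    cls <- if (any(inside)) {
      names(sort(table(ann$region_class[inside]), decreasing = TRUE))[1]
    } else "intergenic"
    tibble::tibble(tss_distance = dist, nearest_gene = gene,
                   region_class = cls)
  })
  dplyr::bind_cols(tibble::as_tibble(dmrs), res)
}
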