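#' Read an association catalog from TSV
#'
#' Reads a tab-separated catalog of case-control association records and
#' validates each row: genotype frequency triples must sum to 1 (within
#' 1e-6), sample_size must equal n_cases + n_controls, and p_value must
#' lie in (0, 1]. Invalid rows are dropped with a warning naming their
#' row numbers; valid rows are kept.
#'
#' @param path TSV file with the catalog columns (see
#'   [AssociationCatalog-class]).
#' @return An [AssociationCatalog-class]. Rejected row indices (in file
#'   order) are attached as attribute `"rejected"` of the records.
#' @export
readAssociationCatalog <- function(path) {
  stopIfNot(file.exists(path), paste("no such catalog file:", path))
  rec <- readTsv(path)
  missing_cols <- setdiff(CATALOG_COLUMNS, names(rec))
  stopIfNot(length(missing_cols) == 0L,
            paste("catalog header missing columns:",
                  paste(missing_cols, collapse = ", ")))
  rec <- rec[CATALOG_COLUMNS]
  fc <- rec$freq0_cases + rec$freq1_cases + rec$freq2_cases
  fn <- rec$freq0_controls + rec$freq1_controls + rec$freq2_controls
  freq_mat <- as.matrix(rec[grep("^freq", names(rec))])
  bad <- abs(fc - 1) > 1e-6 | abs(fn - 1) > 1e-6 |
    rec$sample_size != rec$n_cases + rec$n_controls |
    rec$p_value <= 0 | rec$p_value > 1 |
    rowSums(freq_mat < 0) > 0 |
    !stats::complete.cases(rec[c("disease", "snp_id", "p_value",
                                 "n_cases", "n_controls", "sample_size")])
  if (any(bad))
    warning(sprintf("rejected %d invalid catalog row(s): %s", sum(bad),
                    paste(which(bad), collapse = ", ")), call. = FALSE)
  out <- rec[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- which(bad)
  new("AssociationCatalog", records = out)
}

#' Write an association catalog to TSV
#'
#' @param catalog An [AssociationCatalog-class].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeAssociationCatalog <- function(catalog, path) {
  writeTsv(records(catalog), path)
}

#' Keep SNPs with at least one genome-wide significant study
#'
#' A SNP x disease pair is retained if and only if at least one of its
#' studies both matches the requested ancestry label (exact string
#' equality) and has `p_value` below the threshold. All studies of a
#' retained SNP are kept, so that subsequent likelihood-ratio estimation
#' can weight across them.
#'
#' @param catalog An [AssociationCatalog-class].
#' @param ancestry ancestry label the qualifying study must carry
#'   (default "European").
#' @param threshold significance threshold (default 1e-6).
#' @return A filtered [AssociationCatalog-class] (possibly empty).
#' @export
filterSignificant <- function(catalog, ancestry = "European",
                              threshold = 1e-6) {
  rec <- records(catalog)
  if (!nrow(rec)) return(catalog)
  key <- paste(rec$disease, rec$snp_id, sep = "\r")
  hit <- rec$p_value < threshold & rec$ancestry == ancestry
  keep_keys <- unique(key[hit])
  out <- rec[key %in% keep_keys, , drop = FALSE]
  rownames(out) <- NULL
  new("AssociationCatalog", records = out)
}

#' Read a pairwise r-squared table
#'
#' @param path TSV with columns snp_a, snp_b, r2.
#' @return data.frame(snp_a, snp_b, r2) with r2 validated to lie in
#'   \[0, 1\].
#' @export
readLdInfo <- function(path) {
  ld <- readTsv(path)
  stopIfNot(all(c("snp_a", "snp_b", "r2") %in% names(ld)),
            "LD file needs columns snp_a, snp_b, r2")
  stopIfNot(all(ld$r2 >= 0 & ld$r2 <= 1), "r2 values must lie in [0,1]")
  ld
}

## Haplotype-block membership: connected components of the graph whose
## edges are SNP pairs with r2 >= threshold (transitive closure, so the
## result is order-independent). Returns a named vector snp -> block.
ldBlocks <- function(snpIds, ld, r2Threshold) {
  blocks <- stats::setNames(paste0("singleton_", snpIds), snpIds)
  edges <- ld[ld$r2 >= r2Threshold &
                ld$snp_a %in% snpIds & ld$snp_b %in% snpIds, , drop = FALSE]
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges[c("snp_a", "snp_b")],
                                       directed = FALSE,
                                       vertices = unique(c(edges$snp_a,
                                                           edges$snp_b)))
    comp <- igraph::components(g)
    blocks[names(comp$membership)] <- paste0("ldblock_", comp$membership)
  }
  blocks
}

#' Prune linked SNPs to the most significant site per haplotype block
#'
#' Within each group of SNPs mutually linked at `r2 >= r2Threshold`
#' (connected components of the linkage graph, or a shared `block_id`
#' when no pairwise table is supplied), only the SNP with the smallest
#' best P-value across its studies is retained; ties are broken by
#' (chrom, pos, snp_id). SNPs absent from the LD information are treated
#' as their own block, with a warning. Pruning is performed per disease.
#'
#' @param catalog An [AssociationCatalog-class].
#' @param ld optional data.frame(snp_a, snp_b, r2) as from [readLdInfo()];
#'   when `NULL`, the catalog's `block_id` column is used.
#' @param r2Threshold linkage threshold (default 0.8).
#' @return A pruned [AssociationCatalog-class].
#' @export
ldPrune <- function(catalog, ld = NULL, r2Threshold = 0.8) {
  rec <- records(catalog)
  if (!nrow(rec)) return(catalog)
  if (is.null(ld)) {
    noInfo <- is.na(rec$block_id) | rec$block_id == ""
    if (any(noInfo)) {
      warning(sprintf("%d SNP(s) without LD information treated as their own block",
                      length(unique(rec$snp_id[noInfo]))), call. = FALSE)
      rec$block_id[noInfo] <- paste0("singleton_", rec$snp_id[noInfo])
    }
    block <- rec$block_id
  } else {
    ids <- unique(rec$snp_id)
    inLd <- ids %in% c(ld$snp_a, ld$snp_b)
    if (any(!inLd))
      warning(sprintf("%d SNP(s) without LD information treated as their own block",
                      sum(!inLd)), call. = FALSE)
    map <- ldBlocks(ids, ld, r2Threshold)
    block <- unname(map[rec$snp_id])
  }
  ## best (smallest) P per SNP x disease, then one winner per block x disease
  key <- paste(rec$disease, rec$snp_id, sep = "\r")
  bestP <- tapply(rec$p_value, key, min)
  snpRow <- !duplicated(key)
  snpTab <- data.frame(disease = rec$disease[snpRow],
                       snp_id = rec$snp_id[snpRow],
                       chrom = rec$chrom[snpRow], pos = rec$pos[snpRow],
                       block = block[snpRow],
                       best_p = as.vector(bestP[key[snpRow]]),
                       stringsAsFactors = FALSE)
  ord <- order(snpTab$disease, snpTab$block, snpTab$best_p,
               snpTab$chrom, snpTab$pos, snpTab$snp_id)
  snpTab <- snpTab[ord, ]
  winner <- snpTab[!duplicated(paste(snpTab$disease, snpTab$block, sep = "\r")), ]
  keep <- key %in% paste(winner$disease, winner$snp_id, sep = "\r")
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  new("AssociationCatalog", records = out)
}

#' Flag strand-ambiguous records
#'
#' A/T and C/G SNPs cannot be oriented across strand flips; they are
#' excluded from genotype matching by default.
#'
#' @param catalog An [AssociationCatalog-class].
#' @return Logical vector, one entry per record.
#' @export
strandAmbiguous <- function(catalog) {
  rec <- records(catalog)
  isStrandAmbiguous(rec$effect_allele, rec$other_allele)
}
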