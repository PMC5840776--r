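# Plate-level Z-scoring, viability filtering, phenotype classification and
# hit-table summaries for the migration screen.

SCREEN_CATEGORIES <- c("impaired", "accelerated", "hgf_impaired",
                       "hgf_accelerated", "none")
GENE_CLASSES <- c("GTPase", "GEF", "GAP", "effector", "other")

#' Plate Z-score
#'
#' The Z-score of a gene is the difference between its per-gene plate
#' mean and the mean over all genes on the plate, divided by the SD over
#' all genes on the plate (sample SD, n-1 denominator).
#'
#' @param values Named numeric vector of per-gene plate means (one value
#'   per gene; replicates are averaged beforehand).
#' @param gene Optional gene label; if omitted, Z-scores for all genes
#'   are returned.
#' @return Z-score(s), dimensionless.
#' @export
zscore <- function(values, gene = NULL) {
  if (length(values) < 3L)
    stop("plate Z-scores require at least 3 genes", call. = FALSE)
  if (any(!is.finite(values))) stop("non-finite plate values", call. = FALSE)
  s <- sd(values)
  if (s == 0) stop("plate SD is zero; Z-scores undefined", call. = FALSE)
  z <- (values - mean(values)) / s
  if (is.null(gene)) z else {
    if (!gene %in% names(values)) stop("unknown gene: ", gene, call. = FALSE)
    unname(z[gene])
  }
}

#' Viability index
#'
#' Ratio of fluorescence at 72 h to fluorescence at 48 h after
#' transfection; proliferating wells have a ratio above 1, dying wells
#' below 1. Plate Z-scores of the ratio flag low-viability wells
#' (Z < -1).
#'
#' @param f72,f48 Fluorescence readings (arbitrary units, nonnegative);
#'   `f48` must be positive.
#' @return The ratio `f72 / f48`, vectorized.
#' @export
viability_index <- function(f72, f48) {
  if (any(!is.finite(f72)) || any(!is.finite(f48)) || any(f72 < 0))
    stop("fluorescence values must be finite and nonnegative", call. = FALSE)
  if (any(f48 <= 0)) stop("'f48' must be positive", call. = FALSE)
  f72 / f48
}

#' Phenotype classification from migration Z-scores
#'
#' A gene is `impaired` if its basal-medium Z-score is below `-threshold`
#' and `accelerated` if above `+threshold` (strict inequalities). Genes
#' with no basal phenotype are `hgf_impaired` / `hgf_accelerated` when
#' only the HGF-medium Z-score crosses the threshold, and `none`
#' otherwise.
#'
#' @param z_basal,z_hgf Migration Z-scores in normal and HGF-supplemented
#'   medium (vectorized).
#' @param threshold Positive classification cutoff (default 1.0).
#' @return Character vector of categories.
#' @export
classify_phenotype <- function(z_basal, z_hgf, threshold = 1.0) {
  stopifnot_scalar(threshold)
  if (threshold <= 0) stop("'threshold' must be positive", call. = FALSE)
  if (length(z_basal) != length(z_hgf))
    stop("'z_basal' and 'z_hgf' must have equal length", call. = FALSE)
  out <- rep("none", length(z_basal))
  out[z_basal < -threshold] <- "impaired"
  out[z_basal > threshold] <- "accelerated"
  basal_quiet <- out == "none"
  out[basal_quiet & z_hgf < -threshold] <- "hgf_impaired"
  out[basal_quiet & z_hgf > threshold] <- "hgf_accelerated"
  out
}

#' Score a migration screen
#'
#' Averages replicate migration indices per gene and condition, computes
#' per-plate Z-scores for basal and HGF migration and for the viability
#' index, classifies each gene (see [classify_phenotype()]) and applies
#' the viability exclusion: a gene is excluded only when its viability
#' Z-score is below `viability_threshold` in every replicate screen.
#' Excluded genes are assigned category `none`.
#'
#' @param wells Data frame of well records with columns `gene_id`,
#'   `replicate`, `migration_index_basal`, `migration_index_hgf`,
#'   `fluor_48h`, `fluor_72h`.
#' @param classes Optional data frame with columns `gene_id`,
#'   `gene_class` (one of GTPase, GEF, GAP, effector, other).
#' @param threshold Migration Z-score cutoff (default 1.0).
#' @param viability_threshold Viability Z-score below which a well is
#'   called low-viability (default -1.0).
#' @return A hit-table data frame with one row per gene: `gene_id`,
#'   `gene_class` (if supplied), `z_basal`, `z_hgf`, `z_viability`
#'   (mean across replicates), `category`, `excluded`.
#' @export
score_screen <- function(wells, classes = NULL, threshold = 1.0,
                         viability_threshold = -1.0) {
  need <- c("gene_id", "replicate", "migration_index_basal",
            "migration_index_hgf", "fluor_48h", "fluor_72h")
  miss <- setdiff(need, names(wells))
  if (length(miss)) stop("wells table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  genes <- sort(unique(wells$gene_id))
  mean_by_gene <- function(v)
    vapply(split(v, wells$gene_id)[genes], mean, numeric(1))
  z_basal <- zscore(mean_by_gene(wells$migration_index_basal))
  z_hgf <- zscore(mean_by_gene(wells$migration_index_hgf))

  # viability: Z-score within each replicate screen, exclusion only if
  # low in all replicate screens
  ratio <- viability_index(wells$fluor_72h, wells$fluor_48h)
  reps <- sort(unique(wells$replicate))
  z_by_rep <- sapply(reps, function(r) {
    sel <- wells$replicate == r
    v <- setNames(ratio[sel], wells$gene_id[sel])[genes]
    zscore(v)
  })
  z_by_rep <- matrix(z_by_rep, nrow = length(genes),
                     dimnames = list(genes, reps))
  excluded <- apply(z_by_rep < viability_threshold, 1, all)
  category <- classify_phenotype(z_basal, z_hgf, threshold)
  category[excluded] <- "none"

  out <- data.frame(gene_id = genes,
                    z_basal = unname(z_basal),
                    z_hgf = unname(z_hgf),
                    z_viability = unname(rowMeans(z_by_rep)),
                    category = category,
                    excluded = unname(excluded),
                    stringsAsFactors = FALSE)
  if (!is.null(classes)) {
    if (!all(c("gene_id", "gene_class") %in% names(classes)))
      stop("'classes' needs columns gene_id, gene_class", call. = FALSE)
    out$gene_class <- classes$gene_class[match(out$gene_id, classes$gene_id)]
    out <- out[, c("gene_id", "gene_class", "z_basal", "z_hgf",
                   "z_viability", "category", "excluded")]
  }
  out
}

#' Summarize a hit table
#'
#' Counts hits per phenotype category and per gene class, and reports
#' the hit rate as a percentage of the screened library, rounded to the
#' nearest integer.
#'
#' @param hit_table Data frame with at least columns `gene_id` and
#'   `category`; `gene_class` is required for per-class counts.
#' @param library_size Number of genes screened. Defaults to the number
#'   of rows in `hit_table` (appropriate when the table covers the whole
#'   library, not only the hits).
#' @return A list with `n_category` (named counts over all five
#'   categories), `n_hgf_only` (hgf_impaired + hgf_accelerated),
#'   `n_hits`, `hit_percent`, and `n_class` (hits per gene class).
#' @export
summarize_hits <- function(hit_table, library_size = nrow(hit_table)) {
  if (!nrow(hit_table)) {
    zc <- setNames(integer(length(SCREEN_CATEGORIES)), SCREEN_CATEGORIES)
    return(list(n_category = zc, n_hgf_only = 0L, n_hits = 0L,
                hit_percent = 0,
                n_class = setNames(integer(length(GENE_CLASSES)), GENE_CLASSES)))
  }
  if (anyDuplicated(hit_table$gene_id))
    stop("duplicate gene_id in hit table", call. = FALSE)
  cat <- hit_table$category
  bad <- setdiff(unique(cat), SCREEN_CATEGORIES)
  if (length(bad)) stop("unknown category: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  n_category <- vapply(SCREEN_CATEGORIES, function(k) sum(cat == k), integer(1))
  hits <- cat != "none"
  n_class <- setNames(integer(length(GENE_CLASSES)), GENE_CLASSES)
  if ("gene_class" %in% names(hit_table)) {
    cls <- hit_table$gene_class[hits]
    badc <- setdiff(unique(cls), GENE_CLASSES)
    if (length(badc)) stop("unknown gene_class: ",
                           paste(badc, collapse = ", "), call. = FALSE)
    n_class <- vapply(GENE_CLASSES, function(k) sum(cls == k), integer(1))
  }
  list(n_category = n_category,
       n_hgf_only = unname(n_category["hgf_impaired"] +
                           n_category["hgf_accelerated"]),
       n_hits = sum(hits),
       hit_percent = round(100 * sum(hits) / library_size),
       n_class = n_class)
}

#' Transwell chemotaxis index
#'
#' Total number of migrated cells across all fields, divided by the
#' corresponding total for control-transfected cells.
#'
#' @param counts,control_counts Per-image cell counts (nonnegative).
#' @return Dimensionless index (1 = same as control).
#' @export
chemotaxis_index <- function(counts, control_counts) {
  if (any(counts < 0) || any(control_counts < 0))
    stop("cell counts must be nonnegative", call. = FALSE)
  tot <- sum(control_counts)
  if (tot <= 0) stop("control total must be positive", call. = FALSE)
  sum(counts) / tot
}

#' Published migration hit table
#'
#' The 51 significant migration hits of the 202-gene Rho-network siRNA
#' screen in PC3 prostate-cancer cells: gene symbol, RefSeq accession,
#' gene class, printed migration Z-score and phenotype category.
#' Categories are stored as published; BCR, which carries both GEF and
#' GAP domains, is classed as a GAP, the convention used for the
#' screen's per-class tallies.
#'
#' @return Data frame with columns `gene_id`, `accession`, `gene_class`,
#'   `zscore`, `category`.
#' @export
table1_hits <- function() {
  path <- system.file("extdata", "table1_hits.csv", package = "rhoscreen",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
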