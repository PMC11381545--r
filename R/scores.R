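#' Standardize species abundances across all samples
#'
#' z_ij = (A_ij - mu_i) / sigma_i, with mu_i and sigma_i taken over *all*
#' samples (zeros included) and the n-1 denominator for sigma. Zero-variance
#' species cannot be standardized and are dropped with a warning.
#'
#' @param abundances species x sample matrix.
#' @param species optional subset of species ids to standardize.
#' @return z-score matrix (species x samples).
#' @export
species_zscores <- function(abundances, species = NULL) {
  if (!is.null(species)) {
    if (length(species) == 0) stop("empty species subset")
    missing <- setdiff(species, rownames(abundances))
    if (length(missing) > 0)
      stop("species not in abundance matrix: ", paste(missing, collapse = ", "))
    abundances <- abundances[species, , drop = FALSE]
  }
  mu <- rowMeans(abundances)
  sigma <- apply(abundances, 1, stats::sd)
  keep <- sigma > 0
  if (!all(keep))
    warning("dropping ", sum(!keep), " zero-variance species: ",
            paste(rownames(abundances)[!keep], collapse = ", "))
  if (!any(keep)) stop("no species with positive variance")
  (abundances[keep, , drop = FALSE] - mu[keep]) / sigma[keep]
}

#' Aggregate standardized abundances of a species class
#'
#' Z(j) = (1 / sqrt(n)) * sum over the n class species of z_ij. With iid
#' standard-normal z the aggregate is standard normal for every class size n,
#' which makes Z_PCS and Z_TCS comparable across classes.
#'
#' @param zmatrix z-score matrix from [species_zscores()].
#' @param species_ids class member species (must be rows of `zmatrix`).
#' @return named numeric vector of per-sample aggregated scores.
#' @export
aggregate_group_score <- function(zmatrix, species_ids) {
  ids <- intersect(species_ids, rownames(zmatrix))
  if (length(ids) == 0) stop("class has no species in the z-score matrix")
  colSums(zmatrix[ids, , drop = FALSE]) / sqrt(length(ids))
}

#' Per-sample Z_PCS / Z_TCS score series
#'
#' Standardizes abundances over all samples and aggregates the PCS and TCS
#' classes; richness is the per-sample count of detected species when a
#' presence matrix is supplied.
#'
#' @param abundances species x sample matrix.
#' @param classification classified flux table ([classify_colonizers()]).
#' @param metadata sample metadata.
#' @param presence optional 0/1 matrix for species richness.
#' @return data.frame `sample_id`, `subject_id`, `visit_index`, `Z_PCS`,
#'   `Z_TCS`, and `richness` when presence is given.
#' @export
aggregate_scores <- function(abundances, classification, metadata,
                             presence = NULL) {
  md <- validate_metadata(metadata, samples = colnames(abundances))
  pcs <- classification$species_id[classification$class == "PCS"]
  tcs <- classification$species_id[classification$class == "TCS"]
  if (length(pcs) == 0) stop("no PCS species in the classification")
  if (length(tcs) == 0) stop("no TCS species in the classification")
  z <- species_zscores(abundances)
  out <- data.frame(sample_id = md$sample_id, subject_id = md$subject_id,
                    visit_index = md$visit_index,
                    Z_PCS = aggregate_group_score(z, pcs)[md$sample_id],
                    Z_TCS = aggregate_group_score(z, tcs)[md$sample_id],
                    stringsAsFactors = FALSE)
  if (!is.null(presence))
    out$richness <- colSums(presence[, md$sample_id, drop = FALSE] > 0)
  rownames(out) <- NULL
  out
}

#' Consecutive-visit score dynamics
#'
#' For every adjacent same-subject visit pair, the mean
#' mu = (Z_t + Z_t1) / 2 and change delta = Z_t1 - Z_t of each class score.
#'
#' @param scores score series from [aggregate_scores()].
#' @param metadata sample metadata.
#' @return pair table: `subject_id`, `visit_t`, `visit_t1`, `mu_PCS`,
#'   `delta_PCS`, `mu_TCS`, `delta_TCS`.
#' @export
consecutive_dynamics <- function(scores, metadata) {
  pairs <- consecutive_pairs(metadata)
  if (nrow(pairs) == 0) stop("no consecutive visit pairs")
  idx <- match(pairs$sample_t, scores$sample_id)
  idx1 <- match(pairs$sample_t1, scores$sample_id)
  data.frame(subject_id = pairs$subject_id,
             sample_t = pairs$sample_t, sample_t1 = pairs$sample_t1,
             visit_t = pairs$visit_t, visit_t1 = pairs$visit_t1,
             mu_PCS = (scores$Z_PCS[idx] + scores$Z_PCS[idx1]) / 2,
             delta_PCS = scores$Z_PCS[idx1] - scores$Z_PCS[idx],
             mu_TCS = (scores$Z_TCS[idx] + scores$Z_TCS[idx1]) / 2,
             delta_TCS = scores$Z_TCS[idx1] - scores$Z_TCS[idx],
             stringsAsFactors = FALSE)
}

#' Stratify consecutive-visit pairs by class enrichment
#'
#' A pair is `enriched` when its class mean score mu exceeds `hi`, `depleted`
#' below `lo`, otherwise `neither` (e.g. TCS-enriched individuals at
#' mu_TCS > 2).
#'
#' @param pair_table from [consecutive_dynamics()].
#' @param hi,lo stratification cutoffs (defaults +2 / -2).
#' @param class `"TCS"` or `"PCS"`.
#' @return factor of labels aligned with `pair_table` rows.
#' @export
stratify_individuals <- function(pair_table, hi = 2, lo = -2,
                                 class = c("TCS", "PCS")) {
  class <- match.arg(class)
  mu <- pair_table[[paste0("mu_", class)]]
  factor(ifelse(mu > hi, "enriched", ifelse(mu < lo, "depleted", "neither")),
         levels = c("enriched", "depleted", "neither"))
}

#' Jaccard similarity of consecutive-visit communities
#'
#' |intersection| / |union| of the present-species sets of adjacent visits;
#' when both sets are empty the similarity is undefined (`NA`).
#'
#' @param presence species x sample 0/1 matrix.
#' @param metadata sample metadata.
#' @return pair table with a `jaccard` column.
#' @export
jaccard_consecutive <- function(presence, metadata) {
  pairs <- consecutive_pairs(metadata)
  a <- presence[, pairs$sample_t, drop = FALSE] > 0
  b <- presence[, pairs$sample_t1, drop = FALSE] > 0
  inter <- colSums(a & b)
  uni <- colSums(a | b)
  pairs$jaccard <- ifelse(uni > 0, inter / uni, NA_real_)
  pairs
}

#' Compare community similarity between enriched and depleted pairs
#'
#' One-sided test that the class-enriched group is *less* similar between
#' visits than the class-depleted group (community destabilization). Both
#' the Wilcoxon rank-sum and Student's t versions are available.
#'
#' @param jaccard numeric similarity per pair.
#' @param labels factor from [stratify_individuals()] aligned with `jaccard`.
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @return list `test`, `p_value`, `n_enriched`, `n_depleted`.
#' @export
compare_similarity <- function(jaccard, labels, test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  x <- jaccard[labels == "enriched" & !is.na(jaccard)]
  y <- jaccard[labels == "depleted" & !is.na(jaccard)]
  if (length(x) < 2 || length(y) < 2)
    stop("need at least 2 pairs per group (enriched: ", length(x),
         ", depleted: ", length(y), ")")
  p <- if (test == "wilcoxon")
    suppressWarnings(stats::wilcox.test(x, y, alternative = "less"))$p.value
  else stats::t.test(x, y, alternative = "less")$p.value
  list(test = test, p_value = p, n_enriched = length(x),
       n_depleted = length(y))
}

#' Correlation between class-score changes and richness changes
#'
#' Spearman correlation between delta of the chosen class score and the
#' change in richness over the same consecutive-visit pairs. Richness is
#' species richness from the presence matrix, or gene richness when a gene
#' count matrix is supplied instead.
#'
#' @param counts species presence (0/1) or gene count matrix; richness is the
#'   number of nonzero rows per sample.
#' @param pair_table from [consecutive_dynamics()].
#' @param class `"PCS"` (default) or `"TCS"`.
#' @return list `rho`, `p_value`, and the augmented pair table.
#' @export
richness_dynamics <- function(counts, pair_table, class = c("PCS", "TCS")) {
  class <- match.arg(class)
  rich <- colSums(counts > 0)
  d_rich <- rich[pair_table$sample_t1] - rich[pair_table$sample_t]
  delta <- pair_table[[paste0("delta_", class)]]
  ct <- suppressWarnings(stats::cor.test(delta, d_rich, method = "spearman"))
  pair_table$delta_richness <- as.numeric(d_rich)
  list(rho = unname(ct$estimate), p_value = ct$p.value, pairs = pair_table)
}
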