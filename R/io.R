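#' Read a species-by-sample abundance table with its metadata
#'
#' The abundance TSV has species ids in the first column and one column per
#' sample; the metadata TSV has columns `sample_id`, `subject_id`,
#' `visit_index` and optionally `group`. Every abundance column must be
#' described in the metadata; offenders are named in the error.
#'
#' @param path abundance TSV.
#' @param metadata_path metadata TSV.
#' @return list with `abundance` (numeric matrix) and `metadata` (data.frame).
#' @export
read_abundance_table <- function(path, metadata_path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- tab[[1]]
  if (anyDuplicated(ids))
    stop("duplicate species ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (anyDuplicated(colnames(mat)))
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(colnames(mat)[duplicated(colnames(mat))]), collapse = ", "))
  if (!is.numeric(mat))
    stop("non-numeric abundance cells in ", path)
  if (any(mat < 0)) stop("negative abundances in ", path)
  rownames(mat) <- ids
  metadata <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  md <- validate_metadata(metadata, samples = colnames(mat))
  list(abundance = mat, metadata = md)
}

#' Write a matrix as the package's TSV dialect
#'
#' Tab-separated, header row of sample ids, first column of row ids, no
#' quoting. Round-trips through [read_abundance_table()].
#'
#' @param mat matrix with row and column names.
#' @param path output file.
#' @param id_column name of the first column.
#' @export
write_matrix_tsv <- function(mat, path, id_column = "species_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a species-to-marker-gene map
#'
#' @param path TSV with columns `species_id`, `gene_id`.
#' @return data.frame; errors if any species has no marker gene.
#' @export
read_marker_map <- function(path) {
  mm <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("species_id", "gene_id") %in% names(mm)))
    stop("marker map needs columns species_id, gene_id")
  if (any(is.na(mm$gene_id) | mm$gene_id == ""))
    stop("species with empty marker list in ", path)
  mm
}

#' Downsize gene counts to a fixed library size
#'
#' Each sample column is subsampled without replacement to exactly
#' `target_reads` (rarefaction); columns with fewer total reads than the
#' target are dropped and reported via the `"dropped_samples"` attribute and
#' a warning, mirroring the exclusion of under-sequenced samples.
#'
#' @param gene_counts integer gene x sample matrix.
#' @param target_reads library size after downsizing (default 10 million).
#' @param seed RNG seed for the subsample.
#' @return downsized count matrix (retained columns only); attribute
#'   `"dropped_samples"` lists excluded samples.
#' @export
downsize_counts <- function(gene_counts, target_reads = 1e7, seed = 1) {
  stopifnot(target_reads >= 1)
  if (any(gene_counts < 0) || any(gene_counts != round(gene_counts)))
    stop("gene counts must be non-negative integers")
  totals <- colSums(gene_counts)
  drop <- totals < target_reads
  if (any(drop))
    warning("dropping ", sum(drop), " sample(s) with fewer than ",
            format(target_reads, scientific = FALSE), " reads: ",
            paste(colnames(gene_counts)[drop], collapse = ", "))
  kept <- gene_counts[, !drop, drop = FALSE]
  out <- with_seed(substream_seed(seed, "downsize"), {
    apply(kept, 2, function(cnt) {
      tot <- sum(cnt)
      if (tot == target_reads) return(as.integer(cnt))
      # multivariate hypergeometric draw: sequential rhyper over genes
      remaining <- target_reads
      left <- tot
      res <- integer(length(cnt))
      for (i in seq_along(cnt)) {
        if (remaining == 0L) break
        res[i] <- stats::rhyper(1, cnt[i], left - cnt[i], remaining)
        remaining <- remaining - res[i]
        left <- left - cnt[i]
      }
      res
    })
  })
  if (ncol(kept) > 0) dimnames(out) <- dimnames(kept)
  attr(out, "dropped_samples") <- colnames(gene_counts)[drop]
  out
}

#' Quantify species abundance from marker-gene counts
#'
#' Species abundance is the arithmetic mean over *all* of the species' marker
#' genes (zero-count markers included). If fewer than 10% of a species'
#' markers have a nonzero count in a sample (strict `<`; exactly 10% is
#' retained), the species' abundance in that sample is set to 0. Columns are
#' then scaled to per-million (each nonzero column sums to 1e6).
#'
#' @param gene_counts gene x sample count matrix.
#' @param marker_map data.frame `species_id`, `gene_id`.
#' @param min_marker_fraction detection rule threshold (default 0.10).
#' @return species x sample abundance matrix on the per-million scale.
#' @export
mgs_abundance <- function(gene_counts, marker_map,
                          min_marker_fraction = 0.10) {
  mm <- marker_map[marker_map$gene_id %in% rownames(gene_counts), , drop = FALSE]
  n_markers <- table(marker_map$species_id)
  if (any(n_markers == 0) || !all(marker_map$gene_id %in% rownames(gene_counts)))
    stop("marker map references gene(s) absent from the count table")
  counts <- gene_counts[mm$gene_id, , drop = FALSE]
  sums <- rowsum(counts, group = mm$species_id)
  seen <- rowsum((counts > 0) + 0L, group = mm$species_id)
  nm <- as.numeric(n_markers[rownames(sums)])
  ab <- sums / nm
  ab[seen / nm < min_marker_fraction] <- 0
  tot <- colSums(ab)
  sweep(ab, 2, ifelse(tot > 0, tot, 1), "/") * 1e6
}
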