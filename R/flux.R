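#' Count two-state transitions over consecutive same-subject visits
#'
#' Pools, per species, the four transition-pair counts (absent->absent,
#' absent->present, present->absent, present->present) over all adjacent
#' observed visit pairs of every subject. Adjacency is defined by observed
#' visit order (a skipped visit index does not break a pair). Species present
#' in no sample or in every sample carry no transition information for a
#' two-state chain and are flagged `excluded`.
#'
#' @param presence species x sample 0/1 matrix.
#' @param metadata sample metadata (see [validate_metadata()]).
#' @return data.frame: `species_id`, `n_aa`, `n_ap`, `n_pa`, `n_pp`,
#'   `prevalence`, `excluded`; attribute `"n_pairs"` holds the number of
#'   consecutive pairs, which every species' four counts sum to.
#' @export
count_transitions <- function(presence, metadata) {
  md <- validate_metadata(metadata, samples = colnames(presence))
  single <- names(which(table(md$subject_id) < 2))
  if (length(single) > 0)
    warning("subject(s) with a single visit contribute no transition pairs: ",
            paste(single, collapse = ", "))
  pairs <- consecutive_pairs(md)
  if (nrow(pairs) == 0) stop("no consecutive same-subject visit pairs")
  a <- presence[, pairs$sample_t, drop = FALSE] > 0
  b <- presence[, pairs$sample_t1, drop = FALSE] > 0
  prev <- rowMeans(presence[, md$sample_id, drop = FALSE] > 0)
  out <- data.frame(species_id = rownames(presence),
                    n_aa = as.integer(rowSums(!a & !b)),
                    n_ap = as.integer(rowSums(!a & b)),
                    n_pa = as.integer(rowSums(a & !b)),
                    n_pp = as.integer(rowSums(a & b)),
                    prevalence = prev,
                    excluded = prev == 0 | prev == 1,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_pairs") <- nrow(pairs)
  out
}

#' Estimate inflow/outflow transition probabilities (microbial flux)
#'
#' Maximum-likelihood row-normalization of the pooled transition counts:
#' inflow = n_ap / (n_aa + n_ap) and outflow = n_pa / (n_pp + n_pa). A row
#' with a zero denominator has no observed transitions out of that state and
#' its probability is left `NA` (flagged, never imputed); species excluded
#' for 0% or 100% prevalence get `NA` for both.
#'
#' @param counts result of [count_transitions()].
#' @return data.frame `species_id`, counts, `inflow`, `outflow`,
#'   `prevalence`, `excluded`.
#' @export
estimate_flux <- function(counts) {
  req <- c("species_id", "n_aa", "n_ap", "n_pa", "n_pp")
  stopifnot(all(req %in% names(counts)))
  den_in <- counts$n_aa + counts$n_ap
  den_out <- counts$n_pp + counts$n_pa
  inflow <- ifelse(den_in > 0, counts$n_ap / den_in, NA_real_)
  outflow <- ifelse(den_out > 0, counts$n_pa / den_out, NA_real_)
  excl <- if ("excluded" %in% names(counts)) counts$excluded else FALSE
  inflow[excl] <- NA_real_
  outflow[excl] <- NA_real_
  out <- counts
  out$inflow <- inflow
  out$outflow <- outflow
  out
}

#' Classify persistent vs transient colonizing species
#'
#' PCS: inflow > `t_in` and outflow < `t_out` (appear and stay); TCS:
#' outflow > `t_out` and inflow < `t_in` (appear briefly and are lost).
#' Inequalities are strict; species at a threshold, stochastic colonizers,
#' and species with undefined probabilities are `UNCLASSIFIED`.
#'
#' @param flux result of [estimate_flux()].
#' @param t_in,t_out classification thresholds (defaults 0.3).
#' @return the flux table with a `class` column; thresholds kept as
#'   attributes `t_in`, `t_out`.
#' @export
classify_colonizers <- function(flux, t_in = 0.3, t_out = 0.3) {
  lab <- rep("UNCLASSIFIED", nrow(flux))
  ok <- !is.na(flux$inflow) & !is.na(flux$outflow)
  lab[ok & flux$inflow > t_in & flux$outflow < t_out] <- "PCS"
  lab[ok & flux$outflow > t_out & flux$inflow < t_in] <- "TCS"
  out <- flux
  out$class <- lab
  attr(out, "t_in") <- t_in
  attr(out, "t_out") <- t_out
  out
}

#' Compare two flux tables by rank correlation
#'
#' Spearman correlation of inflow and of outflow over the species shared by
#' two cohorts (e.g. discovery vs validation), the cross-cohort consistency
#' check for PCS/TCS assignments.
#'
#' @param flux_a,flux_b flux tables from [estimate_flux()].
#' @param min_shared minimum shared species with defined probabilities.
#' @return data.frame with rows `inflow` and `outflow`: `rho`, `p_value`,
#'   `n_shared`.
#' @export
compare_flux_estimates <- function(flux_a, flux_b, min_shared = 10) {
  m <- merge(flux_a[, c("species_id", "inflow", "outflow")],
             flux_b[, c("species_id", "inflow", "outflow")],
             by = "species_id", suffixes = c("_a", "_b"))
  res <- lapply(c("inflow", "outflow"), function(what) {
    x <- m[[paste0(what, "_a")]]; y <- m[[paste0(what, "_b")]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_shared)
      stop("only ", sum(ok), " shared species with defined ", what,
           " (need >= ", min_shared, ")")
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman"))
    data.frame(score = what, rho = unname(ct$estimate),
               p_value = ct$p.value, n_shared = sum(ok))
  })
  do.call(rbind, res)
}
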