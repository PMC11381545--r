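# Independent brute-force oracles used to cross-check the implementation.

# Naive per-species transition counting: explicit loops over subjects and
# ordered visits, no sharing with count_transitions()/estimate_flux().
oracle_flux <- function(presence, metadata) {
  md <- metadata[order(metadata$subject_id, metadata$visit_index), ]
  out <- data.frame(species_id = rownames(presence),
                    n_aa = 0L, n_ap = 0L, n_pa = 0L, n_pp = 0L,
                    stringsAsFactors = FALSE)
  for (subj in unique(md$subject_id)) {
    ids <- md$sample_id[md$subject_id == subj]
    if (length(ids) < 2) next
    for (sp in seq_len(nrow(presence))) {
      for (t in seq_len(length(ids) - 1)) {
        from <- presence[sp, ids[t]] > 0
        to <- presence[sp, ids[t + 1]] > 0
        if (!from && !to) out$n_aa[sp] <- out$n_aa[sp] + 1L
        if (!from && to)  out$n_ap[sp] <- out$n_ap[sp] + 1L
        if (from && !to)  out$n_pa[sp] <- out$n_pa[sp] + 1L
        if (from && to)   out$n_pp[sp] <- out$n_pp[sp] + 1L
      }
    }
  }
  out$inflow <- ifelse(out$n_aa + out$n_ap > 0,
                       out$n_ap / (out$n_aa + out$n_ap), NA_real_)
  out$outflow <- ifelse(out$n_pp + out$n_pa > 0,
                        out$n_pa / (out$n_pp + out$n_pa), NA_real_)
  out
}

# Exhaustive hypergeometric upper tail: enumerate every possible hit set of
# the given size over the universe and count those overlapping the class by
# >= k.
oracle_hyper_upper <- function(n_universe, n_class, n_hits, k) {
  universe <- seq_len(n_universe)
  class_set <- seq_len(n_class)
  sets <- utils::combn(universe, n_hits)
  hits_ge <- sum(apply(sets, 2, function(s) length(intersect(s, class_set)) >= k))
  hits_ge / ncol(sets)
}

# Small presence matrix + metadata from a per-subject list of 0/1 vectors.
toy_cohort <- function(profiles_by_subject, species_ids = NULL) {
  n_species <- nrow(profiles_by_subject[[1]])
  if (is.null(species_ids)) species_ids <- sprintf("sp_%02d", seq_len(n_species))
  cols <- list(); meta <- list()
  for (s in seq_along(profiles_by_subject)) {
    m <- profiles_by_subject[[s]]
    ids <- sprintf("s%02d_v%02d", s, seq_len(ncol(m)))
    colnames(m) <- ids
    cols[[s]] <- m
    meta[[s]] <- data.frame(sample_id = ids,
                            subject_id = sprintf("subj_%02d", s),
                            visit_index = seq_len(ncol(m)),
                            stringsAsFactors = FALSE)
  }
  presence <- do.call(cbind, cols)
  rownames(presence) <- species_ids
  list(presence = presence, metadata = do.call(rbind, meta))
}
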