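#' Co-abundance network among colonizing species
#'
#' Pairwise Spearman correlations among all PCS and TCS species; edges are
#' kept where the Benjamini-Hochberg adjusted p-value falls below the
#' threshold, signed by the correlation.
#'
#' @param abundances species x sample matrix (>= 3 samples).
#' @param classification classified flux table.
#' @param p_adj_threshold BH-adjusted p cutoff for an edge (default 0.05).
#' @return data.frame of edges: `species_a`, `species_b`, `rho`, `p_value`,
#'   `p_adj`, `sign`; attribute `"n_tested"` gives the number of pairs.
#' @export
coabundance_network <- function(abundances, classification,
                                p_adj_threshold = 0.05) {
  if (ncol(abundances) < 3) stop("need at least 3 samples")
  ids <- classification$species_id[classification$class %in% c("PCS", "TCS")]
  ids <- intersect(ids, rownames(abundances))
  sub <- abundances[ids, , drop = FALSE]
  const <- apply(sub, 1, stats::sd) == 0
  if (any(const)) {
    warning("excluding constant species: ",
            paste(ids[const], collapse = ", "))
    sub <- sub[!const, , drop = FALSE]
    ids <- ids[!const]
  }
  if (length(ids) < 2) stop("fewer than 2 usable species")
  combs <- utils::combn(ids, 2)
  res <- apply(combs, 2, function(pr) {
    ct <- suppressWarnings(stats::cor.test(sub[pr[1], ], sub[pr[2], ],
                                           method = "spearman"))
    c(rho = unname(ct$estimate), p = ct$p.value)
  })
  edges <- data.frame(species_a = combs[1, ], species_b = combs[2, ],
                      rho = res["rho", ], p_value = res["p", ],
                      stringsAsFactors = FALSE)
  edges$p_adj <- stats::p.adjust(edges$p_value, method = "BH")
  n_tested <- nrow(edges)
  edges <- edges[edges$p_adj < p_adj_threshold, , drop = FALSE]
  edges$sign <- ifelse(edges$rho >= 0, "positive", "negative")
  rownames(edges) <- NULL
  attr(edges, "n_tested") <- n_tested
  edges
}

#' Function enrichment against inflow/outflow scores
#'
#' For each binary function annotation, a univariate linear regression of the
#' species' inflow (or outflow) score on the annotation. A function is
#' flagged enriched when its BH-adjusted p-value is below `p_adj_threshold`
#' and the coefficient is positive (functions over-represented among
#' persistent colonizers for inflow, transient for outflow). Functions
#' present in no or all species have no contrast and are skipped.
#'
#' @param flux flux table with defined scores for >= 10 species.
#' @param annotations species x function 0/1 matrix (rownames = species ids).
#' @param score `"inflow"` or `"outflow"`.
#' @param p_adj_threshold adjusted-p cutoff (default 1e-3).
#' @return data.frame per function: `function_id`, `coefficient`, `p_value`,
#'   `p_adj`, `enriched`.
#' @export
function_enrichment <- function(flux, annotations,
                                score = c("inflow", "outflow"),
                                p_adj_threshold = 1e-3) {
  score <- match.arg(score)
  common <- intersect(flux$species_id, rownames(annotations))
  y <- flux[[score]][match(common, flux$species_id)]
  ok <- !is.na(y)
  y <- y[ok]; common <- common[ok]
  if (length(y) < 10)
    stop("need >= 10 species with a defined ", score, " score")
  ann <- annotations[common, , drop = FALSE]
  res <- lapply(colnames(ann), function(f) {
    x <- ann[, f]
    if (all(x == x[1])) return(NULL)  # no contrast
    fit <- summary(stats::lm(y ~ x))$coefficients
    data.frame(function_id = f, coefficient = fit["x", "Estimate"],
               p_value = fit["x", "Pr(>|t|)"], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no function with a usable contrast")
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out$enriched <- out$p_adj < p_adj_threshold & out$coefficient > 0
  rownames(out) <- NULL
  out
}

#' Two-group differential abundance by Wilcoxon rank-sum tests
#'
#' Per-species two-sided rank-sum test between the groups; species with
#' p < `p_threshold` are split into enriched/depleted by the direction of
#' the case-vs-control median shift (ties broken by mean). Species that are
#' all-zero in both groups are skipped.
#'
#' @param abundances species x sample matrix.
#' @param groups two-level factor aligned with the columns; the second level
#'   is treated as the case group.
#' @param p_threshold significance cutoff (default 0.01).
#' @return list `table` (per-species statistics), `enriched`, `depleted`
#'   (character vectors of species ids).
#' @export
differential_abundance <- function(abundances, groups, p_threshold = 0.01) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  if (any(table(groups) < 3)) stop("each group needs >= 3 samples")
  g1 <- groups == levels(groups)[1]
  g2 <- groups == levels(groups)[2]
  res <- lapply(rownames(abundances), function(sp) {
    x <- abundances[sp, g1]; y <- abundances[sp, g2]
    if (all(x == 0) && all(y == 0)) return(NULL)
    p <- suppressWarnings(stats::wilcox.test(y, x)$p.value)
    shift <- stats::median(y) - stats::median(x)
    if (shift == 0) shift <- mean(y) - mean(x)
    data.frame(species_id = sp, p_value = p, shift = shift,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  if (is.null(tab)) stop("no species with nonzero abundance")
  sig <- !is.na(tab$p_value) & tab$p_value < p_threshold
  list(table = tab,
       enriched = tab$species_id[sig & tab$shift > 0],
       depleted = tab$species_id[sig & tab$shift < 0])
}

#' Overlap enrichment of a hit set with a species class
#'
#' Builds the 2x2 hit x class contingency table over the universe and tests
#' over-representation of the class among the hits with a Pearson chi-square
#' test and the exact hypergeometric upper tail P(X >= overlap).
#'
#' @param hit_set,class_set subsets of `universe` (e.g. disease-enriched
#'   species and TCS).
#' @param universe all species considered.
#' @return object of class `enrichment_result`: `table` (2x2 counts),
#'   `odds_ratio`, `chisq_stat`, `chisq_p`, `hyper_p`, `direction`.
#' @export
overlap_enrichment <- function(hit_set, class_set, universe) {
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  hit_set <- unique(hit_set); class_set <- unique(class_set)
  if (!all(hit_set %in% universe) || !all(class_set %in% universe))
    stop("hit_set and class_set must be subsets of the universe")
  k <- length(intersect(hit_set, class_set))
  a <- k
  b <- length(hit_set) - k
  c_ <- length(class_set) - k
  d <- length(universe) - length(hit_set) - length(class_set) + k
  tab <- matrix(c(a, b, c_, d), 2, 2, byrow = TRUE,
                dimnames = list(hit = c("hit", "not_hit"),
                                class = c("in_class", "not_in_class")))
  chi <- tryCatch(suppressWarnings(stats::chisq.test(tab, correct = FALSE)),
                  error = function(e) list(statistic = NA_real_,
                                           p.value = NA_real_))
  hyper_p <- stats::phyper(k - 1, length(class_set),
                           length(universe) - length(class_set),
                           length(hit_set), lower.tail = FALSE)
  expected <- length(hit_set) * length(class_set) / length(universe)
  out <- list(table = tab,
              odds_ratio = (a * d) / (b * c_),
              chisq_stat = unname(chi$statistic),
              chisq_p = chi$p.value,
              hyper_p = hyper_p,
              direction = if (k >= expected) "over" else "under")
  class(out) <- "enrichment_result"
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Overlap enrichment (", x$direction, "-represented)\n", sep = "")
  print(x$table)
  cat(sprintf("odds ratio %.3g; chi-square p = %.3g; hypergeometric p = %.3g\n",
              x$odds_ratio, x$chisq_p, x$hyper_p))
  invisible(x)
}

#' Mixed-model association of a phenotype with Z_PCS and Z_TCS
#'
#' Fits Y = Z_PCS * beta_PCS + Z_TCS * beta_TCS + u_subject + eps with a
#' per-subject random intercept (restricted maximum likelihood,
#' Satterthwaite p-values). When the fit is singular with every subject
#' observed once, or fails, the model falls back to ordinary least squares
#' with a warning.
#'
#' @param scores score series ([aggregate_scores()]).
#' @param phenotype data.frame `sample_id`, `phenotype` (numeric).
#' @param alpha significance flag cutoff (default 0.05).
#' @return object of class `association_result`: `coefficients` (term,
#'   estimate, se, p_value, ci_lower, ci_upper, significant),
#'   `random_intercept_var`, `residual_var`, `model` ("lmm" or "ols").
#' @export
mixed_model_association <- function(scores, phenotype, alpha = 0.05) {
  dat <- merge(scores, phenotype[, c("sample_id", "phenotype")],
               by = "sample_id")
  fit_ols <- function() {
    m <- stats::lm(phenotype ~ Z_PCS + Z_TCS, data = dat)
    co <- summary(m)$coefficients
    list(co = co[c("Z_PCS", "Z_TCS"), c("Estimate", "Std. Error", "Pr(>|t|)"),
                 drop = FALSE],
         ran = 0, res = summary(m)$sigma^2, model = "ols")
  }
  fit <- tryCatch({
    if (max(table(dat$subject_id)) < 2) stop("one sample per subject")
    m <- lmerTest::lmer(phenotype ~ Z_PCS + Z_TCS + (1 | subject_id),
                        data = dat)
    co <- stats::coef(summary(m))
    vc <- as.data.frame(lme4::VarCorr(m))
    list(co = co[c("Z_PCS", "Z_TCS"), c("Estimate", "Std. Error", "Pr(>|t|)"),
                 drop = FALSE],
         ran = vc$vcov[vc$grp == "subject_id"],
         res = vc$vcov[vc$grp == "Residual"], model = "lmm")
  }, error = function(e) {
    warning("mixed model unavailable (", conditionMessage(e),
            "); falling back to OLS")
    fit_ols()
  })
  est <- fit$co[, "Estimate"]; se <- fit$co[, "Std. Error"]
  out <- list(coefficients = data.frame(
    term = rownames(fit$co), estimate = unname(est), se = unname(se),
    p_value = unname(fit$co[, "Pr(>|t|)"]),
    ci_lower = unname(est - stats::qnorm(0.975) * se),
    ci_upper = unname(est + stats::qnorm(0.975) * se),
    significant = unname(fit$co[, "Pr(>|t|)"] < alpha),
    stringsAsFactors = FALSE),
    random_intercept_var = fit$ran, residual_var = fit$res,
    model = fit$model)
  class(out) <- "association_result"
  out
}

#' @export
print.association_result <- function(x, ...) {
  cat("Phenotype association (", x$model, ")\n", sep = "")
  print(x$coefficients, row.names = FALSE)
  cat(sprintf("random intercept var %.4g, residual var %.4g\n",
              x$random_intercept_var, x$residual_var))
  invisible(x)
}

#' Per-species mixed-model associations with a phenotype
#'
#' For each species, Y = A_i * beta_i + u_subject + eps with a random
#' intercept. Significance follows the explained-variance-of-fixed-effect
#' rule: var(fixed-effect predictions) /
#' (var(fixed) + var(random intercept) + var(residual)) — the marginal-R2
#' style decomposition — retained when it exceeds `variance_threshold`.
#' Zero-variance species are skipped.
#'
#' @param abundances species x sample matrix.
#' @param phenotype data.frame `sample_id`, `phenotype`.
#' @param metadata sample metadata.
#' @param variance_threshold retention cutoff on the explained-variance
#'   fraction (default 0.10).
#' @param species optional subset (e.g. PCS and TCS members only).
#' @return data.frame `species_id`, `beta`, `p_value`,
#'   `explained_variance`, `retained`, `model`.
#' @export
per_species_association <- function(abundances, phenotype, metadata,
                                    variance_threshold = 0.10,
                                    species = NULL) {
  md <- validate_metadata(metadata, samples = colnames(abundances))
  if (is.null(species)) species <- rownames(abundances)
  dat0 <- merge(md, phenotype[, c("sample_id", "phenotype")], by = "sample_id")
  repeated <- max(table(dat0$subject_id)) >= 2
  res <- lapply(species, function(sp) {
    a <- abundances[sp, dat0$sample_id]
    if (stats::sd(a) == 0) return(NULL)
    dat <- cbind(dat0, abundance = as.numeric(a))
    fit <- tryCatch({
      if (!repeated) stop("one sample per subject")
      m <- lmerTest::lmer(phenotype ~ abundance + (1 | subject_id),
                          data = dat)
      vc <- as.data.frame(lme4::VarCorr(m))
      co <- stats::coef(summary(m))
      list(beta = co["abundance", "Estimate"],
           p = co["abundance", "Pr(>|t|)"],
           var_fixed = stats::var(stats::predict(m, re.form = NA)),
           var_ran = vc$vcov[vc$grp == "subject_id"],
           var_res = vc$vcov[vc$grp == "Residual"], model = "lmm")
    }, error = function(e) {
      m <- stats::lm(phenotype ~ abundance, data = dat)
      co <- summary(m)$coefficients
      list(beta = co["abundance", "Estimate"],
           p = co["abundance", "Pr(>|t|)"],
           var_fixed = stats::var(stats::fitted(m)),
           var_ran = 0, var_res = summary(m)$sigma^2, model = "ols")
    })
    ev <- fit$var_fixed / (fit$var_fixed + fit$var_ran + fit$var_res)
    data.frame(species_id = sp, beta = fit$beta, p_value = fit$p,
               explained_variance = ev,
               retained = ev > variance_threshold, model = fit$model,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no species with positive variance")
  rownames(out) <- NULL
  out
}
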