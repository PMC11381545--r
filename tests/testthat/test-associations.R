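test_that("co-abundance edges capture exact monotone relations", {
  set.seed(1)
  base <- rlnorm(30)
  ab <- rbind(p1 = base, p2 = base, t1 = max(base) + 1 - base,
              noise = rlnorm(30))
  colnames(ab) <- sprintf("s%02d", 1:30)
  cls <- data.frame(species_id = rownames(ab),
                    class = c("PCS", "PCS", "TCS", "UNCLASSIFIED"))
  edges <- coabundance_network(ab, cls, p_adj_threshold = 0.05)
  dup <- edges[edges$species_a == "p1" & edges$species_b == "p2", ]
  expect_equal(dup$rho, 1)
  expect_equal(dup$sign, "positive")
  anti <- edges[edges$species_a == "p1" & edges$species_b == "t1", ]
  expect_equal(anti$rho, -1)
  expect_equal(anti$sign, "negative")
  expect_false(any(grepl("noise", c(edges$species_a, edges$species_b))))
  expect_equal(attr(edges, "n_tested"), 3)  # PCS/TCS members only
})

test_that("null co-abundance edge rate is controlled by BH", {
  set.seed(91)
  n_sp <- 40
  ab <- matrix(rlnorm(n_sp * 50), nrow = n_sp,
               dimnames = list(sprintf("sp%02d", 1:n_sp), sprintf("s%02d", 1:50)))
  cls <- data.frame(species_id = rownames(ab),
                    class = rep(c("PCS", "TCS"), n_sp / 2))
  edges <- coabundance_network(ab, cls, p_adj_threshold = 0.05)
  # 780 independent null tests: BH controls FDR at 5%
  expect_lte(nrow(edges), ceiling(0.05 * attr(edges, "n_tested")) + 2)
})

test_that("function enrichment has the closed-form coefficient", {
  set.seed(2)
  n <- 200
  flux <- data.frame(species_id = sprintf("sp%03d", 1:n),
                     inflow = runif(n), outflow = runif(n))
  ann <- cbind(f_all = 1L, f_half = rep(c(0L, 1L), n / 2),
               f_signal = rbinom(n, 1, 0.5))
  rownames(ann) <- flux$species_id
  flux$inflow <- flux$inflow + 0.3 * ann[, "f_signal"]
  res <- function_enrichment(flux, ann, score = "inflow")
  expect_false("f_all" %in% res$function_id)  # no contrast -> skipped
  rh <- res[res$function_id == "f_half", ]
  grp <- split(flux$inflow, ann[, "f_half"])
  expect_equal(rh$coefficient, mean(grp[["1"]]) - mean(grp[["0"]]))
  rs <- res[res$function_id == "f_signal", ]
  expect_true(rs$coefficient > 0 && rs$p_adj < 1e-3)
  expect_true(rs$enriched)
})

test_that("differential abundance recovers strong shifts and their direction", {
  cfg <- sim_config(n_subjects = 50, n_species = 100,
                    abundance_log_sd = 0.6, seed = 13)
  shifted <- sprintf("sp_%04d", 1:20)
  run <- simulate_case_control(cfg, shifted_species = shifted,
                               log2_fold_change = 3,
                               occupancy_increase = 0.4)
  da <- differential_abundance(run$abundance, run$groups, p_threshold = 0.01)
  hits <- intersect(da$enriched, shifted)
  expect_gte(length(hits), 18)  # >= 90% of the 20 shifted species
  expect_lte(length(setdiff(da$enriched, shifted)), 5)
})

test_that("null differential abundance is calibrated at alpha", {
  cfg <- sim_config(n_subjects = 50, n_species = 200, seed = 29)
  run <- simulate_case_control(cfg)  # no shift
  da <- differential_abundance(run$abundance, run$groups, p_threshold = 0.01)
  n_false <- length(da$enriched) + length(da$depleted)
  n_tested <- nrow(da$table)
  # observed false calls within the central 99% binomial band at alpha = 0.01
  expect_lte(n_false, qbinom(0.995, n_tested, 0.01))
})

test_that("hypergeometric overlap equals exhaustive enumeration", {
  # worked example: universe 10, class 4, 3 hits all in class -> 1/30
  u <- sprintf("sp%02d", 1:10)
  res <- overlap_enrichment(hit_set = u[1:3], class_set = u[1:4], universe = u)
  expect_equal(res$hyper_p, 1 / 30)
  expect_equal(res$direction, "over")
  expect_equal(sum(res$table), 10)

  set.seed(15)
  for (rep in 1:25) {
    N <- sample(4:15, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:N, 1)
    uni <- sprintf("e%02d", 1:N)
    hits <- sample(uni, n)
    k <- length(intersect(hits, uni[1:K]))
    res <- overlap_enrichment(hits, uni[1:K], uni)
    expect_equal(res$hyper_p, oracle_hyper_upper(N, K, n, k))
  }
})

test_that("degenerate overlaps behave as expected", {
  u <- sprintf("sp%02d", 1:12)
  disj <- overlap_enrichment(u[1:3], u[4:6], u)
  expect_equal(disj$hyper_p, 1)  # zero overlap: P(X >= 0) = 1
  full <- overlap_enrichment(u, u[1:4], u)
  expect_equal(full$table["hit", "in_class"], 4L)
  expect_equal(full$hyper_p, 1)  # hits = universe carries no signal
  expect_error(overlap_enrichment(u[1], u[2], character(0)), "empty universe")
})

test_that("chi-square and hypergeometric point the same way on strong signals", {
  u <- sprintf("sp%03d", 1:100)
  res <- overlap_enrichment(u[1:25], u[1:30], u)  # hits nested in class
  expect_lt(res$chisq_p, 0.01)
  expect_lt(res$hyper_p, 0.01)
  expect_equal(res$direction, "over")
})

test_that("BH adjustment is monotone in the raw p-value rank", {
  set.seed(3)
  p <- runif(50)^2
  adj <- p.adjust(p, "BH")
  expect_true(all(diff(adj[order(p)]) >= 0))
})

test_that("mixed model reduces to OLS without between-subject variance", {
  set.seed(41)
  n_subj <- 30; n_vis <- 4
  scores <- data.frame(sample_id = sprintf("s%03d", 1:(n_subj * n_vis)),
                       subject_id = rep(sprintf("u%02d", 1:n_subj), each = n_vis),
                       visit_index = rep(1:n_vis, n_subj),
                       Z_PCS = rnorm(n_subj * n_vis),
                       Z_TCS = rnorm(n_subj * n_vis))
  # noise centered within subject: the between-subject residual variance is
  # exactly zero, so the random-intercept estimate sits at the boundary
  eps <- rnorm(n_subj * n_vis)
  eps <- eps - ave(eps, scores$subject_id)
  ph <- data.frame(sample_id = scores$sample_id,
                   phenotype = 0.4 * scores$Z_PCS - 0.2 * scores$Z_TCS + eps)
  res <- suppressWarnings(
    suppressMessages(mixed_model_association(scores, ph)))
  ols <- coef(lm(ph$phenotype ~ scores$Z_PCS + scores$Z_TCS))
  expect_equal(res$coefficients$estimate, unname(ols[2:3]), tolerance = 1e-6)
  expect_lt(res$random_intercept_var, 1e-8)
})

test_that("mixed model recovers generating coefficients within the 95% CI", {
  set.seed(52)
  n_subj <- 86; n_vis <- 4
  scores <- data.frame(sample_id = sprintf("s%03d", 1:(n_subj * n_vis)),
                       subject_id = rep(sprintf("u%02d", 1:n_subj), each = n_vis),
                       visit_index = rep(1:n_vis, n_subj),
                       Z_PCS = rnorm(n_subj * n_vis),
                       Z_TCS = rnorm(n_subj * n_vis))
  cfg <- sim_config(n_species = 2, beta_pcs = 0.5, beta_tcs = -0.5,
                    subject_random_sd = 0.5, residual_sd = 1, seed = 8)
  ph <- simulate_phenotype(scores, cfg)
  res <- mixed_model_association(scores, ph)
  co <- res$coefficients
  expect_equal(res$model, "lmm")
  expect_true(co$ci_lower[co$term == "Z_PCS"] < 0.5 &&
                co$ci_upper[co$term == "Z_PCS"] > 0.5)
  expect_true(co$ci_lower[co$term == "Z_TCS"] < -0.5 &&
                co$ci_upper[co$term == "Z_TCS"] > -0.5)
  expect_true(all(co$significant))
})

test_that("single-visit cohorts fall back to OLS with a warning", {
  set.seed(61)
  scores <- data.frame(sample_id = sprintf("s%02d", 1:40),
                       subject_id = sprintf("u%02d", 1:40),
                       visit_index = 1L,
                       Z_PCS = rnorm(40), Z_TCS = rnorm(40))
  ph <- data.frame(sample_id = scores$sample_id,
                   phenotype = scores$Z_PCS + rnorm(40, 0, 0.5))
  expect_warning(res <- mixed_model_association(scores, ph), "OLS")
  expect_equal(res$model, "ols")
})

test_that("per-species explained variance separates signal from noise", {
  set.seed(71)
  n_subj <- 40; n_vis <- 3; n <- n_subj * n_vis
  md <- data.frame(sample_id = sprintf("s%03d", 1:n),
                   subject_id = rep(sprintf("u%02d", 1:n_subj), each = n_vis),
                   visit_index = rep(1:n_vis, n_subj))
  ab <- matrix(rlnorm(3 * n), nrow = 3,
               dimnames = list(c("exact", "partial", "null"), md$sample_id))
  # fixed-effect variance share about 0.2 for "partial":
  # y = a + noise with var(a)/ (var(a) + var(noise)) = 0.2
  a <- scale(ab["partial", ])[, 1]
  ph_list <- list(
    exact = as.numeric(ab["exact", ]),
    partial = as.numeric(a + rnorm(n, 0, 2)),
    null = rnorm(n))
  for (sp in names(ph_list)) {
    ph <- data.frame(sample_id = md$sample_id, phenotype = ph_list[[sp]])
    res <- suppressWarnings(suppressMessages(
      per_species_association(ab, ph, md, species = sp)))
    if (sp == "exact") expect_gt(res$explained_variance, 0.95)
    if (sp == "partial") {
      expect_gt(res$explained_variance, 0.10)
      expect_lt(res$explained_variance, 0.35)
      expect_true(res$retained)
    }
    if (sp == "null") {
      expect_lt(res$explained_variance, 0.10)
      expect_false(res$retained)
    }
  }
})
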