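make_scored_cohort <- function(n_subj = 20, n_vis = 4, n_sp = 40, seed = 17) {
  cfg <- sim_config(n_subjects = n_subj, n_visits = n_vis, n_species = n_sp,
                    read_depth = 1e5, seed = seed)
  sim <- simulate_presence_paths(cfg)
  ab <- simulate_abundances(sim, cfg)
  flux <- classify_colonizers(estimate_flux(
    count_transitions(sim$presence, sim$metadata)))
  list(cfg = cfg, sim = sim, ab = ab, flux = flux)
}

test_that("standardization matches the n-1 convention and drops constants", {
  mat <- rbind(a = c(1, 3), b = c(5, 5))
  colnames(mat) <- c("s1", "s2")
  expect_warning(z <- species_zscores(mat), "zero-variance")
  expect_equal(unname(z["a", ]), c(-1, 1) / sqrt(2))  # sd = sqrt(2) with n-1
  expect_false("b" %in% rownames(z))
  expect_error(species_zscores(mat, species = character(0)), "empty")

  set.seed(4)
  big <- matrix(rlnorm(300), nrow = 10,
                dimnames = list(sprintf("sp%02d", 1:10), sprintf("s%02d", 1:30)))
  zb <- species_zscores(big)
  expect_equal(unname(rowMeans(zb)), rep(0, 10))
  expect_equal(unname(apply(zb, 1, sd)), rep(1, 10))
})

test_that("aggregated class score reduces to a single species at n = 1", {
  set.seed(6)
  z <- matrix(rnorm(30), nrow = 3,
              dimnames = list(c("a", "b", "c"), sprintf("s%02d", 1:10)))
  expect_equal(aggregate_group_score(z, "b"), z["b", ])
  expect_equal(aggregate_group_score(z, c("a", "b", "c")),
               colSums(z) / sqrt(3))
  z0 <- z; z0[, 1] <- 0
  expect_equal(unname(aggregate_group_score(z0, rownames(z))[1]), 0)
  expect_error(aggregate_group_score(z, "missing"), "no species")
})

test_that("aggregated score is standard normal for any class size", {
  set.seed(2024)
  n_samples <- 10000
  for (n in c(5, 50, 500)) {
    z <- matrix(rnorm(n * n_samples), nrow = n)
    agg <- colSums(z) / sqrt(n)
    expect_gt(ks.test(agg, "pnorm")$p.value, 0.01)
  }
})

test_that("consecutive dynamics compute mu and delta per pair", {
  scores <- data.frame(sample_id = c("s1", "s2", "s3"),
                       subject_id = "u", visit_index = 1:3,
                       Z_PCS = c(1, 3, 3), Z_TCS = c(0, -2, -2))
  md <- scores[, 1:3]
  pairs <- consecutive_dynamics(scores, md)
  expect_equal(pairs$mu_PCS, c(2, 3))
  expect_equal(pairs$delta_PCS, c(2, 0))
  expect_equal(pairs$mu_TCS, c(-1, -2))
  expect_equal(pairs$delta_TCS, c(-2, 0))
})

test_that("stratification cutoffs are strict and monotone in hi", {
  pairs <- data.frame(mu_TCS = c(2.5, -2.5, 0, 2, -2))
  lab <- stratify_individuals(pairs, class = "TCS")
  expect_equal(as.character(lab),
               c("enriched", "depleted", "neither", "neither", "neither"))
  n_enriched <- sapply(c(1, 2, 3), function(hi)
    sum(stratify_individuals(pairs, hi = hi, class = "TCS") == "enriched"))
  expect_true(all(diff(n_enriched) <= 0))
})

test_that("Jaccard similarity handles the standard set cases", {
  pres <- cbind(s1 = c(1, 1, 1, 0), s2 = c(0, 1, 1, 1),
                s3 = c(0, 1, 1, 1), s4 = c(1, 0, 0, 0))
  rownames(pres) <- c("A", "B", "C", "D")
  md <- data.frame(sample_id = paste0("s", 1:4), subject_id = "u",
                   visit_index = 1:4)
  jac <- jaccard_consecutive(pres, md)
  expect_equal(jac$jaccard, c(0.5, 1, 0))  # {A,B,C}v{B,C,D}; equal; disjoint
  # both-empty pair is NA-flagged
  pres0 <- cbind(s1 = c(0, 0), s2 = c(0, 0))
  rownames(pres0) <- c("A", "B")
  md0 <- data.frame(sample_id = c("s1", "s2"), subject_id = "u",
                    visit_index = 1:2)
  expect_true(is.na(jaccard_consecutive(pres0, md0)$jaccard))
})

test_that("similarity comparison is one-sided in the stated direction", {
  set.seed(10)
  jac <- c(runif(20, 0.2, 0.5), runif(20, 0.5, 0.9))
  labels <- factor(rep(c("enriched", "depleted"), each = 20),
                   levels = c("enriched", "depleted", "neither"))
  expect_lt(compare_similarity(jac, labels)$p_value, 0.05)
  # swapped direction: p near 1
  expect_gt(compare_similarity(jac, rev(labels))$p_value, 0.9)
  # identical groups: no shift
  same <- c(runif(30, 0.4, 0.6), runif(30, 0.4, 0.6))
  lab2 <- factor(rep(c("enriched", "depleted"), each = 30),
                 levels = levels(labels))
  p_same <- compare_similarity(same, lab2)$p_value
  expect_gt(p_same, 0.05)
  expect_lt(compare_similarity(jac, labels, test = "t")$p_value, 0.05)
  expect_error(compare_similarity(jac[1:3], labels[1:3]), "at least 2")
})

test_that("anti-correlated class dynamics are recovered", {
  set.seed(33)
  n <- 60
  delta_pcs <- rnorm(n)
  delta_tcs <- -delta_pcs + rnorm(n, 0, 0.3)
  rho <- suppressWarnings(cor.test(delta_pcs, delta_tcs,
                                   method = "spearman"))$estimate
  expect_lt(rho, -0.5)
})

test_that("richness dynamics recover constructed monotone relations", {
  set.seed(20)
  pairs <- data.frame(sample_t = sprintf("a%02d", 1:15),
                      sample_t1 = sprintf("b%02d", 1:15),
                      delta_PCS = rnorm(15))
  # presence matrix whose richness change is monotone in delta_PCS
  rank_d <- rank(pairs$delta_PCS)
  pres <- matrix(0L, nrow = 40, ncol = 30,
                 dimnames = list(sprintf("sp%02d", 1:40),
                                 c(pairs$sample_t, pairs$sample_t1)))
  for (i in 1:15) {
    pres[seq_len(10), pairs$sample_t[i]] <- 1L
    pres[seq_len(10 + rank_d[i]), pairs$sample_t1[i]] <- 1L
  }
  res <- richness_dynamics(pres, pairs, class = "PCS")
  expect_equal(unname(res$rho), 1)
  # sign flip
  pairs2 <- pairs; pairs2$delta_PCS <- -pairs$delta_PCS
  expect_equal(unname(richness_dynamics(pres, pairs2, "PCS")$rho), -1)
})

test_that("score series wire together on a simulated cohort", {
  sc <- make_scored_cohort(n_subj = 40, n_vis = 5, n_sp = 80, seed = 44)
  expect_true(any(sc$flux$class == "PCS") && any(sc$flux$class == "TCS"))
  scores <- aggregate_scores(sc$ab$abundance, sc$flux, sc$sim$metadata,
                             presence = sc$sim$presence)
  expect_true(all(is.finite(scores$Z_PCS)))
  pairs <- consecutive_dynamics(scores, sc$sim$metadata)
  expect_equal(nrow(pairs), 40 * 4)
  expect_true(all(c("mu_TCS", "delta_TCS") %in% names(pairs)))
})
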