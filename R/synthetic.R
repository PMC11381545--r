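#' Configuration for the synthetic longitudinal cohort
#'
#' Defines a cohort of `n_subjects` sampled at `n_visits` ordered visits, with
#' `n_species` species whose occupancy follows a per-species two-state Markov
#' chain (absence -> presence with probability `true_inflow`, presence ->
#' absence with probability `true_outflow`). When present, a species carries a
#' log-normal abundance mass; sequencing is emulated by multinomial read
#' sampling at `read_depth`. Defaults mirror the shape of a wellness-cohort
#' study: 86 subjects, 4 quarterly visits, hundreds of species, 100 marker
#' genes per species, 10 million reads per sample.
#'
#' Per-species parameters left `NULL` are drawn once, reproducibly from
#' `seed`: inflow/outflow uniform on (0.05, 0.95) and log-abundance means
#' normal with sd 1.5, so that cohorts span rare-to-common and
#' transient-to-persistent species.
#'
#' @param n_subjects,n_visits,n_species cohort dimensions (counts >= 1).
#' @param true_inflow,true_outflow per-species transition probabilities in
#'   \[0,1\]; scalars are recycled.
#' @param abundance_log_mean,abundance_log_sd per-species meanlog/sdlog of the
#'   log-normal abundance mass when present.
#' @param read_depth reads drawn per sample by the multinomial noise model.
#' @param n_markers_per_species marker genes per species for gene-level output.
#' @param beta_pcs,beta_tcs fixed-effect coefficients linking the aggregated
#'   Z_PCS/Z_TCS scores to a simulated phenotype.
#' @param subject_random_sd,residual_sd standard deviations of the per-subject
#'   random intercept and the residual in the phenotype model.
#' @param t_in,t_out classification thresholds used to derive the ground-truth
#'   PCS/TCS labels from the generating probabilities.
#' @param seed integer master seed; every stage derives its own substream.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 86, n_visits = 4, n_species = 300,
                       true_inflow = NULL, true_outflow = NULL,
                       abundance_log_mean = NULL, abundance_log_sd = 1,
                       read_depth = 1e7, n_markers_per_species = 100,
                       beta_pcs = 0, beta_tcs = 0,
                       subject_random_sd = 0.5, residual_sd = 1,
                       t_in = 0.3, t_out = 0.3, seed = 1) {
  stopifnot(n_subjects >= 1, n_visits >= 1, n_species >= 1,
            n_markers_per_species >= 1, read_depth >= 1,
            subject_random_sd >= 0, residual_sd >= 0,
            all(abundance_log_sd >= 0))
  if (is.null(true_inflow))
    true_inflow <- with_seed(substream_seed(seed, "config_inflow"),
                             stats::runif(n_species, 0.05, 0.95))
  if (is.null(true_outflow))
    true_outflow <- with_seed(substream_seed(seed, "config_outflow"),
                              stats::runif(n_species, 0.05, 0.95))
  if (is.null(abundance_log_mean))
    abundance_log_mean <- with_seed(substream_seed(seed, "config_abund"),
                                    stats::rnorm(n_species, 0, 1.5))
  true_inflow <- rep_len(true_inflow, n_species)
  true_outflow <- rep_len(true_outflow, n_species)
  abundance_log_mean <- rep_len(abundance_log_mean, n_species)
  abundance_log_sd <- rep_len(abundance_log_sd, n_species)
  if (any(true_inflow < 0 | true_inflow > 1) ||
      any(true_outflow < 0 | true_outflow > 1))
    stop("transition probabilities must lie in [0, 1]")
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_visits = as.integer(n_visits),
              n_species = as.integer(n_species),
              true_inflow = true_inflow, true_outflow = true_outflow,
              abundance_log_mean = abundance_log_mean,
              abundance_log_sd = abundance_log_sd,
              read_depth = read_depth,
              n_markers_per_species = as.integer(n_markers_per_species),
              beta_pcs = beta_pcs, beta_tcs = beta_tcs,
              subject_random_sd = subject_random_sd,
              residual_sd = residual_sd,
              t_in = t_in, t_out = t_out, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Read a simulation configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the arguments of [sim_config()].
#' @return a `sim_config` object.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(sim_config, vals)
}

truth_class <- function(inflow, outflow, t_in, t_out) {
  ifelse(inflow > t_in & outflow < t_out, "PCS",
         ifelse(outflow > t_out & inflow < t_in, "TCS", "UNCLASSIFIED"))
}

#' Simulate ground-truth presence/absence trajectories
#'
#' Each subject x species trajectory starts from the chain's stationary
#' distribution pi = inflow / (inflow + outflow) (pi := 0 when both are 0,
#' recorded in the truth table) and then follows the two-state chain across
#' visits. Starting at stationarity keeps the per-visit prevalence
#' time-homogeneous, which makes downstream recovery tests well posed.
#'
#' @param config a [sim_config()] object.
#' @param seed optional override of the config seed.
#' @return list with `presence` (species x samples 0/1 matrix), `metadata`
#'   (sample_id, subject_id, visit_index), `truth` (per-species generating
#'   parameters, stationary prevalence `pi`, and class label derived with the
#'   same thresholds as the classifier), and the `config`.
#' @export
simulate_presence_paths <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  ns <- config$n_species; nb <- config$n_subjects; nv <- config$n_visits
  inflow <- config$true_inflow; outflow <- config$true_outflow
  denom <- inflow + outflow
  pi0 <- ifelse(denom > 0, inflow / denom, 0)

  species_id <- sprintf("sp_%04d", seq_len(ns))
  subject_id <- sprintf("subj_%03d", seq_len(nb))
  metadata <- data.frame(
    sample_id = sprintf("%s_v%02d", rep(subject_id, each = nv),
                        rep(seq_len(nv), nb)),
    subject_id = rep(subject_id, each = nv),
    visit_index = rep(seq_len(nv), nb),
    stringsAsFactors = FALSE)

  presence <- with_seed(substream_seed(seed, "presence"), {
    P <- matrix(0L, nrow = ns, ncol = nb * nv)
    state <- matrix(stats::runif(ns * nb) < pi0, nrow = ns)  # visit 1
    P[, seq(1, by = nv, length.out = nb)] <- state + 0L
    if (nv > 1) {
      for (v in 2:nv) {
        u <- matrix(stats::runif(ns * nb), nrow = ns)
        state <- ifelse(state, u >= outflow, u < inflow)
        P[, seq(v, by = nv, length.out = nb)] <- state + 0L
      }
    }
    P
  })
  dimnames(presence) <- list(species_id, metadata$sample_id)

  truth <- data.frame(species_id = species_id,
                      true_inflow = inflow, true_outflow = outflow,
                      pi = pi0, degenerate_chain = denom == 0,
                      true_class = truth_class(inflow, outflow,
                                               config$t_in, config$t_out),
                      stringsAsFactors = FALSE)
  list(presence = presence, metadata = metadata, truth = truth,
       config = config)
}

#' Simulate abundances (and optionally marker-gene counts) from presence
#'
#' Present species receive a log-normal abundance mass, absent species zero;
#' each sample is renormalized to relative abundances. With
#' `noise = "multinomial"`, reads are drawn without structure at
#' `config$read_depth` per sample (species level), emulating sequencing-depth
#' noise; with `genes = TRUE` the species mass is first split uniformly over
#' its marker genes and a gene x sample count table is returned alongside the
#' marker map.
#'
#' @param sim result of [simulate_presence_paths()], or any list with
#'   `presence` and `metadata`.
#' @param config a [sim_config()].
#' @param noise `"multinomial"` (sequencing reads at `read_depth`) or
#'   `"none"` (exact relative abundances).
#' @param genes also emit a marker-gene count table and marker map.
#' @param seed optional override of the config seed.
#' @return list with `abundance` (species x samples, per-million scale),
#'   `metadata`, and when `genes = TRUE` also `gene_counts` and `marker_map`.
#' @export
simulate_abundances <- function(sim, config = sim$config,
                                noise = c("multinomial", "none"),
                                genes = FALSE, seed = config$seed) {
  noise <- match.arg(noise)
  presence <- sim$presence
  ns <- nrow(presence); nsamp <- ncol(presence)
  stopifnot(ns == config$n_species)

  rel <- with_seed(substream_seed(seed, "abundance"), {
    mass <- matrix(0, nrow = ns, ncol = nsamp, dimnames = dimnames(presence))
    idx <- which(presence == 1L)
    if (length(idx) > 0) {
      row_of <- ((idx - 1L) %% ns) + 1L
      mass[idx] <- stats::rlnorm(length(idx),
                                 meanlog = config$abundance_log_mean[row_of],
                                 sdlog = config$abundance_log_sd[row_of])
    }
    tot <- colSums(mass)
    if (any(tot == 0))
      warning("sample(s) with no present species produce all-zero columns: ",
              paste(colnames(mass)[tot == 0], collapse = ", "))
    sweep(mass, 2, ifelse(tot > 0, tot, 1), "/")
  })

  out <- list(metadata = sim$metadata, truth = sim$truth, config = config)
  if (genes) {
    nm <- config$n_markers_per_species
    gene_id <- sprintf("%s_g%03d", rep(rownames(rel), each = nm),
                       rep(seq_len(nm), ns))
    gene_prob <- rel[rep(seq_len(ns), each = nm), , drop = FALSE] / nm
    counts <- with_seed(substream_seed(seed, "reads"), {
      apply(gene_prob, 2, function(p) {
        if (sum(p) == 0) integer(length(p))
        else as.integer(stats::rmultinom(1, size = config$read_depth, prob = p))
      })
    })
    dimnames(counts) <- list(gene_id, colnames(rel))
    out$gene_counts <- counts
    out$marker_map <- data.frame(
      species_id = rep(rownames(rel), each = nm),
      gene_id = gene_id, stringsAsFactors = FALSE)
    sp_counts <- rowsum(counts, group = out$marker_map$species_id)[rownames(rel), ,
                                                                   drop = FALSE]
    out$abundance <- sweep(sp_counts, 2, rep(config$read_depth, nsamp), "/") * 1e6
  } else if (noise == "multinomial") {
    counts <- with_seed(substream_seed(seed, "reads"), {
      apply(rel, 2, function(p) {
        if (sum(p) == 0) integer(length(p))
        else as.integer(stats::rmultinom(1, size = config$read_depth, prob = p))
      })
    })
    dimnames(counts) <- dimnames(rel)
    out$abundance <- counts / config$read_depth * 1e6
  } else {
    out$abundance <- rel * 1e6
  }
  out
}

#' Simulate a host phenotype from aggregated colonizer scores
#'
#' Y = Z_PCS * beta_PCS + Z_TCS * beta_TCS + u_subject + eps, with
#' u ~ N(0, subject_random_sd^2) and eps ~ N(0, residual_sd^2) — the
#' generative mirror of the random-intercept association model.
#'
#' @param scores a score series with columns `sample_id`, `subject_id`,
#'   `Z_PCS`, `Z_TCS` (see [aggregate_scores()]).
#' @param config a [sim_config()] carrying the coefficients and sds.
#' @param seed optional override.
#' @return data.frame `sample_id`, `subject_id`, `phenotype`, plus the true
#'   subject intercepts as attribute `"subject_intercepts"`.
#' @export
simulate_phenotype <- function(scores, config, seed = config$seed) {
  stopifnot(all(c("sample_id", "subject_id", "Z_PCS", "Z_TCS") %in%
                  names(scores)))
  subjects <- unique(scores$subject_id)
  with_seed(substream_seed(seed, "phenotype"), {
    u <- stats::rnorm(length(subjects), 0, config$subject_random_sd)
    names(u) <- subjects
    eps <- stats::rnorm(nrow(scores), 0, config$residual_sd)
    y <- scores$Z_PCS * config$beta_pcs + scores$Z_TCS * config$beta_tcs +
      u[scores$subject_id] + eps
    out <- data.frame(sample_id = scores$sample_id,
                      subject_id = scores$subject_id,
                      phenotype = as.numeric(y), stringsAsFactors = FALSE)
    attr(out, "subject_intercepts") <- u
    out
  })
}

#' Simulate a two-group cross-sectional cohort with known shifted species
#'
#' Generates case and control samples whose species occupancy follows the
#' stationary prevalence of the configured chains; a designated subset of
#' species receives a log2 fold-change in abundance mass (and optionally an
#' occupancy increase) in cases. The truly shifted species are recorded so
#' differential-abundance recovery and overlap enrichment can be scored
#' against truth.
#'
#' @param config a [sim_config()]; `n_subjects` is the per-group sample size.
#' @param shifted_species character vector of species ids to perturb in cases
#'   (empty = null cohort).
#' @param log2_fold_change abundance shift applied to cases.
#' @param occupancy_increase added to the presence probability in cases
#'   (clamped to 1).
#' @param seed optional override.
#' @return list `abundance` (species x samples, per-million), `groups`
#'   (factor control/case per sample), `metadata`, `truth` (shifted ids).
#' @export
simulate_case_control <- function(config, shifted_species = character(0),
                                  log2_fold_change = 2,
                                  occupancy_increase = 0,
                                  seed = config$seed) {
  ns <- config$n_species; n <- config$n_subjects
  species_id <- sprintf("sp_%04d", seq_len(ns))
  stopifnot(all(shifted_species %in% species_id))
  denom <- config$true_inflow + config$true_outflow
  pi0 <- ifelse(denom > 0, config$true_inflow / denom, 0)
  shifted <- species_id %in% shifted_species

  with_seed(substream_seed(seed, "case_control"), {
    p_ctrl <- matrix(pi0, ns, n)
    p_case <- matrix(pmin(pi0 + occupancy_increase * shifted, 1), ns, n)
    pres <- cbind(matrix(stats::runif(ns * n), ns) < p_ctrl,
                  matrix(stats::runif(ns * n), ns) < p_case)
    mass <- matrix(0, ns, 2 * n)
    idx <- which(pres)
    row_of <- ((idx - 1L) %% ns) + 1L
    mass[idx] <- stats::rlnorm(length(idx),
                               meanlog = config$abundance_log_mean[row_of],
                               sdlog = config$abundance_log_sd[row_of])
    case_cols <- (n + 1):(2 * n)
    mass[shifted, case_cols] <- mass[shifted, case_cols] * 2^log2_fold_change
    tot <- colSums(mass)
    rel <- sweep(mass, 2, ifelse(tot > 0, tot, 1), "/") * 1e6
    sample_id <- c(sprintf("ctrl_%03d", seq_len(n)),
                   sprintf("case_%03d", seq_len(n)))
    dimnames(rel) <- list(species_id, sample_id)
    groups <- factor(rep(c("control", "case"), each = n),
                     levels = c("control", "case"))
    metadata <- data.frame(sample_id = sample_id,
                           subject_id = sample_id,
                           visit_index = 1L,
                           group = as.character(groups),
                           stringsAsFactors = FALSE)
    list(abundance = rel, groups = groups, metadata = metadata,
         truth = data.frame(species_id = species_id, shifted = shifted,
                            stringsAsFactors = FALSE))
  })
}
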