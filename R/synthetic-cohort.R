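# Seeded synthetic multi-omic cohorts with the statistical structure the
# screen assumes.
#
# A standard-normal latent angiogenic activity A_s drives everything:
#   panel gene g:      mu_g + beta_g * A_s + N(0, sigma)
#   planted miRNA m:   gaussian mode:  nu_m - gamma_m * A_s + N(0, sigma)
#                      count mode:     NB(mean = exp(nu_m - gamma_m * A_s),
#                                         dispersion)
#   null miRNA:        same forms with gamma = 0
#   vessel count:      Poisson(exp(alpha0 + alpha1 * A_s))
#   event time:        Exponential(h0 * exp(theta * A_s))
#   censoring:         min(Exponential(censor_rate), T_max)
#   methylation beta:  inverse-logit(delta0 + delta1 * A_s) + bounded noise,
#                      clipped to [0, 1]  (planted probes; nulls delta1 = 0)
#
# Every component draws from its own deterministic sub-stream (derived from
# the base seed and the component name), so adding a component never
# perturbs another's draws; identical configs give bit-identical cohorts.

#' Configuration for a synthetic cohort
#'
#' Defaults are the package's reference study conditions (see the methods
#' vignette): 400 samples, one planted miRNA with coupling 0.8 among 50
#' nulls, a 20-gene pro-angiogenic panel with unit effects, count-mode
#' miRNAs (negative binomial, dispersion 0.2), vessel counts centred at 24
#' per HPF, proportional-hazards survival with ~30% censoring, and four
#' planted methylation probes.
#'
#' @param n_samples number of samples (>= 4).
#' @param planted_mirnas data.frame with columns `mirna`, `gamma` (>= 0) and
#'   optionally `baseline` (Gaussian mean or log count mean).
#' @param n_null_mirnas number of uncoupled miRNAs (>= 0).
#' @param panel_genes data.frame with columns `gene`, `beta` (>= 0), `mu`.
#' @param noise_sd Gaussian noise SD sigma (> 0).
#' @param mirna_mode "counts" (negative binomial, log link) or "gaussian".
#' @param mirna_baseline default baseline for miRNAs without one (log-mean
#'   in count mode).
#' @param nb_dispersion negative-binomial dispersion (count mode).
#' @param mvd_intercept,mvd_slope log-scale Poisson rate coefficients for
#'   vessels per high-power field.
#' @param baseline_hazard h0 (> 0).
#' @param hazard_coupling theta (log hazard per unit latent activity).
#' @param censor_rate exponential censoring rate (>= 0; 0 = administrative
#'   censoring only).
#' @param admin_censor_time administrative censoring horizon T_max (> 0).
#' @param n_meth_planted,n_meth_null planted / null methylation probes.
#' @param meth_delta0,meth_delta1 logit-scale intercept and latent-activity
#'   slope of planted probe betas.
#' @param meth_noise_sd half-width of the uniform noise added to betas.
#' @param seed integer base seed.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 400L,
                          planted_mirnas = data.frame(
                            mirna = "mir-planted-1", gamma = 0.8),
                          n_null_mirnas = 50L,
                          panel_genes = data.frame(
                            gene = sprintf("ANGIO%02d", 1:20),
                            beta = 1, mu = 8),
                          noise_sd = 1,
                          mirna_mode = c("counts", "gaussian"),
                          mirna_baseline = log(500),
                          nb_dispersion = 0.2,
                          mvd_intercept = log(24),
                          mvd_slope = 0.5,
                          baseline_hazard = 0.1,
                          hazard_coupling = 0.8,
                          censor_rate = 0.01,
                          admin_censor_time = 15,
                          n_meth_planted = 4L,
                          n_meth_null = 8L,
                          meth_delta0 = 0,
                          meth_delta1 = 1,
                          meth_noise_sd = 0.05,
                          seed = 1L) {
  mirna_mode <- match.arg(mirna_mode)
  cfg <- list(n_samples = as.integer(n_samples),
              planted_mirnas = planted_mirnas,
              n_null_mirnas = as.integer(n_null_mirnas),
              panel_genes = panel_genes, noise_sd = noise_sd,
              mirna_mode = mirna_mode, mirna_baseline = mirna_baseline,
              nb_dispersion = nb_dispersion,
              mvd_intercept = mvd_intercept, mvd_slope = mvd_slope,
              baseline_hazard = baseline_hazard,
              hazard_coupling = hazard_coupling,
              censor_rate = censor_rate,
              admin_censor_time = admin_censor_time,
              n_meth_planted = as.integer(n_meth_planted),
              n_meth_null = as.integer(n_meth_null),
              meth_delta0 = meth_delta0, meth_delta1 = meth_delta1,
              meth_noise_sd = meth_noise_sd, seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_config <- function(cfg) {
  if (cfg$n_samples < 4L) stop_field("n_samples", "must be >= 4")
  if (cfg$n_null_mirnas < 0L) stop_field("n_null_mirnas", "must be >= 0")
  pm <- cfg$planted_mirnas
  if (nrow(pm) > 0) {
    if (!all(c("mirna", "gamma") %in% names(pm)))
      stop_field("planted_mirnas", "needs columns 'mirna' and 'gamma'")
    if (any(pm$gamma < 0)) stop_field("planted_mirnas", "gamma must be >= 0")
    if (anyDuplicated(pm$mirna))
      stop_field("planted_mirnas", "miRNA names must be unique")
  }
  pg <- cfg$panel_genes
  if (!all(c("gene", "beta", "mu") %in% names(pg)))
    stop_field("panel_genes", "needs columns 'gene', 'beta', 'mu'")
  if (any(pg$beta < 0)) stop_field("panel_genes", "beta must be >= 0")
  if (anyDuplicated(pg$gene))
    stop_field("panel_genes", "gene names must be unique")
  check_scalar_number(cfg$noise_sd, "noise_sd", positive = TRUE)
  check_scalar_number(cfg$nb_dispersion, "nb_dispersion", positive = TRUE)
  check_scalar_number(cfg$baseline_hazard, "baseline_hazard", positive = TRUE)
  check_scalar_number(cfg$hazard_coupling, "hazard_coupling")
  check_scalar_number(cfg$censor_rate, "censor_rate", nonnegative = TRUE)
  check_scalar_number(cfg$admin_censor_time, "admin_censor_time",
                      positive = TRUE)
  check_scalar_number(cfg$meth_noise_sd, "meth_noise_sd", nonnegative = TRUE)
  if (cfg$n_meth_planted < 0L) stop_field("n_meth_planted", "must be >= 0")
  if (cfg$n_meth_null < 0L) stop_field("n_meth_null", "must be >= 0")
  invisible(cfg)
}

#' Write / read a cohort configuration (exact round trip)
#'
#' Configurations serialize to YAML; numeric fields are written with full
#' precision so that a round trip preserves every field exactly.
#'
#' @param config a [cohort_config()].
#' @param path file path.
#' @return `read_cohort_config` returns the config; `write_cohort_config`
#'   returns `path` invisibly.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  plain <- unclass(config)
  plain$planted_mirnas <- as.list(config$planted_mirnas)
  plain$panel_genes <- as.list(config$panel_genes)
  yaml::write_yaml(plain, path, precision = 17L)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  plain <- yaml::read_yaml(path)
  plain$planted_mirnas <- as.data.frame(plain$planted_mirnas,
                                        stringsAsFactors = FALSE)
  plain$panel_genes <- as.data.frame(plain$panel_genes,
                                     stringsAsFactors = FALSE)
  do.call(cohort_config, plain)
}

#' Generate a synthetic cohort
#'
#' @param config a [cohort_config()].
#' @return list of class `cohort` with elements `mirna_expr`, `mrna_expr`
#'   (feature x sample matrices sharing sample ids in the same order),
#'   `latent_activity`, `mvd` (data.frame sample / vessels_per_hpf),
#'   `clinical` (sample / time / event), `methylation` (probe x sample beta
#'   matrix) and `truth` (planted couplings and parameters).
#' @export
generate_cohort <- function(config) {
  validate_config(config)
  n <- config$n_samples
  samples <- sprintf("S%03d", seq_len(n))
  seed <- config$seed

  A <- with_seed(sub_seed(seed, "latent"), stats::rnorm(n))
  names(A) <- samples

  pg <- config$panel_genes
  mrna <- with_seed(sub_seed(seed, "mrna"), {
    vals <- vapply(seq_len(nrow(pg)), function(i)
      pg$mu[i] + pg$beta[i] * A + stats::rnorm(n, sd = config$noise_sd),
      numeric(n))
    t(vals)
  })
  dimnames(mrna) <- list(pg$gene, samples)

  pm <- config$planted_mirnas
  mir_names <- c(if (nrow(pm) > 0) pm$mirna,
                 if (config$n_null_mirnas > 0)
                   sprintf("mir-null-%03d", seq_len(config$n_null_mirnas)))
  gammas <- c(if (nrow(pm) > 0) pm$gamma,
              rep(0, config$n_null_mirnas))
  baselines <- rep(config$mirna_baseline, length(mir_names))
  if (nrow(pm) > 0 && "baseline" %in% names(pm))
    baselines[seq_len(nrow(pm))] <- pm$baseline
  mirna <- with_seed(sub_seed(seed, "mirna"), {
    vals <- vapply(seq_along(mir_names), function(i) {
      lin <- baselines[i] - gammas[i] * A
      if (config$mirna_mode == "counts")
        as.numeric(stats::rnbinom(n, mu = exp(lin),
                                  size = 1 / config$nb_dispersion))
      else lin + stats::rnorm(n, sd = config$noise_sd)
    }, numeric(n))
    t(vals)
  })
  dimnames(mirna) <- list(mir_names, samples)

  mvd_counts <- with_seed(sub_seed(seed, "mvd"),
    stats::rpois(n, lambda = exp(config$mvd_intercept +
                                   config$mvd_slope * A)))
  mvd <- data.frame(sample = samples, vessels_per_hpf = mvd_counts,
                    stringsAsFactors = FALSE)

  clinical <- with_seed(sub_seed(seed, "survival"), {
    ev_time <- stats::rexp(n, rate = config$baseline_hazard *
                             exp(config$hazard_coupling * A))
    cens <- if (config$censor_rate > 0)
      pmin(stats::rexp(n, rate = config$censor_rate),
           config$admin_censor_time)
    else rep(config$admin_censor_time, n)
    data.frame(sample = samples,
               time = pmin(ev_time, cens),
               event = as.integer(ev_time <= cens),
               stringsAsFactors = FALSE)
  })

  n_probe <- config$n_meth_planted + config$n_meth_null
  methylation <- NULL
  if (n_probe > 0) {
    probe_names <- c(
      if (config$n_meth_planted > 0)
        sprintf("cg-planted-%02d", seq_len(config$n_meth_planted)),
      if (config$n_meth_null > 0)
        sprintf("cg-null-%02d", seq_len(config$n_meth_null)))
    deltas <- c(rep(config$meth_delta1, config$n_meth_planted),
                rep(0, config$n_meth_null))
    methylation <- with_seed(sub_seed(seed, "methylation"), {
      vals <- vapply(seq_len(n_probe), function(i) {
        beta <- stats::plogis(config$meth_delta0 + deltas[i] * A) +
          stats::runif(n, -config$meth_noise_sd, config$meth_noise_sd)
        pmin(pmax(beta, 0), 1)
      }, numeric(n))
      t(vals)
    })
    dimnames(methylation) <- list(probe_names, samples)
  }

  structure(list(
    mirna_expr = mirna, mrna_expr = mrna, latent_activity = A,
    mvd = mvd, clinical = clinical, methylation = methylation,
    truth = list(planted_mirnas = pm, panel_genes = pg,
                 hazard_coupling = config$hazard_coupling,
                 mvd_slope = config$mvd_slope,
                 meth_planted = if (n_probe > 0 && config$n_meth_planted > 0)
                   sprintf("cg-planted-%02d",
                           seq_len(config$n_meth_planted)) else character(0)),
    config = config), class = "cohort")
}

#' Synthetic TF-binding and miRNA-target prediction tables with truth
#'
#' Emulates the inputs of the transcription-factor cascade: planted TFs
#' carry matrix-similarity scores at or above the truth cutoff on their true
#' target genes and predictions from at least the truth number of
#' algorithms; decoy TFs carry sub-cutoff scores or too few algorithms.
#'
#' @param gene_universe character vector of candidate target genes (>= 1).
#' @param mirna the miRNA whose targets are being predicted.
#' @param planted_tfs data.frame with columns `tf`, `n_targets`, `score`,
#'   `n_algorithms`.
#' @param decoy_tfs data.frame with the same columns (scores below cutoff
#'   or algorithm counts below threshold make them decoys).
#' @param algorithms algorithm vocabulary to draw from.
#' @param seed integer seed (deterministic tables).
#' @return list with `binding` (TF-binding table), `targets` (miRNA-target
#'   table) and `truth` (the planted TF names).
#' @export
generate_tf_tables <- function(gene_universe, mirna = "mir-planted-1",
                               planted_tfs = data.frame(
                                 tf = "TF-planted-1", n_targets = 6,
                                 score = 0.95, n_algorithms = 4),
                               decoy_tfs = data.frame(
                                 tf = c("TF-decoy-lowscore", "TF-decoy-fewalg",
                                        "TF-decoy-fewgenes"),
                                 n_targets = c(6, 6, 3),
                                 score = c(0.85, 0.95, 0.95),
                                 n_algorithms = c(4, 3, 4)),
                               algorithms = c("miRanda", "TargetScan", "PITA",
                                              "RNA22", "microT", "PicTar"),
                               seed = 1L) {
  gene_universe <- unique(as.character(gene_universe))
  if (length(gene_universe) == 0L)
    stop_field("gene_universe", "must contain at least one gene")
  all_tf <- rbind(planted_tfs, decoy_tfs)
  if (any(all_tf$n_targets > length(gene_universe)))
    stop_field("n_targets", "exceeds the gene universe size")
  if (any(all_tf$n_algorithms > length(algorithms)))
    stop_field("n_algorithms", "exceeds the algorithm vocabulary size")
  with_seed(sub_seed(seed, "tf_tables"), {
    binding <- do.call(rbind, lapply(seq_len(nrow(all_tf)), function(i) {
      genes <- sample(gene_universe, all_tf$n_targets[i])
      data.frame(tf = all_tf$tf[i], gene = genes,
                 matrix_similarity = all_tf$score[i],
                 stringsAsFactors = FALSE)
    }))
    targets <- do.call(rbind, lapply(seq_len(nrow(all_tf)), function(i) {
      algs <- sample(algorithms, all_tf$n_algorithms[i])
      data.frame(mirna = mirna, gene = all_tf$tf[i], algorithm = algorithms,
                 predicted = algorithms %in% algs, stringsAsFactors = FALSE)
    }))
    list(binding = binding, targets = targets,
         truth = list(planted = planted_tfs$tf, decoys = decoy_tfs$tf))
  })
}

#' Synthetic node-weighted network for the random-walk scorer
#'
#' @param kind "k_regular" (connected k-regular graph on `n_nodes` with
#'   uniform data values), "path" (path graph with supplied `values`), or
#'   "random" (connected Erdos-Renyi graph with positive lognormal values).
#' @param n_nodes number of nodes (>= 2).
#' @param k degree for `k_regular`.
#' @param values node data values for `path` (length `n_nodes`).
#' @param p edge probability for `random`.
#' @param seed integer seed.
#' @return a [gene_network()].
#' @export
generate_network <- function(kind = c("k_regular", "path", "random"),
                             n_nodes = 8L, k = 3L, values = NULL, p = 0.4,
                             seed = 1L) {
  kind <- match.arg(kind)
  if (n_nodes < 2L) stop_field("n_nodes", "must be >= 2")
  ids <- sprintf("g%02d", seq_len(n_nodes))
  with_seed(sub_seed(seed, "network"), {
    if (kind == "path") {
      if (is.null(values)) values <- rep(1, n_nodes)
      if (length(values) != n_nodes)
        stop_field("values", "length must equal n_nodes")
      edges <- data.frame(from = ids[-n_nodes], to = ids[-1L])
      return(gene_network(data.frame(id = ids, value = values), edges))
    }
    if (kind == "k_regular") {
      g <- igraph::sample_k_regular(n_nodes, k)
      while (!igraph::is_connected(g)) g <- igraph::sample_k_regular(n_nodes, k)
      el <- igraph::as_edgelist(g)
      edges <- data.frame(from = ids[el[, 1]], to = ids[el[, 2]])
      vals <- if (is.null(values)) rep(1, n_nodes) else values
      return(gene_network(data.frame(id = ids, value = vals), edges))
    }
    # random: connected Erdos-Renyi with lognormal node values
    repeat {
      g <- igraph::sample_gnp(n_nodes, p)
      if (igraph::is_connected(g)) break
    }
    el <- igraph::as_edgelist(g)
    edges <- data.frame(from = ids[el[, 1]], to = ids[el[, 2]])
    vals <- if (is.null(values)) stats::rlnorm(n_nodes) else values
    gene_network(data.frame(id = ids, value = vals), edges)
  })
}

#' Synthetic Nanostring-style count fixture for the median-decrease screen
#'
#' Negative-binomial counts for two microvessel-density groups, with a
#' chosen number of planted probes whose high-MVD group mean is reduced by
#' `planted_decrease` relative to the low-MVD group. Baseline means are
#' log-uniform across probes. Deterministic under `seed`.
#'
#' @param n_high,n_low samples per group (defaults 12/12).
#' @param n_mirnas total probes.
#' @param n_planted probes with a planted decrease.
#' @param planted_decrease fractional decrease of the high-group mean.
#' @param dispersion negative-binomial dispersion.
#' @param mean_range range of baseline means (log-uniform).
#' @param seed integer seed.
#' @return list with `counts` (probe x sample matrix), `mvd` (a group table
#'   with vessel counts placing the groups at >36 and <16 per HPF) and
#'   `truth` (planted probe names).
#' @export
generate_nanostring_counts <- function(n_high = 12L, n_low = 12L,
                                       n_mirnas = 200L, n_planted = 1L,
                                       planted_decrease = 0.9,
                                       dispersion = 0.2,
                                       mean_range = c(100, 2000),
                                       seed = 1L) {
  if (n_high < 1L || n_low < 1L)
    stop_field("n_high", "both groups need at least one sample")
  if (n_planted > n_mirnas)
    stop_field("n_planted", "cannot exceed n_mirnas")
  samples <- c(sprintf("H%02d", seq_len(n_high)),
               sprintf("L%02d", seq_len(n_low)))
  probes <- c(if (n_planted > 0) sprintf("mir-dec-%03d", seq_len(n_planted)),
              if (n_mirnas > n_planted)
                sprintf("mir-null-%03d", seq_len(n_mirnas - n_planted)))
  with_seed(sub_seed(seed, "nanostring"), {
    base <- exp(stats::runif(n_mirnas, log(mean_range[1]), log(mean_range[2])))
    counts <- t(vapply(seq_len(n_mirnas), function(i) {
      dec <- if (i <= n_planted) planted_decrease else 0
      mu <- c(rep(base[i] * (1 - dec), n_high), rep(base[i], n_low))
      as.numeric(stats::rnbinom(n_high + n_low, mu = mu,
                                size = 1 / dispersion))
    }, numeric(n_high + n_low)))
    dimnames(counts) <- list(probes, samples)
    mvd <- data.frame(
      sample = samples,
      vessels_per_hpf = c(stats::rpois(n_high, 45), stats::rpois(n_low, 8)),
      stringsAsFactors = FALSE)
    # guarantee the intended extreme-group assignment
    mvd$vessels_per_hpf[seq_len(n_high)] <-
      pmax(mvd$vessels_per_hpf[seq_len(n_high)], 37)
    mvd$vessels_per_hpf[n_high + seq_len(n_low)] <-
      pmin(mvd$vessels_per_hpf[n_high + seq_len(n_low)], 15)
    list(counts = counts, mvd = mvd,
         truth = list(planted = if (n_planted > 0)
           sprintf("mir-dec-%03d", seq_len(n_planted)) else character(0)))
  })
}

#' Synthetic stand-in for the deposited 24-tumour Nanostring table
#'
#' A deterministic synthetic counterpart of a Nanostring miRNA screen of 12
#' highly and 12 poorly angiogenic tumours: 250 probes, 13 of which carry a
#' strong (95%) planted median decrease in the high-MVD group, with
#' negative-binomial count noise. This is a constructed fixture emulating
#' the structure of such an experiment, not measured data.
#'
#' @return as [generate_nanostring_counts()].
#' @export
synthetic_supplementary_counts <- function() {
  generate_nanostring_counts(n_high = 12L, n_low = 12L, n_mirnas = 250L,
                             n_planted = 13L, planted_decrease = 0.95,
                             dispersion = 0.2, seed = 24L)
}

#' Write a cohort's tables to a directory as plain text
#'
#' Emits `mirna.tsv`, `mrna.tsv`, `clinical.tsv`, `mvd.tsv`,
#' `methylation.tsv` and `truth.json`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(cohort$mirna_expr, file.path(dir, "mirna.tsv"), "mirna")
  write_matrix(cohort$mrna_expr, file.path(dir, "mrna.tsv"), "gene")
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$mvd, file.path(dir, "mvd.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$methylation))
    write_matrix(cohort$methylation, file.path(dir, "methylation.tsv"),
                 "probe")
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
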