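#' Configuration for the synthetic cohort simulator
#'
#' The simulator emulates the statistical structure the subtype classifier
#' assumes: two latent biological axes (immune activity and pathological
#' angiogenesis) drive blocks of axis genes with an additive mean shift,
#' quadrants of the latent plane define the four TME subtypes, and RECIST
#' responses are Bernoulli draws whose rate depends on subtype through a
#' mechanism-of-action response model.
#'
#' @param n_samples Number of samples (>= 8 so all four subtypes can be
#'   stratified).
#' @param subtype_proportions Probabilities for subtypes A, IA, ID, IS;
#'   must sum to 1. Default equal; across real tumor cohorts each subtype is
#'   reported to hold roughly 15-40% of samples, so equal quarters are a
#'   realistic central case.
#' @param n_genes_per_axis Genes per biological axis.
#' @param n_noise_genes Genes with no axis loading (pure noise).
#' @param loading_effect Mean expression shift (z-units, log2 scale) of an
#'   axis gene between axis-high and axis-low samples.
#' @param cross_loading Crosstalk coefficient in \[0, 1): each axis gene
#'   also responds to the *other* axis's activity at this fraction of its
#'   own loading (default 0, independent axes). Vascular and immune stromal
#'   programs are biologically interconnected, so nonzero values emulate
#'   panels whose genes report on both biologies.
#' @param noise_sd Residual standard deviation per gene (z-units).
#' @param platform_shift List with `location_sd` and `scale_sd`: per-dataset
#'   per-gene location jitter (log2 units) and log-normal scale jitter used
#'   by [simulate_multidataset()]. A single number is shorthand for
#'   `list(location_sd = x, scale_sd = 0)`.
#' @param response_model Named numeric vector of objective response rates per
#'   subtype (names A, IA, ID, IS). The default encodes an immune-therapy
#'   mechanism: immune-high subtypes (IA, IS) respond at 34.4%, immune-low
#'   (A, ID) at 4.9%.
#' @param latent_mode `"mixture"` (axis activity is a two-point low/high
#'   mixture at -1/+1, so quadrant truth is unambiguous) or `"continuous"`
#'   (standard normal activity, for boundary-behavior studies).
#' @param loading_jitter Standard deviation of optional per-gene jitter on
#'   the loading (default 0, constant loading within axis).
#' @param baseline_range Range of per-gene baseline expression (log2 scale).
#' @param seed Integer seed; everything downstream is reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 298,
                       subtype_proportions = c(A = 0.25, IA = 0.25, ID = 0.25, IS = 0.25),
                       n_genes_per_axis = 62,
                       n_noise_genes = 20,
                       loading_effect = 2,
                       cross_loading = 0,
                       noise_sd = 1,
                       platform_shift = list(location_sd = 0.3, scale_sd = 0.1),
                       response_model = c(A = 0.049, IA = 0.344, ID = 0.049, IS = 0.344),
                       latent_mode = c("mixture", "continuous"),
                       loading_jitter = 0,
                       baseline_range = c(4, 12),
                       seed = 1L) {
  latent_mode <- match.arg(latent_mode)
  if (length(subtype_proportions) != 4 ||
      abs(sum(subtype_proportions) - 1) > 1e-12) {
    abort("subtype_proportions must be 4 probabilities summing to 1 (order A, IA, ID, IS)")
  }
  names(subtype_proportions) <- TME_SUBTYPES
  if (loading_effect < 0 || noise_sd < 0) abort("loading_effect and noise_sd must be nonnegative")
  if (cross_loading < 0 || cross_loading >= 1) abort("cross_loading must be in [0, 1)")
  if (is.numeric(platform_shift) && length(platform_shift) == 1) {
    platform_shift <- list(location_sd = platform_shift, scale_sd = 0)
  }
  if (any(response_model < 0 | response_model > 1)) abort("response rates must be in [0, 1]")
  if (is.null(names(response_model))) names(response_model) <- TME_SUBTYPES
  structure(list(
    n_samples = as.integer(n_samples),
    subtype_proportions = subtype_proportions,
    n_genes_per_axis = as.integer(n_genes_per_axis),
    n_noise_genes = as.integer(n_noise_genes),
    loading_effect = loading_effect,
    cross_loading = cross_loading,
    noise_sd = noise_sd,
    platform_shift = platform_shift,
    response_model = response_model[TME_SUBTYPES],
    latent_mode = latent_mode,
    loading_jitter = loading_jitter,
    baseline_range = baseline_range,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# run code under a seed without disturbing the caller's RNG stream
with_sim_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# gene metadata shared by single- and multi-dataset simulation
sim_gene_info <- function(config) {
  n_axis <- config$n_genes_per_axis
  gene_id <- c(sprintf("IMM%03d", seq_len(n_axis)),
               sprintf("ANG%03d", seq_len(n_axis)),
               if (config$n_noise_genes > 0) sprintf("NSE%03d", seq_len(config$n_noise_genes)))
  role <- c(rep("immune", n_axis), rep("angiogenesis", n_axis),
            rep("noise", config$n_noise_genes))
  baseline <- stats::runif(length(gene_id), config$baseline_range[1], config$baseline_range[2])
  loading <- ifelse(role == "noise", 0,
                    config$loading_effect +
                      if (config$loading_jitter > 0) {
                        stats::rnorm(length(gene_id), 0, config$loading_jitter)
                      } else 0)
  tibble::tibble(gene_id = gene_id, role = role, baseline = baseline, loading = loading)
}

# latent activities and subtypes for one cohort
sim_latents <- function(config, n) {
  subtype <- sample(TME_SUBTYPES, n, replace = TRUE, prob = config$subtype_proportions)
  if (config$latent_mode == "mixture") {
    immune <- ifelse(subtype %in% c("IA", "IS"), 1, -1)
    angio <- ifelse(subtype %in% c("A", "IS"), 1, -1)
  } else {
    immune <- stats::rnorm(n)
    angio <- stats::rnorm(n)
    subtype <- quadrant_of(immune, angio)
  }
  tibble::tibble(sample_id = sprintf("S%04d", seq_len(n)),
                 immune_activity = immune, angio_activity = angio,
                 subtype = subtype)
}

quadrant_of <- function(immune, angio, thresholds = c(0, 0)) {
  dplyr::case_when(
    immune > thresholds[1] & angio > thresholds[2] ~ "IS",
    immune > thresholds[1] ~ "IA",
    angio > thresholds[2] ~ "A",
    TRUE ~ "ID"
  )
}

# expression matrix given gene info and latents; activity in {-1, +1} (or
# continuous z); mean shift between activity -1 and +1 equals the loading
sim_expression <- function(gene_info, latents, noise_sd, cross_loading = 0) {
  g <- nrow(gene_info); n <- nrow(latents)
  activity <- rbind(
    immune = latents$immune_activity,
    angiogenesis = latents$angio_activity,
    noise = rep(0, n)
  )
  other_role <- c(immune = "angiogenesis", angiogenesis = "immune", noise = "noise")
  act <- activity[gene_info$role, , drop = FALSE]
  cross <- activity[other_role[gene_info$role], , drop = FALSE]
  mu <- gene_info$baseline + (gene_info$loading / 2) * (act + cross_loading * cross)
  vals <- mu + if (noise_sd > 0) stats::rnorm(g * n, 0, noise_sd) else 0
  m <- matrix(vals, nrow = g, ncol = n,
              dimnames = list(gene_info$gene_id, latents$sample_id))
  m
}

#' Simulate a synthetic tumor expression cohort with clinical response
#'
#' Draws subtypes from the configured proportions, places each sample in the
#' matching quadrant of the latent (immune, angiogenesis) plane, generates
#' axis-gene expression as baseline + loading x activity / 2 + Gaussian
#' noise, and draws RECIST best responses Bernoulli(ORR(subtype)) under the
#' configured mechanism-of-action response model. Responders receive CR/PR,
#' non-responders SD/PD.
#'
#' @param config A [sim_config()].
#' @return A list with `expression` (genes x samples matrix), `clinical`
#'   (tibble: sample_id, bor, responder), `truth` (tibble: per-sample latent
#'   activities, true subtype, true responder probability), `panel` (the
#'   axis genes as a [gene_panel()], all weighted) and `gene_info`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_samples < 8) {
    abort("n_samples must be >= 8 to stratify four subtypes")
  }
  with_sim_seed(config$seed, {
    gene_info <- sim_gene_info(config)
    latents <- sim_latents(config, config$n_samples)
    expr <- sim_expression(gene_info, latents, config$noise_sd, config$cross_loading)
    p_resp <- unname(config$response_model[latents$subtype])
    responder <- stats::runif(config$n_samples) < p_resp
    bor <- ifelse(responder,
                  sample(c("CR", "PR"), config$n_samples, replace = TRUE, prob = c(0.25, 0.75)),
                  sample(c("SD", "PD"), config$n_samples, replace = TRUE))
    clinical <- as_clinical(tibble::tibble(sample_id = latents$sample_id, bor = bor))
    truth <- dplyr::mutate(latents, responder_probability = p_resp)
    axis_genes <- gene_info[gene_info$role != "noise", ]
    panel <- gene_panel(axis_genes$gene_id, axis_genes$role, weighted = TRUE)
    list(expression = expr, clinical = clinical, truth = truth,
         panel = panel, gene_info = gene_info, seed = config$seed)
  })
}

#' Simulate a multi-dataset (multi-platform) collection of cohorts
#'
#' All datasets share the same generative model (baselines, loadings, latent
#' structure) but each receives its own per-gene platform perturbation:
#' location jitter and multiplicative scale jitter, emulating different
#' expression platforms. Optionally, `n_unstable` axis genes are designated
#' platform-inconsistent: their loading sign flips between datasets and
#' their baseline is displaced by `unstable_shift / 2` with alternating sign
#' per dataset, the way a probe that fails on some platforms behaves. Such
#' genes should be caught by [transferability_scores()].
#'
#' @param config A [sim_config()].
#' @param n_datasets Number of datasets (>= 2).
#' @param n_unstable Number of designated unstable axis genes.
#' @param unstable_shift Total baseline displacement (log2 units) of an
#'   unstable gene between odd and even datasets.
#' @return A list with `datasets` (named list of expression matrices),
#'   `panel` (axis genes), `gene_info`, and `unstable_genes` (ids).
#' @export
simulate_multidataset <- function(config = sim_config(), n_datasets = 3,
                                  n_unstable = 0, unstable_shift = 8) {
  stopifnot(inherits(config, "sim_config"))
  if (n_datasets < 2) abort("n_datasets must be >= 2")
  with_sim_seed(config$seed, {
    gene_info <- sim_gene_info(config)
    axis_ids <- gene_info$gene_id[gene_info$role != "noise"]
    if (n_unstable > length(axis_ids)) abort("n_unstable exceeds number of axis genes")
    unstable <- if (n_unstable > 0) sample(axis_ids, n_unstable) else character(0)
    loc_sd <- config$platform_shift$location_sd
    scale_sd <- config$platform_shift$scale_sd
    datasets <- lapply(seq_len(n_datasets), function(d) {
      gi <- gene_info
      flip <- gi$gene_id %in% unstable
      dataset_sign <- if (d %% 2 == 1) 1 else -1
      gi$loading[flip] <- gi$loading[flip] * dataset_sign
      gi$baseline[flip] <- gi$baseline[flip] + dataset_sign * unstable_shift / 2
      latents <- sim_latents(config, config$n_samples)
      latents$sample_id <- sprintf("D%d_%s", d, latents$sample_id)
      m <- sim_expression(gi, latents, config$noise_sd, config$cross_loading)
      if (loc_sd > 0 || scale_sd > 0) {
        loc <- stats::rnorm(nrow(m), 0, loc_sd)
        scl <- exp(stats::rnorm(nrow(m), 0, scale_sd))
        ctr <- rowMeans(m)
        m <- (m - ctr) * scl + ctr + loc
      }
      m
    })
    names(datasets) <- sprintf("dataset_%d", seq_len(n_datasets))
    axis_genes <- gene_info[gene_info$role != "noise", ]
    panel <- gene_panel(axis_genes$gene_id, axis_genes$role, weighted = TRUE)
    list(datasets = datasets, panel = panel, gene_info = gene_info,
         unstable_genes = unstable, seed = config$seed)
  })
}
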