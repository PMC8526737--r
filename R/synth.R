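# Synthetic cohorts with planted cross-modal structure.
#
# The generator emulates the shape of a two-group neonatal cohort: paired
# feature views sharing a per-subject latent score expressed on known edge
# supports, a standardized group-mean shift on those edges, and preterm
# birth ages linear in the latent score. Everything is a pure function of
# (config, seed).

#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the study cohort the package targets: 32 preterm + 32
#' term subjects, ~2,000 candidate edges with 50 signal edges per view, a
#' cross-view latent correlation of 0.7 on signal edges, a 0.8-SD group
#' shift, and preterm birth ages spanning 28-36 weeks.
#'
#' @param n_preterm,n_term subjects per group.
#' @param n_patches number of parcellation patches (even; half per
#'   hemisphere). Must satisfy `m_edges <= n_patches*(n_patches-1)/2`.
#' @param m_edges number of candidate edges (feature columns).
#' @param k_signal planted support size per view.
#' @param latent_corr cross-view correlation of a signal edge pair, in
#'   (0, 1).
#' @param group_shift standardized group-mean shift on signal edges; the
#'   functional view shifts toward the term group, the structural view
#'   toward the preterm group.
#' @param age_slope weeks of birth age per latent-score SD.
#' @param age_noise_sd SD (weeks) of the age noise.
#' @param age_intercept mean preterm birth age (weeks).
#' @param seed RNG seed.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_preterm = 32L, n_term = 32L, n_patches = 64L,
                         m_edges = 2000L, k_signal = 50L, latent_corr = 0.7,
                         group_shift = 0.8, age_slope = 1.5,
                         age_noise_sd = 0.8, age_intercept = 32,
                         seed = 1L) {
  cfg <- list(n_preterm = as.integer(n_preterm), n_term = as.integer(n_term),
              n_patches = as.integer(n_patches), m_edges = as.integer(m_edges),
              k_signal = as.integer(k_signal), latent_corr = latent_corr,
              group_shift = group_shift, age_slope = age_slope,
              age_noise_sd = age_noise_sd, age_intercept = age_intercept,
              seed = as.integer(seed))
  if (cfg$k_signal > cfg$m_edges) stop("k_signal must be <= m_edges")
  if (cfg$m_edges > cfg$n_patches * (cfg$n_patches - 1) / 2) {
    stop("m_edges exceeds the number of patch pairs")
  }
  if (!(latent_corr > 0 && latent_corr < 1)) stop("latent_corr must be in (0, 1)")
  if (age_noise_sd <= 0) stop("age_noise_sd must be positive")
  if (cfg$n_preterm < 2L || cfg$n_term < 2L) stop("need at least 2 subjects per group")
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic parcellation table
#'
#' Patch centroids are sampled in two mirrored hemispheric slabs (left
#' x < 0, right x > 0, mm-scale coordinates), mean curvature is uniform on
#' (0, 1), and RSN labels are uniform over 1..9 with 10% of patches left
#' unassigned (NA). Atlas areas cycle through 17 labels.
#'
#' @param n_patches even number of patches.
#' @param seed RNG seed.
#' @return a `parcellation` data.frame.
#' @export
generate_parcellation <- function(n_patches, seed = 1L) {
  n_patches <- as.integer(n_patches)
  if (n_patches %% 2L != 0L) stop("n_patches must be even (half per hemisphere)")
  h <- n_patches %/% 2L
  with_seed(seed, {
    xl <- -stats::runif(h, 3, 70)
    xr <- stats::runif(h, 3, 70)
    df <- data.frame(
      patch_id = seq_len(n_patches),
      x = c(xl, xr),
      y = stats::runif(n_patches, -90, 60),
      z = stats::runif(n_patches, -50, 70),
      hemisphere = rep(c("left", "right"), each = h),
      mean_curvature = stats::runif(n_patches, 0, 1),
      rsn_label = sample.int(9L, n_patches, replace = TRUE),
      atlas_area = sprintf("A%02d", (seq_len(n_patches) - 1L) %% 17L + 1L),
      stringsAsFactors = FALSE
    )
    df$rsn_label[stats::runif(n_patches) < 0.1] <- NA_integer_
    as_parcellation(df)
  })
}

#' Generate a synthetic two-view cohort with planted signal
#'
#' Sampling model (per subject i, edge j): a latent score `z_i ~ N(0,1)`;
#' on the planted supports the views load on it with
#' `x_ij = sqrt(rho) z_i + sqrt(1-rho) e_ij` (and likewise for y with its
#' own support and noise), giving cross-view correlation `rho =
#' latent_corr` between paired signal edges; all other edges are N(0,1)
#' noise. Signal edges additionally receive a between-group mean shift of
#' `group_shift` SD (functional view higher in term subjects, structural
#' view higher in preterm). Preterm birth ages are `age_intercept +
#' age_slope * z + N(0, age_noise_sd)`, clipped to 28-36 weeks.
#'
#' @param cfg a `synth_config`.
#' @return an object of class `synth_truth`: `data` (a [feature_pair()]),
#'   `parcellation`, `index_map` (edge -> patch pair), `support_u`,
#'   `support_v`, `latent`, `config`.
#' @export
generate_cohort <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_preterm + cfg$n_term
    m <- cfg$m_edges
    labels <- factor(rep(c("preterm", "term"), c(cfg$n_preterm, cfg$n_term)),
                     levels = c("preterm", "term"))
    z <- stats::rnorm(n)
    rho <- cfg$latent_corr
    X <- matrix(stats::rnorm(n * m), n, m)
    Y <- matrix(stats::rnorm(n * m), n, m)
    support_u <- sort(sample.int(m, cfg$k_signal))
    support_v <- sort(sample.int(m, cfg$k_signal))
    X[, support_u] <- sqrt(rho) * z + sqrt(1 - rho) * X[, support_u]
    Y[, support_v] <- sqrt(rho) * z + sqrt(1 - rho) * Y[, support_v]
    half <- cfg$group_shift / 2
    is_term <- labels == "term"
    X[is_term, support_u] <- X[is_term, support_u] + half
    X[!is_term, support_u] <- X[!is_term, support_u] - half
    Y[!is_term, support_v] <- Y[!is_term, support_v] + half
    Y[is_term, support_v] <- Y[is_term, support_v] - half
    z1 <- z[!is_term]
    ages <- cfg$age_intercept + cfg$age_slope * z1 +
      stats::rnorm(cfg$n_preterm, 0, cfg$age_noise_sd)
    ages <- pmin(pmax(ages, 28), 36)
    parc <- generate_parcellation(cfg$n_patches, seed = sample.int(.Machine$integer.max, 1L))
    all_pairs <- edge_index_map(cfg$n_patches)
    index_map <- all_pairs[sort(sample.int(nrow(all_pairs), m)), , drop = FALSE]
    subject_id <- sprintf("sub%03d", seq_len(n))
    rownames(X) <- rownames(Y) <- subject_id
    data <- feature_pair(X, Y, labels, ages = ages, age_group = "preterm")
    structure(list(data = data, parcellation = parc, index_map = index_map,
                   support_u = support_u, support_v = support_v,
                   latent = z, config = cfg),
              class = "synth_truth")
  })
}

#' Generate block-correlated patch time series for one subject
#'
#' Smooth AR(1)-style series in which patches belong to blocks sharing a
#' latent series, so same-block patches correlate more strongly than
#' cross-block ones. Feeds [build_functional_connectome()].
#'
#' @param n_patches number of patches.
#' @param T number of time points (>= 3).
#' @param seed RNG seed.
#' @param n_blocks number of correlated blocks (default 4).
#' @param ar AR(1) coefficient of the latent and noise series.
#' @param block_weight share of variance from the block latent, in (0, 1).
#' @return numeric T x n_patches matrix with attribute `blocks` giving the
#'   block assignment of each patch.
#' @export
generate_toy_signals <- function(n_patches, T, seed = 1L, n_blocks = 4L,
                                 ar = 0.6, block_weight = 0.5) {
  if (T < 3L) stop("T must be at least 3")
  with_seed(seed, {
    ar1 <- function() as.vector(stats::arima.sim(list(ar = ar), n = T))
    blocks <- rep_len(seq_len(n_blocks), n_patches)
    latents <- replicate(n_blocks, ar1())
    sig <- sapply(seq_len(n_patches), function(p) {
      sqrt(block_weight) * latents[, blocks[p]] + sqrt(1 - block_weight) * ar1()
    })
    attr(sig, "blocks") <- blocks
    sig
  })
}
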