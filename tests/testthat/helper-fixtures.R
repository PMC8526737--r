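# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files.

# Small two-group feature pair with no structure (pure noise).
make_noise_pair <- function(n_per_group = 6, m = 20, seed = 1, with_ages = TRUE) {
  withr_seed <- function(code) cclpp:::with_seed(seed, code)
  withr_seed({
    n <- 2 * n_per_group
    labels <- rep(c("preterm", "term"), each = n_per_group)
    X <- matrix(rnorm(n * m), n, m)
    Y <- matrix(rnorm(n * m), n, m)
    ages <- if (with_ages) runif(n_per_group, 28, 36) else NULL
    feature_pair(X, Y, labels, ages = ages)
  })
}

# Deterministic tiny parcellation with known annotations.
make_tiny_parcellation <- function() {
  as_parcellation(data.frame(
    patch_id = 1:6,
    x = c(-10, -20, -30, 10, 20, 30),
    y = c(0, 5, 10, 0, 5, 10),
    z = c(0, 0, 0, 0, 0, 0),
    hemisphere = rep(c("left", "right"), each = 3),
    mean_curvature = c(0.7, 0.9, 0.3, 0.5, 0.2, 0.8),
    rsn_label = c(5L, 5L, 1L, 2L, NA, 3L),
    atlas_area = c("A1", "A1", "A2", "A2", "A3", "A3"),
    stringsAsFactors = FALSE
  ))
}

# Identified-connections object straight from explicit edges.
make_edges <- function(pairs, weights = NULL, modality = NULL) {
  pairs <- matrix(as.integer(pairs), ncol = 2, byrow = TRUE)
  df <- data.frame(edge_index = seq_len(nrow(pairs)),
                   patch_i = pairs[, 1], patch_j = pairs[, 2],
                   weight = if (is.null(weights)) rep(1, nrow(pairs)) else weights)
  structure(df, class = c("identified_connections", "data.frame"),
            modality = modality, n_edges = nrow(df), rule = "nonzero")
}
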