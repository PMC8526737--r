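# End-to-end pipeline: (synthesize or load) -> t-test screen -> CCA-LPP
# fit -> edge selection -> post-hoc statistics, with a run manifest for
# auditability.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

.default_config <- function() {
  list(
    input = "synth",
    synth = list(),          # overrides for synth_config()
    fit = list(),            # overrides for cclpp_control()
    filter = list(alpha = 0.05),
    select = list(rule = "nonzero", param = NULL),
    stats = list(low = 10, long = 20, curvature_cut = 0.5),
    seed = 1L
  )
}

#' Run the full connectome analysis pipeline
#'
#' Chains edge screening, the sparse CCA-LPP fit, edge selection, and the
#' post-hoc connection statistics, writing every stage's outputs plus a
#' run manifest into `out_dir`. Inputs come either from the synthetic
#' generator (`config$input == "synth"`) or from cohort feature CSVs
#' (`config$input == "files"` with `x`, `y`, `manifest`, `parcellation`
#' paths).
#'
#' @param config named list (see package vignette), or path to a YAML file.
#' @param out_dir output directory, created if missing.
#' @param seed overrides `config$seed` when non-NULL.
#' @return invisibly, a list with the fitted model, selected edges,
#'   annotations and summary (also written to disk).
#' @export
run_pipeline <- function(config = list(), out_dir, seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  cfg <- utils::modifyList(.default_config(), config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  digests <- character(0)

  truth <- NULL
  if (identical(cfg$input, "synth")) {
    synth_args <- utils::modifyList(list(seed = cfg$seed), cfg$synth)
    truth <- .stage("synth", {
      generate_cohort(do.call(synth_config, synth_args))
    })
    data <- truth$data
    parcellation <- truth$parcellation
    index_map <- truth$index_map
    write_feature_matrix(data$X, index_map, file.path(out_dir, "features_functional.csv"))
    write_feature_matrix(data$Y, index_map, file.path(out_dir, "features_structural.csv"))
    write_parcellation(parcellation, file.path(out_dir, "parcellation.csv"))
    write_manifest(data.frame(subject_id = rownames(data$X),
                              group = as.character(data$labels),
                              birth_age_weeks = {
                                a <- rep(NA_real_, nrow(data$X))
                                a[data$age_rows] <- data$ages
                                a
                              }),
                   file.path(out_dir, "subjects.csv"))
  } else {
    loaded <- .stage("load", {
      fx <- read_feature_matrix(cfg$x)
      fy <- read_feature_matrix(cfg$y)
      if (!identical(fx$index_map, fy$index_map)) {
        stop("functional and structural files disagree on edge indexing")
      }
      man <- read_manifest(cfg$manifest)
      pos <- match(rownames(fx$X), man$subject_id)
      if (anyNA(pos)) stop("subjects missing from manifest: ",
                           paste(utils::head(rownames(fx$X)[is.na(pos)], 5L), collapse = ", "))
      man <- man[pos, ]
      ages <- man$birth_age_weeks[man$group == "preterm"]
      list(data = feature_pair(fx$X, fy$X, man$group,
                               ages = if (all(is.finite(ages))) ages else NULL),
           index_map = fx$index_map,
           parcellation = read_parcellation(cfg$parcellation))
    })
    data <- loaded$data
    index_map <- loaded$index_map
    parcellation <- loaded$parcellation
    digests <- tools::md5sum(c(cfg$x, cfg$y, cfg$manifest, cfg$parcellation))
  }

  mask <- .stage("filter", {
    do.call(ttest_filter, c(list(X = data$X, Y = data$Y, labels = data$labels),
                            cfg$filter))
  })
  write_edge_mask(mask, index_map, file.path(out_dir, "edge_mask.csv"))
  kept <- which(mask$kept)
  if (length(kept) < 2L) stop("pipeline stage 'filter' kept fewer than 2 edges")
  fdata <- feature_pair(data$X[, kept, drop = FALSE], data$Y[, kept, drop = FALSE],
                        data$labels, ages = data$ages, age_rows = data$age_rows)
  fmap <- index_map[kept, , drop = FALSE]

  fit <- .stage("fit", {
    hp <- do.call(cclpp_control, utils::modifyList(list(seed = cfg$seed), cfg$fit))
    cclpp_fit(fdata, hp)
  })
  write_weights(fit$u, fmap, file.path(out_dir, "weights_u.csv"))
  write_weights(fit$v, fmap, file.path(out_dir, "weights_v.csv"))
  write_fit_report(fit, file.path(out_dir, "fit_report.json"))

  sel <- .stage("select", {
    ef <- select_edges(fit$u, fmap, rule = cfg$select$rule, param = cfg$select$param,
                       modality = "functional")
    es <- select_edges(fit$v, fmap, rule = cfg$select$rule, param = cfg$select$param,
                       modality = "structural")
    ef$dominance <- edge_dominance(ef, data$X[, kept, drop = FALSE], data$labels)
    es$dominance <- edge_dominance(es, data$Y[, kept, drop = FALSE], data$labels)
    list(functional = ef, structural = es)
  })

  summary <- .stage("stats", {
    ann_f <- annotate_connections(sel$functional, parcellation,
                                  low = cfg$stats$low, long = cfg$stats$long,
                                  curvature_cut = cfg$stats$curvature_cut)
    ann_s <- annotate_connections(sel$structural, parcellation,
                                  low = cfg$stats$low, long = cfg$stats$long,
                                  curvature_cut = cfg$stats$curvature_cut)
    write_identified_connections(ann_f, file.path(out_dir, "connections_functional.csv"))
    write_identified_connections(ann_s, file.path(out_dir, "connections_structural.csv"))
    rsn_f <- rsn_cooccurrence(sel$functional, parcellation)
    rsn_s <- rsn_cooccurrence(sel$structural, parcellation)
    utils::write.csv(rsn_matrix_full(rsn_f), file.path(out_dir, "rsn_functional.csv"))
    utils::write.csv(rsn_matrix_full(rsn_s), file.path(out_dir, "rsn_structural.csv"))
    overlap <- if (nrow(ann_f) > 0L || nrow(ann_s) > 0L) {
      activation_overlap(sel$functional, sel$structural)
    } else c(jaccard_pct = NA_real_, weighted_pct = NA_real_)
    out <- list(
      n_initial_edges = length(mask$kept),
      n_filtered_edges = length(kept),
      n_identified_functional = nrow(ann_f),
      n_identified_structural = nrow(ann_s),
      canonical_corr = fit$canonical_corr,
      converged = fit$converged,
      n_iter = fit$n_iter,
      jaccard_pct = unname(overlap["jaccard_pct"]),
      weighted_overlap_pct = unname(overlap["weighted_pct"]),
      mean_distance_functional = if (nrow(ann_f)) mean(ann_f$distance) else NA_real_,
      mean_distance_structural = if (nrow(ann_s)) mean(ann_s$distance) else NA_real_,
      length_counts_functional = as.list(table(ann_f$length_class)),
      length_counts_structural = as.list(table(ann_s$length_class)),
      hemi_counts_functional = as.list(table(ann_f$hemi_class)),
      hemi_counts_structural = as.list(table(ann_s$hemi_class)),
      fold_counts_functional = as.list(table(ann_f$fold_class)),
      fold_counts_structural = as.list(table(ann_s$fold_class)),
      dominance_functional = as.list(table(sel$functional$dominance)),
      dominance_structural = as.list(table(sel$structural$dominance)),
      rsn_unassigned_functional = rsn_f$unassigned,
      rsn_unassigned_structural = rsn_s$unassigned
    )
    if (!is.null(truth)) {
      # map supports (defined on the pre-filter edge index) into filter space
      sel_u <- kept[sel$functional$edge_index]
      sel_v <- kept[sel$structural$edge_index]
      out$support_f1_u <- support_f1(sel_u, truth$support_u)
      out$support_f1_v <- support_f1(sel_v, truth$support_v)
    }
    out
  })
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  resolved <- cfg
  write_config(resolved, file.path(out_dir, "config_resolved.yml"))
  manifest <- list(command = "run_pipeline",
                   config = resolved,
                   seed = cfg$seed,
                   input_digests = as.list(digests),
                   tool_version = as.character(utils::packageVersion("cclpp")),
                   started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
                   finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(fit = fit, mask = mask, selected = sel, summary = summary,
                 index_map = index_map, filtered_map = fmap, truth = truth))
}
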