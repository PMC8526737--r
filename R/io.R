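# Delimited-text readers/writers. CSV is the single interchange dialect;
# every feature file carries an explicit e<i>_<j> edge-pair header so edge
# indexing can never silently drift between modalities.

#' Write a cohort feature matrix as CSV with an edge-index header
#'
#' @param X subjects x edges matrix (rownames used as subject ids).
#' @param index_map edge -> (patch_i, patch_j) map matching the columns.
#' @param path output file.
#' @export
write_feature_matrix <- function(X, index_map, path) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(index_map)) stop("X columns and index_map disagree")
  df <- data.frame(subject_id = if (is.null(rownames(X)))
    sprintf("sub%03d", seq_len(nrow(X))) else rownames(X),
    X, check.names = FALSE)
  names(df)[-1L] <- edge_names(index_map)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort feature matrix written by [write_feature_matrix()]
#'
#' @param path CSV file with a `subject_id` column and `e<i>_<j>` edge
#'   columns.
#' @return list with `X` (matrix, subject ids as rownames) and `index_map`.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"subject_id" %in% names(df)) stop("feature file is missing column: subject_id")
  en <- setdiff(names(df), "subject_id")
  parts <- regmatches(en, regexec("^e([0-9]+)_([0-9]+)$", en))
  if (any(lengths(parts) != 3L)) {
    stop("malformed edge column name(s): ",
         paste(utils::head(en[lengths(parts) != 3L], 3L), collapse = ", "))
  }
  index_map <- cbind(patch_i = as.integer(vapply(parts, `[`, "", 2L)),
                     patch_j = as.integer(vapply(parts, `[`, "", 3L)))
  X <- as.matrix(df[, en, drop = FALSE])
  rownames(X) <- df$subject_id
  list(X = X, index_map = index_map)
}

#' Read a subject manifest (subject_id, group, birth_age_weeks)
#'
#' @param path CSV file.
#' @return validated data.frame.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "group", "birth_age_weeks")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Write a subject manifest
#' @param manifest data.frame with subject_id, group, birth_age_weeks.
#' @param path output CSV.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a parcellation table from CSV
#' @param path CSV with patch_id, x, y, z, hemisphere, mean_curvature and
#'   optional rsn_label, atlas_area columns.
#' @return a validated `parcellation`.
#' @export
read_parcellation <- function(path) {
  as_parcellation(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a parcellation table to CSV
#' @param parcellation a `parcellation` table.
#' @param path output CSV.
#' @export
write_parcellation <- function(parcellation, path) {
  utils::write.csv(as.data.frame(parcellation), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the kept-edge mask with its per-modality p-values
#' @param mask an `edge_mask`.
#' @param index_map edge -> patch-pair map.
#' @param path output CSV listing kept edges only.
#' @export
write_edge_mask <- function(mask, index_map, path) {
  kept <- which(mask$kept)
  df <- data.frame(edge_index = kept,
                   patch_i = index_map[kept, 1L],
                   patch_j = index_map[kept, 2L],
                   p_functional = mask$p_functional[kept],
                   p_structural = mask$p_structural[kept])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write canonical weights as a two-column table
#' @param w weight vector over the filtered edges.
#' @param index_map patch-pair map for those edges.
#' @param path output CSV (edge name, patch pair, weight).
#' @export
write_weights <- function(w, index_map, path) {
  df <- data.frame(edge = edge_names(index_map),
                   patch_i = index_map[, 1L], patch_j = index_map[, 2L],
                   weight = w)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an identified-connections table (optionally with dominance)
#' @param edges an `identified_connections` object or annotated data.frame.
#' @param path output CSV.
#' @export
write_identified_connections <- function(edges, path) {
  utils::write.csv(as.data.frame(edges), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a JSON fit report
#' @param fit a `cclpp_fit`.
#' @param path output JSON file.
#' @export
write_fit_report <- function(fit, path) {
  rep <- list(n_iter = fit$n_iter,
              converged = fit$converged,
              canonical_corr = fit$canonical_corr,
              n_nonzero_u = length(fit$support_u),
              n_nonzero_v = length(fit$support_v),
              zero_u = fit$zero_u, zero_v = fit$zero_v,
              objective_history = fit$objective_history)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a YAML run configuration
#' @param path YAML file.
#' @return named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' Write a resolved YAML configuration copy
#' @param config named list.
#' @param path output YAML file.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
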