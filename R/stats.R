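# Post-hoc characterization of identified connections: Euclidean length
# classes, hemispheric type, resting-state-network co-occurrence, cortical
# folding classes, activation-area overlap, and grouped connection
# summaries.

#' Validate a parcellation table
#'
#' @param df data.frame with columns `patch_id`, `x`, `y`, `z`,
#'   `hemisphere` (`"left"`/`"right"`), `mean_curvature`, and optionally
#'   `rsn_label` (integer 1..9 or NA for unassigned) and `atlas_area`.
#' @return the validated data.frame, classed `parcellation`.
#' @export
as_parcellation <- function(df) {
  req <- c("patch_id", "x", "y", "z", "hemisphere", "mean_curvature")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("parcellation is missing column(s): ", paste(miss, collapse = ", "))
  if (anyNA(df$hemisphere)) stop("hemisphere must be defined for every patch")
  if (!all(df$hemisphere %in% c("left", "right"))) {
    stop("hemisphere must be 'left' or 'right'")
  }
  if (any(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z))) {
    stop("patch centroids must be finite")
  }
  if (anyDuplicated(df$patch_id)) stop("duplicate patch_id")
  class(df) <- unique(c("parcellation", class(df)))
  df
}

.parc_lookup <- function(parcellation, patch, column) {
  pos <- match(patch, parcellation$patch_id)
  if (anyNA(pos)) {
    stop("patch id(s) not in parcellation: ",
         paste(utils::head(patch[is.na(pos)], 5L), collapse = ", "))
  }
  parcellation[[column]][pos]
}

#' Centroid of a patch from its vertex coordinates
#'
#' @param vertex_coords numeric matrix (k x 3) of vertex positions in mm.
#' @return length-3 coordinate-wise mean.
#' @export
patch_centroid <- function(vertex_coords) {
  vc <- as.matrix(vertex_coords)
  if (nrow(vc) < 1L) stop("need at least one vertex")
  if (ncol(vc) != 3L) stop("vertex coordinates must be (x, y, z)")
  colMeans(vc)
}

#' Euclidean distance between two patch centroids
#' @param c1,c2 length-3 coordinates.
#' @return nonnegative distance in centroid units.
#' @export
connection_distance <- function(c1, c2) {
  if (any(!is.finite(c1)) || any(!is.finite(c2))) stop("centroids must be finite")
  sqrt(sum((c1 - c2)^2))
}

#' Classify connection length
#'
#' Low for distance <= `low`, medium for `low` < distance <= `long`, long
#' above `long`. The default thresholds 10 and 20 are in the same units as
#' the parcellation centroids.
#'
#' @param d nonnegative distance(s).
#' @param low,long class boundaries (defaults 10 and 20).
#' @return factor with levels `c("low", "medium", "long")`.
#' @export
classify_length <- function(d, low = 10, long = 20) {
  if (any(d < 0)) stop("distances must be nonnegative")
  out <- ifelse(d <= low, "low", ifelse(d <= long, "medium", "long"))
  factor(out, levels = c("low", "medium", "long"))
}

#' Classify a connection as inter- or intra-hemispheric
#'
#' @param patch_i,patch_j patch ids (vectorized).
#' @param parcellation a `parcellation` table.
#' @return factor with levels `c("inter", "intra")`.
#' @export
classify_hemisphere <- function(patch_i, patch_j, parcellation) {
  hi <- .parc_lookup(parcellation, patch_i, "hemisphere")
  hj <- .parc_lookup(parcellation, patch_j, "hemisphere")
  factor(ifelse(hi == hj, "intra", "inter"), levels = c("inter", "intra"))
}

#' Percentage of a count, rounded half-up to two decimals
#'
#' @param count,total nonnegative integers with `0 <= count <= total`,
#'   `total > 0`.
#' @return `100 * count / total` rounded half-up to 2 decimals.
#' @examples
#' proportion_pct(4, 89)   # 4.49
#' proportion_pct(27, 97)  # 27.84
#' @export
proportion_pct <- function(count, total) {
  if (any(total <= 0)) stop("total must be positive")
  if (any(count < 0 | count > total)) stop("count must be in [0, total]")
  round_half_up(100 * count / total, 2)
}

#' Resting-state-network co-occurrence matrix of identified connections
#'
#' Each connection whose two patches both carry an RSN label increments
#' exactly one unordered cell (a <= b); self-connections of a network (the
#' diagonal) are allowed. Connections touching an unlabeled patch are
#' tallied in an `unassigned` bucket, so cells + unassigned = n_edges.
#'
#' @param edges an `identified_connections` object (needs `patch_i`,
#'   `patch_j`).
#' @param parcellation a `parcellation` table with an `rsn_label` column.
#' @param n_networks number of reference networks (default 9).
#' @return list of class `rsn_cooccurrence`: `matrix` (counts stored in
#'   the upper triangle including the diagonal), `unassigned`, `n_edges`.
#' @export
rsn_cooccurrence <- function(edges, parcellation, n_networks = 9L) {
  if (is.null(parcellation$rsn_label)) stop("parcellation has no rsn_label column")
  K <- as.integer(n_networks)
  M <- matrix(0L, K, K, dimnames = list(paste0("rsn", 1:K), paste0("rsn", 1:K)))
  n_edges <- NROW(edges)
  unassigned <- 0L
  if (n_edges > 0L) {
    ri <- .parc_lookup(parcellation, edges$patch_i, "rsn_label")
    rj <- .parc_lookup(parcellation, edges$patch_j, "rsn_label")
    bad <- is.na(ri) | is.na(rj)
    unassigned <- sum(bad)
    if (any(!bad)) {
      a <- pmin(ri[!bad], rj[!bad])
      b <- pmax(ri[!bad], rj[!bad])
      if (any(a < 1L | b > K)) stop("rsn_label outside 1..", K)
      for (e in seq_along(a)) M[a[e], b[e]] <- M[a[e], b[e]] + 1L
    }
  }
  structure(list(matrix = M, unassigned = unassigned, n_edges = n_edges),
            class = "rsn_cooccurrence")
}

#' Mirror an RSN co-occurrence matrix for display
#' @param x an `rsn_cooccurrence` object.
#' @return symmetric matrix (diagonal kept once).
#' @export
rsn_matrix_full <- function(x) {
  M <- x$matrix
  M + t(M) - diag(diag(M))
}

#' Classify a connection by the cortical folding of its two patches
#'
#' A patch is a gyrus when its mean curvature is at or above `cut`
#' (default 0.5), a sulcus below; the connection class is the unordered
#' pair: `"g-g"`, `"g-s"`, or `"s-s"`.
#'
#' @param patch_i,patch_j patch ids (vectorized).
#' @param parcellation a `parcellation` table.
#' @param cut gyrus/sulcus curvature boundary (default 0.5; the boundary
#'   value itself counts as gyrus).
#' @return factor with levels `c("g-g", "g-s", "s-s")`.
#' @export
classify_folding <- function(patch_i, patch_j, parcellation, cut = 0.5) {
  ci <- .parc_lookup(parcellation, patch_i, "mean_curvature")
  cj <- .parc_lookup(parcellation, patch_j, "mean_curvature")
  if (anyNA(ci) || anyNA(cj)) stop("missing mean_curvature for some patch")
  gi <- ci >= cut; gj <- cj >= cut
  n_g <- gi + gj
  factor(ifelse(n_g == 2L, "g-g", ifelse(n_g == 1L, "g-s", "s-s")),
         levels = c("g-g", "g-s", "s-s"))
}

#' Overlap of functional and structural activation areas
#'
#' The activation area of a modality is the set of patches touched by at
#' least one identified connection. `jaccard_pct` is the Jaccard similarity
#' of the two patch sets; `weighted_pct` additionally weights each patch by
#' its activation count (number of identified connections touching it),
#' i.e. a weighted Jaccard `sum(min) / sum(max)` over per-patch counts.
#'
#' @param edges_f,edges_s identified connections for the functional and
#'   structural views, over a shared patch index.
#' @return named vector `c(jaccard_pct, weighted_pct)` in percent, rounded
#'   half-up to 2 decimals.
#' @export
activation_overlap <- function(edges_f, edges_s) {
  pf <- c(edges_f$patch_i, edges_f$patch_j)
  ps <- c(edges_s$patch_i, edges_s$patch_j)
  if (length(pf) == 0L && length(ps) == 0L) stop("both edge lists are empty")
  patches <- sort(unique(c(pf, ps)))
  cf <- tabulate(match(pf, patches), nbins = length(patches))
  cs <- tabulate(match(ps, patches), nbins = length(patches))
  inter <- sum(cf > 0 & cs > 0)
  uni <- sum(cf > 0 | cs > 0)
  jac <- 100 * inter / uni
  wjac <- 100 * sum(pmin(cf, cs)) / sum(pmax(cf, cs))
  c(jaccard_pct = round_half_up(jac, 2), weighted_pct = round_half_up(wjac, 2))
}

#' Annotate identified connections with all post-hoc classifications
#'
#' @param edges an `identified_connections` object.
#' @param parcellation a `parcellation` table.
#' @param low,long distance-class boundaries (defaults 10, 20).
#' @param curvature_cut gyrus/sulcus boundary (default 0.5).
#' @return data.frame: the edge columns plus `distance`, `length_class`,
#'   `hemi_class`, `fold_class`, `rsn_i`, `rsn_j`.
#' @export
annotate_connections <- function(edges, parcellation, low = 10, long = 20,
                                 curvature_cut = 0.5) {
  if (NROW(edges) == 0L) {
    return(cbind(as.data.frame(edges),
                 distance = numeric(0), length_class = factor(character(0)),
                 hemi_class = factor(character(0)), fold_class = factor(character(0)),
                 rsn_i = integer(0), rsn_j = integer(0)))
  }
  xi <- cbind(.parc_lookup(parcellation, edges$patch_i, "x"),
              .parc_lookup(parcellation, edges$patch_i, "y"),
              .parc_lookup(parcellation, edges$patch_i, "z"))
  xj <- cbind(.parc_lookup(parcellation, edges$patch_j, "x"),
              .parc_lookup(parcellation, edges$patch_j, "y"),
              .parc_lookup(parcellation, edges$patch_j, "z"))
  d <- sqrt(rowSums((xi - xj)^2))
  out <- as.data.frame(edges)
  out$distance <- d
  out$length_class <- classify_length(d, low = low, long = long)
  out$hemi_class <- classify_hemisphere(edges$patch_i, edges$patch_j, parcellation)
  out$fold_class <- classify_folding(edges$patch_i, edges$patch_j, parcellation,
                                     cut = curvature_cut)
  if (!is.null(parcellation$rsn_label)) {
    out$rsn_i <- .parc_lookup(parcellation, edges$patch_i, "rsn_label")
    out$rsn_j <- .parc_lookup(parcellation, edges$patch_j, "rsn_label")
  }
  out
}

#' Intra- versus inter-cell connection summary under a patch grouping
#'
#' Tallies identified connections into unordered cells of a patch grouping
#' (atlas areas or resting-state networks), then summarizes and compares
#' the intra-cell (diagonal) and inter-cell (off-diagonal) count
#' distributions with the same pooled two-sample t-test used for edge
#' screening.
#'
#' @param edges an `identified_connections` object.
#' @param parcellation a `parcellation` table.
#' @param grouping `"atlas_area"` or `"rsn"`.
#' @return list: `intra` and `inter` (count vectors), `intra_mean`,
#'   `intra_sd`, `inter_mean`, `inter_sd`, `p_value`, `n_unassigned`.
#' @export
group_connection_summary <- function(edges, parcellation,
                                     grouping = c("atlas_area", "rsn")) {
  grouping <- match.arg(grouping)
  col <- if (grouping == "rsn") "rsn_label" else "atlas_area"
  if (is.null(parcellation[[col]])) stop("parcellation has no ", col, " column")
  labs <- sort(unique(stats::na.omit(parcellation[[col]])))
  K <- length(labs)
  if (K < 2L) stop("grouping must have at least 2 cells, got ", K)
  M <- matrix(0L, K, K, dimnames = list(labs, labs))
  n_unassigned <- 0L
  if (NROW(edges) > 0L) {
    gi <- match(.parc_lookup(parcellation, edges$patch_i, col), labs)
    gj <- match(.parc_lookup(parcellation, edges$patch_j, col), labs)
    bad <- is.na(gi) | is.na(gj)
    n_unassigned <- sum(bad)
    a <- pmin(gi[!bad], gj[!bad]); b <- pmax(gi[!bad], gj[!bad])
    for (e in seq_along(a)) M[a[e], b[e]] <- M[a[e], b[e]] + 1L
  }
  intra <- diag(M)
  inter <- M[upper.tri(M)]
  counts <- c(intra, inter)
  side <- factor(rep(c("intra", "inter"), c(length(intra), length(inter))))
  p <- if (length(intra) >= 2L && length(inter) >= 2L) {
    col_ttest(matrix(counts, ncol = 1L), side)$p.value
  } else NA_real_
  list(matrix = M, intra = as.integer(intra), inter = as.integer(inter),
       intra_mean = mean(intra), intra_sd = stats::sd(intra),
       inter_mean = mean(inter), inter_sd = stats::sd(inter),
       p_value = as.numeric(p), n_unassigned = n_unassigned,
       grouping = grouping)
}
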