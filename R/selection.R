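# Turning fitted canonical weights into identified connections.

#' Select identified connections from a canonical weight vector
#'
#' The L1 penalty makes most weights exactly zero, so the natural rule is
#' `"nonzero"` (|w| above a numerical tolerance). `"top_k"` forces an exact
#' count (ties broken toward the lower edge index); `"abs_threshold"` keeps
#' |w| strictly above a user threshold.
#'
#' @param w canonical weight vector over the filtered edge set.
#' @param index_map integer matrix of (patch_i, patch_j) rows matching `w`.
#' @param rule `"nonzero"` (default), `"top_k"`, or `"abs_threshold"`.
#' @param param `k` for `"top_k"`; the threshold for `"abs_threshold"`.
#' @param modality optional `"functional"`/`"structural"` tag.
#' @param zero_tol numerical zero for the `"nonzero"` rule.
#' @return an object of class `identified_connections`: a data.frame with
#'   columns `edge_index`, `patch_i`, `patch_j`, `weight`, plus attributes
#'   `modality`, `n_edges`, `rule`.
#' @export
select_edges <- function(w, index_map, rule = c("nonzero", "top_k", "abs_threshold"),
                         param = NULL, modality = NULL, zero_tol = 1e-8) {
  rule <- match.arg(rule)
  if (length(w) != nrow(index_map)) stop("w and index_map disagree in length")
  idx <- switch(rule,
    nonzero = which(abs(w) > zero_tol),
    top_k = {
      if (is.null(param)) stop("top_k rule needs param = k")
      k <- as.integer(param)
      if (k < 0L || k > length(w)) stop("k must be in [0, ", length(w), "]")
      ord <- order(-abs(w), seq_along(w))
      sort(ord[seq_len(k)])
    },
    abs_threshold = {
      if (is.null(param) || param < 0) stop("abs_threshold rule needs param >= 0")
      which(abs(w) > param)
    })
  if (rule == "nonzero" && length(idx) == 0L) {
    warning("all weights are zero under the nonzero rule; returning an empty set")
  }
  out <- data.frame(edge_index = idx,
                    patch_i = index_map[idx, 1L],
                    patch_j = index_map[idx, 2L],
                    weight = w[idx])
  structure(out, class = c("identified_connections", "data.frame"),
            modality = modality, n_edges = nrow(out), rule = rule)
}

#' Group dominance of identified connections
#'
#' Labels each identified edge by which group has the larger mean feature
#' value: `"<group>_dominant"`, or `"tie"` on exact equality. For the
#' functional view a term-dominant edge means term infants have stronger
#' correlation on it; for the structural view a preterm-dominant edge means
#' preterm infants have more fibers.
#'
#' @param edges an `identified_connections` object (or data.frame with an
#'   `edge_index` column).
#' @param X cohort feature matrix (subjects x edges) the weights were fit on.
#' @param labels two-level group vector.
#' @return factor of per-edge dominance labels, levels
#'   `c("<g1>_dominant", "<g2>_dominant", "tie")`.
#' @export
edge_dominance <- function(edges, X, labels) {
  labels <- as.factor(as.character(labels))
  if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
  idx <- edges$edge_index
  if (any(idx < 1L | idx > ncol(X))) stop("edge_index out of range of X")
  g1 <- levels(labels)[1L]; g2 <- levels(labels)[2L]
  m1 <- colMeans(X[labels == g1, idx, drop = FALSE])
  m2 <- colMeans(X[labels == g2, idx, drop = FALSE])
  lev <- c(paste0(g1, "_dominant"), paste0(g2, "_dominant"), "tie")
  out <- ifelse(m1 > m2, lev[1L], ifelse(m2 > m1, lev[2L], "tie"))
  factor(out, levels = lev)
}
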