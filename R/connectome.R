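# Per-subject connectome construction, edge vectorization, and the
# two-sample t-test edge screen that defines the common initial edge set.

#' Construct a per-subject connectome matrix object
#'
#' Light container used by both modalities: a symmetric patch-by-patch
#' weight matrix tagged with its modality and subject id.
#'
#' @param weights symmetric numeric P x P matrix.
#' @param modality `"functional"` or `"structural"`.
#' @param subject_id optional identifier carried through to outputs.
#' @return an object of class `connectome_matrix`.
#' @export
connectome_matrix <- function(weights, modality = c("functional", "structural"),
                              subject_id = NULL) {
  modality <- match.arg(modality)
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("weights must be square")
  if (max(abs(weights - t(weights))) > 1e-8) stop("weights must be symmetric")
  structure(list(weights = weights, modality = modality, subject_id = subject_id),
            class = "connectome_matrix")
}

#' @export
print.connectome_matrix <- function(x, ...) {
  cat(sprintf("<connectome_matrix> %s, %d patches%s\n", x$modality, nrow(x$weights),
              if (is.null(x$subject_id)) "" else paste0(", subject ", x$subject_id)))
  invisible(x)
}

#' Build a functional connectome from patch-averaged fMRI signals
#'
#' Each edge weight is the Pearson correlation of the mean fMRI time series
#' of the two patches; the diagonal is 1 by construction.
#'
#' @param signals numeric T x P matrix (rows = time points, columns =
#'   patches), or a list of P equal-length numeric vectors.
#' @param subject_id optional identifier.
#' @return a `connectome_matrix` with `modality = "functional"`.
#' @examples
#' s <- generate_toy_signals(n_patches = 8, T = 40, seed = 1)
#' fc <- build_functional_connectome(s)
#' @export
build_functional_connectome <- function(signals, subject_id = NULL) {
  if (is.list(signals) && !is.data.frame(signals)) {
    lens <- vapply(signals, length, integer(1))
    if (length(unique(lens)) != 1L) {
      stop("patch signals differ in length (", paste(unique(lens), collapse = ", "), ")")
    }
    signals <- do.call(cbind, signals)
  }
  signals <- as.matrix(signals)
  if (nrow(signals) < 3L) stop("signals must have at least 3 time points, got ", nrow(signals))
  if (anyNA(signals)) stop("signals contain missing values")
  sds <- apply(signals, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance signal for patch(es): ", paste(which(sds == 0), collapse = ", "))
  }
  W <- stats::cor(signals)
  diag(W) <- 1
  connectome_matrix(W, "functional", subject_id)
}

#' Build a structural connectome from fiber endpoint pairs
#'
#' Each edge weight is the count of tractography fibers whose two endpoints
#' fall in the two patches (unordered). Self-fibers (both endpoints in the
#' same patch) are dropped, so the diagonal is 0.
#'
#' @param fiber_endpoints two-column matrix/data.frame of 1-based patch
#'   indices, one row per fiber; may have zero rows.
#' @param n_patches number of patches P.
#' @param subject_id optional identifier.
#' @return a `connectome_matrix` with `modality = "structural"` and
#'   nonnegative integer weights.
#' @export
build_structural_connectome <- function(fiber_endpoints, n_patches, subject_id = NULL) {
  n_patches <- as.integer(n_patches)
  if (n_patches < 1L) stop("n_patches must be positive")
  W <- matrix(0L, n_patches, n_patches)
  if (!is.null(fiber_endpoints) && NROW(fiber_endpoints) > 0L) {
    ep <- as.matrix(fiber_endpoints)
    if (ncol(ep) != 2L) stop("fiber_endpoints must have two columns")
    storage.mode(ep) <- "integer"
    if (anyNA(ep) || any(ep < 1L) || any(ep > n_patches)) {
      bad <- which(is.na(ep) | ep < 1L | ep > n_patches)
      stop("fiber endpoint index out of range [1, ", n_patches, "] at position(s): ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
    i <- pmin(ep[, 1L], ep[, 2L])
    j <- pmax(ep[, 1L], ep[, 2L])
    keep <- i != j
    if (any(keep)) {
      idx <- (j[keep] - 1L) * n_patches + i[keep]
      counts <- tabulate(idx, nbins = n_patches * n_patches)
      W <- matrix(counts, n_patches, n_patches)
      W <- W + t(W)
    }
  }
  connectome_matrix(W, "structural", subject_id)
}

#' Edge index map for the strict upper triangle
#'
#' Fixed edge ordering shared by all subjects and modalities: row-major
#' strict upper triangle, i.e. (1,2), (1,3), ..., (1,P), (2,3), ...
#'
#' @param n_patches number of patches P.
#' @return integer matrix with columns `patch_i`, `patch_j` (i < j) and
#'   `P*(P-1)/2` rows.
#' @export
edge_index_map <- function(n_patches) {
  P <- as.integer(n_patches)
  if (P < 2L) stop("need at least 2 patches")
  i <- rep.int(seq_len(P - 1L), times = (P - 1L):1L)
  j <- sequence((P - 1L):1L) + i
  cbind(patch_i = i, patch_j = j)
}

#' Human-readable edge names ("e<i>_<j>") for an index map
#' @param index_map matrix from [edge_index_map()].
#' @return character vector of edge names.
#' @export
edge_names <- function(index_map) {
  paste0("e", index_map[, 1L], "_", index_map[, 2L])
}

#' Vectorize a connectome matrix into its upper-triangle edge vector
#'
#' @param x a `connectome_matrix` or plain symmetric matrix.
#' @param tol symmetry tolerance; larger asymmetries are an error.
#' @return an object of class `edge_vector`: list with `values` (length
#'   P*(P-1)/2) and `index_map`.
#' @export
vectorize_connectome <- function(x, tol = 1e-8) {
  W <- if (inherits(x, "connectome_matrix")) x$weights else as.matrix(x)
  if (nrow(W) != ncol(W)) stop("matrix must be square")
  if (max(abs(W - t(W))) > tol) stop("matrix is asymmetric beyond tolerance ", tol)
  im <- edge_index_map(nrow(W))
  structure(list(values = W[im], index_map = im), class = "edge_vector")
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [vectorize_connectome()] up to the diagonal, which is filled
#' with `diag_value`.
#'
#' @param values numeric edge vector.
#' @param index_map matrix from [edge_index_map()].
#' @param n_patches number of patches P.
#' @param diag_value value placed on the diagonal.
#' @return symmetric P x P matrix.
#' @export
devectorize_edges <- function(values, index_map, n_patches, diag_value = 0) {
  if (length(values) != nrow(index_map)) stop("values and index_map disagree in length")
  W <- matrix(0, n_patches, n_patches)
  W[index_map] <- values
  W <- W + t(W)
  diag(W) <- diag_value
  W
}

#' Two-sample t-test edge screen across both modalities
#'
#' Per-edge two-sample t-tests between the two subject groups, computed
#' independently for the functional features `X` and structural features
#' `Y`; an edge enters the common initial set only when it is significant
#' in both modalities (p < alpha in each). No multiple-testing correction
#' is applied at this stage: the screen is a deliberately permissive raw
#' p < alpha filter whose only job is dimension reduction before the
#' canonical analysis.
#'
#' @param X,Y numeric subjects x edges matrices sharing edge indexing.
#' @param labels length-n two-level group vector (e.g. preterm/term).
#' @param alpha significance level in (0, 1); default 0.05.
#' @param var_equal pooled-variance Student test (default) or Welch.
#' @return an object of class `edge_mask`: `kept` (logical), `p_functional`,
#'   `p_structural`, `n_kept`, `alpha`.
#' @export
ttest_filter <- function(X, Y, labels, alpha = 0.05, var_equal = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y))) stop("X and Y must share dimensions")
  if (length(labels) != nrow(X)) stop("labels length must match the number of subjects")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  tx <- col_ttest(X, labels, var_equal = var_equal)
  ty <- col_ttest(Y, labels, var_equal = var_equal)
  n_degen <- sum(tx$degenerate) + sum(ty$degenerate)
  if (n_degen > 0L) {
    warning(n_degen, " edge test(s) had zero within-group variance; their p-values were set to 1")
  }
  kept <- (tx$p.value < alpha) & (ty$p.value < alpha)
  structure(list(kept = kept,
                 p_functional = tx$p.value,
                 p_structural = ty$p.value,
                 n_kept = sum(kept),
                 alpha = alpha,
                 var_equal = var_equal),
            class = "edge_mask")
}

#' @export
print.edge_mask <- function(x, ...) {
  cat(sprintf("<edge_mask> kept %d of %d edges at p < %g in both modalities\n",
              x$n_kept, length(x$kept), x$alpha))
  invisible(x)
}
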