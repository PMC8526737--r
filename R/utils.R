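# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All package randomness flows through this so generators are pure functions
# of (config, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Round half away from zero (printed-table convention), not banker's rounding.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

soft_threshold <- function(x, t) {
  sign(x) * pmax(abs(x) - t, 0)
}

# Column-wise two-sample t-tests of the rows of M split by the two-level
# grouping `g`.  Pooled-variance (Student) by default, Welch optional.
# Columns where the test is degenerate (zero variance in both groups, or a
# zero pooled variance) get p = 1; the caller decides how to report that.
col_ttest <- function(M, g, var_equal = TRUE) {
  M <- as.matrix(M)
  g <- as.factor(as.character(g))
  if (nlevels(g) != 2L) stop("grouping must have exactly two levels, got ", nlevels(g))
  i1 <- g == levels(g)[1L]
  i2 <- g == levels(g)[2L]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 subjects (got ", n1, " and ", n2, ")")
  m1 <- colMeans(M[i1, , drop = FALSE])
  m2 <- colMeans(M[i2, , drop = FALSE])
  v1 <- apply(M[i1, , drop = FALSE], 2L, stats::var)
  v2 <- apply(M[i2, , drop = FALSE], 2L, stats::var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  stat <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(stat), df)
  degenerate <- !is.finite(se) | se == 0
  p[degenerate] <- 1
  stat[degenerate] <- NA_real_
  list(statistic = stat, df = df, p.value = p, degenerate = degenerate)
}

#' F1 score of a recovered edge-support set against a known truth set
#'
#' Harmonic mean of precision and recall of `selected` with respect to
#' `truth`, both given as integer index sets. Used to score how well the
#' sparse canonical weights recover a planted edge support.
#'
#' @param selected integer indices recovered (e.g. nonzero weight positions).
#' @param truth integer indices of the true support.
#' @return a single number in `[0, 1]`; 0 when the intersection is empty.
#' @export
support_f1 <- function(selected, truth) {
  selected <- unique(as.integer(selected))
  truth <- unique(as.integer(truth))
  tp <- length(intersect(selected, truth))
  if (tp == 0L) return(0)
  precision <- tp / length(selected)
  recall <- tp / length(truth)
  2 * precision * recall / (precision + recall)
}
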