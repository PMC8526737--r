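# Sparse CCA with a locality-preserving-projection (LPP) penalty.
#
# The model couples two feature views X, Y (subjects x edges) through a
# bilinear correlation term, discriminates two subject groups through
# graph-Laplacian quadratic forms on the projected scores, regresses the
# preterm canonical scores onto birth age, and induces edge sparsity with
# L1 penalties.  Fitting alternates convex subproblems in u and v, each
# solved by proximal gradient (iterative soft-thresholding) with a
# backtracking line search, then projected back onto its unit-variance
# constraint sphere.

#' Hyperparameters for the sparse CCA-LPP fit
#'
#' The single-value arguments `lambda`, `beta`, `gamma`, `omega` set both
#' per-view weights at once (the usual reporting convention); the
#' `*1`/`*2` arguments override them individually.
#'
#' @param lambda ridge weight on the projected scores `||Xu||^2`, `||Yv||^2`
#'   (suggested 0.9).
#' @param beta LPP (group-discrimination) weight (suggested 0.8).
#' @param gamma birth-age regression weight (suggested 0.8).
#' @param omega L1 sparsity weight. The default 0.5 is calibrated for
#'   column-standardized features (the package's input convention); the
#'   0.8 often suggested in the sparse CCA-LPP literature presumes a
#'   different feature scaling.
#' @param eta elastic-net style L2 penalty on the weight coefficients
#'   themselves (default 2). Controls how strongly the subproblem
#'   solutions shrink before renormalization; larger values damp
#'   in-sample overfitting of the age-regression and LPP terms and give
#'   the grouping effect needed when many signal edges share a latent
#'   factor.
#' @param alpha LPP trade-off in `[0, 1]` between within-group compactness
#'   (`alpha`) and between-group separation (`1 - alpha`); default 0.5.
#' @param tol outer stop threshold (default 1e-6) on the max-norm change of
#'   `(u, v)`; with `convergence = "objective"`, on the relative objective
#'   change instead.
#' @param max_iter outer iteration cap.
#' @param inner_tol,inner_max_iter proximal-gradient subproblem tolerance
#'   and cap.
#' @param eps stabilizing ridge added to `X'X`/`Y'Y` for normalization and
#'   (as `eps * ||w||^2`) to each subproblem; needed because m >> n makes
#'   the Gram matrices singular.
#' @param standardize z-score the columns of X and Y and the age vector
#'   before fitting (default TRUE).
#' @param convergence `"weights"` (default) or `"objective"`.
#' @param gram how the score ridge treats the Gram matrix `X'X`:
#'   `"diagonal"` (default; ridge acts on the coefficients, the usual
#'   high-dimensional sparse-CCA approximation) or `"exact"` (the literal
#'   `||Xu||^2`, used e.g. to reduce to classical CCA).
#' @param init deterministic initialization: `"tstat"` (default; per-edge
#'   standardized group-mean differences) or `"ones"`.
#' @param n_restarts number of additional random initializations (seeded);
#'   0 keeps only the deterministic start.
#' @param seed seed for the random restarts.
#' @param lambda1,lambda2,beta1,beta2,gamma1,gamma2,omega1,omega2,eta1,eta2
#'   per-view overrides of the single-value weights.
#' @return an object of class `cclpp_control`.
#' @export
cclpp_control <- function(lambda = 0.9, beta = 0.8, gamma = 0.8, omega = 0.5,
                          eta = 2, alpha = 0.5, tol = 1e-6, max_iter = 200L,
                          gram = c("diagonal", "exact"),
                          inner_tol = 1e-8, inner_max_iter = 500L,
                          eps = 1e-6, standardize = TRUE,
                          convergence = c("weights", "objective"),
                          init = c("tstat", "ones"),
                          n_restarts = 0L, seed = 1L,
                          lambda1 = lambda, lambda2 = lambda,
                          beta1 = beta, beta2 = beta,
                          gamma1 = gamma, gamma2 = gamma,
                          omega1 = omega, omega2 = omega,
                          eta1 = eta, eta2 = eta) {
  convergence <- match.arg(convergence)
  gram <- match.arg(gram)
  init <- match.arg(init)
  hp <- list(gram = gram, init = init, lambda1 = lambda1, lambda2 = lambda2, beta1 = beta1, beta2 = beta2,
             gamma1 = gamma1, gamma2 = gamma2, omega1 = omega1, omega2 = omega2,
             eta1 = eta1, eta2 = eta2,
             alpha = alpha, tol = tol, max_iter = as.integer(max_iter),
             inner_tol = inner_tol, inner_max_iter = as.integer(inner_max_iter),
             eps = eps, standardize = isTRUE(standardize),
             convergence = convergence, n_restarts = as.integer(n_restarts),
             seed = as.integer(seed))
  stopifnot(all(unlist(hp[c("lambda1", "lambda2", "beta1", "beta2",
                            "gamma1", "gamma2", "omega1", "omega2",
                            "eta1", "eta2")]) >= 0))
  if (!(alpha >= 0 && alpha <= 1)) stop("alpha must be in [0, 1]")
  if (!(tol > 0)) stop("tol must be positive")
  structure(hp, class = "cclpp_control")
}

#' Cohort-level paired feature container
#'
#' @param X,Y numeric subjects x edges matrices (functional and structural
#'   features) sharing shape and edge indexing.
#' @param labels length-n two-level group vector.
#' @param ages birth ages (weeks) of the subjects in `age_group`, in the
#'   order those subjects appear in `X`; may be NULL when the age
#'   regression is not used.
#' @param age_rows row indices of `X`/`Y` the ages correspond to; inferred
#'   from `labels == age_group` when NULL.
#' @param age_group label of the group carrying ages (default "preterm").
#' @return an object of class `feature_pair`.
#' @export
feature_pair <- function(X, Y, labels, ages = NULL, age_rows = NULL,
                         age_group = "preterm") {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y))) stop("X and Y must share shape")
  labels <- as.factor(as.character(labels))
  if (length(labels) != nrow(X)) stop("labels length must match nrow(X)")
  if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
  if (!is.null(ages)) {
    if (is.null(age_rows)) {
      if (!age_group %in% levels(labels)) {
        stop("age_group '", age_group, "' is not a level of labels")
      }
      age_rows <- which(labels == age_group)
    }
    if (length(ages) != length(age_rows)) stop("ages and age_rows disagree in length")
    if (any(!is.finite(ages)) || any(ages <= 0)) stop("ages must be finite and positive")
  }
  structure(list(X = X, Y = Y, labels = labels, ages = ages,
                 age_rows = as.integer(age_rows)),
            class = "feature_pair")
}

#' Within-group and between-group subject graphs and their Laplacians
#'
#' `Gw` connects pairs of subjects in the same group, `Gb` pairs in
#' different groups; `L = D - G` with `D` the degree matrix. With
#' `scale = "subjects"` the adjacencies carry weight `1/n` instead of 1,
#' which bounds the between-group Laplacian's spectrum independently of
#' cohort size (used internally by [cclpp_fit()]).
#'
#' @param labels two-level group vector.
#' @param scale `"none"` (binary adjacency, default) or `"subjects"`.
#' @return an object of class `group_graphs` with `Gw`, `Gb`, `Dw`, `Db`,
#'   `Lw`, `Lb`.
#' @export
build_group_graphs <- function(labels, scale = c("none", "subjects")) {
  scale <- match.arg(scale)
  labels <- as.factor(as.character(labels))
  n <- length(labels)
  if (nlevels(labels) < 2L) stop("need at least two distinct groups, got ", nlevels(labels))
  li <- as.integer(labels)
  same <- outer(li, li, "==")
  w <- if (scale == "subjects") 1 / n else 1
  Gw <- ifelse(same, w, 0); diag(Gw) <- 0
  Gb <- ifelse(same, 0, w)
  Dw <- diag(rowSums(Gw), n)
  Db <- diag(rowSums(Gb), n)
  structure(list(Gw = Gw, Gb = Gb, Dw = Dw, Db = Db,
                 Lw = Dw - Gw, Lb = Db - Gb,
                 labels = labels, scale = scale),
            class = "group_graphs")
}

#' Locality-preserving-projection penalty of a weight vector
#'
#' `alpha * w'Z'Lw Z w - (1 - alpha) * w'Z'Lb Z w`: small when same-group
#' projected scores are close and different-group scores are far apart.
#'
#' @param w weight vector (length m).
#' @param Z subjects x m feature matrix.
#' @param graphs a `group_graphs` object.
#' @param alpha trade-off in `[0, 1]`.
#' @return scalar penalty value.
#' @export
lpp_penalty <- function(w, Z, graphs, alpha = 0.5) {
  if (!(alpha >= 0 && alpha <= 1)) stop("alpha must be in [0, 1]")
  s <- as.vector(Z %*% w)
  if (length(s) != nrow(graphs$Lw)) stop("Z and graphs disagree in subject count")
  alpha * drop(crossprod(s, graphs$Lw %*% s)) -
    (1 - alpha) * drop(crossprod(s, graphs$Lb %*% s))
}

#' Squared residual of regressing projected scores onto birth age
#'
#' @param w weight vector.
#' @param Z1 preterm rows of the feature matrix (n1 x m).
#' @param A birth-age vector of length n1.
#' @return `||Z1 w - A||^2`.
#' @export
age_regression_residual <- function(w, Z1, A) {
  Z1 <- as.matrix(Z1)
  if (nrow(Z1) != length(A)) stop("Z1 rows and A length disagree")
  if (ncol(Z1) != length(w)) stop("Z1 columns and w length disagree")
  sum((as.vector(Z1 %*% w) - A)^2)
}

#' Full penalized objective of the sparse CCA-LPP model
#'
#' `-u'X'Yv + lambda1 ||Xu||^2 + lambda2 ||Yv||^2 + sum(beta_i P_i) +
#' sum(gamma_i R_i) + omega1 ||u||_1 + omega2 ||v||_1` (hard unit-variance
#' constraints are handled by post-fit rescaling, not inside the
#' objective). With `scaling = "average"` the data-fit terms are averaged
#' (bilinear and ridge by n, LPP quadratic forms by n^2, age residuals by
#' n1), which is the scale [cclpp_fit()] minimizes so that O(1) penalty
#' weights mean the same thing at any cohort size.
#'
#' @param u,v weight vectors.
#' @param data a `feature_pair`.
#' @param graphs a `group_graphs` built from `data$labels` with
#'   `scale = "none"`.
#' @param hp a `cclpp_control`.
#' @param scaling `"raw"` (the literal objective, default) or `"average"`.
#' @return scalar objective value.
#' @export
cclpp_objective <- function(u, v, data, graphs, hp = cclpp_control(),
                            scaling = c("raw", "average")) {
  scaling <- match.arg(scaling)
  n <- nrow(data$X)
  cn <- if (scaling == "average") 1 / n else 1
  cl <- if (scaling == "average") 1 / n^2 else 1
  xu <- as.vector(data$X %*% u)
  yv <- as.vector(data$Y %*% v)
  val <- cn * (-sum(xu * yv) + hp$lambda1 * sum(xu^2) + hp$lambda2 * sum(yv^2)) +
    cl * (hp$beta1 * lpp_penalty(u, data$X, graphs, hp$alpha) +
          hp$beta2 * lpp_penalty(v, data$Y, graphs, hp$alpha)) +
    hp$omega1 * sum(abs(u)) + hp$omega2 * sum(abs(v))
  if (!is.null(data$ages) && (hp$gamma1 > 0 || hp$gamma2 > 0)) {
    ca <- if (scaling == "average") 1 / n else 1
    X1 <- data$X[data$age_rows, , drop = FALSE]
    Y1 <- data$Y[data$age_rows, , drop = FALSE]
    val <- val + ca * (hp$gamma1 * age_regression_residual(u, X1, data$ages) +
                       hp$gamma2 * age_regression_residual(v, Y1, data$ages))
  }
  val
}

#' Pearson correlation of the two canonical score vectors
#'
#' @param X,Y feature matrices.
#' @param u,v canonical weight vectors.
#' @return `cor(Xu, Yv)`.
#' @export
canonical_correlation <- function(X, Y, u, v) {
  xu <- as.vector(as.matrix(X) %*% u)
  yv <- as.vector(as.matrix(Y) %*% v)
  if (stats::sd(xu) == 0 || stats::sd(yv) == 0) {
    stop("canonical scores have zero variance; correlation undefined")
  }
  stats::cor(xu, yv)
}

# ---- internal solver machinery ----------------------------------------

# Monotone proximal-gradient (ISTA) solver for min f(w) + omega*||w||_1,
# with backtracking on the quadratic majorization; guarantees the composite
# objective never increases, which is what makes the outer alternation's
# objective history non-increasing.
.prox_solve <- function(w, fval, fgrad, omega, t0, inner_tol, inner_max_iter) {
  t <- t0
  fw <- fval(w)
  for (k in seq_len(inner_max_iter)) {
    g <- fgrad(w)
    repeat {
      w_new <- soft_threshold(w - t * g, t * omega)
      d <- w_new - w
      f_new <- fval(w_new)
      if (f_new <= fw + sum(g * d) + sum(d * d) / (2 * t) + 1e-12) break
      t <- t / 2
      if (t < 1e-20) { w_new <- w; f_new <- fw; break }
    }
    delta <- max(abs(w_new - w))
    w <- w_new
    fw <- f_new
    if (delta <= inner_tol) break
    t <- t * 1.25
  }
  list(w = w, t = t)
}

# Convexity check of a subproblem's smooth Hessian
#   H = Z' C_mid Z + c_age * Z1'Z1 + 2 eps I
# without forming the m x m matrix: the nonzero eigenvalues of B'CB equal
# the eigenvalues of C B B' (size n + n1). The between-group Laplacian
# enters with a negative sign, so H can genuinely be indefinite; callers
# turn a failure into a remediation message.
.min_hessian_eig <- function(Z, Z1, C_mid, c_age, eps) {
  B <- if (!is.null(Z1) && c_age > 0) rbind(Z, Z1) else Z
  G <- B %*% t(B)
  n <- nrow(Z)
  C <- if (!is.null(Z1) && c_age > 0) {
    nb <- nrow(B)
    Cfull <- matrix(0, nb, nb)
    Cfull[1:n, 1:n] <- C_mid
    diag(Cfull)[(n + 1):nb] <- c_age
    Cfull
  } else C_mid
  ev <- eigen(C %*% G, only.values = TRUE)$values
  min(Re(ev)) + 2 * eps
}

#' Fit the sparse CCA-LPP model by alternating proximal minimization
#'
#' Alternates convex subproblems in `u` (with `v` fixed) and `v` (with `u`
#' fixed), each solved by monotone proximal gradient with backtracking.
#' After each subproblem the solution is projected back onto its
#' unit-variance constraint sphere (`var(Xu) = 1`, the usual alternating
#' scheme for constrained sparse CCA), which keeps the bilinear
#' correlation term active at a fixed scale; `objective_history` records
#' the penalized objective at these normalized iterates. Iteration stops
#' when the max-norm change of `(u, v)` drops below `hp$tol` (or the
#' relative objective change, per `hp$convergence`). The final `u`, `v`
#' are rescaled to `u'(X'X + eps I)u = 1`, `v'(Y'Y + eps I)v = 1`.
#'
#' The minimized objective is the per-subject-averaged form (see
#' [cclpp_objective()] with `scaling = "average"`, plus the `eps`
#' stabilizer), so the suggested O(1) penalty weights are meaningful
#' regardless of cohort size, and the between-group LPP term cannot make
#' the subproblems unbounded at the default `alpha = 0.5`.
#'
#' @param data a `feature_pair`.
#' @param hp a `cclpp_control`.
#' @return an object of class `cclpp_fit` with elements `u`, `v`,
#'   `objective_history`, `n_iter`, `converged`, `canonical_corr`,
#'   `zero_u`, `zero_v`, `support_u`, `support_v`, plus the
#'   standardization centers/scales applied.
#' @param warm_start optional list with elements `u`, `v` used as the
#'   starting point (e.g. a previous fit at a smaller L1 weight);
#'   overrides `hp$init`.
#' @examples
#' synth <- generate_cohort(synth_config(n_preterm = 8, n_term = 8,
#'   n_patches = 12, m_edges = 40, k_signal = 5, seed = 1))
#' fit <- cclpp_fit(synth$data, cclpp_control(max_iter = 25))
#' @export
cclpp_fit <- function(data, hp = cclpp_control(), warm_start = NULL) {
  stopifnot(inherits(data, "feature_pair"))
  X <- data$X; Y <- data$Y
  n <- nrow(X); m <- ncol(X)
  if (n < 4L) stop("need at least 4 subjects")
  if (m < 2L) stop("need at least 2 features")
  std <- list(x_center = rep(0, m), x_scale = rep(1, m),
              y_center = rep(0, m), y_scale = rep(1, m),
              a_center = 0, a_scale = 1)
  if (hp$standardize) {
    sdx <- apply(X, 2L, stats::sd); sdy <- apply(Y, 2L, stats::sd)
    if (any(sdx == 0) || any(sdy == 0)) {
      stop("zero-variance feature column(s); drop them before fitting")
    }
    std$x_center <- colMeans(X); std$x_scale <- sdx
    std$y_center <- colMeans(Y); std$y_scale <- sdy
    X <- scale(X, center = std$x_center, scale = std$x_scale)
    Y <- scale(Y, center = std$y_center, scale = std$y_scale)
  }
  use_age <- !is.null(data$ages) && (hp$gamma1 > 0 || hp$gamma2 > 0)
  A <- NULL; X1 <- NULL; Y1 <- NULL; n1 <- 0L
  if (use_age) {
    A <- data$ages
    n1 <- length(A)
    if (hp$standardize) {
      std$a_center <- mean(A)
      std$a_scale <- if (stats::sd(A) > 0) stats::sd(A) else 1
      A <- (A - std$a_center) / std$a_scale
    }
    X1 <- X[data$age_rows, , drop = FALSE]
    Y1 <- Y[data$age_rows, , drop = FALSE]
  }
  graphs <- build_group_graphs(data$labels, scale = "none")
  M <- hp$alpha * graphs$Lw - (1 - hp$alpha) * graphs$Lb
  diagonal_gram <- hp$gram == "diagonal"

  # Smooth-part middle matrices (averaged scaling) and convexity check.
  # Under the diagonal-Gram approximation the score ridge acts on the
  # coefficients directly, so it enters the Hessian as an identity shift.
  lam_mid_u <- if (diagonal_gram) 0 else 2 * hp$lambda1 / n
  lam_mid_v <- if (diagonal_gram) 0 else 2 * hp$lambda2 / n
  shift_u <- hp$eps + hp$eta1 + if (diagonal_gram) hp$lambda1 else 0
  shift_v <- hp$eps + hp$eta2 + if (diagonal_gram) hp$lambda2 else 0
  C_u <- lam_mid_u * diag(n) + (2 * hp$beta1 / n^2) * M
  C_v <- lam_mid_v * diag(n) + (2 * hp$beta2 / n^2) * M
  c_age_u <- if (use_age) 2 * hp$gamma1 / n else 0
  c_age_v <- if (use_age) 2 * hp$gamma2 / n else 0
  for (side in c("u", "v")) {
    lam <- if (side == "u") .min_hessian_eig(X, X1, C_u, c_age_u, shift_u)
           else .min_hessian_eig(Y, Y1, C_v, c_age_v, shift_v)
    if (lam < -1e-8) {
      stop("the ", side, "-subproblem is not convex (min Hessian eigenvalue ",
           format(lam, digits = 3), "): the between-group LPP term dominates; ",
           "increase alpha, lambda, or eps")
    }
  }

  # Gradient closures; half of the bilinear term is charged to each side so
  # the two subproblem smooth parts sum to the full smooth objective.
  smooth_u <- function(u, yv) {
    xu <- as.vector(X %*% u)
    ridge <- if (diagonal_gram) hp$lambda1 * sum(u^2) else hp$lambda1 * sum(xu^2) / n
    val <- -sum(xu * yv) / n + ridge +
      (hp$beta1 / n^2) * drop(crossprod(xu, M %*% xu)) +
      (hp$eta1 + hp$eps) * sum(u^2)
    if (c_age_u > 0) {
      r <- as.vector(X1 %*% u) - A
      val <- val + (hp$gamma1 / n) * sum(r^2)
    }
    val
  }
  grad_u <- function(u, yv) {
    xu <- as.vector(X %*% u)
    base <- if (diagonal_gram) -yv / n + (2 * hp$beta1 / n^2) * (M %*% xu)
            else (-yv + 2 * hp$lambda1 * xu) / n + (2 * hp$beta1 / n^2) * (M %*% xu)
    g <- as.vector(crossprod(X, base)) + 2 * (hp$eta1 + hp$eps) * u
    if (diagonal_gram) g <- g + 2 * hp$lambda1 * u
    if (c_age_u > 0) g <- g + c_age_u * as.vector(crossprod(X1, as.vector(X1 %*% u) - A))
    g
  }
  smooth_v <- function(v, xu) {
    yv <- as.vector(Y %*% v)
    ridge <- if (diagonal_gram) hp$lambda2 * sum(v^2) else hp$lambda2 * sum(yv^2) / n
    val <- -sum(xu * yv) / n + ridge +
      (hp$beta2 / n^2) * drop(crossprod(yv, M %*% yv)) +
      (hp$eta2 + hp$eps) * sum(v^2)
    if (c_age_v > 0) {
      r <- as.vector(Y1 %*% v) - A
      val <- val + (hp$gamma2 / n) * sum(r^2)
    }
    val
  }
  grad_v <- function(v, xu) {
    yv <- as.vector(Y %*% v)
    base <- if (diagonal_gram) -xu / n + (2 * hp$beta2 / n^2) * (M %*% yv)
            else (-xu + 2 * hp$lambda2 * yv) / n + (2 * hp$beta2 / n^2) * (M %*% yv)
    g <- as.vector(crossprod(Y, base)) + 2 * (hp$eta2 + hp$eps) * v
    if (diagonal_gram) g <- g + 2 * hp$lambda2 * v
    if (c_age_v > 0) g <- g + c_age_v * as.vector(crossprod(Y1, as.vector(Y1 %*% v) - A))
    g
  }
  full_objective <- function(u, v) {
    yv <- as.vector(Y %*% v)
    xu <- as.vector(X %*% u)
    # smooth_u + smooth_v double-counts the bilinear term; add it back once.
    smooth_u(u, yv) + smooth_v(v, xu) + sum(xu * yv) / n +
      hp$omega1 * sum(abs(u)) + hp$omega2 * sum(abs(v))
  }

  unit_start <- function(w, Z) {
    s <- stats::sd(as.vector(Z %*% w))
    if (s > 0) w / s else w / sqrt(sum(w^2))
  }
  # Project a subproblem solution back onto the unit-score-variance sphere
  # var(Zw) = 1 (the model's constraint); leaves an all-zero vector
  # untouched.
  renorm <- function(w, Z) {
    s <- stats::sd(as.vector(Z %*% w))
    if (is.finite(s) && s > 0) w / s else w
  }
  run_once <- function(u0, v0) {
    u <- u0; v <- v0
    t_u <- 1; t_v <- 1
    history <- full_objective(u, v)
    converged <- FALSE
    it <- 0L
    for (it in seq_len(hp$max_iter)) {
      u_prev <- u; v_prev <- v
      yv <- as.vector(Y %*% v)
      su <- .prox_solve(u, function(w) smooth_u(w, yv), function(w) grad_u(w, yv),
                        hp$omega1, t_u, hp$inner_tol, hp$inner_max_iter)
      u <- renorm(su$w, X); t_u <- su$t
      xu <- as.vector(X %*% u)
      sv <- .prox_solve(v, function(w) smooth_v(w, xu), function(w) grad_v(w, xu),
                        hp$omega2, t_v, hp$inner_tol, hp$inner_max_iter)
      v <- renorm(sv$w, Y); t_v <- sv$t
      obj <- full_objective(u, v)
      history <- c(history, obj)
      if (hp$convergence == "weights") {
        delta <- max(max(abs(u - u_prev)), max(abs(v - v_prev)))
        if (delta <= hp$tol) { converged <- TRUE; break }
      } else {
        prev <- history[length(history) - 1L]
        if (abs(prev - obj) <= hp$tol * max(1, abs(prev))) { converged <- TRUE; break }
      }
    }
    list(u = u, v = v, history = history, n_iter = it, converged = converged)
  }

  w0 <- if (!is.null(warm_start)) {
    stopifnot(length(warm_start$u) == m, length(warm_start$v) == m)
    list(u = warm_start$u, v = warm_start$v)
  } else if (hp$init == "tstat") {
    # deterministic, discrimination-aware start: per-edge standardized
    # group-mean differences
    g1 <- data$labels == levels(data$labels)[1L]
    list(u = colMeans(X[g1, , drop = FALSE]) - colMeans(X[!g1, , drop = FALSE]),
         v = colMeans(Y[g1, , drop = FALSE]) - colMeans(Y[!g1, , drop = FALSE]))
  } else {
    list(u = rep(1, m), v = rep(1, m))
  }
  if (all(w0$u == 0)) w0$u <- rep(1, m)
  if (all(w0$v == 0)) w0$v <- rep(1, m)
  starts <- list(list(u = unit_start(w0$u, X), v = unit_start(w0$v, Y)))
  if (hp$n_restarts > 0L) {
    extra <- with_seed(hp$seed, lapply(seq_len(hp$n_restarts), function(i) {
      list(u = unit_start(stats::rnorm(m), X), v = unit_start(stats::rnorm(m), Y))
    }))
    starts <- c(starts, extra)
  }
  best <- NULL
  for (s in starts) {
    res <- run_once(s$u, s$v)
    if (is.null(best) || res$history[length(res$history)] <
        best$history[length(best$history)]) best <- res
  }

  u <- best$u; v <- best$v
  zero_u <- all(u == 0); zero_v <- all(v == 0)
  if (zero_u) warning("u collapsed to the zero vector (omega1 too large?)")
  if (zero_v) warning("v collapsed to the zero vector (omega2 too large?)")
  scale_to_sphere <- function(w, Z) {
    s2 <- drop(crossprod(Z %*% w)) + hp$eps * sum(w^2)
    w / sqrt(s2)
  }
  if (!zero_u) u <- scale_to_sphere(u, X)
  if (!zero_v) v <- scale_to_sphere(v, Y)
  cc <- if (zero_u || zero_v ||
            stats::sd(as.vector(X %*% u)) == 0 || stats::sd(as.vector(Y %*% v)) == 0) {
    NA_real_
  } else {
    canonical_correlation(X, Y, u, v)
  }
  structure(list(u = as.vector(u), v = as.vector(v),
                 objective_history = best$history,
                 n_iter = best$n_iter, converged = best$converged,
                 canonical_corr = cc, zero_u = zero_u, zero_v = zero_v,
                 support_u = which(abs(u) > 1e-8),
                 support_v = which(abs(v) > 1e-8),
                 standardization = std, hp = hp),
            class = "cclpp_fit")
}

#' @export
print.cclpp_fit <- function(x, ...) {
  cat(sprintf(paste0("<cclpp_fit> %d iterations (%sconverged), canonical corr %s\n",
                     "  nonzero weights: %d (u), %d (v)\n"),
              x$n_iter, if (x$converged) "" else "NOT ",
              if (is.na(x$canonical_corr)) "undefined" else
                formatC(x$canonical_corr, digits = 4, format = "f"),
              length(x$support_u), length(x$support_v)))
  invisible(x)
}
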