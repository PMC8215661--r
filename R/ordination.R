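#' Iterative variable selection by variance inflation factor
#'
#' The VIF of a predictor is 1/(1 - R^2) with R^2 the coefficient of
#' determination of the multiple regression of that predictor on the
#' remaining ones. While the largest VIF exceeds `threshold`, the offending
#' variable is removed and all VIFs recomputed. Ties break toward the larger
#' VIF, then alphabetically; a perfectly collinear variable (R^2 = 1, VIF
#' infinite) is removed first.
#'
#' @param env data.frame holding the variables.
#' @param variables continuous column names to screen.
#' @param threshold VIF above which a variable is dropped.
#' @return list with `kept` (labels) and `trace` (data.frame of removals
#'   with their VIF at removal time).
#' @export
vif_select <- function(env, variables, threshold = 5) {
  stopifnot(length(variables) >= 2)
  X <- as.matrix(env[variables])
  if (nrow(X) <= length(variables))
    stop("need more samples than variables")
  if (!all(is.finite(X))) stop("non-finite values in variables")
  current <- sort(variables)
  trace <- data.frame(removed = character(0), vif = numeric(0),
                      stringsAsFactors = FALSE)
  repeat {
    if (length(current) < 2) break
    vifs <- vapply(current, function(v) {
      # a perfect fit here is the perfect-collinearity case, not a problem
      fit <- stats::lm(X[, v] ~ X[, setdiff(current, v)])
      r2 <- suppressWarnings(summary(fit)$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
    if (max(vifs) <= threshold) break
    worst <- names(vifs)[vifs == max(vifs)]
    worst <- sort(worst)[1]
    trace <- rbind(trace, data.frame(removed = worst, vif = vifs[worst],
                                     stringsAsFactors = FALSE))
    current <- setdiff(current, worst)
  }
  list(kept = current, trace = trace)
}

#' Hellinger transformation
#'
#' Square roots of within-sample relative frequencies: each row is divided
#' by its sum and square-rooted, making Euclidean distances between rows the
#' Hellinger distance (bounded by sqrt(2)). All-zero rows are left as zeros
#' with a warning.
#'
#' @param mat samples x taxa matrix of non-negative abundances.
#' @return transformed matrix of the same shape; every non-zero row has unit
#'   Euclidean norm.
#' @export
hellinger <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("negative entries")
  rs <- rowSums(mat)
  if (any(rs == 0)) warning("all-zero rows left as zeros")
  rs[rs == 0] <- 1
  sqrt(mat / rs)
}

#' Principal coordinate analysis
#'
#' Classical metric scaling of a symmetric distance matrix by
#' double-centering and eigendecomposition; axes are ordered by eigenvalue
#' and axes with negative eigenvalues are dropped (the eigenvalues
#' themselves are reported).
#'
#' @param d a `dist` object or symmetric matrix with zero diagonal.
#' @return list with `points` (n x k coordinates), `eig` (all eigenvalues,
#'   decreasing) and `negative` (logical, any negative eigenvalues).
#' @export
pcoa <- function(d) {
  m <- as.matrix(d)
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(m)) > 1e-8)) stop("distance matrix diagonal must be zero")
  n <- nrow(m)
  # cmdscale warns when the configuration has fewer positive eigenvalues
  # than k; we report the full eigenvalue spectrum ourselves
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(m), k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > 1e-8 * max(abs(eig), 1))
  if (length(pos) == 0) {
    pts <- matrix(numeric(0), n, 0, dimnames = list(rownames(m), NULL))
  } else {
    pts <- fit$points[, seq_along(pos), drop = FALSE]
    colnames(pts) <- paste0("PCo", seq_along(pos))
  }
  list(points = pts, eig = eig, negative = any(eig < -1e-8))
}

# Build the conditioning / predictor design matrices. Categorical columns
# expand to treatment-contrast indicators.
design_matrix <- function(env, vars) {
  if (length(vars) == 0) return(NULL)
  df <- as.data.frame(env[vars])
  mm <- stats::model.matrix(~ ., data = df)
  mm[, -1, drop = FALSE]
}

residualize <- function(M, Z) {
  if (is.null(Z)) return(scale(M, scale = FALSE))
  Z1 <- cbind(1, Z)
  qz <- qr(Z1)
  qr.resid(qz, M)
}

#' Partial redundancy analysis
#'
#' Constrained ordination of a (Hellinger-transformed) community matrix on
#' scaled environmental predictors, optionally after removing a conditioning
#' block (e.g. Site): community and predictors are residualized on the
#' condition, the community is regressed on the predictors by least squares,
#' and the fitted values eigendecomposed. The constrained R^2 is the fitted
#' fraction of the (conditioned) community variance, adjusted by the Ezekiel
#' formula 1 - (1 - R^2)(n - 1)/(n - m - 1). The permutation p-value
#' permutes rows of the residualized community (reduced-model permutation)
#' or, with `permutation = "free"`, of the raw community.
#'
#' @param community samples x taxa numeric matrix (transform first, e.g.
#'   with [hellinger()]).
#' @param env environment data.frame (rows aligned with `community`).
#' @param variables continuous predictor column names; centered and scaled
#'   internally.
#' @param condition column names (categorical or continuous) to partial out.
#' @param n_perm number of permutations for the p-value (0 skips the test).
#' @param permutation "reduced" (default) or "free".
#' @return list of class `alp_rda`: `eigenvalues`, `scores` (sample scores),
#'   `constrained_R2`, `adjusted_R2`, `perm_p`, `n_perm`, `variables`,
#'   `condition`, `rank`.
#' @export
partial_rda <- function(community, env, variables, condition = NULL,
                        n_perm = 999, permutation = c("reduced", "free")) {
  permutation <- match.arg(permutation)
  Y <- as.matrix(community)
  n <- nrow(Y)
  stopifnot(nrow(env) == n)
  X <- scale(as.matrix(env[variables]))
  if (n <= ncol(X) + 1) stop("need n > number of predictors")
  Z <- design_matrix(env, condition)
  Yr <- scale(residualize(Y, Z), scale = FALSE)
  Xr <- residualize(X, Z)
  qx <- qr(Xr)
  if (qx$rank < ncol(Xr)) {
    aliased <- colnames(Xr)[qx$pivot[(qx$rank + 1):ncol(Xr)]]
    stop("predictor(s) aliased after conditioning: ",
         paste(aliased, collapse = ", "))
  }
  Yhat <- qr.fitted(qx, Yr)
  tot <- sum(Yr^2)
  r2 <- sum(Yhat^2) / tot
  m <- qx$rank
  adj <- 1 - (1 - r2) * (n - 1) / (n - m - 1)
  sv <- svd(Yhat)
  keep <- sv$d^2 / (n - 1) > 1e-12
  eigenvalues <- (sv$d^2 / (n - 1))[keep]
  scores <- sv$u[, keep, drop = FALSE] %*%
    diag(sv$d[keep], sum(keep))
  rownames(scores) <- rownames(Y)
  colnames(scores) <- paste0("RDA", seq_len(sum(keep)))
  perm_p <- NA_real_
  if (n_perm > 0) {
    base <- if (permutation == "reduced") Yr else scale(Y, scale = FALSE)
    ge <- 0L
    for (b in seq_len(n_perm)) {
      Yp <- base[sample.int(n), , drop = FALSE]
      if (permutation == "free") Yp <- scale(residualize(Yp, Z), scale = FALSE)
      r2p <- sum(qr.fitted(qx, Yp)^2) / sum(Yp^2)
      if (r2p >= r2) ge <- ge + 1L
    }
    perm_p <- (1 + ge) / (n_perm + 1)
  }
  structure(list(eigenvalues = eigenvalues, scores = scores,
                 constrained_R2 = r2, adjusted_R2 = adj, perm_p = perm_p,
                 n_perm = n_perm, variables = variables,
                 condition = condition, rank = m),
            class = "alp_rda")
}

#' @export
print.alp_rda <- function(x, ...) {
  cat(sprintf(
    "partial RDA: %d predictor df%s; R2 = %.4f, adjusted R2 = %.4f",
    x$rank,
    if (length(x$condition)) paste0(" | condition: ",
                                    paste(x$condition, collapse = ", "))
    else "", x$constrained_R2, x$adjusted_R2))
  if (!is.na(x$perm_p))
    cat(sprintf(", permutation p = %.4g (n = %d)", x$perm_p, x$n_perm))
  cat("\n")
  invisible(x)
}

#' Forward-backward selection of RDA predictors
#'
#' Greedy forward addition of the candidate with the lowest marginal
#' permutation p-value (the variable tested conditioned on the current model
#' and the conditioning block), accepted while p < `alpha_enter`; after each
#' addition, backward removal of any selected variable whose marginal p
#' rises above `alpha_enter`. Ties break toward the larger partial R^2, then
#' alphabetically. Deterministic under a fixed RNG seed.
#'
#' @param community samples x taxa matrix (transformed).
#' @param env environment data.frame.
#' @param variables candidate predictor columns.
#' @param condition columns partialled out throughout.
#' @param n_perm permutations per marginal test.
#' @param alpha_enter inclusion/retention threshold.
#' @return list with `selected` (labels, in selection order) and `trace`
#'   (data.frame of steps).
#' @export
stepwise_select <- function(community, env, variables, condition = NULL,
                            n_perm = 199, alpha_enter = 0.05,
                            max_steps = 50) {
  selected <- character(0)
  trace <- data.frame(step = character(0), variable = character(0),
                      p = numeric(0), stringsAsFactors = FALSE)
  marginal <- function(v, others) {
    fit <- partial_rda(community, env, v,
                       condition = c(condition, others), n_perm = n_perm)
    c(p = fit$perm_p, r2 = fit$constrained_R2)
  }
  steps <- 0L
  repeat {
    steps <- steps + 1L
    if (steps > max_steps) break
    changed <- FALSE
    cand <- setdiff(variables, selected)
    if (length(cand) > 0) {
      stats_f <- t(vapply(sort(cand), marginal, numeric(2),
                          others = selected))
      ord <- order(stats_f[, "p"], -stats_f[, "r2"], rownames(stats_f))
      best <- rownames(stats_f)[ord[1]]
      if (stats_f[best, "p"] < alpha_enter) {
        selected <- c(selected, best)
        trace <- rbind(trace, data.frame(step = "add", variable = best,
                                         p = stats_f[best, "p"]))
        changed <- TRUE
      }
    }
    if (length(selected) > 1) {
      stats_b <- t(vapply(sort(selected), function(v)
        marginal(v, setdiff(selected, v)), numeric(2)))
      worst <- rownames(stats_b)[order(-stats_b[, "p"], rownames(stats_b))[1]]
      if (stats_b[worst, "p"] > alpha_enter) {
        selected <- setdiff(selected, worst)
        trace <- rbind(trace, data.frame(step = "drop", variable = worst,
                                         p = stats_b[worst, "p"]))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(selected = selected, trace = trace)
}

#' Per-variable variance partitioning
#'
#' For each selected variable, the partial adjusted R^2 is the adjusted R^2
#' of the full model minus that of the model without the variable, the
#' conditioning block held fixed throughout. Partials may be slightly
#' negative on noisy data and are reported unclipped.
#'
#' @param community samples x taxa matrix (transformed).
#' @param env environment data.frame.
#' @param selected selected predictor columns.
#' @param condition columns partialled out.
#' @return data.frame with `variable`, `partial_adj_R2`, plus the full-model
#'   adjusted R^2 as attribute `"full_adj_R2"`.
#' @export
variance_partition <- function(community, env, selected, condition = NULL) {
  stopifnot(length(selected) >= 1)
  full <- partial_rda(community, env, selected, condition, n_perm = 0)
  partial <- vapply(selected, function(v) {
    rest <- setdiff(selected, v)
    if (length(rest) == 0) return(full$adjusted_R2)
    red <- partial_rda(community, env, rest, condition, n_perm = 0)
    full$adjusted_R2 - red$adjusted_R2
  }, numeric(1))
  out <- data.frame(variable = selected, partial_adj_R2 = unname(partial),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$partial_adj_R2), ]
  attr(out, "full_adj_R2") <- full$adjusted_R2
  out
}

#' Robust regression by iteratively reweighted least squares
#'
#' Tukey-bisquare IRLS for outlier-robust straight-line fits (e.g. between
#' log10 relative frequencies measured by two markers): starting from
#' ordinary least squares, weights `w = (1 - (r/(c s))^2)^2` for |r| < c s
#' (0 beyond), with `s` the MAD-based residual scale, are iterated until the
#' coefficient change falls below `tol`. The reported R^2 is weighted.
#'
#' @param x,y paired finite observations (zero-frequency pairs should be
#'   excluded before taking logs; see `exclude_zeros`).
#' @param tuning bisquare constant c (4.685 gives 95% Gaussian efficiency).
#' @param max_iter,tol iteration controls.
#' @param exclude_zeros if TRUE, drops non-finite pairs (e.g. log10 of 0)
#'   with a message.
#' @return list of class `robust_fit`: `intercept`, `slope`, `weights`,
#'   `r_squared`, `scale`, `iterations`, `converged`, `n_excluded`.
#' @export
irls_fit <- function(x, y, tuning = 4.685, max_iter = 50, tol = 1e-8,
                     exclude_zeros = TRUE) {
  ok <- is.finite(x) & is.finite(y)
  n_excluded <- sum(!ok)
  if (exclude_zeros && n_excluded > 0) {
    message(n_excluded, " non-finite pair(s) excluded")
    x <- x[ok]; y <- y[ok]
  } else if (!all(ok)) stop("non-finite observations")
  if (length(x) < 3) stop("need at least 3 points")
  beta <- stats::coef(stats::lm(y ~ x))
  w <- rep(1, length(x))
  converged <- FALSE
  iterations <- 0L
  s <- NA_real_
  for (it in seq_len(max_iter)) {
    iterations <- it
    r <- y - beta[1] - beta[2] * x
    s <- stats::mad(r, center = 0)
    if (s < 1e-12 * max(abs(y), 1)) {  # exact fit up to rounding
      w <- rep(1, length(x))
      converged <- TRUE
      break
    }
    u <- r / (tuning * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    fit <- stats::lm.wfit(cbind(1, x), y, w)
    new_beta <- fit$coefficients
    if (max(abs(new_beta - beta)) < tol) {
      beta <- new_beta
      converged <- TRUE
      break
    }
    beta <- new_beta
  }
  r <- y - beta[1] - beta[2] * x
  ybar <- sum(w * y) / sum(w)
  r2 <- 1 - sum(w * r^2) / sum(w * (y - ybar)^2)
  structure(list(intercept = unname(beta[1]), slope = unname(beta[2]),
                 weights = w, r_squared = r2, scale = s,
                 iterations = iterations, converged = converged,
                 n_excluded = n_excluded),
            class = "robust_fit")
}

#' @export
print.robust_fit <- function(x, ...) {
  cat(sprintf(
    "bisquare IRLS fit: y = %.4g + %.4g x; weighted R2 = %.3f (%d iter%s)\n",
    x$intercept, x$slope, x$r_squared, x$iterations,
    if (x$converged) "" else ", not converged"))
  invisible(x)
}
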