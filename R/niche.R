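# Standardize the environmental block used by the OMI decomposition:
# columns centered and scaled to unit variance over samples.
standardized_env <- function(env, variables) {
  Z <- scale(as.matrix(env[variables]))
  if (any(!is.finite(Z)))
    stop("environment variables must be finite and non-constant")
  Z
}

omi_decompose <- function(Z, w) {
  w <- w / sum(w)
  center <- drop(crossprod(Z, w))
  marginality <- sum(center^2)
  inertia <- sum(w * rowSums(Z^2))
  if (marginality > 1e-12) {
    u <- center / sqrt(marginality)
    t_proj <- drop(Z %*% u)
    marg_tol <- sum(w * (t_proj - sqrt(marginality))^2)
  } else {
    marg_tol <- 0
  }
  c(inertia = inertia, marginality = marginality,
    marginal_tolerance = marg_tol,
    residual_tolerance = inertia - marginality - marg_tol)
}

#' Outlying Mean Index niche decomposition
#'
#' Describes each taxon's niche in the standardized environmental space by
#' three additive terms: the *marginality* (squared distance of the taxon's
#' abundance-weighted environmental centroid from the origin, i.e. from the
#' average sampled environment), the *marginal tolerance* (weighted variance
#' of the samples' projections onto the marginality axis) and the *residual
#' tolerance* (remaining weighted variance, orthogonal to that axis). The
#' three sum to the taxon's total inertia. Weights are the taxon's
#' abundances normalized across samples, so the decomposition is invariant
#' to abundance rescaling.
#'
#' @param community samples x taxa matrix of non-negative abundances
#'   (relative frequencies or counts).
#' @param env environment data.frame, rows aligned with `community`.
#' @param variables continuous environmental columns.
#' @return data.frame with one row per taxon: `taxon`, `inertia`,
#'   `marginality`, `marginal_tolerance`, `residual_tolerance`,
#'   `n_occupied`, `degenerate` (taxon confined to a single sample).
#' @export
omi <- function(community, env, variables) {
  Y <- as.matrix(community)
  stopifnot(nrow(env) == nrow(Y))
  Z <- standardized_env(env, variables)
  tot <- colSums(Y)
  if (any(tot <= 0)) {
    message(sum(tot <= 0), " taxa with zero total abundance excluded")
    Y <- Y[, tot > 0, drop = FALSE]
  }
  out <- t(apply(Y, 2, function(w) omi_decompose(Z, w)))
  data.frame(taxon = colnames(Y),
             as.data.frame(out),
             n_occupied = colSums(Y > 0),
             degenerate = colSums(Y > 0) == 1,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Dual permutation test of niche specialization
#'
#' A taxon counts as specialized if its niche is displaced (marginality
#' larger than expected under random placement) *or* unusually narrow along
#' its marginality axis (marginal tolerance smaller than expected). Both
#' null distributions come from permuting the taxon's abundance weights
#' across samples: `p_marginality` is one-sided high-tail, `p_tolerance`
#' one-sided low-tail, each with the include-observed convention
#' `(1 + exceedances) / (n_perm + 1)` (minimum attainable p is
#' `1/(n_perm + 1)`). The flag is `p_marginality <= alpha` or
#' `p_tolerance <= alpha`.
#'
#' @inheritParams omi
#' @param n_perm number of permutations (a warning is issued below 99:
#'   p-value resolution becomes too coarse).
#' @param alpha level of each one-sided test.
#' @return the [omi()] data.frame with columns `p_marginality`,
#'   `p_tolerance`, `specialized` appended.
#' @export
specialization_test <- function(community, env, variables, n_perm = 999,
                                alpha = 0.05) {
  if (n_perm < 99) warning("n_perm < 99 gives coarse p-value resolution")
  Y <- as.matrix(community)
  Z <- standardized_env(env, variables)
  res <- omi(community, env, variables)
  n <- nrow(Z)
  p_marg <- p_tol <- numeric(nrow(res))
  for (j in seq_len(nrow(res))) {
    w <- Y[, res$taxon[j]]
    w <- w / sum(w)
    obs <- omi_decompose(Z, w)
    # permutation columns: each a reshuffle of the weights across samples
    W <- vapply(seq_len(n_perm), function(b) w[sample.int(n)],
                numeric(n))
    C <- crossprod(Z, W)                       # v x n_perm centroids
    marg <- colSums(C^2)
    P <- Z %*% C                               # n x n_perm projections*|c|
    num <- colSums(W * P^2)
    marg_tol <- ifelse(marg > 1e-12, num / marg - marg, 0)
    p_marg[j] <- (1 + sum(marg >= obs["marginality"])) / (n_perm + 1)
    p_tol[j] <- (1 + sum(marg_tol <= obs["marginal_tolerance"])) /
      (n_perm + 1)
  }
  res$p_marginality <- p_marg
  res$p_tolerance <- p_tol
  res$specialized <- p_marg <= alpha | p_tol <= alpha
  res
}

# Weighted quantile (type-4-style linear interpolation on the weighted cdf)
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1]], numeric(1))
}

# Silverman's rule on weighted data, with effective sample size 1/sum(w^2)
silverman_bw <- function(x, w) {
  w <- w / sum(w)
  mu <- sum(w * x)
  sdw <- sqrt(sum(w * (x - mu)^2))
  q <- weighted_quantile(x, w, c(0.25, 0.75))
  iqr <- q[2] - q[1]
  spread <- min(sdw, if (iqr > 0) iqr / 1.34 else sdw)
  n_eff <- 1 / sum(w^2)
  bw <- 0.9 * spread * n_eff^(-1 / 5)
  if (!is.finite(bw) || bw <= 0) bw <- max(stats::sd(x) / 10, 1e-6)
  bw
}

# Mann-Whitney comparison of read-weighted variable values against the full
# set of sampled values, using the weights' effective sample size in the
# normal approximation (with tie correction).
weighted_mw_p <- function(x, w, ref) {
  w <- w / sum(w)
  n1 <- 1 / sum(w^2)
  n2 <- length(ref)
  gt <- outer(x, ref, ">")
  eq <- outer(x, ref, "==")
  u <- sum(w * (rowSums(gt) + 0.5 * rowSums(eq))) * n1
  mu <- n1 * n2 / 2
  pooled <- c(x, ref)
  ties <- table(pooled)
  nn <- n1 + n2
  tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
  sigma2 <- n1 * n2 / 12 * (nn + 1 - tie_term)
  if (sigma2 <= 0) return(NA_real_)
  z <- (u - mu) / sqrt(sigma2)
  2 * stats::pnorm(-abs(z))
}

#' Optimal range of a taxon along an environmental variable
#'
#' Abundance-weighted kernel density of the variable across samples
#' (Gaussian kernel, Silverman bandwidth on the weighted values by
#' default): the *peak* is the density argmax; the *range* is the smallest
#' interval around the peak containing `mass` of the weighted density
#' (grown outward from the peak, always extending the denser side); the
#' *median* is the weighted median of the sampled values. The p-value
#' compares the taxon's read-weighted variable values with all sampled
#' values by a Mann--Whitney test (`weighting = "presence"` instead
#' compares the values of occupied samples, unweighted).
#'
#' @param community samples x taxa abundance matrix.
#' @param env environment data.frame aligned with `community`.
#' @param variable continuous column name.
#' @param taxon column name in `community`.
#' @param mass density mass contained in the reported range.
#' @param bw bandwidth: "silverman" or a fixed number.
#' @param weighting "reads" (default) or "presence" for the test.
#' @return list of class `optimal_range`: `taxon`, `variable`, `peak`,
#'   `range_low`, `range_high`, `median`, `mw_p`, `degenerate`.
#' @export
optimal_range <- function(community, env, variable, taxon, mass = 0.5,
                          bw = "silverman", weighting = c("reads",
                                                          "presence")) {
  weighting <- match.arg(weighting)
  Y <- as.matrix(community)
  w <- Y[, taxon]
  if (sum(w) <= 0) stop("taxon absent from all samples")
  w <- w / sum(w)
  x <- env[[variable]]
  occupied <- x[w > 0]
  if (length(unique(occupied)) == 1) {
    v <- unique(occupied)
    return(structure(list(taxon = taxon, variable = variable, peak = v,
                          range_low = v, range_high = v, median = v,
                          mw_p = NA_real_, degenerate = TRUE),
                     class = "optimal_range"))
  }
  bwv <- if (identical(bw, "silverman")) silverman_bw(x[w > 0], w[w > 0])
  else as.numeric(bw)
  d <- stats::density(x, weights = w, bw = bwv, n = 512,
                      from = min(x) - 3 * bwv, to = max(x) + 3 * bwv)
  peak_i <- which.max(d$y)
  binmass <- d$y / sum(d$y)
  lo <- hi <- peak_i
  acc <- binmass[peak_i]
  while (acc < mass && (lo > 1 || hi < length(d$y))) {
    left <- if (lo > 1) d$y[lo - 1] else -Inf
    right <- if (hi < length(d$y)) d$y[hi + 1] else -Inf
    if (left >= right) {
      lo <- lo - 1
      acc <- acc + binmass[lo]
    } else {
      hi <- hi + 1
      acc <- acc + binmass[hi]
    }
  }
  p <- if (weighting == "reads") weighted_mw_p(x[w > 0], w[w > 0], x)
  else suppressWarnings(stats::wilcox.test(x[w > 0], x,
                                           exact = FALSE)$p.value)
  structure(list(taxon = taxon, variable = variable, peak = d$x[peak_i],
                 range_low = d$x[lo], range_high = d$x[hi],
                 median = weighted_quantile(x, w, 0.5), mw_p = p,
                 degenerate = FALSE),
            class = "optimal_range")
}

#' @export
print.optimal_range <- function(x, ...) {
  cat(sprintf("%s / %s: peak %.4g, range [%.4g, %.4g], median %.4g",
              x$taxon, x$variable, x$peak, x$range_low, x$range_high,
              x$median))
  if (!is.na(x$mw_p)) cat(sprintf(", MW p = %.3g", x$mw_p))
  cat("\n")
  invisible(x)
}

#' Optimal ranges of all taxa over several variables
#'
#' @inheritParams optimal_range
#' @param variables continuous column names.
#' @param taxa taxa to process (default: all columns of `community` with
#'   positive total abundance).
#' @return data.frame, one row per taxon x variable.
#' @export
optimal_ranges <- function(community, env, variables, taxa = NULL,
                           mass = 0.5, bw = "silverman") {
  Y <- as.matrix(community)
  if (is.null(taxa)) taxa <- colnames(Y)[colSums(Y) > 0]
  rows <- list()
  for (tx in taxa) for (v in variables) {
    r <- optimal_range(community, env, v, tx, mass = mass, bw = bw)
    rows[[length(rows) + 1]] <-
      data.frame(taxon = tx, variable = v, peak = r$peak,
                 range_low = r$range_low, range_high = r$range_high,
                 median = r$median, mw_p = r$mw_p,
                 degenerate = r$degenerate, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Optimum-interval centers for the niche PCA
#'
#' Midpoint of each taxon's optimal range per variable, assembled into a
#' taxa x variables matrix.
#'
#' @param ranges output of [optimal_ranges()].
#' @return numeric matrix, taxa in rows, variables in columns.
#' @export
niche_centers <- function(ranges) {
  taxa <- unique(ranges$taxon)
  vars <- unique(ranges$variable)
  M <- matrix(NA_real_, length(taxa), length(vars),
              dimnames = list(taxa, vars))
  mid <- (ranges$range_low + ranges$range_high) / 2
  M[cbind(match(ranges$taxon, taxa), match(ranges$variable, vars))] <- mid
  M
}

#' PCA of specialized-taxon niche centers
#'
#' Principal component analysis (centered, scaled) of the taxa x variables
#' matrix of optimum-interval centers; constant columns are dropped with a
#' warning. Optionally contrasts the first-axis scores of two taxonomic
#' classes by a Mann--Whitney test.
#'
#' @param centers taxa x variables matrix (see [niche_centers()]).
#' @param classes optional factor of class labels per taxon (rows of
#'   `centers`).
#' @param class_a,class_b the two classes to contrast on axis 1.
#' @return list with `scores`, `percent_variance`, `loadings` and (when
#'   classes are given) `class_p` and `class_means`.
#' @export
niche_pca <- function(centers, classes = NULL, class_a = "Chlorophyceae",
                      class_b = "Trebouxiophyceae") {
  M <- as.matrix(centers)
  if (nrow(M) < 3) stop("need at least 3 taxa")
  const <- apply(M, 2, function(v) stats::sd(v) < 1e-12)
  if (any(const)) {
    warning("dropping constant column(s): ",
            paste(colnames(M)[const], collapse = ", "))
    M <- M[, !const, drop = FALSE]
  }
  fit <- stats::prcomp(M, center = TRUE, scale. = TRUE)
  pv <- 100 * fit$sdev^2 / sum(fit$sdev^2)
  out <- list(scores = fit$x, percent_variance = pv,
              loadings = fit$rotation)
  if (!is.null(classes)) {
    classes <- as.character(classes)
    a <- fit$x[classes == class_a, 1]
    b <- fit$x[classes == class_b, 1]
    if (length(a) > 0 && length(b) > 0) {
      w <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
      out$class_p <- w$p.value
      out$class_means <- c(stats::setNames(mean(a), class_a),
                           stats::setNames(mean(b), class_b))
    }
  }
  out
}
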