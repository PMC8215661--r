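#' Hill number of order q
#'
#' Effective number of equally abundant species: `(sum p_i^q)^(1/(1-q))` for
#' `q != 1`, and the exponential of the Shannon entropy at `q = 1` (the
#' continuous limit). `q = 1` down-weights rare taxa -- including the
#' low-frequency artefactual variants typical of metabarcoding data -- which
#' is why the pipeline defaults to it.
#'
#' @param freqs non-negative abundances; renormalized internally.
#' @param q order, >= 0.
#' @return effective number of species (a single number).
#' @examples
#' hill(rep(1, 4), q = 1)            # 4: even community
#' hill(mock_community(13, 0.5), 1)  # ~4.0: halving mock community
#' @export
hill <- function(freqs, q = 1) {
  if (any(freqs < 0)) stop("negative frequencies")
  if (sum(freqs) <= 0) stop("all-zero frequency vector")
  stopifnot(q >= 0)
  p <- freqs[freqs > 0] / sum(freqs)
  if (abs(q - 1) < 1e-10) exp(-sum(p * log(p)))
  else sum(p^q)^(1 / (1 - q))
}

#' Gamma, alpha and beta diversity of a community matrix
#'
#' Alpha is the mean per-sample Hill number, gamma the Hill number of the
#' pooled community (mean of the samples' frequency vectors, each sample
#' weighted equally, matching alpha's equal weighting), and beta the
#' multiplicative ratio gamma/alpha -- the effective number of distinct
#' communities.
#'
#' @param mat samples x taxa matrix of non-negative abundances.
#' @param q Hill order.
#' @return list with `gamma`, `alpha`, `beta`.
#' @export
gamma_alpha_beta <- function(mat, q = 1) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) >= 1)
  rs <- rowSums(mat)
  if (any(rs <= 0)) stop("samples with zero total abundance")
  P <- mat / rs
  alpha <- mean(apply(P, 1, hill, q = q))
  gamma <- hill(colMeans(P), q = q)
  list(gamma = gamma, alpha = alpha, beta = gamma / alpha)
}

#' Per-PCR Hill diversity
#'
#' @param x a [motu_table()].
#' @param pcrs PCR metadata; only `control_type == "sample"` PCRs are kept.
#' @param q Hill order.
#' @return data.frame with `unit_id`, `sample_id`, `q`, `value`.
#' @export
pcr_diversity <- function(x, pcrs, q = 1) {
  pcrs <- validate_pcrs(x, pcrs)
  keep <- pcrs$control_type == "sample" & colSums(x$counts) > 0
  data.frame(
    unit_id = pcrs$pcr_id[keep],
    sample_id = pcrs$sample_id[keep],
    q = q,
    value = apply(x$counts[, keep, drop = FALSE], 2, hill, q = q),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Diversity along a discretized environmental gradient
#'
#' The gradient is divided into `n_slices` equal-width intervals over its
#' observed range (empty slices are merged away, with a message); the
#' strength of the relationship is the one-factor ANOVA coefficient of
#' determination (between-slice / total sum of squares) and its
#' significance a Kruskal--Wallis test across slices. Per-slice means carry
#' normal-approximation 95% confidence intervals.
#'
#' @param values diversity values, one per unit.
#' @param env_values the continuous gradient, aligned with `values`.
#' @param variable gradient label (carried into the output).
#' @param n_slices number of equal-width slices.
#' @return list of class `slice_test`: `variable`, `n_slices` (effective),
#'   `r_squared`, `kw_p`, `slice_means` (data.frame).
#' @export
slice_anova <- function(values, env_values, variable = "gradient",
                        n_slices = 7) {
  stopifnot(length(values) == length(env_values), n_slices >= 2)
  ok <- is.finite(values) & is.finite(env_values)
  values <- values[ok]; env_values <- env_values[ok]
  breaks <- seq(min(env_values), max(env_values), length.out = n_slices + 1)
  slice <- cut(env_values, breaks, include.lowest = TRUE)
  empty <- sum(table(slice) == 0)
  if (empty > 0) {
    message(empty, " empty slice(s) merged for ", variable)
    slice <- droplevels(slice)
  }
  if (nlevels(slice) < 2) stop("fewer than 2 non-empty slices")
  fit <- stats::lm(values ~ slice)
  # a perfect between-slice fit is a legitimate degenerate input
  r2 <- suppressWarnings(summary(fit)$r.squared)
  kw <- stats::kruskal.test(values, slice)
  sm <- do.call(rbind, lapply(levels(slice), function(l) {
    v <- values[slice == l]
    se <- stats::sd(v) / sqrt(length(v))
    data.frame(slice = l, n = length(v), mean = mean(v),
               ci_lo = mean(v) - 1.96 * se, ci_hi = mean(v) + 1.96 * se)
  }))
  structure(list(variable = variable, n_slices = nlevels(slice),
                 r_squared = r2,
                 kw_p = kw$p.value, slice_means = sm),
            class = "slice_test")
}

#' @export
print.slice_test <- function(x, ...) {
  cat(sprintf("slice test [%s]: %d slices, R2 = %.3f, KW p = %.3g\n",
              x$variable, x$n_slices, x$r_squared, x$kw_p))
  invisible(x)
}

#' Slice tests across several gradients with FDR adjustment
#'
#' Runs [slice_anova()] for each variable and adjusts the Kruskal--Wallis
#' p-values across variables by the Benjamini--Hochberg false discovery
#' rate.
#'
#' @param values diversity values.
#' @param env environment data.frame aligned with `values`.
#' @param variables continuous column names to test.
#' @param n_slices slices per gradient.
#' @return data.frame with one row per variable: `variable`, `n_slices`,
#'   `r_squared`, `kw_p`, `fdr_p`.
#' @export
slice_tests <- function(values, env, variables, n_slices = 7) {
  res <- lapply(variables, function(v)
    slice_anova(values, env[[v]], v, n_slices))
  out <- data.frame(
    variable = variables,
    n_slices = vapply(res, `[[`, 0, "n_slices"),
    r_squared = vapply(res, `[[`, 0, "r_squared"),
    kw_p = vapply(res, `[[`, 0, "kw_p"),
    stringsAsFactors = FALSE)
  out$fdr_p <- stats::p.adjust(out$kw_p, method = "BH")
  attr(out, "details") <- res
  out
}

#' Two-group comparison of diversity
#'
#' Two-sided Mann--Whitney (Wilcoxon rank-sum) test with tie correction,
#' plus group means with normal-approximation 95% confidence intervals.
#'
#' @param values numeric values.
#' @param groups two-level factor aligned with `values`.
#' @return list with `means` (data.frame per group) and `p_value`.
#' @export
group_test <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  if (any(table(groups) == 0)) stop("one group is empty")
  a <- values[groups == levels(groups)[1]]
  b <- values[groups == levels(groups)[2]]
  # exact distribution when tie-free and small, tie-corrected normal
  # approximation otherwise (wilcox.test's own switch)
  w <- suppressWarnings(stats::wilcox.test(a, b))
  means <- do.call(rbind, lapply(list(a, b), function(v) {
    se <- stats::sd(v) / sqrt(length(v))
    data.frame(n = length(v), mean = mean(v),
               ci_lo = mean(v) - 1.96 * se, ci_hi = mean(v) + 1.96 * se)
  }))
  means$group <- levels(groups)
  list(means = means[c("group", "n", "mean", "ci_lo", "ci_hi")],
       statistic = unname(w$statistic), p_value = w$p.value)
}

#' Endemism profile of the MOTUs
#'
#' For each MOTU, the number of sites where it occurs and its maximum
#' within-site mean relative frequency. In datasets of under-sampled rare
#' communities these two are strongly linked: MOTUs reaching high frequency
#' somewhere tend to be found at many sites.
#'
#' @param x a [motu_table()].
#' @param pcrs PCR metadata.
#' @param site_of named character vector mapping `sample_id` to site.
#' @return data.frame with `motu_id`, `n_sites_present`,
#'   `max_site_frequency`, sorted by decreasing maximum frequency.
#' @export
endemism_profile <- function(x, pcrs, site_of) {
  pcrs <- validate_pcrs(x, pcrs)
  keep <- pcrs$control_type == "sample"
  rf <- pcr_rel_freq(x$counts[, keep, drop = FALSE])
  sites <- unname(site_of[pcrs$sample_id[keep]])
  if (anyNA(sites)) stop("site_of does not cover all sample ids")
  usites <- unique(sites)
  if (length(usites) < 2) stop("need at least 2 sites")
  site_mean <- sapply(usites, function(s)
    rowMeans(rf[, sites == s, drop = FALSE]))
  out <- data.frame(
    motu_id = x$motus$motu_id,
    n_sites_present = rowSums(site_mean > 0),
    max_site_frequency = apply(site_mean, 1, max),
    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$max_site_frequency), ]
}

#' Relative-abundance balance of two classes along a gradient
#'
#' Per sample, the fraction of reads of `class_a` among the reads of the
#' two classes, regressed linearly on the environmental variable
#' (least squares).
#'
#' @param x a [motu_table()].
#' @param pcrs PCR metadata.
#' @param env environment table with `sample_id` and the variable.
#' @param class_a,class_b class labels in the MOTU annotations.
#' @param variable continuous environmental column.
#' @return list with `data` (per-sample fraction and variable), `slope`,
#'   `intercept`, `r_squared`, `n_excluded` (samples with no reads of
#'   either class).
#' @export
class_abundance_trend <- function(x, pcrs, env, class_a, class_b, variable) {
  pcrs <- validate_pcrs(x, pcrs)
  keep <- pcrs$control_type == "sample"
  cls <- x$motus$class
  if (is.null(cls)) stop("MOTU table carries no class annotation")
  if (!any(cls == class_a, na.rm = TRUE) && !any(cls == class_b, na.rm = TRUE))
    stop("neither class present in the table")
  cnt <- x$counts[, keep, drop = FALSE]
  a_reads <- colSums(cnt[which(cls == class_a), , drop = FALSE])
  b_reads <- colSums(cnt[which(cls == class_b), , drop = FALSE])
  samples <- pcrs$sample_id[keep]
  agg <- function(v) tapply(v, samples, sum)
  a_s <- agg(a_reads); b_s <- agg(b_reads)
  tot <- a_s + b_s
  ok <- tot > 0
  n_excluded <- sum(!ok)
  if (n_excluded > 0)
    message(n_excluded, " sample(s) with no reads of either class excluded")
  frac <- a_s[ok] / tot[ok]
  v <- env[[variable]][match(names(frac), env$sample_id)]
  fit <- stats::lm(frac ~ v)
  list(data = data.frame(sample_id = names(frac), fraction = unname(frac),
                         variable = v, stringsAsFactors = FALSE),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = suppressWarnings(summary(fit)$r.squared),
       n_excluded = n_excluded)
}
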