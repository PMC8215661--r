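# Shared fixtures and independent oracles used across the test files.

# Small hand-built MOTU table: lengths/taxonomy chosen to exercise filters.
toy_table <- function(counts, lengths = NULL, clades = NULL) {
  n <- nrow(counts)
  ids <- sprintf("m%02d", seq_len(n))
  if (is.null(lengths)) lengths <- rep(100L, n)
  if (is.null(clades))
    clades <- rep("Eukaryota;Chlorophyta;Chlorophyceae;GenusA", n)
  rownames(counts) <- ids
  motu_table(
    data.frame(motu_id = ids, length = as.integer(lengths),
               clade_path = clades, stringsAsFactors = FALSE),
    counts)
}

toy_pcrs <- function(pcr_ids, sample_ids = pcr_ids,
                     control_type = rep("sample", length(pcr_ids)),
                     marker = "Chlo01") {
  data.frame(pcr_id = pcr_ids, sample_id = sample_ids, marker = marker,
             replicate = stats::ave(seq_along(pcr_ids), sample_ids,
                                    FUN = seq_along),
             control_type = control_type, stringsAsFactors = FALSE)
}

# A reduced synthetic study for fast unit tests.
small_config <- function(seed = 1, ...) {
  generator_config(n_sites = 3, levels_per_site = 4, n_taxa = 20,
                   depth_mean = 3000, seed = seed, ...)
}

# ---- independent oracles -------------------------------------------------

# Exact Mann-Whitney p by full enumeration of group assignments.
mw_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  obs <- u_stat(a, b)
  mu <- length(a) * length(b) / 2
  idx <- utils::combn(n, length(a))
  us <- apply(idx, 2, function(i) u_stat(pooled[i], pooled[-i]))
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# Brute-force OMI decomposition straight from the definition.
omi_oracle <- function(Z, w) {
  w <- w / sum(w)
  center <- colSums(Z * w)
  marginality <- sum(center^2)
  inertia <- sum(w * rowSums(Z^2))
  if (marginality > 1e-12) {
    u <- center / sqrt(marginality)
    proj <- as.numeric(Z %*% u)
    mt <- sum(w * (proj - sum(w * proj))^2)
  } else mt <- 0
  c(inertia = inertia, marginality = marginality, marginal_tolerance = mt,
    residual_tolerance = inertia - marginality - mt)
}

# Multivariate least-squares RDA oracle via explicit normal equations.
rda_oracle <- function(Y, X) {
  Yc <- scale(Y, scale = FALSE)
  Xs <- scale(X)
  B <- solve(crossprod(Xs), crossprod(Xs, Yc))
  Yhat <- Xs %*% B
  eig <- eigen(crossprod(Yhat) / (nrow(Y) - 1), symmetric = TRUE)$values
  list(fitted = Yhat, eigenvalues = eig[eig > 1e-12],
       r2 = sum(Yhat^2) / sum(Yc^2))
}

# Between/total sum-of-squares R2 by direct grouping.
anova_r2_oracle <- function(values, groups) {
  gm <- tapply(values, groups, mean)
  ss_between <- sum(tapply(values, groups, length) * (gm - mean(values))^2)
  ss_total <- sum((values - mean(values))^2)
  ss_between / ss_total
}
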