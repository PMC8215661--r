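#' Configuration of the synthetic elevational study
#'
#' Bundles every knob of the synthetic metabarcoding study: the sampling
#' design (sites along 1,250--2,940 m, ~200 m steps, two soil horizons, PCR
#' triplicates), the taxon pool (class mixture, generalist fraction, niche
#' breadths), sequencing depth and overdispersion, and the planted artefacts
#' (contaminant MOTUs concentrated in blanks, forced low-depth PCRs, rare
#' sequence variants, off-target amplification).
#'
#' @param n_sites number of elevational gradients (sites).
#' @param elevation_range numeric length-2, overall elevation span in metres.
#' @param elevation_step vertical spacing between sampling levels, metres.
#' @param levels_per_site sampling levels per site; each site covers a
#'   sub-range of the overall span, as in staggered mountain transects.
#' @param horizons soil horizon labels (litter is nutrient-enriched).
#' @param n_replicates PCR replicates per sample (>= 2).
#' @param n_taxa number of real (non-artefact) taxa in the pool.
#' @param class_mix named proportions of taxonomic classes; normalised
#'   internally. Defaults follow the read shares typical of alpine soil
#'   Chlorophyta communities (Trebouxiophyceae-dominated).
#' @param generalist_fraction proportion of taxa with niches spanning the
#'   whole sampled gradient.
#' @param specialist_breadth range (metres) from which each specialist's
#'   elevational niche breadth (Gaussian sd) is drawn.
#' @param class_ph_effect logistic slope of the pH-driven shift in the
#'   Chlorophyceae : Trebouxiophyceae balance (0 disables it).
#' @param depth_mean,depth_dispersion mean reads per PCR and the
#'   Dirichlet-multinomial overdispersion (0 gives plain multinomial noise).
#' @param fail_rate proportion of sample PCRs forced to low depth (failed
#'   amplifications).
#' @param n_contaminants number of contaminant MOTUs spiked predominantly
#'   into negative controls.
#' @param contaminant_intensity expected contaminant reads per blank PCR.
#' @param contaminant_spillover expected contaminant reads leaking into each
#'   sample PCR (kept well below the blank signal).
#' @param n_offtarget number of off-target (non-Chlorophyta) MOTUs.
#' @param n_rare_artifacts number of rare sequence-variant artefacts (never
#'   more than 10 reads in any PCR).
#' @param marker marker label; sets default length bounds and the failed-PCR
#'   read threshold ("Chlo01", "Chlo02" or "Euka03").
#' @param env_correlation optional correlation matrix for the continuous
#'   environmental variables (Gaussian copula); must be positive
#'   semi-definite, with variables in the order of [default_env_correlation()].
#' @param seed integer seed; identical seed + config gives bit-identical
#'   output.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_sites = 5,
                             elevation_range = c(1250, 2940),
                             elevation_step = 200,
                             levels_per_site = 6,
                             horizons = c("litter", "deep"),
                             n_replicates = 3,
                             n_taxa = 60,
                             class_mix = c(Trebouxiophyceae = 0.823,
                                           Chlorophyceae = 0.111,
                                           Ulvophyceae = 0.016,
                                           Pedinophyceae = 0.0002),
                             generalist_fraction = 0.3,
                             specialist_breadth = c(100, 250),
                             class_ph_effect = 0.75,
                             depth_mean = 10000,
                             depth_dispersion = 0.005,
                             fail_rate = 0.05,
                             n_contaminants = 3,
                             contaminant_intensity = 150,
                             contaminant_spillover = 0.3,
                             n_offtarget = 8,
                             n_rare_artifacts = 5,
                             marker = "Chlo01",
                             env_correlation = NULL,
                             seed = 1L) {
  stopifnot(elevation_step > 0,
            length(elevation_range) == 2,
            elevation_range[1] < elevation_range[2],
            n_replicates >= 2, n_sites >= 1, levels_per_site >= 2)
  if (length(class_mix) == 0 || sum(class_mix) <= 0)
    stop("class_mix must contain at least one class with positive weight")
  class_mix <- class_mix / sum(class_mix)
  if (is.null(env_correlation)) env_correlation <- default_env_correlation()
  check_correlation(env_correlation)
  structure(list(
    n_sites = n_sites, elevation_range = elevation_range,
    elevation_step = elevation_step, levels_per_site = levels_per_site,
    horizons = horizons, n_replicates = n_replicates, n_taxa = n_taxa,
    class_mix = class_mix, generalist_fraction = generalist_fraction,
    specialist_breadth = specialist_breadth,
    class_ph_effect = class_ph_effect,
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    fail_rate = fail_rate, n_contaminants = n_contaminants,
    contaminant_intensity = contaminant_intensity,
    contaminant_spillover = contaminant_spillover,
    n_offtarget = n_offtarget, n_rare_artifacts = n_rare_artifacts,
    marker = marker, env_correlation = env_correlation,
    seed = as.integer(seed)), class = "generator_config")
}

#' Default correlation structure of the synthetic environment
#'
#' Moderate, elevation-anchored collinearity: freezing degree days track
#' elevation strongly, pH, nitrogen and climatic water stress decline with
#' it. The matrix deliberately contains enough collinearity to exercise
#' iterative VIF selection.
#'
#' @return A 7x7 correlation matrix over Elevation, pH, Nitrogen, C_N_ratio,
#'   FDD, CWD, DTR.
#' @export
default_env_correlation <- function() {
  v <- c("Elevation", "pH", "Nitrogen", "C_N_ratio", "FDD", "CWD", "DTR")
  R <- diag(7)
  dimnames(R) <- list(v, v)
  set_cor <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set_cor("Elevation", "pH", -0.40)
  set_cor("Elevation", "Nitrogen", -0.30)
  set_cor("Elevation", "C_N_ratio", 0.20)
  set_cor("Elevation", "FDD", 0.80)
  set_cor("Elevation", "CWD", -0.45)
  set_cor("Elevation", "DTR", 0.30)
  set_cor("pH", "Nitrogen", 0.20)
  set_cor("Nitrogen", "C_N_ratio", -0.30)
  set_cor("FDD", "CWD", -0.40)
  set_cor("FDD", "DTR", 0.25)
  R
}

check_correlation <- function(R) {
  if (!is.matrix(R) || nrow(R) != ncol(R) || !isTRUE(all.equal(R, t(R))) ||
      any(abs(diag(R) - 1) > 1e-10))
    stop("env_correlation must be a symmetric correlation matrix")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("env_correlation is not positive semi-definite (min eigenvalue ",
         signif(min(ev), 3), ")")
  invisible(R)
}

#' Generate the environmental table of the synthetic study
#'
#' One row per sample (site x elevation level x horizon). Sites cover
#' staggered sub-ranges of the overall elevation span, sampled every
#' `elevation_step` metres. Continuous variables (pH, Nitrogen, C/N ratio,
#' FDD, CWD, DTR) are drawn from a Gaussian copula conditioned on the
#' standardized elevation using the configured correlation matrix, then
#' mapped to field-realistic scales; Carbon and OrganicMatter are derived
#' from Nitrogen and the C/N ratio (hence strongly collinear, on purpose).
#' The litter horizon is enriched in Nitrogen/Carbon/OrganicMatter.
#'
#' @param config a [generator_config()].
#' @return data.frame with `sample_id`, categorical `Site`, `Environment`,
#'   `Horizon` and the continuous variables.
#' @export
generate_env <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  rng <- config$elevation_range
  span <- (config$levels_per_site - 1) * config$elevation_step
  span <- min(span, diff(rng))
  starts <- if (config$n_sites == 1) rng[1] else
    round(seq(rng[1], rng[2] - span, length.out = config$n_sites) / 10) * 10
  sites <- sprintf("S%02d", seq_len(config$n_sites))
  grid <- do.call(rbind, lapply(seq_along(sites), function(i) {
    elev <- starts[i] + (seq_len(config$levels_per_site) - 1) *
      config$elevation_step
    elev <- pmin(elev, rng[2])
    expand.grid(Site = sites[i], Elevation = elev,
                Horizon = config$horizons, stringsAsFactors = FALSE)
  }))
  n <- nrow(grid)
  R <- config$env_correlation
  vars <- rownames(R)
  others <- setdiff(vars, "Elevation")
  z_elev <- as.numeric(scale(grid$Elevation))
  r_oe <- R[others, "Elevation"]
  cond_cov <- R[others, others] - tcrossprod(r_oe)
  ee <- eigen(cond_cov, symmetric = TRUE)
  L <- ee$vectors %*% diag(sqrt(pmax(ee$values, 0)), length(others))
  Zo <- tcrossprod(z_elev, r_oe) +
    matrix(stats::rnorm(n * length(others)), n) %*% t(L)
  colnames(Zo) <- others
  litter <- grid$Horizon == config$horizons[1]
  env <- data.frame(
    sample_id = sprintf("%s_E%04d_%s", grid$Site, grid$Elevation,
                        substr(grid$Horizon, 1, 3)),
    Site = grid$Site,
    Elevation = grid$Elevation,
    Horizon = grid$Horizon,
    Environment = ifelse(grid$Elevation < 2000, "forest", "open-area"),
    pH = pmin(7.8, pmax(3.5, 5.3 + 0.7 * Zo[, "pH"])),
    Nitrogen = exp(log(0.45) + 0.45 * Zo[, "Nitrogen"]) *
      ifelse(litter, 1.5, 1),
    C_N_ratio = pmax(5, 14 + 3 * Zo[, "C_N_ratio"] + ifelse(litter, 2, 0)),
    FDD = pmax(0, 180 + 130 * Zo[, "FDD"]),
    CWD = 120 + 40 * Zo[, "CWD"],
    DTR = 9.5 + 1.6 * Zo[, "DTR"],
    stringsAsFactors = FALSE)
  env$Carbon <- env$Nitrogen * env$C_N_ratio
  env$OrganicMatter <- env$Carbon * 1.72 * exp(stats::rnorm(n, 0, 0.03))
  env
}

#' Generate the ground-truth taxon pool
#'
#' Each taxon gets a taxonomic class (drawn from `class_mix`), a Gaussian
#' niche over elevation and pH (specialists: narrow breadths; generalists:
#' breadths spanning several times the sampled range, i.e. effectively flat
#' responses) and a log-normal peak abundance. The Chlorophyceae /
#' Trebouxiophyceae balance additionally shifts logistically with pH
#' (Chlorophyceae favoured at higher pH), so class-level abundance trends
#' are recoverable downstream. An optional `min_elevation` hard floor allows
#' snow-algae-like taxa absent below a threshold elevation.
#'
#' @param config a [generator_config()].
#' @return data.frame of true niches: `taxon_id`, `class_label`,
#'   `generalist`, `opt_elevation`, `breadth_elevation`, `opt_pH`,
#'   `breadth_pH`, `min_elevation`, `ph_class_slope`, `peak_abundance`.
#' @export
generate_taxa <- function(config) {
  stopifnot(inherits(config, "generator_config"), config$n_taxa >= 2)
  set.seed(config$seed + 1L)
  n <- config$n_taxa
  rng <- config$elevation_range
  cls <- sample(names(config$class_mix), n, replace = TRUE,
                prob = config$class_mix)
  generalist <- stats::runif(n) < config$generalist_fraction
  breadth_e <- ifelse(generalist,
                      3 * diff(rng),
                      stats::runif(n, config$specialist_breadth[1],
                                   config$specialist_breadth[2]))
  breadth_p <- ifelse(generalist, 40, stats::runif(n, 0.5, 1.0))
  # generalists are ubiquitous by definition: flat over every gradient,
  # so the class-level pH shift applies to specialists only
  slope <- ifelse(generalist, 0,
                  ifelse(cls == "Chlorophyceae", config$class_ph_effect,
                         ifelse(cls == "Trebouxiophyceae",
                                -config$class_ph_effect, 0)))
  data.frame(
    taxon_id = sprintf("motu_%03d", seq_len(n)),
    class_label = cls,
    generalist = generalist,
    opt_elevation = stats::runif(n, rng[1], rng[2]),
    breadth_elevation = breadth_e,
    opt_pH = stats::runif(n, 4.2, 7.2),
    breadth_pH = breadth_p,
    min_elevation = NA_real_,
    ph_class_slope = slope,
    # generalists are the abundant, cosmopolitan background of the
    # community (as ubiquitous taxa are in field data); specialists ride
    # on top of it
    peak_abundance = stats::rlnorm(n, 0, 0.6) * ifelse(generalist, 5, 1),
    stringsAsFactors = FALSE)
}

#' Expected relative abundances under the true niches
#'
#' Evaluates each taxon's Gaussian response at each sample's environment and
#' normalises within samples.
#'
#' @param taxa data.frame from [generate_taxa()] (or hand-built with the
#'   same columns).
#' @param env data.frame from [generate_env()].
#' @return matrix samples x taxa of expected relative abundances (rows sum
#'   to 1).
#' @export
niche_response <- function(taxa, env) {
  stopifnot(nrow(taxa) >= 1, nrow(env) >= 1)
  A <- sapply(seq_len(nrow(taxa)), function(j) {
    t <- taxa[j, ]
    a <- t$peak_abundance *
      exp(-0.5 * ((env$Elevation - t$opt_elevation) / t$breadth_elevation)^2) *
      exp(-0.5 * ((env$pH - t$opt_pH) / t$breadth_pH)^2)
    if (!is.na(t$ph_class_slope) && t$ph_class_slope != 0)
      a <- a * stats::plogis(t$ph_class_slope * (env$pH - 5.5))
    if (!is.na(t$min_elevation))
      a[env$Elevation < t$min_elevation] <- 0
    a
  })
  A <- matrix(A, nrow = nrow(env),
              dimnames = list(env$sample_id, taxa$taxon_id))
  rs <- rowSums(A)
  rs[rs == 0] <- 1
  A / rs
}

#' Mock-community concentration series
#'
#' Concentrations of an n-species positive-control community in which each
#' species' DNA concentration is a fixed fraction (`dilution`) of the
#' previous one, normalised to sum to 1. With `dilution = 0.5` and 13
#' species this is the standard halving-series positive control whose
#' theoretical Hill diversity of order 1 is 4.0 (the infinite series gives
#' exactly exp(2 log 2) = 4).
#'
#' @param n_species number of species (>= 1).
#' @param dilution ratio in (0, 1] between consecutive concentrations.
#' @return numeric vector of length `n_species` summing to 1.
#' @examples
#' hill(mock_community(13, 0.5), q = 1)  # ~4.0
#' @export
mock_community <- function(n_species, dilution = 0.5) {
  if (n_species < 1) stop("n_species must be >= 1")
  if (dilution <= 0 || dilution > 1) stop("dilution must be in (0, 1]")
  cc <- dilution^(seq_len(n_species) - 1)
  cc / sum(cc)
}

random_sequences <- function(n, min_bp, max_bp) {
  vapply(seq_len(n), function(i) {
    len <- sample(seq(min_bp, max_bp), 1)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

dirichlet_multinomial <- function(depth, p, dispersion) {
  if (depth == 0 || sum(p) == 0) return(integer(length(p)))
  p <- p / sum(p)
  if (dispersion > 0) {
    g <- stats::rgamma(length(p), shape = p / dispersion)
    p <- if (sum(g) == 0) p else g / sum(g)
  }
  as.integer(stats::rmultinom(1, depth, p))
}

#' Simulate a full sequencing run into a MOTU table
#'
#' Draws per-PCR read counts from the true niches: expected proportions come
#' from [niche_response()] evaluated at each sample's environment,
#' compounded with Dirichlet-multinomial overdispersion; total depth is
#' negative-binomial around `depth_mean`. A configured fraction of sample
#' PCRs is forced to low depth (failed amplifications). Extraction and PCR
#' blanks are near-empty apart from the planted contaminant MOTUs (with a
#' small spillover into samples); positive-control PCRs contain the 13-species
#' halving mock community. Off-target MOTUs (non-Chlorophyta, partly with
#' out-of-bounds amplicon lengths) and rare sequence-variant artefacts are
#' added so that every QC filter has work to do.
#'
#' @param env data.frame from [generate_env()].
#' @param taxa data.frame from [generate_taxa()].
#' @param config the same [generator_config()] used for `env` and `taxa`.
#' @return list with `table` (a [motu_table()]), `pcrs` (PCR metadata
#'   data.frame with `pcr_id`, `sample_id`, `marker`, `replicate`,
#'   `control_type`, realized `depth`) and `truth` (ground-truth ids:
#'   `taxa`, `contaminants`, `failed_pcrs`, `mock`, `offtarget`, `rare`).
#' @export
simulate_reads <- function(env, taxa, config) {
  stopifnot(inherits(config, "generator_config"))
  if (nrow(taxa) == 0) stop("zero-taxon input")
  set.seed(config$seed + 2L)
  bounds <- marker_length_bounds(config$marker)
  min_reads <- marker_min_reads(config$marker)

  sample_pcrs <- expand.grid(sample_id = env$sample_id,
                             replicate = seq_len(config$n_replicates),
                             stringsAsFactors = FALSE)
  sample_pcrs <- sample_pcrs[order(sample_pcrs$sample_id,
                                   sample_pcrs$replicate), ]
  pcrs <- data.frame(
    pcr_id = sprintf("%s_r%d", sample_pcrs$sample_id, sample_pcrs$replicate),
    sample_id = sample_pcrs$sample_id,
    marker = config$marker,
    replicate = sample_pcrs$replicate,
    control_type = "sample",
    stringsAsFactors = FALSE)
  blanks <- data.frame(
    pcr_id = c(sprintf("extblank_%02d", seq_len(config$n_sites)),
               sprintf("pcrblank_%02d", 1:3),
               sprintf("positive_%02d", 1:3)),
    sample_id = c(sprintf("extblank_%02d", seq_len(config$n_sites)),
                  sprintf("pcrblank_%02d", 1:3),
                  sprintf("positive_%02d", 1:3)),
    marker = config$marker,
    replicate = 1L,
    control_type = c(rep("extraction_blank", config$n_sites),
                     rep("pcr_blank", 3), rep("positive", 3)),
    stringsAsFactors = FALSE)
  pcrs <- rbind(pcrs, blanks)
  n_pcr <- nrow(pcrs)
  is_sample <- pcrs$control_type == "sample"
  is_blank <- pcrs$control_type %in% c("extraction_blank", "pcr_blank")
  is_pos <- pcrs$control_type == "positive"

  # MOTU pool: real taxa + mock + contaminants + off-target + rare artefacts
  ids_mock <- sprintf("mock_%02d", 1:13)
  ids_cont <- if (config$n_contaminants > 0)
    sprintf("contam_%02d", seq_len(config$n_contaminants)) else character(0)
  ids_off <- if (config$n_offtarget > 0)
    sprintf("offt_%02d", seq_len(config$n_offtarget)) else character(0)
  ids_rare <- if (config$n_rare_artifacts > 0)
    sprintf("rare_%02d", seq_len(config$n_rare_artifacts)) else character(0)
  all_ids <- c(taxa$taxon_id, ids_mock, ids_cont, ids_off, ids_rare)

  genus <- function(id) paste0("Genus_", sub("_", "", id))
  off_class <- rep(c("Fungi", "Streptophyta"), length.out = length(ids_off))
  motus <- data.frame(
    motu_id = all_ids,
    sequence = NA_character_,
    length = NA_integer_,
    class = c(taxa$class_label, rep("Mock", 13),
              rep("Chlorophyceae", length(ids_cont)),
              off_class, rep("Trebouxiophyceae", length(ids_rare))),
    genus = genus(all_ids),
    species = paste0(genus(all_ids), " sp."),
    stringsAsFactors = FALSE)
  in_target <- c(rep(TRUE, nrow(taxa) + 13 + length(ids_cont)),
                 rep(FALSE, length(ids_off)), rep(TRUE, length(ids_rare)))
  motus$clade_path <- ifelse(
    in_target,
    paste("Eukaryota", "Chlorophyta", motus$class, motus$genus, sep = ";"),
    paste("Eukaryota", motus$class, motus$genus, sep = ";"))
  seq_in <- random_sequences(sum(in_target), bounds[1], bounds[2])
  # half of the off-target MOTUs get out-of-bounds amplicon lengths
  n_off <- length(ids_off)
  seq_out <- character(0)
  if (n_off > 0) {
    short <- random_sequences(ceiling(n_off / 2), max(20, bounds[1] - 30),
                              bounds[1] - 1)
    inb <- random_sequences(floor(n_off / 2), bounds[1], bounds[2])
    seq_out <- c(short, inb)
  }
  motus$sequence[in_target][seq_len(nrow(taxa) + 13 + length(ids_cont))] <-
    seq_in[seq_len(nrow(taxa) + 13 + length(ids_cont))]
  motus$sequence[!in_target] <- seq_out
  motus$sequence[match(ids_rare, motus$motu_id)] <-
    seq_in[nrow(taxa) + 13 + length(ids_cont) + seq_along(ids_rare)]
  motus$length <- nchar(motus$sequence)

  counts <- matrix(0L, nrow = length(all_ids), ncol = n_pcr,
                   dimnames = list(all_ids, pcrs$pcr_id))
  P <- niche_response(taxa, env)

  # forced failures among sample PCRs
  n_fail <- floor(config$fail_rate * sum(is_sample))
  fail_idx <- if (n_fail > 0) sample(which(is_sample), n_fail) else integer(0)

  for (k in which(is_sample)) {
    depth <- if (k %in% fail_idx)
      stats::rpois(1, 0.25 * min_reads) else
      stats::rnbinom(1, size = 8, mu = config$depth_mean)
    p <- P[match(pcrs$sample_id[k], rownames(P)), ]
    counts[taxa$taxon_id, k] <-
      dirichlet_multinomial(depth, p, config$depth_dispersion)
    if (length(ids_cont) > 0)
      counts[ids_cont, k] <- counts[ids_cont, k] +
        stats::rpois(length(ids_cont), config$contaminant_spillover)
  }

  # blanks: tiny background of the most abundant real taxa + contaminants
  top <- taxa$taxon_id[order(colMeans(P), decreasing = TRUE)]
  top <- utils::head(top, 10)
  for (k in which(is_blank)) {
    bg <- stats::rpois(1, if (pcrs$control_type[k] == "extraction_blank")
      10 else 4)
    counts[top, k] <- dirichlet_multinomial(bg, colMeans(P)[top], 0)
    if (length(ids_cont) > 0)
      counts[ids_cont, k] <- stats::rpois(length(ids_cont),
                                          config$contaminant_intensity)
  }

  # positive controls: mock halving community
  mock_p <- mock_community(13, 0.5)
  for (k in which(is_pos)) {
    depth <- stats::rnbinom(1, size = 8, mu = config$depth_mean)
    counts[ids_mock, k] <-
      dirichlet_multinomial(depth, mock_p, config$depth_dispersion)
  }

  # off-target MOTUs: sporadic mid-abundance noise in sample PCRs
  for (id in ids_off) {
    hit <- which(is_sample & stats::runif(n_pcr) < 0.3)
    counts[id, hit] <- stats::rpois(length(hit), 40)
  }
  # rare artefacts: never more than 10 reads in any PCR
  for (id in ids_rare) {
    hit <- sample(which(is_sample), min(3, sum(is_sample)))
    counts[id, hit] <- sample(1:10, length(hit), replace = TRUE)
  }

  pcrs$depth <- colSums(counts)
  list(table = motu_table(motus, counts),
       pcrs = pcrs,
       truth = list(taxa = taxa,
                    contaminants = ids_cont,
                    failed_pcrs = pcrs$pcr_id[fail_idx],
                    mock = ids_mock,
                    offtarget = ids_off,
                    rare = ids_rare))
}

#' Run the whole generator
#'
#' Convenience wrapper: environment, taxon pool and simulated reads from one
#' configuration.
#'
#' @param config a [generator_config()].
#' @return list with `env`, `taxa`, `table`, `pcrs`, `truth`.
#' @export
simulate_study <- function(config = generator_config()) {
  env <- generate_env(config)
  taxa <- generate_taxa(config)
  sim <- simulate_reads(env, taxa, config)
  list(env = env, taxa = taxa, table = sim$table, pcrs = sim$pcrs,
       truth = sim$truth)
}

#' Paired marker detection of the same communities
#'
#' Emulates measuring the same per-PCR target-clade relative frequencies
#' with two markers whose detection differs by log-normal noise (and
#' occasional dropout), the situation handled downstream by the robust
#' log-log regression.
#'
#' @param study output of [simulate_study()].
#' @param detection_sd sd of the log-normal marker-specific noise.
#' @param dropout probability that the second marker misses the clade in a
#'   PCR entirely.
#' @param seed integer seed for the marker-specific noise.
#' @return data.frame with per-PCR `freq1`, `freq2`.
#' @export
marker_pair_frequencies <- function(study, detection_sd = 0.3,
                                    dropout = 0.05, seed = 1L) {
  set.seed(seed + 99L)
  tab <- study$table
  pcrs <- study$pcrs
  keep <- pcrs$control_type == "sample"
  rf <- pcr_rel_freq(tab$counts)[, keep, drop = FALSE]
  chloro <- grepl("Chlorophyta", tab$motus$clade_path)
  f1 <- colSums(rf[chloro, , drop = FALSE])
  f2 <- pmin(1, f1 * exp(stats::rnorm(length(f1), 0, detection_sd)))
  f2[stats::runif(length(f2)) < dropout] <- 0
  data.frame(pcr_id = pcrs$pcr_id[keep], freq1 = f1, freq2 = f2)
}

#' Write all generator outputs as plain text
#'
#' Emits the MOTU table (TSV), PCR metadata, environment table and
#' ground-truth niches (CSV), plus the annotated FASTA. Output is
#' byte-identical for a given seed and configuration.
#'
#' @param study output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_motu_table(study$table, file.path(dir, "motu_table.tsv"))
  utils::write.csv(study$pcrs, file.path(dir, "pcrs.csv"), row.names = FALSE)
  utils::write.csv(study$env, file.path(dir, "env.csv"), row.names = FALSE)
  utils::write.csv(study$taxa, file.path(dir, "true_niches.csv"),
                   row.names = FALSE)
  write_annotated_fasta(study$table$motus, file.path(dir, "motus.fasta"))
  invisible(dir)
}
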