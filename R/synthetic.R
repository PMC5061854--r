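#' Design of a synthetic benthic community experiment
#'
#' Collects every knob of the generator. Defaults emulate the statistical
#' structure of a chronically PAH-impacted coastal sediment survey: 42
#' sediment samples along strongly
#' rank-correlated salinity/temperature/latitude gradients (target rho
#' -0.8, via a Gaussian copula), a suite of 11 mutually correlated
#' log-normal PAH concentrations elevated ~20-fold at contaminated sites,
#' environmentally filtered core OTUs (some organised into co-occurring
#' modules driven by shared latent factors), one module negatively coupled
#' to fluoranthene containing a negatively correlated predator-prey OTU
#' pair, and sparse satellite OTUs that are homogeneous Poisson across
#' samples (so they are genuinely randomly dispersed, as the core/satellite
#' partition assumes).
#'
#' @param n_samples number of sediment samples.
#' @param n_core,n_satellite number of planted core and satellite OTUs.
#' @param n_modules number of planted co-occurrence modules among the core
#'   OTUs (0 for none).
#' @param module_size_range min/max OTUs per module.
#' @param env_rho target rank correlation of salinity and temperature with
#'   latitude (negative: salinity and temperature fall with latitude).
#' @param pah_site_sdlog10 log10 SD of the shared per-sample PAH site
#'   factor; with `pah_compound_sdlog10` it sets the inter-compound
#'   correlation (defaults give rho about 0.9 > 0.75).
#' @param pah_compound_sdlog10 log10 SD of per-compound noise.
#' @param contamination_multiplier fold elevation of all PAHs at
#'   contaminated sites (1 = null design).
#' @param pah_sensitive_module index of the module whose latent factor
#'   decreases with log fluoranthene (`NULL` = min(5, n_modules)).
#' @param base_meanlog,base_sdlog log-normal baseline abundance of core OTUs
#'   (expected counts before depth scaling).
#' @param beta_range magnitude range of per-OTU environmental responses
#'   (log scale per SD of the driver) for non-module core OTUs.
#' @param module_gamma,module_eps_sd environmental loading and shared-noise
#'   SD of module latent factors.
#' @param module_loading_sd SD of member loadings around 1.
#' @param pah_gamma,pah_eps_sd loading of the PAH-sensitive module's factor
#'   on -log10(fluoranthene) and its shared-noise SD.
#' @param predator_delta strength with which the predator OTU's latent
#'   factor suppresses its prey's expected abundance.
#' @param core_idio_sd SD of per-OTU idiosyncratic log-normal noise added to
#'   non-module core OTUs (environmental stochasticity; keeps OTUs sharing a
#'   driver from being deterministically correlated).
#' @param attenuation_contaminated factor (0-1) by which the shared module
#'   signal is attenuated in contaminated samples (replaced by idiosyncratic
#'   noise of equal variance), degrading module edges there.
#' @param satellite_lambda_range per-OTU Poisson mean range of satellite
#'   OTUs (before depth scaling).
#' @param depth sequencing depth per sample (multinomial resampling of
#'   expected relative abundances).
#' @param noise `"poisson"` (multinomial depth resampling, the Poisson
#'   analogue under fixed depth) or `"negative_binomial"`.
#' @param nb_dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @return list of class `synthetic_design`.
#' @export
synthetic_design <- function(n_samples = 42L,
                             n_core = 120L,
                             n_satellite = 900L,
                             n_modules = 6L,
                             module_size_range = c(8L, 15L),
                             env_rho = -0.8,
                             pah_site_sdlog10 = 0.30,
                             pah_compound_sdlog10 = 0.10,
                             contamination_multiplier = 20,
                             pah_sensitive_module = NULL,
                             base_meanlog = log(20),
                             base_sdlog = 0.8,
                             beta_range = c(0.5, 1.0),
                             module_gamma = 0.6,
                             module_eps_sd = 0.9,
                             module_loading_sd = 0.15,
                             pah_gamma = 0.9,
                             pah_eps_sd = 0.5,
                             predator_delta = 1.0,
                             core_idio_sd = 0.7,
                             attenuation_contaminated = 0.7,
                             satellite_lambda_range = c(0.05, 0.6),
                             depth = 3238L,
                             noise = c("poisson", "negative_binomial"),
                             nb_dispersion = 0.3) {
  noise <- match.arg(noise)
  if (n_core + n_satellite < 2) stop("need at least 2 OTUs in total")
  if (abs(env_rho) >= 1) stop("|env_rho| must be < 1")
  if (n_modules > 0 && n_modules * module_size_range[1] > n_core)
    stop("module sizes exceed the number of core OTUs")
  if (attenuation_contaminated < 0 || attenuation_contaminated > 1)
    stop("attenuation_contaminated must lie in [0, 1]")
  if (is.null(pah_sensitive_module))
    pah_sensitive_module <- if (n_modules > 0) min(5L, n_modules) else 0L
  structure(as.list(environment()), class = "synthetic_design")
}

#' Baseline (pristine) geometric-mean PAH concentrations, ug/kg DW
#'
#' Moderate urban-background levels with phenanthrene/anthracene about 7 and
#' fluoranthene/pyrene about 1.3, so that pristine and contaminated sites
#' alike read as pyrogenic under the diagnostic ratios (combustion-derived
#' atmospheric deposition, the chronic input regime the design emulates).
#'
#' @return named numeric vector over [pah_compounds()].
#' @export
pah_baseline <- function() {
  c(fluoranthene = 40, fluorene = 10, pyrene = 30, anthracene = 5,
    benz_a_anthracene = 15, benzo_a_pyrene = 20, benzo_ghi_perylene = 12,
    chrysene = 18, dibenz_ah_anthracene = 3, indeno_123cd_pyrene = 10,
    phenanthrene = 35)
}

#' Simulate sample metadata and per-sample ground truth
#'
#' Environmental gradients come from a Gaussian copula: a latent latitude
#' axis drives salinity and temperature with rank correlation `env_rho`.
#' Samples north of the latitude midpoint are "Atlantic", the rest
#' "Mediterranean"; within each region half the samples are contaminated.
#' All 11 PAH concentrations share a per-sample log-normal site factor (plus
#' per-compound noise), multiplied by `contamination_multiplier` at
#' contaminated sites, so inter-compound rank correlations exceed 0.75 and
#' contamination is a common enrichment of the whole suite.
#'
#' @param design a [synthetic_design()].
#' @param seed integer seed.
#' @return list: `metadata` (data.frame, one row per sample with sample_id,
#'   region, latitude, salinity, temperature, psd, toc, the 11 PAH columns
#'   and a_priori_label) and `truth` (list with `contaminated` logical and
#'   `region`).
#' @export
simulate_metadata <- function(design, seed = 1L) {
  stopifnot(inherits(design, "synthetic_design"))
  set.seed(seed)
  n <- design$n_samples
  rho <- design$env_rho
  z_lat <- rnorm(n)
  coupled <- function() rho * z_lat + sqrt(1 - rho^2) * rnorm(n)
  latitude <- 40 + 4 * z_lat
  salinity <- 37 + 2 * coupled()
  temperature <- 16 + 3 * coupled()
  psd <- pmin(pmax(rnorm(n, 55, 15), 5), 95)
  toc <- rlnorm(n, log(1.5), 0.5)
  region <- ifelse(latitude > 40, "Atlantic", "Mediterranean")
  contaminated <- logical(n)
  for (r in unique(region)) {
    idx <- which(region == r)
    contaminated[sample(idx, floor(length(idx) / 2))] <- TRUE
  }
  base <- pah_baseline()
  site <- rnorm(n, 0, design$pah_site_sdlog10) +
    contaminated * log10(design$contamination_multiplier)
  pah <- sapply(names(base), function(cp)
    10^(log10(base[[cp]]) + site + rnorm(n, 0, design$pah_compound_sdlog10)))
  metadata <- data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                         region = region, latitude = latitude,
                         salinity = salinity, temperature = temperature,
                         psd = psd, toc = toc,
                         a_priori_label = ifelse(contaminated, "contaminated",
                                                 "pristine"),
                         stringsAsFactors = FALSE)
  metadata <- cbind(metadata, as.data.frame(pah))
  list(metadata = metadata,
       truth = list(contaminated = contaminated, region = region))
}

#' Simulate an OTU count table with planted structure
#'
#' Core OTUs have log expected abundance `base + beta * env` (free core) or
#' `base + loading * module factor` (module members). Module latent factors
#' are shared per module per sample and carry an environmental driver; the
#' PAH-sensitive module's factor decreases with log fluoranthene. In
#' contaminated samples the shared module signal is attenuated and replaced
#' by idiosyncratic noise of equal variance, so module co-occurrence decays
#' there. The predator OTU's latent factor enters its prey's expectation
#' with negative sign. Satellite OTUs are homogeneous Poisson with small
#' per-OTU means. Expected abundances are rescaled per sample and counts are
#' drawn by multinomial resampling at the target depth (or a
#' negative-binomial noise model).
#'
#' @param design a [synthetic_design()].
#' @param metadata,truth output of [simulate_metadata()].
#' @param seed integer seed.
#' @return list: `table` (an [abundance_table()]) and `truth` extended with
#'   per-OTU class, module id, predator/prey ids and module factors.
#' @export
simulate_counts <- function(design, metadata, truth, seed = 1L) {
  stopifnot(inherits(design, "synthetic_design"))
  set.seed(seed + 1L)
  n <- nrow(metadata)
  n_core <- design$n_core
  n_sat <- design$n_satellite
  env <- cbind(salinity = scale(metadata$salinity)[, 1],
               temperature = scale(metadata$temperature)[, 1],
               toc = scale(log(metadata$toc))[, 1],
               psd = scale(metadata$psd)[, 1])
  env[is.nan(env)] <- 0
  z_fluo <- scale(log10(metadata$fluoranthene))[, 1]
  if (anyNA(z_fluo) || all(z_fluo == 0)) z_fluo <- rep(0, n)

  core_ids <- sprintf("core_%03d", seq_len(n_core))
  sat_ids <- sprintf("sat_%03d", seq_len(n_sat))

  # module memberships
  module <- rep(0L, n_core)
  n_mod <- design$n_modules
  pah_mod <- design$pah_sensitive_module
  if (n_mod > 0) {
    size_pool <- seq(design$module_size_range[1],
                     design$module_size_range[2])
    sizes <- size_pool[sample.int(length(size_pool), n_mod, replace = TRUE)]
    while (sum(sizes) > n_core) sizes[which.max(sizes)] <-
        sizes[which.max(sizes)] - 1L
    module[seq_len(sum(sizes))] <- rep(seq_len(n_mod), sizes)
  }

  # module latent factors: gamma * env driver + shared noise
  drivers <- list(c("salinity", 1), c("salinity", -1), c("temperature", 1),
                  c("toc", -1), c("psd", 1), c("temperature", -1))
  fac <- matrix(0, nrow = max(n_mod, 1), ncol = n)
  for (m in seq_len(n_mod)) {
    if (m == pah_mod) {
      fac[m, ] <- -design$pah_gamma * z_fluo + rnorm(n, 0, design$pah_eps_sd)
    } else {
      d <- drivers[[(m - 1) %% length(drivers) + 1]]
      fac[m, ] <- design$module_gamma * as.numeric(d[2]) * env[, d[1]] +
        rnorm(n, 0, design$module_eps_sd)
    }
  }
  fac_sd <- apply(fac, 1, sd)
  fac_sd[fac_sd == 0] <- 1

  att <- design$attenuation_contaminated
  cont <- truth$contaminated
  base <- rnorm(n_core, design$base_meanlog, design$base_sdlog)
  betas <- matrix(0, n_core, ncol(env),
                  dimnames = list(core_ids, colnames(env)))
  L <- matrix(rep(base, n), n_core, n)
  contrib <- matrix(0, n_core, n) # realized latent factor per core OTU
  for (i in seq_len(n_core)) {
    if (module[i] > 0) {
      m <- module[i]
      load <- rnorm(1, 1, design$module_loading_sd)
      g <- fac[m, ]
      if (any(cont) && att < 1) {
        idio <- rnorm(n, 0, fac_sd[m])
        g[cont] <- att * g[cont] + sqrt(1 - att^2) * idio[cont]
      }
      contrib[i, ] <- load * g
    } else {
      v <- sample(ncol(env), 1)
      b <- sample(c(-1, 1), 1) *
        runif(1, design$beta_range[1], design$beta_range[2])
      betas[i, v] <- b
      contrib[i, ] <- b * env[, v] + rnorm(n, 0, design$core_idio_sd)
    }
    L[i, ] <- L[i, ] + contrib[i, ]
  }

  # predator-prey pair inside the PAH-sensitive module
  predator <- prey <- NA_character_
  if (n_mod > 0 && pah_mod > 0 && sum(module == pah_mod) >= 2) {
    members <- which(module == pah_mod)
    predator <- core_ids[members[1]]
    prey <- core_ids[members[2]]
    ip <- members[1]; iy <- members[2]
    L[iy, ] <- base[iy] - design$predator_delta * contrib[ip, ]
    contrib[iy, ] <- -design$predator_delta * contrib[ip, ]
  }

  E_core <- exp(L)
  lam_sat <- runif(n_sat, design$satellite_lambda_range[1],
                   design$satellite_lambda_range[2])
  E_sat <- matrix(rep(lam_sat, n), n_sat, n)
  E <- rbind(E_core, E_sat)
  rownames(E) <- c(core_ids, sat_ids)
  colnames(E) <- metadata$sample_id

  depth <- design$depth
  counts <- matrix(0, nrow(E), n, dimnames = dimnames(E))
  if (design$noise == "poisson") {
    for (s in seq_len(n))
      counts[, s] <- rmultinom(1, depth, E[, s] / sum(E[, s]))
  } else {
    for (s in seq_len(n)) {
      mu <- E[, s] * depth / sum(E[, s])
      counts[, s] <- rnbinom(nrow(E), mu = mu,
                             size = 1 / design$nb_dispersion)
    }
  }
  truth$otu_class <- setNames(c(rep("core", n_core), rep("satellite", n_sat)),
                              rownames(E))
  truth$module <- setNames(c(module, rep(0L, n_sat)), rownames(E))
  truth$predator <- predator
  truth$prey <- prey
  truth$pah_sensitive_module <- if (n_mod > 0) pah_mod else NA_integer_
  truth$betas <- betas
  truth$module_factors <- fac
  list(table = abundance_table(counts), truth = truth)
}

#' Simulate taxonomy for a synthetic community
#'
#' Assigns domains at the network's observed proportions (Bacteria 76%,
#' Eukarya 15%, Archaea 9%) and a class-level lineage from a small pool per
#' domain. The planted predator is an Alveolata (Eukarya) and its prey an
#' Actinobacteria (Bacteria), mirroring the predator-prey motif in the
#' PAH-sensitive module.
#'
#' @param truth ground truth from [simulate_counts()].
#' @param seed integer seed.
#' @return taxonomy data.frame (otu_id, domain, phylum, class).
#' @export
simulate_taxonomy <- function(truth, seed = 1L) {
  set.seed(seed + 2L)
  ids <- names(truth$otu_class)
  pools <- list(
    Bacteria = c("Gammaproteobacteria", "Deltaproteobacteria",
                 "Actinobacteria", "Bacteroidia", "Planctomycetia",
                 "Anaerolineae"),
    Archaea = c("Thermoplasmata", "Nitrososphaeria", "Methanomicrobia"),
    Eukarya = c("Alveolata", "Diatomea", "Cercozoa", "Fungi"))
  domain <- sample(names(pools), length(ids), replace = TRUE,
                   prob = c(0.76, 0.09, 0.15))
  names(domain) <- ids
  cls <- vapply(domain, function(d) sample(pools[[d]], 1), character(1))
  if (!is.na(truth$predator)) {
    domain[truth$predator] <- "Eukarya"; cls[truth$predator] <- "Alveolata"
    domain[truth$prey] <- "Bacteria"; cls[truth$prey] <- "Actinobacteria"
  }
  data.frame(otu_id = ids, domain = unname(domain),
             phylum = unname(domain), class = unname(cls),
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic community
#'
#' Convenience wrapper chaining [simulate_metadata()], [simulate_counts()]
#' and [simulate_taxonomy()] under one seed.
#'
#' @param design a [synthetic_design()].
#' @param seed integer seed.
#' @return list: table, metadata, taxonomy, truth.
#' @export
simulate_community <- function(design = synthetic_design(), seed = 1L) {
  md <- simulate_metadata(design, seed)
  ct <- simulate_counts(design, md$metadata, md$truth, seed)
  tax <- simulate_taxonomy(ct$truth, seed)
  list(table = ct$table, metadata = md$metadata, taxonomy = tax,
       truth = ct$truth)
}

#' Deterministic miniature community used across unit tests
#'
#' 12 samples x 40 OTUs (10 core of which 2 modules of 4, 30 satellites),
#' fixed internal seed: calling it twice returns identical objects.
#'
#' @return list: table, metadata, taxonomy, truth, design.
#' @export
fixture_small <- function() {
  design <- synthetic_design(n_samples = 12L, n_core = 10L,
                             n_satellite = 30L, n_modules = 2L,
                             module_size_range = c(4L, 4L),
                             pah_sensitive_module = 2L,
                             depth = 800L)
  out <- simulate_community(design, seed = 42L)
  out$design <- design
  out
}
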