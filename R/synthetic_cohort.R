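# Synthetic multi-site cohort generator.
#
# Emulates the kind of multi-center MS connectivity dataset the pipeline is
# meant for: 13 acquisition sites with realistically unequal sizes, sparse
# log-normal structural streamline weights, functional correlations derived
# from latent-factor time series with community structure, additive site
# effects on connectivity, and a cognition z-score generated as a linear
# function of age, gender and the *pipeline's own* multiplex frontoparietal
# centrality plus Gaussian noise. Because the planted outcome uses the
# downstream graph + metric stack, recovering the planted coefficient is a
# closed-loop correctness test of the whole pipeline.

# Site labels and relative sizes of a typical 13-center European MS cohort.
DEFAULT_SITES <- c("Amsterdam", "Barcelona", "Basel", "Graz", "London",
                   "Mainz", "Milan", "Naples", "Oslo", "Oxford", "Siena",
                   "Vanvitelli", "Verona")
DEFAULT_SITE_WEIGHTS <- c(238, 51, 8, 127, 18, 40, 29, 30, 56, 16, 73,
                          51, 43)

# deterministic per-subject / per-stream substream seed (< 2^31)
substream_seed <- function(seed, stream, index = 0L) {
  as.integer((as.numeric(seed) * 69069 + stream * 104729 +
                as.numeric(index) * 7919) %% 2147483629)
}

#' Configuration for a synthetic cohort
#'
#' Defaults describe the emulated study population: 114 regions, 13 sites
#' with unequal sizes, and planted standardized effects of the magnitude
#' reported for large MS cohorts (age -0.18 per SD, males about a third of
#' the cohort scoring 0.33 lower, multiplex frontoparietal centrality
#' -0.117 per SD) on a cognition z-score with unit residual SD.
#'
#' @param n_subjects Number of subjects.
#' @param n_regions Number of brain regions (>= 4; default 114).
#' @param n_sites Number of acquisition sites (default 13).
#' @param site_effect_sd SD of the per-site additive connectivity offset.
#' @param structural_density Fraction of nonzero off-diagonal structural
#'   weights, in (0, 1]; must be at least `2 / n_regions` so a connected
#'   graph is achievable.
#' @param ts_length Functional time-series length (>= 2 recommended
#'   `>= 2 * n_regions`; a warning is raised otherwise).
#' @param age_range Numeric length-2, years (uniform draw).
#' @param p_male Probability of gender code 1 (male).
#' @param effect_coeffs List with `intercept`, `beta_age` (per SD of age),
#'   `beta_sex` (raw 0/1 contrast), `beta_mplex_ecfpn` (per SD of multiplex
#'   ECfpn).
#' @param noise_sd Residual SD of the cognition score.
#' @param factor_loading Loading of each region on its community factor in
#'   the functional time-series model, in [0, 1).
#' @param seed Integer master seed; identical config + seed gives a
#'   bit-identical cohort.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_subjects,
                          n_regions = 114L,
                          n_sites = 13L,
                          site_effect_sd = 0.1,
                          structural_density = 0.3,
                          ts_length = 240L,
                          age_range = c(20, 60),
                          p_male = 0.31,
                          effect_coeffs = list(intercept = -0.7,
                                               beta_age = -0.18,
                                               beta_sex = -0.33,
                                               beta_mplex_ecfpn = -0.117),
                          noise_sd = 1,
                          factor_loading = 0.6,
                          seed = 1L) {
  stopifnot(n_subjects >= 1, n_regions >= 4, n_sites >= 1,
            site_effect_sd >= 0, ts_length >= 2,
            length(age_range) == 2, age_range[1] < age_range[2],
            p_male >= 0, p_male <= 1, noise_sd >= 0,
            factor_loading >= 0, factor_loading < 1)
  if (structural_density <= 0 || structural_density > 1) {
    stop("structural_density must be in (0, 1]", call. = FALSE)
  }
  if (structural_density < 2 / n_regions) {
    stop(sprintf(paste0("structural_density %.4f below the connectivity ",
                        "bound 2/n_regions = %.4f"),
                 structural_density, 2 / n_regions), call. = FALSE)
  }
  need <- c("intercept", "beta_age", "beta_sex", "beta_mplex_ecfpn")
  miss <- setdiff(need, names(effect_coeffs))
  if (length(miss) > 0) {
    stop("effect_coeffs missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (ts_length < 2 * n_regions) {
    warning(sprintf("ts_length %d < 2 * n_regions = %d; correlations noisy",
                    ts_length, 2L * n_regions))
  }
  sites <- if (n_sites <= length(DEFAULT_SITES)) {
    DEFAULT_SITES[seq_len(n_sites)]
  } else {
    c(DEFAULT_SITES, paste0("Site", seq_len(n_sites - length(DEFAULT_SITES))))
  }
  site_w <- if (n_sites <= length(DEFAULT_SITE_WEIGHTS)) {
    DEFAULT_SITE_WEIGHTS[seq_len(n_sites)]
  } else {
    c(DEFAULT_SITE_WEIGHTS,
      rep(mean(DEFAULT_SITE_WEIGHTS), n_sites - length(DEFAULT_SITE_WEIGHTS)))
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_regions = as.integer(n_regions),
         n_sites = as.integer(n_sites),
         sites = sites, site_weights = site_w / sum(site_w),
         site_effect_sd = site_effect_sd,
         structural_density = structural_density,
         ts_length = as.integer(ts_length),
         age_range = as.numeric(age_range), p_male = p_male,
         effect_coeffs = effect_coeffs, noise_sd = noise_sd,
         factor_loading = factor_loading, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Generate one subject's raw structural connectivity matrix
#'
#' Sparse symmetric matrix with log-normal positive weights emulating
#' streamline-weight sums: a fraction `structural_density` of off-diagonal
#' pairs gets a `lognormal(0, 1)` weight. If the resulting graph is
#' disconnected it is resampled up to 20 times, then augmented with a
#' random spanning tree's edges so the positive-weight graph is always
#' connected.
#'
#' @param config A [cohort_config].
#' @param subject_index 1-based subject index (selects the RNG substream).
#' @return A raw structural [connectivity_matrix].
#' @export
generate_structural_matrix <- function(config, subject_index) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(substream_seed(config$seed, 1L, subject_index))
  n <- config$n_regions
  m <- n * (n - 1L) / 2
  n_edges <- max(1L, round(config$structural_density * m))
  ut <- which(upper.tri(matrix(0, n, n)))
  W <- NULL
  for (try in seq_len(20L)) {
    W <- matrix(0, n, n)
    picked <- if (n_edges >= m) ut else sample(ut, n_edges)
    W[picked] <- stats::rlnorm(length(picked), meanlog = 0, sdlog = 1)
    W <- W + t(W)
    if (is_connected_adjacency(W > 0)) break
    W <- NULL
  }
  if (is.null(W)) {
    # augment the last resample with a random spanning tree (random
    # Hamiltonian path over a permuted node order)
    W <- matrix(0, n, n)
    picked <- if (n_edges >= m) ut else sample(ut, n_edges)
    W[picked] <- stats::rlnorm(length(picked), meanlog = 0, sdlog = 1)
    W <- W + t(W)
    perm <- sample.int(n)
    for (i in seq_len(n - 1L)) {
      a <- perm[i]; b <- perm[i + 1L]
      if (W[a, b] == 0) {
        w <- stats::rlnorm(1, meanlog = 0, sdlog = 1)
        W[a, b] <- w; W[b, a] <- w
      }
    }
  }
  connectivity_matrix(W, sprintf("sub-%04d", subject_index), "structural")
}

#' Generate one subject's regional time-series panel
#'
#' Latent community-factor model: each region loads (with
#' `factor_loading`) on the factor of its community — the parcellation's
#' canonical network when a parcellation is given, otherwise eight
#' contiguous blocks — plus independent Gaussian noise, so that the derived
#' correlation matrix has realistic block structure.
#'
#' @param config A [cohort_config].
#' @param subject_index 1-based subject index.
#' @param parcellation Optional [parcellation] providing the communities.
#' @return Numeric `n_regions x ts_length` matrix.
#' @export
generate_functional_timeseries <- function(config, subject_index,
                                           parcellation = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(substream_seed(config$seed, 2L, subject_index))
  n <- config$n_regions
  t_len <- config$ts_length
  communities <- if (!is.null(parcellation)) {
    stopifnot(n_regions(parcellation) == n)
    as.integer(factor(parcellation$network))
  } else {
    as.integer(cut(seq_len(n), breaks = 8, labels = FALSE))
  }
  k <- max(communities)
  factors <- matrix(stats::rnorm(k * t_len), nrow = k)
  lam <- config$factor_loading
  panel <- lam * factors[communities, , drop = FALSE] +
    sqrt(1 - lam^2) * matrix(stats::rnorm(n * t_len), nrow = n)
  panel
}

# internal: multiplex + single-layer ECfpn for one subject's matrix pair
subject_ecfpn <- function(struct_raw, func_r, parc) {
  st <- preprocess_structural(struct_raw)
  fn <- preprocess_functional(func_r)
  mst_s <- maximum_spanning_tree(st)
  mst_f <- maximum_spanning_tree(fn)
  mplex <- build_multiplex(list(mst_s, mst_f))
  ec_s <- eigenvector_centrality(mst_s$adjacency)
  ec_f <- eigenvector_centrality(mst_f$adjacency)
  ec_m <- multilayer_nodal_ec(mplex)
  c(ec_fpn_structural = as.numeric(subnetwork_mean(ec_s, parc,
                                                   "frontoparietal")),
    ec_fpn_functional = as.numeric(subnetwork_mean(ec_f, parc,
                                                   "frontoparietal")),
    ec_fpn_multiplex = as.numeric(subnetwork_mean(ec_m, parc,
                                                  "frontoparietal")))
}

#' Generate a full synthetic cohort
#'
#' Draws covariates and site assignments, generates each subject's
#' structural matrix and functional time series, applies per-site additive
#' offsets to the connectivity weights (structural: added to nonzero
#' weights; functional: added to off-diagonal correlations before
#' clipping), runs the real spanning-tree + multiplex centrality pipeline
#' on each subject, and plants the cognition score
#' \deqn{sdmt_z = b_0 + b_{age} z(age) + b_{sex} gender +
#'   b_{mplex} z(ECfpn_{mplex}) + N(0, noise\_sd).}
#'
#' @param config A [cohort_config].
#' @param parc A [parcellation] with `n_regions(parc) == config$n_regions`
#'   containing at least one frontoparietal region.
#' @return A `synthetic_cohort`: list with `manifest` ([cohort_manifest]),
#'   `structural` / `functional` (lists of raw [connectivity_matrix]; the
#'   functional entries hold site-shifted Pearson correlations), `metrics`
#'   (data.frame of the generator's own per-subject ECfpn values, for
#'   closed-loop checks) and `config`.
#' @export
generate_cohort <- function(config, parc) {
  stopifnot(inherits(config, "cohort_config"), inherits(parc, "parcellation"))
  if (n_regions(parc) != config$n_regions) {
    stop(sprintf("parcellation has %d regions, config expects %d",
                 n_regions(parc), config$n_regions), call. = FALSE)
  }
  if (length(network_members(parc, "frontoparietal")) == 0) {
    stop("parcellation has no frontoparietal regions", call. = FALSE)
  }
  ns <- config$n_subjects

  # cohort-level draws (covariates, site assignment, site offsets)
  set.seed(substream_seed(config$seed, 3L))
  age <- stats::runif(ns, config$age_range[1], config$age_range[2])
  gender <- stats::rbinom(ns, 1L, config$p_male)
  site_idx <- sample.int(config$n_sites, ns, replace = TRUE,
                         prob = config$site_weights)
  # guarantee every site appears when the cohort is large enough
  if (ns >= config$n_sites) {
    missing_sites <- setdiff(seq_len(config$n_sites), unique(site_idx))
    if (length(missing_sites) > 0) {
      site_idx[sample.int(ns, length(missing_sites))] <- missing_sites
    }
  }
  off_struct <- stats::rnorm(config$n_sites, 0, config$site_effect_sd)
  off_func <- stats::rnorm(config$n_sites, 0, config$site_effect_sd)
  mean_fd <- stats::rlnorm(ns, meanlog = log(0.12), sdlog = 0.4)
  edss <- pmin(7.5, round(stats::rgamma(ns, shape = 2, scale = 1.25) * 2) / 2)

  structural <- vector("list", ns)
  functional <- vector("list", ns)
  met <- matrix(NA_real_, ns, 3,
                dimnames = list(NULL, c("ec_fpn_structural",
                                        "ec_fpn_functional",
                                        "ec_fpn_multiplex")))
  ids <- sprintf("sub-%04d", seq_len(ns))
  for (i in seq_len(ns)) {
    sm <- generate_structural_matrix(config, i)
    W <- sm$weights
    pos <- W > 0
    W[pos] <- pmax(W[pos] + off_struct[site_idx[i]], 1e-6)
    sm <- connectivity_matrix(W, ids[i], "structural")

    panel <- generate_functional_timeseries(config, i, parc)
    r <- stats::cor(t(panel))
    r <- r + off_func[site_idx[i]]
    r <- pmin(pmax(r, -0.999), 0.999)
    diag(r) <- 0
    fm <- connectivity_matrix(r, ids[i], "functional")

    res <- tryCatch(subject_ecfpn(sm, fm, parc), error = function(e) {
      stop(sprintf("subject %s: %s", ids[i], conditionMessage(e)),
           call. = FALSE)
    })
    structural[[i]] <- sm
    functional[[i]] <- fm
    met[i, ] <- res
  }

  zscore <- function(x) (x - mean(x)) / stats::sd(x)
  b <- config$effect_coeffs
  set.seed(substream_seed(config$seed, 4L))
  noise <- stats::rnorm(ns, 0, config$noise_sd)
  z_ec <- if (ns > 1 && stats::sd(met[, "ec_fpn_multiplex"]) > 0) {
    zscore(met[, "ec_fpn_multiplex"])
  } else {
    rep(0, ns)
  }
  z_age <- if (ns > 1) zscore(age) else rep(0, ns)
  sdmt_z <- b$intercept + b$beta_age * z_age + b$beta_sex * gender +
    b$beta_mplex_ecfpn * z_ec + noise

  manifest <- cohort_manifest(data.frame(
    subject_id = ids, site = config$sites[site_idx], age = age,
    gender = gender, sdmt_z = sdmt_z, edss = edss, mean_fd = mean_fd,
    stringsAsFactors = FALSE
  ))
  structure(
    list(manifest = manifest, structural = structural,
         functional = functional,
         metrics = data.frame(subject_id = ids, met),
         config = config),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %d regions, %d sites\n",
              x$config$n_subjects, x$config$n_regions,
              length(attr(x$manifest, "site_set"))))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Layout: `manifest.tsv`, `config.json` (full config + seed sidecar), and
#' one TSV per subject per modality under `matrices/`
#' (`<id>_structural.tsv`, `<id>_functional.tsv`; the functional file holds
#' raw site-shifted correlations).
#'
#' @param cohort A [generate_cohort] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(file.path(dir, "matrices"), recursive = TRUE,
             showWarnings = FALSE)
  write_manifest(cohort$manifest, file.path(dir, "manifest.tsv"))
  cfg <- cohort$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (i in seq_along(cohort$structural)) {
    id <- cohort$manifest$subject_id[i]
    write_matrix(cohort$structural[[i]],
                 file.path(dir, "matrices", paste0(id, "_structural.tsv")))
    write_matrix(cohort$functional[[i]],
                 file.path(dir, "matrices", paste0(id, "_functional.tsv")))
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort]
#'
#' @param dir Cohort directory.
#' @return List with `manifest`, `structural`, `functional` (raw
#'   [connectivity_matrix] lists in manifest order).
#' @export
read_cohort <- function(dir) {
  manifest <- read_manifest(file.path(dir, "manifest.tsv"))
  ids <- manifest$subject_id
  structural <- lapply(ids, function(id) {
    read_matrix(file.path(dir, "matrices", paste0(id, "_structural.tsv")),
                id, "structural")
  })
  functional <- lapply(ids, function(id) {
    read_matrix(file.path(dir, "matrices", paste0(id, "_functional.tsv")),
                id, "functional")
  })
  list(manifest = manifest, structural = structural,
       functional = functional)
}
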