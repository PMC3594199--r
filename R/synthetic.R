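#' Specification for synthetic grey-matter data
#'
#' Describes a synthetic "cortex" with known ground truth so every stage of
#' the network pipeline can be exercised without MRI data. The model has
#' three layers:
#'
#' * **Template anatomy** (fixed by `template_seed`, shared by all subjects
#'   of a cohort, like the shared anatomy of real brains): a curved
#'   sheet-like mask inside a small volume, a set of `n_latent` latent
#'   morphological components, each with a smooth spatial *loading map* over
#'   the cube grid and a fixed 27-voxel *pattern*. Cubes with similar
#'   loadings have correlated contents, so the loading maps induce the
#'   inter-cube similarity structure: spatially smooth loadings give local
#'   (lattice-like) connectivity with high clustering, which is what makes
#'   control graphs small-world.
#' * **Subject variation** (per-subject seed): a smooth subject-specific
#'   perturbation of the loading maps (`subject_loading_sd`), a smooth
#'   random voxel field (`field_sd`, `smoothing_scale`), and i.i.d. voxel
#'   noise (`noise_sd`).
#' * **Disease effect** (patient group only): for a fraction
#'   `disease_fraction` of cubes the loading vector is *polarized* — raised
#'   elementwise to `disease_power` (sign kept, energy renormalized) — so
#'   their similarity concentrates onto their dominant latent mode. This
#'   moves topology toward random: connectivity centralizes on hub
#'   communities, lowering the normalized clustering coefficient gamma and
#'   the normalized path length lambda at comparable density, while leaving
#'   total grey matter essentially unchanged (patterns are zero-mean). A
#'   literal within-cube value shuffle (`shuffle_fraction`) and a global
#'   intensity scaling (`atrophy_scale`) are also available; both default
#'   off. The shuffle destroys the affected cubes' similarity (producing
#'   focal disconnection rather than randomization) and the atrophy scale
#'   exercises volumetric covariate adjustment.
#'
#' A cognitive score is linked linearly to each subject's realized
#' normalized path length: `score = intercept + slope * lambda + noise`.
#'
#' @param shape volume dimensions in voxels (default `c(30, 30, 18)`,
#'   a desk-scale volume whose full pipeline runs in seconds).
#' @param voxel_size_mm voxel edge lengths in mm.
#' @param sheet_thickness thickness of the cortical sheet in voxels.
#' @param surface_amplitude SD (voxels) of the smooth random undulation of
#'   the sheet's mid-surface.
#' @param base_gm baseline grey-matter value inside the sheet.
#' @param smoothing_scale Gaussian sigma (voxels) of the smooth voxel field.
#' @param field_sd SD of the smooth voxel field.
#' @param n_latent number of latent components.
#' @param latent_smoothing Gaussian sigma (cube-grid units) of the loading
#'   maps.
#' @param latent_amplitude SD of the total latent contribution per voxel.
#' @param subject_loading_sd SD of the subject-specific loading
#'   perturbation, relative to the template loading SD of 1.
#' @param noise_sd SD of i.i.d. voxel noise.
#' @param template_seed seed fixing the template anatomy.
#' @param disease_fraction fraction of cubes affected in the patient group
#'   (topology randomization strength, in `[0, 1]`).
#' @param disease_power polarization exponent applied to affected cubes'
#'   loadings.
#' @param shuffle_fraction fraction of cubes whose 27 voxel values are
#'   permuted in place in the patient group (default 0).
#' @param atrophy_scale global intensity scale for patient volumes (1 =
#'   no atrophy).
#' @param n_regions number of synthetic atlas regions (spatial blocks).
#' @param age_mean named length-2 vector of group age means (years).
#' @param age_sd age SD (years).
#' @param score_intercept,score_slope,score_sd cognitive score model.
#' @return An object of class `gm_synth_spec`.
#' @export
synthetic_spec <- function(shape = c(30L, 30L, 18L),
                           voxel_size_mm = c(1, 1, 1),
                           sheet_thickness = 9,
                           surface_amplitude = 1.5,
                           base_gm = 0.6,
                           smoothing_scale = 1.5,
                           field_sd = 0.15,
                           n_latent = 4L,
                           latent_smoothing = 1.5,
                           latent_amplitude = 0.3,
                           subject_loading_sd = 0.3,
                           noise_sd = 0.04,
                           template_seed = 42L,
                           disease_fraction = 0.3,
                           disease_power = 4,
                           shuffle_fraction = 0,
                           atrophy_scale = 1,
                           n_regions = 8L,
                           age_mean = c(control = 71.91, patient = 72.06),
                           age_sd = 4.32,
                           score_intercept = -48.3,
                           score_slope = 60,
                           score_sd = 2.2) {
  spec <- list(shape = as.integer(shape), voxel_size_mm = voxel_size_mm,
               sheet_thickness = sheet_thickness,
               surface_amplitude = surface_amplitude, base_gm = base_gm,
               smoothing_scale = smoothing_scale, field_sd = field_sd,
               n_latent = as.integer(n_latent),
               latent_smoothing = latent_smoothing,
               latent_amplitude = latent_amplitude,
               subject_loading_sd = subject_loading_sd,
               noise_sd = noise_sd,
               template_seed = as.integer(template_seed),
               disease_fraction = disease_fraction,
               disease_power = disease_power,
               shuffle_fraction = shuffle_fraction,
               atrophy_scale = atrophy_scale,
               n_regions = as.integer(n_regions),
               age_mean = age_mean, age_sd = age_sd,
               score_intercept = score_intercept,
               score_slope = score_slope, score_sd = score_sd)
  stopifnot(length(spec$shape) == 3L, all(spec$shape >= 3L),
            spec$disease_fraction >= 0, spec$disease_fraction <= 1,
            spec$shuffle_fraction >= 0, spec$shuffle_fraction <= 1,
            spec$noise_sd >= 0)
  structure(spec, class = "gm_synth_spec")
}

# separable Gaussian smoothing of a 3D array, with kernel renormalization
# at the edges
gaussian_smooth <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  rad <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-rad:rad, sd = sigma)
  k <- k / sum(k)
  smooth_axis <- function(a, axis) {
    d <- dim(a)
    perm <- c(axis, setdiff(seq_along(d), axis))
    m <- aperm(a, perm)
    dm <- dim(m)
    m <- matrix(m, nrow = dm[1])
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    wt <- numeric(n)
    for (i in seq_along(k)) {
      off <- i - rad - 1L
      src <- seq_len(n) + off
      valid <- src >= 1L & src <= n
      out[valid, ] <- out[valid, ] + k[i] * m[src[valid], , drop = FALSE]
      wt[valid] <- wt[valid] + k[i]
    }
    out <- out / wt
    dim(out) <- dm
    aperm(out, order(perm))
  }
  res <- arr
  for (ax in seq_along(dim(res))) {
    if (dim(res)[ax] > 1L) res <- smooth_axis(res, ax)
  }
  res
}

# smooth standard-normal random field of the given dimensions
smooth_field <- function(dims, sigma) {
  f <- gaussian_smooth(array(stats::rnorm(prod(dims)), dim = dims), sigma)
  (f - mean(f)) / stats::sd(f)
}

# template anatomy shared by all subjects generated from the same spec:
# mid-surface, latent loading maps over the cube grid, voxel patterns
synth_template <- function(spec) {
  d <- spec$shape
  gd <- d %/% 3L
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(spec$template_seed)
  surf <- d[3] / 2 +
    spec$surface_amplitude * smooth_field(c(d[1], d[2], 1L), 2)
  W <- vapply(seq_len(spec$n_latent),
              function(k) as.vector(smooth_field(gd, spec$latent_smoothing)),
              numeric(prod(gd)))
  P <- vapply(seq_len(spec$n_latent), function(k) {
    p <- stats::rnorm(27)
    (p - mean(p)) / stats::sd(p)
  }, numeric(27))
  list(surface = surf, loadings = W, patterns = P, grid_dims = gd)
}

#' Generate one synthetic grey-matter volume with labels
#'
#' Builds the volume described by [synthetic_spec()]: template anatomy plus
#' subject-specific variation, and — for `group = "patient"` — the disease
#' effect (loading polarization for a `disease_fraction` of cubes, optional
#' within-cube shuffling and global atrophy scaling). All subject-level
#' randomness derives from `seed`; the template depends only on the spec.
#'
#' @param spec a [synthetic_spec()].
#' @param group `"control"` or `"patient"`.
#' @param seed integer subject seed.
#' @return List with `volume` (a [gm_volume()]), `labels` (a [gm_labels()]),
#'   and `truth` (list: `group`, `affected_cubes` and `shuffled_cubes` —
#'   0-based corner coordinates, `n_cubes_grid`, `seed`).
#' @export
generate_volume <- function(spec, group = c("control", "patient"),
                            seed = 1L) {
  stopifnot(inherits(spec, "gm_synth_spec"))
  group <- match.arg(group)
  d <- spec$shape
  tpl <- synth_template(spec)
  gd <- tpl$grid_dims
  n_grid <- prod(gd)
  if (n_grid < 50L) {
    stop("volume shape supports only ", n_grid,
         " cubes; need at least 50 for a meaningful graph")
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))

  # sheet mask around the template mid-surface
  zc <- array(rep(seq_len(d[3]), each = d[1] * d[2]), dim = d)
  surf3 <- array(rep(as.vector(tpl$surface), times = d[3]), dim = d)
  mask <- abs(zc - surf3) <= spec$sheet_thickness / 2

  data <- spec$base_gm + spec$field_sd * smooth_field(d, spec$smoothing_scale)

  # subject loading maps: template + smooth subject perturbation
  ssd <- spec$subject_loading_sd
  W <- vapply(seq_len(spec$n_latent), function(k) {
    (tpl$loadings[, k] + ssd * as.vector(smooth_field(gd,
                                                      spec$latent_smoothing))) /
      sqrt(1 + ssd^2)
  }, numeric(n_grid))

  affected <- matrix(integer(0), 0, 3)
  shuffled <- matrix(integer(0), 0, 3)
  corners <- as.matrix(expand.grid(
    x = seq.int(0L, by = 3L, length.out = gd[1]),
    y = seq.int(0L, by = 3L, length.out = gd[2]),
    z = seq.int(0L, by = 3L, length.out = gd[3])))
  if (group == "patient" && spec$disease_fraction > 0) {
    aff <- sample.int(n_grid, floor(spec$disease_fraction * n_grid))
    Wp <- sign(W[aff, , drop = FALSE]) * abs(W[aff, , drop = FALSE])^
      spec$disease_power
    # renormalize so the affected cubes keep their total loading energy
    Wp <- sweep(Wp, 2, sqrt(colMeans(Wp^2)), "/")
    W[aff, ] <- Wp
    affected <- corners[aff, , drop = FALSE]
  }

  cube_lin <- as.matrix(expand.grid(dx = 0:2, dy = 0:2, dz = 0:2))
  lin0 <- (corners[, 1] + 1L) + corners[, 2] * d[1] + corners[, 3] * d[1] * d[2]
  off_lin <- cube_lin[, 1] + cube_lin[, 2] * d[1] + cube_lin[, 3] * d[1] * d[2]
  idx <- outer(lin0, off_lin, `+`)
  if (spec$n_latent > 0L) {
    data[idx] <- data[idx] +
      W %*% t(tpl$patterns) * spec$latent_amplitude / sqrt(spec$n_latent)
  }

  if (spec$noise_sd > 0) {
    data <- data + array(stats::rnorm(prod(d), sd = spec$noise_sd), dim = d)
  }
  data[!mask] <- 0
  data[mask & data < 0] <- 0

  if (group == "patient") {
    if (spec$shuffle_fraction > 0) {
      n_shuf <- floor(spec$shuffle_fraction * n_grid)
      which_cubes <- sample.int(n_grid, n_shuf)
      for (ci in which_cubes) {
        data[idx[ci, ]] <- data[idx[ci, sample.int(27L)]]
      }
      shuffled <- corners[which_cubes, , drop = FALSE]
    }
    if (spec$atrophy_scale != 1) data <- data * spec$atrophy_scale
  }

  # synthetic atlas: spatial blocks over the mask
  nb_per_axis <- ceiling(spec$n_regions^(1 / 3))
  blocks <- lapply(1:3, function(ax)
    cut(seq_len(d[ax]), min(nb_per_axis, d[ax]), labels = FALSE))
  coords <- arrayInd(seq_len(prod(d)), d)
  lab_idx <- (blocks[[1]][coords[, 1]] - 1L) +
    (blocks[[2]][coords[, 2]] - 1L) * max(blocks[[1]]) +
    (blocks[[3]][coords[, 3]] - 1L) * max(blocks[[1]]) * max(blocks[[2]])
  lab <- array(ifelse(as.vector(mask), lab_idx + 1L, 0L), dim = d)

  list(volume = gm_volume(data, voxel_size_mm = spec$voxel_size_mm),
       labels = gm_labels(lab),
       truth = list(group = group, affected_cubes = affected,
                    shuffled_cubes = shuffled, n_cubes_grid = n_grid,
                    seed = as.integer(seed)))
}

#' Generate a balanced synthetic cohort with known ground truth
#'
#' Generates `n_per_group` volumes per group with matched age and sex
#' margins. When the score model has a nonzero slope (or
#' `compute_networks = TRUE`), each subject's network is extracted and
#' normalized so the cognitive score can be linked to the realized lambda;
#' per-subject graph results are returned so callers need not recompute
#' them.
#'
#' @param spec a [synthetic_spec()].
#' @param n_per_group subjects per group (>= 3).
#' @param seed master seed; per-subject seeds are derived from it.
#' @param compute_networks force (with `TRUE`) or suppress (with `FALSE`,
#'   valid only when `score_slope = 0`) the per-subject network
#'   computation; default decides from the score model.
#' @param network list of analysis settings used when networks are
#'   computed: `target_spurious`, `n_null_pairs`, `n_reference`,
#'   `swaps_per_edge`, `min_mask_voxels`.
#' @return List with `subjects` (list of [generate_volume()] results),
#'   `cohort` (data.frame: id, group, age, sex, global_gm_volume,
#'   cognitive_score), `networks` (list of per-subject lists with `graph`,
#'   `report`, `smallworld`, or `NULL`s), and `truth` (score model
#'   parameters and per-subject realized lambda when computed).
#' @export
generate_cohort <- function(spec, n_per_group, seed = 1L,
                            compute_networks = NULL,
                            network = list()) {
  stopifnot(inherits(spec, "gm_synth_spec"))
  if (n_per_group < 3L) stop("need at least 3 subjects per group")
  net_defaults <- list(target_spurious = 0.05, n_null_pairs = 20000L,
                       n_reference = 20L, swaps_per_edge = 10L,
                       min_mask_voxels = 14L)
  network <- utils::modifyList(net_defaults, network)
  if (is.null(compute_networks)) compute_networks <- spec$score_slope != 0
  if (!compute_networks && spec$score_slope != 0) {
    stop("cognitive scores depend on realized lambda; cannot skip network ",
         "computation while score_slope != 0")
  }

  groups <- rep(c("control", "patient"), each = n_per_group)
  sexes <- rep(rep(c("F", "M"), length.out = n_per_group), 2)
  ids <- sprintf("%s%02d", ifelse(groups == "control", "C", "P"),
                 rep(seq_len(n_per_group), 2))

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  ages <- stats::rnorm(2 * n_per_group,
                       mean = spec$age_mean[ifelse(groups == "control",
                                                   "control", "patient")],
                       sd = spec$age_sd)
  subj_seeds <- sample.int(2^30, 2 * n_per_group)
  score_noise <- stats::rnorm(2 * n_per_group, sd = spec$score_sd)

  subjects <- vector("list", 2 * n_per_group)
  networks <- vector("list", 2 * n_per_group)
  gm_vol <- numeric(2 * n_per_group)
  lambda <- rep(NA_real_, 2 * n_per_group)
  for (i in seq_len(2 * n_per_group)) {
    subjects[[i]] <- generate_volume(spec, group = groups[i],
                                     seed = subj_seeds[i])
    v <- subjects[[i]]$volume
    gm_vol[i] <- sum(v$data[v$mask]) * prod(v$voxel_size_mm)
    if (compute_networks) {
      g <- extract_network(v, target_spurious = network$target_spurious,
                           n_null_pairs = network$n_null_pairs,
                           seed = subj_seeds[i] %% 2^20 + 1L,
                           min_mask_voxels = network$min_mask_voxels,
                           subject_id = ids[i])
      rep_ <- graph_report(g)
      sw <- suppressWarnings(
        small_world(g, n_reference = network$n_reference,
                    swaps_per_edge = network$swaps_per_edge,
                    seed = subj_seeds[i] %% 2^20 + 7L))
      networks[[i]] <- list(graph = g, report = rep_, smallworld = sw)
      lambda[i] <- sw$lambda
    }
  }
  score <- spec$score_intercept +
    spec$score_slope * ifelse(is.na(lambda), 0, lambda) + score_noise
  cohort <- data.frame(id = ids, group = groups, age = ages, sex = sexes,
                       global_gm_volume = gm_vol, cognitive_score = score,
                       stringsAsFactors = FALSE)
  list(subjects = subjects, cohort = validate_cohort(cohort),
       networks = networks,
       truth = list(score_intercept = spec$score_intercept,
                    score_slope = spec$score_slope, score_sd = spec$score_sd,
                    lambda = lambda, seed = as.integer(seed),
                    disease_fraction = spec$disease_fraction,
                    shuffle_fraction = spec$shuffle_fraction))
}
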