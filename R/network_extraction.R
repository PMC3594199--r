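#' Tile a grey-matter volume into 3x3x3 cube nodes
#'
#' Nodes of a single-subject grey-matter network are non-overlapping
#' 3x3x3 voxel cubes, aligned to a 3-voxel grid starting at `offset`
#' (0-based). Partial cubes at the far faces of the volume are discarded.
#' A cube is retained when at least `min_mask_voxels` of its 27 voxels fall
#' inside the volume's mask and its 27 values have nonzero variance
#' (a zero-variance cube has an undefined correlation with anything).
#'
#' @param vol a [gm_volume()].
#' @param min_mask_voxels minimum number of in-mask voxels for a cube to
#'   count as cortical (default 14, a strict majority of the 27 voxels;
#'   cubes dominated by background tend to behave as near-duplicates and
#'   destabilize threshold calibration on sharply masked volumes).
#' @param offset integer length-3, 0-based grid origin offset (each in 0..2).
#' @return An object of class `gm_cubes`: a list with `values` (n x 27 matrix,
#'   one row per cube, x-fastest voxel order), `corners` (n x 3 integer matrix
#'   of 0-based minimum-corner voxel indices), `n_nodes`, `voxel_size_mm`, and
#'   `dropped` (counts of cubes discarded by the mask and variance rules).
#' @export
extract_cubes <- function(vol, min_mask_voxels = 14L, offset = c(0L, 0L, 0L)) {
  stopifnot(inherits(vol, "gm_volume"))
  d <- dim(vol$data)
  if (any(d < 3L)) stop("volume must be at least 3 voxels along every axis")
  offset <- as.integer(offset)
  if (length(offset) != 3L || any(offset < 0L) || any(offset > 2L)) {
    stop("`offset` must be three integers in 0..2")
  }
  if (!any(vol$mask)) stop("empty mask: no grey-matter voxels, no nodes")

  starts <- lapply(1:3, function(ax) {
    s <- seq.int(offset[ax] + 1L, d[ax], by = 3L)   # 1-based starts
    s[s + 2L <= d[ax]]                              # drop partial cubes
  })
  grid <- as.matrix(expand.grid(x = starts[[1]], y = starts[[2]],
                                z = starts[[3]]))
  if (nrow(grid) == 0L) stop("volume too small for any complete cube")

  # gather the 27 voxel values of every cube via linear indexing
  cube_lin <- as.matrix(expand.grid(dx = 0:2, dy = 0:2, dz = 0:2))
  lin0 <- grid[, 1] + (grid[, 2] - 1L) * d[1] + (grid[, 3] - 1L) * d[1] * d[2]
  off_lin <- cube_lin[, 1] + cube_lin[, 2] * d[1] + cube_lin[, 3] * d[1] * d[2]
  idx <- outer(lin0, off_lin, `+`)                  # n x 27 linear indices
  vals <- matrix(vol$data[idx], nrow = nrow(grid))
  in_mask <- matrix(vol$mask[idx], nrow = nrow(grid))

  mask_ok <- rowSums(in_mask) >= min_mask_voxels
  v <- rowSums((vals - rowMeans(vals))^2)
  var_ok <- v > 0
  keep <- mask_ok & var_ok
  if (!any(keep)) stop("no nodes: every candidate cube was dropped")

  structure(
    list(values = vals[keep, , drop = FALSE],
         corners = grid[keep, , drop = FALSE] - 1L,   # 0-based corners
         n_nodes = sum(keep),
         voxel_size_mm = vol$voxel_size_mm,
         dropped = c(mask = sum(!mask_ok),
                     zero_variance = sum(mask_ok & !var_ok))),
    class = "gm_cubes"
  )
}

#' @export
print.gm_cubes <- function(x, ...) {
  cat("<gm_cubes> ", x$n_nodes, " cube nodes (dropped: ",
      x$dropped[["mask"]], " off-mask, ", x$dropped[["zero_variance"]],
      " zero-variance)\n", sep = "")
  invisible(x)
}

#' Pearson correlation between two cube value vectors
#'
#' The similarity between two cube nodes is the product-moment correlation of
#' their 27 grey-matter values: the mean-centred cross-product divided by the
#' product of the cubes' standard deviations.
#'
#' @param v_j,v_m numeric vectors of equal length with nonzero variance.
#' @return Correlation in `[-1, 1]`.
#' @export
cube_correlation <- function(v_j, v_m) {
  if (length(v_j) != length(v_m)) stop("cube vectors must have equal length")
  if (stats::var(v_j) == 0 || stats::var(v_m) == 0) {
    stop("correlation undefined for a zero-variance cube; ",
         "such cubes must be excluded upstream")
  }
  stats::cor(v_j, v_m)
}

# rows of `m` standardized to mean 0, sd 1 (n-1 denominator), so that the
# Pearson correlation of rows j and m is crossprod(z_j, z_m) / (ncol - 1)
standardize_rows <- function(m) {
  c_ <- m - rowMeans(m)
  s <- sqrt(rowSums(c_^2) / (ncol(m) - 1))
  if (any(s == 0)) stop("zero-variance row in cube matrix")
  c_ / s
}

#' Rotation-maximized correlation between two cubes
#'
#' Maximum of `cube_correlation(v_j[p], v_m)` over every permutation `p` in
#' `rotations`. Because the rotation set is closed under inversion, the result
#' is symmetric in its arguments.
#'
#' @param v_j,v_m numeric length-27 vectors with nonzero variance.
#' @param rotations permutation list from [rotation_set()].
#' @return The maximum correlation over the rotation set.
#' @export
max_rotation_correlation <- function(v_j, v_m, rotations = rotation_set()) {
  z_j <- standardize_rows(matrix(v_j, nrow = 1))[1, ]
  z_m <- standardize_rows(matrix(v_m, nrow = 1))[1, ]
  n1 <- length(v_j) - 1
  best <- -Inf
  for (p in rotations) {
    r <- sum(z_j[p] * z_m) / n1
    if (r > best) best <- r
  }
  best
}

#' Rotation-maximized similarity matrix over all cube pairs
#'
#' Computes the full symmetric matrix of rotation-maximized correlations
#' between every pair of cube nodes. For each rotation the correlations of
#' all pairs are obtained in one standardized cross-product, and the maximum
#' is accumulated across rotations; symmetry is guaranteed by closure of the
#' rotation set under inversion.
#'
#' @param cubes a [extract_cubes()] result (or a plain n x 27 matrix).
#' @param rotations permutation list from [rotation_set()].
#' @return An n x n symmetric numeric matrix; the diagonal is set to `NA`
#'   (self-similarity is not a graph quantity).
#' @export
similarity_matrix <- function(cubes, rotations = rotation_set()) {
  vals <- if (inherits(cubes, "gm_cubes")) cubes$values else as.matrix(cubes)
  n <- nrow(vals)
  if (n < 2L) stop("need at least 2 cubes to build a similarity matrix")
  z <- standardize_rows(vals)
  n1 <- ncol(vals) - 1
  s <- matrix(-Inf, n, n)
  for (p in rotations) {
    s <- pmax(s, tcrossprod(z[, p, drop = FALSE], z) / n1)
  }
  # the max over the closed rotation set is symmetric; enforce it exactly
  # against floating-point summation-order noise
  s <- pmax(s, t(s))
  diag(s) <- NA_real_
  s
}

#' Permutation-calibrated similarity threshold
#'
#' Calibrates a per-subject binarization threshold so that the expected
#' proportion of retained edges attributable to chance equals
#' `target_spurious` (default 5%). A null distribution is built by sampling
#' cube pairs, independently permuting the 27 within-cube values of each
#' member (destroying spatial structure while preserving the marginal value
#' distribution), and applying the same rotation-maximized correlation. The
#' chosen threshold `t` is the smallest candidate for which
#'
#'   `E[# null similarities > t] / # real similarities > t <= target_spurious`
#'
#' where the expectation is the null exceedance fraction scaled to the number
#' of real pairs (an empirical false-discovery proportion on edges).
#'
#' @param cubes a [extract_cubes()] result.
#' @param rotations permutation list from [rotation_set()].
#' @param S optional precomputed [similarity_matrix()] (recomputed if `NULL`).
#' @param target_spurious target proportion of chance edges, in (0, 1).
#' @param n_null_pairs number of null pairs to sample; pairs are drawn with
#'   replacement and each member receives a fresh within-cube permutation,
#'   so the null sample may exceed the number of distinct pairs.
#' @param seed integer seed for the null sampling.
#' @return A list with `threshold`, `achieved_spurious`, `status` (`"ok"` or
#'   `"no_signal"` when no candidate meets the target and the maximum real
#'   similarity is returned, yielding an empty graph), `n_real_pairs`,
#'   `n_null_pairs`.
#' @export
permutation_threshold <- function(cubes, rotations = rotation_set(),
                                  S = NULL, target_spurious = 0.05,
                                  n_null_pairs = 100000L, seed = 1L) {
  stopifnot(target_spurious > 0, target_spurious < 1)
  vals <- if (inherits(cubes, "gm_cubes")) cubes$values else as.matrix(cubes)
  n <- nrow(vals)
  if (n < 2L) stop("need at least 2 cubes")
  if (is.null(S)) S <- similarity_matrix(cubes, rotations)
  real <- S[upper.tri(S)]
  null <- null_similarities(vals, rotations, n_null_pairs, seed)

  scan <- scan_spurious(real, null, target_spurious)
  if (is.na(scan$threshold)) {
    warning("no threshold meets the target spurious proportion; ",
            "returning the maximum real similarity (empty graph)")
    return(list(threshold = max(real), achieved_spurious = NA_real_,
                status = "no_signal", n_real_pairs = length(real),
                n_null_pairs = length(null)))
  }
  list(threshold = scan$threshold, achieved_spurious = scan$achieved,
       status = "ok", n_real_pairs = length(real), n_null_pairs = length(null))
}

# max-rotation correlations of value-permuted sampled cube pairs
null_similarities <- function(vals, rotations, n_null_pairs, seed) {
  n <- nrow(vals)
  k <- ncol(vals)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  j <- sample.int(n, n_null_pairs, replace = TRUE)
  m <- sample.int(n - 1L, n_null_pairs, replace = TRUE)
  m <- ifelse(m >= j, m + 1L, m)                     # distinct partner
  shuffle_rows <- function(x) {
    nr <- nrow(x)
    nc <- ncol(x)
    # one global order() keyed by (row, random) gives an independent random
    # permutation of every row without a per-row loop
    o <- order(rep(seq_len(nr), each = nc), stats::runif(nr * nc))
    cols <- (o - 1L) %% nc + 1L
    matrix(x[cbind(rep(seq_len(nr), each = nc), cols)], nr, nc,
           byrow = TRUE)
  }
  a <- standardize_rows(shuffle_rows(vals[j, , drop = FALSE]))
  b <- standardize_rows(shuffle_rows(vals[m, , drop = FALSE]))
  best <- rep(-Inf, n_null_pairs)
  for (p in rotations) {
    best <- pmax(best, rowSums(a[, p, drop = FALSE] * b) / (k - 1))
  }
  best
}

# Smallest threshold whose empirical edge FDR <= target. Candidate
# thresholds sit just below each distinct real similarity value, so the
# strict `S > t` edge rule keeps every pair tied at that value; the edge
# set can only change at real values, so no other candidates matter.
scan_spurious <- function(real, null, target, tie_eps = 1e-9) {
  cand <- sort(unique(real))
  sr <- sort(real)
  sn <- sort(null)
  n_real <- length(real)
  n_null <- length(null)
  # counts >= each candidate value (== strictly above candidate - eps)
  at_or_above_real <- n_real - findInterval(cand, sr, left.open = TRUE)
  at_or_above_null <- n_null - findInterval(cand, sn, left.open = TRUE)
  expected_null <- at_or_above_null / n_null * n_real
  fdr <- ifelse(at_or_above_real > 0, expected_null / at_or_above_real, Inf)
  ok <- which(fdr <= target & at_or_above_real > 0)
  if (!length(ok)) return(list(threshold = NA_real_, achieved = NA_real_))
  i <- ok[1]
  list(threshold = cand[i] - tie_eps, achieved = fdr[i])
}

#' Evaluate the spurious-edge proportion at a given threshold
#'
#' Estimates, from a fresh (independent) null realization, what proportion
#' of the edges retained at `threshold` is expected by chance: the null
#' exceedance fraction scaled to the number of real pairs, divided by the
#' number of retained edges. Used to validate the calibration of
#' [permutation_threshold()] out of sample.
#'
#' @inheritParams permutation_threshold
#' @param threshold the binarization threshold to evaluate.
#' @return List with `spurious` (the estimated chance proportion),
#'   `n_edges`, `expected_null_edges`, `n_null_pairs`.
#' @export
evaluate_spurious <- function(cubes, S, threshold,
                              rotations = rotation_set(),
                              n_null_pairs = 100000L, seed = 1L) {
  vals <- if (inherits(cubes, "gm_cubes")) cubes$values else as.matrix(cubes)
  real <- S[upper.tri(S)]
  null <- null_similarities(vals, rotations, n_null_pairs, seed)
  n_edges <- sum(real > max(threshold, 0))
  expected <- mean(null > max(threshold, 0)) * length(real)
  list(spurious = if (n_edges > 0) expected / n_edges else NA_real_,
       n_edges = n_edges, expected_null_edges = expected,
       n_null_pairs = n_null_pairs)
}

#' Binarize a similarity matrix into an unweighted, undirected graph
#'
#' An edge connects cubes `j` and `m` when their similarity exceeds the
#' threshold *and* is positive: only positive similarity values survive, so
#' a negative threshold behaves exactly like a threshold of zero.
#'
#' @param S symmetric similarity matrix from [similarity_matrix()].
#' @param threshold finite scalar.
#' @param cubes optional [extract_cubes()] result supplying node provenance.
#' @param subject_id optional subject identifier stored with the graph.
#' @param achieved_spurious optional calibration diagnostic stored with the
#'   graph.
#' @return A `gm_graph`: list with `graph` (an [igraph::graph]), `nodes`
#'   (data.frame of 0-based cube corner coordinates), `threshold`,
#'   `achieved_spurious`, `subject_id`.
#' @export
binarize <- function(S, threshold, cubes = NULL, subject_id = NA_character_,
                     achieved_spurious = NA_real_) {
  if (!is.finite(threshold)) stop("`threshold` must be finite")
  adj <- !is.na(S) & S > max(threshold, 0)
  adj <- adj | t(adj)      # defensive; S is symmetric by construction
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  nodes <- if (!is.null(cubes)) {
    data.frame(node = seq_len(nrow(S)), x = cubes$corners[, 1],
               y = cubes$corners[, 2], z = cubes$corners[, 3])
  } else {
    data.frame(node = seq_len(nrow(S)), x = NA_integer_, y = NA_integer_,
               z = NA_integer_)
  }
  structure(
    list(graph = g, nodes = nodes, threshold = threshold,
         achieved_spurious = achieved_spurious, subject_id = subject_id),
    class = "gm_graph"
  )
}

#' @export
print.gm_graph <- function(x, ...) {
  n <- igraph::vcount(x$graph)
  e <- igraph::ecount(x$graph)
  cat("<gm_graph> ", n, " nodes, ", e, " edges (density ",
      signif(2 * e / (n * (n - 1)), 3), "), threshold ",
      signif(x$threshold, 4), "\n", sep = "")
  invisible(x)
}

#' Extract a single-subject grey-matter network end to end
#'
#' Convenience wrapper: tiles the volume into cubes, computes the
#' rotation-maximized similarity matrix, calibrates the permutation
#' threshold, and binarizes.
#'
#' @inheritParams extract_cubes
#' @inheritParams permutation_threshold
#' @param subject_id identifier stored with the graph.
#' @param include_reflections passed to [rotation_set()].
#' @return A `gm_graph` (see [binarize()]); the calibration result is
#'   attached as attribute `"calibration"`.
#' @export
extract_network <- function(vol, target_spurious = 0.05,
                            n_null_pairs = 100000L, seed = 1L,
                            min_mask_voxels = 14L, offset = c(0L, 0L, 0L),
                            include_reflections = FALSE,
                            subject_id = NA_character_) {
  rots <- rotation_set(include_reflections)
  cubes <- extract_cubes(vol, min_mask_voxels = min_mask_voxels,
                         offset = offset)
  S <- similarity_matrix(cubes, rots)
  cal <- permutation_threshold(cubes, rots, S = S,
                               target_spurious = target_spurious,
                               n_null_pairs = n_null_pairs, seed = seed)
  g <- binarize(S, cal$threshold, cubes = cubes, subject_id = subject_id,
                achieved_spurious = cal$achieved_spurious)
  attr(g, "calibration") <- cal
  g
}

# save/restore .Random.seed so seeded internals do not disturb the caller's
# RNG stream
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
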