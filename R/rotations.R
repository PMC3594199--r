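#' Rigid rotations of a 3x3x3 voxel cube as permutations
#'
#' The cortex is a curved sheet, so two locally similar cubes of grey matter
#' may sit at an angle to each other. Similarity between cubes is therefore
#' taken as the maximum correlation over rigid rotations of one cube. Because
#' cubes live on a voxel lattice, the only rotations that map the lattice onto
#' itself are the 24 proper rotations of the cube (multiples of 90 degrees);
#' each acts as a permutation of the 27 voxel positions. With
#' `include_reflections = TRUE` the full orthogonal group of the cube
#' (48 elements) is returned.
#'
#' Voxel positions are linearized x-fastest: position `(i, j, k)` with
#' `i, j, k` in `0:2` maps to index `1 + i + 3*j + 9*k`, matching how
#' [as.vector()] unrolls a `3 x 3 x 3` R array.
#'
#' @param include_reflections logical; if `TRUE`, include the 24 improper
#'   elements (determinant -1) as well.
#' @return A list of integer vectors, each a permutation of `1:27`. The first
#'   element is always the identity. Applying element `p` to a cube vector `v`
#'   is `v[p]`.
#' @examples
#' rots <- rotation_set()
#' length(rots)          # 24
#' rots[[1]]             # identity
#' @export
rotation_set <- function(include_reflections = FALSE) {
  # all 48 signed permutation matrices; keep det = +1 (or all, with flag)
  perms3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  signs <- expand.grid(s1 = c(1, -1), s2 = c(1, -1), s3 = c(1, -1))
  mats <- list()
  for (p in perms3) {
    for (r in seq_len(nrow(signs))) {
      m <- matrix(0, 3, 3)
      for (ax in 1:3) m[ax, p[ax]] <- signs[r, ax]
      if (include_reflections || round(det(m)) == 1L) {
        mats[[length(mats) + 1L]] <- m
      }
    }
  }
  # voxel offsets from the cube center, x-fastest
  offsets <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  idx_of <- function(v) 1L + (v[1] + 1L) + 3L * (v[2] + 1L) + 9L * (v[3] + 1L)
  perms <- lapply(mats, function(m) {
    # rotated cube u[p] = v[R^T p]; R^T = R^-1 for orthogonal R
    src <- offsets %*% m   # row p gives R^T p since (R^T p)^T = p^T R
    perm <- integer(27)
    for (i in 1:27) perm[i] <- idx_of(src[i, ])
    perm
  })
  # put the identity first; order of the rest is immaterial
  is_id <- vapply(perms, function(p) all(p == 1:27), logical(1))
  c(perms[is_id], perms[!is_id])
}
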