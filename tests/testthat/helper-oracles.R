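# Independent oracles used to validate the package's computational kernels.
# Each is written for clarity and obvious correctness, not speed, and shares
# no code with the implementations under test.

# ---- flood-fill connected-component oracle -------------------------------

neighbor_offsets <- function(connectivity) {
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 "6"  = rowSums(abs(offs)) == 1,
                 "18" = rowSums(abs(offs)) <= 2,
                 "26" = rep(TRUE, nrow(offs)))
  offs[keep, , drop = FALSE]
}

# Union-find component oracle: enumerate all adjacent foreground voxel
# pairs (vectorized over half the neighbor offsets so each pair appears
# once), then merge with a classic disjoint-set forest. A deliberately
# different algorithm from the implementation under test.
oracle_flood_fill <- function(binary, connectivity) {
  stopifnot(is.logical(binary), length(dim(binary)) == 3L)
  shape <- dim(binary)
  offs <- neighbor_offsets(connectivity)
  # keep one offset per unordered pair: first nonzero coordinate positive
  first_nz <- apply(offs, 1, function(o) o[which(o != 0)[1]])
  offs <- offs[first_nz > 0, , drop = FALSE]
  fg_lin <- which(binary)
  n <- length(fg_lin)
  lab <- array(0L, shape)
  if (!n) { attr(lab, "n_components") <- 0L; return(lab) }
  id_of <- array(0L, shape)
  id_of[fg_lin] <- seq_len(n)
  fz <- ((fg_lin - 1L) %% shape[1]) + 1L
  fy <- (((fg_lin - 1L) %/% shape[1]) %% shape[2]) + 1L
  fx <- ((fg_lin - 1L) %/% (shape[1] * shape[2])) + 1L
  parent <- seq_len(n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  for (k in seq_len(nrow(offs))) {
    nz <- fz + offs[k, 1]; ny <- fy + offs[k, 2]; nx <- fx + offs[k, 3]
    ok <- nz >= 1 & nz <= shape[1] & ny >= 1 & ny <= shape[2] & nx >= 1 & nx <= shape[3]
    nl <- nz[ok] + shape[1] * (ny[ok] - 1L) + shape[1] * shape[2] * (nx[ok] - 1L)
    a <- which(ok)[binary[nl]]
    b <- id_of[nl[binary[nl]]]
    for (p in seq_along(a)) {
      ra <- find(a[p]); rb <- find(b[p])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- match(roots, unique(roots))
  lab[fg_lin] <- comp
  attr(lab, "n_components") <- length(unique(roots))
  lab
}

# TRUE when two label arrays describe the same partition of the foreground
same_partition <- function(a, b) {
  if (!identical(dim(a), dim(b))) return(FALSE)
  if (!identical(a > 0L, b > 0L)) return(FALSE)
  nz <- which(a > 0L)
  if (!length(nz)) return(TRUE)
  # each a-component maps to exactly one b-label and vice versa
  tab <- table(a[nz], b[nz])
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# ---- brute-force convex hull membership (Caratheodory) -------------------

det3 <- function(u, v, w) {
  u[1] * (v[2] * w[3] - v[3] * w[2]) -
    u[2] * (v[1] * w[3] - v[3] * w[1]) +
    u[3] * (v[1] * w[2] - v[2] * w[1])
}

# q is inside/on tetrahedron ABCD iff for each face q lies on the same
# closed side as the opposite vertex; exact for integer coordinates.
in_tetra <- function(q, A, B, C, D) {
  side <- function(p1, p2, p3, opp, pt) {
    s_opp <- det3(p2 - p1, p3 - p1, opp - p1)
    s_pt <- det3(p2 - p1, p3 - p1, pt - p1)
    s_opp * s_pt >= 0
  }
  side(A, B, C, D, q) && side(A, B, D, C, q) && side(A, C, D, B, q) && side(B, C, D, A, q)
}

# Counts bounding-box voxel centers inside the convex hull of `vox` by
# Caratheodory's theorem: a point of R^3 lies in the hull iff it lies in
# some tetrahedron of 4 input points. Returns NA when every 4-subset is
# degenerate (affine rank < 3).
oracle_hull_count <- function(vox) {
  vox <- as.matrix(vox)
  n <- nrow(vox)
  rng <- lapply(1:3, function(a) min(vox[, a]):max(vox[, a]))
  qry <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  inside <- rep(FALSE, nrow(qry))
  any_tet <- FALSE
  if (n >= 4) {
    subs <- utils::combn(n, 4)
    for (s in seq_len(ncol(subs))) {
      A <- vox[subs[1, s], ]; B <- vox[subs[2, s], ]
      C <- vox[subs[3, s], ]; D <- vox[subs[4, s], ]
      if (det3(B - A, C - A, D - A) == 0) next
      any_tet <- TRUE
      todo <- which(!inside)
      if (!length(todo)) break
      for (i in todo) inside[i] <- in_tetra(qry[i, ], A, B, C, D)
    }
  }
  if (!any_tet) return(NA_integer_)
  sum(inside)
}

# ---- exact-rational Fleiss kappa -----------------------------------------

# kappa = [(S - Nn) Nn - (n-1) sum(Tj^2)] / [(n-1) ((Nn)^2 - sum(Tj^2))]
# derived by clearing denominators in p0 and pe; every term is an integer
# well below 2^53, so the double evaluation of this ratio is exact up to
# one final division.
oracle_fleiss_exact <- function(counts) {
  counts <- as.matrix(counts)
  N <- nrow(counts); n <- sum(counts[1, ])
  S <- sum(counts^2)
  Tj2 <- sum(colSums(counts)^2)
  num <- (S - N * n) * N * n - (n - 1) * Tj2
  den <- (n - 1) * ((N * n)^2 - Tj2)
  if (den == 0) return(NA_real_)
  num / den
}

# ---- brute-force dilation ------------------------------------------------

oracle_dilate <- function(mask, radius_um, voxel_size_um) {
  shape <- dim(mask)
  src <- which(mask, arr.ind = TRUE)
  if (!nrow(src)) return(mask)
  src_um <- sweep(src - 0.5, 2, voxel_size_um, `*`)
  out <- array(FALSE, shape)
  all_idx <- which(array(TRUE, shape), arr.ind = TRUE)
  ctr <- sweep(all_idx - 0.5, 2, voxel_size_um, `*`)
  for (i in seq_len(nrow(all_idx))) {
    d2 <- (src_um[, 1] - ctr[i, 1])^2 + (src_um[, 2] - ctr[i, 2])^2 + (src_um[, 3] - ctr[i, 3])^2
    out[all_idx[i, 1], all_idx[i, 2], all_idx[i, 3]] <- min(d2) <= radius_um^2 + 1e-9
  }
  out
}

# lattice-ball count: voxel offsets with ||d * voxel_size|| <= r
oracle_ball_count <- function(radius_um, voxel_size_um) {
  m <- ceiling(radius_um / min(voxel_size_um)) + 1L
  g <- as.matrix(expand.grid(-m:m, -m:m, -m:m))
  d2 <- (g[, 1] * voxel_size_um[1])^2 + (g[, 2] * voxel_size_um[2])^2 + (g[, 3] * voxel_size_um[3])^2
  sum(d2 <= radius_um^2 + 1e-9)
}
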