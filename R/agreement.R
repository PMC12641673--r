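#' Build a voxel-wise rating matrix from rater label maps
#'
#' Each aligned label map is one rater's segmentation; the category set is
#' the union of labels present across maps, with background (0) counted as
#' a category, so agreement is computed over every voxel of the stack. An
#' optional mask restricts the tabulated voxels.
#'
#' @param label_maps list of >= 2 [label_volume()]s (or integer arrays) with
#'   identical shapes.
#' @param restrict_mask optional logical array selecting the voxels to rate.
#' @return A `rating_matrix`: list with `counts` (N x k integer matrix,
#'   `n_ij` = raters assigning voxel i to category j), `n` raters,
#'   `categories`.
#' @export
build_ratings <- function(label_maps, restrict_mask = NULL) {
  arrs <- lapply(label_maps, function(m) if (inherits(m, "label_volume")) m$labels else m)
  if (length(arrs) < 2L) stop("at least 2 rater maps are required")
  d <- dim(arrs[[1]])
  for (a in arrs) if (!identical(dim(a), d))
    stop(sprintf("rater map shapes differ: %s vs %s",
                 paste(d, collapse = ","), paste(dim(a), collapse = ",")))
  sel <- if (is.null(restrict_mask)) TRUE else {
    if (!identical(dim(restrict_mask), d)) stop("restrict_mask shape differs from maps")
    as.vector(restrict_mask)
  }
  vecs <- lapply(arrs, function(a) as.vector(a)[sel])
  categories <- sort(unique(unlist(lapply(vecs, unique))))
  counts <- sapply(categories, function(cat)
    Reduce(`+`, lapply(vecs, function(v) as.integer(v == cat))))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  colnames(counts) <- as.character(categories)
  rating_matrix(counts, categories)
}

#' Construct a rating matrix from a count table
#'
#' @param counts N x k non-negative integer matrix; every row must sum to
#'   the same number of raters `n >= 2`.
#' @param categories optional category labels (length k).
#' @return A `rating_matrix` object.
#' @export
rating_matrix <- function(counts, categories = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != floor(counts))) stop("counts must be non-negative integers")
  if (nrow(counts) < 1L) stop("N must be >= 1")
  rs <- rowSums(counts)
  if (length(unique(rs)) != 1L) stop("every voxel must be rated by the same number of raters")
  n <- rs[1]
  if (n < 2) stop("at least 2 raters are required")
  if (ncol(counts) < 2L) stop("at least 2 categories are required")
  if (is.null(categories)) categories <- colnames(counts)
  if (is.null(categories)) categories <- seq_len(ncol(counts))
  structure(list(counts = counts, n = as.integer(n), N = nrow(counts),
                 k = ncol(counts), categories = categories),
            class = "rating_matrix")
}

#' Fleiss kappa for multi-rater voxel-wise agreement
#'
#' Chance-corrected agreement for `n` raters assigning `N` voxels to `k`
#' categories:
#' \deqn{p_0 = \frac{1}{N n (n-1)} \left(\sum_i \sum_j n_{ij}^2 - N n\right)}
#' \deqn{p_e = \sum_j p_j^2, \quad p_j = \frac{\sum_i n_{ij}}{N n}}
#' \deqn{\kappa = \frac{p_0 - p_e}{1 - p_e}}
#' When every rating falls in a single category, `p_e = 1` and kappa is
#' undefined ("degenerate agreement").
#'
#' @param ratings a `rating_matrix` (from [build_ratings()] or
#'   [rating_matrix()]).
#' @return An `agreement_result`: list with `kappa`, `p0`, `pe`, `p_j`,
#'   `N`, `n`, `k`.
#' @export
fleiss_kappa <- function(ratings) {
  stopifnot(inherits(ratings, "rating_matrix"))
  cnt <- ratings$counts
  N <- ratings$N; n <- ratings$n
  S <- sum(cnt^2)
  p0 <- (S - N * n) / (N * n * (n - 1))
  p_j <- colSums(cnt) / (N * n)
  pe <- sum(p_j^2)
  if (pe >= 1) stop("degenerate agreement: all ratings fall in one category, kappa undefined")
  structure(list(kappa = (p0 - pe) / (1 - pe), p0 = p0, pe = pe, p_j = p_j,
                 N = N, n = n, k = ratings$k),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Fleiss kappa = %.4f (p0 = %.4f, pe = %.4f; N = %d, n = %d, k = %d)\n",
              x$kappa, x$p0, x$pe, x$N, x$n, x$k))
  invisible(x)
}

#' Fleiss kappa over whole stacks, computed in streaming chunks
#'
#' Equivalent to `fleiss_kappa(build_ratings(label_maps, restrict_mask))`
#' but accumulates only the sufficient statistics (sum of squared cell
#' counts and category marginals) chunk by chunk, so whole stacks never
#' materialize an N x k rating table.
#'
#' @param label_maps list of >= 2 [label_volume()]s (or integer arrays)
#'   with identical shapes.
#' @param restrict_mask optional logical array selecting the voxels rated.
#' @param chunk voxels per accumulation chunk.
#' @return An `agreement_result`, as from [fleiss_kappa()].
#' @export
fleiss_kappa_maps <- function(label_maps, restrict_mask = NULL, chunk = 262144L) {
  arrs <- lapply(label_maps, function(m) if (inherits(m, "label_volume")) m$labels else m)
  if (length(arrs) < 2L) stop("at least 2 rater maps are required")
  n <- length(arrs)
  sel <- if (is.null(restrict_mask)) seq_along(arrs[[1]]) else which(as.vector(restrict_mask))
  N <- length(sel)
  if (N == 0L) stop("empty mask")
  categories <- sort(unique(unlist(lapply(arrs, function(a) unique(as.vector(a)[sel])))))
  k <- length(categories)
  S <- 0
  Tj <- stats::setNames(numeric(k), as.character(categories))
  for (start in seq(1L, N, by = chunk)) {
    ix <- sel[start:min(start + chunk - 1L, N)]
    acc <- matrix(0L, length(ix), k)
    for (a in arrs) {
      v <- a[ix]
      for (j in seq_len(k)) acc[, j] <- acc[, j] + (v == categories[j])
    }
    S <- S + sum(acc^2)
    Tj <- Tj + colSums(acc)
  }
  p0 <- (S - N * n) / (N * n * (n - 1))
  p_j <- Tj / (N * n)
  pe <- sum(p_j^2)
  if (pe >= 1) stop("degenerate agreement: all ratings fall in one category, kappa undefined")
  structure(list(kappa = (p0 - pe) / (1 - pe), p0 = p0, pe = pe, p_j = p_j,
                 N = N, n = n, k = k),
            class = "agreement_result")
}

#' Per-structure Fleiss kappa and the across-structure average
#'
#' For each structure the rater maps are binarized to structure versus
#' not-structure (k = 2) and kappa is computed voxel-wise; the mean and
#' sample sd across structures summarize overall rater agreement.
#'
#' @param label_maps list of >= 2 [label_volume()]s sharing one shape. Maps
#'   must share label indices for common structures; structures are matched
#'   by name when `label_names` are present, else by index.
#' @param structures character vector of structure names (default: union of
#'   names across maps).
#' @param restrict_mask optional logical array.
#' @return List with `per_structure` (named kappa vector), `mean`, `sd`, and
#'   `skipped` (structures absent from every map).
#' @export
per_structure_kappa <- function(label_maps, structures = NULL, restrict_mask = NULL) {
  named <- vapply(label_maps, function(m) inherits(m, "label_volume") &&
                    length(m$label_names) > 0, logical(1))
  if (is.null(structures)) {
    if (all(named)) {
      structures <- sort(unique(unlist(lapply(label_maps, function(m) unname(m$label_names)))))
    } else {
      idx <- sort(unique(unlist(lapply(label_maps, function(m) {
        a <- if (inherits(m, "label_volume")) m$labels else m
        setdiff(unique(as.vector(a)), 0L)
      }))))
      structures <- as.character(idx)
    }
  }
  kap <- numeric(0)
  skipped <- character(0)
  for (s in structures) {
    bins <- lapply(label_maps, function(m) {
      if (inherits(m, "label_volume") && length(m$label_names)) {
        hit <- which(m$label_names == s)
        idx <- if (length(hit)) as.integer(names(m$label_names)[hit[1]]) else -1L
        arr <- m$labels
      } else {
        arr <- if (inherits(m, "label_volume")) m$labels else m
        idx <- suppressWarnings(as.integer(s))
        if (is.na(idx)) idx <- -1L
      }
      array(as.integer(arr == idx), dim(arr))
    })
    if (!any(vapply(bins, function(b) any(b > 0L), logical(1)))) {
      warning(sprintf("structure '%s' absent from every map: skipped", s))
      skipped <- c(skipped, s)
      next
    }
    kap[s] <- fleiss_kappa_maps(bins, restrict_mask)$kappa
  }
  list(per_structure = kap,
       mean = if (length(kap)) mean(kap) else NA_real_,
       sd = if (length(kap) >= 2) stats::sd(kap) else NA_real_,
       skipped = skipped)
}

#' Simulate imperfect rater segmentations from a reference map
#'
#' Degrades a reference label map by flipping a fraction of voxels: a
#' flipped foreground voxel becomes background and vice versa (binary maps),
#' giving controllable disagreement for validating the kappa computation.
#'
#' @param reference a [label_volume()] with a single foreground label.
#' @param n_raters number of raters to simulate.
#' @param flip_fraction fraction of voxels flipped per rater (scalar or per
#'   rater).
#' @param seed integer seed.
#' @return List of [label_volume()]s.
#' @export
simulate_raters <- function(reference, n_raters = 3L, flip_fraction = 0.02, seed = 1L) {
  stopifnot(inherits(reference, "label_volume"))
  set.seed(seed)
  fr <- rep_len(flip_fraction, n_raters)
  base <- reference$labels > 0L
  nvox <- length(base)
  lapply(seq_len(n_raters), function(r) {
    b <- base
    nf <- round(fr[r] * nvox)
    if (nf > 0) {
      ix <- sample.int(nvox, nf)
      b[ix] <- !b[ix]
    }
    label_volume(array(as.integer(b), dim(base)), reference$geometry,
                 stats::setNames("macrophage", "1"))
  })
}
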