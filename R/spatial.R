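#' Pool hemispheres by mirroring right-hemisphere contacts to the left
#'
#' Mirror flip (x -> -x) of right-hemisphere MNI coordinates so both
#' hemispheres can be analyzed in a common (left) template space.
#' Precomputed nonlinearly flipped coordinates may be supplied instead, in
#' which case rows already carrying \code{flipped = TRUE} are left untouched.
#'
#' @param geoms Data frame with columns patient_id, hemisphere ("L"/"R"),
#'   contact, x, y, z (mm, MNI).
#' @return The same data frame with right-hemisphere x negated and a
#'   \code{flipped} provenance column.
#' @export
pool_hemispheres <- function(geoms) {
  stopifnot(all(c("hemisphere", "x", "y", "z") %in% names(geoms)))
  if (is.null(geoms$flipped)) geoms$flipped <- FALSE
  todo <- geoms$hemisphere == "R" & !geoms$flipped
  geoms$x[todo] <- -geoms$x[todo]
  geoms$flipped[todo] <- TRUE
  geoms
}

#' Spatial distribution of power over contacts
#'
#' Couples contact coordinates with nonnegative power weights. Periodic
#' (log-residual) power can be negative; since the focality statistic
#' presumes mass-like weights, negative inputs are shifted to zero minimum
#' per analysis (recorded in the \code{shift} field).
#'
#' @param coords N x 3 matrix of MNI coordinates (mm).
#' @param weights Length-N power values.
#' @return An object of class \code{spatial_distribution} with fields
#'   \code{coords}, \code{weights} (shifted nonnegative), \code{shift}.
#' @export
spatial_distribution <- function(coords, weights) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must be N x 3")
  weights <- as.numeric(weights)
  if (length(weights) != nrow(coords)) stop("weights must match coords rows")
  if (any(!is.finite(weights)) || any(!is.finite(coords))) stop("non-finite input")
  shift <- if (min(weights) < 0) -min(weights) else 0
  structure(list(coords = coords, weights = weights + shift, shift = shift),
            class = "spatial_distribution")
}

#' Centroid of the top power percentile
#'
#' The spatial peak of alpha activity: the unweighted mean coordinate of
#' contacts whose power reaches the top \code{pct} percent.
#'
#' @param dist A \code{spatial_distribution}.
#' @param pct Top percentile (default 5).
#' @return Length-3 coordinate (mm).
#' @export
top_percentile_centroid <- function(dist, pct = 5) {
  stopifnot(inherits(dist, "spatial_distribution"))
  thr <- stats::quantile(dist$weights, 1 - pct / 100, names = FALSE)
  # strict inequality so a single dominant contact defines the peak even
  # when the remaining weights tie at the threshold; degenerate all-equal
  # inputs fall back to the argmax set
  sel <- dist$weights > thr
  if (!any(sel)) sel <- dist$weights == max(dist$weights)
  if (!any(sel)) stop("empty top-percentile selection")
  colMeans(dist$coords[sel, , drop = FALSE])
}

#' Spearman correlation of power with distance to the spatial peak
#'
#' Spatial focality analysis: ranks power against Euclidean distance to the
#' top-percentile centroid. A decay of power with distance yields a negative
#' raw correlation; following the reporting convention for focality, the
#' returned R has its sign inverted so that decay-with-distance is positive.
#'
#' @param dist A \code{spatial_distribution}.
#' @param centroid Length-3 coordinate of the spatial peak.
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Integer seed.
#' @return List with \code{R} (sign-inverted Spearman), \code{ci} (95%
#'   percentile bootstrap), \code{distances}.
#' @export
distance_power_correlation <- function(dist, centroid, n_boot = 10000, seed = 1) {
  stopifnot(inherits(dist, "spatial_distribution"))
  n <- nrow(dist$coords)
  if (n < 5) stop("need at least 5 contacts")
  if (stats::sd(dist$weights) == 0) stop("constant power: correlation undefined")
  d <- sqrt(rowSums((dist$coords - matrix(centroid, n, 3, byrow = TRUE))^2))
  r <- -stats::cor(dist$weights, d, method = "spearman")
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    if (stats::sd(dist$weights[idx]) == 0 || stats::sd(d[idx]) == 0) return(NA_real_)
    -stats::cor(dist$weights[idx], d[idx], method = "spearman")
  }, numeric(1))
  list(R = r, ci = unname(stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE)),
       distances = d)
}

#' Moment of inertia of a power distribution
#'
#' Power-weighted mean squared distance to the power-weighted center of
#' mass:
#' \deqn{I = \sum_i w_i \|\bar r_i - \bar r_{avg}\|^2 / \sum_i w_i}
#' The denominator gives I units of mm² and makes it scale-invariant across
#' power definitions.
#'
#' @param dist A \code{spatial_distribution}.
#' @return I in mm².
#' @export
moment_of_inertia <- function(dist) {
  stopifnot(inherits(dist, "spatial_distribution"))
  w <- dist$weights
  if (sum(w) <= 0) stop("all-zero weights")
  ctr <- colSums(dist$coords * w) / sum(w)
  sum(w * rowSums((dist$coords - matrix(ctr, nrow(dist$coords), 3, byrow = TRUE))^2)) / sum(w)
}

#' Radius of gyration
#'
#' Square root of the moment of inertia: the effective radius of a sphere
#' with the same moment of inertia as the observed distribution.
#'
#' @param I Moment of inertia (mm²), nonnegative.
#' @return Radius in mm.
#' @export
radius_of_gyration <- function(I) {
  if (I < 0) stop("I must be nonnegative")
  sqrt(I)
}

#' Permutation test of spatial focality
#'
#' Left-sided test of whether the observed moment of inertia is smaller
#' (more focal) than expected under spatial shuffling that respects the lead
#' geometry: power is first averaged within each hemisphere; residuals
#' (contact minus hemisphere mean) are shuffled within hemisphere and added
#' to hemisphere means permuted across hemispheres; I is recomputed from each
#' reconstructed weight field. Reconstructed negative weights are clipped to
#' zero (count reported).
#'
#' @param dist A \code{spatial_distribution}.
#' @param hemi_labels Factor/character label per contact identifying its
#'   hemisphere (lead).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return A \code{permutation_result} (left-sided); attribute
#'   \code{"n_clipped"} counts clipped negative weights across permutations.
#' @export
inertia_permutation_test <- function(dist, hemi_labels, n_perm = 10000, seed = 1) {
  stopifnot(inherits(dist, "spatial_distribution"))
  hemi_labels <- as.character(hemi_labels)
  if (length(hemi_labels) != nrow(dist$coords)) stop("one label per contact required")
  obs <- moment_of_inertia(dist)
  hl <- unique(hemi_labels)
  if (length(hl) == 1)
    warning("single hemisphere: falling back to residual shuffling only")
  idx <- split(seq_along(hemi_labels), hemi_labels)
  means <- vapply(idx, function(i) mean(dist$weights[i]), numeric(1))
  resid <- dist$weights - means[match(hemi_labels, names(means))]
  set.seed(seed)
  nH <- length(idx); nC <- length(hemi_labels)
  # reconstructed weight fields, one column per permutation
  PM <- vapply(seq_len(n_perm), function(p) means[sample.int(nH)], numeric(nH))
  W <- matrix(0, nC, n_perm)
  for (j in seq_len(nH)) {
    i <- idx[[j]]; k <- length(i)
    if (k == 1) {
      RS <- matrix(resid[i], 1, n_perm)
    } else if (k <= 6) {
      P <- pracma::perms(seq_len(k))
      ids <- sample.int(nrow(P), n_perm, replace = TRUE)
      RS <- matrix(resid[i][t(P[ids, , drop = FALSE])], k, n_perm)
    } else {
      RS <- vapply(seq_len(n_perm), function(p) resid[i][sample.int(k)],
                   numeric(k))
    }
    W[i, ] <- RS + rep(PM[j, ], each = k)
  }
  neg <- W < 0
  n_clip <- sum(neg)
  W[neg] <- 0
  sw <- colSums(W)
  ok <- sw > 0
  q <- rowSums(dist$coords^2)
  C <- t(dist$coords) %*% W[, ok, drop = FALSE]
  C <- sweep(C, 2, sw[ok], "/")
  null <- as.numeric(q %*% W[, ok, drop = FALSE]) / sw[ok] - colSums(C^2)
  out <- permutation_result(obs, null, .perm_p(null, obs, "left"), "left")
  attr(out, "n_clipped") <- n_clip
  out
}

#' Construct an anatomical structure geometry
#'
#' Structures near the lead trajectory (GPe, NAcc, BNST) represented either
#' as a surface point cloud (mm) or a voxel mask with an affine transform.
#'
#' @param name Structure name.
#' @param points N x 3 matrix of surface points (mm), or NULL.
#' @param mask 3D logical/numeric array, or NULL.
#' @param affine 4 x 4 voxel-to-mm affine (required with \code{mask}).
#' @return An object of class \code{structure_geometry} exposing a border
#'   point set (mask: centers of boundary voxels, i.e. mask voxels with at
#'   least one 6-neighbor outside the mask).
#' @export
structure_geometry <- function(name, points = NULL, mask = NULL, affine = NULL) {
  if (is.null(points) && is.null(mask)) stop("structure must be nonempty")
  if (!is.null(mask)) {
    if (is.null(affine)) stop("mask requires an affine")
    mask <- mask != 0
    if (!any(mask)) stop("structure must be nonempty")
    dm <- dim(mask)
    pad <- array(FALSE, dm + 2)
    pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- mask
    inner <- pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] &
      pad[1:dm[1], 2:(dm[2] + 1), 2:(dm[3] + 1)] &
      pad[3:(dm[1] + 2), 2:(dm[2] + 1), 2:(dm[3] + 1)] &
      pad[2:(dm[1] + 1), 1:dm[2], 2:(dm[3] + 1)] &
      pad[2:(dm[1] + 1), 3:(dm[2] + 2), 2:(dm[3] + 1)] &
      pad[2:(dm[1] + 1), 2:(dm[2] + 1), 1:dm[3]] &
      pad[2:(dm[1] + 1), 2:(dm[2] + 1), 3:(dm[3] + 2)]
    bnd <- which(mask & !inner, arr.ind = TRUE)
    # voxel indices are 1-based; affine maps 0-based voxel coords to mm
    vox <- cbind(bnd - 1, 1)
    points <- (vox %*% t(affine))[, 1:3, drop = FALSE]
  }
  points <- as.matrix(points)
  if (ncol(points) != 3 || nrow(points) == 0) stop("points must be N x 3, nonempty")
  structure(list(name = name, border = points), class = "structure_geometry")
}

#' Distance from a contact to the closest structure border
#'
#' @param contact Length-3 coordinate (mm).
#' @param structure A \code{structure_geometry}.
#' @return Minimal (unsigned) Euclidean distance in mm.
#' @export
border_distance <- function(contact, structure) {
  stopifnot(inherits(structure, "structure_geometry"))
  b <- structure$border
  sqrt(min(rowSums((b - matrix(contact, nrow(b), 3, byrow = TRUE))^2)))
}

#' 2D power heatmap in a template plane
#'
#' Projects contacts onto an anatomical plane, interpolates power on a
#' regular grid (inverse-distance weighting, exact at the data points) and
#' applies Gaussian smoothing with sigma = FWHM/2.355 in grid units. Grid
#' nodes outside the convex hull of the projected contacts are NA.
#'
#' @param dist A \code{spatial_distribution}.
#' @param plane "axial" (x, y), "coronal" (x, z) or "sagittal" (y, z).
#' @param fwhm Smoothing kernel FWHM in grid cells (default 0.75).
#' @param grid_step_mm Grid spacing (default 0.5 mm).
#' @return List with \code{gx}, \code{gy} (grid axes, mm), \code{values}
#'   (matrix, NA outside the hull), \code{plane}.
#' @export
heatmap_2d <- function(dist, plane = c("axial", "coronal", "sagittal"),
                       fwhm = 0.75, grid_step_mm = 0.5) {
  stopifnot(inherits(dist, "spatial_distribution"))
  plane <- match.arg(plane)
  cols <- switch(plane, axial = c(1, 2), coronal = c(1, 3), sagittal = c(2, 3))
  P <- dist$coords[, cols, drop = FALSE]
  w <- dist$weights
  hull <- grDevices::chull(P)
  if (length(hull) < 3) stop("projected points are collinear")
  gx <- seq(min(P[, 1]), max(P[, 1]), by = grid_step_mm)
  gy <- seq(min(P[, 2]), max(P[, 2]), by = grid_step_mm)
  G <- as.matrix(expand.grid(x = gx, y = gy))
  inside <- mgcv::in.out(rbind(P[hull, , drop = FALSE], P[hull[1], ]), G)
  vals <- rep(NA_real_, nrow(G))
  gi <- which(inside)
  if (length(gi) > 0) {
    d2 <- outer(rowSums(G[gi, , drop = FALSE]^2), rowSums(P^2), "+") -
      2 * G[gi, , drop = FALSE] %*% t(P)
    d2[d2 < 1e-12] <- 1e-12
    wt <- 1 / d2
    vals[gi] <- as.numeric((wt %*% w) / rowSums(wt))
  }
  V <- matrix(vals, nrow = length(gx), ncol = length(gy))
  # Gaussian smoothing (normalized convolution so NA borders don't bleed)
  sigma <- fwhm / 2.355
  if (sigma > 0) {
    r <- max(1L, ceiling(3 * sigma))
    k <- stats::dnorm(-r:r, sd = sigma)
    k <- k / sum(k)
    sm <- function(M) {
      A <- M; A[is.na(A)] <- 0
      W <- 1 * !is.na(M)
      convrow <- function(X) t(apply(X, 1, function(v)
        stats::filter(c(rep(0, r), v, rep(0, r)), k, sides = 2)[(r + 1):(r + length(v))]))
      A2 <- convrow(t(convrow(t(A)))); W2 <- convrow(t(convrow(t(W))))
      out <- A2 / W2
      out[is.na(M)] <- NA
      out
    }
    V <- sm(V)
  }
  list(gx = gx, gy = gy, values = V, plane = plane)
}
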