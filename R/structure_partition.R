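#' Construct a partition plane
#'
#' A plane `n . x = offset` with unit normal `n`, used to split a C-alpha
#' structure into two labelled sides.
#'
#' @param normal Numeric 3-vector; normalized internally.
#' @param offset Scalar offset of the plane along the normal.
#' @param labels Character vector of 2 side labels; residues with
#'   non-negative signed distance get `labels[2]`.
#' @return Object of class `partition_plane` with `unit_normal`, `offset`
#'   and `labels`.
#' @export
partition_plane <- function(normal, offset, labels = c("left", "right")) {
  stopifnot(is.numeric(normal), length(normal) == 3L,
            all(is.finite(normal)), length(labels) == 2L)
  nrm <- sqrt(sum(normal^2))
  if (nrm < 1e-12) stop("degenerate (zero) plane normal")
  structure(
    list(unit_normal = normal / nrm, offset = as.numeric(offset) / nrm,
         labels = as.character(labels)),
    class = "partition_plane"
  )
}

#' Fit the plane of best fit through C-alpha coordinates
#'
#' The default method regresses the z coordinate on x and y by ordinary
#' least squares, mirroring a fit of a plane `z = b0 + b1 x + b2 y` by
#' linear regression; the fitted surface is returned as a unit normal and
#' offset. Because the OLS plane depends on which axis plays the response,
#' a total-least-squares alternative (`method = "pca"`: the plane through
#' the centroid normal to the smallest-variance principal axis) is exposed
#' for sensitivity analysis; it is invariant under rotation of the
#' coordinate frame.
#'
#' @param structure A [structure_model()].
#' @param method `"ols"` (z on x, y) or `"pca"` (total least squares).
#' @param labels Side labels passed to [partition_plane()].
#' @return A [partition_plane()].
#' @export
fit_best_plane <- function(structure, method = c("ols", "pca"),
                           labels = c("left", "right")) {
  method <- match.arg(method)
  xyz <- coords_matrix(structure)
  if (nrow(xyz) < 3L) stop("need at least 3 C-alpha points to fit a plane")
  ctr <- colMeans(xyz)
  cv <- stats::cov(xyz)
  ev <- eigen(cv, symmetric = TRUE)
  if (ev$values[2L] < 1e-9 * max(ev$values[1L], 1)) {
    stop("C-alpha points are collinear or coincident; no unique plane")
  }
  if (method == "pca") {
    normal <- ev$vectors[, 3L]
    return(partition_plane(normal, sum(normal * ctr), labels))
  }
  X <- cbind(1, xyz[, 1L], xyz[, 2L])
  XtX <- crossprod(X)
  if (kappa(XtX) > 1e10) {
    stop(paste(
      "near-vertical plane: normal equations ill-conditioned for the",
      "z-on-(x,y) regression; refit with method = \"pca\""
    ))
  }
  beta <- solve(XtX, crossprod(X, xyz[, 3L]))
  # z = b0 + b1 x + b2 y  <=>  (b1, b2, -1) . (x,y,z) = -b0
  partition_plane(c(beta[2L], beta[3L], -1), -beta[1L], labels)
}

#' Plane perpendicular to a fitted plane
#'
#' Among the infinitely many planes orthogonal to a fitted plane, returns
#' the one through the C-alpha centroid whose normal is the direction of
#' maximal C-alpha variance within the fitted plane — the only
#' coordinate-free choice. Its normal is orthogonal to the fitted plane's
#' normal by construction.
#'
#' @param plane A [partition_plane()] (the fitted plane).
#' @param structure The [structure_model()] the plane was fitted to.
#' @param labels Side labels, default `c("top", "bottom")`.
#' @return A [partition_plane()] with `dot(normals) = 0`.
#' @export
perpendicular_plane <- function(plane, structure,
                                labels = c("top", "bottom")) {
  stopifnot(inherits(plane, "partition_plane"))
  xyz <- coords_matrix(structure)
  if (nrow(xyz) < 3L) stop("need at least 3 points")
  n <- plane$unit_normal
  ctr <- colMeans(xyz)
  centered <- sweep(xyz, 2L, ctr)
  # Project points into the fitted plane and take the leading in-plane axis.
  inplane <- centered - tcrossprod(centered %*% n, n)
  ev <- eigen(stats::cov(inplane), symmetric = TRUE)
  lam <- ev$values
  if (lam[1L] < 1e-12 || (lam[1L] - lam[2L]) / lam[1L] < 1e-8) {
    stop("in-plane variance is isotropic; no unique perpendicular plane")
  }
  axis <- ev$vectors[, 1L]
  axis <- axis - sum(axis * n) * n     # numerical cleanup; already in-plane
  partition_plane(axis, sum(axis * ctr), labels)
}

#' Assign each residue to a side of a plane
#'
#' Side is the sign of the signed distance `n . x - offset`: non-negative
#' maps to the plane's second label, negative to the first. A residue
#' exactly on the plane therefore takes the second label (documented tie
#' convention; measure-zero for real coordinates).
#'
#' @param structure A [structure_model()].
#' @param plane A [partition_plane()].
#' @return Character vector of side labels, named by residue index.
#' @export
assign_sides <- function(structure, plane) {
  stopifnot(inherits(plane, "partition_plane"))
  xyz <- coords_matrix(structure)
  signed <- drop(xyz %*% plane$unit_normal) - plane$offset
  out <- ifelse(signed >= 0, plane$labels[2L], plane$labels[1L])
  names(out) <- rownames(xyz)
  out
}

#' Observed and expected side counts for one paralog's selected sites
#'
#' The expected count on a side is the number of residues on that side
#' divided by the total number of residues, multiplied by the number of
#' selected sites — i.e. selected sites fall on a side in proportion to how
#' much of the molecule lies there.
#'
#' @param side_sizes Named numeric vector of 2: residues per side.
#' @param observed Named numeric vector of 2: selected sites per side, in
#'   the same side order.
#' @return Object of class `partition_counts` with `side_sizes`,
#'   `observed` and `expected`.
#' @export
partition_counts <- function(side_sizes, observed) {
  stopifnot(length(side_sizes) == 2L, length(observed) == 2L,
            all(side_sizes >= 0), all(observed >= 0),
            sum(side_sizes) > 0)
  expected <- side_sizes / sum(side_sizes) * sum(observed)
  structure(
    list(side_sizes = side_sizes, observed = observed, expected = expected),
    class = "partition_counts"
  )
}

#' Chi-square test of selected-site placement across a plane
#'
#' Goodness-of-fit chi-square with 1 degree of freedom comparing the
#' observed split of one paralog's selected sites across the two sides with
#' the split expected from residue numbers alone; upper-tail p-value. Run
#' per paralog separately.
#'
#' @param counts A [partition_counts()].
#' @return List with `statistic`, `df` (1), `p_value`, `observed`,
#'   `expected` and `side_sizes`.
#' @export
side_chi_square <- function(counts) {
  stopifnot(inherits(counts, "partition_counts"))
  if (any(counts$expected <= 0)) {
    stop("expected count of 0 on a side; chi-square undefined")
  }
  if (any(counts$expected < 5)) {
    warning("expected side count below 5; chi-square approximation is crude")
  }
  chi2 <- sum((counts$observed - counts$expected)^2 / counts$expected)
  list(
    statistic = chi2, df = 1L,
    p_value = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
    observed = counts$observed, expected = counts$expected,
    side_sizes = counts$side_sizes
  )
}

#' Plane-partition test of one paralog's selected sites
#'
#' Convenience wrapper: assigns every residue to a side of the plane,
#' tallies the paralog's selected-site residues per side, builds the
#' expected counts from side sizes and runs [side_chi_square()].
#'
#' @param structure A [structure_model()].
#' @param plane A [partition_plane()].
#' @param site_residues Integer vector of residue indices carrying the
#'   paralog's selected sites (e.g. mapped from alignment columns).
#' @return As [side_chi_square()], plus `labels`.
#' @export
plane_partition_test <- function(structure, plane, site_residues) {
  sides <- assign_sides(structure, plane)
  lv <- plane$labels
  side_sizes <- c(sum(sides == lv[1L]), sum(sides == lv[2L]))
  names(side_sizes) <- lv
  site_residues <- as.integer(site_residues)
  missing <- setdiff(site_residues, structure$residues$residue_index)
  if (length(missing)) {
    stop(sprintf("site residue(s) not in structure: %s",
                 paste(missing, collapse = ", ")))
  }
  site_sides <- sides[as.character(site_residues)]
  observed <- c(sum(site_sides == lv[1L]), sum(site_sides == lv[2L]))
  names(observed) <- lv
  out <- side_chi_square(partition_counts(side_sizes, observed))
  out$labels <- lv
  out
}
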