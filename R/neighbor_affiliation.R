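#' Build site instances for the nearest-neighbor affiliation test
#'
#' Places each paralog's selected alignment columns on the structure via a
#' column-to-residue mapping. A column selected in both paralogs is
#' "shared" and contributes two instances — one per paralog — at the same
#' coordinate, since it is under selection independently in both. Columns
#' whose reference position is unmapped (gap in the reference row) are
#' dropped with a message.
#'
#' @param sites_a,sites_b [site_set()] objects.
#' @param mapping Integer vector column -> residue index (NA = unmapped),
#'   as returned by [map_columns_to_residues()].
#' @param structure A [structure_model()].
#' @return Data frame of class `site_instances`: columns `paralog` ("A" or
#'   "B"), `column`, `residue_index`, `x`, `y`, `z`, `shared`.
#' @export
build_instances <- function(sites_a, sites_b, mapping, structure) {
  stopifnot(inherits(sites_a, "site_set"), inherits(sites_b, "site_set"),
            inherits(structure, "structure_model"))
  shared_cols <- intersect(sites_a$columns, sites_b$columns)
  one <- function(cols, paralog) {
    if (length(cols) == 0L) return(NULL)
    if (any(cols > length(mapping))) {
      stop("selected column exceeds mapping length")
    }
    res <- mapping[cols]
    data.frame(paralog = paralog, column = cols, residue_index = res,
               stringsAsFactors = FALSE)
  }
  inst <- rbind(one(sites_a$columns, "A"), one(sites_b$columns, "B"))
  if (is.null(inst) || nrow(inst) == 0L) stop("no selected sites to place")
  unmapped <- is.na(inst$residue_index)
  if (all(unmapped)) stop("all selected columns are unmapped")
  if (any(unmapped)) {
    message(sprintf("dropping %d unmapped selected column(s)",
                    sum(unmapped)))
    inst <- inst[!unmapped, , drop = FALSE]
  }
  ridx <- match(inst$residue_index, structure$residues$residue_index)
  if (anyNA(ridx)) stop("mapped residue index not present in structure")
  inst$x <- structure$residues$x[ridx]
  inst$y <- structure$residues$y[ridx]
  inst$z <- structure$residues$z[ridx]
  inst$shared <- inst$column %in% shared_cols
  rownames(inst) <- NULL
  class(inst) <- c("site_instances", "data.frame")
  inst
}

# Twin exclusion mask: exclude[i, j] is TRUE when j may not serve as i's
# neighbor — itself, or the co-located other-paralog instance of the same
# shared column (otherwise every shared site trivially matches itself at
# distance zero).
instance_exclusion <- function(inst) {
  n <- nrow(inst)
  excl <- diag(TRUE, n)
  same_col <- outer(inst$column, inst$column, "==")
  twin <- same_col & outer(inst$shared, inst$shared, "&") &
    outer(inst$paralog, inst$paralog, "!=")
  excl | twin
}

# Core tally used for both the observed table and permutation replicates:
# geometry (dist, exclusion) fixed, labels free. An instance's neighbor
# counts as "same" when it has the same label or is a shared site (both
# members of a co-located twin pair, i.e. selected in both paralogs).
affiliation_tally <- function(dist, excl, labels, shared,
                              residue_index, paralog_order) {
  n <- nrow(dist)
  out <- c(A_same = 0L, A_other = 0L, B_same = 0L, B_other = 0L)
  for (i in seq_len(n)) {
    d <- dist[i, ]
    d[excl[i, ]] <- Inf
    if (all(!is.finite(d))) stop("instance has no eligible neighbor")
    # Deterministic tie-break: smallest distance, then lower residue
    # index, then paralog A before B.
    ord <- order(d, residue_index, paralog_order)
    j <- ord[1L]
    same <- labels[j] == labels[i] || shared[j]
    key <- paste0(labels[i], "_", if (same) "same" else "other")
    out[key] <- out[key] + 1L
  }
  out
}

#' Nearest-selected-site affiliation counts
#'
#' For every site instance, finds the Euclidean-nearest other instance
#' (excluding itself and, for a shared site, its co-located twin) and
#' classifies that neighbor as belonging to the same paralog or the other.
#' A neighbor that is itself under selection in both paralogs counts as
#' "same" regardless of which paralog's instance it is. Distance ties are
#' broken deterministically by lower residue index, then paralog A before
#' B.
#'
#' @param instances A `site_instances` data frame from [build_instances()].
#' @return Named integer vector `(A_same, A_other, B_same, B_other)`, with
#'   the per-instance neighbor table attached as attribute `"detail"`.
#' @export
nearest_affiliations <- function(instances) {
  inst <- instances
  stopifnot(is.data.frame(inst), nrow(inst) >= 2L)
  if (length(unique(inst$paralog)) < 2L) {
    stop("need selected sites in both paralogs")
  }
  xyz <- as.matrix(inst[, c("x", "y", "z")])
  if (nrow(unique(xyz)) < 2L) stop("fewer than 2 distinct coordinates")
  dd <- as.matrix(stats::dist(xyz))
  excl <- instance_exclusion(inst)
  # Non-twin co-located instances would self-match at distance 0; allowed,
  # but an instance must have at least one eligible neighbor.
  out <- affiliation_tally(
    dd, excl, inst$paralog, inst$shared, inst$residue_index,
    match(inst$paralog, c("A", "B"))
  )
  detail_j <- integer(nrow(inst))
  for (i in seq_len(nrow(inst))) {
    d <- dd[i, ]
    d[excl[i, ]] <- Inf
    detail_j[i] <- order(d, inst$residue_index,
                         match(inst$paralog, c("A", "B")))[1L]
  }
  attr(out, "detail") <- data.frame(
    paralog = inst$paralog, residue_index = inst$residue_index,
    neighbor_residue = inst$residue_index[detail_j],
    neighbor_paralog = inst$paralog[detail_j],
    neighbor_shared = inst$shared[detail_j],
    distance = dd[cbind(seq_len(nrow(inst)), detail_j)]
  )
  out
}

#' Expected affiliation counts under random labeling
#'
#' Under the null that paralog labels are exchangeable over the fixed site
#' positions, the nearest neighbor of an A instance is equally likely to be
#' any of the other `n_a + n_b - 1` instances, of which `n_a - 1` share its
#' label; hence expected `A_same = n_a (n_a - 1) / (n_a + n_b - 1)` and
#' analogously for the other three cells. Per-paralog totals are preserved
#' by construction.
#'
#' @param n_a,n_b Instance counts per paralog (shared sites count in both).
#' @return Named numeric vector `(A_same, A_other, B_same, B_other)`.
#' @export
expected_affiliations <- function(n_a, n_b) {
  stopifnot(is_count(n_a), is_count(n_b))
  if (n_a < 1 || n_b < 1) stop("both paralogs need at least one site")
  if (n_a + n_b < 3) stop("need at least 3 site instances in total")
  m <- n_a + n_b - 1
  c(A_same = n_a * (n_a - 1) / m, A_other = n_a * n_b / m,
    B_same = n_b * (n_b - 1) / m, B_other = n_b * n_a / m)
}

#' Chi-square test of nearest-neighbor paralog affiliation
#'
#' Goodness-of-fit chi-square over the four affiliation cells (A to same,
#' A to other, B to same, B to other) with 3 degrees of freedom and
#' upper-tail p-value. The chi-square reference distribution ignores the
#' dependence between nearest-neighbor outcomes; see the permutation
#' option of [neighbor_test()] for a dependence-respecting alternative.
#'
#' @param observed,expected Numeric vectors of 4 cell counts, same order.
#' @return List with `statistic`, `df` (3), `p_value`, `observed`,
#'   `expected`.
#' @export
affiliation_chi_square <- function(observed, expected) {
  stopifnot(length(observed) == 4L, length(expected) == 4L)
  if (any(expected <= 0)) stop("expected cell count of 0")
  chi2 <- sum((observed - expected)^2 / expected)
  list(
    statistic = chi2, df = 3L,
    p_value = stats::pchisq(chi2, df = 3L, lower.tail = FALSE),
    observed = observed, expected = expected
  )
}

#' Nearest-selected-site paralog-affiliation test
#'
#' Tests whether a selected site's nearest selected site in 3D space
#' belongs to its own paralog more often than random labeling predicts —
#' the signature of paralog-specific spatial clusters. Shared sites
#' contribute one instance per paralog and a shared neighbor always counts
#' as "same". The default p-value comes from the chi-square distribution
#' with 3 df; `null = "permutation"` instead shuffles paralog labels over
#' the fixed positions and reports the fraction of shuffles with a
#' chi-square statistic at least as large as observed.
#'
#' @inheritParams build_instances
#' @param null `"chi2"` or `"permutation"`.
#' @param n_perm Label shuffles for the permutation null (default 10000).
#' @param seed Optional RNG seed for the permutation null.
#' @return Object of class `neighbor_test_result`: `observed`, `expected`,
#'   `statistic`, `df`, `p_value`, `null`, `n_a`, `n_b`, and for the
#'   permutation null `n_perm` and `seed`.
#' @export
neighbor_test <- function(sites_a, sites_b, mapping, structure,
                          null = c("chi2", "permutation"),
                          n_perm = 10000L, seed = NULL) {
  null <- match.arg(null)
  inst <- build_instances(sites_a, sites_b, mapping, structure)
  observed <- nearest_affiliations(inst)
  n_a <- sum(inst$paralog == "A")
  n_b <- sum(inst$paralog == "B")
  expected <- expected_affiliations(n_a, n_b)
  chi <- affiliation_chi_square(observed, expected)
  res <- list(
    observed = observed, expected = expected,
    statistic = chi$statistic, df = chi$df, p_value = chi$p_value,
    null = null, n_a = n_a, n_b = n_b
  )
  if (null == "permutation") {
    xyz <- as.matrix(inst[, c("x", "y", "z")])
    dd <- as.matrix(stats::dist(xyz))
    excl <- instance_exclusion(inst)
    ridx <- inst$residue_index
    perm_stats <- with_seed(seed, {
      vapply(seq_len(n_perm), function(k) {
        lab <- sample(inst$paralog)
        # Shared status under shuffled labels: both members of a
        # co-located twin pair still exist; a pair is "both-paralog" when
        # its two members receive different labels.
        shared_k <- rep(FALSE, nrow(inst))
        for (cl in unique(inst$column[inst$shared])) {
          idx <- which(inst$column == cl & inst$shared)
          if (length(idx) == 2L && lab[idx[1L]] != lab[idx[2L]]) {
            shared_k[idx] <- TRUE
          }
        }
        obs_k <- affiliation_tally(dd, excl, lab, shared_k, ridx,
                                   match(lab, c("A", "B")))
        sum((obs_k - expected)^2 / expected)
      }, numeric(1L))
    })
    res$p_value <- mean(perm_stats >= chi$statistic)
    res$n_perm <- as.integer(n_perm)
    res$seed <- seed
  }
  class(res) <- "neighbor_test_result"
  res
}

#' @export
print.neighbor_test_result <- function(x, ...) {
  cat(sprintf(
    paste0("Nearest-selected-site affiliation test (%s null)\n",
           "  instances: %d A, %d B\n",
           "  observed:  A_same %d, A_other %d, B_same %d, B_other %d\n",
           "  expected:  %s\n",
           "  chi2 = %.4g (df = %d), p = %.4g\n"),
    x$null, x$n_a, x$n_b,
    x$observed[1L], x$observed[2L], x$observed[3L], x$observed[4L],
    paste(sprintf("%.2f", x$expected), collapse = ", "),
    x$statistic, x$df, x$p_value
  ))
  invisible(x)
}
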