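#' Build the ordered category string of selected sites
#'
#' Orders the union of the two paralogs' selected columns along the
#' alignment and labels each column `A_ONLY`, `B_ONLY` or `BOTH`. The
#' resulting string is the data the multi-category runs test operates on.
#' With `exclude_both = TRUE`, columns selected in both paralogs are
#' dropped, giving the two-category variant of the test.
#'
#' @param sites_a,sites_b [site_set()] objects for the two paralogs.
#' @param aln_length Alignment length L; every selected column must be <= L.
#' @param exclude_both Drop columns selected in both paralogs.
#' @return An object of class `category_string`: list with `categories`
#'   (character vector over selected columns) and `source_columns`
#'   (ascending alignment columns).
#' @export
build_category_string <- function(sites_a, sites_b, aln_length,
                                  exclude_both = FALSE) {
  stopifnot(inherits(sites_a, "site_set"), inherits(sites_b, "site_set"),
            is_count(aln_length), aln_length >= 1)
  a <- sites_a$columns
  b <- sites_b$columns
  if (length(c(a, b)) && max(c(a, b)) > aln_length) {
    stop("selected column exceeds alignment length")
  }
  cols <- sort(union(a, b))
  cats <- ifelse(cols %in% a & cols %in% b, "BOTH",
                 ifelse(cols %in% a, "A_ONLY", "B_ONLY"))
  if (exclude_both) {
    keep <- cats != "BOTH"
    cols <- cols[keep]
    cats <- cats[keep]
  }
  if (length(cols) == 0L) stop("no selected sites")
  structure(
    list(categories = cats, source_columns = as.integer(cols)),
    class = "category_string"
  )
}

#' Count runs in a category string
#'
#' A run is a maximal block of identical adjacent categories; the count
#' equals the number of adjacent unequal pairs plus one. Fewer, longer runs
#' indicate clustering of each paralog's selected sites along the
#' alignment.
#'
#' @param s A `category_string` from [build_category_string()], or a plain
#'   character vector of categories.
#' @return Integer run count in `[1, length(s)]`.
#' @export
count_runs <- function(s) {
  cats <- if (inherits(s, "category_string")) s$categories else s
  if (length(cats) == 0L) stop("empty category string")
  sum(cats[-1L] != cats[-length(cats)]) + 1L
}

#' Simulate the bootstrap null distribution of run counts
#'
#' Each replicate simulates an alignment of `length` columns in which every
#' column is independently selected in paralog A with probability `p_a` and
#' in paralog B with probability `p_b`; columns selected in both are marked
#' `BOTH` (or dropped under `exclude_both`), columns selected in neither are
#' dropped, and the run count of the resulting category string is recorded.
#' A replicate whose string is empty records 0 runs, which is below any
#' attainable observed count and therefore conservative.
#'
#' Replicates are drawn sequentially from one seeded generator (per
#' replicate: the A indicators, then the B indicators), so a seed fully
#' determines the null.
#'
#' @param p_a,p_b Per-column selection probabilities in `[0, 1]`.
#' @param length Number of alignment columns per replicate.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Optional RNG seed.
#' @param exclude_both Drop columns simulated as selected in both paralogs.
#' @return Object of class `runs_null`: list with `length`, `p_a`, `p_b`,
#'   `n_reps`, `seed`, `exclude_both` and integer `run_counts`.
#' @export
simulate_null <- function(p_a, p_b, length, n_reps = 1000L, seed = NULL,
                          exclude_both = FALSE) {
  stopifnot(
    is.numeric(p_a), p_a >= 0, p_a <= 1,
    is.numeric(p_b), p_b >= 0, p_b <= 1,
    is_count(length), length >= 1, is_count(n_reps), n_reps >= 1
  )
  n_cols <- as.integer(length)
  run_counts <- with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      a <- stats::runif(n_cols) < p_a
      b <- stats::runif(n_cols) < p_b
      code <- a + 2L * b               # 0 none, 1 A_ONLY, 2 B_ONLY, 3 BOTH
      code <- code[code > 0L]
      if (exclude_both) code <- code[code != 3L]
      n_kept <- base::length(code)
      if (n_kept == 0L) return(0L)
      sum(code[-1L] != code[-n_kept]) + 1L
    }, integer(1L))
  })
  structure(
    list(length = n_cols, p_a = p_a, p_b = p_b,
         n_reps = as.integer(n_reps), seed = seed,
         exclude_both = exclude_both, run_counts = run_counts),
    class = "runs_null"
  )
}

#' One-sided bootstrap p-value for an observed run count
#'
#' The p-value is the fraction of null replicates whose run count is less
#' than or equal to the observed count — the probability that random site
#' placement produces clustering at least as strong as observed. No
#' pseudo-count is added, so the minimum attainable p is 0; the replicate
#' count is reported alongside in [runs_test()] results.
#'
#' @param null A `runs_null` from [simulate_null()], or an integer vector
#'   of null run counts.
#' @param observed Observed run count.
#' @return p-value in `[0, 1]`.
#' @export
runs_p_value <- function(null, observed) {
  counts <- if (inherits(null, "runs_null")) null$run_counts else null
  stopifnot(length(counts) >= 1L, is_count(observed))
  mean(counts <= observed)
}

#' Multi-category runs test for clustering of selected sites
#'
#' Tests whether the selected sites of two paralogs are non-randomly
#' distributed (clustered) along their alignment. The observed data string
#' labels each selected column `A_ONLY`, `B_ONLY` or `BOTH` in alignment
#' order; its run count is compared with a bootstrap null in which each of
#' the L columns is independently selected in each paralog at that
#' paralog's observed marginal proportion (`|A|/L` and `|B|/L`, a `BOTH`
#' column counting toward both). Small p-values mean fewer, longer runs —
#' sites clustered by paralog — than expected by chance.
#'
#' @inheritParams build_category_string
#' @param n_reps Bootstrap replicates for the null (default 1000).
#' @param seed Optional RNG seed for the null.
#' @param exclude_both Run the two-category variant in which columns
#'   selected in both paralogs are eliminated from observed and simulated
#'   strings alike.
#' @return Object of class `runs_test_result`: `observed_runs`, `p_value`,
#'   `variant` (`"three_category"` or `"two_category"`), `p_a`, `p_b`,
#'   `n_sites`, and the `runs_null` used.
#' @export
runs_test <- function(sites_a, sites_b, aln_length, n_reps = 1000L,
                      seed = NULL, exclude_both = FALSE) {
  s <- build_category_string(sites_a, sites_b, aln_length,
                             exclude_both = exclude_both)
  observed <- count_runs(s)
  # Marginal per-paralog proportions: BOTH columns are selected sites in
  # each paralog, so they enter both numerators.
  p_a <- length(sites_a$columns) / aln_length
  p_b <- length(sites_b$columns) / aln_length
  null <- simulate_null(p_a, p_b, aln_length, n_reps = n_reps, seed = seed,
                        exclude_both = exclude_both)
  structure(
    list(
      observed_runs = observed,
      p_value = runs_p_value(null, observed),
      variant = if (exclude_both) "two_category" else "three_category",
      p_a = p_a, p_b = p_b,
      n_sites = length(s$categories),
      null = null
    ),
    class = "runs_test_result"
  )
}

#' @export
print.runs_test_result <- function(x, ...) {
  cat(sprintf(
    paste0("Multi-category runs test (%s)\n",
           "  sites in string: %d (p_a = %.3f, p_b = %.3f)\n",
           "  observed runs:   %d\n",
           "  bootstrap p:     %.4g  (%d replicates)\n"),
    x$variant, x$n_sites, x$p_a, x$p_b, x$observed_runs,
    x$p_value, x$null$n_reps
  ))
  invisible(x)
}
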