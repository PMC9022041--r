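#' Run every clustering test on one paralog-site bundle
#'
#' Orchestrates the full analysis: maps alignment columns to structure
#' residues, runs the multi-category runs test (three-category and
#' both-excluded two-category variants), the plane-partition chi-square
#' tests (plane of best fit and its perpendicular, each paralog
#' separately), and the nearest-selected-site affiliation test, and
#' assembles a single reproducible report. No multiple-testing correction
#' is applied — the raw p-values are reported together with the number of
#' tests run.
#'
#' @param structure A [structure_model()].
#' @param alignment A [pair_alignment()] of the two paralogs.
#' @param sites_a,sites_b [site_set()] objects (A is the paralog whose row
#'   sits on the structure unless `reference_row = "b"`).
#' @param reference_row Which alignment row matches the structure
#'   sequence: `"a"` or `"b"`.
#' @param offset Residue offset passed to [map_columns_to_residues()].
#' @param n_reps Bootstrap replicates for the runs-test null.
#' @param seed RNG seed; the two runs-test variants use `seed` and
#'   `seed + 1`, the permutation null (if selected) `seed + 2`.
#' @param plane_method `"ols"` or `"pca"` for [fit_best_plane()].
#' @param neighbor_null `"chi2"` or `"permutation"`.
#' @param n_perm Label shuffles when `neighbor_null = "permutation"`.
#' @return Object of class `analysis_report`: nested list with `inputs`
#'   (identifiers, counts, thresholds, seeds, flags), `runs_test`,
#'   `plane_test`, `neighbor_test`, `annotations` (per-residue category
#'   and divergence calls) and `n_tests`.
#' @export
run_all <- function(structure, alignment, sites_a, sites_b,
                    reference_row = "a", offset = 0L,
                    n_reps = 1000L, seed = 1L,
                    plane_method = c("ols", "pca"),
                    neighbor_null = c("chi2", "permutation"),
                    n_perm = 10000L) {
  plane_method <- match.arg(plane_method)
  neighbor_null <- match.arg(neighbor_null)
  seed <- as.integer(seed)
  n_reps <- as.integer(n_reps)
  n_perm <- as.integer(n_perm)
  offset <- as.integer(offset)
  fail <- function(stage, e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  }

  mapping <- tryCatch(
    map_columns_to_residues(alignment, reference_row, structure,
                            offset = offset),
    error = function(e) fail("map_columns_to_residues", e)
  )

  runs3 <- tryCatch(
    runs_test(sites_a, sites_b, alignment$length, n_reps = n_reps,
              seed = seed),
    error = function(e) fail("runs_test(three_category)", e)
  )
  runs2 <- tryCatch(
    runs_test(sites_a, sites_b, alignment$length, n_reps = n_reps,
              seed = seed + 1L, exclude_both = TRUE),
    error = function(e) fail("runs_test(two_category)", e)
  )

  plane <- tryCatch(fit_best_plane(structure, method = plane_method),
                    error = function(e) fail("fit_best_plane", e))
  perp <- tryCatch(perpendicular_plane(plane, structure),
                   error = function(e) fail("perpendicular_plane", e))
  res_a <- mapping[sites_a$columns]
  res_b <- mapping[sites_b$columns]
  res_a <- res_a[!is.na(res_a)]
  res_b <- res_b[!is.na(res_b)]
  plane_results <- tryCatch(
    list(
      main = list(
        A = plane_partition_test(structure, plane, res_a),
        B = plane_partition_test(structure, plane, res_b)
      ),
      perpendicular = list(
        A = plane_partition_test(structure, perp, res_a),
        B = plane_partition_test(structure, perp, res_b)
      )
    ),
    error = function(e) fail("plane_partition_test", e)
  )

  neighbor <- tryCatch(
    neighbor_test(sites_a, sites_b, mapping, structure,
                  null = neighbor_null, n_perm = n_perm,
                  seed = seed + 2L),
    error = function(e) fail("neighbor_test", e)
  )

  shared_cols <- intersect(sites_a$columns, sites_b$columns)
  div_cols <- divergent_sites(alignment)
  categ <- rep("none", nrow(structure$residues))
  categ[stats::na.omit(mapping[setdiff(sites_a$columns, shared_cols)])] <- "A"
  categ[stats::na.omit(mapping[setdiff(sites_b$columns, shared_cols)])] <- "B"
  categ[stats::na.omit(mapping[shared_cols])] <- "BOTH"
  annotations <- data.frame(
    residue_index = structure$residues$residue_index,
    category = categ,
    divergent = structure$residues$residue_index %in%
      stats::na.omit(mapping[div_cols])
  )

  report <- list(
    inputs = list(
      alignment = list(id_a = alignment$id_a, id_b = alignment$id_b,
                       length = alignment$length),
      structure = list(chain_id = structure$chain_id,
                       n_residues = nrow(structure$residues)),
      sites = list(
        paralog_a = sites_a$paralog_id, n_a = length(sites_a$columns),
        paralog_b = sites_b$paralog_id, n_b = length(sites_b$columns),
        n_shared = length(shared_cols),
        threshold_a = sites_a$threshold, threshold_b = sites_b$threshold
      ),
      reference_row = reference_row, offset = as.integer(offset),
      seed = as.integer(seed), n_reps = as.integer(n_reps),
      plane_method = plane_method, neighbor_null = neighbor_null,
      percent_identity_all = percent_identity(alignment, "all"),
      percent_identity_ungapped = percent_identity(alignment, "ungapped")
    ),
    runs_test = list(
      three_category = runs_summary(runs3),
      two_category = runs_summary(runs2)
    ),
    plane_test = list(
      plane = plane_summary(plane),
      perpendicular = plane_summary(perp),
      main = lapply(plane_results$main, side_summary),
      perpendicular_axis = lapply(plane_results$perpendicular, side_summary)
    ),
    neighbor_test = neighbor_summary(neighbor),
    annotations = annotations,
    n_tests = 7L
  )
  class(report) <- "analysis_report"
  report
}

runs_summary <- function(r) {
  list(observed_runs = r$observed_runs, p_value = r$p_value,
       variant = r$variant, p_a = r$p_a, p_b = r$p_b,
       n_sites = r$n_sites, n_reps = r$null$n_reps,
       seed = if (is.null(r$null$seed)) NA else r$null$seed)
}

plane_summary <- function(p) {
  list(unit_normal = unname(p$unit_normal), offset = p$offset,
       labels = p$labels)
}

side_summary <- function(s) {
  list(observed = as.list(s$observed), expected = as.list(s$expected),
       side_sizes = as.list(s$side_sizes),
       chi2 = s$statistic, df = s$df, p_value = s$p_value)
}

neighbor_summary <- function(x) {
  out <- list(observed = as.list(as.integer(x$observed)),
              expected = as.list(unname(x$expected)),
              chi2 = x$statistic, df = x$df, p_value = x$p_value,
              null = x$null, n_a = x$n_a, n_b = x$n_b)
  names(out$observed) <- names(x$observed)
  names(out$expected) <- names(x$expected)
  if (!is.null(x$n_perm)) out$n_perm <- x$n_perm
  out
}

#' Run the full analysis from a configuration list or JSON file
#'
#' The configuration names the input files and options: `pdb`, `chain`
#' (optional), `model_number` (optional), `alignment`,
#' `alignment_format` (`"fasta"`/`"clustal"`), `sites_a`, `sites_b`,
#' `threshold` (default 0.75), plus any of the [run_all()] options
#' (`reference_row`, `offset`, `n_reps`, `seed`, `plane_method`,
#' `neighbor_null`, `n_perm`).
#'
#' @param config Named list, or path to a JSON file holding one.
#' @return An `analysis_report` (see [run_all()]).
#' @export
run_all_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config),
            all(c("pdb", "alignment", "sites_a", "sites_b") %in%
                  names(config)))
  get_opt <- function(name, default) {
    if (is.null(config[[name]])) default else config[[name]]
  }
  threshold <- get_opt("threshold", 0.75)
  structure <- read_calpha(config$pdb, chain_id = config$chain,
                           model_number = config$model_number)
  alignment <- read_pair_alignment(config$alignment,
                                   format = get_opt("alignment_format",
                                                    "fasta"))
  run_all(
    structure, alignment,
    read_sites(config$sites_a, "A", threshold),
    read_sites(config$sites_b, "B", threshold),
    reference_row = get_opt("reference_row", "a"),
    offset = get_opt("offset", 0L),
    n_reps = get_opt("n_reps", 1000L),
    seed = get_opt("seed", 1L),
    plane_method = get_opt("plane_method", "ols"),
    neighbor_null = get_opt("neighbor_null", "chi2"),
    n_perm = get_opt("n_perm", 10000L)
  )
}

#' Write an analysis report to JSON (and optionally a residue TSV)
#'
#' The JSON report echoes all inputs, seeds and flags, so identical inputs
#' give byte-identical reports. The optional TSV holds one row per residue
#' with its selected-site category (`A`, `B`, `BOTH`, `none`) and a
#' divergence flag, in a form molecular viewers can consume.
#'
#' @param report An `analysis_report` from [run_all()].
#' @param json_path Output JSON path.
#' @param tsv_path Optional output TSV path for per-residue annotations.
#' @return `json_path`, invisibly.
#' @export
write_report <- function(report, json_path, tsv_path = NULL) {
  stopifnot(inherits(report, "analysis_report"))
  out <- unclass(report)
  out$annotations <- NULL
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(tsv_path)) {
    utils::write.table(report$annotations, tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(json_path)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Paralog selected-site clustering report\n")
  cat(sprintf("  alignment: %s / %s (%d columns, %.1f%% identity)\n",
              x$inputs$alignment$id_a, x$inputs$alignment$id_b,
              x$inputs$alignment$length, x$inputs$percent_identity_all))
  cat(sprintf("  sites: %d A, %d B (%d shared)\n",
              x$inputs$sites$n_a, x$inputs$sites$n_b,
              x$inputs$sites$n_shared))
  cat(sprintf("  runs test: p = %.4g (three-category), p = %.4g (both excluded)\n",
              x$runs_test$three_category$p_value,
              x$runs_test$two_category$p_value))
  cat(sprintf("  plane test (main axis): p_A = %.4g, p_B = %.4g\n",
              x$plane_test$main$A$p_value, x$plane_test$main$B$p_value))
  cat(sprintf("  plane test (perpendicular): p_A = %.4g, p_B = %.4g\n",
              x$plane_test$perpendicular_axis$A$p_value,
              x$plane_test$perpendicular_axis$B$p_value))
  cat(sprintf("  neighbor test: chi2 = %.4g, p = %.4g (%s)\n",
              x$neighbor_test$chi2, x$neighbor_test$p_value,
              x$neighbor_test$null))
  cat(sprintf("  %d tests run; p-values are uncorrected\n", x$n_tests))
  invisible(x)
}
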