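#' Specification for a synthetic paralog-site dataset
#'
#' Collects the parameters of the synthetic generator that emulates the
#' study design the clustering tests assume: one chain of C-alpha
#' coordinates, a gapless two-paralog alignment over its residues, and two
#' selected-site sets. Defaults emulate a 142-column paralog alignment with
#' marginal selection fractions 62/142 and 30/142 — the site densities of a
#' pair of rapidly evolving sperm-protein paralogs mapped onto one
#' structure.
#'
#' @param n_residues Chain length (>= 4); default 142.
#' @param chain_model `"random_walk"` (uniform random step directions) or
#'   `"helix"` (ideal alpha-helical twist).
#' @param bond_length Consecutive C-alpha spacing in Angstrom; default 3.8.
#' @param p_a,p_b Per-column selection probabilities; defaults 62/142 and
#'   30/142.
#' @param clustering `NULL` for spatially uniform (null) site placement, or
#'   a list with `focus_a`, `focus_b` (residue indices of the two cluster
#'   centers) and `decay_length` (Angstrom; smaller = tighter clusters).
#' @param seed Optional base RNG seed; [generate_structure()] uses it
#'   directly and [generate_sites()] uses `seed + 1` so the two draws are
#'   independent streams.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_residues = 142L,
                           chain_model = c("random_walk", "helix"),
                           bond_length = 3.8,
                           p_a = 62 / 142, p_b = 30 / 142,
                           clustering = NULL, seed = NULL) {
  chain_model <- match.arg(chain_model)
  stopifnot(is_count(n_residues), n_residues >= 4L,
            is.numeric(bond_length), bond_length > 0,
            p_a >= 0, p_a <= 1, p_b >= 0, p_b <= 1)
  if (!is.null(clustering)) {
    stopifnot(
      is.list(clustering),
      all(c("focus_a", "focus_b", "decay_length") %in% names(clustering)),
      clustering$decay_length > 0,
      is_count(clustering$focus_a), is_count(clustering$focus_b),
      clustering$focus_a >= 1, clustering$focus_a <= n_residues,
      clustering$focus_b >= 1, clustering$focus_b <= n_residues
    )
  }
  structure(
    list(n_residues = as.integer(n_residues), chain_model = chain_model,
         bond_length = bond_length, p_a = p_a, p_b = p_b,
         clustering = clustering, seed = seed),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic C-alpha chain
#'
#' `random_walk` chains step in uniformly random directions with exact
#' `bond_length` spacing, giving a compact unstructured coil.
#' `helix` chains follow an ideal alpha-helical geometry: radius 2.3
#' Angstrom, 100 degrees of twist per residue, and the rise per residue
#' chosen so that the consecutive C-alpha distance equals `bond_length`
#' exactly. Residue identities are drawn uniformly from the 20 amino
#' acids.
#'
#' @param spec A [synthetic_spec()].
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return A [structure_model()] with chain id `"S"`.
#' @export
generate_structure <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_residues
  b <- spec$bond_length
  with_seed(seed, {
    if (spec$chain_model == "random_walk") {
      steps <- matrix(stats::rnorm(3L * (n - 1L)), ncol = 3L)
      steps <- steps / sqrt(rowSums(steps^2)) * b
      xyz <- rbind(c(0, 0, 0), apply(steps, 2L, cumsum))
    } else {
      radius <- 2.3
      twist <- 100 * pi / 180
      chord <- 2 * radius * sin(twist / 2)
      if (chord >= b) stop("bond_length too short for helix radius/twist")
      rise <- sqrt(b^2 - chord^2)
      i <- seq_len(n) - 1L
      xyz <- cbind(radius * cos(i * twist), radius * sin(i * twist),
                   i * rise)
    }
    letters1 <- sample(names(AA1), n, replace = TRUE)
    structure_model(
      chain_id = "S",
      residue_index = seq_len(n),
      residue_name = aa1_to_3(letters1),
      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L]
    )
  })
}

#' Generate synthetic selected-site sets and their paralog alignment
#'
#' With `clustering = NULL` each column is selected independently in each
#' paralog with probabilities `p_a` / `p_b` — exactly the bootstrap null of
#' the runs test. With clustering, each paralog's per-residue selection
#' probability decays exponentially with 3D distance from that paralog's
#' focus residue, `p_i` proportional to `exp(-d_i / decay_length)`, scaled
#' so the expected site count stays `n * p` (probabilities are capped at
#' 1, so very tight clusters can fall slightly short of the nominal
#' count). As `decay_length` grows the probabilities flatten back to the
#' uniform null.
#'
#' The returned alignment is gapless: row A is the structure sequence and
#' row B carries a substitution at every selected column, so the divergent
#' columns are exactly the union of the two site sets and every column
#' maps to the residue of the same index.
#'
#' Posteriors are drawn uniformly from `[0.75, 1]` so the sets pass the
#' default retention threshold.
#'
#' @param spec A [synthetic_spec()].
#' @param structure A [structure_model()] from [generate_structure()].
#' @param seed RNG seed; defaults to `spec$seed + 1`.
#' @return List with `sites_a`, `sites_b` ([site_set()]), `alignment`
#'   ([pair_alignment()]) and `mapping` (identity column-to-residue map).
#' @export
generate_sites <- function(spec, structure,
                           seed = if (is.null(spec$seed)) NULL else
                             spec$seed + 1L) {
  stopifnot(inherits(spec, "synthetic_spec"),
            inherits(structure, "structure_model"))
  n <- spec$n_residues
  stopifnot(nrow(structure$residues) == n)
  if (spec$p_a > 0 && n * spec$p_a < 1) {
    stop("expected site count below 1 for paralog A")
  }
  if (spec$p_b > 0 && n * spec$p_b < 1) {
    stop("expected site count below 1 for paralog B")
  }

  probs_for <- function(p, focus) {
    if (is.null(spec$clustering)) return(rep(p, n))
    xyz <- coords_matrix(structure)
    d <- sqrt(colSums((t(xyz) - xyz[focus, ])^2))
    w <- exp(-d / spec$clustering$decay_length)
    pmin(1, w / sum(w) * n * p)
  }

  with_seed(seed, {
    pa <- probs_for(spec$p_a, spec$clustering$focus_a)
    pb <- probs_for(spec$p_b, spec$clustering$focus_b)
    sel_a <- which(stats::runif(n) < pa)
    sel_b <- which(stats::runif(n) < pb)
    post_a <- stats::runif(length(sel_a), 0.75, 1)
    post_b <- stats::runif(length(sel_b), 0.75, 1)

    row_a <- strsplit(structure$sequence, "")[[1L]]
    row_b <- row_a
    mutate <- sort(union(sel_a, sel_b))
    aa <- unname(AA3)
    for (i in mutate) {
      row_b[i] <- sample(setdiff(aa, row_a[i]), 1L)
    }
    list(
      sites_a = site_set("A", sel_a, post_a, threshold = 0.75),
      sites_b = site_set("B", sel_b, post_b, threshold = 0.75),
      alignment = pair_alignment("paralog_A", "paralog_B",
                                 paste(row_a, collapse = ""),
                                 paste(row_b, collapse = "")),
      mapping = seq_len(n)
    )
  })
}

#' Generate a complete synthetic analysis bundle
#'
#' Convenience wrapper producing structure, alignment, site sets and
#' mapping in one call, ready for [run_all()].
#'
#' @param spec A [synthetic_spec()].
#' @return List with `structure`, `alignment`, `sites_a`, `sites_b`,
#'   `mapping` and the `spec` used.
#' @export
generate_bundle <- function(spec) {
  structure <- generate_structure(spec)
  sites <- generate_sites(spec, structure)
  c(list(structure = structure, spec = spec), sites)
}
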