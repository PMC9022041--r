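# Shared fixtures and independent oracles, all built in code.

pdb_atom_line <- function(serial, resname, chain, resseq, x, y, z,
                          altloc = " ", atom = "CA") {
  sprintf("ATOM  %5d  %-3s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial, atom, altloc, resname, chain, resseq, x, y, z)
}

toy_pdb <- function(coords, resnames = NULL, chain = "A",
                    resseq = seq_len(nrow(coords))) {
  if (is.null(resnames)) resnames <- rep("ALA", nrow(coords))
  lines <- vapply(seq_len(nrow(coords)), function(i) {
    pdb_atom_line(i, resnames[i], chain, resseq[i],
                  coords[i, 1], coords[i, 2], coords[i, 3])
  }, character(1))
  paste(c(lines, "END"), collapse = "\n")
}

# Structure with residues spaced along a line (consecutive gap `step` A).
line_structure <- function(n, step = 3.8, seq_letters = NULL) {
  if (is.null(seq_letters)) seq_letters <- rep("A", n)
  structure_model(
    chain_id = "A",
    residue_index = seq_len(n),
    residue_name = vapply(seq_letters, selclust:::aa1_to_3, character(1)),
    x = step * (seq_len(n) - 1), y = rep(0, n), z = rep(0, n)
  )
}

# Random site-instance table, optionally containing shared (co-located
# twin) pairs; used to exercise the nearest-neighbor machinery directly.
random_instances <- function(n_a, n_b, n_shared = 0, box = 20) {
  stopifnot(n_shared <= min(n_a, n_b))
  n_pos <- n_a + n_b - n_shared
  xyz <- matrix(runif(3 * n_pos, 0, box), ncol = 3)
  cols <- seq_len(n_pos)
  a_cols <- cols[seq_len(n_a)]
  # Shared columns are the first n_shared of A's; B reuses them.
  b_cols <- c(a_cols[seq_len(n_shared)],
              setdiff(cols, a_cols)[seq_len(n_b - n_shared)])
  build_df <- function(cset, paralog) {
    data.frame(paralog = paralog, column = cset, residue_index = cset,
               x = xyz[cset, 1], y = xyz[cset, 2], z = xyz[cset, 3],
               stringsAsFactors = FALSE)
  }
  inst <- rbind(build_df(a_cols, "A"), build_df(sort(b_cols), "B"))
  shared_cols <- intersect(a_cols, b_cols)
  inst$shared <- inst$column %in% shared_cols
  rownames(inst) <- NULL
  class(inst) <- c("site_instances", "data.frame")
  inst
}

# Independent brute-force oracle for nearest_affiliations: literal
# all-pairs scan applying the twin-exclusion and shared-counts-as-same
# rules, written without reusing any package internals.
brute_affiliations <- function(inst) {
  n <- nrow(inst)
  out <- c(A_same = 0L, A_other = 0L, B_same = 0L, B_other = 0L)
  for (i in seq_len(n)) {
    best <- NA_integer_
    for (j in seq_len(n)) {
      if (j == i) next
      if (inst$shared[i] && inst$shared[j] &&
          inst$column[i] == inst$column[j] &&
          inst$paralog[i] != inst$paralog[j]) next  # co-located twin
      if (is.na(best)) { best <- j; next }
      di <- sqrt(sum((inst[j, c("x", "y", "z")] -
                        inst[i, c("x", "y", "z")])^2))
      db <- sqrt(sum((inst[best, c("x", "y", "z")] -
                        inst[i, c("x", "y", "z")])^2))
      better <- di < db ||
        (di == db && inst$residue_index[j] < inst$residue_index[best]) ||
        (di == db && inst$residue_index[j] == inst$residue_index[best] &&
           inst$paralog[j] < inst$paralog[best])
      if (better) best <- j
    }
    same <- inst$paralog[best] == inst$paralog[i] || inst$shared[best]
    key <- paste0(inst$paralog[i], "_", if (same) "same" else "other")
    out[key] <- out[key] + 1L
  }
  out
}

# Exact run-count distribution of the bootstrap null for small L by
# exhaustive enumeration of the 4^L per-column outcomes.
enumerate_runs_null <- function(p_a, p_b, L, exclude_both = FALSE) {
  probs <- c(none = (1 - p_a) * (1 - p_b), A = p_a * (1 - p_b),
             B = (1 - p_a) * p_b, BOTH = p_a * p_b)
  grid <- expand.grid(rep(list(names(probs)), L), stringsAsFactors = FALSE)
  out <- numeric(L + 1)          # index k+1 = P(runs == k), k = 0..L
  for (r in seq_len(nrow(grid))) {
    cats <- unlist(grid[r, ], use.names = FALSE)
    pr <- prod(probs[cats])
    cats <- cats[cats != "none"]
    if (exclude_both) cats <- cats[cats != "BOTH"]
    k <- if (length(cats) == 0) 0 else
      sum(cats[-1] != cats[-length(cats)]) + 1
    out[k + 1] <- out[k + 1] + pr
  }
  names(out) <- 0:L
  out
}

rigid_transform <- function(xyz, angles = c(0.4, 1.1, -0.7),
                            shift = c(5, -3, 12)) {
  rx <- matrix(c(1, 0, 0, 0, cos(angles[1]), -sin(angles[1]),
                 0, sin(angles[1]), cos(angles[1])), 3, byrow = TRUE)
  ry <- matrix(c(cos(angles[2]), 0, sin(angles[2]), 0, 1, 0,
                 -sin(angles[2]), 0, cos(angles[2])), 3, byrow = TRUE)
  rz <- matrix(c(cos(angles[3]), -sin(angles[3]), 0,
                 sin(angles[3]), cos(angles[3]), 0, 0, 0, 1), 3,
               byrow = TRUE)
  sweep(xyz %*% t(rz %*% ry %*% rx), 2, -shift)
}

transform_structure <- function(structure, ...) {
  xyz <- rigid_transform(coords_matrix(structure), ...)
  structure_model(structure$chain_id,
                  structure$residues$residue_index,
                  structure$residues$residue_name,
                  xyz[, 1], xyz[, 2], xyz[, 3])
}
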