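#' Construct a C-alpha structure model
#'
#' A `structure_model` holds one chain's backbone as an ordered set of
#' C-alpha coordinates, one per residue, together with the one-letter
#' sequence derived from the residue names. Residue indices are 1-based and
#' chain-sequential (first residue with a C-alpha atom is 1), not author
#' PDB numbering; use the `offset` argument of [map_columns_to_residues()]
#' to reconcile the two.
#'
#' @param chain_id Chain identifier (single string).
#' @param residue_index Integer vector, strictly increasing, 1-based.
#' @param residue_name Character vector of 3-letter residue codes.
#' @param x,y,z Numeric coordinate vectors in Angstrom.
#' @return An object of class `structure_model` with elements `chain_id`,
#'   `residues` (a data frame with columns `residue_index`, `residue_name`,
#'   `x`, `y`, `z`) and `sequence` (one-letter string).
#' @export
structure_model <- function(chain_id, residue_index, residue_name, x, y, z) {
  n <- length(residue_index)
  stopifnot(
    length(residue_name) == n, length(x) == n,
    length(y) == n, length(z) == n, n >= 1L
  )
  residue_index <- as.integer(residue_index)
  if (anyDuplicated(residue_index)) {
    stop("duplicate residue_index in structure model")
  }
  if (is.unsorted(residue_index, strictly = TRUE)) {
    stop("residue_index must be strictly increasing")
  }
  coords <- c(x, y, z)
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  res <- data.frame(
    residue_index = residue_index,
    residue_name = toupper(as.character(residue_name)),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      chain_id = as.character(chain_id),
      residues = res,
      sequence = paste(aa3_to_1(res$residue_name), collapse = "")
    ),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf(
    "structure_model: chain %s, %d residues\n  sequence: %s%s\n",
    x$chain_id, nrow(x$residues),
    substr(x$sequence, 1L, 60L),
    if (nchar(x$sequence) > 60L) "..." else ""
  ))
  invisible(x)
}

#' Coordinate matrix of a structure model
#'
#' @param structure A [structure_model()].
#' @return Numeric matrix with one row per residue and columns x, y, z;
#'   rownames are residue indices.
#' @export
coords_matrix <- function(structure) {
  stopifnot(inherits(structure, "structure_model"))
  m <- as.matrix(structure$residues[, c("x", "y", "z")])
  rownames(m) <- structure$residues$residue_index
  m
}

#' Read C-alpha coordinates from PDB text
#'
#' Parses fixed-width `ATOM` records and keeps one C-alpha per residue, in
#' file order. For multi-model (NMR ensemble) files only the requested
#' `MODEL` block is read; the default is the first model, the conventional
#' representative of a lowest-energy NMR ensemble. When one residue carries
#' several alternate locations the first-listed C-alpha wins and a warning
#' is emitted; PDB dialect quirks must not silently drop residues.
#'
#' @param pdb_text PDB file content: a single string or a character vector
#'   of lines. A path to an existing file is also accepted.
#' @param chain_id Chain to extract; default: the chain of the first CA atom.
#' @param model_number For multi-model files, which `MODEL` block to read
#'   (matched against the model serial number); default: first model.
#' @return A [structure_model()].
#' @export
read_calpha <- function(pdb_text, chain_id = NULL, model_number = NULL) {
  lines <- pdb_lines(pdb_text)
  rec <- substr(lines, 1L, 6L)

  # Partition lines into MODEL blocks; a single-model file is one block.
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) == 0L) {
    if (!is.null(model_number) && !identical(as.integer(model_number), 1L)) {
      stop("model_number requested but file has a single implicit model")
    }
    block <- lines
  } else {
    serials <- suppressWarnings(
      as.integer(substr(lines[model_starts], 7L, 80L))
    )
    pick <- if (is.null(model_number)) 1L else {
      match(as.integer(model_number), serials)
    }
    if (is.na(pick)) {
      stop(sprintf("MODEL %s not found in PDB text", model_number))
    }
    from <- model_starts[pick] + 1L
    ends <- which(rec == "ENDMDL")
    to <- ends[ends >= from][1L]
    if (is.na(to)) to <- length(lines) + 1L
    block <- lines[seq(from, to - 1L)]
  }

  atom <- block[substr(block, 1L, 6L) == "ATOM  "]
  name <- trimws(substr(atom, 13L, 16L))
  atom <- atom[name == "CA"]
  if (length(atom) == 0L) stop("no CA atoms found in PDB text")

  chain <- substr(atom, 22L, 22L)
  if (is.null(chain_id)) chain_id <- chain[1L]
  atom <- atom[chain == chain_id]
  if (length(atom) == 0L) {
    stop(sprintf("no CA atoms for chain '%s'", chain_id))
  }

  # Residue identity in the file is (resSeq, iCode); altlocs duplicate it.
  res_key <- paste0(substr(atom, 23L, 26L), substr(atom, 27L, 27L))
  dup <- duplicated(res_key)
  if (any(dup)) {
    warning(sprintf(
      "%d duplicate CA record(s) (alternate locations); keeping first-listed",
      sum(dup)
    ))
    atom <- atom[!dup]
  }

  structure_model(
    chain_id = chain_id,
    residue_index = seq_along(atom),
    residue_name = trimws(substr(atom, 18L, 20L)),
    x = as.numeric(substr(atom, 31L, 38L)),
    y = as.numeric(substr(atom, 39L, 46L)),
    z = as.numeric(substr(atom, 47L, 54L))
  )
}

pdb_lines <- function(pdb_text) {
  stopifnot(is.character(pdb_text), length(pdb_text) >= 1L)
  if (length(pdb_text) == 1L) {
    if (!grepl("\n", pdb_text, fixed = TRUE) && file.exists(pdb_text)) {
      return(readLines(pdb_text, warn = FALSE))
    }
    return(strsplit(pdb_text, "\n", fixed = TRUE)[[1L]])
  }
  pdb_text
}

#' Write a structure model as PDB ATOM records
#'
#' Emits one fixed-width `ATOM` record per residue (C-alpha only) followed
#' by `END`. Coordinates are written at the PDB's 3-decimal precision, so
#' [read_calpha()] round-trips residue count and coordinates exactly at
#' that precision.
#'
#' @param structure A [structure_model()].
#' @param path Optional file path; when `NULL` the lines are returned.
#' @return Character vector of PDB lines, invisibly when `path` is given.
#' @export
write_pdb <- function(structure, path = NULL) {
  stopifnot(inherits(structure, "structure_model"))
  r <- structure$residues
  lines <- sprintf(
    "ATOM  %5d  CA  %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    r$residue_index, substr(r$residue_name, 1L, 3L),
    substr(structure$chain_id, 1L, 1L), r$residue_index,
    r$x, r$y, r$z
  )
  lines <- c(lines, "END")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Construct a pairwise paralog alignment
#'
#' @param id_a,id_b Sequence identifiers.
#' @param row_a,row_b Gapped sequences (gap character `-`) of equal length.
#' @return An object of class `pair_alignment` with elements `id_a`, `id_b`,
#'   `row_a`, `row_b` and `length` (the column count L).
#' @export
pair_alignment <- function(id_a, id_b, row_a, row_b) {
  row_a <- toupper(as.character(row_a))
  row_b <- toupper(as.character(row_b))
  if (nchar(row_a) != nchar(row_b)) {
    stop("alignment rows must have equal length")
  }
  if (nchar(row_a) == 0L) stop("empty alignment")
  a <- strsplit(row_a, "")[[1L]]
  b <- strsplit(row_b, "")[[1L]]
  if (any(a == "-" & b == "-")) {
    stop("alignment has a column gapped in both rows")
  }
  structure(
    list(
      id_a = as.character(id_a), id_b = as.character(id_b),
      row_a = row_a, row_b = row_b, length = nchar(row_a)
    ),
    class = "pair_alignment"
  )
}

#' @export
print.pair_alignment <- function(x, ...) {
  cat(sprintf(
    "pair_alignment: %s / %s, %d columns\n", x$id_a, x$id_b, x$length
  ))
  invisible(x)
}

#' Read a two-paralog alignment from FASTA or Clustal text
#'
#' Reads a protein multiple alignment with Biostrings and extracts two rows
#' as a [pair_alignment()]. With more than two sequences, `ids` selects the
#' pair; by default the first two rows are taken.
#'
#' @param text Alignment content (single string or lines) or a file path.
#' @param format `"fasta"` or `"clustal"`.
#' @param ids Optional character vector of length 2 naming the rows to keep.
#' @return A [pair_alignment()].
#' @export
read_pair_alignment <- function(text, format = c("fasta", "clustal"),
                                ids = NULL) {
  format <- match.arg(format)
  path <- if (length(text) == 1L && !grepl("\n", text, fixed = TRUE) &&
              file.exists(text)) {
    text
  } else {
    tmp <- tempfile(fileext = paste0(".", format))
    writeLines(if (length(text) == 1L) strsplit(text, "\n")[[1L]] else text,
               tmp)
    tmp
  }
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  seqs <- as.character(aln)
  if (length(seqs) < 2L) stop("alignment must contain at least 2 sequences")
  if (!is.null(ids)) {
    stopifnot(length(ids) == 2L)
    missing <- setdiff(ids, names(seqs))
    if (length(missing)) {
      stop(sprintf("sequence id(s) not in alignment: %s",
                   paste(missing, collapse = ", ")))
    }
    seqs <- seqs[ids]
  } else {
    seqs <- seqs[1:2]
  }
  pair_alignment(names(seqs)[1L], names(seqs)[2L], seqs[[1L]], seqs[[2L]])
}

#' Construct a selected-site set
#'
#' Holds one paralog's positively selected alignment columns with their
#' posterior probabilities, after applying the posterior threshold
#' (inclusive). The defaults mirror the standard site-model workflow of
#' retaining Bayes Empirical Bayes sites at posterior >= 0.75.
#'
#' @param paralog_id Identifier of the paralog.
#' @param columns Integer vector of 1-based alignment columns.
#' @param posteriors Numeric vector of posterior probabilities in `[0, 1]`,
#'   parallel to `columns`. Defaults to 1 for every column.
#' @param threshold Retention threshold (inclusive), default 0.75.
#' @return An object of class `site_set` with sorted `columns`, matching
#'   `posteriors`, `threshold` and `paralog_id`.
#' @export
site_set <- function(paralog_id, columns, posteriors = NULL,
                     threshold = 0.75) {
  columns <- as.numeric(columns)
  if (length(columns) && any(columns != round(columns) | columns < 1)) {
    stop("columns must be positive integers")
  }
  columns <- as.integer(columns)
  if (is.null(posteriors)) posteriors <- rep(1, length(columns))
  stopifnot(length(posteriors) == length(columns))
  if (length(posteriors) && (any(!is.finite(posteriors)) ||
                             any(posteriors < 0 | posteriors > 1))) {
    stop("posteriors must lie in [0, 1]")
  }
  if (anyDuplicated(columns)) stop("duplicate column in site set")
  keep <- posteriors >= threshold
  columns <- columns[keep]
  posteriors <- posteriors[keep]
  ord <- order(columns)
  structure(
    list(
      paralog_id = as.character(paralog_id),
      columns = columns[ord],
      posteriors = as.numeric(posteriors[ord]),
      threshold = as.numeric(threshold)
    ),
    class = "site_set"
  )
}

#' @export
print.site_set <- function(x, ...) {
  cat(sprintf(
    "site_set: %s, %d sites at posterior >= %.3g\n",
    x$paralog_id, length(x$columns), x$threshold
  ))
  invisible(x)
}

#' Read a selected-site list from TSV
#'
#' Expects tab-separated rows with header `column<TAB>posterior`. Columns
#' with posterior below `threshold` are dropped (the comparison is
#' inclusive: a posterior exactly at the threshold is retained).
#'
#' @param text TSV content (single string or lines) or a file path.
#' @param paralog_id Identifier attached to the resulting set.
#' @param threshold Posterior retention threshold, default 0.75.
#' @return A [site_set()].
#' @export
read_sites <- function(text, paralog_id = "paralog", threshold = 0.75) {
  txt <- if (length(text) == 1L && !grepl("\n", text, fixed = TRUE) &&
             file.exists(text)) {
    readLines(text, warn = FALSE)
  } else if (length(text) == 1L) {
    strsplit(text, "\n", fixed = TRUE)[[1L]]
  } else {
    text
  }
  txt <- txt[nzchar(trimws(txt))]
  if (length(txt) <= 1L) {
    return(site_set(paralog_id, integer(0), numeric(0), threshold))
  }
  df <- utils::read.delim(text = paste(txt, collapse = "\n"),
                          stringsAsFactors = FALSE)
  if (!all(c("column", "posterior") %in% names(df))) {
    stop("site TSV must have header 'column<TAB>posterior'")
  }
  if (any(df$column != round(df$column))) {
    stop("non-integer alignment column in site TSV")
  }
  site_set(paralog_id, df$column, df$posterior, threshold)
}

#' Map alignment columns to structure residue indices
#'
#' Maps each non-gap column of the chosen reference row to a residue of the
#' structure, position by position after removing gaps. The ungapped
#' reference, shifted by `offset` residues into the chain, must match the
#' structure sequence at or above `min_identity`; the mapping is strictly
#' monotone and injective on mapped columns, and gap columns map to `NA`.
#'
#' @param aln A [pair_alignment()].
#' @param reference_row `"a"` or `"b"`: which paralog row sits on the
#'   structure.
#' @param structure A [structure_model()].
#' @param offset Number of structure residues preceding the first reference
#'   position (default 0).
#' @param min_identity Minimum fraction of matching residues between the
#'   ungapped reference and the structure sequence (default 0.95). `X`
#'   positions in either sequence are not counted as mismatches.
#' @return Integer vector of length `aln$length`: `residue_index` for each
#'   column, `NA` at reference-gap columns.
#' @export
map_columns_to_residues <- function(aln, reference_row = c("a", "b"),
                                    structure, offset = 0L,
                                    min_identity = 0.95) {
  stopifnot(inherits(aln, "pair_alignment"),
            inherits(structure, "structure_model"))
  reference_row <- match.arg(reference_row)
  row <- strsplit(if (reference_row == "a") aln$row_a else aln$row_b,
                  "")[[1L]]
  nongap <- which(row != "-")
  n_ref <- length(nongap)
  if (n_ref == 0L) stop("reference row has no residues")
  sseq <- strsplit(structure$sequence, "")[[1L]]
  offset <- as.integer(offset)
  if (offset < 0L || offset + n_ref > length(sseq)) {
    stop(sprintf(
      "reference row (%d residues, offset %d) does not fit in structure (%d residues)",
      n_ref, offset, length(sseq)
    ))
  }
  ref <- row[nongap]
  str_slice <- sseq[offset + seq_len(n_ref)]
  comparable <- ref != "X" & str_slice != "X"
  matches <- ref == str_slice & comparable
  identity <- if (any(comparable)) sum(matches) / sum(comparable) else 1
  if (identity < min_identity) {
    first_bad <- which(!matches & comparable)[1L]
    stop(sprintf(
      "reference/structure identity %.1f%% below %.1f%%; first mismatch at reference position %d (column %d): %s vs %s",
      100 * identity, 100 * min_identity, first_bad, nongap[first_bad],
      ref[first_bad], str_slice[first_bad]
    ))
  }
  mapping <- rep(NA_integer_, aln$length)
  mapping[nongap] <- structure$residues$residue_index[offset + seq_len(n_ref)]
  mapping
}

#' Percent identity of a pairwise alignment
#'
#' Counts columns where the two rows carry the same residue, divides by the
#' chosen denominator and scales to a percentage. `mode = "all"` (default)
#' counts every alignment column in the denominator; `mode = "ungapped"`
#' restricts it to columns with no gap in either row. Both conventions are
#' exposed because published identity figures rarely state which was used.
#'
#' @param aln A [pair_alignment()].
#' @param mode `"all"` or `"ungapped"`.
#' @return Percentage in `[0, 100]`.
#' @export
percent_identity <- function(aln, mode = c("all", "ungapped")) {
  stopifnot(inherits(aln, "pair_alignment"))
  mode <- match.arg(mode)
  if (aln$length == 0L) stop("empty alignment")
  a <- strsplit(aln$row_a, "")[[1L]]
  b <- strsplit(aln$row_b, "")[[1L]]
  ungapped <- a != "-" & b != "-"
  ident <- sum(a == b & ungapped)
  denom <- if (mode == "all") aln$length else sum(ungapped)
  if (denom == 0L) stop("no ungapped columns")
  100 * ident / denom
}

#' Columns that differ between the two paralog rows
#'
#' A column is divergent when the rows carry different residues or exactly
#' one row is gapped. The result composes with
#' [map_columns_to_residues()] to annotate divergent positions on a
#' structure, and intersects with a [site_set()]'s columns for counts of
#' selected sites that also differ in sequence.
#'
#' @param aln A [pair_alignment()].
#' @return Sorted integer vector of 1-based divergent columns.
#' @export
divergent_sites <- function(aln) {
  stopifnot(inherits(aln, "pair_alignment"))
  a <- strsplit(aln$row_a, "")[[1L]]
  b <- strsplit(aln$row_b, "")[[1L]]
  which(a != b)
}
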