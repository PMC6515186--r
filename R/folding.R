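#' Base-pair set
#'
#' A nested (pseudoknot-free) set of base pairs over a strand of given
#' length. Each index participates in at most one pair, every pair encloses a
#' hairpin loop of at least `min_loop` unpaired bases (j - i >= min_loop + 1),
#' and any two pairs are either nested or disjoint.
#'
#' @param pairs Two-column integer matrix (or empty) of pairs `(i, j)` with
#'   `i < j`, 1-based.
#' @param length Strand length.
#' @param min_loop Minimum hairpin loop length (default 3).
#' @return A `base_pair_set` object.
#' @export
base_pair_set <- function(pairs, length, min_loop = 3L) {
  length <- as.integer(length)
  stopifnot(length >= 1)
  if (is.null(pairs) || NROW(pairs) == 0) {
    pairs <- matrix(integer(0), ncol = 2)
  } else {
    pairs <- matrix(as.integer(as.matrix(pairs)), ncol = 2)
    swap <- pairs[, 1] > pairs[, 2]
    pairs[swap, ] <- pairs[swap, c(2, 1)]
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  }
  if (NROW(pairs)) {
    idx <- c(pairs)
    if (any(idx < 1 | idx > length)) stop("pair index out of range 1..length")
    dup <- idx[duplicated(idx)]
    if (length(dup) > 0) {
      stop("base(s) ", paste(unique(dup), collapse = ", "),
           " participate in more than one pair")
    }
    short <- pairs[, 2] - pairs[, 1] < min_loop + 1L
    if (any(short)) {
      stop("pair(s) with hairpin loop shorter than ", min_loop, ": ",
           paste(sprintf("(%d,%d)", pairs[short, 1], pairs[short, 2]),
                 collapse = " "))
    }
    pk <- .find_pseudoknot(pairs)
    if (!is.null(pk)) {
      stop(sprintf("pseudoknotted pairs (%d,%d) and (%d,%d)",
                   pk[1], pk[2], pk[3], pk[4]))
    }
  }
  structure(list(pairs = pairs, length = length,
                 min_loop = as.integer(min_loop)),
            class = "base_pair_set")
}

# returns c(i, j, k, l) of a crossing pair, or NULL when nested
.find_pseudoknot <- function(pairs) {
  if (NROW(pairs) < 2) return(NULL)
  # pairs sorted by i; scan with a stack of open j's
  stack <- integer(0)
  n <- NROW(pairs)
  for (r in seq_len(n)) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    while (length(stack) && stack[length(stack)] < i) {
      stack <- stack[-length(stack)]
    }
    if (length(stack) && j > stack[length(stack)]) {
      # find the crossing partner for the message
      for (q in seq_len(r - 1)) {
        k <- pairs[q, 1]; l <- pairs[q, 2]
        if (k < i && i < l && l < j) return(c(k, l, i, j))
      }
      return(c(pairs[r - 1, 1], pairs[r - 1, 2], i, j))
    }
    stack <- c(stack, j)
  }
  NULL
}

#' @export
print.base_pair_set <- function(x, ...) {
  cat(sprintf("base_pair_set: %d nt, %d pairs\n", x$length, NROW(x$pairs)))
  invisible(x)
}

#' Partner vector of a base-pair set
#' @param bps A `base_pair_set`.
#' @return Integer vector `p` with `p[i]` the partner of base `i` (0 when
#'   unpaired).
#' @export
partner_vector <- function(bps) {
  p <- integer(bps$length)
  if (NROW(bps$pairs)) {
    p[bps$pairs[, 1]] <- bps$pairs[, 2]
    p[bps$pairs[, 2]] <- bps$pairs[, 1]
  }
  p
}

#' Folded structure
#'
#' A base-pair set together with its free energy and rank label. Ranks are
#' `S1` (most negative dG, the dominant structure) through `Sn` in ascending
#' dG order; suboptimal structures are those within the free-energy window of
#' the dominant one.
#'
#' @param sequence_id Label of the folded sequence.
#' @param pairs A [base_pair_set()].
#' @param dG Free energy in kcal/mol (<= 0; 0 for the unfolded structure).
#' @param rank_label `"S1"`, `"S2"`, ...
#' @param pseudo Logical; `TRUE` when `dG` is a pseudo-energy (baseline
#'   folder) rather than a thermodynamic value.
#' @return A `folded_structure` object.
#' @export
folded_structure <- function(sequence_id, pairs, dG, rank_label = "S1",
                             pseudo = FALSE) {
  stopifnot(inherits(pairs, "base_pair_set"), is.numeric(dG))
  structure(list(sequence_id = as.character(sequence_id), pairs = pairs,
                 dG = as.numeric(dG), rank_label = rank_label,
                 pseudo = isTRUE(pseudo)),
            class = "folded_structure")
}

#' @export
print.folded_structure <- function(x, ...) {
  cat(sprintf("%s.%s  dG = %.2f%s  (%d pairs / %d nt)\n", x$sequence_id,
              x$rank_label, x$dG, if (x$pseudo) " (pseudo)" else "",
              NROW(x$pairs$pairs), x$pairs$length))
  invisible(x)
}

#' Folding conditions
#'
#' Buffer and selection settings used when folding: monovalent and divalent
#' salt, temperature, and the suboptimal free-energy window expressed as a
#' fraction of the dominant structure's dG. Defaults mirror the aptamer
#' binding buffer: 152 mM Na+, 4 mM Mg++, 23 degrees C, 5% window.
#'
#' @param sodium Na+ concentration, mM.
#' @param magnesium Mg++ concentration, mM.
#' @param temperature Temperature, degrees C.
#' @param subopt_window Suboptimal window as a fraction of |dG1|.
#' @return A `folding_conditions` object.
#' @export
folding_conditions <- function(sodium = 152, magnesium = 4, temperature = 23,
                               subopt_window = 0.05) {
  if (subopt_window < 0) stop("subopt_window must be >= 0")
  structure(list(sodium = sodium, magnesium = magnesium,
                 temperature = temperature, subopt_window = subopt_window),
            class = "folding_conditions")
}

#' Baseline maximum-pairing folder
#'
#' A self-contained, non-thermodynamic folder: maximum-cardinality nested
#' pairing under allowed pairs A.T, G.C and G.T with a minimum hairpin loop,
#' computed by dynamic programming with a deterministic traceback (the 5'
#' base is paired with the largest admissible partner achieving the optimum,
#' bifurcating at the smallest split point). The reported dG is the negated
#' pair count, flagged as a pseudo-energy. It is not equivalent to a
#' nearest-neighbor thermodynamic model; it exists so every downstream stage
#' runs without an external engine.
#'
#' @param seq A [sequence_record()] or plain A/C/G/T string.
#' @param min_loop Minimum hairpin loop length.
#' @return A [folded_structure()] with `pseudo = TRUE`.
#' @examples
#' baseline_fold("GGGAAACCC")$pairs$pairs
#' @export
baseline_fold <- function(seq, min_loop = 3L) {
  if (inherits(seq, "sequence_record")) {
    id <- seq$id; s <- seq$sequence
  } else {
    id <- "seq"; s <- .check_dna(seq)
  }
  if (nchar(s) == 0) stop("empty sequence")
  p <- .nussinov_fold(s, as.integer(min_loop))
  i <- which(p > seq_along(p))
  pairs <- cbind(i, p[i])
  bps <- base_pair_set(pairs, nchar(s), min_loop = min_loop)
  folded_structure(id, bps, dG = -NROW(bps$pairs), rank_label = "S1",
                   pseudo = TRUE)
}

#' Folding engines
#'
#' An engine is an adapter satisfying one contract: given a sequence record
#' and [folding_conditions()], return one or more [folded_structure()]s with
#' free energies. `baseline_engine()` wraps [baseline_fold()] (single
#' structure, pseudo-energy). `vienna_engine()` shells out to ViennaRNA's
#' `RNAfold`/`RNAsubopt` with DNA (Mathews 2004) parameters, the requested
#' temperature and a salt correction, producing the minimum-free-energy
#' structure and every structure within the suboptimal window.
#' `ct_dir_engine()` serves pre-computed mfold-style CT files from a
#' directory (one or more `<id>*.ct` files per sequence).
#'
#' @param min_loop Minimum hairpin loop for the baseline engine.
#' @return An engine object for use with [fold()].
#' @export
baseline_engine <- function(min_loop = 3L) {
  structure(list(min_loop = as.integer(min_loop)),
            class = c("baseline_engine", "fold_engine"))
}

#' @rdname baseline_engine
#' @export
vienna_engine <- function() {
  structure(list(), class = c("vienna_engine", "fold_engine"))
}

#' @param dir Directory of CT files for `ct_dir_engine`.
#' @rdname baseline_engine
#' @export
ct_dir_engine <- function(dir) {
  stopifnot(dir.exists(dir))
  structure(list(dir = dir), class = c("ct_dir_engine", "fold_engine"))
}

#' Is the ViennaRNA toolchain available?
#' @return Logical.
#' @export
vienna_available <- function() {
  nzchar(Sys.which("RNAfold")) && nzchar(Sys.which("RNAsubopt"))
}

engine_fold <- function(engine, seq, cond) UseMethod("engine_fold")

#' @export
engine_fold.baseline_engine <- function(engine, seq, cond) {
  list(baseline_fold(seq, min_loop = engine$min_loop))
}

# Effective monovalent concentration: Na+ plus a sqrt-law Mg++ equivalence
# (120 mM per sqrt(mM Mg)); returned in molar for RNAfold --salt.
.effective_salt <- function(cond) {
  (cond$sodium + 120 * sqrt(cond$magnesium)) / 1000
}

#' @export
engine_fold.vienna_engine <- function(engine, seq, cond) {
  if (!vienna_available()) {
    stop("RNAfold/RNAsubopt not found on PATH; use baseline_engine() or ",
         "ct_dir_engine() instead")
  }
  res <- .vienna_fold_many(list(seq), cond)
  res[[1]]
}

# Batch interface used by fold_population(): one RNAfold call and (for
# sequences that fold at all) one RNAsubopt call for the whole set.
.vienna_fold_many <- function(records, cond) {
  ids <- vapply(records, `[[`, "", "id")
  seqs <- vapply(records, `[[`, "", "sequence")
  fa <- tempfile(fileext = ".fa")
  on.exit(unlink(fa), add = TRUE)
  writeLines(paste0(">", ids, "\n", seqs), fa)
  args_common <- c("-T", format(cond$temperature),
                   "--paramFile=DNA",
                   paste0("--salt=", format(.effective_salt(cond))),
                   "--noconv")
  mfe_out <- suppressWarnings(
    system2("RNAfold", c("--noPS", args_common), stdin = fa, stdout = TRUE,
            stderr = FALSE))
  mfe <- .parse_rnafold(mfe_out)
  if (length(mfe$id) != length(ids)) stop("RNAfold returned unexpected output")
  window <- cond$subopt_window
  out <- vector("list", length(ids))
  # suboptimal enumeration per sequence; the energy range depends on the MFE
  for (r in seq_along(ids)) {
    dG1 <- mfe$dG[r]
    structs <- data.frame(db = mfe$db[r], dG = dG1)
    if (dG1 < 0 && window > 0) {
      # pad the kcal range slightly; the exact window is re-applied later
      erange <- max(window * abs(dG1), 0.01) + 0.01
      sub_out <- suppressWarnings(
        system2("RNAsubopt", c(args_common, "-e", format(round(erange, 2))),
                input = c(paste0(">", ids[r]), seqs[r]), stdout = TRUE,
                stderr = FALSE))
      sub <- .parse_rnasubopt(sub_out)
      if (NROW(sub)) structs <- sub
    }
    structs <- structs[!duplicated(structs$db), , drop = FALSE]
    fs <- lapply(seq_len(NROW(structs)), function(q) {
      bps <- parse_dotbracket(structs$db[q])
      folded_structure(ids[r], bps, dG = structs$dG[q])
    })
    out[[r]] <- .rank_structures(fs)
  }
  out
}

.parse_rnafold <- function(lines) {
  hdr <- grep("^>", lines)
  id <- sub("^>\\s*", "", sub("\\s.*$", "", lines[hdr]))
  db_lines <- lines[hdr + 2]
  db <- sub("\\s.*$", "", db_lines)
  dG <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", db_lines))
  list(id = id, db = db, dG = dG)
}

.parse_rnasubopt <- function(lines) {
  body <- lines[grepl("^[.()]+\\s+-?[0-9.]+\\s*$", lines)]
  if (!length(body)) return(data.frame(db = character(0), dG = numeric(0)))
  db <- sub("\\s.*$", "", body)
  dG <- as.numeric(sub("^[.()]+\\s+", "", body))
  data.frame(db = db, dG = dG)
}

#' @export
engine_fold.ct_dir_engine <- function(engine, seq, cond) {
  files <- sort(list.files(engine$dir, full.names = TRUE,
                           pattern = paste0("^", seq$id, ".*\\.ct$")))
  if (!length(files)) stop("no CT file for sequence ", seq$id)
  out <- lapply(files, function(f) parse_ct(f)$structure)
  out <- lapply(out, function(fs) { fs$sequence_id <- seq$id; fs })
  .rank_structures(out)
}

# sort by dG ascending; ties by fewer pairs, then lexicographic dot-bracket;
# relabel S1..Sn
.rank_structures <- function(structs) {
  dg <- vapply(structs, `[[`, 0, "dG")
  np <- vapply(structs, function(s) NROW(s$pairs$pairs), 0L)
  db <- vapply(structs, function(s) write_dotbracket(s$pairs), "")
  o <- order(dg, np, db)
  structs <- structs[o]
  for (i in seq_along(structs)) structs[[i]]$rank_label <- paste0("S", i)
  structs
}

#' Fold a sequence with an engine
#'
#' Runs the engine, validates the returned base-pair sets, sorts structures
#' by ascending dG (S1 = most negative) and applies the suboptimal window of
#' `cond`.
#'
#' @param seq A [sequence_record()].
#' @param cond [folding_conditions()].
#' @param engine An engine from [baseline_engine()], [vienna_engine()] or
#'   [ct_dir_engine()].
#' @return List of [folded_structure()]s, `S1` first.
#' @export
fold <- function(seq, cond = folding_conditions(), engine = baseline_engine()) {
  stopifnot(inherits(engine, "fold_engine"))
  structs <- engine_fold(engine, seq, cond)
  if (!length(structs)) stop("engine returned no structure for ", seq$id)
  structs <- .rank_structures(structs)
  select_suboptimal(structs, cond$subopt_window)
}

#' Fold a population of sequences
#'
#' Vectorized front end to [fold()]; with the ViennaRNA engine the whole set
#' is folded in a single external call.
#'
#' @param records List of [sequence_record()]s.
#' @inheritParams fold
#' @return List (one element per record) of lists of [folded_structure()]s.
#' @export
fold_population <- function(records, cond = folding_conditions(),
                            engine = baseline_engine()) {
  if (inherits(engine, "vienna_engine")) {
    if (!vienna_available()) {
      stop("RNAfold/RNAsubopt not found on PATH")
    }
    res <- .vienna_fold_many(records, cond)
    lapply(res, select_suboptimal, window = cond$subopt_window)
  } else {
    lapply(records, fold, cond = cond, engine = engine)
  }
}

#' Apply the suboptimal free-energy window
#'
#' Keeps the dominant structure S1 plus every structure whose dG lies within
#' `window * |dG1|` of it, relabelling S1..Sn in ascending dG order. When the
#' dominant structure is unfolded (dG1 = 0) the window has zero width and
#' only S1 is retained.
#'
#' @param structures Non-empty list of [folded_structure()]s.
#' @param window Fraction of |dG1| (>= 0).
#' @return Filtered, relabelled list.
#' @examples
#' # dGs -10.0, -9.6, -9.4 with a 5% window keep -10.0 and -9.6
#' @export
select_suboptimal <- function(structures, window = 0.05) {
  if (window < 0) stop("window must be >= 0")
  if (!length(structures)) stop("no structures")
  structures <- .rank_structures(structures)
  dG1 <- structures[[1]]$dG
  keep <- vapply(structures, function(s) {
    abs(s$dG - dG1) <= window * abs(dG1) + 1e-9
  }, TRUE)
  keep[1] <- TRUE
  .rank_structures(structures[keep])
}
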