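#' Screening library design
#'
#' Describes the fixed-flank library layout used for aptamer screening: a
#' constant 5' primer-binding flank, a randomized variable insert drawn i.i.d.
#' from a base composition, and a constant 3' flank. The standard design is a
#' 69-nt strand with a 14-nt 5' flank, a 40-nt variable segment and a 15-nt
#' 3' flank.
#'
#' @param flank5,flank3 Constant flank sequences (A/C/G/T).
#' @param variable_length Length of the randomized insert, in bases.
#' @param composition Named numeric vector of base probabilities for the
#'   variable segment; names must be `A`, `C`, `G`, `T` and values must sum
#'   to 1.
#' @return A `library_design` object.
#' @examples
#' equibase_design()
#' arich_design()
#' @export
library_design <- function(flank5 = "GGGACAGGGCTAGC",
                           flank3 = "GAGGCAAAGCTTCCG",
                           variable_length = 40L,
                           composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  flank5 <- .check_dna(flank5, "flank5")
  flank3 <- .check_dna(flank3, "flank3")
  stopifnot(is.numeric(variable_length), variable_length >= 0)
  if (!setequal(names(composition), c("A", "C", "G", "T"))) {
    stop("composition must be named with A, C, G, T")
  }
  composition <- composition[c("A", "C", "G", "T")]
  if (any(composition < 0) || abs(sum(composition) - 1) > 1e-12) {
    stop("composition probabilities must be non-negative and sum to 1")
  }
  structure(list(flank5 = flank5, flank3 = flank3,
                 variable_length = as.integer(variable_length),
                 composition = composition),
            class = "library_design")
}

#' @rdname library_design
#' @export
equibase_design <- function() library_design()

#' @rdname library_design
#' @export
arich_design <- function() {
  library_design(composition = c(A = 0.40, C = 0.20, G = 0.20, T = 0.20))
}

#' @export
print.library_design <- function(x, ...) {
  cat(sprintf("library design: %s-[%dN]-%s  (total %d nt)\n",
              x$flank5, x$variable_length, x$flank3, total_length(x)))
  cat("  variable-base composition:",
      paste(sprintf("%s=%.2f", names(x$composition), x$composition),
            collapse = " "), "\n")
  invisible(x)
}

total_length <- function(design) {
  nchar(design$flank5) + design$variable_length + nchar(design$flank3)
}

.check_dna <- function(x, what = "sequence") {
  stopifnot(is.character(x), length(x) == 1)
  if (x != toupper(x)) {
    warning(sprintf("%s contained lowercase letters; uppercased", what))
    x <- toupper(x)
  }
  bad <- regexpr("[^ACGT]", x)
  if (bad > 0) {
    stop(sprintf("%s contains a non-ACGT character at position %d", what, bad))
  }
  x
}

#' Sequence record
#'
#' A single candidate strand with its flank/variable segmentation (1-based,
#' inclusive spans). For the standard design the fixed segments are bases
#' 1-14 and 55-69 and the variable segment is bases 15-54.
#'
#' @param id Record label.
#' @param sequence A/C/G/T string.
#' @param segments Named list of `c(start, end)` spans (`fixed5`, `variable`,
#'   `fixed3`) tiling the sequence; computed from `design` when supplied.
#' @param origin One of `"equibase"`, `"arich"`, `"aptamer"`, `"planted"`.
#' @param design Optional `library_design` used to derive `segments`.
#' @return A `sequence_record` object.
#' @export
sequence_record <- function(id, sequence, segments = NULL,
                            origin = "aptamer", design = NULL) {
  sequence <- .check_dna(sequence, id)
  n <- nchar(sequence)
  if (is.null(segments)) {
    if (!is.null(design)) {
      a <- nchar(design$flank5)
      b <- design$variable_length
      segments <- list(fixed5 = c(1L, a),
                       variable = c(a + 1L, a + b),
                       fixed3 = c(a + b + 1L, n))
    } else {
      segments <- list(fixed5 = c(1L, 0L), variable = c(1L, n),
                       fixed3 = c(n + 1L, n))
    }
  }
  ends <- vapply(segments, `[`, integer(1), 2L)
  starts <- vapply(segments, `[`, integer(1), 1L)
  keep <- ends >= starts
  if (any(keep)) {
    sp <- cbind(starts[keep], ends[keep])
    sp <- sp[order(sp[, 1]), , drop = FALSE]
    covered <- unlist(apply(sp, 1, function(r) seq.int(r[1], r[2]), simplify = FALSE))
    if (!identical(as.integer(covered), seq_len(n))) {
      stop("segment spans must tile the sequence without overlap")
    }
  }
  structure(list(id = as.character(id), sequence = sequence,
                 segments = segments, origin = origin),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<%s> (%s, %d nt)\n%s\n", x$id, x$origin, nchar(x$sequence),
              x$sequence))
  invisible(x)
}

#' Extract the variable-segment substring of a record
#' @param rec A `sequence_record`.
#' @return Character string.
#' @export
variable_segment <- function(rec) {
  sp <- rec$segments$variable
  substr(rec$sequence, sp[1], sp[2])
}

#' Generate a random screening library
#'
#' Draws `n` strands from a fixed-flank design: the flanks are copied
#' verbatim and the variable bases are sampled i.i.d. from the design's base
#' composition. Generation is seedable and bit-reproducible.
#'
#' @param design A [library_design()].
#' @param n Number of sequences (>= 1).
#' @param seed Integer RNG seed.
#' @param prefix Label prefix for record ids.
#' @return List of [sequence_record()] objects.
#' @examples
#' lib <- generate_library(equibase_design(), n = 3, seed = 1)
#' lib[[1]]
#' @export
generate_library <- function(design, n, seed = 1L, prefix = "R") {
  stopifnot(inherits(design, "library_design"), n >= 1)
  origin <- if (isTRUE(all.equal(unname(design$composition),
                                 rep(0.25, 4)))) "equibase" else "arich"
  bases <- names(design$composition)
  old <- .save_rng(seed)
  on.exit(.restore_rng(old))
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    var <- paste(sample(bases, design$variable_length, replace = TRUE,
                        prob = design$composition), collapse = "")
    recs[[i]] <- sequence_record(
      id = sprintf("%s%04d", prefix, i),
      sequence = paste0(design$flank5, var, design$flank3),
      origin = origin, design = design)
  }
  recs
}

.save_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Read and write FASTA
#'
#' Thin wrappers over Biostrings FASTA I/O returning/consuming
#' [sequence_record()] lists. Lowercase input is uppercased with a warning;
#' non-ACGT characters are rejected with their position.
#'
#' @param path File path.
#' @param origin Origin tag applied to all records read.
#' @param design Optional `library_design` used for segment spans.
#' @return `read_fasta` returns a list of records; `write_fasta` is called
#'   for its side effect and returns `path` invisibly.
#' @export
read_fasta <- function(path, origin = "aptamer", design = NULL) {
  ss <- Biostrings::readBStringSet(path)
  mapply(function(id, seq) sequence_record(id, seq, origin = origin,
                                           design = design),
         names(ss), as.character(ss), SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' @param records List of `sequence_record` objects.
#' @rdname read_fasta
#' @export
write_fasta <- function(records, path) {
  ss <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "sequence"))
  names(ss) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
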