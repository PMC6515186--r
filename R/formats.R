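#' Parse a dot-bracket string
#'
#' Single-tier Vienna dot-bracket (no pseudoknot bracket tiers): `(` opens a
#' pair, `)` closes it, `.` is unpaired.
#'
#' @param text Dot-bracket string.
#' @param min_loop Minimum hairpin loop enforced on the result.
#' @return A [base_pair_set()].
#' @examples
#' parse_dotbracket("((((...))))")$pairs
#' @export
parse_dotbracket <- function(text, min_loop = 3L) {
  ch <- strsplit(text, "")[[1]]
  bad <- which(!ch %in% c("(", ")", "."))
  if (length(bad)) {
    stop("unexpected character '", ch[bad[1]], "' at position ", bad[1])
  }
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced ')' at position ", i)
      pairs <- rbind(pairs, c(stack[length(stack)], i))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced '(' at position ", stack[1])
  base_pair_set(pairs, length(ch), min_loop = min_loop)
}

#' Write a dot-bracket string
#' @param bps A [base_pair_set()].
#' @return Dot-bracket string of length `bps$length`.
#' @export
write_dotbracket <- function(bps) {
  ch <- rep(".", bps$length)
  if (NROW(bps$pairs)) {
    ch[bps$pairs[, 1]] <- "("
    ch[bps$pairs[, 2]] <- ")"
  }
  paste(ch, collapse = "")
}

#' Parse an mfold-style CT file
#'
#' Connectivity table: a header line containing the length and a `dG = x`
#' token, followed by six-column rows (index, base, previous, next, pair,
#' index). Reciprocal pairing is checked: if row i names j, row j must name
#' i.
#'
#' @param path CT file path.
#' @param min_loop Minimum hairpin loop enforced on the result.
#' @return List with `sequence` (character) and `structure`
#'   (a [folded_structure()]).
#' @export
parse_ct <- function(path, min_loop = 3L) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- suppressWarnings(as.integer(hdr[1]))
  if (is.na(n)) stop("CT header must begin with the sequence length")
  dg_m <- regmatches(lines[1],
                     regexpr("dG\\s*=\\s*-?[0-9.]+", lines[1], ignore.case = TRUE))
  dG <- if (length(dg_m)) as.numeric(sub(".*=\\s*", "", dg_m)) else 0
  id_m <- sub(".*dG\\s*=\\s*-?[0-9.]+\\s*", "", lines[1], ignore.case = TRUE)
  id <- if (nzchar(trimws(id_m))) trimws(id_m) else "ct"
  body <- lines[-1]
  if (length(body) < n) stop("CT body shorter than header length")
  body <- body[seq_len(n)]
  fields <- do.call(rbind, strsplit(trimws(body), "\\s+"))
  if (ncol(fields) < 5) stop("CT rows must have at least 5 columns")
  idx <- as.integer(fields[, 1])
  base <- fields[, 2]
  mate <- as.integer(fields[, 5])
  if (!identical(idx, seq_len(n))) stop("CT row indices must run 1..length")
  # reciprocity
  paired <- which(mate > 0)
  bad <- paired[mate[mate[paired]] != paired]
  if (length(bad)) {
    stop("inconsistent CT reciprocal pairing at row(s) ",
         paste(bad, collapse = ", "))
  }
  i <- which(mate > idx)
  bps <- base_pair_set(cbind(i, mate[i]), n, min_loop = min_loop)
  list(sequence = paste(toupper(base), collapse = ""),
       structure = folded_structure(id, bps, dG = dG))
}

#' Write an mfold-style CT file
#' @param sequence A/C/G/T string.
#' @param structure A [folded_structure()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct <- function(sequence, structure, path) {
  n <- nchar(sequence)
  stopifnot(n == structure$pairs$length)
  p <- partner_vector(structure$pairs)
  ch <- strsplit(sequence, "")[[1]]
  hdr <- sprintf("%d dG = %.2f %s", n, structure$dG, structure$sequence_id)
  rows <- sprintf("%d %s %d %d %d %d", seq_len(n), ch, seq_len(n) - 1L,
                  ifelse(seq_len(n) == n, 0L, seq_len(n) + 1L), p, seq_len(n))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a Clustal-format alignment
#'
#' Accepts the plain Clustal dialect written by ClustalW/MEGA: a header line
#' starting with `CLUSTAL`, then blocks of `name  segment` rows (conservation
#' lines and blank lines are skipped). All rows must assemble to the same
#' length.
#'
#' @param path File path.
#' @return A [multiple_alignment()].
#' @export
read_clustal <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^CLUSTAL", lines[1], ignore.case = TRUE)) {
    stop("not a Clustal file (missing CLUSTAL header)")
  }
  rows <- list()
  for (ln in lines[-1]) {
    if (!nzchar(trimws(ln))) next
    m <- regmatches(ln, regexec("^(\\S+)\\s+([A-Za-z-]+)\\s*\\d*\\s*$", ln))[[1]]
    if (length(m) != 3) next  # conservation line or ruler
    nm <- m[2]; seg <- m[3]
    rows[[nm]] <- paste0(if (is.null(rows[[nm]])) "" else rows[[nm]], seg)
  }
  if (!length(rows)) stop("no alignment rows found")
  lens <- nchar(unlist(rows))
  if (length(unique(lens)) != 1) {
    stop("inconsistent block lengths: rows assemble to lengths ",
         paste(unique(lens), collapse = ", "))
  }
  multiple_alignment(unlist(rows))
}

#' Write a Clustal-format alignment
#' @param aln A [multiple_alignment()].
#' @param path Output path.
#' @param width Characters per block row.
#' @return `path`, invisibly.
#' @export
write_clustal <- function(aln, path, width = 60L) {
  rows <- aln$rows
  n <- aln$n_columns
  nm <- formatC(names(rows), width = max(nchar(names(rows))) + 2, flag = "-")
  out <- c("CLUSTAL W multiple sequence alignment", "")
  for (start in seq(1, n, by = width)) {
    end <- min(start + width - 1, n)
    out <- c(out, paste0(nm, substr(rows, start, end)), "")
  }
  writeLines(out, path)
  invisible(path)
}
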