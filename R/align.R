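#' Substitution scheme for structural alignment
#'
#' Identity substitution over the seven-letter structural alphabet: a single
#' match score, a single mismatch score, and affine gap penalties (a gap of
#' length L costs `gap_open + gap_extend * L`). Defaults are ClustalW-like
#' magnitudes with the identity matrix.
#'
#' @param match Match score (> mismatch).
#' @param mismatch Mismatch score.
#' @param gap_open,gap_extend Gap penalties (>= 0).
#' @return A `substitution_scheme` object.
#' @export
substitution_scheme <- function(match = 10, mismatch = 0, gap_open = 10,
                                gap_extend = 0.2) {
  if (match <= mismatch) stop("match score must exceed mismatch score")
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be >= 0")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "substitution_scheme")
}

#' Global pairwise alignment of two structure strings
#'
#' Optimal global alignment with affine gaps (Gotoh algorithm) under an
#' identity substitution scheme. The traceback is deterministic: ties prefer
#' diagonal, then a gap in `b`, then a gap in `a`.
#'
#' @param a,b Non-empty strings.
#' @param scheme A [substitution_scheme()].
#' @return List with gapped strings `a` and `b` and the `score`.
#' @examples
#' pairwise_align("SSH", "SH")
#' @export
pairwise_align <- function(a, b, scheme = substitution_scheme()) {
  stopifnot(nzchar(a), nzchar(b))
  .gotoh_align(a, b, scheme$match, scheme$mismatch, scheme$gap_open,
               scheme$gap_extend)
}

#' Multiple alignment container
#'
#' Named gapped rows of equal length; removing the gaps from any row must
#' reproduce the input string exactly.
#'
#' @param rows Named character vector of gapped strings.
#' @return A `multiple_alignment` object with `rows` and `n_columns`.
#' @export
multiple_alignment <- function(rows) {
  stopifnot(length(rows) >= 1, !is.null(names(rows)))
  lens <- nchar(rows)
  if (length(unique(lens)) != 1) stop("all rows must have equal length")
  structure(list(rows = rows, n_columns = unname(lens[1])),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("multiple_alignment: %d rows x %d columns\n",
              length(x$rows), x$n_columns))
  invisible(x)
}

#' Character matrix of an alignment
#' @param aln A [multiple_alignment()].
#' @return Character matrix, one row per sequence.
#' @export
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln$rows), ""))
  rownames(m) <- names(aln$rows)
  m
}

#' Strip gaps from an alignment row
#' @param x Gapped string(s).
#' @return String(s) with `-` removed.
#' @export
ungap <- function(x) gsub("-", "", x, fixed = TRUE)

# ---- guide tree -----------------------------------------------------------

# Neighbor-joining over a distance matrix, returning the merge order as a
# list of index pairs into a growing node list (leaves 1..n first). Ties join
# the pair whose (lexicographically sorted) labels are smallest.
.nj_merges <- function(D, labels) {
  n <- nrow(D)
  if (n == 2) return(list(c(1L, 2L)))
  node_label <- labels          # per node id; representative = smallest member
  Dm <- D
  merges <- list()
  next_id <- n + 1L
  id_of <- seq_len(n)           # node id for each row of Dm
  while (nrow(Dm) > 2) {
    m <- nrow(Dm)
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij) {
      paste(sort(c(node_label[id_of[ij[1]]], node_label[id_of[ij[2]]])),
            collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    merges[[length(merges) + 1]] <- c(id_of[i], id_of[j])
    dnew <- 0.5 * (Dm[i, -c(i, j)] + Dm[j, -c(i, j)] - Dm[i, j])
    new_lab <- min(node_label[id_of[i]], node_label[id_of[j]])
    Dm <- Dm[-c(i, j), -c(i, j), drop = FALSE]
    Dm <- rbind(cbind(Dm, dnew), c(dnew, 0))
    id_of <- c(id_of[-c(i, j)], next_id)
    node_label <- c(node_label, new_lab)
    next_id <- next_id + 1L
  }
  merges[[length(merges) + 1]] <- c(id_of[1], id_of[2])
  merges
}

# pairwise identity distance matrix: d = 1 - matches / alignment columns
.identity_distances <- function(ss_strings, scheme) {
  n <- length(ss_strings)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      al <- .gotoh_align(ss_strings[i], ss_strings[j], scheme$match,
                         scheme$mismatch, scheme$gap_open, scheme$gap_extend)
      ca <- strsplit(al$a, "")[[1]]
      cb <- strsplit(al$b, "")[[1]]
      ident <- sum(ca == cb & ca != "-") / length(ca)
      D[i, j] <- D[j, i] <- 1 - ident
    }
  }
  D
}

# 7 x ncol frequency profile of an alignment chunk (gap row omitted; columns
# with gaps sum to < 1)
.profile_of <- function(rows) {
  m <- do.call(rbind, strsplit(rows, ""))
  vapply(seq_len(ncol(m)), function(j) {
    tab <- table(factor(m[, j], levels = SSE_KINDS))
    as.numeric(tab) / nrow(m)
  }, numeric(7))
}

.apply_path <- function(rows_a, rows_b, path) {
  na <- nchar(rows_a[1]); nb <- nchar(rows_b[1])
  ia <- 0L; ib <- 0L
  take_a <- integer(0); take_b <- integer(0)  # 0 = gap, else source column
  for (mv in path) {
    if (mv == 0L) { ia <- ia + 1L; ib <- ib + 1L
      take_a <- c(take_a, ia); take_b <- c(take_b, ib)
    } else if (mv == 1L) { ia <- ia + 1L
      take_a <- c(take_a, ia); take_b <- c(take_b, 0L)
    } else { ib <- ib + 1L
      take_a <- c(take_a, 0L); take_b <- c(take_b, ib)
    }
  }
  stopifnot(ia == na, ib == nb)
  expand <- function(rows, take) {
    vapply(rows, function(r) {
      ch <- strsplit(r, "")[[1]]
      paste(ifelse(take == 0L, "-", ch[pmax(take, 1L)]), collapse = "")
    }, "", USE.NAMES = TRUE)
  }
  c(expand(rows_a, take_a), expand(rows_b, take_b))
}

#' Progressive multiple alignment of structure strings
#'
#' Aligns two or more secondary structure strings over the seven-letter
#' alphabet: pairwise identity distances (`d = 1 - identity fraction` from
#' global pairwise alignments) feed a neighbor-joining guide tree, and
#' profiles are merged leaf-to-root by profile-profile affine-gap alignment.
#' Once inserted, a gap is never removed. The result is deterministic for a
#' fixed input order; distance ties in the guide tree join the
#' lexicographically smallest label pair.
#'
#' @param ss_strings Named character vector of structure strings (>= 2; a
#'   single string is returned as-is with a warning).
#' @param scheme A [substitution_scheme()].
#' @return A [multiple_alignment()] with rows in input order.
#' @export
progressive_align <- function(ss_strings, scheme = substitution_scheme()) {
  ss <- unlist(ss_strings)
  labels <- names(ss)
  if (is.null(labels)) {
    labels <- sprintf("seq_%d", seq_along(ss))
    names(ss) <- labels
  }
  if (anyDuplicated(labels)) stop("row labels must be unique")
  if (length(ss) == 1) {
    warning("single input string; returned unaligned")
    return(multiple_alignment(ss))
  }
  D <- .identity_distances(unname(ss), scheme)
  merges <- .nj_merges(D, labels)
  nodes <- lapply(seq_along(ss), function(i) ss[i])  # each: named rows
  for (mg in merges) {
    a <- nodes[[mg[1]]]; b <- nodes[[mg[2]]]
    pa <- .profile_of(unname(a)); pb <- .profile_of(unname(b))
    res <- .profile_align(pa, pb, scheme$match, scheme$mismatch,
                          scheme$gap_open, scheme$gap_extend)
    nodes[[length(nodes) + 1]] <- .apply_path(a, b, res$path)
  }
  rows <- nodes[[length(nodes)]]
  multiple_alignment(rows[labels])
}
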