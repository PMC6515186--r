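#' The seven secondary structure elements
#'
#' One-letter codes for the elements a self-hybridized single strand can be
#' decomposed into: `S` single-stranded segment, `H` hairpin stem, `L`
#' hairpin loop, `I` internal loop, `G` bulge, `D` duplex, `M` multi-branched
#' loop.
#' @export
SSE_KINDS <- c("S", "H", "L", "I", "G", "D", "M")

#' Decompose a base-pair structure into secondary structure elements
#'
#' Standard loop-taxonomy decomposition of a nested base-pair set:
#' \itemize{
#'   \item helices are maximal runs of contiguously stacked pairs;
#'   \item the loop enclosed by a helix's innermost pair is classified by its
#'     branching: no inner helix = hairpin loop (`L`); one inner helix with
#'     unpaired bases on both sides = internal loop (`I`), on one side =
#'     bulge (`G`); two or more inner helices = multi-branched loop (`M`);
#'   \item a helix whose innermost pair directly closes a hairpin loop is a
#'     hairpin stem (`H`, both strands); every other helix is a duplex (`D`);
#'   \item each maximal run of bases exterior to all pairs is one
#'     single-stranded segment (`S`).
#' }
#' Counting granularity: one helix (both strands) is one element, as is one
#' internal loop (both unpaired stretches) and one multi-branched loop (all
#' its stretches). A multi-branched loop with no unpaired bases still counts
#' as one element with an empty span.
#'
#' @param pairs A [base_pair_set()].
#' @return A `structure_annotation`: list with `ss_string` (per-base letter
#'   string), `elements` (data frame: `kind`, `element`, `start`, `end`, one
#'   row per span), and `count_vector` (named 7-long integer vector in
#'   S,H,L,I,G,D,M order).
#' @examples
#' bps <- base_pair_set(cbind(1:5, 13:9), 15)
#' annotate_structure(bps)$ss_string  # "HHHHHLLLHHHHHSS"
#' @export
annotate_structure <- function(pairs) {
  stopifnot(inherits(pairs, "base_pair_set"))
  n <- pairs$length
  p <- partner_vector(pairs)
  letters_out <- rep(NA_character_, n)
  spans <- list()   # each: list(kind, spans = list(c(start,end)))

  ## helices: maximal stacked runs among pairs sorted by i
  helices <- list()  # each: c(i_outer, j_outer, i_inner, j_inner)
  pr <- pairs$pairs
  if (NROW(pr)) {
    open <- pr[, 1]
    for (r in seq_len(NROW(pr))) {
      i <- pr[r, 1]; j <- pr[r, 2]
      # start of a helix unless the previous stacked pair exists
      if (i > 1 && p[i - 1] == j + 1) next
      i2 <- i; j2 <- j
      while (i2 + 1 <= n && p[i2 + 1] == j2 - 1) { i2 <- i2 + 1; j2 <- j2 - 1 }
      helices[[length(helices) + 1]] <- c(i, j, i2, j2)
    }
  }

  ## classify the loop closed by each helix's innermost pair
  helix_kind <- character(length(helices))
  for (h in seq_along(helices)) {
    hh <- helices[[h]]
    a <- hh[3]; b <- hh[4]  # innermost (closing) pair
    k <- a + 1
    children <- list()
    runs <- list()
    run_start <- NA_integer_
    while (k <= b - 1) {
      if (p[k] == 0) {
        if (is.na(run_start)) run_start <- k
        k <- k + 1
      } else {
        if (!is.na(run_start)) {
          runs[[length(runs) + 1]] <- c(run_start, k - 1)
          run_start <- NA_integer_
        }
        children[[length(children) + 1]] <- c(k, p[k])
        k <- p[k] + 1
      }
    }
    if (!is.na(run_start)) runs[[length(runs) + 1]] <- c(run_start, b - 1)
    nch <- length(children)
    if (nch == 0) {
      helix_kind[h] <- "H"
      spans[[length(spans) + 1]] <- list(kind = "L", spans = runs)
    } else if (nch == 1) {
      helix_kind[h] <- "D"
      if (length(runs) == 2) {
        spans[[length(spans) + 1]] <- list(kind = "I", spans = runs)
      } else if (length(runs) == 1) {
        spans[[length(spans) + 1]] <- list(kind = "G", spans = runs)
      } else {
        stop("contiguously stacked pairs classified as separate helices")
      }
    } else {
      helix_kind[h] <- "D"
      spans[[length(spans) + 1]] <- list(kind = "M", spans = runs)
    }
  }

  ## helix letter spans
  for (h in seq_along(helices)) {
    hh <- helices[[h]]
    spans[[length(spans) + 1]] <-
      list(kind = helix_kind[h],
           spans = list(c(hh[1], hh[3]), c(hh[4], hh[2])))
  }

  ## exterior single-stranded runs
  ext <- rep(TRUE, n)
  if (NROW(pr)) {
    for (r in seq_len(NROW(pr))) ext[pr[r, 1]:pr[r, 2]] <- FALSE
  }
  if (any(ext)) {
    rl <- rle(ext)
    stops <- cumsum(rl$lengths)
    starts <- stops - rl$lengths + 1L
    for (q in which(rl$values)) {
      spans[[length(spans) + 1]] <- list(kind = "S",
                                         spans = list(c(starts[q], stops[q])))
    }
  }

  ## assemble: order elements by first base (empty-span elements by the
  ## position of their closing pair region, i.e. after everything at their
  ## start); fill the letter string
  first_pos <- vapply(spans, function(e) {
    if (length(e$spans)) min(vapply(e$spans, function(s) as.numeric(s[1]),
                                    numeric(1)))
    else NA_real_
  }, numeric(1))
  # empty-span multiloops sort after everything else
  first_pos[is.na(first_pos)] <- n + 1
  o <- order(first_pos, vapply(spans, function(e) match(e$kind, SSE_KINDS), 0))
  spans <- spans[o]
  rows <- list()
  for (e_id in seq_along(spans)) {
    e <- spans[[e_id]]
    if (!length(e$spans)) {
      rows[[length(rows) + 1]] <- data.frame(kind = e$kind, element = e_id,
                                             start = NA_integer_,
                                             end = NA_integer_)
      next
    }
    for (sp in e$spans) {
      letters_out[sp[1]:sp[2]] <- e$kind
      rows[[length(rows) + 1]] <- data.frame(kind = e$kind, element = e_id,
                                             start = as.integer(sp[1]),
                                             end = as.integer(sp[2]))
    }
  }
  elements <- if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(0), element = integer(0),
               start = integer(0), end = integer(0))
  if (anyNA(letters_out)) stop("internal error: unlabelled base")
  kinds <- vapply(spans, `[[`, "", "kind")
  cv <- vapply(SSE_KINDS, function(k) sum(kinds == k), 0L)
  structure(list(ss_string = paste(letters_out, collapse = ""),
                 elements = elements, count_vector = cv,
                 length = n),
            class = "structure_annotation")
}

#' @export
print.structure_annotation <- function(x, ...) {
  cat(x$ss_string, "\n")
  cat("elements:", paste(sprintf("%s=%d", names(x$count_vector),
                                 x$count_vector), collapse = " "), "\n")
  invisible(x)
}

#' Secondary structure string of an annotation
#' @param ann A `structure_annotation`.
#' @return The per-base letter string over `S,H,L,I,G,D,M`.
#' @export
to_ss_string <- function(ann) {
  stopifnot(inherits(ann, "structure_annotation"))
  ann$ss_string
}

#' Group structures into secondary structure families
#'
#' Two or more structures belong to the same family when they share exactly
#' the same count of each of the seven elements; base length, sequence
#' content and position play no role. Structures whose count vector is unique
#' remain unassigned. Assignment is invariant under permutation of the input.
#'
#' @param annotations List of `structure_annotation`s.
#' @param labels Structure labels (default names of `annotations`, or
#'   `structure_1` ...).
#' @return An `ssf_catalog`: list with `families` (named list, key =
#'   collapsed count vector, value = member labels), `unassigned` (labels),
#'   and `table` (data frame: label, key, family).
#' @export
assign_families <- function(annotations, labels = NULL) {
  stopifnot(length(annotations) >= 1)
  if (is.null(labels)) {
    labels <- names(annotations)
    if (is.null(labels)) labels <- sprintf("structure_%d", seq_along(annotations))
  }
  keys <- vapply(annotations, function(a)
    paste(sprintf("%s%d", SSE_KINDS, a$count_vector), collapse = ""), "")
  tab <- table(keys)
  fam_keys <- sort(names(tab)[tab >= 2])
  families <- lapply(fam_keys, function(k) labels[keys == k])
  names(families) <- fam_keys
  fam_id <- match(keys, fam_keys)
  df <- data.frame(label = labels, key = keys,
                   family = ifelse(is.na(fam_id), NA_character_,
                                   paste0("SSF", fam_id)))
  structure(list(families = families,
                 unassigned = labels[is.na(fam_id)],
                 table = df),
            class = "ssf_catalog")
}

#' @export
print.ssf_catalog <- function(x, ...) {
  cat(sprintf("%d families (>=2 members), %d unassigned structures\n",
              length(x$families), length(x$unassigned)))
  invisible(x)
}

#' Annotate a list of folded structures
#'
#' Convenience wrapper: annotates every structure of a folded population and
#' returns the annotations named `<sequence_id>.<rank>`.
#'
#' @param folded List of lists of [folded_structure()]s (as returned by
#'   [fold_population()]), or a flat list of structures.
#' @param dominant_only Keep only each sequence's S1 structure.
#' @return Named list of `structure_annotation`s.
#' @export
annotate_population <- function(folded, dominant_only = FALSE) {
  if (length(folded) && inherits(folded[[1]], "folded_structure")) {
    folded <- list(folded)
  }
  out <- list()
  for (fs_list in folded) {
    for (fs in fs_list) {
      if (dominant_only && fs$rank_label != "S1") next
      out[[paste0(fs$sequence_id, ".", fs$rank_label)]] <-
        annotate_structure(fs$pairs)
    }
  }
  out
}
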