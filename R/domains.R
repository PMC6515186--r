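#' Classify alignment columns
#'
#' Each column of a structural alignment is classified, in order: a *gap*
#' column when the gap fraction is >= 0.5; else a *consensus* column when a
#' single element letter reaches a fraction >= 0.5 of all rows (gaps counted
#' in the denominator); else a *non-gap* column.
#'
#' @param aln A [multiple_alignment()].
#' @return Data frame, one row per column: `class`
#'   (`"consensus"|"gap"|"nongap"`), `consensus_letter` (NA unless
#'   consensus), `consensus_fraction` (top letter fraction), `gap_fraction`.
#' @export
classify_columns <- function(aln) {
  m <- alignment_matrix(aln)
  nr <- nrow(m)
  out <- lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    gf <- sum(col == "-") / nr
    tab <- table(factor(col[col != "-"], levels = SSE_KINDS))
    top <- if (sum(tab)) which.max(tab) else NA_integer_
    cf <- if (sum(tab)) as.numeric(tab[top]) / nr else 0
    cls <- if (gf >= 0.5) "gap" else if (cf >= 0.5) "consensus" else "nongap"
    data.frame(class = cls,
               consensus_letter = if (cls == "consensus")
                 SSE_KINDS[top] else NA_character_,
               consensus_fraction = cf, gap_fraction = gf)
  })
  cc <- do.call(rbind, out)
  cc$column <- seq_len(nrow(cc))
  cc
}

#' Segment classified columns into regions
#'
#' Maximal runs of one class become regions; consensus domains, gap regions
#' and non-gap regions are each numbered 1..n from the 5' end. A consensus
#' domain's `ss_identity` concatenates its column consensus letters.
#'
#' @param cc Output of [classify_columns()].
#' @return Data frame: `kind`, `start`, `end` (column span), `index` (within
#'   kind), `ss_identity`.
#' @export
segment_regions <- function(cc) {
  rl <- rle(as.character(cc$class))
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  df <- data.frame(kind = rl$values, start = starts, end = ends)
  df$index <- stats::ave(seq_len(nrow(df)), df$kind, FUN = seq_along)
  df$ss_identity <- vapply(seq_len(nrow(df)), function(r) {
    if (df$kind[r] != "consensus") return(NA_character_)
    paste(cc$consensus_letter[df$start[r]:df$end[r]], collapse = "")
  }, "")
  df
}

# per-row original base position of every alignment cell (0 for gaps)
.base_positions <- function(m) {
  t(apply(m, 1, function(row) cumsum(row != "-") * (row != "-")))
}

# does each row "contain" each consensus domain? (matches the column
# consensus letter in >= `threshold` of the domain's columns)
.membership <- function(m, cc, regions, threshold = 0.5) {
  dom <- regions[regions$kind == "consensus", , drop = FALSE]
  if (!nrow(dom)) return(matrix(FALSE, nrow(m), 0))
  sapply(seq_len(nrow(dom)), function(d) {
    cols <- dom$start[d]:dom$end[d]
    cons <- cc$consensus_letter[cols]
    apply(m[, cols, drop = FALSE], 1, function(row)
      mean(row == cons) >= threshold)
  }) -> mm
  matrix(mm, nrow = nrow(m))
}

#' Per-region and per-population domain statistics
#'
#' For every region: the mean and SD of its per-sequence projected length
#' (non-gap characters a row places in the region's columns). For consensus
#' domains additionally: `conserved` (mean top-letter fraction over the
#' domain's columns), `frequency` (fraction of rows that contain the domain,
#' i.e. match the column consensus letter in >= 50% of its columns) and
#' `fraction_fixed_base` (mean over rows of the fraction of the row's domain
#' characters whose original base position lies in a fixed flank). Population
#' summaries: the mean number of consensus domains contained per row, and
#' the mean percentage of a row's characters lying in consensus-domain
#' columns.
#'
#' @param aln A [multiple_alignment()].
#' @param regions Output of [segment_regions()].
#' @param cc Output of [classify_columns()] (recomputed when omitted).
#' @param fixed_positions Base positions counted as fixed flanks (default
#'   `c(1:14, 55:69)`, the standard design).
#' @param membership_threshold Fraction of matching domain columns required
#'   for a row to contain a domain.
#' @return List of class `domain_stats`: `regions` (the region table with
#'   `mean_length`, `sd_length`, `conserved`, `frequency`,
#'   `fraction_fixed_base` columns added), `domains_per_sequence`,
#'   `pct_in_domains`, and the per-row vectors `row_domain_counts` and
#'   `row_pct_in_domains`.
#' @export
domain_stats <- function(aln, regions, cc = NULL,
                         fixed_positions = c(1:14, 55:69),
                         membership_threshold = 0.5) {
  if (is.null(cc)) cc <- classify_columns(aln)
  m <- alignment_matrix(aln)
  bp <- .base_positions(m)
  nr <- nrow(m)
  regions$mean_length <- NA_real_
  regions$sd_length <- NA_real_
  regions$conserved <- NA_real_
  regions$frequency <- NA_real_
  regions$fraction_fixed_base <- NA_real_
  mem <- .membership(m, cc, regions, membership_threshold)
  d <- 0L
  for (r in seq_len(nrow(regions))) {
    cols <- regions$start[r]:regions$end[r]
    lens <- apply(m[, cols, drop = FALSE], 1, function(row) sum(row != "-"))
    regions$mean_length[r] <- mean(lens)
    regions$sd_length[r] <- stats::sd(lens)
    if (regions$kind[r] == "consensus") {
      d <- d + 1L
      regions$conserved[r] <- mean(cc$consensus_fraction[cols])
      regions$frequency[r] <- mean(mem[, d])
      fr <- vapply(seq_len(nr), function(i) {
        pos <- bp[i, cols]
        pos <- pos[pos > 0]
        if (!length(pos)) return(NA_real_)
        mean(pos %in% fixed_positions)
      }, 0)
      regions$fraction_fixed_base[r] <- mean(fr, na.rm = TRUE)
    }
  }
  dom_cols <- unlist(lapply(which(regions$kind == "consensus"), function(r)
    regions$start[r]:regions$end[r]))
  row_pct <- vapply(seq_len(nr), function(i) {
    nongap <- bp[i, ] > 0
    100 * sum(nongap[dom_cols]) / sum(nongap)
  }, 0)
  row_counts <- if (ncol(mem)) rowSums(mem) else rep(0, nr)
  names(row_counts) <- rownames(m)
  names(row_pct) <- rownames(m)
  structure(list(regions = regions,
                 domains_per_sequence = mean(row_counts),
                 pct_in_domains = mean(row_pct),
                 row_domain_counts = row_counts,
                 row_pct_in_domains = row_pct),
            class = "domain_stats")
}

#' @export
print.domain_stats <- function(x, ...) {
  nd <- sum(x$regions$kind == "consensus")
  cat(sprintf("%d consensus domains; %.2f domains per sequence; %.1f%% of SS$ in domains\n",
              nd, x$domains_per_sequence, x$pct_in_domains))
  invisible(x)
}

#' Project consensus domains onto ungapped base coordinates
#'
#' After gap removal, each row's characters inside a consensus domain map to
#' original base positions; the projection yields per-base inclusion ratios
#' and the distance statistics:
#' \itemize{
#'   \item `d_between[n]`: mean over rows of (start of domain n+1 - end of
#'     domain n - 1) in base coordinates;
#'   \item `d_prior`, `d_next`: mean distance from a domain to the previous /
#'     next domain, or to the strand end when none exists (5' to 3');
#'   \item `domain_loss`: mean count of a domain's columns where a row
#'     carries a gap (bases missing from the domain's interior).
#' }
#'
#' @inheritParams domain_stats
#' @return List of class `projected_domains`: `spans` (data frame: row,
#'   domain, start, end in base coordinates; NA when a row has no character
#'   in the domain), `inclusion` (domains x length matrix of per-base
#'   inclusion ratios), `d_between`, `d_prior`, `d_next`, `domain_loss`,
#'   `n_missing` (rows lacking any character for at least one domain).
#' @export
project_domains <- function(aln, regions, cc = NULL) {
  if (is.null(cc)) cc <- classify_columns(aln)
  m <- alignment_matrix(aln)
  bp <- .base_positions(m)
  nr <- nrow(m)
  dom <- regions[regions$kind == "consensus", , drop = FALSE]
  nd <- nrow(dom)
  if (!nd) stop("no consensus domains to project")
  seq_lens <- rowSums(m != "-")
  spans <- do.call(rbind, lapply(seq_len(nr), function(i) {
    do.call(rbind, lapply(seq_len(nd), function(d) {
      cols <- dom$start[d]:dom$end[d]
      pos <- bp[i, cols]; pos <- pos[pos > 0]
      loss <- sum(bp[i, cols] == 0)
      if (!length(pos)) {
        data.frame(row = rownames(m)[i], domain = d, start = NA_integer_,
                   end = NA_integer_, loss = loss)
      } else {
        data.frame(row = rownames(m)[i], domain = d, start = min(pos),
                   end = max(pos), loss = loss)
      }
    }))
  }))
  L <- max(seq_lens)
  inclusion <- matrix(0, nd, L)
  for (d in seq_len(nd)) {
    sp <- spans[spans$domain == d & !is.na(spans$start), , drop = FALSE]
    for (q in seq_len(nrow(sp))) {
      inclusion[d, sp$start[q]:sp$end[q]] <-
        inclusion[d, sp$start[q]:sp$end[q]] + 1
    }
    inclusion[d, ] <- inclusion[d, ] / nr
  }
  d_between <- if (nd > 1) vapply(seq_len(nd - 1), function(d) {
    a <- spans[spans$domain == d, ]
    b <- spans[spans$domain == d + 1, ]
    mean(b$start - a$end - 1, na.rm = TRUE)
  }, 0) else numeric(0)
  d_prior <- vapply(seq_len(nd), function(d) {
    cur <- spans[spans$domain == d, ]
    prev_end <- if (d > 1) spans[spans$domain == d - 1, ]$end else rep(0L, nr)
    prev_end[is.na(prev_end)] <- 0L
    mean(cur$start - prev_end - 1, na.rm = TRUE)
  }, 0)
  d_next <- vapply(seq_len(nd), function(d) {
    cur <- spans[spans$domain == d, ]
    nxt <- if (d < nd) spans[spans$domain == d + 1, ]$start else seq_lens + 1L
    nxt[is.na(nxt)] <- (seq_lens + 1L)[is.na(nxt)]
    mean(nxt - cur$end - 1, na.rm = TRUE)
  }, 0)
  loss <- vapply(seq_len(nd), function(d)
    mean(spans$loss[spans$domain == d]), 0)
  n_missing <- sum(is.na(spans$start))
  if (n_missing) {
    message(n_missing, " row/domain projections are empty (row lacks any ",
            "character in the domain)")
  }
  structure(list(spans = spans, inclusion = inclusion, d_between = d_between,
                 d_prior = d_prior, d_next = d_next, domain_loss = loss,
                 n_missing = n_missing),
            class = "projected_domains")
}
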