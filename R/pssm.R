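.ss_matrix <- function(ss_strings) {
  lens <- nchar(ss_strings)
  if (length(unique(lens)) != 1) {
    stop("ragged lengths: all structure strings must have equal length")
  }
  m <- do.call(rbind, strsplit(ss_strings, ""))
  bad <- !m %in% SSE_KINDS
  if (any(bad)) {
    stop("letter outside the S,H,L,I,G,D,M alphabet: '",
         m[which(bad)[1]], "'")
  }
  m
}

#' Per-position element frequencies
#'
#' For a set of equal-length secondary structure strings, the fraction of
#' strings carrying each of the seven element letters at each position.
#'
#' @param ss_strings Character vector of structure strings (letters
#'   `S,H,L,I,G,D,M`), all the same length.
#' @return A `position_frequency_matrix`: list with `freq` (7 x l matrix,
#'   rows in `S,H,L,I,G,D,M` order, columns summing to 1), `n_strings` and
#'   `l`.
#' @examples
#' compute_frequencies(c("SSH", "SHH", "SSL", "SSH"))$freq
#' @export
compute_frequencies <- function(ss_strings) {
  m <- .ss_matrix(ss_strings)
  f <- vapply(seq_len(ncol(m)), function(j) {
    tab <- table(factor(m[, j], levels = SSE_KINDS))
    as.numeric(tab) / nrow(m)
  }, numeric(7))
  rownames(f) <- SSE_KINDS
  structure(list(freq = f, n_strings = nrow(m), l = ncol(m)),
            class = "position_frequency_matrix")
}

#' Frequency difference between dominant-only and dominant+suboptimal sets
#'
#' Percentage-point difference `100 * (f_dom - f_domsub)` per element and
#' position; every column sums to zero.
#'
#' @param pfm_dom,pfm_domsub [compute_frequencies()] results of equal length.
#' @return 7 x l numeric matrix of percentage points.
#' @export
delta_sse <- function(pfm_dom, pfm_domsub) {
  if (pfm_dom$l != pfm_domsub$l) {
    stop("frequency matrices have different lengths (",
         pfm_dom$l, " vs ", pfm_domsub$l, ")")
  }
  100 * (pfm_dom$freq - pfm_domsub$freq)
}

#' Position-specific score matrix against a random background
#'
#' Scores the per-position enrichment of each structural element in a
#' foreground population of structure strings relative to a random-sequence
#' background, with additive smoothing:
#' \deqn{\mu_{k,j} = (c^{bg}_{k,j} + \alpha) / (N_{bg} + 7\alpha)}
#' \deqn{\theta_{k,j} = (7\alpha\,\mu_{k,j} + c_{k,j}) / (7\alpha + N)}
#' \deqn{W_{k,j} = f_{k,j} \log_2(\theta_{k,j}/\mu_{k,j})}
#' \deqn{H_j = \max\{0,\ \log_2 7 - \sum_k f_{k,j}\log_2(1/\mu_{k,j})\}}
#' \deqn{S_{k,j} = H_j W_{k,j}}
#' where `c` and `f` are foreground counts and frequencies. `S` is zero
#' wherever the foreground matches the background exactly and zero for
#' absent elements (`c = 0`); the signed display score
#' `Dsp = H_j log2(theta/mu)` stays negative for absent-but-expected
#' elements and is the quantity to plot below the axis.
#'
#' @param foreground,background Character vectors of equal-length structure
#'   strings.
#' @param alpha Additive smoothing parameter (> 0).
#' @return A `pssm` object: list of 7 x l matrices `counts`, `f`, `mu`,
#'   `theta`, `W`, `S`, `Dsp` and the vector `H`, plus `alpha`, `n_fg`,
#'   `n_bg`, `l`.
#' @export
compute_pssm <- function(foreground, background, alpha = 1) {
  if (alpha <= 0) stop("alpha must be > 0 (mu could vanish)")
  if (!length(background)) stop("background must be non-empty")
  fg <- .ss_matrix(foreground)
  bg <- .ss_matrix(background)
  if (ncol(fg) != ncol(bg)) {
    stop("foreground and background strings have different lengths")
  }
  l <- ncol(fg); N <- nrow(fg); Nbg <- nrow(bg)
  count_mat <- function(m) {
    vapply(seq_len(ncol(m)), function(j)
      as.numeric(table(factor(m[, j], levels = SSE_KINDS))), numeric(7))
  }
  c_fg <- count_mat(fg); rownames(c_fg) <- SSE_KINDS
  c_bg <- count_mat(bg)
  f <- c_fg / N
  mu <- (c_bg + alpha) / (Nbg + 7 * alpha)
  theta <- sweep(7 * alpha * mu + c_fg, 2, rep(7 * alpha + N, l), "/")
  W <- f * log2(theta / mu)
  H <- pmax(0, log2(7) - colSums(f * log2(1 / mu)))
  S <- sweep(W, 2, H, "*")
  Dsp <- sweep(log2(theta / mu), 2, H, "*")
  dimnames(mu) <- dimnames(theta) <- dimnames(W) <- dimnames(S) <-
    dimnames(Dsp) <- dimnames(f) <- list(SSE_KINDS, NULL)
  structure(list(alpha = alpha, counts = c_fg, f = f, mu = mu, theta = theta,
                 W = W, H = H, S = S, Dsp = Dsp, n_fg = N, n_bg = Nbg, l = l),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("pssm: %d positions, %d foreground / %d background strings, alpha = %g\n",
              x$l, x$n_fg, x$n_bg, x$alpha))
  invisible(x)
}

#' Score a structure string against a PSSM
#'
#' Total score in bits: the sum over positions of `S[letter_j, j]`.
#'
#' @param pssm A [compute_pssm()] result.
#' @param ss_string Structure string of the PSSM's length.
#' @return Numeric scalar (bits).
#' @export
score_string <- function(pssm, ss_string) {
  ch <- strsplit(ss_string, "")[[1]]
  if (length(ch) != pssm$l) {
    stop("string length ", length(ch), " does not match PSSM length ", pssm$l)
  }
  k <- match(ch, SSE_KINDS)
  if (anyNA(k)) {
    stop("letter outside the S,H,L,I,G,D,M alphabet: '", ch[which(is.na(k))[1]], "'")
  }
  sum(pssm$S[cbind(k, seq_along(ch))])
}

#' Best-matching structure string in a set
#'
#' Returns the label of the highest-scoring member; ties resolve to the
#' lexicographically smallest label (reported via a message).
#'
#' @param pssm A [compute_pssm()] result.
#' @param ss_strings Named character vector (or list) of structure strings.
#' @return Label of the best match, with the score as attribute `score`.
#' @export
best_match <- function(pssm, ss_strings) {
  ss <- unlist(ss_strings)
  labels <- names(ss)
  if (is.null(labels)) labels <- sprintf("string_%d", seq_along(ss))
  scores <- vapply(ss, function(s) score_string(pssm, s), 0)
  top <- max(scores)
  hits <- sort(labels[scores >= top - 1e-12])
  if (length(hits) > 1) {
    message("tie between ", paste(hits, collapse = ", "),
            "; reporting the lexicographically smallest")
  }
  structure(hits[1], score = top)
}
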