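# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: enumeration instead of dynamic programming, a
# nesting-tree traversal instead of the scan-based classifier.

## exhaustive maximum nested pairing (no DP): at each interval, the first
## base is left unpaired or paired with every admissible partner
oracle_max_pairs <- function(seq, min_loop = 3L) {
  ch <- strsplit(seq, "")[[1]]
  ok <- function(a, b) paste0(ch[a], ch[b]) %in%
    c("AT", "TA", "GC", "CG", "GT", "TG")
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (!ok(i, k)) next
      cand <- 1L + rec(i + 1L, k - 1L) + if (k < j) rec(k + 1L, j) else 0L
      if (cand > best) best <- cand
    }
    best
  }
  if (length(ch) < min_loop + 2L) return(0L)
  rec(1L, length(ch))
}

## independent SSE decomposition: build the nesting tree of pairs, then walk
## it, classifying loops from each node's children and helices from chains
## of single-child nodes with no intervening unpaired bases
oracle_annotate <- function(bps) {
  n <- bps$length
  p <- integer(n)
  pr <- bps$pairs
  if (NROW(pr)) { p[pr[, 1]] <- pr[, 2]; p[pr[, 2]] <- pr[, 1] }
  # children of an interval (a, b): outermost pairs strictly inside
  kids <- function(a, b) {
    out <- list(); k <- a + 1L
    while (k <= b - 1L) {
      if (p[k] > k) { out[[length(out) + 1L]] <- c(k, p[k]); k <- p[k] + 1L }
      else k <- k + 1L
    }
    out
  }
  letters_v <- rep(NA_character_, n)
  counts <- stats::setNames(integer(7), c("S", "H", "L", "I", "G", "D", "M"))
  visit <- function(pair) {
    # walk down the helix starting at `pair`
    top <- pair
    stem <- list(pair)
    repeat {
      ks <- kids(stem[[length(stem)]][1], stem[[length(stem)]][2])
      last <- stem[[length(stem)]]
      if (length(ks) == 1 && ks[[1]][1] == last[1] + 1L &&
          ks[[1]][2] == last[2] - 1L) {
        stem[[length(stem) + 1L]] <- ks[[1]]
      } else break
    }
    inner <- stem[[length(stem)]]
    ks <- kids(inner[1], inner[2])
    unpaired_inside <- setdiff(inner[1]:inner[2], c(inner,
      unlist(lapply(ks, function(q) q[1]:q[2]))))
    loop_kind <- if (length(ks) == 0) "L"
      else if (length(ks) >= 2) "M"
      else {
        left <- sum(unpaired_inside < ks[[1]][1])
        right <- sum(unpaired_inside > ks[[1]][2])
        if (left > 0 && right > 0) "I" else "G"
      }
    helix_kind <- if (loop_kind == "L") "H" else "D"
    counts[helix_kind] <<- counts[helix_kind] + 1L
    counts[loop_kind] <<- counts[loop_kind] + 1L
    for (s in stem) {
      letters_v[s[1]] <<- helix_kind
      letters_v[s[2]] <<- helix_kind
    }
    letters_v[unpaired_inside] <<- loop_kind
    for (k2 in ks) visit(k2)
  }
  top_level <- kids(0L, n + 1L)
  for (tp in top_level) visit(tp)
  ext <- which(is.na(letters_v))
  letters_v[ext] <- "S"
  counts["S"] <- if (length(ext)) {
    sum(diff(c(-1L, ext)) > 1L)
  } else 0L
  list(ss_string = paste(letters_v, collapse = ""), count_vector = counts)
}

## exhaustive global affine alignment: enumerate every alignment path and
## score the resulting gapped strings directly (gap run of length L costs
## open + ext * L in either row)
oracle_align_score <- function(a, b, match = 10, mismatch = 0, open = 10,
                               ext = 0.2) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  best <- -Inf
  # last = 0 none/match column, 1 = inside a gap-in-b run, 2 = gap-in-a run
  rec <- function(i, j, sc, last) {
    if (i > na && j > nb) {
      if (sc > best) best <<- sc
      return(invisible())
    }
    if (i <= na && j <= nb) {
      rec(i + 1L, j + 1L,
          sc + if (ca[i] == cb[j]) match else mismatch, 0L)
    }
    if (i <= na) {
      rec(i + 1L, j, sc - ext - if (last == 1L) 0 else open, 1L)
    }
    if (j <= nb) {
      rec(i, j + 1L, sc - ext - if (last == 2L) 0 else open, 2L)
    }
  }
  rec(1L, 1L, 0, 0L)
  best
}

## random realizable planted specs
random_planted_spec <- function(seed, max_len = 40L) {
  set.seed(seed)
  H <- sample(0:3, 1)
  if (H == 0) {
    cv <- c(S = 1L)
    len <- sample(5:max_len, 1)
    return(planted_spec(len, cv, seed = seed + 1L))
  }
  M <- if (H >= 2) sample(0:min(2, H - 1), 1) else 0L
  I <- sample(0:2, 1)
  G <- sample(0:2, 1)
  D <- I + G + M
  S <- sample(0:(H - M + 1), 1)
  cv <- c(S = S, H = H, L = H, I = I, G = G, D = D, M = M)
  minlen <- 2 * (H + D) + 3 * H + 2 * I + G + M + S
  if (minlen > max_len) return(random_planted_spec(seed + 1000L, max_len))
  len <- if (minlen == max_len) minlen else sample(minlen:max_len, 1)
  planted_spec(len, cv, seed = seed + 1L)
}

random_ss_string <- function(len, alphabet = c("S", "H", "L")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
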