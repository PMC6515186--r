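#' Planted-structure specification
#'
#' Describes a synthetic structure to generate: a strand length and the exact
#' number of each of the seven secondary structure elements the realized
#' base-pair set must decompose into. Realizability is validated
#' constructively; the structural constraints are
#' \itemize{
#'   \item hairpin stems and hairpin loops come in pairs (`H == L`);
#'   \item every duplex is separated from the next helix inward by exactly
#'     one internal loop, bulge or multi-branched loop (`D == I + G + M`);
#'   \item a multi-branched loop needs at least two branches, so `H >= M + 1`
#'     whenever `M > 0`;
#'   \item without any helix the strand is one single-stranded segment
#'     (`S == 1`, all other counts 0);
#'   \item with helices, the exterior single-stranded runs fit around the
#'     `H - M` top-level stems (`S <= H - M + 1`).
#' }
#'
#' @param length Strand length.
#' @param element_counts Named non-negative integer vector over
#'   `S,H,L,I,G,D,M`.
#' @param seed Integer seed controlling the realization.
#' @return A `planted_spec` object.
#' @export
planted_spec <- function(length, element_counts, seed = 1L) {
  cv <- integer(7); names(cv) <- SSE_KINDS
  cv[names(element_counts)] <- as.integer(element_counts)
  if (any(cv < 0)) stop("element counts must be non-negative")
  msg <- .check_plantable(length, cv)
  if (!is.null(msg)) stop("unrealizable spec: ", msg)
  structure(list(length = as.integer(length), element_counts = cv,
                 seed = as.integer(seed)),
            class = "planted_spec")
}

.check_plantable <- function(length, cv) {
  S <- cv["S"]; H <- cv["H"]; L <- cv["L"]; I <- cv["I"]
  G <- cv["G"]; D <- cv["D"]; M <- cv["M"]
  if (H != L) return("hairpin stems and loops must match (H == L)")
  if (D != I + G + M) return("duplex count must equal I + G + M")
  if (M > 0 && H < M + 1) {
    return("each multi-branched loop needs >= 2 branches (H >= M + 1)")
  }
  if (H == 0) {
    if (D + I + G + M > 0) return("loops/duplexes require a hairpin (e.g., a bulge with zero helices)")
    if (S != 1) return("an unpaired strand is exactly one single-stranded segment")
    if (length < 1) return("length must be >= 1")
    return(NULL)
  }
  k <- H - M  # top-level units
  if (S > k + 1) return(sprintf("at most %d exterior runs fit around %d top-level stems", k + 1, k))
  if (length < .plant_min_length(cv)) {
    return(sprintf("length %d below the minimum %d for these counts",
                   length, .plant_min_length(cv)))
  }
  NULL
}

.plant_min_length <- function(cv) {
  # minimal realization: 1-bp helices, 3-nt hairpin loops, 1+1 internal
  # loops, 1-nt bulges, 1-nt multiloop spacer, 1-nt exterior runs
  2 * (cv["H"] + cv["D"]) + 3 * cv["L"] + 2 * cv["I"] + cv["G"] + cv["M"] +
    cv["S"]
}

#' Realize a planted structure
#'
#' Constructs a base-pair set whose [annotate_structure()] decomposition has
#' exactly the requested element counts, plus a sequence whose paired bases
#' are Watson-Crick compatible with the pairs. Surplus length beyond the
#' minimal realization is distributed at random (seeded) over loops, runs and
#' stems; the same spec always yields the same realization.
#'
#' @param spec A [planted_spec()].
#' @param id Record label.
#' @return List with `record` (a [sequence_record()], origin `"planted"`)
#'   and `pairs` (a [base_pair_set()]).
#' @examples
#' ps <- planted_spec(20, c(S = 2, H = 1, L = 1), seed = 7)
#' out <- plant_structure(ps)
#' annotate_structure(out$pairs)$count_vector
#' @export
plant_structure <- function(spec, id = "planted") {
  stopifnot(inherits(spec, "planted_spec"))
  cv <- spec$element_counts
  old <- .save_rng(spec$seed)
  on.exit(.restore_rng(old))

  if (cv["H"] == 0) {
    seqs <- paste(sample(c("A", "C", "G", "T"), spec$length, replace = TRUE),
                  collapse = "")
    rec <- sequence_record(id, seqs, origin = "planted")
    bps <- base_pair_set(NULL, spec$length)
    return(list(record = rec, pairs = bps))
  }

  ## ---- build the unit tree -------------------------------------------
  # node: list(type = "hairpin"|"wrap"|"multi", ...) with unit lengths
  units <- replicate(cv["H"], list(type = "hairpin", bp = 1L, loop = 3L),
                     simplify = FALSE)
  for (m in seq_len(cv["M"])) {
    pick <- sort(sample.int(length(units), 2L))
    node <- list(type = "multi", bp = 1L,
                 children = units[pick],
                 spacers = c(0L, 1L, 0L))
    units <- c(units[-pick], list(node))
  }
  wraps <- c(rep("I", cv["I"]), rep("G", cv["G"]))
  if (length(wraps) > 1) wraps <- sample(wraps)
  for (w in wraps) {
    pick <- sample.int(length(units), 1L)
    node <- if (w == "I") {
      list(type = "wrap", bp = 1L, left = 1L, right = 1L,
           child = units[[pick]])
    } else {
      list(type = "wrap", bp = 1L, left = 1L, right = 0L,
           child = units[[pick]])
    }
    units[[pick]] <- node
  }
  k <- length(units)
  s_lens <- integer(k + 1)
  if (cv["S"] > 0) {
    slots <- sample.int(k + 1, cv["S"])
    s_lens[slots] <- 1L
  }

  ## ---- distribute surplus length -------------------------------------
  unit_len <- function(u) {
    switch(u$type,
           hairpin = 2L * u$bp + u$loop,
           wrap = 2L * u$bp + u$left + u$right + unit_len(u$child),
           multi = 2L * u$bp + sum(u$spacers) +
             sum(vapply(u$children, unit_len, 0L)))
  }
  cur <- sum(vapply(units, unit_len, 0L)) + sum(s_lens)
  extra <- spec$length - cur
  while (extra > 0) {
    # choose: 1 = an S run (if any), 2 = a loop base, 3 = a stem pair (+2)
    choices <- c(if (cv["S"] > 0) "srun", "loop",
                 if (extra >= 2) "stem")
    what <- if (length(choices) == 1) choices else sample(choices, 1)
    if (what == "srun") {
      open_slots <- which(s_lens > 0)
      slot <- if (length(open_slots) == 1) open_slots else sample(open_slots, 1)
      s_lens[slot] <- s_lens[slot] + 1L
      extra <- extra - 1L
    } else {
      pick <- sample.int(length(units), 1L)
      res <- .grow_unit(units[[pick]], what)
      if (res$done) {
        units[[pick]] <- res$unit
        extra <- extra - (if (what == "stem") 2L else 1L)
      }
      # if the chosen unit could not grow that way, resample
    }
  }

  ## ---- materialize to pairs and sequence -----------------------------
  pairs <- matrix(integer(0), ncol = 2)
  seq_ch <- character(spec$length)
  pos <- 1L
  emit_unpaired <- function(len) {
    if (len > 0) {
      seq_ch[pos:(pos + len - 1)] <<- sample(c("A", "C", "G", "T"), len,
                                             replace = TRUE)
      pos <<- pos + len
    }
  }
  emit_unit <- function(u) {
    bp <- u$bp
    left <- pos
    pos <<- pos + bp  # reserve stem left strand; fill later
    inner_start <- pos
    switch(u$type,
           hairpin = emit_unpaired(u$loop),
           wrap = { emit_unpaired(u$left); emit_unit(u$child)
                    emit_unpaired(u$right) },
           multi = {
             emit_unpaired(u$spacers[1])
             for (ci in seq_along(u$children)) {
               emit_unit(u$children[[ci]])
               emit_unpaired(u$spacers[ci + 1])
             }
           })
    right_start <- pos
    pos <<- pos + bp
    for (b in seq_len(bp)) {
      i <- left + b - 1L
      j <- right_start + bp - b
      pairs <<- rbind(pairs, c(i, j))
      wc <- sample(list(c("A", "T"), c("T", "A"), c("G", "C"), c("C", "G")), 1)[[1]]
      seq_ch[i] <<- wc[1]
      seq_ch[j] <<- wc[2]
    }
  }
  emit_unpaired(s_lens[1])
  for (ui in seq_along(units)) {
    emit_unit(units[[ui]])
    emit_unpaired(s_lens[ui + 1])
  }
  stopifnot(pos == spec$length + 1L)
  bps <- base_pair_set(pairs, spec$length)
  rec <- sequence_record(id, paste(seq_ch, collapse = ""), origin = "planted")
  list(record = rec, pairs = bps)
}

# grow a unit in place: add one loop base or one stem pair somewhere inside.
# Returns list(unit, done).
.grow_unit <- function(u, what) {
  if (what == "stem") {
    # grow this unit's own stem; always possible
    u$bp <- u$bp + 1L
    return(list(unit = u, done = TRUE))
  }
  # loop growth: pick a random loop/spacer inside this unit's subtree
  if (u$type == "hairpin") {
    u$loop <- u$loop + 1L
    return(list(unit = u, done = TRUE))
  }
  if (u$type == "wrap") {
    if (u$right == 0L) {
      # bulge: may only grow the bulged side, or recurse into the child
      if (stats::runif(1) < 0.5) {
        u$left <- u$left + 1L
        return(list(unit = u, done = TRUE))
      }
      res <- .grow_unit(u$child, what)
      u$child <- res$unit
      return(list(unit = u, done = res$done))
    }
    r <- stats::runif(1)
    if (r < 1 / 3) u$left <- u$left + 1L
    else if (r < 2 / 3) u$right <- u$right + 1L
    else {
      res <- .grow_unit(u$child, what)
      u$child <- res$unit
      return(list(unit = u, done = res$done))
    }
    return(list(unit = u, done = TRUE))
  }
  # multi: grow a spacer or recurse
  if (stats::runif(1) < 0.5) {
    slot <- sample.int(length(u$spacers), 1L)
    u$spacers[slot] <- u$spacers[slot] + 1L
    return(list(unit = u, done = TRUE))
  }
  ci <- sample.int(length(u$children), 1L)
  res <- .grow_unit(u$children[[ci]], what)
  u$children[[ci]] <- res$unit
  list(unit = u, done = res$done)
}
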