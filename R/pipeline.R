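#' Pipeline configuration
#'
#' Single configuration object for [run_pipeline()]. Every module
#' precondition is validated up front.
#'
#' @param design A [library_design()] for generated populations.
#' @param aptamer_fasta Optional FASTA of candidate (foreground) sequences;
#'   when `NULL` a foreground of `n_foreground` sequences is generated from
#'   `design`.
#' @param n_foreground Foreground population size when generated.
#' @param n_background Background population size.
#' @param seed Integer seed for all randomness.
#' @param engine Folding engine (see [baseline_engine()]).
#' @param conditions [folding_conditions()].
#' @param alpha PSSM smoothing parameter.
#' @param scheme Alignment [substitution_scheme()].
#' @param fixed_positions Base positions treated as fixed flanks.
#' @param out_dir Directory for tabular outputs.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(design = equibase_design(),
                            aptamer_fasta = NULL,
                            n_foreground = 42L,
                            n_background = 1000L,
                            seed = 1L,
                            engine = baseline_engine(),
                            conditions = folding_conditions(),
                            alpha = 1,
                            scheme = substitution_scheme(),
                            fixed_positions = c(1:14, 55:69),
                            out_dir = tempfile("aptastruct_run_")) {
  stopifnot(inherits(design, "library_design"),
            inherits(engine, "fold_engine"),
            inherits(conditions, "folding_conditions"),
            inherits(scheme, "substitution_scheme"),
            n_background >= 1, alpha > 0, seed == as.integer(seed))
  if (!is.null(aptamer_fasta) && !file.exists(aptamer_fasta)) {
    stop("aptamer_fasta does not exist: ", aptamer_fasta)
  }
  structure(list(design = design, aptamer_fasta = aptamer_fasta,
                 n_foreground = as.integer(n_foreground),
                 n_background = as.integer(n_background),
                 seed = as.integer(seed), engine = engine,
                 conditions = conditions, alpha = alpha, scheme = scheme,
                 fixed_positions = fixed_positions, out_dir = out_dir),
            class = "pipeline_config")
}

.config_hash <- function(config) {
  drop <- c("engine", "out_dir")
  x <- config[setdiff(names(config), drop)]
  x$engine_class <- class(config$engine)[1]
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, force = TRUE, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

.write_tsv <- function(df, path, header_lines = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header_lines) writeLines(paste0("# ", h), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.matrix_tsv <- function(mat, path, header_lines = character(0)) {
  df <- data.frame(element = rownames(mat),
                   formatC(mat, format = "g", digits = 10),
                   check.names = FALSE)
  names(df) <- c("element", sprintf("pos%d", seq_len(ncol(mat))))
  .write_tsv(df, path, header_lines)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: generate or ingest the foreground population; generate
#' the random background; fold both; annotate every structure; compute
#' frequency maps, the dominant-vs-dominant+suboptimal difference matrix and
#' the PSSM; align the four canonical string sets (foreground/background x
#' dominant-only/dominant+suboptimal); segment consensus domains and project
#' them onto base coordinates. All tabular artifacts are written under
#' `config$out_dir`; regenerating with the same config and seed reproduces
#' them byte-identically.
#'
#' @param config A [pipeline_config()].
#' @param align_background Also align the background sets (the slowest
#'   stage; skipped when `FALSE`).
#' @param max_align Cap on the number of rows entering each alignment
#'   (subsampling is seeded); `Inf` to align everything.
#' @return A `run_report` (list): populations, folds, annotations, catalog,
#'   matrices, alignments, domain tables, projections, and provenance.
#' @export
run_pipeline <- function(config, align_background = TRUE, max_align = 250L) {
  t0 <- Sys.time()
  log_stage <- function(fmt, ...) {
    message(sprintf("[%5.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                    sprintf(fmt, ...)))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  ## stage 1: populations
  if (!is.null(config$aptamer_fasta)) {
    fg <- read_fasta(config$aptamer_fasta, origin = "aptamer",
                     design = config$design)
  } else {
    fg <- generate_library(config$design, config$n_foreground,
                           seed = config$seed, prefix = "F")
  }
  bg <- generate_library(config$design, config$n_background,
                         seed = config$seed + 1L, prefix = "B")
  log_stage("populations: %d foreground, %d background", length(fg), length(bg))

  ## stage 2: fold
  fg_folds <- fold_population(fg, config$conditions, config$engine)
  bg_folds <- fold_population(bg, config$conditions, config$engine)
  n_unfolded <- sum(vapply(bg_folds, function(x) x[[1]]$dG == 0, TRUE))
  if (n_unfolded) log_stage("note: %d background sequences unfolded", n_unfolded)
  log_stage("folded: %d foreground structures, %d background structures",
            sum(lengths(fg_folds)), sum(lengths(bg_folds)))

  ## stage 3: annotate + families
  ann <- list(
    fg_dom = annotate_population(fg_folds, dominant_only = TRUE),
    fg_all = annotate_population(fg_folds),
    bg_dom = annotate_population(bg_folds, dominant_only = TRUE),
    bg_all = annotate_population(bg_folds))
  catalog <- assign_families(ann$fg_all)
  ss <- lapply(ann, function(a) vapply(a, to_ss_string, ""))
  ss_table <- data.frame(label = names(ann$fg_all),
                         ss = unname(ss$fg_all),
                         t(vapply(ann$fg_all, `[[`, integer(7), "count_vector")),
                         family = catalog$table$family)
  .write_tsv(ss_table, file.path(config$out_dir, "ss_table.tsv"))
  log_stage("families: %d with >= 2 members, %d unassigned",
            length(catalog$families), length(catalog$unassigned))

  ## stage 4: frequencies, delta, PSSM
  pfm <- lapply(ss, compute_frequencies)
  delta_fg <- delta_sse(pfm$fg_dom, pfm$fg_all)
  delta_bg <- delta_sse(pfm$bg_dom, pfm$bg_all)
  pssm_dom <- compute_pssm(ss$fg_dom, ss$bg_dom, alpha = config$alpha)
  pssm_all <- compute_pssm(ss$fg_all, ss$bg_all, alpha = config$alpha)
  hash <- .config_hash(config)
  hdr <- sprintf("config %s seed %d", hash, config$seed)
  .matrix_tsv(pfm$fg_dom$freq, file.path(config$out_dir, "freq_fg_dom.tsv"), hdr)
  .matrix_tsv(pfm$fg_all$freq, file.path(config$out_dir, "freq_fg_all.tsv"), hdr)
  .matrix_tsv(delta_fg, file.path(config$out_dir, "delta_fg.tsv"), hdr)
  .matrix_tsv(delta_bg, file.path(config$out_dir, "delta_bg.tsv"), hdr)
  .matrix_tsv(pssm_dom$S, file.path(config$out_dir, "pssm_S_dom.tsv"), hdr)
  .matrix_tsv(pssm_dom$Dsp, file.path(config$out_dir, "pssm_Dsp_dom.tsv"), hdr)
  .matrix_tsv(pssm_all$S, file.path(config$out_dir, "pssm_S_all.tsv"), hdr)
  log_stage("matrices written")

  ## stage 5: alignments + domains for the canonical sets
  sets <- c("fg_dom", "fg_all", if (align_background) c("bg_dom", "bg_all"))
  alignments <- list(); domain_tables <- list(); projections <- list()
  for (nm in sets) {
    strings <- ss[[nm]]
    if (length(strings) > max_align) {
      old <- .save_rng(config$seed + 2L)
      strings <- strings[sort(sample.int(length(strings), max_align))]
      .restore_rng(old)
    }
    if (length(strings) < 2) {
      log_stage("set %s has < 2 strings; skipped", nm)
      next
    }
    aln <- progressive_align(strings, config$scheme)
    cc <- classify_columns(aln)
    regions <- segment_regions(cc)
    stats <- domain_stats(aln, regions, cc,
                          fixed_positions = config$fixed_positions)
    alignments[[nm]] <- aln
    domain_tables[[nm]] <- stats
    if (any(regions$kind == "consensus")) {
      projections[[nm]] <- suppressMessages(project_domains(aln, regions, cc))
    }
    .write_tsv(stats$regions, file.path(config$out_dir,
                                        paste0("regions_", nm, ".tsv")), hdr)
    write_clustal(aln, file.path(config$out_dir, paste0("mssa_", nm, ".aln")))
    log_stage("aligned %s: %d rows, %d columns, %d consensus domains",
              nm, length(aln$rows), aln$n_columns,
              sum(regions$kind == "consensus"))
  }
  export_1d_map(domain_tables, file.path(config$out_dir, "regions_1d.track"))

  structure(list(config = config, config_hash = hash,
                 foreground = fg, background = bg,
                 fg_folds = fg_folds, bg_folds = bg_folds,
                 annotations = ann, ss = ss, catalog = catalog,
                 pfm = pfm, delta = list(fg = delta_fg, bg = delta_bg),
                 pssm = list(dom = pssm_dom, all = pssm_all),
                 alignments = alignments, domains = domain_tables,
                 projections = projections,
                 out_dir = config$out_dir),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (config", x$config_hash, ")\n")
  cat(sprintf("  %d foreground / %d background sequences; %d families\n",
              length(x$foreground), length(x$background),
              length(x$catalog$families)))
  for (nm in names(x$domains)) {
    ds <- x$domains[[nm]]
    cat(sprintf("  %s: %d consensus domains, %.2f per sequence, %.1f%% of SS$\n",
                nm, sum(ds$regions$kind == "consensus"),
                ds$domains_per_sequence, ds$pct_in_domains))
  }
  invisible(x)
}

#' Export and read 1D region tracks
#'
#' Writes one track line per alignment set: tab-separated
#' `set, kind, start, end, identity` records encoding each consensus
#' domain, gap region and non-gap region, reproducing the 1D projection of
#' the alignment heat maps without graphics.
#'
#' @param domain_tables Named list of [domain_stats()] results (or a single
#'   one).
#' @param path Output file.
#' @return `path` invisibly; `read_1d_map` returns the data frame.
#' @export
export_1d_map <- function(domain_tables, path) {
  if (inherits(domain_tables, "domain_stats")) {
    domain_tables <- list(set = domain_tables)
  }
  rows <- do.call(rbind, lapply(names(domain_tables), function(nm) {
    r <- domain_tables[[nm]]$regions
    data.frame(set = nm, kind = r$kind, start = r$start, end = r$end,
               identity = ifelse(is.na(r$ss_identity), ".", r$ss_identity))
  }))
  .write_tsv(rows, path)
}

#' @rdname export_1d_map
#' @export
read_1d_map <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
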