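#' Pipeline configuration
#'
#' Collects every numeric constant of the workflow in one validated,
#' YAML-serializable object: the read-level (0.85) and full-length (0.97)
#' clustering cutoffs, the screening rule (>= 3 mismatches, >= 10 reads,
#' complete sites, unclassified at domain/phylum), the design gates (first
#' 100 nt, 16-20 nt, 45-52 degrees C, degeneracy cap 32), and the distance
#' conventions (gap runs as one event, terminal gaps ignored, 1200 bp length
#' filter, 0.75 phylum-level identity threshold).
#'
#' @param ... overrides for any field (see defaults in the function body).
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    max_offset = 0L,
    max_ambig_frac = 0.1,
    cluster_cutoff = 0.85,
    identity_mode = "alncols",
    min_mismatches = 3L,
    min_otu_size = 10L,
    require_complete_sites = TRUE,
    novelty_ranks = c("domain", "phylum"),
    design_window = 100L,
    primer_lengths = 16:20,
    tm_range = c(45, 52),
    tm_method = "wallace",
    degeneracy_cap = 32L,
    max_mismatches = 0L,
    full_length_cutoff = 0.97,
    min_full_length = 1200L,
    gap_mode = "onegap",
    terminal_gaps = "ignore",
    max_gap_frac = 0.5,
    identity_threshold = 0.75,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  stopifnot(cfg$cluster_cutoff > 0, cfg$cluster_cutoff <= 1,
            cfg$full_length_cutoff > 0, cfg$full_length_cutoff <= 1,
            cfg$identity_threshold > 0, cfg$identity_threshold < 1,
            cfg$max_offset >= 0L, cfg$min_otu_size >= 1L,
            cfg$min_mismatches >= 0L, cfg$tm_range[1L] <= cfg$tm_range[2L],
            all(cfg$primer_lengths >= 10L), cfg$degeneracy_cap >= 1L)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
load_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Hash of a configuration (for run logs)
#'
#' @param config a `pipeline_config`.
#' @return md5 hex string.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yml")
  on.exit(unlink(tf))
  save_config(config, tf)
  unname(tools::md5sum(tf))
}

#' Write a reproducibility run log
#'
#' Records package and R versions, the seed, the configuration hash and
#' checksums of the input files: enough to regenerate any output.
#'
#' @param path log file path.
#' @param config a `pipeline_config`.
#' @param inputs named character vector of input file paths (checksummed).
#' @return `path`, invisibly.
#' @export
write_run_log <- function(path, config, inputs = character()) {
  lines <- c(
    sprintf("package: primerscout %s",
            as.character(utils::packageVersion("primerscout"))),
    sprintf("R: %s", R.version.string),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    sprintf("seed: %s", config$seed),
    sprintf("config_hash: %s", config_hash(config))
  )
  if (length(inputs)) {
    sums <- tools::md5sum(inputs)
    lines <- c(lines, sprintf("input %s: %s (md5 %s)",
                              names(inputs), inputs, sums))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Run the full primer-evasion discovery pipeline
#'
#' Chains the stages on an in-memory read set: evaluate binding sites
#' against the domain-assigned universal primers, cluster reads (plus any
#' reference sequences) at the read-level cutoff, annotate and screen OTUs
#' for novel primer-evading groups, design targeted forward primers in each
#' screened group's 5' window, and score each group's best candidate by
#' in-silico coverage over the group's complete reads.
#'
#' @param reads named character vector of 5'-anchored reads.
#' @param taxonomy data.frame (`id`, `lineage`) or NULL.
#' @param config a [pipeline_config()].
#' @param references optional named character vector of reference sequences
#'   co-clustered with the reads (never counted in OTU sizes) and used for
#'   candidate specificity checks.
#' @param primers primer set (default [builtin_primers()]).
#' @return list of class `"primer_pipeline"`: `evaluations`, `summary`,
#'   `clustering`, `otus`, `screened`, `mismatch_table`, `designs` (per
#'   screened OTU: candidate table and coverage of the top candidate),
#'   `config`.
#' @export
run_pipeline <- function(reads, taxonomy = NULL, config = pipeline_config(),
                         references = NULL, primers = builtin_primers()) {
  if (length(reads) == 0L) stop("no reads supplied", call. = FALSE)
  evals <- evaluate_reads(reads, taxonomy = taxonomy, primers = primers,
                          max_offset = config$max_offset,
                          max_ambig_frac = config$max_ambig_frac)
  summ <- summarize_evaluations(evals)

  all_seqs <- c(reads, references)
  cl <- cluster_greedy(all_seqs, cutoff = config$cluster_cutoff,
                       identity_mode = config$identity_mode)
  otus <- annotate_otus(cl, evals = evals, taxonomy = taxonomy,
                        ref_ids = names(references))
  crit <- screening_criteria(
    min_mismatches = config$min_mismatches,
    min_otu_size = config$min_otu_size,
    require_complete_sites = config$require_complete_sites,
    novelty_ranks = config$novelty_ranks
  )
  screened <- screen_novel(otus, crit)

  designs <- list()
  mem <- cl$membership
  for (i in seq_len(nrow(screened))) {
    oid <- screened$otu_id[i]
    member_ids <- setdiff(mem$id[mem$otu_id == oid], names(references))
    complete <- evals$read_id[evals$status %in% c("matching", "mismatching")]
    grp <- reads[intersect(member_ids, complete)]
    grp <- grp[nchar(grp) >= config$design_window]
    if (length(grp) == 0L) {
      designs[[oid]] <- list(candidates = NULL, coverage = NULL,
                             note = "no complete read reaches the design window")
      next
    }
    cons <- group_consensus(grp, window = config$design_window)
    cand <- enumerate_candidates(
      cons, window = config$design_window, lengths = config$primer_lengths,
      tm_range = config$tm_range, tm_method = config$tm_method,
      degeneracy_cap = config$degeneracy_cap,
      references = references, target_ids = member_ids,
      max_mismatches = config$max_mismatches
    )
    cov <- if (nrow(cand)) coverage(cand$sequence[1L], grp) else NULL
    designs[[oid]] <- list(consensus = cons, candidates = cand, coverage = cov)
  }

  structure(list(evaluations = evals, summary = summ, clustering = cl,
                 otus = otus, screened = screened,
                 mismatch_table = mismatch_table(screened),
                 designs = designs, config = config),
            class = "primer_pipeline")
}

#' @export
print.primer_pipeline <- function(x, ...) {
  cat(sprintf("<primer-evasion pipeline>\n  reads evaluated: %d\n",
              nrow(x$evaluations)))
  cat(sprintf("  OTUs: %d (cutoff %.2f); screened novel OTUs: %d\n",
              nrow(x$otus), x$config$cluster_cutoff, nrow(x$screened)))
  if (nrow(x$screened)) {
    cat("  mismatch types:\n")
    print(x$mismatch_table[, c("primer", "otu_id", "pattern", "size")])
    ncand <- vapply(x$designs, function(d)
      if (is.null(d$candidates)) 0L else nrow(d$candidates), 0L)
    cat(sprintf("  designed candidates per screened OTU: %s\n",
                paste(sprintf("%s=%d", names(ncand), ncand), collapse = ", ")))
  }
  invisible(x)
}
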