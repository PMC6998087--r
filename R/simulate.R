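#' Mock classified lineages for background reads
#'
#' A small bundled lineage table used by the synthetic generator so that
#' background (non-novel) reads carry classified taxonomies without any
#' external database.
#'
#' @return data.frame with columns `domain`, `lineage`.
#' @export
mock_lineages <- function() {
  bac <- c("Proteobacteria;Gammaproteobacteria", "Bacteroidetes;Bacteroidia",
           "Firmicutes;Clostridia", "Actinobacteria;Actinomycetia",
           "Planctomycetes;Planctomycetia", "Chloroflexi;Anaerolineae",
           "Acidobacteria;Acidobacteriia", "Verrucomicrobia;Verrucomicrobiae",
           "Cyanobacteria;Oxyphotobacteria", "Spirochaetes;Spirochaetia")
  arc <- c("Euryarchaeota;Methanomicrobia", "Crenarchaeota;Thermoprotei",
           "Thaumarchaeota;Nitrososphaeria", "Bathyarchaeota;Bathyarchaeia")
  data.frame(
    domain = c(rep("Bacteria", length(bac)), rep("Archaea", length(arc))),
    lineage = c(paste0("Bacteria;", bac), paste0("Archaea;", arc)),
    stringsAsFactors = FALSE
  )
}

# reference (alphabetically-first) expansion of a primer, used as the
# conserved binding site planted in templates
.reference_site <- function(primer) {
  apply_pattern(primer, strrep("=", nchar(primer_sequence(primer))))
}

#' Build divergent group templates with conserved primer loci
#'
#' Generates one ~full-length SSU-like template per group: a shared random
#' master sequence is mutated per group at the free positions so that
#' between-group identity lands near `between_identity`, while the 5'
#' primer-binding site (and any extra conserved blocks) stay untouched.
#'
#' @param n_groups number of groups (>= 1).
#' @param template_length template length in nt (default 1500, typical 16S).
#' @param between_identity target pairwise identity between group templates.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @param sites character vector (length 1 or `n_groups`) of concrete 5'
#'   binding sites planted at position 1 of each template; default is the
#'   Arch21F site.
#' @param conserved_block optional c(start, length) of an extra conserved
#'   block (default a 30-nt block at position 701).
#' @return named character vector (`G1`, `G2`, ...) of templates.
#' @export
build_templates <- function(n_groups, template_length = 1500L,
                            between_identity = 0.70, seed = 1L,
                            sites = NULL, conserved_block = c(701L, 30L)) {
  stopifnot(n_groups >= 1L, template_length >= 200L)
  if (is.null(sites)) sites <- .reference_site(builtin_primers()$Arch21F)
  sites <- normalize_seq(rep_len(sites, n_groups), "site")
  set.seed(seed)
  master <- paste(sample(c("A", "C", "G", "T"), template_length,
                         replace = TRUE), collapse = "")
  fixed <- seq_len(max(nchar(sites)))
  if (!is.null(conserved_block)) {
    fixed <- union(fixed, seq(conserved_block[1L],
                              length.out = conserved_block[2L]))
  }
  free <- setdiff(seq_len(template_length), fixed)
  frac_free <- length(free) / template_length
  perpos <- (1 - between_identity) / frac_free
  disc <- 4 - (16 / 3) * perpos
  if (disc < 0 || between_identity > 1 || between_identity <= 0) {
    stop("requested between-group identity is infeasible", call. = FALSE)
  }
  d <- (2 - sqrt(disc)) / (8 / 3)

  bases <- c("A", "C", "G", "T")
  out <- character(n_groups)
  mchars <- strsplit(master, "", fixed = TRUE)[[1L]]
  for (g in seq_len(n_groups)) {
    chars <- mchars
    hit <- free[stats::runif(length(free)) < d]
    if (length(hit)) {
      chars[hit] <- vapply(chars[hit], function(b)
        sample(setdiff(bases, b), 1L), "")
    }
    chars[seq_len(nchar(sites[g]))] <- strsplit(sites[g], "", fixed = TRUE)[[1L]]
    out[g] <- paste(chars, collapse = "")
  }
  names(out) <- paste0("G", seq_len(n_groups))
  out
}

#' Specification of one planted read group
#'
#' @param group_id template name the reads derive from.
#' @param primer_name universal primer whose binding site the pattern
#'   describes.
#' @param pattern mismatch-pattern string (`=` / observed base) of primer
#'   length; `strrep("=", L)` plants a perfectly matching group.
#' @param abundance number of reads.
#' @param lineage semicolon-delimited taxonomy assigned to the reads (empty
#'   string = fully unclassified).
#' @param complete_site_fraction fraction of reads left 5'-complete; the
#'   remainder are truncated below primer length to carry incomplete sites.
#' @param variant_sites optional list of `list(pos =, bases =)` describing
#'   within-group variable positions (read coordinates); reads cycle through
#'   `bases`, so the group's design-window consensus becomes degenerate there.
#' @return list of class `"plant_spec"`.
#' @export
plant_spec <- function(group_id, primer_name, pattern, abundance, lineage = "",
                       complete_site_fraction = 1, variant_sites = NULL) {
  stopifnot(abundance >= 1L, complete_site_fraction >= 0,
            complete_site_fraction <= 1)
  structure(list(group_id = group_id, primer_name = primer_name,
                 pattern = pattern, abundance = as.integer(abundance),
                 lineage = lineage,
                 complete_site_fraction = complete_site_fraction,
                 variant_sites = variant_sites),
            class = "plant_spec")
}

# intended evaluation status for a complete read carrying `pattern`
.pattern_status <- function(pattern) {
  L <- nchar(pattern)
  pos <- which(strsplit(pattern, "", fixed = TRUE)[[1L]] != "=")
  if (length(pos) == 0L || (length(pos) == 1L && pos <= L - 4L))
    "matching" else "mismatching"
}

#' Generate 5'-anchored reads with planted primer-site variants
#'
#' For every [plant_spec()], replaces the template's 5' binding site with the
#' site implied by the spec's mismatch pattern, emits `abundance` reads
#' anchored at the template 5' terminus, optionally injects uniform
#' substitution errors (planted sites and variant positions are re-imposed
#' afterwards, so the manifest stays exact), and truncates a
#' `1 - complete_site_fraction` share of reads below primer length so their
#' binding sites are incomplete.
#'
#' @param templates named character vector from [build_templates()].
#' @param specs list of [plant_spec()] objects.
#' @param read_length read length in nt (5'-anchored).
#' @param error_rate uniform per-base substitution error rate (default 0).
#' @param seed integer seed; per-spec substreams are derived from it.
#' @param primers primer set (for pattern-to-site reconstruction).
#' @return list: `reads` (named character), `taxonomy` (data.frame `id`,
#'   `lineage`), `manifest` (data.frame `read_id`, `group`,
#'   `intended_status`, `pattern`, `primer`).
#' @export
plant_and_fragment <- function(templates, specs, read_length = 250L,
                               error_rate = 0, seed = 1L,
                               primers = builtin_primers()) {
  if (inherits(specs, "plant_spec")) specs <- list(specs)
  reads <- character(0L); tax <- list(); man <- list()
  bases <- c("A", "C", "G", "T")
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    tpl <- templates[[sp$group_id]]
    if (is.null(tpl)) stop("unknown template group '", sp$group_id, "'",
                           call. = FALSE)
    pr <- primers[[sp$primer_name]]
    if (is.null(pr)) stop("unknown primer '", sp$primer_name, "'",
                          call. = FALSE)
    L <- nchar(primer_sequence(pr))
    if (nchar(sp$pattern) != L) {
      stop("pattern length differs from primer length in group ",
           sp$group_id, call. = FALSE)
    }
    site <- apply_pattern(pr, sp$pattern)
    planted <- paste0(site, substr(tpl, L + 1L, nchar(tpl)))
    if (sp$abundance > 1e6) stop("abundance too large", call. = FALSE)

    set.seed(as.integer((as.numeric(seed) * 10007 + k) %% 2147483647))
    n_complete <- round(sp$abundance * sp$complete_site_fraction)
    status <- .pattern_status(sp$pattern)
    ids <- sprintf("%s_r%05d", sp$group_id, seq_len(sp$abundance))
    rds <- character(sp$abundance)
    for (j in seq_len(sp$abundance)) {
      if (j <= n_complete) {
        r <- substr(planted, 1L, read_length)
        if (error_rate > 0) {
          chars <- strsplit(r, "", fixed = TRUE)[[1L]]
          hit <- which(stats::runif(length(chars)) < error_rate)
          if (length(hit)) {
            chars[hit] <- vapply(chars[hit], function(b)
              sample(setdiff(bases, b), 1L), "")
            chars[seq_len(L)] <- strsplit(site, "", fixed = TRUE)[[1L]]
            r <- paste(chars, collapse = "")
          }
        }
        if (!is.null(sp$variant_sites)) {
          for (v in sp$variant_sites) {
            b <- v$bases[((j - 1L) %% length(v$bases)) + 1L]
            substr(r, v$pos, v$pos) <- b
          }
        }
        rds[j] <- r
      } else {
        rds[j] <- substr(planted, 1L, sample(5:(L - 1L), 1L))
      }
    }
    names(rds) <- ids
    reads <- c(reads, rds)
    tax[[k]] <- data.frame(id = ids, lineage = sp$lineage,
                           stringsAsFactors = FALSE)
    man[[k]] <- data.frame(
      read_id = ids, group = sp$group_id,
      intended_status = ifelse(seq_len(sp$abundance) <= n_complete,
                               status, "incomplete"),
      pattern = sp$pattern, primer = sp$primer_name,
      stringsAsFactors = FALSE
    )
  }
  list(reads = reads,
       taxonomy = do.call(rbind, tax),
       manifest = do.call(rbind, man))
}

#' Simulate a full primer-evasion study dataset
#'
#' One call builds the whole study regime: a large background of classified
#' reads whose binding sites match their universal primers, plus planted
#' "novel" groups that are unclassified, carry heavily mismatched Arch21F
#' sites, and harbor group-specific design windows (the default two groups
#' reproduce the published Type A / Type B site architecture, including the
#' within-group variant position that makes their merged primer degenerate).
#'
#' @param seed integer seed (drives templates and reads deterministically).
#' @param n_background total background reads.
#' @param n_background_groups number of background template groups.
#' @param frac_bacteria fraction of background groups that are bacterial.
#' @param novel_abundances named integer vector of novel-group read counts
#'   (default `c(typeA = 12, typeB = 25)`, the published OTU sizes).
#' @param read_length,template_length,between_identity,error_rate
#'   generator knobs (see [build_templates()], [plant_and_fragment()]).
#' @param complete_site_fraction background complete-site fraction (novel
#'   groups are always complete: their abundances are defined as
#'   complete-site read counts, as in the screening rule).
#' @return list: `reads`, `taxonomy`, `manifest`, `templates`, `specs`,
#'   `novel_groups` (names of the planted novel groups).
#' @export
simulate_dataset <- function(seed = 1L, n_background = 50000L,
                             n_background_groups = 20L, frac_bacteria = 0.85,
                             novel_abundances = c(typeA = 12L, typeB = 25L),
                             read_length = 250L, template_length = 1500L,
                             between_identity = 0.70, error_rate = 0,
                             complete_site_fraction = 0.98) {
  prs <- builtin_primers()
  n_bac <- round(n_background_groups * frac_bacteria)
  domains <- c(rep("Bacteria", n_bac),
               rep("Archaea", n_background_groups - n_bac))
  site_8f <- "AGAGTTTGATCCTGGCTCAG"          # concrete 8F-compatible site
  site_arch <- .reference_site(prs$Arch21F)
  bg_sites <- ifelse(domains == "Bacteria", site_8f, site_arch)

  # novel-group 5' architecture: published Type A / Type B site + the
  # documented downstream design region
  novel_prefix <- c(
    typeA = paste0("CTCTAGTTGATCCTGCTAGA", "GGACACTGCTATCGGCTT"),
    typeB = paste0("TTCCGTTCGATCCTGACGGA", "GCCTACTGCTATCGGATT")
  )
  novel_pattern <- c(typeA = "C==TA===========TA==",
                     typeB = "=====T=C=======A====")
  novel_variants <- list(typeA = list(list(pos = 23L, bases = c("A", "G"))),
                         typeB = NULL)
  if (!all(names(novel_abundances) %in% names(novel_prefix))) {
    stop("novel_abundances must be named from: ",
         paste(names(novel_prefix), collapse = ", "), call. = FALSE)
  }
  novel <- names(novel_abundances)

  n_groups <- n_background_groups + length(novel)
  sites <- c(bg_sites, rep(site_arch, length(novel)))
  tpl <- build_templates(n_groups, template_length = template_length,
                         between_identity = between_identity, seed = seed,
                         sites = sites)
  names(tpl) <- c(sprintf("BG%02d", seq_len(n_background_groups)), novel)
  for (g in novel) {
    pre <- novel_prefix[[g]]
    tpl[[g]] <- paste0(pre, substr(tpl[[g]], nchar(pre) + 1L, template_length))
  }

  lin <- mock_lineages()
  specs <- list()
  per <- rep(n_background %/% n_background_groups, n_background_groups)
  per[seq_len(n_background %% n_background_groups)] <-
    per[seq_len(n_background %% n_background_groups)] + 1L
  for (i in seq_len(n_background_groups)) {
    pool <- lin$lineage[lin$domain == domains[i]]
    pname <- if (domains[i] == "Bacteria") "8F" else "Arch21F"
    specs[[length(specs) + 1L]] <- plant_spec(
      group_id = sprintf("BG%02d", i), primer_name = pname,
      pattern = strrep("=", nchar(primer_sequence(prs[[pname]]))),
      abundance = per[i],
      lineage = pool[((i - 1L) %% length(pool)) + 1L],
      complete_site_fraction = complete_site_fraction
    )
  }
  for (g in novel) {
    specs[[length(specs) + 1L]] <- plant_spec(
      group_id = g, primer_name = "Arch21F", pattern = novel_pattern[[g]],
      abundance = novel_abundances[[g]], lineage = "",
      complete_site_fraction = 1, variant_sites = novel_variants[[g]]
    )
  }
  sim <- plant_and_fragment(tpl, specs, read_length = read_length,
                            error_rate = error_rate, seed = seed,
                            primers = prs)
  c(sim, list(templates = tpl, specs = specs, novel_groups = novel))
}
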