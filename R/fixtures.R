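#' Published mismatch-type groups from the mudflat meta-transcriptome survey
#'
#' The eleven primer-evading OTUs recovered from mudflat sediment
#' meta-transcriptomes that met the screening rule (unclassified at domain
#' and/or phylum, complete binding sites, >= 3 mismatches, >= 10 reads):
#' six bacterial groups under 8F and five archaeal groups under Arch21F,
#' including the two fully unclassified groups "Type A" (OTU11) and
#' "Type B" (OTU8) that seeded the targeted-primer design.
#'
#' @return data.frame: `primer`, `otu`, `label`, `pattern`, `size`,
#'   `lineage` (domain-level call used for fixtures; empty = unclassified).
#' @export
novel_group_table <- function() {
  data.frame(
    primer = c(rep("8F", 6L), rep("Arch21F", 5L)),
    otu = paste0("OTU", 1:11),
    label = c(rep("", 7L), "TypeB", "", "", "TypeA"),
    pattern = c("==G==A====A=========",
                "==G==A====A=========",
                "==G==A====A=========",
                "==G==A====A=C=======",
                "==G==A=====T========",
                "==G==A====A=C=======",
                "C==T=============A==",
                "=====T=C=======A====",
                "=A=T=============A==",
                "C===A===========T===",
                "C==TA===========TA=="),
    size = c(49L, 33L, 34L, 11L, 10L, 10L, 69L, 25L, 24L, 10L, 12L),
    lineage = c(rep("Bacteria", 6L), "Archaea", "", "Archaea", "Archaea", ""),
    stringsAsFactors = FALSE
  )
}

#' Build a synthetic read set reproducing the published screened groups
#'
#' Reconstructs each screened group's binding site from its primer and
#' mismatch pattern, plants it on its own divergent template at the printed
#' read support, and adds classified, primer-matching background groups.
#' Running evaluate -> cluster -> screen on this fixture recovers exactly
#' the eleven groups.
#'
#' @param seed integer seed.
#' @param n_background_groups number of classified background groups.
#' @param background_size reads per background group.
#' @param read_length read length in nt.
#' @param groups group table (defaults to [novel_group_table()]).
#' @return list as from [plant_and_fragment()] plus `templates`, `groups`.
#' @export
screen_fixture <- function(seed = 1L, n_background_groups = 3L,
                           background_size = 30L, read_length = 250L,
                           groups = novel_group_table()) {
  prs <- builtin_primers()
  lin <- mock_lineages()
  site_8f <- "AGAGTTTGATCCTGGCTCAG"
  n_total <- nrow(groups) + n_background_groups
  sites <- c(vapply(seq_len(nrow(groups)), function(i)
    apply_pattern(prs[[groups$primer[i]]], groups$pattern[i]), ""),
    rep(site_8f, n_background_groups))
  tpl <- build_templates(n_total, seed = seed, sites = sites)
  names(tpl) <- c(groups$otu, sprintf("BG%02d", seq_len(n_background_groups)))

  specs <- lapply(seq_len(nrow(groups)), function(i) {
    plant_spec(group_id = groups$otu[i], primer_name = groups$primer[i],
               pattern = groups$pattern[i], abundance = groups$size[i],
               lineage = groups$lineage[i], complete_site_fraction = 1)
  })
  bac <- lin$lineage[lin$domain == "Bacteria"]
  for (i in seq_len(n_background_groups)) {
    specs[[length(specs) + 1L]] <- plant_spec(
      group_id = sprintf("BG%02d", i), primer_name = "8F",
      pattern = strrep("=", 20L), abundance = background_size,
      lineage = bac[((i - 1L) %% length(bac)) + 1L],
      complete_site_fraction = 1
    )
  }
  sim <- plant_and_fragment(tpl, specs, read_length = read_length, seed = seed,
                            primers = prs)
  c(sim, list(templates = tpl, groups = groups))
}
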