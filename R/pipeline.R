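#' Pipeline configuration
#'
#' Holds every numeric constant of the integration procedure with its
#' standard value, so nothing is hard-coded in the stages: the Jaccard
#' merge thresholds (0.8 coding / 0.5 non-coding), the 40 bp RNA-family
#' hit clustering overlap, the 2000 bp site-to-gene association cut-off
#' (200 bp for orphan sites), the 15 bp minimum UTR length, the 70 % TU
#' gene-overlap fraction, the 25 bp site-into-gene tolerance, the
#' quarter-genome giant-TU rule and the 64-path cap per TU.
#'
#' @param genome_length Genome length in bp (required).
#' @param ji_coding,ji_noncoding,rfam_overlap_bp,assoc_cutoff_bp,orphan_cutoff_bp,min_utr_bp,tu_gene_overlap_frac,site_overlap_tolerance_bp,giant_tu_fraction,path_cap
#'   Thresholds; see above for meaning and defaults.
#' @param do_not_merge Gene names never merged despite overlap.
#' @param excluded_tus TU ids or gene ids/names whose TUs are excluded
#'   from UTR/transcript/operon inference.
#' @param name_preference Resource order for primary naming.
#' @return A list with class `pipeline_config`.
#' @export
pipeline_config <- function(genome_length,
                            ji_coding = 0.8, ji_noncoding = 0.5,
                            rfam_overlap_bp = 40L,
                            assoc_cutoff_bp = 2000L, orphan_cutoff_bp = 200L,
                            min_utr_bp = 15L, tu_gene_overlap_frac = 0.70,
                            site_overlap_tolerance_bp = 25L,
                            giant_tu_fraction = 0.25, path_cap = 64L,
                            do_not_merge = c("cotT", "yoyG", "yqjU", "yrzH"),
                            excluded_tus = character(),
                            name_preference = NULL) {
  nums <- c(ji_coding, ji_noncoding, rfam_overlap_bp, assoc_cutoff_bp,
            orphan_cutoff_bp, min_utr_bp, tu_gene_overlap_frac,
            site_overlap_tolerance_bp, giant_tu_fraction, path_cap)
  if (any(nums <= 0)) abort("all thresholds must be positive")
  if (ji_coding > 1 || ji_noncoding > 1 || tu_gene_overlap_frac > 1 ||
      giant_tu_fraction > 1) {
    abort("fractions must be in (0, 1]")
  }
  structure(
    list(genome_length = as.integer(genome_length),
         ji_coding = ji_coding, ji_noncoding = ji_noncoding,
         rfam_overlap_bp = as.integer(rfam_overlap_bp),
         assoc_cutoff_bp = as.integer(assoc_cutoff_bp),
         orphan_cutoff_bp = as.integer(orphan_cutoff_bp),
         min_utr_bp = as.integer(min_utr_bp),
         tu_gene_overlap_frac = tu_gene_overlap_frac,
         site_overlap_tolerance_bp = as.integer(site_overlap_tolerance_bp),
         giant_tu_fraction = giant_tu_fraction, path_cap = as.integer(path_cap),
         do_not_merge = do_not_merge, excluded_tus = excluded_tus,
         name_preference = name_preference),
    class = "pipeline_config"
  )
}

#' Run the full annotation-unification pipeline
#'
#' Executes ingest, gene merging, site unification, TU complementation,
#' UTR inference, transcript enumeration, novel-TU derivation, operon
#' assembly and classification in one deterministic pass, and keeps a
#' structured log of every merge, drop and dummy insertion.
#'
#' @param resources A list of resource views. Each view is a list with
#'   `config` (a [resource_config()]) and either `path` (a TSV in the
#'   [load_resource_table()] schema) or in-memory tibbles
#'   `annotations`, `sites`, `tus`.
#' @param config A [pipeline_config()].
#' @return An object of class `operon_atlas`: a list of tibbles `genes`,
#'   `sites`, `tus`, `novel_tus`, `associations`, `utrs`, `transcripts`,
#'   `operons`, plus `log` and `config`.
#' @export
run_pipeline <- function(resources, config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  note <- function(stage, action, object, detail = "") {
    log[[length(log) + 1]] <<- tibble(stage = stage, action = action,
                                      object = object, detail = detail)
  }
  loaded <- lapply(resources, function(res) {
    if (!is.null(res$path)) {
      if (!file.exists(res$path)) {
        abort(paste0("ingest: resource file not found: ", res$path))
      }
      load_resource_table(res$path, res$config)
    } else {
      res[c("annotations", "sites", "tus")]
    }
  })
  annotations <- bind_rows(map(loaded, "annotations"))
  sites <- bind_rows(map(loaded, "sites"))
  tus <- bind_rows(map(loaded, "tus"))

  pairs <- find_match_pairs(annotations, ji_coding = config$ji_coding,
                            ji_noncoding = config$ji_noncoding,
                            do_not_merge = config$do_not_merge)
  genes <- merge_annotations(annotations, pairs,
                             name_preference = config$name_preference)
  prov <- merge_provenance(genes)
  absorbed <- prov[prov$disposition %in% c("absorbed", "tied"), ]
  for (i in seq_len(nrow(absorbed))) {
    note("gene_merge", "merge", absorbed$member_id[[i]],
         paste0("into ", absorbed$merged_id[[i]]))
  }
  id_map <- setNames(prov$merged_id, prov$member_id)

  unified <- bind_rows(
    unify_sites(sites[sites$site_type == "TSS", ]),
    unify_sites(sites[sites$site_type == "TTS", ])
  )
  for (i in which(lengths(unified$merged_from) > 0)) {
    note("site_unify", "drop_lower_resolution",
         paste(unified$merged_from[[i]], collapse = ","),
         paste0("kept ", unified$site_id[[i]]))
  }

  if (nrow(tus) > 0) {
    tus$genes <- map(tus$genes, function(ids) {
      mapped <- unname(id_map[ids])
      if (any(is.na(mapped))) {
        abort(paste0("TU references gene id(s) absent from the merged set: ",
                     paste(ids[is.na(mapped)], collapse = ", ")))
      }
      unique(mapped)
    })
  }
  n_before <- nrow(tus)
  tus <- complement_tus(tus, genes, genome_length = config$genome_length,
                        overlap_frac = config$tu_gene_overlap_frac,
                        giant_fraction = config$giant_tu_fraction,
                        excluded_tus = config$excluded_tus)
  if (nrow(tus) < n_before) {
    note("tu_complement", "drop_or_dedupe", "",
         paste0(n_before - nrow(tus), " TU(s) removed (giant or duplicate)"))
  }
  for (id in tus$tu_id[tus$excluded]) note("tu_complement", "exclude", id)

  assoc <- associate_sites_to_genes(
    unified, genes, cutoff = config$assoc_cutoff_bp,
    orphan_cutoff = config$orphan_cutoff_bp,
    overlap_tolerance = config$site_overlap_tolerance_bp, tus = tus
  )
  for (id in assoc$site_id[assoc$status == "unassociated"]) {
    note("site_association", "unassociated", id)
  }
  utrs <- bind_rows(
    infer_flanking_utrs(assoc, genes, min_utr = config$min_utr_bp),
    infer_internal_utrs(tus, genes, min_utr = config$min_utr_bp)
  )
  graph <- build_transcript_graph(tus, assoc, utrs, genes,
                                  min_utr = config$min_utr_bp)
  for (nd in graph$nodes$node[startsWith(graph$nodes$node, "dummy")]) {
    note("transcript_graph", "dummy_site", nd)
  }
  transcripts <- enumerate_transcripts(graph, tus, genes, utrs,
                                       path_cap = config$path_cap)
  novel_tus <- derive_tus_from_transcripts(transcripts, tus)
  operons <- build_operons(transcripts, genes)

  structure(
    list(genes = genes, sites = unified, tus = tus, novel_tus = novel_tus,
         associations = assoc, utrs = utrs, transcripts = transcripts,
         operons = operons, log = bind_rows(log), config = config),
    class = "operon_atlas"
  )
}

#' Summary counts of an atlas
#'
#' Per-biotype gene counts, unified site counts, UTR counts by class,
#' TU/novel-TU/transcript counts, operon counts by class, and the
#' fraction of genes covered by at least one operon.
#'
#' @param atlas A `operon_atlas`.
#' @return A tibble with `metric` and `value` columns.
#' @export
report_counts <- function(atlas) {
  g <- atlas$genes
  biotype_counts <- if (nrow(g) > 0) table(factor(g$biotype, levels = BIOTYPES))
    else setNames(rep(0L, length(BIOTYPES)), BIOTYPES)
  utr_counts <- table(factor(atlas$utrs$utr_class,
                             levels = c("five_prime", "three_prime", "internal")))
  op_counts <- table(factor(atlas$operons$operon_class,
                            levels = c("simple", "traditional", "complex")))
  covered <- unique(unlist(atlas$operons$genes))
  tibble(
    metric = c(paste0("genes_", BIOTYPES), "genes_total",
               "tss", "tts", "utr_five_prime", "utr_three_prime",
               "utr_internal", "utr_total", "tus", "novel_tus", "transcripts",
               "operons_simple", "operons_traditional", "operons_complex",
               "operons_total", "operons_monocistronic", "operons_polycistronic",
               "gene_coverage"),
    value = c(as.numeric(biotype_counts), nrow(g),
              sum(atlas$sites$site_type == "TSS"),
              sum(atlas$sites$site_type == "TTS"),
              as.numeric(utr_counts), nrow(atlas$utrs),
              nrow(atlas$tus), nrow(atlas$novel_tus), nrow(atlas$transcripts),
              as.numeric(op_counts), nrow(atlas$operons),
              sum(atlas$operons$n_genes == 1), sum(atlas$operons$n_genes > 1),
              if (nrow(g) == 0) 0 else length(intersect(covered, g$id)) / nrow(g))
  )
}
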