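#' Complement transcription units with the merged gene set
#'
#' TU gene lists collected from different resources are incomplete and
#' refer to different gene catalogues. This step (i) re-expresses each TU
#' against the merged gene set, (ii) adds every same-strand merged gene
#' that is (a) fully contained in the TU region, (b) fully contains the
#' TU, or (c) overlaps the TU by at least `overlap_frac` of the gene's
#' own length, (iii) re-sorts genes in transcription direction and
#' recomputes the region to span all members, (iv) drops TUs whose
#' region exceeds a quarter of the genome (erroneous giants), (v)
#' deduplicates TUs with identical gene sets, and (vi) flags
#' configuration-listed TUs as excluded from downstream inference.
#'
#' @param tus A TU tibble (gene ids refer to `merged_genes$id`).
#' @param merged_genes Merged annotation tibble.
#' @param genome_length Genome length in bp (for the giant-TU rule).
#' @param overlap_frac Minimum overlap fraction of the gene length for
#'   rule (c); default 0.70.
#' @param giant_fraction TUs spanning more than this fraction of the
#'   genome are dropped; default 0.25.
#' @param excluded_tus Character vector of TU ids or member gene
#'   ids/names marking TUs to exclude (e.g. the sigK TU, whose internal
#'   region is excised DNA and never transcribed).
#' @return The complemented TU tibble with updated `genes`, `start`,
#'   `end`, `source` and `excluded` columns.
#' @export
complement_tus <- function(tus, merged_genes, genome_length,
                           overlap_frac = 0.70, giant_fraction = 0.25,
                           excluded_tus = character()) {
  tus <- as_tibble(tus)
  gtab <- as_tibble(merged_genes)
  unknown <- setdiff(unlist(tus$genes), gtab$id)
  if (length(unknown) > 0) {
    abort(paste0("TU references unknown gene id(s): ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  if (nrow(tus) == 0) return(mutate(tus, n_genes = integer()))
  # region from listed member genes when not provided
  region <- map(tus$genes, function(ids) {
    m <- gtab[match(ids, gtab$id), ]
    c(min(m$start), max(m$end))
  })
  tus$start <- ifelse(is.na(tus$start), map_int(region, ~ as.integer(.x[[1]])), tus$start)
  tus$end <- ifelse(is.na(tus$end), map_int(region, ~ as.integer(.x[[2]])), tus$end)

  tu_gr <- GenomicRanges::GRanges("genome",
                                  IRanges::IRanges(tus$start, tus$end), tus$strand)
  gene_gr <- ann_to_granges(gtab)
  ov <- GenomicRanges::findOverlaps(tu_gr, gene_gr)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  ow <- GenomicRanges::width(GenomicRanges::pintersect(tu_gr[qi], gene_gr[si]))
  glen <- gtab$end[si] - gtab$start[si] + 1
  rule_a <- gtab$start[si] >= tus$start[qi] & gtab$end[si] <= tus$end[qi]
  rule_b <- gtab$start[si] <= tus$start[qi] & gtab$end[si] >= tus$end[qi]
  rule_c <- ow / glen >= overlap_frac
  add <- rule_a | rule_b | rule_c
  added_by_tu <- split(gtab$id[si[add]], factor(qi[add], levels = seq_len(nrow(tus))))

  tus$genes <- pmap(list(tus$genes, added_by_tu, tus$strand), function(ids, extra, strand) {
    ids <- union(ids, extra)
    m <- gtab[match(ids, gtab$id), ]
    ids[order(if (strand == "+") m$start else -m$end)]
  })
  tus <- tus |>
    mutate(
      start = map_int(.data$genes, ~ min(gtab$start[match(.x, gtab$id)])),
      end = map_int(.data$genes, ~ max(gtab$end[match(.x, gtab$id)]))
    )
  giants <- tus$end - tus$start + 1 > giant_fraction * genome_length
  tus <- tus[!giants, ]
  # deduplicate on identical ordered gene sets, unioning sources
  key <- map_chr(tus$genes, paste, collapse = "|")
  tus <- tus |>
    mutate(.key = key) |>
    group_by(.data$.key) |>
    summarise(
      tu_id = sort(.data$tu_id)[[1]], genes = .data$genes[1],
      strand = .data$strand[[1]], start = .data$start[[1]], end = .data$end[[1]],
      source = paste(sort(unique(stats::na.omit(.data$source))), collapse = "+"),
      excluded = any(.data$excluded), .groups = "drop"
    ) |>
    select(-".key")
  hit <- map_lgl(seq_len(nrow(tus)), function(i) {
    ids <- tus$genes[[i]]
    nm <- unlist(gtab$names[match(ids, gtab$id)])
    tus$tu_id[[i]] %in% excluded_tus || any(ids %in% excluded_tus) ||
      any(nm %in% excluded_tus)
  })
  tus |>
    mutate(excluded = .data$excluded | hit,
           n_genes = lengths(.data$genes)) |>
    arrange(.data$start, .data$end, .data$tu_id)
}
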