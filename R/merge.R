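#' Find pairs of annotations that describe the same feature
#'
#' Inspects every overlapping same-strand pair of annotations and keeps a
#' pair when at least one of the matching criteria holds:
#'
#' 1. their Jaccard index is at least `ji_coding` (default 0.8),
#' 2. both annotations are non-coding and their Jaccard index is at
#'    least `ji_noncoding` (default 0.5), or
#' 3. a non-coding annotation is fully contained within the other
#'    (the container may be coding or non-coding).
#'
#' Two exclusions apply: riboswitches are never paired with overlapping
#' coding genes (a riboswitch typically lives in the 5' UTR of the gene
#' it regulates and must stay a separate feature), and pairs whose shared
#' name is on the `do_not_merge` list are kept apart. The default list
#' holds four genes with irreconcilably divergent annotations between
#' curated resources (cotT, yoyG, yqjU, yrzH) that are deliberately kept
#' as duplicate entries.
#'
#' @param annotations An annotation tibble.
#' @param ji_coding Jaccard threshold for criterion 1.
#' @param ji_noncoding Jaccard threshold for criterion 2 (non-coding pairs).
#' @param do_not_merge Character vector of gene names whose divergent
#'   duplicate annotations must not be merged.
#' @return A tibble of unordered pairs: `id1`, `id2`, `ji`, `criterion`.
#' @export
find_match_pairs <- function(annotations, ji_coding = 0.8, ji_noncoding = 0.5,
                             do_not_merge = c("cotT", "yoyG", "yqjU", "yrzH")) {
  a <- as_tibble(annotations)
  if (nrow(a) < 2) {
    return(tibble(id1 = character(), id2 = character(), ji = numeric(),
                  criterion = character()))
  }
  gr <- ann_to_granges(a)
  ov <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  i <- S4Vectors::queryHits(ov); j <- S4Vectors::subjectHits(ov)
  if (length(i) == 0) {
    return(tibble(id1 = character(), id2 = character(), ji = numeric(),
                  criterion = character()))
  }
  same_strand <- a$strand[i] == a$strand[j]
  i <- i[same_strand]; j <- j[same_strand]
  ji <- interval_jaccard(a$start[i], a$end[i], a$start[j], a$end[j])
  nc_i <- a$biotype[i] != "CDS"; nc_j <- a$biotype[j] != "CDS"
  contained_ij <- a$start[i] >= a$start[j] & a$end[i] <= a$end[j]  # i inside j
  contained_ji <- a$start[j] >= a$start[i] & a$end[j] <= a$end[i]
  crit1 <- ji >= ji_coding
  crit2 <- nc_i & nc_j & ji >= ji_noncoding
  crit3 <- (contained_ij & nc_i) | (contained_ji & nc_j)
  riboswitch_cds <- (a$biotype[i] == "riboswitch" & a$biotype[j] == "CDS") |
    (a$biotype[j] == "riboswitch" & a$biotype[i] == "CDS")
  dnm <- str_to_lower(do_not_merge)
  shared_dnm <- map2_lgl_names(a$names[i], a$names[j], dnm)
  keep <- (crit1 | crit2 | crit3) & !riboswitch_cds & !shared_dnm
  tibble(
    id1 = a$id[i][keep], id2 = a$id[j][keep], ji = ji[keep],
    criterion = dplyr::case_when(
      crit1[keep] ~ "jaccard",
      crit2[keep] ~ "jaccard_noncoding",
      TRUE ~ "containment"
    )
  )
}

map2_lgl_names <- function(names_i, names_j, dnm_lower) {
  if (length(dnm_lower) == 0) return(rep(FALSE, length(names_i)))
  mapply(function(x, y) {
    shared <- intersect(str_to_lower(x), str_to_lower(y))
    length(intersect(shared, dnm_lower)) > 0
  }, names_i, names_j, USE.NAMES = FALSE)
}

#' Merge matched annotations into a non-redundant set
#'
#' Groups are the connected components of the match-pair graph, so
#' correspondence propagates across resources, priority levels and even
#' within one resource in a single merging step. Each group collapses to
#' one annotation:
#'
#' * coordinates come from the highest-priority member (lowest rank); if
#'   several members tie at the highest priority, the bounding interval
#'   (union) of the tied members is used;
#' * the biotype is the most specific one in the group ([assign_biotype()]);
#' * meta-information is the origin-tagged union over members
#'   ([attach_meta()]);
#' * names and locus tags are unioned.
#'
#' Singletons pass through unchanged. Member provenance is recorded in a
#' `members` list-column.
#'
#' @param annotations An annotation tibble.
#' @param pairs Pair table from [find_match_pairs()].
#' @param name_preference Optional character vector of resource names;
#'   the merged record's id and primary name are taken from the first
#'   listed resource present in the group. Default: the highest-priority
#'   member.
#' @return A merged annotation tibble with a `members` list-column.
#' @export
merge_annotations <- function(annotations, pairs, name_preference = NULL) {
  a <- as_tibble(annotations)
  if (anyDuplicated(a$id)) abort("annotation ids must be unique before merging")
  g <- igraph::graph_from_data_frame(
    pairs[, c("id1", "id2")], directed = FALSE,
    vertices = data.frame(name = a$id)
  )
  memb <- igraph::components(g)$membership
  a$.group <- unname(memb[a$id])
  merged <- a |>
    group_by(.data$.group) |>
    group_map(~ merge_one_group(.x, name_preference)) |>
    bind_rows()
  arrange(merged, .data$start, .data$end, .data$id)
}

merge_one_group <- function(g, name_preference = NULL) {
  if (nrow(g) == 1) {
    out <- g
    out$primary_name <- c(unlist(g$names), g$id)[[1]]
    out$members <- list(tibble(member_id = g$id, resource = g$resource,
                               disposition = "singleton"))
    return(out)
  }
  minp <- min(g$priority)
  winners <- g[g$priority == minp, ]
  if (nrow(winners) == 1) {
    start <- winners$start; end <- winners$end
  } else {
    start <- min(winners$start); end <- max(winners$end)
  }
  lead <- winners[order(winners$id), ][1, ]
  # primary naming may be delegated to a preferred (community) resource
  name_source <- lead
  if (!is.null(name_preference)) {
    pref <- match(g$resource, name_preference)
    if (any(!is.na(pref))) {
      name_source <- g[which.min(replace(pref, is.na(pref), Inf)), ]
    }
  }
  primary_name <- c(unlist(name_source$names), name_source$id)[[1]]
  disposition <- ifelse(g$id == lead$id, "winner",
                        ifelse(g$priority == minp & nrow(winners) > 1,
                               "tied", "absorbed"))
  tibble(
    id = lead$id, primary_name = primary_name,
    start = as.integer(start), end = as.integer(end),
    strand = g$strand[[1]],
    biotype = assign_biotype(g$biotype),
    resource = paste(sort(unique(g$resource)), collapse = "+"),
    priority = minp,
    names = list(sort(unique(unlist(g$names)))),
    locus_tags = list(sort(unique(unlist(g$locus_tags)))),
    meta = list(attach_meta(g)),
    members = list(tibble(member_id = g$id, resource = g$resource,
                          disposition = disposition))
  )
}

# specificity ranking used to resolve biotype conflicts; a specific
# biotype always beats putative_ncRNA, and asRNA > sRNA > riboswitch
BIOTYPE_SPECIFICITY <- c(
  "asRNA", "sRNA", "riboswitch", "rRNA", "tRNA", "self_splicing_intron",
  "cis_regulatory_structure", "other_ncRNA", "putative_ncRNA"
)

#' Most specific biotype of a merge group
#'
#' Groups containing a coding member stay `CDS` (only putative
#' annotations can be absorbed into a coding gene; a specific ncRNA
#' grouped with a CDS indicates an upstream matching error). For
#' non-coding groups any specific biotype beats `putative_ncRNA`, and
#' conflicting specific biotypes resolve as asRNA over sRNA over
#' riboswitch (followed by the remaining vocabulary in fixed order).
#'
#' @param biotypes Character vector of member biotypes.
#' @return A single biotype string.
#' @export
assign_biotype <- function(biotypes) {
  if (length(biotypes) == 0) abort("empty group")
  if ("CDS" %in% biotypes) {
    specific_nc <- setdiff(biotypes, c("CDS", "putative_ncRNA", "other_ncRNA"))
    if (length(specific_nc) > 0) {
      abort(paste0("CDS merged with specific ncRNA biotype(s): ",
                   paste(specific_nc, collapse = ", ")))
    }
    return("CDS")
  }
  BIOTYPE_SPECIFICITY[min(match(biotypes, BIOTYPE_SPECIFICITY))]
}

#' Union of member meta-information with origins
#'
#' Conflicting values for one key are all kept, each tagged with the
#' resource it originated from, so no information is lost in merging and
#' every value stays traceable.
#'
#' @param group Annotation tibble rows of one merge group (with `meta`
#'   list-column and `resource`).
#' @return A meta tibble (`key`, `value`, `origin`).
#' @export
attach_meta <- function(group) {
  metas <- map2(group$meta, group$resource, function(m, r) {
    if (is.null(m) || nrow(m) == 0) return(empty_meta())
    m$origin <- ifelse(is.na(m$origin), r, m$origin)
    m
  })
  bind_rows(metas) |> distinct() |> arrange(.data$key, .data$origin)
}

#' Provenance table of a merged annotation set
#'
#' @param merged Output of [merge_annotations()].
#' @return A tibble: `merged_id`, `member_id`, `resource`, `disposition`
#'   (winner / tied / absorbed / singleton).
#' @export
merge_provenance <- function(merged) {
  merged |>
    select(merged_id = "id", "members") |>
    unnest("members")
}
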