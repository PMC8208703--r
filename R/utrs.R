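#' Associate boundary sites with their nearest genes
#'
#' Builds the site-to-gene map from which flanking UTRs are derived:
#' each TSS is matched to the same-strand gene with the closest 5' end
#' and each TTS to the gene with the closest 3' end. The search distance
#' is capped at `cutoff` bp (default 2000, roughly the maximal UTR
#' length observed in bacterial transcriptomes), lowered to
#' `orphan_cutoff` (default 200) for sites whose source study found no
#' associated transcribed region. A site may fall up to
#' `overlap_tolerance` bp (default 25) beyond the gene end it associates
#' with, absorbing resolution limits of array-derived sites and the
#' hairpin extent of terminators; such overlapping associations produce
#' no UTR.
#'
#' Ties between two equidistant gene ends break toward a gene that
#' leads a known TU, then toward the smaller start coordinate.
#'
#' @param sites Unified boundary-site tibble (both site types allowed).
#' @param genes Merged annotation tibble.
#' @param cutoff,orphan_cutoff,overlap_tolerance Distances in bp.
#' @param tus Optional TU tibble used for tie-breaking.
#' @return A tibble: `site_id`, `site_type`, `position`, `strand`,
#'   `gene_id`, `dist` (bp from site to the matched gene end in
#'   transcription direction; negative = inside the gene), `gap`
#'   (`dist - 1`: bp strictly between site and gene), `status`
#'   (`"associated"` / `"unassociated"`).
#' @export
associate_sites_to_genes <- function(sites, genes, cutoff = 2000L,
                                     orphan_cutoff = 200L,
                                     overlap_tolerance = 25L, tus = NULL) {
  s <- as_tibble(sites)
  g <- transcription_ends(as_tibble(genes))
  first_genes <- if (!is.null(tus) && nrow(tus) > 0) {
    unique(map_chr(tus$genes, 1))
  } else character()
  assoc_one <- function(row) {
    side <- if (row$site_type == "TSS") "five" else "three"
    cand <- g[g$strand == row$strand, ]
    if (nrow(cand) == 0) return(unassociated(row))
    ends <- if (side == "five") cand$five_prime else cand$three_prime
    d <- directed_distance(row$position, ends, row$strand, side)
    lim <- if (isTRUE(row$orphan)) orphan_cutoff else cutoff
    ok <- d >= -overlap_tolerance & d <= lim
    if (!any(ok)) return(unassociated(row))
    cand <- cand[ok, ]; d <- d[ok]
    best <- which(abs(d) == min(abs(d)))
    if (length(best) > 1) {
      lead <- best[cand$id[best] %in% first_genes]
      best <- if (length(lead) > 0) lead else best
      best <- best[order(cand$start[best])][[1]]
    }
    tibble(site_id = row$site_id, site_type = row$site_type,
           position = row$position, strand = row$strand,
           gene_id = cand$id[[best]], dist = d[[best]], gap = d[[best]] - 1,
           status = "associated")
  }
  unassociated <- function(row) {
    tibble(site_id = row$site_id, site_type = row$site_type,
           position = row$position, strand = row$strand,
           gene_id = NA_character_, dist = NA_real_, gap = NA_real_,
           status = "unassociated")
  }
  if (nrow(s) == 0) {
    return(tibble(site_id = character(), site_type = character(),
                  position = integer(), strand = character(),
                  gene_id = character(), dist = numeric(), gap = numeric(),
                  status = character()))
  }
  out <- bind_rows(lapply(seq_len(nrow(s)), function(i) assoc_one(s[i, ])))
  arrange(out, .data$site_type, .data$strand, .data$position, .data$site_id)
}

#' Infer 5' and 3' UTRs from site-to-gene associations
#'
#' A TSS associated with a gene at a distance of at least `min_utr` bp
#' yields a 5' UTR filling the space between the site and the gene's 5'
#' end; a TTS symmetrically yields a 3' UTR at the gene's 3' end.
#' Shorter gaps (including overlapping sites) keep the association but
#' produce no UTR. When a 5' association's anchor is a cis-regulatory
#' RNA structure (a riboswitch or similar leader element), the 5' UTR is
#' extended downstream across the structure up to, but not including,
#' the next coding gene on the strand, since the structure is itself
#' part of the untranslated leader of that gene; if no downstream coding
#' gene exists the UTR is truncated at the structure's 3' end with a
#' warning.
#'
#' @param associations Output of [associate_sites_to_genes()].
#' @param genes Merged annotation tibble.
#' @param min_utr Minimum UTR length in bp (default 15).
#' @param structure_biotypes Biotypes treated as cis-regulatory
#'   structures for the extension rule.
#' @return A UTR tibble: `utr_id`, `start`, `end`, `strand`, `utr_class`
#'   (`"five_prime"`/`"three_prime"`), `anchor_gene`, `source_site`,
#'   `extended` (logical).
#' @export
infer_flanking_utrs <- function(associations, genes, min_utr = 15L,
                                structure_biotypes = STRUCTURE_BIOTYPES) {
  g <- transcription_ends(as_tibble(genes))
  a <- associations |>
    filter(.data$status == "associated", .data$dist >= min_utr)
  if (nrow(a) == 0) return(empty_utrs())
  rows <- lapply(seq_len(nrow(a)), function(i) {
    row <- a[i, ]
    anchor <- g[g$id == row$gene_id, ]
    plus <- row$strand == "+"
    if (row$site_type == "TSS") {
      start <- if (plus) row$position else anchor$five_prime + 1
      end <- if (plus) anchor$five_prime - 1 else row$position
      cls <- "five_prime"
    } else {
      start <- if (plus) anchor$three_prime + 1 else row$position
      end <- if (plus) row$position else anchor$three_prime - 1
      cls <- "three_prime"
    }
    extended <- FALSE
    if (cls == "five_prime" && anchor$biotype %in% structure_biotypes) {
      cds <- g[g$strand == row$strand & g$biotype == "CDS", ]
      downstream <- if (plus) cds[cds$five_prime > anchor$five_prime, ]
                    else cds[cds$five_prime < anchor$five_prime, ]
      if (nrow(downstream) == 0) {
        warn(sprintf("no coding gene downstream of structure %s; 5' UTR truncated at structure end",
                     anchor$id))
        if (plus) end <- anchor$three_prime else start <- anchor$three_prime
      } else if (plus) {
        end <- min(downstream$five_prime) - 1
      } else {
        start <- max(downstream$five_prime) + 1
      }
      extended <- TRUE
    }
    tibble(
      utr_id = paste0(if (cls == "five_prime") "utr5_" else "utr3_", row$site_id),
      start = as.integer(start), end = as.integer(end), strand = row$strand,
      utr_class = cls, anchor_gene = row$gene_id, source_site = row$site_id,
      extended = extended
    )
  })
  bind_rows(rows) |> arrange(.data$start, .data$end, .data$utr_id)
}

empty_utrs <- function() {
  tibble(utr_id = character(), start = integer(), end = integer(),
         strand = character(), utr_class = character(),
         anchor_gene = character(), source_site = character(),
         extended = logical())
}

# per-TU gaps between consecutive genes in transcription order, measured
# against the merged footprint so nested/overlapping genes never create
# spurious gaps; returns one row per adjacent pair
tu_gene_gaps <- function(tu_genes, strand, genes) {
  m <- genes[match(tu_genes, genes$id), ]
  n <- nrow(m)
  if (n < 2) {
    return(tibble(from = character(), to = character(), gap = integer(),
                  gap_start = integer(), gap_end = integer()))
  }
  if (strand == "+") {
    frontier <- cummax(m$end)[-n]
    gap <- m$start[-1] - frontier - 1L
    tibble(from = m$id[-n], to = m$id[-1], gap = as.integer(gap),
           gap_start = as.integer(frontier + 1L),
           gap_end = as.integer(m$start[-1] - 1L))
  } else {
    frontier <- cummin(m$start)[-n]
    gap <- frontier - m$end[-1] - 1L
    tibble(from = m$id[-n], to = m$id[-1], gap = as.integer(gap),
           gap_start = as.integer(m$end[-1] + 1L),
           gap_end = as.integer(frontier - 1L))
  }
}

#' Infer internal UTRs from transcription-unit gaps
#'
#' Consecutive co-transcribed genes separated by at least `min_utr` bp
#' have the intervening region transcribed as part of the common mRNA;
#' each such gap yields one internal UTR. Gaps are measured against the
#' merged footprint of the genes seen so far, so overlapping or nested
#' genes never produce a UTR. Identical gaps shared by several TUs are
#' deduplicated. TUs flagged `excluded` contribute nothing (their
#' internal regions are not actually transcribed).
#'
#' @param tus Complemented TU tibble.
#' @param genes Merged annotation tibble.
#' @param min_utr Minimum UTR length in bp (default 15).
#' @return A UTR tibble with `utr_class = "internal"`; `anchor_gene` is
#'   the upstream gene of the gap.
#' @export
infer_internal_utrs <- function(tus, genes, min_utr = 15L) {
  tus <- filter(as_tibble(tus), !.data$excluded)
  g <- as_tibble(genes)
  if (nrow(tus) == 0) return(empty_utrs())
  gaps <- bind_rows(lapply(seq_len(nrow(tus)), function(i) {
    gg <- tu_gene_gaps(tus$genes[[i]], tus$strand[[i]], g)
    gg$strand <- tus$strand[[i]]
    gg
  }))
  utr <- gaps |>
    filter(.data$gap >= min_utr) |>
    distinct(.data$gap_start, .data$gap_end, .data$strand, .keep_all = TRUE) |>
    arrange(.data$gap_start, .data$gap_end)
  if (nrow(utr) == 0) return(empty_utrs())
  tibble(
    utr_id = sprintf("utri_%04d", seq_len(nrow(utr))),
    start = utr$gap_start, end = utr$gap_end, strand = utr$strand,
    utr_class = "internal", anchor_gene = utr$from,
    source_site = NA_character_, extended = FALSE
  )
}
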