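#' Build the per-TU transcript graph
#'
#' Directed acyclic graph underlying transcript enumeration. Per TU the
#' nodes are its associated TSSs and TTSs, the UTRs, and the member
#' genes; edges follow the direction of transcription: a TSS connects to
#' its 5' UTR and from there to the anchor gene (or directly to the gene
#' when the gap was too short for a UTR), consecutive genes connect
#' through their internal UTR or directly when the gap is below the UTR
#' minimum, and a gene connects through its 3' UTR (or directly) to a
#' TTS. When a TU has no associated TSS anywhere, a dummy TSS is placed
#' exactly at the first gene's 5' end so a transcript can still be
#' formed (symmetrically for TTSs); dummy-bounded transcripts carry no
#' UTR on that side. Excluded TUs produce no graph.
#'
#' @param tus Complemented TU tibble.
#' @param associations Output of [associate_sites_to_genes()].
#' @param utrs UTR tibble (flanking and internal combined).
#' @param genes Merged annotation tibble.
#' @param min_utr Minimum UTR length used when the UTRs were inferred.
#' @return A list with tibbles `nodes` (`tu_id`, `node`, `kind`,
#'   `position`) and `edges` (`tu_id`, `from`, `to`).
#' @export
build_transcript_graph <- function(tus, associations, utrs, genes,
                                   min_utr = 15L) {
  tus <- filter(as_tibble(tus), !.data$excluded)
  g <- transcription_ends(as_tibble(genes))
  assoc <- filter(associations, .data$status == "associated")
  all_nodes <- list(); all_edges <- list()
  for (i in seq_len(nrow(tus))) {
    tu <- tus[i, ]
    ids <- tu$genes[[1]]
    m <- g[match(ids, g$id), ]
    if (any(is.na(m$id))) abort(paste0("TU ", tu$tu_id, " references unknown genes"))
    ord_ok <- if (tu$strand == "+") !is.unsorted(m$start) else !is.unsorted(-m$end)
    if (!ord_ok) abort(paste0("TU ", tu$tu_id, ": gene order violates coordinates"))
    nodes <- tibble(tu_id = tu$tu_id, node = m$id, kind = "gene",
                    position = NA_integer_)
    edges <- tibble(tu_id = character(), from = character(), to = character())
    # chain: gene_i -> (internal UTR) -> gene_{i+1}
    gaps <- tu_gene_gaps(ids, tu$strand, g)
    for (k in seq_len(nrow(gaps))) {
      gp <- gaps[k, ]
      iu <- utrs[utrs$utr_class == "internal" & utrs$strand == tu$strand &
                   utrs$start == gp$gap_start & utrs$end == gp$gap_end, ]
      if (gp$gap >= min_utr && nrow(iu) == 1) {
        nodes <- add_node(nodes, tu$tu_id, iu$utr_id, "internal")
        edges <- add_edge(edges, tu$tu_id, gp$from, iu$utr_id)
        edges <- add_edge(edges, tu$tu_id, iu$utr_id, gp$to)
      } else {
        edges <- add_edge(edges, tu$tu_id, gp$from, gp$to)
      }
    }
    # entries (TSS) and exits (TTS) at any member gene
    tss <- assoc[assoc$site_type == "TSS" & assoc$gene_id %in% ids, ]
    tts <- assoc[assoc$site_type == "TTS" & assoc$gene_id %in% ids, ]
    for (k in seq_len(nrow(tss))) {
      row <- tss[k, ]
      nodes <- add_node(nodes, tu$tu_id, row$site_id, "TSS", row$position)
      u <- utrs[!is.na(utrs$source_site) & utrs$source_site == row$site_id &
                  utrs$utr_class == "five_prime", ]
      if (nrow(u) == 1) {
        nodes <- add_node(nodes, tu$tu_id, u$utr_id, "five_prime")
        edges <- add_edge(edges, tu$tu_id, row$site_id, u$utr_id)
        edges <- add_edge(edges, tu$tu_id, u$utr_id, row$gene_id)
      } else {
        edges <- add_edge(edges, tu$tu_id, row$site_id, row$gene_id)
      }
    }
    for (k in seq_len(nrow(tts))) {
      row <- tts[k, ]
      nodes <- add_node(nodes, tu$tu_id, row$site_id, "TTS", row$position)
      u <- utrs[!is.na(utrs$source_site) & utrs$source_site == row$site_id &
                  utrs$utr_class == "three_prime", ]
      if (nrow(u) == 1) {
        nodes <- add_node(nodes, tu$tu_id, u$utr_id, "three_prime")
        edges <- add_edge(edges, tu$tu_id, row$gene_id, u$utr_id)
        edges <- add_edge(edges, tu$tu_id, u$utr_id, row$site_id)
      } else {
        edges <- add_edge(edges, tu$tu_id, row$gene_id, row$site_id)
      }
    }
    # dummies at terminal gene ends when a side has no real site at all
    if (nrow(tss) == 0) {
      dummy <- paste0("dummyTSS_", tu$tu_id)
      first <- m[1, ]
      nodes <- add_node(nodes, tu$tu_id, dummy, "TSS", first$five_prime)
      edges <- add_edge(edges, tu$tu_id, dummy, first$id)
    }
    if (nrow(tts) == 0) {
      dummy <- paste0("dummyTTS_", tu$tu_id)
      last <- m[nrow(m), ]
      nodes <- add_node(nodes, tu$tu_id, dummy, "TTS", last$three_prime)
      edges <- add_edge(edges, tu$tu_id, last$id, dummy)
    }
    all_nodes[[i]] <- nodes; all_edges[[i]] <- edges
  }
  list(nodes = bind_rows(all_nodes), edges = bind_rows(all_edges))
}

add_node <- function(nodes, tu_id, node, kind, position = NA_integer_) {
  if (node %in% nodes$node) return(nodes)
  bind_rows(nodes, tibble(tu_id = tu_id, node = node, kind = kind,
                          position = as.integer(position)))
}

add_edge <- function(edges, tu_id, from, to) {
  bind_rows(edges, tibble(tu_id = tu_id, from = from, to = to))
}

#' Enumerate transcripts as TSS-to-TTS paths
#'
#' Every directed path from a TSS node to a TTS node in the per-TU
#' transcript graph is one transcript carrying the genes and UTRs along
#' the path. Transcripts identical in strand, gene content and boundary
#' positions that arise from overlapping TUs are deduplicated. A cap on
#' the number of paths per TU guards against combinatorial explosion in
#' malformed inputs.
#'
#' @param graph Output of [build_transcript_graph()].
#' @param tus Complemented TU tibble (for strand lookup).
#' @param genes Merged annotation tibble (for coordinates).
#' @param utrs UTR tibble (for coordinates).
#' @param path_cap Maximum paths per TU (default 64); exceeding it is an
#'   error naming the TU.
#' @return A transcript tibble: `transcript_id`, `tss`, `tts`,
#'   `tss_pos`, `tts_pos`, `elements` (ordered UTR/gene ids), `gene_set`
#'   (ordered gene ids), `tu_ref`, `strand`, `start`, `end`.
#' @export
enumerate_transcripts <- function(graph, tus, genes, utrs, path_cap = 64L) {
  coords <- bind_rows(
    tibble(id = genes$id, start = genes$start, end = genes$end),
    if (nrow(utrs) > 0) tibble(id = utrs$utr_id, start = utrs$start, end = utrs$end)
  )
  out <- list()
  for (tu_id in unique(graph$nodes$tu_id)) {
    nodes <- graph$nodes[graph$nodes$tu_id == tu_id, ]
    edges <- graph$edges[graph$edges$tu_id == tu_id, ]
    ig <- igraph::graph_from_data_frame(edges[, c("from", "to")], directed = TRUE,
                                        vertices = nodes$node)
    if (!igraph::is_dag(ig)) abort(paste0("transcript graph for ", tu_id, " is cyclic"))
    sources <- nodes$node[nodes$kind == "TSS"]
    sinks <- nodes$node[nodes$kind == "TTS"]
    strand <- tus$strand[match(tu_id, tus$tu_id)]
    paths <- list()
    for (s in sources) {
      sp <- igraph::all_simple_paths(ig, from = s, to = sinks, mode = "out")
      paths <- c(paths, lapply(sp, function(p) igraph::as_ids(p)))
      if (length(paths) > path_cap) {
        abort(paste0("path cap (", path_cap, ") exceeded for TU ", tu_id))
      }
    }
    if (length(paths) == 0) next
    kind_of <- setNames(nodes$kind, nodes$node)
    pos_of <- setNames(nodes$position, nodes$node)
    rows <- lapply(paths, function(p) {
      inner <- p[!kind_of[p] %in% c("TSS", "TTS")]
      gene_set <- inner[kind_of[inner] == "gene"]
      if (length(gene_set) == 0) return(NULL)
      span <- coords[match(inner, coords$id), ]
      tibble(
        tss = p[[1]], tts = p[[length(p)]],
        tss_pos = pos_of[[p[[1]]]], tts_pos = pos_of[[p[[length(p)]]]],
        elements = list(inner), gene_set = list(gene_set),
        tu_ref = tu_id, strand = strand,
        start = min(span$start, pos_of[[p[[1]]]], pos_of[[p[[length(p)]]]]),
        end = max(span$end, pos_of[[p[[1]]]], pos_of[[p[[length(p)]]]])
      )
    })
    out[[tu_id]] <- bind_rows(compact(rows))
  }
  tx <- bind_rows(out)
  if (nrow(tx) == 0) {
    return(tibble(transcript_id = character(), tss = character(), tts = character(),
                  tss_pos = integer(), tts_pos = integer(), elements = list(),
                  gene_set = list(), tu_ref = character(), strand = character(),
                  start = integer(), end = integer()))
  }
  tx <- tx |>
    mutate(.key = paste(.data$strand, map_chr(.data$gene_set, paste, collapse = "|"),
                        .data$tss_pos, .data$tts_pos)) |>
    distinct(.data$.key, .keep_all = TRUE) |>
    select(-".key") |>
    arrange(.data$start, .data$end, .data$tss, .data$tts)
  tx |> mutate(transcript_id = sprintf("tx_%04d", seq_len(nrow(tx))),
               .before = 1)
}

#' Derive novel TUs from enumerated transcripts
#'
#' A TSS or TTS located inside a known TU implies a shorter
#' co-transcribed gene set. Each distinct transcript gene set not equal
#' to any known TU gene set becomes a novel TU, unless an adjacently
#' located TU already explains the boundary: for an internal TSS a known
#' TU starting at the transcript's first gene, for an internal TTS a
#' known TU ending at the transcript's last gene.
#'
#' @param transcripts Output of [enumerate_transcripts()].
#' @param known_tus Complemented TU tibble.
#' @return A TU tibble of novel TUs (source `"inferred"`), deduplicated
#'   by gene set.
#' @export
derive_tus_from_transcripts <- function(transcripts, known_tus) {
  known_keys <- map_chr(known_tus$genes, paste, collapse = "|")
  known_first <- map_chr(known_tus$genes, 1)
  known_last <- map_chr(known_tus$genes, ~ .x[[length(.x)]])
  tx <- transcripts |>
    mutate(.key = map_chr(.data$gene_set, paste, collapse = "|")) |>
    filter(!.data$.key %in% known_keys) |>
    distinct(.data$.key, .keep_all = TRUE)
  if (nrow(tx) == 0) {
    return(tu_tbl(character(), list(), character()))
  }
  parent_genes <- known_tus$genes[match(tx$tu_ref, known_tus$tu_id)]
  first_tx <- map_chr(tx$gene_set, 1)
  last_tx <- map_chr(tx$gene_set, ~ .x[[length(.x)]])
  first_parent <- map_chr(parent_genes, ~ if (is.null(.x)) NA_character_ else .x[[1]])
  last_parent <- map_chr(parent_genes, ~ if (is.null(.x)) NA_character_ else .x[[length(.x)]])
  internal_tss <- !is.na(first_parent) & first_tx != first_parent
  internal_tts <- !is.na(last_parent) & last_tx != last_parent
  suppressed <- (internal_tss & first_tx %in% known_first) |
    (internal_tts & last_tx %in% known_last)
  tx <- tx[!suppressed, ]
  if (nrow(tx) == 0) return(tu_tbl(character(), list(), character()))
  tu_tbl(
    tu_id = sprintf("novel_tu_%04d", seq_len(nrow(tx))),
    genes = tx$gene_set, strand = tx$strand,
    start = tx$start, end = tx$end, source = "inferred"
  )
}

#' Assemble operons from transcripts
#'
#' Two transcripts sharing the full sequence of at least one gene are
#' isoforms of the same operon. Operons are the connected components of
#' the bipartite graph whose nodes are transcripts and genes, with an
#' edge whenever the gene belongs to the transcript's gene set and is
#' fully contained in its interval.
#'
#' @param transcripts Output of [enumerate_transcripts()].
#' @param genes Merged annotation tibble.
#' @return An operon tibble: `operon_id`, `transcripts` (list),
#'   `genes` (list, coordinate order), `strand`, `start`, `end`,
#'   `n_genes`, `n_transcripts`, `n_isoforms`, `operon_class`,
#'   `has_full_transcript`.
#' @export
build_operons <- function(transcripts, genes) {
  tx <- as_tibble(transcripts)
  if (nrow(tx) == 0) {
    return(tibble(operon_id = character(), transcripts = list(), genes = list(),
                  strand = character(), start = integer(), end = integer(),
                  n_genes = integer(), n_transcripts = integer(),
                  n_isoforms = integer(), operon_class = character(),
                  has_full_transcript = logical()))
  }
  edges <- tx |>
    select("transcript_id", "gene_set", "start", "end") |>
    unnest("gene_set") |>
    rename(gene_id = "gene_set")
  gm <- match(edges$gene_id, genes$id)
  contained <- genes$start[gm] >= edges$start & genes$end[gm] <= edges$end
  edges <- edges[contained, c("transcript_id", "gene_id")]
  ig <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = unique(c(tx$transcript_id, edges$gene_id)))
  )
  memb <- igraph::components(ig)$membership
  tx$.comp <- unname(memb[tx$transcript_id])
  ops <- tx |>
    group_by(.data$.comp) |>
    group_map(function(d, key) {
      gene_ids <- unique(unlist(d$gene_set))
      gidx <- match(gene_ids, genes$id)
      gene_ids <- gene_ids[order(genes$start[gidx])]
      full <- any(map_lgl(d$gene_set, ~ setequal(.x, gene_ids)))
      tibble(
        transcripts = list(sort(d$transcript_id)),
        genes = list(gene_ids),
        strand = d$strand[[1]],
        start = min(d$start), end = max(d$end),
        n_genes = length(gene_ids),
        n_transcripts = nrow(d),
        n_isoforms = nrow(distinct(d, .data$tss_pos, .data$tts_pos)),
        has_full_transcript = full
      )
    }) |>
    bind_rows() |>
    arrange(.data$start, .data$end)
  ops |>
    mutate(
      operon_id = sprintf("operon_%04d", seq_len(nrow(ops))),
      operon_class = classify_operon(.data$n_genes, .data$n_isoforms),
      .before = 1
    )
}

#' Classify operons as simple, traditional or complex
#'
#' `simple`: one gene and a single isoform (monocistronic, no
#' alternatives). `traditional`: two or more genes and a single isoform
#' (the textbook polycistronic operon). `complex`: two or more isoforms
#' regardless of gene count — alternative TSSs/TTSs make even a
#' monocistronic operon complex. Isoform identity is the distinct
#' (TSS, TTS) boundary pair, not merely the gene set.
#'
#' @param n_genes,n_isoforms Integer vectors.
#' @return Character vector of class labels.
#' @export
classify_operon <- function(n_genes, n_isoforms) {
  if (any(n_isoforms < 1)) abort("operon with no transcripts")
  dplyr::case_when(
    n_isoforms >= 2 ~ "complex",
    n_genes == 1 ~ "simple",
    TRUE ~ "traditional"
  )
}

#' Expand CRISPR guide off-target gene lists by operon context
#'
#' A dCas9/Cas9 complex binding within one gene of a polycistronic
#' operon affects the whole co-transcribed unit, so the putative gene
#' off-target list of a guide whose cut position falls inside such a
#' gene is expanded to all genes of the operon. Cuts in monocistronic
#' operons keep the direct gene only; intergenic cuts expand to nothing.
#'
#' @param targets A tibble with `guide_id` and `cut_position` (bp).
#' @param operons Output of [build_operons()].
#' @param genes Merged annotation tibble.
#' @return `targets` with `direct_gene` and `operon_expanded_genes`
#'   (list-column) appended.
#' @export
expand_offtargets_by_operon <- function(targets, operons, genes) {
  op_of_gene <- operons |>
    select("operon_id", "genes", "n_genes") |>
    unnest("genes") |>
    rename(gene_id = "genes")
  res <- lapply(targets$cut_position, function(pos) {
    hit <- genes[genes$start <= pos & genes$end >= pos, ]
    if (nrow(hit) == 0) {
      return(list(direct = NA_character_, expanded = character()))
    }
    direct <- hit$id[order(hit$start)][[1]]
    expanded <- unique(unlist(lapply(hit$id, function(gid) {
      ops <- op_of_gene[op_of_gene$gene_id == gid, ]
      if (nrow(ops) > 0 && any(ops$n_genes > 1)) {
        poly <- ops$operon_id[ops$n_genes > 1]
        unlist(operons$genes[match(poly, operons$operon_id)])
      } else {
        gid
      }
    })))
    list(direct = direct, expanded = sort(expanded))
  })
  targets |>
    mutate(direct_gene = map_chr(res, "direct"),
           operon_expanded_genes = map(res, "expanded"))
}
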