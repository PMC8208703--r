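#' Specification for a synthetic ground-truth atlas
#'
#' Parameters of the simulated genome from which multi-resource input
#' views are emitted. The defaults describe a compact but realistic
#' bacterial arrangement: operons of 1-3 genes of a few hundred bp,
#' intra-operon gaps that are sometimes long enough (>= 15 bp) to be
#' transcribed as internal UTRs, 5'/3' UTRs of 20-150 bp, and a 30 %
#' chance per operon of an additional (alternative or internal) TSS or
#' TTS, which is what creates isoforms and hence complex operons.
#'
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param genome_length Genome length in bp.
#' @param n_operons Number of operons to place.
#' @param genes_per_operon Integer range `c(min, max)`.
#' @param gene_length bp range for coding genes.
#' @param ncrna_length bp range for ncRNA genes.
#' @param gap_length bp range for intra-operon gene gaps (gaps below 15
#'   bp join genes directly; longer gaps become internal UTRs).
#' @param utr_length bp range for 5'/3' UTR lengths (all >= 15).
#' @param spacing bp range between consecutive operon envelopes.
#' @param p_extra_tss,p_extra_tts Probability per operon of one extra
#'   TSS/TTS (an alternative boundary for monocistronic operons, an
#'   internal site otherwise).
#' @param p_ncrna_operon Probability that an operon is a monocistronic
#'   ncRNA (sRNA) instead of a coding operon.
#' @param resource_noise Per-view noise settings; see
#'   [emit_resource_views()].
#' @param tu_gene_dropout Probability that a TU list of >= 3 genes drops
#'   one internal gene (exercising TU complementation).
#' @return A list with class `truth_spec`.
#' @export
truth_spec <- function(seed,
                       genome_length = 500000L,
                       n_operons = 20L,
                       genes_per_operon = c(1L, 3L),
                       gene_length = c(300L, 900L),
                       ncrna_length = c(80L, 200L),
                       gap_length = c(0L, 80L),
                       utr_length = c(20L, 150L),
                       spacing = c(300L, 800L),
                       p_extra_tss = 0.3,
                       p_extra_tts = 0.3,
                       p_ncrna_operon = 0.2,
                       resource_noise = default_resource_noise(),
                       tu_gene_dropout = 0.3) {
  probs <- c(p_extra_tss, p_extra_tts, p_ncrna_operon, tu_gene_dropout)
  if (any(probs < 0 | probs > 1)) abort("probabilities must be in [0, 1]")
  if (genome_length < 1 || n_operons < 1) abort("lengths/counts must be positive")
  if (utr_length[[1]] < 15) abort("utr_length must be >= 15 bp")
  structure(
    list(seed = as.integer(seed), genome_length = as.integer(genome_length),
         n_operons = as.integer(n_operons), genes_per_operon = genes_per_operon,
         gene_length = gene_length, ncrna_length = ncrna_length,
         gap_length = gap_length, utr_length = utr_length, spacing = spacing,
         p_extra_tss = p_extra_tss, p_extra_tts = p_extra_tts,
         p_ncrna_operon = p_ncrna_operon, resource_noise = resource_noise,
         tu_gene_dropout = tu_gene_dropout),
    class = "truth_spec"
  )
}

#' @rdname truth_spec
#' @export
default_resource_noise <- function() {
  list(
    curated = list(jitter_sd = 0, jitter_max = 0, site_jitter_max = 0,
                   halfwidth = 0L, dropout = 0, orphan_rate = 0, redundancy = 0),
    array = list(jitter_sd = 6, jitter_max = 15, site_jitter_max = 22,
                 halfwidth = 22L, dropout = 0.2, orphan_rate = 0.1, redundancy = 0),
    redundant = list(jitter_sd = 4, jitter_max = 12, site_jitter_max = 0,
                     halfwidth = 0L, dropout = 0, orphan_rate = 0, redundancy = 1)
  )
}

rint <- function(n, range) {
  if (range[[1]] == range[[2]]) rep(range[[1]], n)
  else sample(seq.int(range[[1]], range[[2]]), n, replace = TRUE)
}

#' Generate a ground-truth atlas
#'
#' Lays out operons along a simulated genome and derives the complete,
#' internally consistent truth: genes, TUs, boundary sites, UTRs,
#' transcripts (every TSS/TTS combination in transcription order) and
#' classified operons. All downstream pipeline stages can be validated
#' against this truth via [score_recovery()].
#'
#' @param spec A [truth_spec()].
#' @return A list with class `sim_truth` holding tibbles `genes`, `tus`,
#'   `sites`, `utrs`, `transcripts`, `operons` and the `spec`.
#' @export
generate_truth <- function(spec) {
  stopifnot(inherits(spec, "truth_spec"))
  withr::with_seed(spec$seed, generate_truth_impl(spec))
}

generate_truth_impl <- function(spec) {
  genes <- list(); tus <- list(); sites <- list(); utrs <- list()
  transcripts <- list(); operons <- list()
  cursor <- 500L  # leave room for the first operon's upstream features
  for (i in seq_len(spec$n_operons)) {
    strand <- sample(c("+", "-"), 1)
    is_nc <- runif(1) < spec$p_ncrna_operon
    n <- if (is_nc) 1L else rint(1, spec$genes_per_operon)
    glen <- rint(n, if (is_nc) spec$ncrna_length else spec$gene_length)
    gaps <- if (n > 1) rint(n - 1, spec$gap_length) else integer()
    utr5 <- rint(1, spec$utr_length); utr3 <- rint(1, spec$utr_length)
    # coordinate layout left to right; transcription order follows strand
    starts <- cursor + cumsum(c(0L, glen[-n] + gaps))
    ends <- starts + glen - 1L
    right <- ends[[n]]
    ord <- if (strand == "+") seq_len(n) else rev(seq_len(n))
    gid <- sprintf("g%03d_%d", i, seq_len(n))
    op_genes <- annotation_tbl(
      id = gid, start = starts, end = ends, strand = strand,
      biotype = if (is_nc) "sRNA" else "CDS", resource = "truth", priority = 1L,
      names = as.list(sprintf("gene%03d_%d", i, seq_len(n)))
    )
    five <- if (strand == "+") starts else ends    # per-gene 5' ends
    three <- if (strand == "+") ends else starts
    dir <- if (strand == "+") 1L else -1L
    tx_genes <- gid[ord]; tx_five <- five[ord]; tx_three <- three[ord]
    # primary boundary sites always exist and carry the full UTRs
    entries <- tibble(site_id = sprintf("tss%03d_a", i),
                      position = tx_five[[1]] - dir * utr5,
                      anchor = 1L, sigma = sample(c("SigA", "SigB"), 1))
    exits <- tibble(site_id = sprintf("tts%03d_a", i),
                    position = tx_three[[n]] + dir * utr3,
                    anchor = n)
    if (runif(1) < spec$p_extra_tss) {
      if (n >= 2) {
        k <- if (n == 2) 2L else sample(2:n, 1)
        d <- rint(1, c(15L, 40L))
        entries <- bind_rows(entries, tibble(
          site_id = sprintf("tss%03d_b", i), position = tx_five[[k]] - dir * d,
          anchor = k, sigma = sample(c("SigA", "SigB"), 1)))
      } else {
        off <- rint(1, c(100L, 160L))
        entries <- bind_rows(entries, tibble(
          site_id = sprintf("tss%03d_b", i),
          position = entries$position[[1]] - dir * off,
          anchor = 1L, sigma = sample(c("SigA", "SigB"), 1)))
      }
    }
    if (runif(1) < spec$p_extra_tts) {
      if (n >= 2) {
        k <- if (n == 2) 1L else sample(1:(n - 1), 1)
        d <- rint(1, c(15L, 40L))
        exits <- bind_rows(exits, tibble(
          site_id = sprintf("tts%03d_b", i), position = tx_three[[k]] + dir * d,
          anchor = k))
      } else {
        off <- rint(1, c(100L, 160L))
        exits <- bind_rows(exits, tibble(
          site_id = sprintf("tts%03d_b", i),
          position = exits$position[[1]] + dir * off, anchor = 1L))
      }
    }
    op_sites <- bind_rows(
      site_tbl(entries$site_id, entries$position, strand, "TSS",
               halfwidth = 0L, sigma = entries$sigma, resource = "truth"),
      site_tbl(exits$site_id, exits$position, strand, "TTS",
               halfwidth = 0L, resource = "truth")
    )
    # truth UTRs mirror the inference rules exactly
    op_utrs <- bind_rows(
      lapply(seq_len(nrow(entries)), function(e) {
        p <- entries$position[[e]]; g5 <- tx_five[[entries$anchor[[e]]]]
        tibble(utr_id = paste0("utr5_", entries$site_id[[e]]),
               start = as.integer(if (strand == "+") p else g5 + 1L),
               end = as.integer(if (strand == "+") g5 - 1L else p),
               strand = strand, utr_class = "five_prime",
               anchor_gene = tx_genes[[entries$anchor[[e]]]],
               source_site = entries$site_id[[e]], extended = FALSE)
      }),
      lapply(seq_len(nrow(exits)), function(e) {
        p <- exits$position[[e]]; g3 <- tx_three[[exits$anchor[[e]]]]
        tibble(utr_id = paste0("utr3_", exits$site_id[[e]]),
               start = as.integer(if (strand == "+") g3 + 1L else p),
               end = as.integer(if (strand == "+") p else g3 - 1L),
               strand = strand, utr_class = "three_prime",
               anchor_gene = tx_genes[[exits$anchor[[e]]]],
               source_site = exits$site_id[[e]], extended = FALSE)
      })
    )
    if (n > 1) {
      long <- which(gaps >= 15L)
      if (length(long) > 0) {
        anchor_idx <- if (strand == "+") long else long + 1L
        op_utrs <- bind_rows(op_utrs, tibble(
          utr_id = sprintf("utri%03d_%d", i, long),
          start = ends[long] + 1L, end = starts[long + 1L] - 1L,
          strand = strand, utr_class = "internal",
          anchor_gene = gid[anchor_idx],
          source_site = NA_character_, extended = FALSE
        ))
      }
    }
    # transcripts: every entry/exit pair in transcription order
    combos <- tidyr::expand_grid(e = seq_len(nrow(entries)), x = seq_len(nrow(exits)))
    combos <- combos[entries$anchor[combos$e] <= exits$anchor[combos$x], ]
    op_tx <- bind_rows(lapply(seq_len(nrow(combos)), function(r) {
      e <- combos$e[[r]]; x <- combos$x[[r]]
      idx <- seq.int(entries$anchor[[e]], exits$anchor[[x]])
      tibble(transcript_id = sprintf("truth_tx%03d_%d", i, r),
             tss = entries$site_id[[e]], tts = exits$site_id[[x]],
             tss_pos = entries$position[[e]], tts_pos = exits$position[[x]],
             gene_set = list(tx_genes[idx]), tu_ref = sprintf("tu%03d", i),
             strand = strand,
             start = min(entries$position[[e]], exits$position[[x]]),
             end = max(entries$position[[e]], exits$position[[x]]))
    }))
    operons[[i]] <- tibble(
      operon_id = sprintf("truth_op%03d", i),
      transcripts = list(op_tx$transcript_id), genes = list(gid),
      strand = strand, start = min(op_tx$start), end = max(op_tx$end),
      n_genes = n, n_transcripts = nrow(op_tx), n_isoforms = nrow(op_tx),
      operon_class = classify_operon(n, nrow(op_tx)),
      has_full_transcript = TRUE
    )
    genes[[i]] <- op_genes
    tus[[i]] <- tu_tbl(sprintf("tu%03d", i), list(tx_genes), strand,
                       start = starts[[1]], end = right, source = "truth")
    sites[[i]] <- op_sites
    utrs[[i]] <- op_utrs
    transcripts[[i]] <- op_tx
    cursor <- right + max(utr3, utr5) + 200L + rint(1, spec$spacing)
    if (cursor > spec$genome_length - 3000L) {
      if (i < spec$n_operons) abort("infeasible packing: operons exceed genome length")
    }
  }
  structure(
    list(genes = bind_rows(genes), tus = bind_rows(tus),
         sites = bind_rows(sites), utrs = bind_rows(utrs),
         transcripts = bind_rows(transcripts), operons = bind_rows(operons),
         spec = spec),
    class = "sim_truth"
  )
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

jitter_int <- function(n, sd, max_abs) {
  if (sd == 0 || max_abs == 0) return(rep(0L, n))
  as.integer(clamp(round(rnorm(n, 0, sd)), -max_abs, max_abs))
}

#' Emit per-resource input views of a ground truth
#'
#' Simulates the heterogeneity of real annotation resources:
#'
#' * `curated`: exact coordinates, nucleotide-resolution sites with
#'   sigma factors, and the TU lists (optionally with an internal gene
#'   dropped, to exercise TU complementation);
#' * `array`: tiling-array-like predictions — gene coordinates jittered
#'   (bounded so the Jaccard index against truth stays above the merge
#'   thresholds), sites jittered within +/- 22 bp and carrying a 22 bp
#'   resolution half-width, some sites orphan-flagged, specific ncRNA
#'   biotypes degraded to `putative_ncRNA`, and random dropout;
#' * `redundant`: an ncRNA-only view duplicating truth ncRNAs with a
#'   small jitter (Jaccard still >= 0.5 against truth).
#'
#' @param truth A [generate_truth()] result.
#' @param spec The [truth_spec()] (defaults to the one in `truth`).
#' @return A named list of views; each view is a list with `config`
#'   (a [resource_config()]) and tibbles `annotations`, `sites`, `tus`.
#' @export
emit_resource_views <- function(truth, spec = truth$spec) {
  stopifnot(inherits(truth, "sim_truth"))
  withr::with_seed(spec$seed + 1L, emit_views_impl(truth, spec))
}

emit_views_impl <- function(truth, spec) {
  nz <- spec$resource_noise
  prefix_ids <- function(tbl, col, pre) {
    tbl[[col]] <- paste0(pre, tbl[[col]]); tbl
  }
  # curated view: the reference-quality resource
  cur_genes <- truth$genes |>
    mutate(resource = "curated", priority = 1L) |>
    prefix_ids("id", "cur|")
  cur_sites <- truth$sites |>
    mutate(resource = "curated", halfwidth = 0L) |>
    prefix_ids("site_id", "cur|")
  cur_tus <- truth$tus
  drop_gene <- lengths(cur_tus$genes) >= 3 & runif(nrow(cur_tus)) < spec$tu_gene_dropout
  cur_tus$genes <- pmap(list(cur_tus$genes, drop_gene), function(gs, dr) {
    gs <- paste0("cur|", gs)
    if (dr) {
      inner <- seq(2, length(gs) - 1)  # only internal genes may be dropped
      gs[-inner[sample.int(length(inner), 1)]]
    } else {
      gs
    }
  })
  cur_tus <- mutate(cur_tus, tu_id = paste0("cur|", .data$tu_id),
                    source = "curated", start = NA_integer_, end = NA_integer_)
  curated <- list(
    config = resource_config("curated", 1L, 1L, nz$curated$halfwidth, curated = TRUE),
    annotations = cur_genes, sites = cur_sites, tus = cur_tus
  )
  # array view: predictions with bounded noise and dropout
  arr <- nz$array
  keep <- runif(nrow(truth$genes)) >= arr$dropout
  ag <- truth$genes[keep, ]
  ag$start <- ag$start + jitter_int(nrow(ag), arr$jitter_sd, arr$jitter_max)
  ag$end <- ag$end + jitter_int(nrow(ag), arr$jitter_sd, arr$jitter_max)
  ag$biotype <- ifelse(ag$biotype == "CDS", "CDS", "putative_ncRNA")
  ag <- ag |> mutate(resource = "array", priority = 3L) |> prefix_ids("id", "arr|")
  skeep <- runif(nrow(truth$sites)) >= arr$dropout
  as_ <- truth$sites[skeep, ]
  as_$position <- as_$position +
    jitter_int(nrow(as_), max(1, arr$jitter_sd), arr$site_jitter_max)
  as_ <- as_ |>
    mutate(halfwidth = arr$halfwidth, sigma = NA_character_, resource = "array",
           orphan = runif(nrow(as_)) < arr$orphan_rate) |>
    prefix_ids("site_id", "arr|")
  array_view <- list(
    config = resource_config("array", 3L, 3L, arr$halfwidth),
    annotations = ag, sites = as_, tus = tu_tbl(character(), list(), character())
  )
  # redundant ncRNA view: duplicated non-coding annotations
  red <- nz$redundant
  rg <- truth$genes[truth$genes$biotype != "CDS", ]
  rg <- rg[runif(nrow(rg)) < red$redundancy, ]
  rg$start <- rg$start + jitter_int(nrow(rg), red$jitter_sd, red$jitter_max)
  rg$end <- rg$end + jitter_int(nrow(rg), red$jitter_sd, red$jitter_max)
  rg <- rg |> mutate(resource = "redundant", priority = 2L) |> prefix_ids("id", "red|")
  redundant <- list(
    config = resource_config("redundant", 2L, 2L, red$halfwidth),
    annotations = rg,
    sites = site_tbl(character(), integer(), character(), character()),
    tus = tu_tbl(character(), list(), character())
  )
  list(curated = curated, array = array_view, redundant = redundant)
}

#' Score pipeline output against a ground truth
#'
#' Exact-match recovery metrics for every pipeline stage: gene-level
#' precision/recall on (start, end, strand), biotype accuracy on the
#' matched genes, unified-site precision/recall on (position, strand,
#' type), per-class UTR precision/recall on exact coordinates,
#' transcript-count ratio, operon recall (matched by member gene
#' coordinates) and operon class accuracy on the matched operons.
#'
#' @param atlas Pipeline output ([run_pipeline()]).
#' @param truth A [generate_truth()] result.
#' @return A tibble with `metric` and `value` columns; all values equal
#'   1 when recovery is exact.
#' @export
score_recovery <- function(atlas, truth) {
  key_ann <- function(x) paste(x$start, x$end, x$strand)
  key_site <- function(x) paste(x$position, x$strand, x$site_type)
  key_utr <- function(x) paste(x$start, x$end, x$strand, x$utr_class)
  pr <- function(out_keys, truth_keys) {
    c(precision = if (length(out_keys) == 0) 1 else
        mean(out_keys %in% truth_keys),
      recall = if (length(truth_keys) == 0) 1 else
        mean(truth_keys %in% out_keys))
  }
  g <- pr(key_ann(atlas$genes), key_ann(truth$genes))
  matched <- match(key_ann(atlas$genes), key_ann(truth$genes))
  bio_acc <- if (all(is.na(matched))) 0 else
    mean(atlas$genes$biotype[!is.na(matched)] ==
           truth$genes$biotype[matched[!is.na(matched)]])
  s <- pr(key_site(atlas$sites), key_site(truth$sites))
  u <- unlist(lapply(c("five_prime", "three_prime", "internal"), function(cl) {
    out <- atlas$utrs[atlas$utrs$utr_class == cl, ]
    tru <- truth$utrs[truth$utrs$utr_class == cl, ]
    setNames(pr(key_utr(out), key_utr(tru)),
             paste0("utr_", cl, c("_precision", "_recall")))
  }))
  tx_ratio <- if (nrow(truth$transcripts) == 0) 1 else
    nrow(atlas$transcripts) / nrow(truth$transcripts)
  op_key <- function(ops, genes) {
    map_chr(ops$genes, function(ids) {
      m <- genes[match(ids, genes$id), ]
      paste(sort(paste(m$start, m$end)), collapse = ";")
    })
  }
  out_keys <- op_key(atlas$operons, atlas$genes)
  tru_keys <- op_key(truth$operons, truth$genes)
  m <- match(tru_keys, out_keys)
  op_recall <- mean(!is.na(m))
  class_acc <- if (all(is.na(m))) 0 else
    mean(truth$operons$operon_class[!is.na(m)] ==
           atlas$operons$operon_class[m[!is.na(m)]])
  tibble(
    metric = c("gene_precision", "gene_recall", "biotype_accuracy",
               "site_precision", "site_recall", names(u),
               "transcript_count_ratio", "operon_recall",
               "operon_class_accuracy"),
    value = unname(c(g["precision"], g["recall"], bio_acc,
                     s["precision"], s["recall"], u,
                     tx_ratio, op_recall, class_acc))
  )
}
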