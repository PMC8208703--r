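#' @export
print.operon_atlas <- function(x, ...) {
  cat("<operon_atlas>\n")
  cat(sprintf("  genes:       %d (%d coding, %d non-coding)\n",
              nrow(x$genes), sum(x$genes$biotype == "CDS"),
              sum(x$genes$biotype != "CDS")))
  cat(sprintf("  sites:       %d TSS, %d TTS\n",
              sum(x$sites$site_type == "TSS"), sum(x$sites$site_type == "TTS")))
  cat(sprintf("  UTRs:        %d five_prime, %d three_prime, %d internal\n",
              sum(x$utrs$utr_class == "five_prime"),
              sum(x$utrs$utr_class == "three_prime"),
              sum(x$utrs$utr_class == "internal")))
  cat(sprintf("  TUs:         %d known (+%d novel)\n",
              nrow(x$tus), nrow(x$novel_tus)))
  cat(sprintf("  transcripts: %d\n", nrow(x$transcripts)))
  cat(sprintf("  operons:     %d (%s)\n", nrow(x$operons),
              paste(names(table(x$operons$operon_class)),
                    table(x$operons$operon_class), collapse = ", ")))
  invisible(x)
}

#' Tidy an atlas into one long feature table
#'
#' @param x A `operon_atlas`.
#' @param ... Unused.
#' @return A tibble with one row per feature: `feature` (gene / site /
#'   utr / transcript / operon), `id`, `start`, `end`, `strand`,
#'   `class` (biotype, site type, UTR class or operon class).
#' @export
tidy.operon_atlas <- function(x, ...) {
  bind_rows(
    tibble(feature = "gene", id = x$genes$id, start = x$genes$start,
           end = x$genes$end, strand = x$genes$strand, class = x$genes$biotype),
    tibble(feature = "site", id = x$sites$site_id, start = x$sites$position,
           end = x$sites$position, strand = x$sites$strand,
           class = x$sites$site_type),
    tibble(feature = "utr", id = x$utrs$utr_id, start = x$utrs$start,
           end = x$utrs$end, strand = x$utrs$strand, class = x$utrs$utr_class),
    tibble(feature = "transcript", id = x$transcripts$transcript_id,
           start = x$transcripts$start, end = x$transcripts$end,
           strand = x$transcripts$strand, class = "transcript"),
    tibble(feature = "operon", id = x$operons$operon_id,
           start = x$operons$start, end = x$operons$end,
           strand = x$operons$strand, class = x$operons$operon_class)
  )
}

#' One-row summary of an atlas
#'
#' @param x A `operon_atlas`.
#' @param ... Unused.
#' @return A one-row tibble of headline counts and fractions.
#' @export
glance.operon_atlas <- function(x, ...) {
  rc <- report_counts(x)
  v <- setNames(rc$value, rc$metric)
  n_op <- max(v[["operons_total"]], 1)
  tibble(
    n_genes = v[["genes_total"]], n_coding = v[["genes_CDS"]],
    n_ncrna = v[["genes_total"]] - v[["genes_CDS"]],
    n_tss = v[["tss"]], n_tts = v[["tts"]],
    n_utr5 = v[["utr_five_prime"]], n_utr3 = v[["utr_three_prime"]],
    n_utr_internal = v[["utr_internal"]],
    n_tus = v[["tus"]], n_novel_tus = v[["novel_tus"]],
    n_transcripts = v[["transcripts"]], n_operons = v[["operons_total"]],
    frac_simple = v[["operons_simple"]] / n_op,
    frac_traditional = v[["operons_traditional"]] / n_op,
    frac_complex = v[["operons_complex"]] / n_op,
    gene_coverage = v[["gene_coverage"]]
  )
}

#' Plot atlas composition
#'
#' Bar panels of gene biotypes, UTR classes and operon classes.
#'
#' @param object A `operon_atlas`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.operon_atlas <- function(object, ...) {
  d <- bind_rows(
    tibble(panel = "genes", class = object$genes$biotype),
    tibble(panel = "UTRs", class = object$utrs$utr_class),
    tibble(panel = "operons", class = object$operons$operon_class)
  ) |> count(.data$panel, .data$class)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$panel), scales = "free") +
    ggplot2::labs(x = NULL, y = "count", title = "Atlas composition") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot recovery metrics against ground truth
#'
#' @param recovery Output of [score_recovery()].
#' @return A ggplot object.
#' @export
plot_recovery <- function(recovery) {
  ggplot2::ggplot(recovery,
                  ggplot2::aes(x = stats::reorder(.data$metric, .data$value),
                               y = .data$value)) +
    ggplot2::geom_col(fill = "darkseagreen") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "recovery", title = "Ground-truth recovery") +
    ggplot2::theme_minimal()
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth>\n")
  cat(sprintf("  %d operons, %d genes, %d sites, %d UTRs, %d transcripts\n",
              nrow(x$operons), nrow(x$genes), nrow(x$sites), nrow(x$utrs),
              nrow(x$transcripts)))
  invisible(x)
}
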