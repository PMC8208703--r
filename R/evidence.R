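#' Mean max log2 signal (ML2) of annotations
#'
#' The transcription-evidence statistic: for every bp position of an
#' annotation take the maximum log2 signal across all experimental
#' conditions, then average those per-position maxima over the
#' annotation. An annotation transcribed in any condition therefore
#' scores high even if silent in most conditions. Signals are used
#' as-is; no normalization is applied.
#'
#' @param annotations A data frame with `start`, `end` (and optionally
#'   `strand`) columns.
#' @param signal Long-format signal table with columns `position`,
#'   `condition`, `value` and optionally `strand` (then per-position
#'   maxima are computed per strand and matched to the annotation
#'   strand).
#' @param fill Value assumed at positions absent from `signal`
#'   (sparse storage); default 0.
#' @param genome_length Length of the signal domain; defaults to the
#'   largest position in `signal`. Annotations outside `[1,
#'   genome_length]` are an error.
#' @return `annotations` as a tibble with an `ml2` column appended.
#' @export
compute_ml2 <- function(annotations, signal, fill = 0, genome_length = NULL) {
  a <- as_tibble(annotations)
  s <- as_tibble(signal)
  if (nrow(s) == 0 || length(unique(s$condition)) < 1) {
    abort("signal must contain at least one condition")
  }
  if (any(!is.finite(s$value))) abort("signal values must be finite")
  genome_length <- genome_length %||% max(s$position)
  if (any(a$start < 1) || any(a$end > genome_length)) {
    abort("annotation outside the signal range")
  }
  stranded <- "strand" %in% names(s)
  if (stranded && !"strand" %in% names(a)) {
    abort("stranded signal requires a strand column on the annotations")
  }
  grouping <- if (stranded) c("strand", "position") else "position"
  mp <- s |>
    group_by(across(all_of(grouping))) |>
    summarise(m = max(.data$value), .groups = "drop")
  ml2_one <- function(start, end, strand) {
    pos <- seq.int(start, end)
    m <- if (stranded) {
      mp$m[match(paste(strand, pos), paste(mp$strand, mp$position))]
    } else {
      mp$m[match(pos, mp$position)]
    }
    mean(ifelse(is.na(m), fill, m))
  }
  a$ml2 <- pmap_dbl_safe(a, ml2_one, stranded)
  a
}

pmap_dbl_safe <- function(a, f, stranded) {
  vapply(seq_len(nrow(a)), function(i) {
    f(a$start[[i]], a$end[[i]], if (stranded) a$strand[[i]] else NA)
  }, numeric(1))
}

#' ML2 percentile summary of an annotation set
#'
#' Reports the ML2 level exceeded by 90 % of the annotations (the 10th
#' percentile) and by 50 % (the median), using linear-interpolation
#' percentiles (R quantile type 7); the method is stated in the output
#' so thresholds are comparable across tools.
#'
#' @param ml2 Numeric vector of ML2 values, or a data frame with an
#'   `ml2` column.
#' @return A one-row tibble: `exceeded_by_90pct`, `median`, `n`,
#'   `method`.
#' @export
ml2_percentiles <- function(ml2) {
  if (is.data.frame(ml2)) ml2 <- ml2$ml2
  if (length(ml2) == 0) abort("empty annotation set")
  q <- stats::quantile(ml2, probs = c(0.1, 0.5), type = 7, names = FALSE)
  tibble(exceeded_by_90pct = q[[1]], median = q[[2]], n = length(ml2),
         method = "linear interpolation (quantile type 7)")
}

#' Biotype agreement between two UTR annotation sets
#'
#' Counts, for every source UTR, how its class relates to the target
#' set under same-strand overlap of at least 1 bp: overlap with a
#' target of the same class counts as agreement (even if other classes
#' are also touched); overlap with several different other classes —
#' typically a region straddling both a 5' and a 3' UTR of two operons —
#' goes to the dedicated `both` cell; overlap with exactly one other
#' class goes to that class's cell; no overlap is counted as such.
#' Every source UTR is counted exactly once, so row sums equal the
#' source class sizes.
#'
#' @param source_utrs,target_utrs UTR tibbles with `start`, `end`,
#'   `strand`, `utr_class`.
#' @return A tibble with one row per source class and columns `agree`,
#'   `five_prime`, `three_prime`, `internal`, `both`, `no_overlap`, `n`.
#' @export
biotype_agreement <- function(source_utrs, target_utrs) {
  src <- as_tibble(source_utrs); tgt <- as_tibble(target_utrs)
  outcome <- function(i) {
    ov <- tgt$strand == src$strand[[i]] &
      tgt$start <= src$end[[i]] & tgt$end >= src$start[[i]]
    classes <- unique(tgt$utr_class[ov])
    if (length(classes) == 0) return("no_overlap")
    if (src$utr_class[[i]] %in% classes) return("agree")
    if (length(classes) >= 2) return("both")
    classes
  }
  src$outcome <- vapply(seq_len(nrow(src)), outcome, character(1))
  cells <- c("agree", "five_prime", "three_prime", "internal", "both", "no_overlap")
  src |>
    count(.data$utr_class, .data$outcome) |>
    mutate(outcome = factor(.data$outcome, levels = cells)) |>
    pivot_wider(names_from = "outcome", values_from = "n", values_fill = 0L,
                names_expand = TRUE) |>
    mutate(n = rowSums(across(all_of(cells))))
}
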