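#' Jaccard index between genomic intervals
#'
#' The similarity measure used to decide whether two overlapping gene
#' annotations from different resources describe the same feature: the
#' number of base pairs shared by both intervals divided by the number of
#' base pairs covered by either. All coordinates are 1-based and
#' inclusive, so an interval `[s, e]` covers `e - s + 1` bp.
#'
#' Intervals on opposite strands always score 0: antisense overlaps (for
#' example an asRNA across an mRNA) must never be treated as the same
#' feature.
#'
#' @param start1,end1 Integer vectors, first interval(s).
#' @param start2,end2 Integer vectors, second interval(s).
#' @param strand1,strand2 Strand characters (`"+"` or `"-"`), recycled.
#' @return Numeric vector of Jaccard indices in `[0, 1]`.
#' @examples
#' interval_jaccard(1, 182, 76, 182)  # 107 bp overlap inside 182 bp: ~0.59
#' @export
interval_jaccard <- function(start1, end1, start2, end2,
                             strand1 = "+", strand2 = "+") {
  validate_interval(start1, end1)
  validate_interval(start2, end2)
  n <- max(length(start1), length(start2))
  start1 <- rep_len(as.numeric(start1), n); end1 <- rep_len(as.numeric(end1), n)
  start2 <- rep_len(as.numeric(start2), n); end2 <- rep_len(as.numeric(end2), n)
  strand1 <- rep_len(strand1, n); strand2 <- rep_len(strand2, n)
  inter <- pmax(0, pmin(end1, end2) - pmax(start1, start2) + 1)
  uni <- (end1 - start1 + 1) + (end2 - start2 + 1) - inter
  ifelse(strand1 == strand2, inter / uni, 0)
}

validate_interval <- function(start, end) {
  if (any(is.na(start)) || any(is.na(end))) {
    abort("interval coordinates must not be NA")
  }
  if (any(start < 1) || any(end < start)) {
    abort("invalid interval: need 1 <= start <= end")
  }
  invisible(TRUE)
}

#' Strand-aware transcription ends of intervals
#'
#' Adds `five_prime` and `three_prime` columns to a table of intervals.
#' On the plus strand the 5' end is `start` and the 3' end is `end`; on
#' the minus strand the two are mirrored. Site-to-gene association works
#' on these transcription ends, not on raw coordinates.
#'
#' @param x A data frame with `start`, `end` and `strand` columns.
#' @return `x` as a tibble with `five_prime` and `three_prime` appended.
#' @examples
#' transcription_ends(tibble::tibble(start = 100, end = 200, strand = "-"))
#' @export
transcription_ends <- function(x) {
  stopifnot(all(c("start", "end", "strand") %in% names(x)))
  validate_interval(x$start, x$end)
  as_tibble(x) |>
    mutate(
      five_prime = ifelse(.data$strand == "+", .data$start, .data$end),
      three_prime = ifelse(.data$strand == "+", .data$end, .data$start)
    )
}

# signed distance from a position to a gene's 5'/3' end, measured in the
# direction of transcription (positive = site upstream of a 5' end /
# downstream of a 3' end)
directed_distance <- function(position, end_coord, strand, side = c("five", "three")) {
  side <- match.arg(side)
  dir <- ifelse(strand == "+", 1, -1)
  if (side == "five") (end_coord - position) * dir else (position - end_coord) * dir
}
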