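#' Construct an annotation table
#'
#' The common tabular model for a located gene or structured-RNA
#' annotation. Every downstream stage (merging, TU complementation, UTR
#' inference) consumes and produces this shape.
#'
#' @param id Character, unique feature keys.
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"` or `"-"`.
#' @param biotype One of the closed vocabulary: `r paste(BIOTYPES, collapse = ", ")`.
#' @param resource Resource identifier the record came from.
#' @param priority Integer rank of the resource (lower = higher priority).
#' @param names,locus_tags Lists of character vectors (synonyms / tags).
#' @param meta List of data frames with columns `key`, `value`, `origin`;
#'   every piece of meta-information carries the resource it came from.
#' @return A tibble with one row per annotation.
#' @export
annotation_tbl <- function(id, start, end, strand, biotype,
                           resource = NA_character_, priority = NA_integer_,
                           names = NULL, locus_tags = NULL, meta = NULL) {
  validate_interval(start, end)
  if (!all(strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  if (!all(biotype %in% BIOTYPES)) {
    abort(paste0(
      "unknown biotype(s): ",
      paste(setdiff(unique(biotype), BIOTYPES), collapse = ", ")
    ))
  }
  if (anyDuplicated(id)) abort("annotation ids must be unique")
  n <- length(id)
  names <- names %||% rep(list(character()), n)
  locus_tags <- locus_tags %||% rep(list(character()), n)
  meta <- meta %||% rep(list(empty_meta()), n)
  tibble(
    id = as.character(id),
    start = as.integer(start), end = as.integer(end),
    strand = as.character(strand), biotype = as.character(biotype),
    resource = rep_len(as.character(resource), n),
    priority = rep_len(as.integer(priority), n),
    names = names, locus_tags = locus_tags, meta = meta
  )
}

empty_meta <- function() {
  tibble(key = character(), value = character(), origin = character())
}

#' Construct a boundary-site table
#'
#' A TSS or TTS with a per-resource resolution half-width: 0 means
#' single-nucleotide resolution (curated sites), 22 the half-width of
#' tiling-array predictions whose true position lies in a 45 bp window.
#'
#' @param site_id Character keys.
#' @param position 1-based bp position.
#' @param strand `"+"` or `"-"`.
#' @param site_type `"TSS"` or `"TTS"`.
#' @param halfwidth Resolution half-width in bp, `>= 0`.
#' @param sigma Optional sigma-factor label (TSS only).
#' @param resource Resource identifier.
#' @param orphan Logical: site had no associated transcribed region in
#'   its source study (triggers the stricter association cut-off).
#' @param dummy Logical: placeholder site inserted at a TU boundary.
#' @return A tibble with one row per site.
#' @export
site_tbl <- function(site_id, position, strand, site_type,
                     halfwidth = 0L, sigma = NA_character_,
                     resource = NA_character_, orphan = FALSE, dummy = FALSE) {
  if (!all(site_type %in% c("TSS", "TTS"))) abort("site_type must be TSS or TTS")
  if (!all(strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  if (any(halfwidth < 0)) abort("halfwidth must be >= 0")
  n <- length(site_id)
  out <- tibble(
    site_id = as.character(site_id),
    position = as.integer(position),
    strand = as.character(strand),
    site_type = as.character(site_type),
    halfwidth = rep_len(as.integer(halfwidth), n),
    sigma = rep_len(as.character(sigma), n),
    resource = rep_len(as.character(resource), n),
    orphan = rep_len(as.logical(orphan), n),
    dummy = rep_len(as.logical(dummy), n)
  )
  if (any(out$dummy & (!is.na(out$sigma) | !is.na(out$resource)))) {
    abort("dummy sites carry no sigma factor and no resource")
  }
  out
}

#' Construct a transcription-unit table
#'
#' A TU is an ordered set of genes that can be transcribed together,
#' without transcript boundaries; one TU may be covered by several
#' transcripts.
#'
#' @param tu_id Character keys.
#' @param genes List of character vectors: member gene ids in
#'   transcription order.
#' @param strand `"+"` or `"-"`.
#' @param start,end Bounding region (optional; recomputed from member
#'   genes by [complement_tus()]).
#' @param source Resource identifier(s).
#' @param excluded Logical: TU is excluded from UTR/transcript/operon
#'   inference (e.g. a TU whose internal region is not actually
#'   transcribed, as for the sporulation sigma-factor gene sigK).
#' @return A tibble with one row per TU.
#' @export
tu_tbl <- function(tu_id, genes, strand, start = NA_integer_, end = NA_integer_,
                   source = NA_character_, excluded = FALSE) {
  n <- length(tu_id)
  if (any(lengths(genes) < 1)) abort("each TU needs at least one gene")
  tibble(
    tu_id = as.character(tu_id),
    genes = genes,
    strand = rep_len(as.character(strand), n),
    start = rep_len(as.integer(start), n),
    end = rep_len(as.integer(end), n),
    source = rep_len(as.character(source), n),
    excluded = rep_len(as.logical(excluded), n)
  )
}

#' Genome reference
#'
#' @param id Sequence identifier.
#' @param length Genome length in bp. Derived from `sequence` when given.
#' @param sequence Optional nucleotide string over A, C, G, T.
#' @return A list with class `genome_ref`.
#' @export
genome_ref <- function(id, length = NULL, sequence = NULL) {
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (str_detect(sequence, "[^ACGT]")) abort("sequence must be over {A,C,G,T}")
    if (is.null(length)) length <- nchar(sequence)
    if (length != nchar(sequence)) abort("length must equal the sequence length")
  }
  if (is.null(length) || length < 1) abort("genome length must be >= 1")
  structure(list(id = id, length = as.integer(length), sequence = sequence),
            class = "genome_ref")
}

# annotations tibble -> GRanges (internal; seqname is a placeholder as all
# coordinates live on one reference sequence)
ann_to_granges <- function(x, seqname = "genome") {
  GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = x$start, end = x$end),
    strand = x$strand
  )
}
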