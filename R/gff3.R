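#' Read a GFF3 file into an annotation table
#'
#' Thin bridge from GFF3 (1-based, inclusive) to the package's tabular
#' annotation model, built on rtracklayer. Feature types not in the
#' biotype vocabulary are mapped through `type_map`; anything still
#' unknown becomes `putative_ncRNA` (or `CDS` for `gene`/`mRNA`-like
#' types). All GFF3 attributes are preserved as meta entries whose origin
#' is the file name.
#'
#' @param path Path to a GFF3 file.
#' @param type_map Named character vector mapping GFF3 `type` values to
#'   biotypes; merged over the built-in defaults.
#' @param resource Resource label stamped on the records (default: file
#'   base name).
#' @param priority Integer priority rank stamped on the records.
#' @return An annotation tibble (see [annotation_tbl()]).
#' @export
read_gff3 <- function(path, type_map = NULL, resource = NULL, priority = NA_integer_) {
  resource <- resource %||% basename(path)
  check_gff3_lines(path)
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0) {
    return(annotation_tbl(character(), integer(), integer(), character(), character()))
  }
  tm <- c(default_type_map(), type_map)
  tm <- tm[!duplicated(names(tm), fromLast = TRUE)]
  md <- as.data.frame(S4Vectors::mcols(gr))
  type <- as.character(md$type)
  biotype <- ifelse(type %in% BIOTYPES, type, unname(tm[type]))
  biotype[is.na(biotype)] <- "putative_ncRNA"
  id <- if ("ID" %in% names(md)) as.character(md$ID) else NA_character_
  id[is.na(id)] <- paste0(resource, "_", which(is.na(id)))
  nm <- if ("Name" %in% names(md)) as.character(md$Name) else rep(NA_character_, length(gr))
  lt <- if ("locus_tag" %in% names(md)) as.character(md$locus_tag) else rep(NA_character_, length(gr))
  keep_attr <- setdiff(names(md), c("source", "phase", "score"))
  meta <- lapply(seq_along(gr), function(i) {
    vals <- lapply(keep_attr, function(a) {
      v <- md[[a]][[i]]
      if (length(v) == 0 || all(is.na(v))) NULL else paste(as.character(v), collapse = ",")
    })
    keep <- !vapply(vals, is.null, logical(1))
    tibble(key = keep_attr[keep], value = unlist(vals[keep]) %||% character(),
           origin = resource)
  })
  annotation_tbl(
    id = id,
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
    biotype = biotype, resource = resource, priority = priority,
    names = lapply(seq_along(gr), function(i) {
      unique(stats::na.omit(c(nm[i], lt[i])))
    }),
    locus_tags = lapply(lt, function(x) unique(stats::na.omit(x))),
    meta = meta
  )
}

default_type_map <- function() {
  c(
    gene = "CDS", CDS = "CDS", mRNA = "CDS",
    ncRNA = "other_ncRNA", ncRNA_gene = "other_ncRNA",
    rRNA = "rRNA", tRNA = "tRNA", sRNA = "sRNA",
    antisense_RNA = "asRNA", riboswitch = "riboswitch",
    tmRNA = "other_ncRNA", SRP_RNA = "other_ncRNA", RNase_P_RNA = "other_ncRNA"
  )
}

# pre-validate a GFF3 body so malformed input fails with the line number
check_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 9) {
      abort(sprintf("malformed GFF3 line %d: expected 9 tab-separated fields", i))
    }
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e)) {
      abort(sprintf("malformed GFF3 line %d: non-numeric coordinates", i))
    }
    if (s > e) abort(sprintf("invalid GFF3 line %d: start > end", i))
  }
  invisible(TRUE)
}

#' Write an atlas to GFF3
#'
#' Emits the full annotation hierarchy in GFF3 (1-based inclusive):
#' genes typed by biotype (`CDS` features for coding genes), transcripts
#' as `transcript` features with `Parent` links to an `operon` feature,
#' `five_prime_UTR`/`three_prime_UTR` features, and internal UTRs as type
#' `UTR` with attribute `utr_class=internal`. Rows are ordered
#' deterministically by (start, end, id) so identical atlases produce
#' byte-identical files.
#'
#' @param atlas An atlas as returned by [run_pipeline()], or any list
#'   with some of `genes`, `utrs`, `transcripts`, `operons` tibbles.
#' @param path Output file path.
#' @param seqname Sequence name for column 1.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(atlas, path, seqname = "genome") {
  rows <- list()
  if (!is.null(atlas$operons) && nrow(atlas$operons) > 0) {
    o <- atlas$operons
    rows$operon <- tibble(
      start = o$start, end = o$end, strand = o$strand, type = "operon",
      ID = o$operon_id, Parent = NA_character_,
      extra = paste0("operon_class=", o$operon_class)
    )
  }
  tx_parent_of_gene <- NULL
  if (!is.null(atlas$transcripts) && nrow(atlas$transcripts) > 0) {
    tx <- atlas$transcripts
    parent <- rep(NA_character_, nrow(tx))
    if (!is.null(atlas$operons) && nrow(atlas$operons) > 0) {
      op_of_tx <- atlas$operons |>
        select("operon_id", "transcripts") |>
        unnest("transcripts")
      parent <- op_of_tx$operon_id[match(tx$transcript_id, op_of_tx$transcripts)]
    }
    rows$transcript <- tibble(
      start = tx$start, end = tx$end, strand = tx$strand, type = "transcript",
      ID = tx$transcript_id, Parent = parent, extra = NA_character_
    )
    tx_parent_of_gene <- tx |>
      select("transcript_id", "gene_set") |>
      unnest("gene_set") |>
      group_by(.data$gene_set) |>
      summarise(Parent = paste(sort(.data$transcript_id), collapse = ","),
                .groups = "drop")
  }
  if (!is.null(atlas$genes) && nrow(atlas$genes) > 0) {
    g <- atlas$genes
    parent <- rep(NA_character_, nrow(g))
    if (!is.null(tx_parent_of_gene)) {
      parent <- tx_parent_of_gene$Parent[match(g$id, tx_parent_of_gene$gene_set)]
    }
    rows$gene <- tibble(
      start = g$start, end = g$end, strand = g$strand, type = g$biotype,
      ID = g$id, Parent = parent,
      extra = ifelse(is.na(g$resource), NA_character_, paste0("resource=", g$resource))
    )
  }
  if (!is.null(atlas$utrs) && nrow(atlas$utrs) > 0) {
    u <- atlas$utrs
    gff_type <- c(five_prime = "five_prime_UTR", three_prime = "three_prime_UTR",
                  internal = "UTR")[u$utr_class]
    extra <- ifelse(u$utr_class == "internal", "utr_class=internal", NA_character_)
    extra <- paste0(
      ifelse(is.na(extra), "", paste0(extra, ";")),
      "anchor_gene=", u$anchor_gene
    )
    rows$utr <- tibble(
      start = u$start, end = u$end, strand = u$strand, type = unname(gff_type),
      ID = u$utr_id, Parent = NA_character_, extra = extra
    )
  }
  body <- bind_rows(rows)
  # referential integrity: operon membership must resolve to exported
  # transcripts, and transcript gene sets to exported genes
  dangling <- character()
  if (!is.null(atlas$operons) && !is.null(atlas$transcripts)) {
    dangling <- c(dangling, setdiff(unlist(atlas$operons$transcripts),
                                    atlas$transcripts$transcript_id))
  }
  if (!is.null(atlas$transcripts) && !is.null(atlas$genes)) {
    dangling <- c(dangling, setdiff(unlist(atlas$transcripts$gene_set),
                                    atlas$genes$id))
  }
  if (length(dangling) > 0) {
    abort(paste0("dangling Parent reference(s): ", paste(dangling, collapse = ", ")))
  }
  lines <- "##gff-version 3"
  if (nrow(body) > 0) {
    body <- arrange(body, .data$start, .data$end, .data$ID)
    attrs <- paste0(
      "ID=", body$ID,
      ifelse(is.na(body$Parent), "", paste0(";Parent=", body$Parent)),
      ifelse(is.na(body$extra), "", paste0(";", body$extra))
    )
    lines <- c(lines, paste(seqname, "operonatlas", body$type, body$start,
                            body$end, ".", body$strand, ".", attrs, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
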