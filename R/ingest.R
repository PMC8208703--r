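#' Describe an annotation resource
#'
#' Per-resource integration settings: separate priority ranks for the
#' coding and non-coding parts (lower = higher priority; curated
#' reference annotations outrank computational predictions), and the
#' positional resolution half-width of its boundary sites (0 bp for
#' curated single-nucleotide sites, 22 bp for tiling-array predictions).
#'
#' @param name Resource identifier.
#' @param priority_coding,priority_noncoding Integer ranks `>= 1`.
#' @param resolution_halfwidth Site resolution half-width in bp.
#' @param curated Flag: manually curated resource.
#' @return A list with class `resource_config`.
#' @export
resource_config <- function(name, priority_coding = 1L, priority_noncoding = 1L,
                            resolution_halfwidth = 0L, curated = FALSE) {
  if (priority_coding < 1 || priority_noncoding < 1) abort("priority ranks must be >= 1")
  if (resolution_halfwidth < 0) abort("resolution_halfwidth must be >= 0")
  structure(
    list(name = name,
         priority_coding = as.integer(priority_coding),
         priority_noncoding = as.integer(priority_noncoding),
         resolution_halfwidth = as.integer(resolution_halfwidth),
         curated = isTRUE(curated)),
    class = "resource_config"
  )
}

#' Locate a nucleotide sequence uniquely in a genome
#'
#' Exact-match coordinate restoration for records that come with a
#' binding-site or gene sequence but no coordinates. Both strands are
#' searched with no mismatches allowed; only a single occurrence across
#' both strands is accepted, so that ambiguous placements are never
#' invented. A self-reverse-complementary (palindromic) sequence matching
#' one locus on both strands counts as one unique plus-strand match.
#'
#' @param genome A [genome_ref()] with its sequence present.
#' @param query Character vector of nucleotide strings over A, C, G, T.
#' @return A tibble with one row per query: `query`, `status` (`"unique"`,
#'   `"ambiguous"`, `"no_match"`), and `start`, `end`, `strand` (NA unless
#'   unique).
#' @export
locate_unique_sequence <- function(genome, query) {
  if (is.null(genome$sequence)) abort("genome sequence is required")
  query <- toupper(query)
  if (any(nchar(query) == 0) || any(str_detect(query, "[^ACGT]"))) {
    abort("query must be non-empty over {A,C,G,T}")
  }
  subject <- Biostrings::DNAString(genome$sequence)
  one <- function(q) {
    pat <- Biostrings::DNAString(q)
    fwd <- Biostrings::matchPattern(pat, subject)
    rcp <- Biostrings::reverseComplement(pat)
    hits <- tibble(
      start = BiocGenerics::start(fwd), end = BiocGenerics::end(fwd), strand = "+"
    )
    if (as.character(rcp) != q) {
      rev <- Biostrings::matchPattern(rcp, subject)
      hits <- bind_rows(hits, tibble(
        start = BiocGenerics::start(rev), end = BiocGenerics::end(rev), strand = "-"
      ))
    }
    if (nrow(hits) == 0) {
      tibble(status = "no_match", start = NA_integer_, end = NA_integer_,
             strand = NA_character_)
    } else if (nrow(hits) > 1) {
      tibble(status = "ambiguous", start = NA_integer_, end = NA_integer_,
             strand = NA_character_)
    } else {
      tibble(status = "unique", start = hits$start, end = hits$end,
             strand = hits$strand)
    }
  }
  bind_cols(tibble(query = query), bind_rows(lapply(query, one)))
}

#' Derive TSS positions from sigma-factor binding sites
#'
#' Curated sigma-factor binding sites often state the transcription start
#' as an offset relative to the site rather than as a coordinate. The TSS
#' is placed at the site's downstream (3') boundary shifted by the offset
#' in the direction of transcription, yielding a nucleotide-resolution
#' site (half-width 0) carrying the sigma factor.
#'
#' @param sites A data frame with columns `start`, `end`, `strand`,
#'   `sigma_factor`, `offset_to_tss` (signed bp; NA rows are skipped with
#'   a warning) and optionally `resource`.
#' @return A boundary-site tibble (see [site_tbl()]) of TSSs.
#' @export
tss_from_sigma_site <- function(sites) {
  sites <- as_tibble(sites)
  missing_off <- is.na(sites$offset_to_tss)
  if (any(missing_off)) {
    warn(sprintf("%d sigma site(s) without TSS offset skipped", sum(missing_off)))
    sites <- sites[!missing_off, ]
  }
  if (nrow(sites) == 0) return(site_tbl(character(), integer(), character(), character()))
  downstream <- ifelse(sites$strand == "+", sites$end, sites$start)
  pos <- downstream + ifelse(sites$strand == "+", 1, -1) * sites$offset_to_tss
  site_tbl(
    site_id = paste0("sigma_tss_", seq_len(nrow(sites))),
    position = pos, strand = sites$strand, site_type = "TSS",
    halfwidth = 0L, sigma = sites$sigma_factor,
    resource = if ("resource" %in% names(sites)) sites$resource else NA_character_
  )
}

#' Match external records to merged genes by name
#'
#' Resolves name-only records (e.g. community-database TU gene lists)
#' against the merged gene set by case-insensitive comparison of names,
#' synonyms and locus tags, keeping only unambiguous matches.
#'
#' @param query_names A list of character vectors (one name-set per query).
#' @param gene_index An annotation tibble with `names` and `locus_tags`
#'   populated.
#' @return A tibble with one row per query: `query_index`, `status`
#'   (`"matched"`, `"ambiguous"`, `"unmatched"`) and `gene_id` (NA unless
#'   matched).
#' @export
match_by_name <- function(query_names, gene_index) {
  lookup <- tibble(
    gene_id = rep(gene_index$id, times = lengths(gene_index$names) +
                    lengths(gene_index$locus_tags)),
    key = str_to_lower(unlist(map2(gene_index$names, gene_index$locus_tags, c)))
  ) |> distinct()
  res <- lapply(seq_along(query_names), function(i) {
    q <- str_to_lower(query_names[[i]])
    hits <- unique(lookup$gene_id[lookup$key %in% q])
    if (length(hits) == 0) {
      tibble(query_index = i, status = "unmatched", gene_id = NA_character_)
    } else if (length(hits) > 1) {
      tibble(query_index = i, status = "ambiguous", gene_id = NA_character_)
    } else {
      tibble(query_index = i, status = "matched", gene_id = hits)
    }
  })
  bind_rows(res)
}

#' Read Infernal cmsearch --tblout hits
#'
#' Parses the whitespace-delimited tabular output of a covariance-model
#' genome scan into the hit table consumed by [rfam_postfilter()]. The
#' gathering score (the family-curated bit-score threshold) is not part
#' of the tblout format and must be supplied per family.
#'
#' @param path Path to a `cmsearch --tblout` file.
#' @param gathering_scores Named numeric vector: gathering score per
#'   family accession/name; families absent from it get `NA`.
#' @return A tibble of hits: `family_id`, `start`, `end`, `strand`,
#'   `bit_score`, `e_value`, `gathering_score`.
#' @export
read_cmsearch_tblout <- function(path, gathering_scores = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(family_id = character(), start = integer(), end = integer(),
                  strand = character(), bit_score = numeric(),
                  e_value = numeric(), gathering_score = numeric()))
  }
  f <- str_split(trimws(lines), "\\s+")
  bad <- which(lengths(f) < 18)
  if (length(bad) > 0) abort(sprintf("malformed tblout record %d", bad[[1]]))
  fam <- map_chr(f, 3)
  fam[fam == "-"] <- map_chr(f, 2)[fam == "-"]
  from <- as.integer(map_chr(f, 8)); to <- as.integer(map_chr(f, 9))
  tibble(
    family_id = fam,
    start = pmin(from, to), end = pmax(from, to),
    strand = map_chr(f, 10),
    bit_score = as.numeric(map_chr(f, 15)),
    e_value = as.numeric(map_chr(f, 16)),
    gathering_score = if (is.null(gathering_scores)) NA_real_ else
      unname(gathering_scores[fam])
  )
}

#' Post-filter covariance-model scan hits
#'
#' Confidence filtering and de-redundancy of genome-wide RNA-family scan
#' hits. Three confidence levels are supported: `conservative` (E-value
#' below 1e-6 and bit score at least the family gathering score),
#' `medium` (E-value below 1e-6) and `relaxed` (E-value below 1e-3).
#' Within a level, same-strand hits overlapping by at least
#' `min_overlap` bp are merged by single linkage and each cluster is
#' represented by its best hit: minimal E-value, ties broken by maximal
#' bit score.
#'
#' @param hits A tibble with `start`, `end`, `strand`, `bit_score`,
#'   `e_value`, `gathering_score` (see [read_cmsearch_tblout()]).
#' @param level Confidence level.
#' @param min_overlap Minimum bp overlap for clustering (default 40).
#' @return The filtered subset of `hits`, ordered by (start, end).
#' @export
rfam_postfilter <- function(hits, level = c("conservative", "medium", "relaxed"),
                            min_overlap = 40L) {
  level <- match.arg(level)
  hits <- as_tibble(hits)
  if (any(hits$e_value <= 0)) abort("e_value must be > 0")
  keep <- switch(level,
    conservative = hits$e_value < 1e-6 & hits$bit_score >= hits$gathering_score,
    medium = hits$e_value < 1e-6,
    relaxed = hits$e_value < 1e-3
  )
  hits <- hits[which(keep), ]
  if (nrow(hits) == 0) return(hits)
  hits$.cluster <- overlap_components(hits, min_overlap = min_overlap)
  hits |>
    group_by(.data$.cluster) |>
    arrange(.data$e_value, desc(.data$bit_score), .data$start, .data$end,
            .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select(-".cluster") |>
    arrange(.data$start, .data$end)
}

# single-linkage components of same-strand intervals overlapping by at
# least min_overlap bp
overlap_components <- function(x, min_overlap = 1L) {
  gr <- ann_to_granges(x)
  ov <- GenomicRanges::findOverlaps(gr, minoverlap = min_overlap,
                                    drop.self = TRUE, drop.redundant = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = S4Vectors::queryHits(ov), to = S4Vectors::subjectHits(ov)),
    directed = FALSE, vertices = data.frame(name = seq_len(nrow(x)))
  )
  comp <- igraph::components(g)$membership
  unname(comp[as.character(seq_len(nrow(x)))])
}

#' Load a resource table in the common TSV schema
#'
#' Generic tabular ingest replacing per-database parsers. The schema has
#' columns `seqid`, `start`, `end`, `strand`, `type`, `id` and optionally
#' `names`, `locus_tags` (comma-separated), `genes` (comma-separated
#' ordered gene ids, TU rows only), `sigma`, `orphan` (TRUE/FALSE, site
#' rows). Rows are typed by `type`: a biotype makes an annotation, `TSS`/
#' `TTS` a boundary site, `TU` a transcription unit. Resource name,
#' priorities and site resolution half-width are stamped from the
#' [resource_config()].
#'
#' @param path Path to a tab-separated file.
#' @param config A [resource_config()].
#' @return A list with tibbles `annotations`, `sites`, `tus`.
#' @export
load_resource_table <- function(path, config) {
  stopifnot(inherits(config, "resource_config"))
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("seqid", "start", "end", "strand", "type", "id")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort(paste0("resource table lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tab$start <- as.integer(tab$start); tab$end <- as.integer(tab$end)
  bad_type <- setdiff(unique(tab$type), c(BIOTYPES, "TSS", "TTS", "TU"))
  if (length(bad_type) > 0) {
    abort(paste0("unknown row type(s): ", paste(bad_type, collapse = ", ")))
  }
  split_csv <- function(x) {
    lapply(x, function(v) if (is.na(v) || v == "") character() else
      strsplit(v, ",", fixed = TRUE)[[1]])
  }
  ann_rows <- tab[tab$type %in% BIOTYPES, ]
  annotations <- annotation_tbl(
    id = ann_rows$id, start = ann_rows$start, end = ann_rows$end,
    strand = ann_rows$strand, biotype = ann_rows$type,
    resource = config$name,
    priority = ifelse(ann_rows$type == "CDS", config$priority_coding,
                      config$priority_noncoding),
    names = split_csv(ann_rows$names %||% rep(NA_character_, nrow(ann_rows))),
    locus_tags = split_csv(ann_rows$locus_tags %||% rep(NA_character_, nrow(ann_rows)))
  )
  site_rows <- tab[tab$type %in% c("TSS", "TTS"), ]
  sites <- site_tbl(
    site_id = site_rows$id, position = site_rows$start,
    strand = site_rows$strand, site_type = site_rows$type,
    halfwidth = config$resolution_halfwidth,
    sigma = site_rows$sigma %||% rep(NA_character_, nrow(site_rows)),
    resource = config$name,
    orphan = as.logical(site_rows$orphan %||% rep("FALSE", nrow(site_rows))) %in% TRUE
  )
  tu_rows <- tab[tab$type == "TU", ]
  if (nrow(tu_rows) > 0 && !"genes" %in% names(tu_rows)) {
    abort("TU rows require a 'genes' column")
  }
  tus <- tu_tbl(
    tu_id = tu_rows$id, genes = split_csv(tu_rows$genes %||% character()),
    strand = tu_rows$strand, start = tu_rows$start, end = tu_rows$end,
    source = config$name
  )
  list(annotations = annotations, sites = sites, tus = tus)
}

#' Write model objects back to the resource TSV schema
#'
#' Inverse of [load_resource_table()]; used for exporting fixtures and
#' for round-trip checks.
#'
#' @param objects A list with any of `annotations`, `sites`, `tus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_resource_table <- function(objects, path) {
  join_csv <- function(x) map_chr(x, function(v) if (length(v) == 0) NA_character_ else
    paste(v, collapse = ","))
  # schema header must survive even when every table is empty
  rows <- list(template = tibble(
    seqid = character(), start = integer(), end = integer(),
    strand = character(), type = character(), id = character(),
    names = character(), locus_tags = character(), genes = character(),
    sigma = character(), orphan = logical()
  ))
  a <- objects$annotations
  if (!is.null(a) && nrow(a) > 0) {
    rows$a <- tibble(seqid = "genome", start = a$start, end = a$end,
                     strand = a$strand, type = a$biotype, id = a$id,
                     names = join_csv(a$names), locus_tags = join_csv(a$locus_tags),
                     genes = NA_character_, sigma = NA_character_, orphan = NA)
  }
  s <- objects$sites
  if (!is.null(s) && nrow(s) > 0) {
    rows$s <- tibble(seqid = "genome", start = s$position, end = s$position,
                     strand = s$strand, type = s$site_type, id = s$site_id,
                     names = NA_character_, locus_tags = NA_character_,
                     genes = NA_character_, sigma = s$sigma, orphan = s$orphan)
  }
  u <- objects$tus
  if (!is.null(u) && nrow(u) > 0) {
    rows$u <- tibble(seqid = "genome", start = u$start, end = u$end,
                     strand = u$strand, type = "TU", id = u$tu_id,
                     names = NA_character_, locus_tags = NA_character_,
                     genes = join_csv(u$genes), sigma = NA_character_, orphan = NA)
  }
  readr::write_tsv(bind_rows(rows), path, progress = FALSE)
  invisible(path)
}
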