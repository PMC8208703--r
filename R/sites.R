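#' Group boundary sites that overlap within their resolution limits
#'
#' Each site expands to the window
#' `[position - halfwidth, position + halfwidth]`; a curated
#' nucleotide-resolution site has a 1 bp window, a tiling-array
#' prediction a 45 bp window. Groups are the single-linkage components
#' of window overlap among sites of one strand. TSSs and TTSs are
#' processed in entirely separate passes, so the input must hold one
#' site type only.
#'
#' @param sites A boundary-site tibble of a single `site_type`.
#' @return `sites` with a `group` integer column, ordered by
#'   (strand, position, site_id).
#' @export
group_sites <- function(sites) {
  s <- as_tibble(sites)
  if (length(unique(s$site_type)) > 1) {
    abort("group_sites expects sites of a single site_type (TSS or TTS)")
  }
  if (nrow(s) == 0) return(mutate(s, group = integer()))
  s <- s |>
    mutate(wstart = .data$position - .data$halfwidth,
           wend = .data$position + .data$halfwidth) |>
    # the sweep is only exact when windows are ordered by their left edge
    arrange(.data$strand, .data$wstart, .data$wend, .data$site_id) |>
    group_by(.data$strand) |>
    mutate(
      # a window starts a new group iff it misses every window seen so far
      .new = as.numeric(.data$wstart) >
        lag(cummax(as.numeric(.data$wend)), default = -Inf)
    ) |>
    ungroup() |>
    mutate(group = cumsum(.data$.new)) |>
    select(-"wstart", -"wend", -".new")
  arrange(s, .data$strand, .data$position, .data$site_id)
}

#' Unify grouped boundary sites into a single promoter/terminator map
#'
#' Within each group only the members whose resolution half-width equals
#' the group minimum are kept, so a curated nucleotide-resolution site
#' displaces the array predictions that fall inside its window, while
#' groups of equally precise but distinct positions keep all of them.
#' Members kept at identical positions collapse to one site. The sigma
#' factor of a kept TSS is taken from the group member with the lowest
#' half-width that has one; sigma labels of discarded members are
#' retained in the `merged_sigma` column, and discarded member ids in
#' `merged_from`.
#'
#' @param sites A boundary-site tibble of one site type (grouping is done
#'   internally via [group_sites()] if no `group` column is present).
#' @return The unified site tibble, one row per kept position, with
#'   provenance columns `merged_from` and `merged_sigma`.
#' @export
unify_sites <- function(sites) {
  s <- as_tibble(sites)
  if (!"group" %in% names(s)) s <- group_sites(s)
  if (nrow(s) == 0) {
    return(s |> select(-any_of("group")) |>
             mutate(merged_from = list(), merged_sigma = list()))
  }
  out <- s |>
    group_by(.data$group) |>
    group_map(~ unify_group(.x)) |>
    bind_rows()
  arrange(out, .data$strand, .data$position, .data$site_id)
}

unify_group <- function(g) {
  if (nrow(g) == 0) abort("empty site group")
  minhw <- min(g$halfwidth)
  kept <- g[g$halfwidth == minhw, ]
  dropped <- g[g$halfwidth > minhw, ]
  # sigma donor: lowest-halfwidth member carrying a sigma label
  donors <- g[!is.na(g$sigma), ]
  donor_sigma <- if (nrow(donors) > 0) {
    donors$sigma[order(donors$halfwidth, donors$position)][[1]]
  } else NA_character_
  kept |>
    group_by(.data$position) |>
    summarise(
      site_id = sort(.data$site_id)[[1]],
      strand = .data$strand[[1]], site_type = .data$site_type[[1]],
      halfwidth = minhw,
      sigma = {
        sig <- unique(stats::na.omit(.data$sigma))
        if (length(sig) > 0) paste(sort(sig), collapse = ",") else donor_sigma
      },
      resource = paste(sort(unique(.data$resource)), collapse = "+"),
      orphan = all(.data$orphan),
      dummy = FALSE,
      collapsed = list(setdiff(.data$site_id, sort(.data$site_id)[[1]])),
      .groups = "drop"
    ) |>
    mutate(
      merged_from = map(.data$collapsed, ~ sort(c(.x, dropped$site_id))),
      merged_sigma = list(sort(unique(stats::na.omit(dropped$sigma))))
    ) |>
    select("site_id", "position", "strand", "site_type", "halfwidth",
           "sigma", "resource", "orphan", "dummy", "merged_from", "merged_sigma")
}
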