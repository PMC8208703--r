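# a reusable 3-gene plus-strand TU with configurable sites
chain_fixture <- function(tss_at = 1L, tts_at = 3L, extra_tss = NULL,
                          extra_tts = NULL) {
  genes <- ann(c("gA", "gB", "gC"), c(200, 500, 900), c(400, 800, 1200))
  tus <- complement_tus(tu_tbl("tu1", list(c("gA", "gB", "gC")), "+"),
                        genes, genome_length = 100000L)
  pos5 <- c(gA = 200L, gB = 500L, gC = 900L)
  pos3 <- c(gA = 400L, gB = 800L, gC = 1200L)
  site_rows <- list()
  add_tss <- function(lab, k) {
    site_tbl(lab, pos5[[k]] - 50L, "+", "TSS")
  }
  add_tts <- function(lab, k) {
    site_tbl(lab, pos3[[k]] + 50L, "+", "TTS")
  }
  site_rows$t1 <- add_tss("tss1", tss_at)
  site_rows$t2 <- add_tts("tts1", tts_at)
  if (!is.null(extra_tss)) site_rows$t3 <- add_tss("tss2", extra_tss)
  if (!is.null(extra_tts)) site_rows$t4 <- add_tts("tts2", extra_tts)
  sites <- dplyr::bind_rows(site_rows)
  assoc <- associate_sites_to_genes(sites, genes, tus = tus)
  utrs <- dplyr::bind_rows(
    infer_flanking_utrs(assoc, genes),
    infer_internal_utrs(tus, genes)
  )
  list(genes = genes, tus = tus, assoc = assoc, utrs = utrs,
       graph = build_transcript_graph(tus, assoc, utrs, genes))
}

test_that("the transcript graph chains sites, UTRs and genes in order", {
  fx <- chain_fixture()
  # 3 genes + 2 internal UTRs + 1 TSS + 1 5'UTR + 1 TTS + 1 3'UTR = 9 nodes
  expect_equal(nrow(fx$graph$nodes), 9)
  tx <- enumerate_transcripts(fx$graph, fx$tus, fx$genes, fx$utrs)
  expect_equal(nrow(tx), 1)
  expect_equal(tx$gene_set[[1]], c("gA", "gB", "gC"))
  # 5' UTR, 3 genes, 2 internal UTRs, 3' UTR along the single path
  expect_equal(length(tx$elements[[1]]), 7)
})

test_that("TUs without sites get dummy boundaries at the terminal gene ends", {
  genes <- ann(c("gA", "gB"), c(200, 500), c(400, 800))
  tus <- complement_tus(tu_tbl("tu1", list(c("gA", "gB")), "+"), genes, 100000L)
  empty_assoc <- associate_sites_to_genes(
    site_tbl(character(), integer(), character(), character()), genes)
  gr <- build_transcript_graph(tus, empty_assoc, infer_internal_utrs(tus, genes),
                               genes)
  kinds <- gr$nodes$kind
  expect_equal(sum(kinds == "TSS"), 1)
  expect_equal(sum(kinds == "TTS"), 1)
  expect_equal(gr$nodes$position[kinds == "TSS"], 200L)
  expect_equal(gr$nodes$position[kinds == "TTS"], 800L)
  tx <- enumerate_transcripts(gr, tus, genes,
                              infer_internal_utrs(tus, genes))
  expect_equal(nrow(tx), 1)
  # dummy-bounded transcripts carry no UTR on that side
  expect_false(any(grepl("^utr5|^utr3", tx$elements[[1]])))
})

test_that("transcript enumeration equals the DFS path oracle", {
  fx <- chain_fixture(extra_tss = 2L, extra_tts = 2L)
  tx <- enumerate_transcripts(fx$graph, fx$tus, fx$genes, fx$utrs)
  # entries at gA and gB, exits at gB and gC: 4 transcripts
  expect_equal(nrow(tx), 4)
  keys <- sort(purrr::map_chr(tx$gene_set, paste, collapse = ","))
  expect_equal(keys, sort(c("gA,gB,gC", "gA,gB", "gB,gC", "gB")))
  # independent recursive DFS on the same edge list
  edges <- fx$graph$edges
  sinks <- fx$graph$nodes$node[fx$graph$nodes$kind == "TTS"]
  sources <- fx$graph$nodes$node[fx$graph$nodes$kind == "TSS"]
  oracle <- unlist(lapply(sources, dfs_paths, edges = edges, to_set = sinks),
                   recursive = FALSE)
  expect_equal(nrow(tx), length(oracle))
  oracle_keys <- sort(vapply(oracle, function(p) paste(p, collapse = ">"),
                             character(1)))
  got_keys <- sort(vapply(seq_len(nrow(tx)), function(i) {
    paste(c(tx$tss[i], tx$elements[[i]], tx$tts[i]), collapse = ">")
  }, character(1)))
  expect_equal(got_keys, oracle_keys)
})

test_that("a TSS downstream of the only TTS yields no transcript", {
  fx <- chain_fixture(tss_at = 3L, tts_at = 1L)
  tx <- enumerate_transcripts(fx$graph, fx$tus, fx$genes, fx$utrs)
  expect_equal(nrow(tx), 0)
})

test_that("the path cap guards combinatorial explosion", {
  fx <- chain_fixture(extra_tss = 2L, extra_tts = 2L)
  expect_error(
    enumerate_transcripts(fx$graph, fx$tus, fx$genes, fx$utrs, path_cap = 2L),
    "path cap.*tu1"
  )
})

test_that("novel TUs arise from internal sites unless an adjacent TU explains them", {
  fx <- chain_fixture(extra_tss = 2L)
  tx <- enumerate_transcripts(fx$graph, fx$tus, fx$genes, fx$utrs)
  novel <- derive_tus_from_transcripts(tx, fx$tus)
  expect_equal(nrow(novel), 1)
  expect_equal(novel$genes[[1]], c("gB", "gC"))
  # an adjacently located known TU starting at gB suppresses the novel TU
  genes_d <- dplyr::bind_rows(fx$genes, ann("gD", 1300, 1500))
  tus2 <- complement_tus(
    tu_tbl(c("tu1", "tu2"), list(c("gA", "gB", "gC"), c("gB", "gC", "gD")), "+"),
    genes_d, 100000L)
  novel2 <- derive_tus_from_transcripts(tx, tus2)
  expect_equal(nrow(novel2), 0)
  # a transcript identical to a known TU is never novel
  fx0 <- chain_fixture()
  tx0 <- enumerate_transcripts(fx0$graph, fx0$tus, fx0$genes, fx0$utrs)
  expect_equal(nrow(derive_tus_from_transcripts(tx0, fx0$tus)), 0)
})

test_that("operon components equal the union-find oracle", {
  set.seed(47)
  n_genes <- 40
  gs <- seq(100, by = 500, length.out = n_genes)
  genes <- ann(paste0("g", 1:n_genes), gs, gs + 300)
  tx <- dplyr::bind_rows(lapply(1:100, function(i) {
    a <- sample(n_genes - 2, 1); b <- a + sample(0:2, 1)
    ids <- paste0("g", a:b)
    tibble::tibble(
      transcript_id = paste0("tx", i), tss = paste0("s", i), tts = paste0("e", i),
      tss_pos = as.integer(gs[a] - i %% 7), tts_pos = as.integer(gs[b] + 300 + i %% 5),
      elements = list(ids), gene_set = list(ids), tu_ref = "tu",
      strand = "+", start = as.integer(gs[a] - 10), end = as.integer(gs[b] + 320)
    )
  }))
  ops <- build_operons(tx, genes)
  # oracle: union-find over transcripts joined through shared genes
  pairs_a <- character(); pairs_b <- character()
  for (i in 1:99) for (j in (i + 1):100) {
    if (length(intersect(tx$gene_set[[i]], tx$gene_set[[j]])) > 0) {
      pairs_a <- c(pairs_a, tx$transcript_id[i])
      pairs_b <- c(pairs_b, tx$transcript_id[j])
    }
  }
  comp <- union_find(tx$transcript_id, pairs_a, pairs_b)
  expect_equal(nrow(ops), length(unique(comp)))
  # same partition of transcripts
  oracle_key <- sort(vapply(split(tx$transcript_id, comp),
                            function(x) paste(sort(x), collapse = ","), character(1)))
  got_key <- sort(vapply(ops$transcripts,
                         function(x) paste(sort(x), collapse = ","), character(1)))
  expect_equal(unname(got_key), unname(oracle_key))
  # class partition covers all operons
  expect_equal(sum(ops$operon_class %in% c("simple", "traditional", "complex")),
               nrow(ops))
})

test_that("operon classes follow the isoform and gene-count definitions", {
  expect_equal(classify_operon(1, 1), "simple")
  expect_equal(classify_operon(3, 1), "traditional")
  expect_equal(classify_operon(1, 2), "complex")  # monocistronic with isoforms
  expect_equal(classify_operon(4, 3), "complex")
  expect_error(classify_operon(1, 0), "no transcripts")
})

test_that("guide off-target expansion follows polycistronic operons", {
  genes <- ann(paste0("g", 1:5), c(100, 500, 900, 2000, 3000),
               c(400, 800, 1200, 2300, 3300))
  ops <- tibble::tibble(
    operon_id = c("op1", "op2"),
    transcripts = list("tx1", "tx2"),
    genes = list(c("g1", "g2", "g3", "g4"), "g5"),
    strand = "+", start = c(100L, 3000L), end = c(2300L, 3300L),
    n_genes = c(4L, 1L), n_transcripts = c(1L, 1L), n_isoforms = c(1L, 1L),
    operon_class = c("traditional", "simple"), has_full_transcript = TRUE
  )
  targets <- tibble::tibble(guide_id = c("q1", "q2", "q3"),
                            cut_position = c(600L, 3100L, 2700L))
  out <- expand_offtargets_by_operon(targets, ops, genes)
  expect_equal(out$direct_gene, c("g2", "g5", NA))
  expect_equal(out$operon_expanded_genes[[1]], c("g1", "g2", "g3", "g4"))
  expect_equal(out$operon_expanded_genes[[2]], "g5")
  expect_equal(length(out$operon_expanded_genes[[3]]), 0)
})
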