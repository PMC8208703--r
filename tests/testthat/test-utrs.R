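test_that("TU complementation applies the containment and 70% overlap rules", {
  genes <- ann(c("in", "big", "edge", "listed"),
               c(120, 90, 450, 200), c(180, 600, 550, 300))
  tus <- tu_tbl("tu1", list("listed"), "+", start = 100L, end = 500L)
  out <- complement_tus(tus, genes, genome_length = 100000L)
  # contained gene and containing gene are added; 51/101 = 50% overlap is not
  expect_setequal(out$genes[[1]], c("in", "big", "listed"))
  genes2 <- genes; genes2$start[3] <- 430L; genes2$end[3] <- 530L  # 71/101
  out2 <- complement_tus(tus, genes2, genome_length = 100000L)
  expect_true("edge" %in% out2$genes[[1]])
  # gene order follows transcription direction
  expect_equal(out2$genes[[1]], c("big", "in", "listed", "edge"))
})

test_that("giant TUs are dropped and duplicates deduplicated", {
  genes <- ann(c("a", "b"), c(100, 50000), c(200, 50100))
  tus <- tu_tbl(c("t1", "t2", "t3"),
                list(c("a", "b"), "a", "a"), "+",
                source = c("r1", "r1", "r2"))
  out <- complement_tus(tus, genes, genome_length = 100000L)
  # t1 spans half the genome -> dropped; t2/t3 have identical gene sets
  expect_equal(nrow(out), 1)
  expect_equal(out$source, "r1+r2")
  # unknown gene references are an integrity error
  expect_error(complement_tus(tu_tbl("x", list("nope"), "+"), genes, 1000L),
               "unknown gene")
  # excluded TUs can be named by TU id or by member gene
  out2 <- complement_tus(tus[2, ], genes, genome_length = 100000L,
                         excluded_tus = "a")
  expect_true(out2$excluded)
})

test_that("site association picks the closest gene end within the cut-offs", {
  genes <- ann(c("g1", "g2"), c(150, 3000), c(900, 3500))
  sites <- site_tbl(c("t1", "t2", "t3"), c(100L, 100L, 890L), "+",
                    c("TSS", "TSS", "TTS"), orphan = c(FALSE, TRUE, FALSE))
  # non-orphan TSS at 100 -> gene g1 (gap 49); orphan with 5' end at 350
  genes_far <- ann("g1", 350, 900)
  a1 <- associate_sites_to_genes(sites[1, ], genes)
  expect_equal(a1$gene_id, "g1")
  expect_equal(a1$gap, 49)
  expect_equal(a1$status, "associated")
  a2 <- associate_sites_to_genes(sites[2, ], genes_far)
  expect_equal(a2$status, "unassociated")  # 250 > 200 orphan cut-off
  a2b <- associate_sites_to_genes(sites[1, ], genes_far)
  expect_equal(a2b$status, "associated")   # 250 <= 2000 for non-orphans
  # TTS slightly inside the gene is tolerated up to 25 bp
  a3 <- associate_sites_to_genes(sites[3, ], genes)
  expect_equal(a3$gene_id, "g1")
  expect_lt(a3$dist, 0)
})

test_that("site association equals the brute-force nearest-neighbour oracle", {
  set.seed(41)
  n_g <- 60; n_s <- 200
  gs <- sort(sample(seq(500, 80000, by = 400), n_g))
  genes <- ann(paste0("g", 1:n_g), gs, gs + sample(200:350, n_g, replace = TRUE),
               strand = sample(c("+", "-"), n_g, replace = TRUE))
  sites <- site_tbl(paste0("s", 1:n_s), sample(82000L, n_s),
                    sample(c("+", "-"), n_s, replace = TRUE),
                    sample(c("TSS", "TTS"), n_s, replace = TRUE),
                    orphan = sample(c(TRUE, FALSE), n_s, replace = TRUE, prob = c(.2, .8)))
  got <- associate_sites_to_genes(sites, genes)
  ends <- transcription_ends(genes)
  for (i in seq_len(nrow(got))) {
    row <- got[i, ]
    cand <- ends[ends$strand == row$strand, ]
    ec <- if (row$site_type == "TSS") cand$five_prime else cand$three_prime
    d <- if (row$site_type == "TSS") {
      (ec - row$position) * ifelse(row$strand == "+", 1, -1)
    } else {
      (row$position - ec) * ifelse(row$strand == "+", 1, -1)
    }
    lim <- if (sites$orphan[sites$site_id == row$site_id]) 200 else 2000
    ok <- d >= -25 & d <= lim
    if (!any(ok)) {
      expect_equal(row$status, "unassociated")
    } else {
      expect_equal(row$status, "associated")
      expect_equal(abs(row$dist), min(abs(d[ok])))
      expect_true(row$gene_id %in% cand$id[ok][abs(d[ok]) == min(abs(d[ok]))])
    }
  }
})

test_that("flanking UTRs require a 15 bp gap and abut the gene end", {
  genes <- ann("g1", 150, 900)
  sites <- site_tbl(c("t1", "t2"), c(100L, 140L), "+", "TSS")
  assoc <- associate_sites_to_genes(sites, genes)
  utr <- infer_flanking_utrs(assoc, genes)
  # TSS at 100: 5' UTR [100,149]; TSS at 140: gap 10 < 15 -> none
  expect_equal(nrow(utr), 1)
  expect_equal(c(utr$start, utr$end), c(100L, 149L))
  expect_equal(utr$utr_class, "five_prime")
  expect_equal(utr$end - utr$start + 1, 50L)
  # minus strand mirror for a TTS
  genes_m <- ann("gm", 150, 900, strand = "-")
  sites_m <- site_tbl("tts1", 100L, "-", "TTS")
  utr_m <- infer_flanking_utrs(associate_sites_to_genes(sites_m, genes_m), genes_m)
  expect_equal(c(utr_m$start, utr_m$end), c(100L, 149L))
  expect_equal(utr_m$utr_class, "three_prime")
})

test_that("5' UTRs over regulatory structures extend to the next coding gene", {
  genes <- ann(c("ribo", "cds"), c(140, 260), c(220, 800),
               biotype = c("riboswitch", "CDS"))
  sites <- site_tbl("t1", 100L, "+", "TSS")
  assoc <- associate_sites_to_genes(sites, genes)
  expect_equal(assoc$gene_id, "ribo")
  utr <- infer_flanking_utrs(assoc, genes)
  expect_equal(c(utr$start, utr$end), c(100L, 259L))  # spans the structure
  expect_true(utr$extended)
  # without a downstream coding gene the UTR truncates at the structure end
  expect_warning(
    utr2 <- infer_flanking_utrs(assoc, genes[1, ]),
    "truncated"
  )
  expect_equal(utr2$end, 220L)
})

test_that("internal UTRs fill gaps of at least 15 bp between TU genes", {
  genes <- ann(c("a", "b", "c"), c(100, 231, 415), c(200, 400, 700))
  tus <- complement_tus(tu_tbl("tu1", list(c("a", "b", "c")), "+"),
                        genes, genome_length = 100000L)
  utr <- infer_internal_utrs(tus, genes)
  # a|b gap 30 -> UTR [201,230]; b|c gap 14 -> none
  expect_equal(nrow(utr), 1)
  expect_equal(c(utr$start, utr$end), c(201L, 230L))
  expect_equal(utr$utr_class, "internal")
  # excluded TUs contribute nothing regardless of gaps
  tus$excluded <- TRUE
  expect_equal(nrow(infer_internal_utrs(tus, genes)), 0)
  # overlapping genes produce no internal UTR
  genes2 <- ann(c("a", "b"), c(100, 180), c(200, 400))
  tus2 <- complement_tus(tu_tbl("t", list(c("a", "b")), "+"), genes2, 100000L)
  expect_equal(nrow(infer_internal_utrs(tus2, genes2)), 0)
})

test_that("every emitted UTR is >= 15 bp and avoids its anchor gene", {
  set.seed(43)
  spec <- truth_spec(seed = 5, n_operons = 25)
  truth <- generate_truth(spec)
  atlas <- run_pipeline(emit_resource_views(truth),
                        pipeline_config(genome_length = spec$genome_length))
  u <- atlas$utrs
  expect_true(all(u$end - u$start + 1 >= 15))
  g <- atlas$genes
  anchors <- g[match(u$anchor_gene, g$id), ]
  overlap <- pmin(u$end, anchors$end) - pmax(u$start, anchors$start) + 1
  expect_true(all(overlap[!u$extended] <= 0))
  # flanking UTRs abut their anchor's transcription end
  ends <- transcription_ends(anchors)
  five <- u$utr_class == "five_prime" & !u$extended
  expect_true(all(ifelse(u$strand[five] == "+",
                         u$end[five] + 1 == ends$five_prime[five],
                         u$start[five] - 1 == ends$five_prime[five])))
  # class counts are disjoint and additive
  expect_equal(sum(table(u$utr_class)), nrow(u))
})
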