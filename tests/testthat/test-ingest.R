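test_that("unique sequence lookup handles palindromes and ambiguity", {
  g <- genome_ref("toy", sequence = "AAACGTAAA")
  # ACGT is its own reverse complement: one locus, counted once
  hit <- locate_unique_sequence(g, "ACGT")
  expect_equal(hit$status, "unique")
  expect_equal(c(hit$start, hit$end), c(3L, 6L))
  expect_equal(hit$strand, "+")
  g2 <- genome_ref("toy2", sequence = "ACGTACGT")
  expect_equal(locate_unique_sequence(g2, "ACGT")$status, "ambiguous")
  expect_equal(locate_unique_sequence(g, "GGGG")$status, "no_match")
  expect_error(locate_unique_sequence(g, "ACNT"), "A,C,G,T")
  # reverse-complement-only matches come back on the minus strand
  g3 <- genome_ref("toy3", sequence = "TTTTCCAATTTT")
  hit3 <- locate_unique_sequence(g3, "ATTGG")
  expect_equal(hit3$status, "unique")
  expect_equal(hit3$strand, "-")
  expect_equal(c(hit3$start, hit3$end), c(5L, 9L))
})

test_that("random probes are located at their source position", {
  set.seed(7)
  seqc <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE), collapse = "")
  g <- genome_ref("rand", sequence = seqc)
  starts <- sample(4980, 30)
  queries <- substring(seqc, starts, starts + 17)
  res <- locate_unique_sequence(g, queries)
  # naive position-by-position scan oracle
  naive_count <- function(q) {
    rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(q, "")[[1]]), collapse = ""))
    n_f <- sum(vapply(1:(5000 - 17), function(p) substring(seqc, p, p + 17) == q,
                      logical(1)))
    n_r <- if (rc == q) 0 else
      sum(vapply(1:(5000 - 17), function(p) substring(seqc, p, p + 17) == rc,
                 logical(1)))
    n_f + n_r
  }
  counts <- vapply(queries, naive_count, numeric(1))
  expect_equal(res$status, unname(ifelse(counts > 1, "ambiguous", "unique")))
  uq <- res$status == "unique"
  expect_equal(res$start[uq & res$strand == "+"], starts[uq & res$strand == "+"])
})

test_that("sigma-site TSS derivation shifts the downstream end by the offset", {
  s <- tibble::tibble(start = c(100L, 100L, 100L), end = c(150L, 150L, 150L),
                      strand = c("+", "-", "+"),
                      sigma_factor = c("SigA", "SigB", "SigA"),
                      offset_to_tss = c(10L, 10L, 0L))
  tss <- tss_from_sigma_site(s)
  expect_equal(tss$position, c(160L, 90L, 150L))
  expect_equal(tss$strand, c("+", "-", "+"))
  expect_equal(tss$halfwidth, c(0L, 0L, 0L))
  expect_equal(tss$sigma, c("SigA", "SigB", "SigA"))
  s$offset_to_tss[2] <- NA
  expect_warning(out <- tss_from_sigma_site(s), "skipped")
  expect_equal(nrow(out), 2)
})

test_that("name matching keeps only unambiguous hits", {
  idx <- ann(c("g1", "g2", "g3"), c(1, 100, 200), c(50, 150, 250),
             names = list(c("thrS"), c("yabC", "dnaB"), c("yabC")))
  res <- match_by_name(list("thrS", "yabC", c("THRS"), "nope"), idx)
  expect_equal(res$status, c("matched", "ambiguous", "matched", "unmatched"))
  expect_equal(res$gene_id, c("g1", NA, "g1", NA))
})

test_that("name matching equals the exhaustive cross-product oracle", {
  set.seed(11)
  pool <- paste0("syn", 1:40)
  gene_names <- lapply(1:100, function(i) {
    c(paste0("gene", i), sample(pool, sample(0:3, 1)))
  })
  idx <- ann(paste0("g", 1:100), seq(1, by = 100, length.out = 100),
             seq(50, by = 100, length.out = 100), names = gene_names)
  queries <- lapply(1:60, function(i) sample(pool, sample(1:2, 1)))
  res <- match_by_name(queries, idx)
  for (i in seq_along(queries)) {
    hits <- which(vapply(gene_names, function(nm) {
      length(intersect(tolower(nm), tolower(queries[[i]]))) > 0
    }, logical(1)))
    want <- if (length(hits) == 0) "unmatched" else
      if (length(hits) > 1) "ambiguous" else "matched"
    expect_equal(res$status[[i]], want)
    if (want == "matched") expect_equal(res$gene_id[[i]], paste0("g", hits))
  }
})

rand_hits <- function(n, seed) {
  set.seed(seed)
  s <- sample(10000, n, replace = TRUE)
  tibble::tibble(
    family_id = paste0("RF", sample(9, n, replace = TRUE)),
    start = s, end = s + sample(30:120, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    bit_score = round(runif(n, 20, 90), 1),
    e_value = 10^runif(n, -12, -2),
    gathering_score = round(runif(n, 25, 60), 1)
  )
}

test_that("scan-hit post-filtering applies level cut-offs and keeps best hits", {
  h <- tibble::tibble(
    family_id = c("a", "b"), start = c(100L, 140L), end = c(200L, 260L),
    strand = "+", bit_score = c(50, 60), e_value = c(1e-8, 1e-7),
    gathering_score = c(30, 30)
  )
  out <- rfam_postfilter(h, "conservative")  # 61 bp overlap: one cluster
  expect_equal(nrow(out), 1)
  expect_equal(out$e_value, 1e-8)
  # a 1e-4 hit is excluded at medium, retained at relaxed
  h1 <- h[1, ]; h1$e_value <- 1e-4
  expect_equal(nrow(rfam_postfilter(h1, "medium")), 0)
  expect_equal(nrow(rfam_postfilter(h1, "relaxed")), 1)
  # conservative also requires the gathering score
  h2 <- h[1, ]; h2$bit_score <- 20
  expect_equal(nrow(rfam_postfilter(h2, "conservative")), 0)
  expect_equal(nrow(rfam_postfilter(h2, "medium")), 1)
  # E-value ties break by score
  h3 <- h; h3$e_value <- c(1e-8, 1e-8)
  expect_equal(rfam_postfilter(h3, "medium")$bit_score, 60)
})

test_that("scan-hit post-filtering equals the exhaustive oracle", {
  for (seed in c(3, 19)) {
    h <- rand_hits(200, seed)
    for (lv in c("conservative", "medium", "relaxed")) {
      got <- rfam_postfilter(h, lv)
      want <- rfam_oracle(as.data.frame(h), lv)
      expect_equal(as.data.frame(got), as.data.frame(want),
                   ignore_attr = TRUE)
      # output subset of input, pairwise < 40 bp overlap within strand
      expect_true(all(got$start %in% h$start))
      if (nrow(got) > 1) {
        for (i in 1:(nrow(got) - 1)) for (j in (i + 1):nrow(got)) {
          if (got$strand[i] != got$strand[j]) next
          ov <- min(got$end[i], got$end[j]) - max(got$start[i], got$start[j]) + 1
          expect_lt(ov, 40)
        }
      }
      # idempotence
      expect_equal(rfam_postfilter(got, lv), got)
    }
  }
})

test_that("cmsearch tblout parsing extracts hits with strand-normalized coordinates", {
  path <- withr::local_tempfile(fileext = ".tbl")
  writeLines(c(
    "#target name accession query name accession mdl mdl from mdl to seq from seq to strand trunc pass gc bias score E-value inc description",
    "genome - RF00162 RF00162 cm 1 108 1075 1181 + no 1 0.5 0.0 85.1 1.4e-18 ! SAM riboswitch",
    "genome - RF00050 RF00050 cm 1 140 2300 2161 - no 1 0.5 0.0 55.2 2.1e-09 ! FMN riboswitch"
  ), path)
  hits <- read_cmsearch_tblout(path, gathering_scores = c(RF00162 = 44, RF00050 = 40))
  expect_equal(nrow(hits), 2)
  expect_equal(hits$start, c(1075L, 2161L))
  expect_equal(hits$end, c(1181L, 2300L))
  expect_equal(hits$strand, c("+", "-"))
  expect_equal(hits$e_value, c(1.4e-18, 2.1e-09))
  expect_equal(hits$gathering_score, c(44, 40))
})

test_that("resource tables round-trip through the TSV schema", {
  cfg <- resource_config("curated", 1, 1, 0, curated = TRUE)
  objs <- list(
    annotations = ann(c("gA", "gB"), c(100, 300), c(200, 420),
                      biotype = c("CDS", "sRNA"),
                      names = list("thrS", c("fsrA", "alt"))),
    sites = site_tbl(c("s1", "s2"), c(80L, 450L), c("+", "+"), c("TSS", "TTS"),
                     sigma = c("SigA", NA), resource = "curated",
                     orphan = c(FALSE, TRUE)),
    tus = tu_tbl("tu1", list(c("gA", "gB")), "+", source = "curated")
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_resource_table(objs, path)
  back <- load_resource_table(path, cfg)
  expect_equal(back$annotations$id, objs$annotations$id)
  expect_equal(back$annotations$start, objs$annotations$start)
  expect_equal(back$annotations$biotype, objs$annotations$biotype)
  expect_equal(back$annotations$names, objs$annotations$names)
  expect_equal(back$sites$position, objs$sites$position)
  expect_equal(back$sites$orphan, objs$sites$orphan)
  expect_equal(back$sites$sigma, objs$sites$sigma)
  expect_equal(back$tus$genes, objs$tus$genes)
  # schema violations are descriptive errors
  writeLines("foo\tbar", path)
  expect_error(load_resource_table(path, cfg), "required column")
})
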