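test_that("extraction pools mates into one fragment and respects filters", {
  g <- two_isoform_gene()
  bam <- make_bam(c(
    sam_pair("frag1", 111, "50M", 621, "50M"),
    sam_pair("lowq", 111, "50M", 621, "50M", mapq = 3L),
    sam_rec("secondary", 256L + 99L, 120, "50M"),
    sam_rec("singleton", 0L, 130, "40M"),
    sam_rec("outside", 0L, 5000, "50M")
  ))
  frags <- extract_gene_fragments(bam, g)
  ids <- S4Vectors::mcols(frags)$fragment_id
  expect_setequal(ids, c("frag1", "singleton"))
  f1 <- frags[[which(ids == "frag1")]]
  expect_equal(IRanges::start(f1), c(111L, 621L))
  expect_equal(IRanges::end(f1), c(160L, 670L))
  # proper-pair requirement drops the singleton
  frags_pp <- extract_gene_fragments(bam, g, require_proper_pair = TRUE)
  expect_setequal(S4Vectors::mcols(frags_pp)$fragment_id, "frag1")
  # low-mapq fragment kept when the threshold allows it
  frags_all <- extract_gene_fragments(bam, g, min_mapq = 0)
  expect_true("lowq" %in% S4Vectors::mcols(frags_all)$fragment_id)
})

test_that("extraction from an empty or wrong-chromosome BAM is empty", {
  g <- two_isoform_gene()
  bam <- make_bam(character(0))
  expect_length(extract_gene_fragments(bam, g), 0L)
  bam2 <- make_bam(sam_rec("r1", 0L, 150, "50M"), chrom = "chrOther")
  expect_warning(
    frags <- extract_gene_fragments(bam2, g),
    "absent from BAM header"
  )
  expect_length(frags, 0L)
})

test_that("a missing BAM index is an error for region extraction", {
  g <- two_isoform_gene()
  bam <- make_bam(sam_rec("r1", 0L, 150, "50M"))
  file.remove(paste0(bam, ".bai"))
  expect_error(extract_gene_fragments(bam, g), "index")
})

test_that("fragments in shared exons count for every compatible isoform", {
  g <- two_isoform_gene()
  # fully inside the shared first exon -> both isoforms
  bam <- make_bam(sam_pair("shared", 105, "40M", 150, "40M"))
  frags <- extract_gene_fragments(bam, g)
  a <- assign_fragments(frags, g)
  expect_equal(unname(a$counts[c("txA", "txB")]), c(1L, 1L))
  expect_equal(a$unassigned, 0L)
})

test_that("a fragment crossing one isoform's intron is contained only in the other", {
  # txC is spliced (intron 201-300), txD retains the intron as exonic
  txC <- transcript_model("txC", "gI", "chr1", "+",
                          IRanges::IRanges(c(101, 301), c(200, 400)))
  txD <- transcript_model("txD", "gI", "chr1", "+", IRanges::IRanges(101, 400))
  g <- gene_model("gI", list(txC, txD))
  # read1 runs 181-220, straight through txC's intron boundary
  bam <- make_bam(sam_pair("span", 181, "40M", 321, "40M"))
  frags <- extract_gene_fragments(bam, g)
  a_cont <- assign_fragments(frags, g, mode = "contained")
  expect_equal(unname(a_cont$counts[c("txC", "txD")]), c(0L, 1L))
  a_over <- assign_fragments(frags, g, mode = "overlap")
  expect_equal(unname(a_over$counts[c("txC", "txD")]), c(1L, 1L))
  # a spliced fragment skipping exactly that intron is contained in txC
  bam2 <- make_bam(sam_pair("junc", 181, "20M100N20M", 341, "40M"))
  frags2 <- extract_gene_fragments(bam2, g)
  a2 <- assign_fragments(frags2, g, mode = "contained")
  expect_equal(unname(a2$counts[c("txC", "txD")]), c(1L, 1L))
})

test_that("a fragment compatible with no isoform is tallied as unassigned", {
  g <- two_isoform_gene()
  bam <- make_bam(sam_pair("intronic", 451, "40M", 501, "40M"))
  frags <- extract_gene_fragments(bam, g)
  a <- assign_fragments(frags, g)
  expect_equal(sum(a$counts), 0L)
  expect_equal(a$unassigned, 1L)
})

test_that("assignment counts equal the per-base brute-force oracle in both modes", {
  sim <- small_sim()
  bam <- sim$manifest$path[sim$manifest$condition == "WT_IP"][1]
  for (g in sim$genes[1:4]) {
    frags <- extract_gene_fragments(bam, g)
    blocks <- frag_block_list(frags)
    for (mode in c("contained", "overlap")) {
      got <- assign_fragments(frags, g, mode = mode)
      want <- oracle_assign(blocks, g, mode = mode)
      expect_identical(got$counts, want$counts)
      expect_identical(got$unassigned, want$unassigned)
    }
  }
})

test_that("contained-mode counts never exceed overlap-mode counts or the fragment total", {
  sim <- small_sim()
  bam <- sim$manifest$path[1]
  for (g in sim$genes) {
    frags <- extract_gene_fragments(bam, g)
    cont <- assign_fragments(frags, g, mode = "contained")$counts
    over <- assign_fragments(frags, g, mode = "overlap")$counts
    expect_true(all(cont <= over))
    expect_true(all(over <= length(frags)))
  }
})

test_that("extraction recovers exactly the simulated fragments of a gene region", {
  sim <- small_sim()
  lib <- "WT_TOTAL_rep1"
  bam <- sim$manifest$path[match(lib, paste0(sim$manifest$condition, "_rep", sim$manifest$replicate))]
  g <- sim$genes[[3]]
  frags <- extract_gene_fragments(bam, g, min_mapq = 0)
  # simulated qnames encode the source transcript (last token)
  src <- sub(".*_", "", S4Vectors::mcols(frags)$fragment_id)
  expect_true(all(src %in% names(g$transcripts)))
  tx_of_gene <- names(g$transcripts)
  want_n <- sum(sim$truth[[paste0("count_", lib)]][sim$truth$gene_id == g$gene_id])
  expect_equal(length(frags), want_n)
})

test_that("assignment is independent of BAM record order at equal coordinates", {
  g <- two_isoform_gene()
  recs <- c(
    sam_pair("a1", 105, "40M", 150, "40M"),
    sam_pair("a2", 105, "40M", 150, "40M"),
    sam_pair("a3", 105, "30M", 621, "40M")
  )
  bam_fwd <- make_bam(recs)
  bam_rev <- make_bam(rev(recs))
  f_fwd <- extract_gene_fragments(bam_fwd, g)
  f_rev <- extract_gene_fragments(bam_rev, g)
  expect_identical(
    S4Vectors::mcols(f_fwd)$fragment_id,
    S4Vectors::mcols(f_rev)$fragment_id
  )
  expect_identical(
    assign_fragments(f_fwd, g)$counts,
    assign_fragments(f_rev, g)$counts
  )
})

test_that("library size counts distinct mapped templates once", {
  expect_equal(library_size(make_bam(character(0))), 0L)
  pairs <- unlist(lapply(1:20, function(i) {
    sam_pair(sprintf("p%03d", i), 100 + i, "50M", 300 + i, "50M")
  }))
  expect_equal(library_size(make_bam(pairs)), 20L)
  mixed <- c(
    pairs,
    vapply(1:7, function(i) sam_rec(sprintf("s%02d", i), 0L, 1000 + i, "40M"), ""),
    sam_rec("p001", 256L + 99L, 2000, "50M") # secondary copy of a pair
  )
  bam <- make_bam(mixed)
  expect_equal(library_size(bam), oracle_library_size(bam))
  expect_equal(library_size(bam), 27L)
})
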