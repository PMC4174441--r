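test_that("a one-gene single-isoform annotation is minimal and fully constitutive", {
  p <- sim_params(seed = 3L, n_genes = 1L, isoform_range = c(1L, 1L))
  genes <- simulate_annotation(p)
  expect_length(genes, 1L)
  expect_length(genes[[1]]$transcripts, 1L)
  expect_true(all(exon_occurrence(genes[[1]])$fraction == 1))
})

test_that("isoforms of a simulated gene always share at least one exon", {
  p <- sim_params(seed = 21L, n_genes = 30L)
  genes <- simulate_annotation(p)
  for (g in genes) {
    if (length(g$transcripts) < 2L) next
    shared <- Reduce(function(a, b) IRanges::intersect(a, b),
                     lapply(g$transcripts, `[[`, "exons"))
    expect_true(sum(IRanges::width(shared)) > 0)
  }
})

test_that("simulated gene regions do not overlap", {
  p <- sim_params(seed = 22L, n_genes = 40L)
  genes <- simulate_annotation(p)
  starts <- vapply(genes, `[[`, 0L, "region_start")
  ends <- vapply(genes, `[[`, 0L, "region_end")
  ord <- order(starts)
  expect_true(all(starts[ord][-1L] > ends[ord][-length(ord)]))
})

test_that("a fixed chromosome length that cannot hold the genes is an error", {
  p <- sim_params(seed = 3L, n_genes = 50L, chrom_len = 1000L)
  expect_error(simulate_annotation(p), "do not fit")
})

test_that("annotation generation is byte-deterministic and round-trips through GFF", {
  p <- sim_params(seed = 101L, n_genes = 6L)
  f1 <- tempfile(fileext = ".gff3")
  f2 <- tempfile(fileext = ".gff3")
  g1 <- simulate_annotation(p, gff_path = f1)
  g2 <- simulate_annotation(p, gff_path = f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_gff(f1)
  expect_setequal(names(back), names(g1))
  for (gid in names(g1)) {
    for (tid in names(g1[[gid]]$transcripts)) {
      expect_equal(
        as.data.frame(back[[gid]]$transcripts[[tid]]$exons),
        as.data.frame(g1[[gid]]$transcripts[[tid]]$exons)
      )
    }
  }
})

test_that("simulated libraries conserve the requested fragment total", {
  sim <- small_sim()
  count_cols <- grep("^count_", names(sim$truth), value = TRUE)
  expect_length(count_cols, 12L)
  for (cc in count_cols) {
    expect_equal(sum(sim$truth[[cc]]), sim$params$n_fragments)
  }
})

test_that("every simulated fragment maps back inside its source transcript's exons", {
  sim <- small_sim()
  bam <- sim$manifest$path[1]
  frags <- ripenrich:::.read_fragments(bam)
  src <- sub(".*_", "", S4Vectors::mcols(frags)$fragment_id)
  tx_exons <- list()
  for (g in sim$genes) {
    for (t in g$transcripts) tx_exons[[t$transcript_id]] <- t$exons
  }
  ub <- unlist(frags, use.names = FALSE)
  fi <- rep(seq_along(frags), S4Vectors::elementNROWS(frags))
  ok <- logical(length(ub))
  for (tid in unique(src)) {
    sel <- src[fi] == tid
    ok[sel] <- IRanges::countOverlaps(
      IRanges::ranges(ub[sel]), tx_exons[[tid]], type = "within"
    ) > 0
  }
  expect_true(all(ok))
})

test_that("realized counts in the truth table match the emitted alignments", {
  sim <- small_sim()
  for (i in c(1L, 5L)) {
    lib <- paste0(sim$manifest$condition[i], "_rep", sim$manifest$replicate[i])
    frags <- ripenrich:::.read_fragments(sim$manifest$path[i])
    src <- sub(".*_", "", S4Vectors::mcols(frags)$fragment_id)
    realized <- table(src)
    want <- sim$truth[[paste0("count_", lib)]]
    names(want) <- sim$truth$transcript_id
    want <- want[want > 0]
    expect_identical(as.integer(realized[names(want)]), unname(want))
  }
})

test_that("a single-transcript genome yields counts equal to the truth table exactly", {
  p <- sim_params(seed = 31L, n_genes = 1L, isoform_range = c(1L, 1L),
                  n_fragments = 500L, replicates = 1L)
  dir <- file.path(tempdir(), "ripenrich_single_tx")
  genes <- simulate_annotation(p)
  out <- simulate_experiment(genes, p, dir, conditions = "WT_IP")
  lq <- quantify_library(out$manifest$path[1], genes, condition = "WT_IP")
  expect_equal(unname(lq$counts), 500L)
  expect_equal(unname(lq$counts), out$truth$count_WT_IP_rep1)
  expect_equal(lq$N, 500L)
})

test_that("the full experiment is reproducible from the master seed", {
  p <- sim_params(seed = 77L, n_genes = 4L, n_fragments = 300L, replicates = 1L)
  d1 <- file.path(tempdir(), "ripenrich_repro1")
  d2 <- file.path(tempdir(), "ripenrich_repro2")
  o1 <- simulate_dataset(p, d1, conditions = c("WT_IP", "WT_TOTAL"))
  o2 <- simulate_dataset(p, d2, conditions = c("WT_IP", "WT_TOTAL"))
  expect_identical(readLines(o1$truth_path), readLines(o2$truth_path))
  for (i in seq_len(nrow(o1$manifest))) {
    a1 <- Rsamtools::scanBam(o1$manifest$path[i])[[1]]
    a2 <- Rsamtools::scanBam(o2$manifest$path[i])[[1]]
    expect_identical(a1$qname, a2$qname)
    expect_identical(a1$pos, a2$pos)
    expect_identical(a1$cigar, a2$cigar)
  }
})

test_that("null IP libraries ignore the enrichment factor", {
  sim <- small_sim()
  tgt <- sim$truth$is_target
  expect_true(any(tgt))
  # expected counts scale with abundance*L in every non-WT_IP library;
  # targets' WT_IP share exceeds their NULL_IP share by design
  wt_ip <- rowSums(as.matrix(sim$truth[grep("count_WT_IP", names(sim$truth))]))
  null_ip <- rowSums(as.matrix(sim$truth[grep("count_NULL_IP", names(sim$truth))]))
  expect_gt(
    sum(wt_ip[tgt]) / sum(wt_ip),
    sum(null_ip[tgt]) / sum(null_ip)
  )
})
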