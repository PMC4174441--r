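gff_lines <- function(...) {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", ...), f)
  f
}

test_that("GFF parsing builds the gene/transcript/exon hierarchy with 1-based closed coordinates", {
  f <- gff_lines(
    "chr1\tsrc\tgene\t101\t400\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t101\t400\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tParent=t1",
    "chr1\tsrc\texon\t301\t400\t.\t+\t.\tParent=t1"
  )
  genes <- read_gff(f)
  expect_length(genes, 1L)
  g <- genes[[1]]
  expect_equal(g$region_start, 101L)
  expect_equal(g$region_end, 400L)
  expect_equal(exon_model_length(g$transcripts$t1), 200L)
})

test_that("malformed coordinates and orphan exons are skipped with a warning", {
  f <- gff_lines(
    "chr1\tsrc\tmRNA\t101\t400\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tsrc\texon\t200\t101\t.\t+\t.\tParent=t1",
    "chr1\tsrc\texon\t301\t400\t.\t+\t.\tParent=t1"
  )
  expect_warning(genes <- read_gff(f), "malformed")
  expect_equal(exon_model_length(genes[[1]]$transcripts$t1), 100L)

  f2 <- gff_lines(
    "chr1\tsrc\tmRNA\t101\t400\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tParent=t1",
    "chr1\tsrc\texon\t301\t400\t.\t+\t.\tParent=ghost"
  )
  expect_warning(genes2 <- read_gff(f2), "unknown Parent")
  expect_equal(exon_model_length(genes2[[1]]$transcripts$t1), 100L)
})

test_that("an annotation with no usable feature is an error", {
  f <- gff_lines("chr1\tsrc\tCDS\t1\t10\t.\t+\t.\tID=x")
  expect_error(read_gff(f))
})

test_that("an exon line with several Parents attaches to each transcript", {
  f <- gff_lines(
    "chr1\tsrc\tmRNA\t101\t400\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tsrc\tmRNA\t101\t400\t.\t+\t.\tID=t2;Parent=g1",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tParent=t1,t2",
    "chr1\tsrc\texon\t301\t400\t.\t+\t.\tParent=t1"
  )
  genes <- read_gff(f)
  g <- genes[[1]]
  expect_equal(exon_model_length(g$transcripts$t1), 200L)
  expect_equal(exon_model_length(g$transcripts$t2), 100L)
})

test_that("exon-model length uses union semantics and is representation invariant", {
  mk <- function(starts, ends) {
    transcript_model("t", "g", "chr1", "+", IRanges::IRanges(starts, ends))
  }
  expect_equal(exon_model_length(mk(c(1, 201), c(100, 300))), 200L)
  # overlapping records merge
  expect_equal(exon_model_length(mk(c(1, 51), c(100, 150))), 150L)
  # invariant under record order and splitting into abutting records
  expect_equal(
    exon_model_length(mk(c(201, 1), c(300, 100))),
    exon_model_length(mk(c(1, 201), c(100, 300)))
  )
  expect_equal(
    exon_model_length(mk(c(1, 51, 201), c(50, 100, 300))),
    exon_model_length(mk(c(1, 201), c(100, 300)))
  )
})

test_that("exon-model length matches the per-base oracle on simulated transcripts", {
  sim <- small_sim()
  for (g in sim$genes[1:4]) {
    for (t in g$transcripts) {
      expect_identical(
        exon_model_length(t),
        oracle_exon_length(IRanges::start(t$exons), IRanges::end(t$exons))
      )
    }
  }
})

test_that("exon occurrence fractions follow isoform membership", {
  t1 <- transcript_model("t1", "g", "chr1", "+", IRanges::IRanges(1, 100))
  g1 <- gene_model("g", list(t1))
  occ1 <- exon_occurrence(g1)
  expect_true(all(occ1$fraction == 1))

  g2 <- two_isoform_gene()
  occ2 <- exon_occurrence(g2)
  # shared first/last exons at 1.0, middle exon private to txA at 0.5
  expect_equal(
    occ2$fraction[match(c(101, 301, 601), occ2$start)],
    c(1, 0.5, 1)
  )
})

test_that("occurrence intervals tile the exonic union and match the per-base oracle", {
  sim <- small_sim()
  for (g in sim$genes) {
    occ <- exon_occurrence(g)
    union_size <- sum(IRanges::width(IRanges::reduce(
      do.call(c, lapply(unname(g$transcripts), `[[`, "exons"))
    )))
    expect_equal(sum(occ$end - occ$start + 1L), union_size)
    ob <- oracle_occurrence(g)
    for (i in seq_len(nrow(occ))) {
      bases <- as.character(seq.int(occ$start[i], occ$end[i]))
      expect_true(all(ob[bases] == occ$fraction[i]))
    }
  }
})

test_that("GFF write-read round-trip reproduces the models", {
  sim <- small_sim()
  f <- tempfile(fileext = ".gff3")
  write_gff(sim$genes, f)
  back <- read_gff(f)
  expect_setequal(names(back), names(sim$genes))
  for (gid in names(sim$genes)) {
    a <- sim$genes[[gid]]
    b <- back[[gid]]
    expect_equal(b$region_start, a$region_start)
    expect_equal(b$region_end, a$region_end)
    expect_setequal(names(b$transcripts), names(a$transcripts))
    for (tid in names(a$transcripts)) {
      expect_equal(
        as.data.frame(b$transcripts[[tid]]$exons),
        as.data.frame(a$transcripts[[tid]]$exons)
      )
      expect_equal(b$transcripts[[tid]]$strand, a$transcripts[[tid]]$strand)
    }
  }
})

test_that("chromosome aliasing renames sequences at parse time", {
  f <- gff_lines(
    "2L\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=t1;Parent=g1",
    "2L\tsrc\texon\t101\t200\t.\t+\t.\tParent=t1"
  )
  genes <- read_gff(f, chrom_alias = c("2L" = "chr2L"))
  expect_equal(genes[[1]]$chrom, "chr2L")
})
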