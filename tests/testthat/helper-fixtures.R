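# Shared fixtures, built in code and cached for the test session.

.fixture_env <- new.env(parent = emptyenv())

# small but complete simulated experiment: 8 genes, ~800 fragments/library,
# triplicates, all four conditions; used by the oracle-equivalence and
# contract tests (fixtures stay under 1000 fragments per library)
small_sim <- function() {
  if (is.null(.fixture_env$small)) {
    dir <- file.path(tempdir(), "ripenrich_small_sim")
    p <- sim_params(
      seed = 7L, n_genes = 8L, n_fragments = 800L,
      target_fraction = 0.25
    )
    .fixture_env$small <- c(simulate_dataset(p, dir), list(params = p, dir = dir))
  }
  .fixture_env$small
}

# two-transcript gene with a shared and a private exon (classic fixture)
two_isoform_gene <- function() {
  tA <- transcript_model(
    "txA", "g1", "chr1", "+",
    IRanges::IRanges(start = c(101, 301, 601), end = c(200, 400, 700))
  )
  tB <- transcript_model(
    "txB", "g1", "chr1", "+",
    IRanges::IRanges(start = c(101, 601), end = c(200, 700))
  )
  gene_model("g1", list(tA, tB))
}

# build an indexed BAM from SAM record lines; returns the BAM path
make_bam <- function(records, chrom = "chr1", chrom_len = 100000L,
                     prefix = tempfile("fixture_")) {
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len)
  )
  sam <- paste0(prefix, ".sam")
  if (length(records)) {
    pos <- as.integer(vapply(strsplit(records, "\t"), `[[`, "", 4L))
    records <- records[order(pos)] # stable: same-pos order preserved
  }
  writeLines(c(header, records), sam)
  bam <- Rsamtools::asBam(sam, prefix, overwrite = TRUE, indexDestination = TRUE)
  unlink(sam)
  bam
}

# SAM record constructor with sane defaults
sam_rec <- function(qname, flag, pos, cigar, chrom = "chr1", mapq = 60L,
                    rnext = "*", pnext = 0L, tlen = 0L) {
  paste(qname, flag, chrom, pos, mapq, cigar, rnext, pnext, tlen, "*", "*",
        sep = "\t")
}

# a proper read pair (flags 99/147) with given positions and cigars
sam_pair <- function(qname, pos1, cigar1, pos2, cigar2, chrom = "chr1",
                     mapq = 60L) {
  c(
    sam_rec(qname, 99L, pos1, cigar1, chrom, mapq, rnext = "=", pnext = pos2),
    sam_rec(qname, 147L, pos2, cigar2, chrom, mapq, rnext = "=", pnext = pos1)
  )
}
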