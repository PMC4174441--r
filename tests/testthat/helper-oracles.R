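# Independent brute-force oracles. These deliberately re-derive every
# quantity from per-base set membership or per-name counting, without using
# the package's interval machinery, so they can check it.

# exon set -> vector of covered base positions
.bases <- function(starts, ends) {
  unique(unlist(Map(seq.int, starts, ends)))
}

# exon-model length by per-base set membership
oracle_exon_length <- function(starts, ends) {
  length(.bases(starts, ends))
}

# per-base occurrence fraction over a gene: named vector base -> fraction
oracle_occurrence <- function(g) {
  tx_bases <- lapply(g$transcripts, function(t) {
    .bases(IRanges::start(t$exons), IRanges::end(t$exons))
  })
  all_bases <- sort(unique(unlist(tx_bases)))
  counts <- vapply(all_bases, function(b) {
    sum(vapply(tx_bases, function(tb) b %in% tb, TRUE))
  }, 0L)
  stats::setNames(counts / length(g$transcripts), all_bases)
}

# fragments as list of block matrices (start, end rows); per-base assignment
oracle_assign <- function(frag_blocks, g, mode = "contained") {
  tx_bases <- lapply(g$transcripts, function(t) {
    .bases(IRanges::start(t$exons), IRanges::end(t$exons))
  })
  counts <- stats::setNames(integer(length(tx_bases)), names(g$transcripts))
  unassigned <- 0L
  for (fb in frag_blocks) {
    frag_bases <- .bases(fb[, 1L], fb[, 2L])
    hit_any <- FALSE
    for (k in seq_along(tx_bases)) {
      ok <- if (mode == "contained") {
        all(frag_bases %in% tx_bases[[k]])
      } else {
        any(frag_bases %in% tx_bases[[k]])
      }
      if (ok) {
        counts[k] <- counts[k] + 1L
        hit_any <- TRUE
      }
    }
    if (!hit_any) unassigned <- unassigned + 1L
  }
  list(counts = counts, unassigned = unassigned)
}

# GRangesList of fragments -> list of block matrices (in region order)
frag_block_list <- function(frags) {
  lapply(seq_along(frags), function(i) {
    gr <- frags[[i]]
    cbind(IRanges::start(gr), IRanges::end(gr))
  })
}

# per-base coverage by counting fragments containing each base
oracle_coverage <- function(frag_blocks, from, to) {
  depth <- integer(to - from + 1L)
  for (fb in frag_blocks) {
    for (b in .bases(fb[, 1L], fb[, 2L])) {
      if (b >= from && b <= to) depth[b - from + 1L] <- depth[b - from + 1L] + 1L
    }
  }
  depth
}

# FPKM by an independently arranged formula
oracle_fpkm <- function(f, l, n) {
  (f / (l / 1000)) / (n / 1e6)
}

# library size by raw name-set counting with hand-rolled flag arithmetic
oracle_library_size <- function(bam) {
  x <- Rsamtools::scanBam(bam)[[1L]]
  flag <- x$flag
  mapped <- bitwAnd(flag, 4L) == 0L
  primary <- bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L
  length(unique(x$qname[mapped & primary]))
}
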