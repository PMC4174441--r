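#' @importFrom Rsamtools BamFile ScanBamParam scanBamFlag scanBam scanBamHeader
#'   countBam bamFlagTest asBam sortBam indexBam
#' @importFrom GenomicRanges GRanges seqnames granges coverage
#' @importFrom GenomicAlignments readGAlignments grglist cigar
#' @importFrom S4Vectors elementNROWS splitAsList Rle runValue runLength
NULL

# Read primary mapped alignments and pool them into fragments keyed by query
# name: one fragment per template, blocks = union of both mates' aligned
# blocks (junction-aware, mate overlap collapsed). Returns a GRangesList with
# mcols fragment_id, mapq_min, is_proper_pair; fragments ordered by name so
# the result is independent of BAM record order.
.read_fragments <- function(bam, which = NULL) {
  flag <- scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE
  )
  param <- if (is.null(which)) {
    ScanBamParam(flag = flag, what = c("qname", "mapq", "flag"))
  } else {
    ScanBamParam(flag = flag, what = c("qname", "mapq", "flag"), which = which)
  }
  gal <- readGAlignments(bam, param = param)
  qname <- mcols(gal)$qname
  if (length(gal) == 0L) {
    out <- GenomicRanges::GRangesList()
    mcols(out) <- S4Vectors::DataFrame(
      fragment_id = character(0), mapq_min = integer(0),
      is_proper_pair = logical(0)
    )
    return(out)
  }
  # a mate can be returned twice when `which` contains overlapping windows
  dup <- duplicated(paste(qname, mcols(gal)$flag))
  if (any(dup)) gal <- gal[!dup]
  qname <- mcols(gal)$qname
  read_blocks <- grglist(gal)
  f <- factor(qname, levels = sort(unique(qname)))
  ub <- unlist(read_blocks, use.names = FALSE)
  # counting is unstranded: drop strand so overlapping mate blocks merge
  GenomicRanges::strand(ub) <- "*"
  fb <- rep(as.integer(f), elementNROWS(read_blocks))
  frag_blocks <- reduce(S4Vectors::split(ub, factor(fb, levels = seq_len(nlevels(f)))))
  names(frag_blocks) <- levels(f)
  mapq <- mcols(gal)$mapq
  mapq[is.na(mapq)] <- 0L
  mapq_min <- as.integer(min(splitAsList(mapq, f)))
  proper <- bamFlagTest(mcols(gal)$flag, "isProperPair")
  is_proper <- as.logical(all(splitAsList(proper, f)))
  mcols(frag_blocks) <- S4Vectors::DataFrame(
    fragment_id = levels(f), mapq_min = mapq_min, is_proper_pair = is_proper
  )
  frag_blocks
}

.bam_has_chrom <- function(bam, chrom) {
  chrom %in% names(scanBamHeader(bam)[[1L]]$targets)
}

#' Extract aligned fragments overlapping a gene region
#'
#' Reads primary mapped alignments from a coordinate-sorted, indexed BAM file
#' and pools mates into fragments (the counting unit of paired-end FPKM). A
#' fragment is returned when at least one aligned base of either mate
#' overlaps the gene region; a mate whose pair falls outside the region is
#' still included in the fragment's blocks. Unmapped, secondary and
#' supplementary records are never used; a fragment whose minimum mapping
#' quality over its mates is below `min_mapq` (or that is not a proper pair,
#' when `require_proper_pair`) is dropped. Singletons (mate unmapped) count
#' as fragments with one mate's blocks.
#'
#' @param bam Path to an indexed BAM file.
#' @param g A `GeneModel`.
#' @param min_mapq Minimum of the mates' mapping qualities (default 10).
#' @param require_proper_pair Keep only proper pairs (default `FALSE`).
#' @param flank Bases of padding around the gene region when querying the
#'   index, so that out-of-region mate blocks are recovered (default 10000).
#' @return A [GenomicRanges::GRangesList]: one element per fragment holding
#'   its merged aligned blocks, with metadata columns `fragment_id`,
#'   `mapq_min` and `is_proper_pair`. Fragments are ordered by id.
#' @export
extract_gene_fragments <- function(bam, g, min_mapq = 10, require_proper_pair = FALSE,
                                   flank = 10000L) {
  stopifnot(inherits(g, "GeneModel"))
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam))) {
    stop("BAM index (.bai) not found for ", bam)
  }
  empty <- function() {
    out <- GenomicRanges::GRangesList()
    mcols(out) <- S4Vectors::DataFrame(
      fragment_id = character(0), mapq_min = integer(0),
      is_proper_pair = logical(0)
    )
    out
  }
  if (!.bam_has_chrom(bam, g$chrom)) {
    warning("chromosome ", g$chrom, " absent from BAM header of ", bam)
    return(empty())
  }
  window <- GRanges(g$chrom, IRanges(
    max(1L, g$region_start - as.integer(flank)),
    g$region_end + as.integer(flank)
  ))
  frags <- .read_fragments(bam, which = window)
  if (length(frags) == 0L) return(frags)
  keep <- mcols(frags)$mapq_min >= min_mapq
  if (require_proper_pair) keep <- keep & mcols(frags)$is_proper_pair
  frags <- frags[keep]
  region <- GRanges(g$chrom, IRanges(g$region_start, g$region_end))
  frags[GenomicRanges::countOverlaps(frags, region) > 0L]
}

#' Assign fragments to the exon models of a gene's transcripts
#'
#' In `contained` mode (the default, stricter reading) a fragment is
#' compatible with a transcript when every aligned base of every block lies
#' within the transcript's exon union; in `overlap` mode one overlapping
#' aligned base suffices. A fragment compatible with several isoforms
#' increments each of their counts; fragments compatible with none are
#' tallied as unassigned.
#'
#' @param frags Fragments from [extract_gene_fragments()].
#' @param g The `GeneModel` the fragments were extracted for.
#' @param mode `"contained"` or `"overlap"`.
#' @return A list with `counts` (named integer vector, one per transcript),
#'   `unassigned` (count of fragments compatible with no transcript),
#'   `n_fragments`, and `assigned_fragment_ids` (ids of fragments compatible
#'   with at least one transcript).
#' @export
assign_fragments <- function(frags, g, mode = c("contained", "overlap")) {
  mode <- match.arg(mode)
  stopifnot(inherits(g, "GeneModel"))
  tx_ids <- vapply(g$transcripts, `[[`, "", "transcript_id")
  counts <- stats::setNames(integer(length(tx_ids)), tx_ids)
  n <- length(frags)
  if (n == 0L) {
    return(list(
      counts = counts, unassigned = 0L, n_fragments = 0L,
      assigned_fragment_ids = character(0)
    ))
  }
  ub <- unlist(frags, use.names = FALSE)
  fid <- rep(seq_len(n), elementNROWS(frags))
  assigned_any <- logical(n)
  for (t in g$transcripts) {
    exgr <- GRanges(t$chrom, t$exons)
    if (mode == "contained") {
      # exons are reduced, so a block is inside the union iff inside one exon
      inside <- GenomicRanges::countOverlaps(ub, exgr, type = "within") > 0L
      bad <- unique(fid[!inside])
      ok <- setdiff(seq_len(n), bad)
    } else {
      hit <- GenomicRanges::countOverlaps(ub, exgr) > 0L
      ok <- unique(fid[hit])
    }
    counts[[t$transcript_id]] <- length(ok)
    assigned_any[ok] <- TRUE
  }
  list(
    counts = counts,
    unassigned = sum(!assigned_any),
    n_fragments = n,
    assigned_fragment_ids = mcols(frags)$fragment_id[assigned_any]
  )
}

#' Total mapped fragments in a library
#'
#' The "per million mapped reads" denominator of FPKM, counted in fragment
#' units: the number of distinct query names with at least one primary mapped
#' alignment, so a read pair counts once and a singleton counts once. The
#' whole file is scanned (an index is not needed for a full scan).
#'
#' @param bam Path to a BAM file.
#' @return Integer fragment count.
#' @export
library_size <- function(bam) {
  bf <- BamFile(bam, yieldSize = 5e6L)
  flag <- scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE
  )
  param <- ScanBamParam(flag = flag, what = "qname")
  open(bf)
  on.exit(close(bf))
  seen <- character(0)
  repeat {
    chunk <- scanBam(bf, param = param)[[1L]]$qname
    if (length(chunk) == 0L) break
    seen <- unique(c(seen, chunk))
  }
  length(seen)
}
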