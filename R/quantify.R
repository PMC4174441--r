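#' Conditions of a RIP-Seq experiment
#'
#' The four library conditions of an IP-versus-input design with a
#' null-mutant specificity control: antibody IP from wild-type lysate, total
#' RNA from wild type, antibody IP from null-mutant lysate, and total RNA
#' from the null mutant.
#' @export
RIP_CONDITIONS <- c("WT_IP", "WT_TOTAL", "NULL_IP", "NULL_TOTAL")

#' Fragments per kilobase of exon model per million mapped fragments
#'
#' FPKM for paired-end data: `F * 1e9 / (L * N)` where `F` is the fragment
#' count assigned to the transcript, `L` the transcript's exon-model length
#' in bases and `N` the library's total mapped fragments. Vectorized over
#' `f_t` and `l`.
#'
#' @param f_t Fragment count(s), >= 0.
#' @param l Exon-model length(s) in bases, > 0.
#' @param n Total mapped fragments in the library, > 0.
#' @return FPKM value(s).
#' @export
fpkm <- function(f_t, l, n) {
  if (any(l <= 0)) stop("exon-model length must be positive")
  if (any(n <= 0)) stop("library size must be positive")
  if (any(f_t < 0)) stop("fragment counts must be non-negative")
  as.numeric(f_t) * 1e9 / (as.numeric(l) * as.numeric(n))
}

#' Quantify one library: per-transcript counts and FPKM
#'
#' Extracts fragments per annotated gene region, assigns them to transcript
#' exon models, and converts counts to FPKM using the library's genome-wide
#' mapped-fragment total. Every annotated transcript gets an FPKM (0 when no
#' fragment is assigned). The BAM is read once and partitioned across gene
#' regions, which is equivalent to calling [extract_gene_fragments()] per
#' gene.
#'
#' @param bam Path to an indexed, coordinate-sorted BAM file.
#' @param genes List of `GeneModel` objects from [read_gff()].
#' @param condition One of `RIP_CONDITIONS`.
#' @param replicate Replicate number.
#' @param library_id Library label; defaults to `condition_rep<replicate>`.
#' @param min_mapq,require_proper_pair,mode Assignment parameters, see
#'   [extract_gene_fragments()] and [assign_fragments()].
#' @return A `LibraryQuant` object: list with `library_id`, `condition`,
#'   `replicate`, `counts` (named integer), `N`, `fpkm` (named numeric),
#'   `assigned` and `unassigned` fragment totals.
#' @export
quantify_library <- function(bam, genes, condition, replicate = 1L,
                             library_id = NULL,
                             min_mapq = 10, require_proper_pair = FALSE,
                             mode = c("contained", "overlap")) {
  mode <- match.arg(mode)
  condition <- match.arg(condition, RIP_CONDITIONS)
  if (is.null(library_id)) {
    library_id <- sprintf("%s_rep%d", condition, as.integer(replicate))
  }
  idx <- .transcript_index(genes)
  frags <- .read_fragments(bam)
  n_lib <- length(frags) # distinct primary-mapped query names
  keep <- mcols(frags)$mapq_min >= min_mapq
  if (require_proper_pair) keep <- keep & mcols(frags)$is_proper_pair
  frags <- frags[keep]

  header_chroms <- names(scanBamHeader(bam)[[1L]]$targets)
  regions <- GRanges(
    vapply(genes, `[[`, "", "chrom"),
    IRanges(
      vapply(genes, `[[`, 0L, "region_start"),
      vapply(genes, `[[`, 0L, "region_end")
    )
  )
  missing_chrom <- !as.character(seqnames(regions)) %in% header_chroms
  if (any(missing_chrom)) {
    warning(
      "chromosome(s) absent from BAM header: ",
      paste(unique(as.character(seqnames(regions))[missing_chrom]), collapse = ", ")
    )
  }
  ov <- GenomicRanges::findOverlaps(frags, regions)
  counts <- stats::setNames(integer(nrow(idx)), idx$transcript_id)
  assigned_ids <- character(0)
  for (gi in unique(subjectHits(ov))) {
    g <- genes[[gi]]
    sub <- frags[queryHits(ov)[subjectHits(ov) == gi]]
    a <- assign_fragments(sub, g, mode = mode)
    counts[names(a$counts)] <- a$counts
    assigned_ids <- c(assigned_ids, a$assigned_fragment_ids)
  }
  structure(
    list(
      library_id = library_id,
      condition = condition,
      replicate = as.integer(replicate),
      counts = counts,
      N = n_lib,
      fpkm = if (n_lib > 0L) {
        stats::setNames(fpkm(counts, idx$L, n_lib), names(counts))
      } else {
        counts * 0
      },
      assigned = length(unique(assigned_ids))
    ),
    class = "LibraryQuant"
  )
}

#' @export
print.LibraryQuant <- function(x, ...) {
  cat(sprintf(
    "LibraryQuant %s (%s, replicate %d): N = %d mapped fragments, %d transcripts\n",
    x$library_id, x$condition, x$replicate, x$N, length(x$counts)
  ))
  invisible(x)
}

#' Aggregate replicate libraries of one condition into an FPKM table
#'
#' Per-transcript arithmetic mean of the replicate FPKM values; the
#' individual replicate values are retained. Mixing conditions is an error.
#'
#' @param libs List of `LibraryQuant` objects sharing one condition.
#' @return An `FPKMTable`: `data.frame` with `transcript_id`, `gene_id`, one
#'   `fpkm_rep<k>` column per replicate and `mean_fpkm`; attributes
#'   `condition` and `n_rep`.
#' @param genes The gene models the libraries were quantified against (used
#'   for the `gene_id` column).
#' @export
aggregate_replicates <- function(libs, genes) {
  stopifnot(length(libs) >= 1L)
  conds <- unique(vapply(libs, `[[`, "", "condition"))
  if (length(conds) != 1L) {
    stop("libraries from mixed conditions: ", paste(conds, collapse = ", "))
  }
  idx <- .transcript_index(genes)
  mat <- vapply(libs, function(l) l$fpkm[idx$transcript_id], numeric(nrow(idx)))
  mat <- matrix(mat, nrow = nrow(idx))
  out <- data.frame(
    transcript_id = idx$transcript_id,
    gene_id = idx$gene_id,
    stringsAsFactors = FALSE
  )
  for (k in seq_along(libs)) {
    out[[sprintf("fpkm_rep%d", libs[[k]]$replicate)]] <- mat[, k]
  }
  out$mean_fpkm <- rowMeans(mat)
  attr(out, "condition") <- conds
  attr(out, "n_rep") <- length(libs)
  class(out) <- c("FPKMTable", "data.frame")
  out
}

#' Gene-level FPKM roll-up
#'
#' Collapses a transcript-level `FPKMTable` to one row per gene, taking the
#' maximum mean FPKM over the gene's isoforms -- a reporting convenience for
#' gene-centric summaries; selection and ranking stay transcript-level.
#'
#' @param tab An `FPKMTable` from [aggregate_replicates()].
#' @return `data.frame` with `gene_id`, `mean_fpkm` and `top_transcript_id`.
#' @export
gene_level_fpkm <- function(tab) {
  parts <- split(seq_len(nrow(tab)), tab$gene_id)
  rows <- lapply(parts, function(i) {
    top <- i[which.max(tab$mean_fpkm[i])]
    data.frame(
      gene_id = tab$gene_id[top],
      mean_fpkm = tab$mean_fpkm[top],
      top_transcript_id = tab$transcript_id[top],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an FPKM table as TSV
#'
#' @param tab An `FPKMTable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fpkm_table <- function(tab, path) {
  df <- as.data.frame(tab)
  df$condition <- attr(tab, "condition")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
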