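#' @import methods
#' @importFrom IRanges IRanges reduce width start end disjoin findOverlaps
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<-
NULL

#' Construct a transcript exon model
#'
#' A transcript model is the set of exons of one annotated isoform, stored as
#' a merged (non-overlapping, start-sorted) [IRanges::IRanges] on a single
#' chromosome and strand, together with the exon-model length `L`: the total
#' number of bases in the union of the exons. `L` is the length denominator
#' of FPKM.
#'
#' Overlapping or book-ended exon records are merged, so `L` is well defined
#' regardless of how the annotation splits exons into records.
#'
#' @param transcript_id Transcript identifier.
#' @param gene_id Identifier of the parent gene.
#' @param chrom Chromosome (sequence) name.
#' @param strand `"+"` or `"-"`.
#' @param exons An [IRanges::IRanges] of exon coordinates (1-based, closed),
#'   in any order; overlapping records are merged.
#' @return An object of class `TranscriptModel`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons) {
  stopifnot(length(exons) >= 1L)
  if (any(width(exons) < 1L)) {
    stop("transcript ", transcript_id, ": exon with non-positive width")
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exons <- reduce(exons) # merged and start-sorted
  structure(
    list(
      transcript_id = as.character(transcript_id),
      gene_id = as.character(gene_id),
      chrom = as.character(chrom),
      strand = strand,
      exons = exons,
      L = sum(width(exons))
    ),
    class = "TranscriptModel"
  )
}

#' Construct a gene model from transcript models
#'
#' The gene region is the minimal interval spanning every exon of every
#' isoform; fragment extraction from BAM files is done per gene region.
#'
#' @param gene_id Gene identifier.
#' @param transcripts List of [transcript_model()] objects, all on the same
#'   chromosome and strand.
#' @return An object of class `GeneModel` with fields `gene_id`, `chrom`,
#'   `strand`, `region_start`, `region_end` and `transcripts`.
#' @export
gene_model <- function(gene_id, transcripts) {
  stopifnot(length(transcripts) >= 1L)
  chroms <- unique(vapply(transcripts, `[[`, "", "chrom"))
  strands <- unique(vapply(transcripts, `[[`, "", "strand"))
  if (length(chroms) != 1L) {
    stop("gene ", gene_id, ": transcripts on multiple chromosomes")
  }
  starts <- vapply(transcripts, function(t) min(start(t$exons)), 0L)
  ends <- vapply(transcripts, function(t) max(end(t$exons)), 0L)
  names(transcripts) <- vapply(transcripts, `[[`, "", "transcript_id")
  structure(
    list(
      gene_id = as.character(gene_id),
      chrom = chroms,
      strand = strands[1L],
      region_start = min(starts),
      region_end = max(ends),
      transcripts = transcripts
    ),
    class = "GeneModel"
  )
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf(
    "GeneModel %s  %s:%d-%d (%s)  %d transcript(s)\n",
    x$gene_id, x$chrom, x$region_start, x$region_end, x$strand,
    length(x$transcripts)
  ))
  invisible(x)
}

#' Exon-model length of a transcript
#'
#' Size, in bases, of the union of a transcript's exons -- the "kilobase of
#' exon model" denominator of FPKM (after division by 1000).
#'
#' @param t A `TranscriptModel`.
#' @return Integer number of bases.
#' @export
exon_model_length <- function(t) {
  stopifnot(inherits(t, "TranscriptModel"))
  sum(width(t$exons))
}

#' Per-interval transcript occurrence of a gene's exonic space
#'
#' Partitions the exonic space of a gene into maximal intervals with constant
#' isoform membership and reports, for each interval, the fraction of the
#' gene's annotated transcripts whose exon model contains it. Used to shade
#' exons in coverage figures: constitutive exons are fully opaque, exons
#' private to one of several isoforms are paler.
#'
#' @param g A `GeneModel`.
#' @return A `data.frame` with columns `chrom`, `start`, `end` (1-based,
#'   closed), and `fraction` in (0, 1].
#' @export
exon_occurrence <- function(g) {
  stopifnot(inherits(g, "GeneModel"))
  n_tx <- length(g$transcripts)
  all_exons <- do.call(c, lapply(unname(g$transcripts), `[[`, "exons"))
  pieces <- disjoin(all_exons)
  counts <- integer(length(pieces))
  for (t in g$transcripts) {
    hits <- findOverlaps(pieces, t$exons, type = "within")
    counts[unique(queryHits(hits))] <- counts[unique(queryHits(hits))] + 1L
  }
  # merge adjacent pieces with identical occurrence back into maximal runs
  out <- data.frame(
    chrom = g$chrom,
    start = start(pieces),
    end = end(pieces),
    fraction = counts / n_tx,
    stringsAsFactors = FALSE
  )
  if (nrow(out) > 1L) {
    joinable <- out$start[-1L] == out$end[-nrow(out)] + 1L &
      out$fraction[-1L] == out$fraction[-nrow(out)]
    grp <- cumsum(c(TRUE, !joinable))
    out <- do.call(rbind, lapply(split(out, grp), function(d) {
      data.frame(
        chrom = d$chrom[1L], start = min(d$start), end = max(d$end),
        fraction = d$fraction[1L], stringsAsFactors = FALSE
      )
    }))
    rownames(out) <- NULL
  }
  out
}

## ---- GFF3 I/O ---------------------------------------------------------------

.parse_gff_attributes <- function(attr) {
  fields <- strsplit(attr, ";", fixed = TRUE)
  lapply(fields, function(f) {
    f <- f[nzchar(f)]
    kv <- regmatches(f, regexpr("=", f, fixed = TRUE), invert = TRUE)
    keys <- trimws(vapply(kv, `[[`, "", 1L))
    vals <- vapply(kv, function(x) if (length(x) >= 2L) x[[2L]] else "", "")
    names(vals) <- keys
    vals
  })
}

#' Read gene models from a GFF3 annotation file
#'
#' Parses `gene`, `mRNA`/`transcript` and `exon` features into the
#' [gene_model()] hierarchy. Exons are attached to transcripts through their
#' `Parent` attribute (an exon with several comma-separated parents is
#' attached to each); transcripts are attached to genes through `Parent` or a
#' `gene_id` attribute. All other feature types are ignored. Coordinates are
#' 1-based closed, as in the file.
#'
#' Malformed lines (end < start) and orphan exons whose parent transcript is
#' unknown are skipped with a warning; an annotation yielding no gene is an
#' error.
#'
#' @param path Path to a GFF3 file.
#' @param chrom_alias Optional named character vector mapping annotation
#'   chromosome names to the names used in the alignment files
#'   (e.g. `c("2L" = "chr2L")`).
#' @return Named list of `GeneModel` objects, ordered by chromosome and
#'   region start.
#' @export
read_gff <- function(path, chrom_alias = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no feature lines in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok9 <- lengths(parts) >= 9L
  if (any(!ok9)) {
    warning(sum(!ok9), " line(s) with fewer than 9 fields skipped")
    parts <- parts[ok9]
  }
  tab <- data.frame(
    chrom = vapply(parts, `[[`, "", 1L),
    type = vapply(parts, `[[`, "", 3L),
    start = suppressWarnings(as.integer(vapply(parts, `[[`, "", 4L))),
    end = suppressWarnings(as.integer(vapply(parts, `[[`, "", 5L))),
    strand = vapply(parts, `[[`, "", 7L),
    attr = vapply(parts, `[[`, "", 9L),
    stringsAsFactors = FALSE
  )
  tab <- tab[tab$type %in% c("gene", "mRNA", "transcript", "exon"), ]
  if (nrow(tab) == 0L) stop("no gene/mRNA/exon features in ", path)
  bad <- is.na(tab$start) | is.na(tab$end) | tab$end < tab$start
  if (any(bad)) {
    warning(sum(bad), " feature line(s) with malformed coordinates skipped")
    tab <- tab[!bad, ]
  }
  if (!is.null(chrom_alias)) {
    hit <- tab$chrom %in% names(chrom_alias)
    tab$chrom[hit] <- unname(chrom_alias[tab$chrom[hit]])
  }
  attrs <- .parse_gff_attributes(tab$attr)
  get1 <- function(a, key) if (key %in% names(a)) unname(a[[key]]) else NA_character_

  is_tx <- tab$type %in% c("mRNA", "transcript")
  tx_idx <- which(is_tx)
  tx_id <- vapply(attrs[tx_idx], get1, "", key = "ID")
  tx_parent <- vapply(attrs[tx_idx], function(a) {
    p <- get1(a, "Parent")
    if (is.na(p)) p <- get1(a, "gene_id")
    p
  }, "")
  if (anyNA(tx_id) || any(!nzchar(tx_id))) stop("transcript feature without ID attribute")
  tx_gene <- ifelse(is.na(tx_parent) | !nzchar(tx_parent), tx_id, tx_parent)
  names(tx_gene) <- tx_id
  tx_meta <- data.frame(
    transcript_id = tx_id, gene_id = tx_gene,
    chrom = tab$chrom[tx_idx], strand = tab$strand[tx_idx],
    stringsAsFactors = FALSE
  )

  ex_idx <- which(tab$type == "exon")
  ex_parents <- lapply(attrs[ex_idx], get1, key = "Parent")
  orphan_note <- 0L
  ex_rows <- vector("list", length(ex_idx))
  for (i in seq_along(ex_idx)) {
    p <- ex_parents[[i]]
    if (is.na(p) || !nzchar(p)) {
      orphan_note <- orphan_note + 1L
      next
    }
    ps <- strsplit(p, ",", fixed = TRUE)[[1L]]
    known <- ps %in% tx_meta$transcript_id
    orphan_note <- orphan_note + sum(!known)
    ps <- ps[known]
    if (length(ps)) {
      j <- ex_idx[i]
      ex_rows[[i]] <- data.frame(
        transcript_id = ps, chrom = tab$chrom[j], start = tab$start[j],
        end = tab$end[j], strand = tab$strand[j], stringsAsFactors = FALSE
      )
    }
  }
  if (orphan_note > 0L) {
    warning(orphan_note, " exon attachment(s) with unknown Parent skipped")
  }
  ex <- do.call(rbind, ex_rows)
  if (is.null(ex) || nrow(ex) == 0L) stop("no exon could be attached to a transcript")

  tx_list <- lapply(split(ex, ex$transcript_id), function(d) {
    tid <- d$transcript_id[1L]
    transcript_model(
      transcript_id = tid,
      gene_id = tx_gene[[tid]],
      chrom = d$chrom[1L],
      strand = d$strand[1L],
      exons = IRanges(d$start, d$end)
    )
  })
  genes <- lapply(split(tx_list, vapply(tx_list, `[[`, "", "gene_id")), function(txs) {
    gene_model(txs[[1L]]$gene_id, txs)
  })
  if (length(genes) == 0L) stop("annotation yielded no gene model")
  ord <- order(
    vapply(genes, `[[`, "", "chrom"),
    vapply(genes, `[[`, 0L, "region_start")
  )
  genes[ord]
}

#' Write gene models as GFF3
#'
#' Emits `gene`, `mRNA` and `exon` features with `ID`/`Parent` attributes in
#' the dialect [read_gff()] reads, so that write followed by read reproduces
#' the models. Output is deterministic for a given model list.
#'
#' @param genes Named list of `GeneModel` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (g in genes) {
    lines <- c(lines, sprintf(
      "%s\tripenrich\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      g$chrom, g$region_start, g$region_end, g$strand, g$gene_id
    ))
    for (t in g$transcripts) {
      lines <- c(lines, sprintf(
        "%s\tripenrich\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        t$chrom, min(start(t$exons)), max(end(t$exons)), t$strand,
        t$transcript_id, t$gene_id
      ))
      lines <- c(lines, sprintf(
        "%s\tripenrich\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
        t$chrom, start(t$exons), end(t$exons), t$strand, t$transcript_id
      ))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# flat transcript index over a gene list: one row per transcript
.transcript_index <- function(genes) {
  rows <- lapply(genes, function(g) {
    data.frame(
      transcript_id = vapply(g$transcripts, `[[`, "", "transcript_id"),
      gene_id = g$gene_id,
      L = vapply(g$transcripts, `[[`, 0L, "L"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, unname(rows))
  rownames(out) <- NULL
  out
}
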