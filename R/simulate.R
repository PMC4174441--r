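#' Parameters of the synthetic RIP-Seq experiment
#'
#' Bundles all knobs of the generator: annotation geometry, fragment-length
#' model, sequencing depth, the log-normal transcript abundance
#' distribution, and the enrichment structure (fraction of transcripts that
#' are true antibody targets and the fold by which the IP boosts them in
#' wild-type lysate). The defaults describe the study conditions used
#' throughout the package's benchmarks: about 500 transcripts (250 genes
#' with 1-3 isoforms each), 10% true targets at 4-fold IP enrichment,
#' 200,000 fragments per library, triplicate libraries for the four
#' conditions.
#'
#' @param seed Master seed (mandatory); every stream of randomness in the
#'   generator derives from it.
#' @param n_genes Number of non-overlapping genes.
#' @param isoform_range,exon_range Integer ranges (min, max) for isoforms
#'   per gene and exons per gene locus.
#' @param exon_len_range,intron_len_range,intergenic_range Base-pair ranges.
#' @param frag_len_mean,frag_len_sd Fragment (insert) length model, bases.
#' @param read_len Read length, bases.
#' @param n_fragments Fragments sequenced per library.
#' @param abundance_meanlog,abundance_sdlog Log-normal relative abundance
#'   parameters (natural-log scale).
#' @param target_fraction Fraction of transcripts that are true targets.
#' @param target_fold IP enrichment factor applied to targets in WT IP
#'   libraries (null IP always uses 1).
#' @param replicates Replicates per condition.
#' @param chrom Synthetic chromosome name.
#' @param chrom_len Optional fixed chromosome length; genes that do not fit
#'   raise an error. `NULL` sizes the chromosome to the genes.
#' @return A `SimParams` list.
#' @export
sim_params <- function(seed,
                       n_genes = 250L,
                       isoform_range = c(1L, 3L),
                       exon_range = c(2L, 8L),
                       exon_len_range = c(80L, 400L),
                       intron_len_range = c(60L, 300L),
                       intergenic_range = c(500L, 2000L),
                       frag_len_mean = 250,
                       frag_len_sd = 30,
                       read_len = 75L,
                       n_fragments = 2e5,
                       abundance_meanlog = 0,
                       abundance_sdlog = 1,
                       target_fraction = 0.10,
                       target_fold = 4,
                       replicates = 3L,
                       chrom = "chrS",
                       chrom_len = NULL) {
  if (missing(seed) || is.null(seed)) stop("a master seed is mandatory")
  p <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    isoform_range = as.integer(isoform_range),
    exon_range = as.integer(exon_range),
    exon_len_range = as.integer(exon_len_range),
    intron_len_range = as.integer(intron_len_range),
    intergenic_range = as.integer(intergenic_range),
    frag_len_mean = frag_len_mean, frag_len_sd = frag_len_sd,
    read_len = as.integer(read_len), n_fragments = as.integer(n_fragments),
    abundance_meanlog = abundance_meanlog, abundance_sdlog = abundance_sdlog,
    target_fraction = target_fraction, target_fold = target_fold,
    replicates = as.integer(replicates), chrom = chrom, chrom_len = chrom_len
  )
  stopifnot(
    p$n_genes >= 1L, all(p$isoform_range >= 1L), all(p$exon_range >= 1L),
    all(p$exon_len_range >= 1L), p$read_len >= 1L, p$n_fragments >= 1L,
    p$target_fraction >= 0, p$target_fraction <= 1, p$target_fold >= 0,
    p$frag_len_mean > 0, p$frag_len_sd >= 0, p$replicates >= 1L
  )
  class(p) <- "SimParams"
  p
}

.rint <- function(n, range) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else sample(seq.int(range[1L], range[2L]), n, replace = TRUE)
}

#' Simulate a multi-gene, multi-isoform annotation
#'
#' Places non-overlapping genes along one synthetic chromosome. Each gene
#' locus carries a chain of exons; each isoform is a subset of that chain
#' that always includes a designated anchor exon, so all isoforms of a gene
#' share at least one exon (exercising occurrence shading and ambiguous
#' fragment assignment). The first isoform uses the full chain. Output is
#' deterministic for a fixed seed.
#'
#' @param params A `SimParams` from [sim_params()].
#' @param gff_path Optional path; when given, the models are also written as
#'   GFF3 with [write_gff()].
#' @return Named list of `GeneModel`s (attribute `chrom_len` holds the
#'   chromosome length used).
#' @export
simulate_annotation <- function(params, gff_path = NULL) {
  stopifnot(inherits(params, "SimParams"))
  set.seed(params$seed)
  genes <- vector("list", params$n_genes)
  pos <- 0L
  for (i in seq_len(params$n_genes)) {
    gene_id <- sprintf("G%04d", i)
    n_ex <- .rint(1L, params$exon_range)
    ex_w <- .rint(n_ex, params$exon_len_range)
    in_w <- if (n_ex > 1L) .rint(n_ex - 1L, params$intron_len_range) else integer(0)
    gap <- .rint(1L, params$intergenic_range)
    g_start <- pos + gap + 1L
    ex_starts <- g_start + c(0L, cumsum(ex_w[-n_ex] + in_w))
    exons <- IRanges(ex_starts, width = ex_w)
    strand <- sample(c("+", "-"), 1L)
    k <- .rint(1L, params$isoform_range)
    anchor <- sample.int(n_ex, 1L)
    subsets <- list(seq_len(n_ex))
    tries <- 0L
    while (length(subsets) < k && tries < 50L) {
      tries <- tries + 1L
      keep <- unique(sort(c(anchor, which(stats::runif(n_ex) < 0.7))))
      if (!any(vapply(subsets, identical, TRUE, y = keep))) {
        subsets <- c(subsets, list(keep))
      }
    }
    txs <- lapply(seq_along(subsets), function(j) {
      transcript_model(
        transcript_id = sprintf("%s.T%d", gene_id, j),
        gene_id = gene_id, chrom = params$chrom, strand = strand,
        exons = exons[subsets[[j]]]
      )
    })
    genes[[i]] <- gene_model(gene_id, txs)
    pos <- max(end(exons))
  }
  chrom_len <- pos + params$intergenic_range[2L]
  if (!is.null(params$chrom_len)) {
    if (pos > params$chrom_len) {
      stop("simulated genes (", pos, " bp) do not fit chrom_len = ",
           params$chrom_len)
    }
    chrom_len <- params$chrom_len
  }
  names(genes) <- vapply(genes, `[[`, "", "gene_id")
  attr(genes, "chrom_len") <- as.integer(chrom_len)
  if (!is.null(gff_path)) write_gff(genes, gff_path)
  genes
}

# one row per exon of every transcript chain, in transcript order, with
# global transcript-coordinate offsets so exon lookup is one findInterval
.sim_exon_table <- function(genes) {
  idx <- .transcript_index(genes)
  chains <- unlist(lapply(genes, function(g) {
    lapply(unname(g$transcripts), function(t) {
      data.frame(
        genome_start = start(t$exons), width = width(t$exons),
        stringsAsFactors = FALSE
      )
    })
  }), recursive = FALSE)
  n_ex <- vapply(chains, nrow, 0L)
  tab <- do.call(rbind, chains)
  tab$tx <- rep(seq_len(nrow(idx)), n_ex)
  cum_before <- unlist(lapply(chains, function(d) c(0L, cumsum(d$width))[seq_len(nrow(d))]))
  tab$cum_before <- cum_before
  offset <- c(0L, cumsum(idx$L))[seq_len(nrow(idx))]
  tab$gb_start <- offset[tab$tx] + tab$cum_before
  rownames(tab) <- NULL
  list(idx = idx, exons = tab, offset = offset)
}

# map transcript-coordinate reads to genomic position + CIGAR (M/N ops).
# p_s/p_e are 1-based transcript coordinates, txi the transcript row index.
.map_reads <- function(p_s, p_e, txi, et) {
  gb <- et$exons$gb_start
  gstart <- et$exons$genome_start
  wd <- et$exons$width
  cumb <- et$exons$cum_before
  gp_s <- et$offset[txi] + p_s
  gp_e <- et$offset[txi] + p_e
  ei <- findInterval(gp_s - 1, gb)
  ej <- findInterval(gp_e - 1, gb)
  pos <- gstart[ei] + (p_s - cumb[ei] - 1L)
  gend <- gstart[ej] + (p_e - cumb[ej] - 1L)
  rlen <- p_e - p_s + 1L
  cigar <- character(length(p_s))
  single <- ei == ej
  cigar[single] <- sprintf("%dM", rlen[single])
  if (any(!single)) {
    mi <- which(!single)
    first_m <- (cumb[ei[mi]] + wd[ei[mi]]) - p_s[mi] + 1L
    last_m <- p_e[mi] - cumb[ej[mi]]
    key <- ei[mi] * 100000 + ej[mi]
    uk <- unique(key)
    inner <- vapply(uk, function(k) {
      a <- k %/% 100000
      b <- k %% 100000
      parts <- character(0)
      for (r in a:(b - 1L)) {
        intr <- gstart[r + 1L] - (gstart[r] + wd[r])
        parts <- c(parts, sprintf("%dN", intr))
        if (r + 1L < b) parts <- c(parts, sprintf("%dM", wd[r + 1L]))
      }
      paste(parts, collapse = "")
    }, "")
    cigar[mi] <- paste0(first_m, "M", inner[match(key, uk)], last_m, "M")
  }
  list(pos = pos, end = gend, cigar = cigar)
}

.lib_id <- function(condition, replicate) sprintf("%s_rep%d", condition, replicate)

# simulate one library and write an indexed BAM; returns realized counts
.simulate_library <- function(et, truth, params, condition, replicate,
                              lib_seed, chrom_len, bam_prefix) {
  set.seed(lib_seed)
  idx <- et$idx
  usable <- truth$usable
  w <- truth$abundance * idx$L
  if (condition == "WT_IP") w <- w * truth$rho
  w[!usable] <- 0
  counts <- as.integer(stats::rmultinom(1L, params$n_fragments, w / sum(w)))
  n_frag <- sum(counts)
  txi <- rep(seq_len(nrow(idx)), counts)
  tx_len <- idx$L[txi]
  flen <- as.integer(round(stats::rnorm(n_frag, params$frag_len_mean, params$frag_len_sd)))
  flen <- pmax(params$read_len, pmin(tx_len, flen))
  s <- as.integer(floor(stats::runif(n_frag) * (tx_len - flen + 1))) + 1L
  rl <- params$read_len
  r1 <- .map_reads(s, pmin(s + rl - 1L, tx_len), txi, et)
  r2 <- .map_reads(pmax(s, s + flen - rl), s + flen - 1L, txi, et)
  lib <- .lib_id(condition, replicate)
  # source transcript is encoded in the query name (last _-separated token)
  # so truth-based per-fragment checks are possible downstream
  qname <- sprintf("%s_f%07d_%s", lib, seq_len(n_frag), idx$transcript_id[txi])
  tlen <- r2$end - r1$pos + 1L
  chrom <- params$chrom
  sam1 <- paste(qname, 99L, chrom, r1$pos, 60L, r1$cigar, "=", r2$pos, tlen,
                "*", "*", sep = "\t")
  sam2 <- paste(qname, 147L, chrom, r2$pos, 60L, r2$cigar, "=", r1$pos, -tlen,
                "*", "*", sep = "\t")
  recs <- c(sam1, sam2)
  ord <- order(c(r1$pos, r2$pos), c(qname, qname), c(r1$cigar, r2$cigar),
               method = "radix")
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len),
    sprintf("@RG\tID:%s\tSM:%s", lib, lib)
  )
  sam_path <- paste0(bam_prefix, ".sam")
  writeLines(c(header, recs[ord]), sam_path)
  bam <- asBam(sam_path, bam_prefix, overwrite = TRUE, indexDestination = TRUE)
  unlink(sam_path)
  list(bam = bam, counts = counts)
}

#' Simulate the full RIP-Seq experiment: BAM libraries plus ground truth
#'
#' Draws per-transcript relative abundances from the log-normal model,
#' designates true antibody targets gene-by-gene until the target fraction
#' of transcripts is reached (all isoforms of a gene share target status, as
#' an antibody pulling a gene's mRNA pulls the isoforms sharing the bound
#' region), then samples every library independently: transcript sampling
#' weight `abundance * L * rho` (the enrichment factor `rho` applies only in
#' wild-type IP libraries; null-mutant IP libraries always use 1), fragment
#' counts multinomial at fixed depth, fragment start uniform on the
#' transcript, fragment length normal truncated to `[read_len, L]`. Mates
#' are written as aligned, coordinate-sorted, indexed BAM records with
#' splice-aware (M/N) CIGARs mapped through the exon chain. Transcripts
#' shorter than the read length are excluded from sampling with a warning.
#' Each library uses a seed derived from the master seed, so the full output
#' (truth table included) is byte-reproducible.
#'
#' @param genes Annotation from [simulate_annotation()].
#' @param params The same `SimParams`.
#' @param outdir Output directory (created if needed).
#' @param conditions Conditions to simulate (default all four).
#' @return List with `manifest` (`data.frame`: `path`, `condition`,
#'   `replicate`), `truth` (`data.frame` with abundance, rho, is_target and
#'   realized per-library counts), `truth_path`, and `metadata_path`.
#' @export
simulate_experiment <- function(genes, params, outdir,
                                conditions = RIP_CONDITIONS) {
  stopifnot(inherits(params, "SimParams"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  et <- .sim_exon_table(genes)
  idx <- et$idx
  n_tx <- nrow(idx)
  chrom_len <- attr(genes, "chrom_len")
  if (is.null(chrom_len)) {
    chrom_len <- max(vapply(genes, `[[`, 0L, "region_end")) +
      params$intergenic_range[2L]
  }

  set.seed(params$seed + 7L)
  abundance <- stats::rlnorm(n_tx, params$abundance_meanlog, params$abundance_sdlog)
  n_target <- ceiling(params$target_fraction * n_tx)
  gene_order <- sample(unique(idx$gene_id))
  is_target <- logical(n_tx)
  for (gid in gene_order) {
    if (sum(is_target) >= n_target) break
    is_target[idx$gene_id == gid] <- TRUE
  }
  rho <- ifelse(is_target, params$target_fold, 1)
  usable <- idx$L >= params$read_len
  if (any(!usable)) {
    warning(sum(!usable), " transcript(s) shorter than the read length excluded")
  }
  truth <- list(abundance = abundance, rho = rho, usable = usable)

  truth_df <- data.frame(
    transcript_id = idx$transcript_id,
    gene_id = idx$gene_id,
    L = idx$L,
    abundance = abundance,
    rho = rho,
    is_target = is_target,
    excluded = !usable,
    stringsAsFactors = FALSE
  )

  manifest <- NULL
  lib_index <- 0L
  for (cond in conditions) {
    for (rep_k in seq_len(params$replicates)) {
      lib_index <- lib_index + 1L
      lib_seed <- (params$seed + 101L * lib_index) %% 2147483647L
      prefix <- file.path(outdir, .lib_id(cond, rep_k))
      res <- .simulate_library(
        et, truth, params, cond, rep_k, lib_seed, chrom_len, prefix
      )
      truth_df[[sprintf("count_%s_rep%d", cond, rep_k)]] <- res$counts
      manifest <- rbind(manifest, data.frame(
        path = res$bam, condition = cond, replicate = rep_k,
        stringsAsFactors = FALSE
      ))
    }
  }

  truth_path <- file.path(outdir, "truth.tsv")
  fmt <- truth_df
  fmt$abundance <- sprintf("%.10g", fmt$abundance)
  fmt$rho <- sprintf("%.6g", fmt$rho)
  utils::write.table(fmt, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)

  metadata_path <- file.path(outdir, "sim_metadata.yaml")
  meta <- unclass(params)
  meta$chrom_len <- as.integer(chrom_len)
  meta$conditions <- conditions
  meta$n_transcripts <- n_tx
  meta$n_target_transcripts <- sum(is_target)
  yaml::write_yaml(meta, metadata_path)

  list(
    manifest = manifest, truth = truth_df,
    truth_path = truth_path, metadata_path = metadata_path
  )
}

#' Simulate annotation plus experiment in one call
#'
#' Convenience wrapper: [simulate_annotation()] (writing `annotation.gff3`
#' into `outdir`) followed by [simulate_experiment()].
#'
#' @param params A `SimParams`.
#' @param outdir Output directory.
#' @param conditions Conditions to simulate.
#' @return As [simulate_experiment()], plus `genes` and `gff_path`.
#' @export
simulate_dataset <- function(params, outdir, conditions = RIP_CONDITIONS) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  gff_path <- file.path(outdir, "annotation.gff3")
  genes <- simulate_annotation(params, gff_path = gff_path)
  out <- simulate_experiment(genes, params, outdir, conditions = conditions)
  out$genes <- genes
  out$gff_path <- gff_path
  out
}
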