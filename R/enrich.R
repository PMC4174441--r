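#' Log2 IP-versus-input enrichment
#'
#' `log2((fpkm_ip + eps) / (fpkm_ref + eps))`. The pseudocount `eps` keeps
#' the ratio finite for transcripts absent from one library; with `eps = 0`
#' both values must be positive.
#'
#' @param fpkm_ip IP-library FPKM value(s), >= 0.
#' @param fpkm_ref Reference (input/total) FPKM value(s), >= 0.
#' @param eps Pseudocount in FPKM units (default 0.1).
#' @return Log2 enrichment value(s).
#' @export
log2_enrichment <- function(fpkm_ip, fpkm_ref, eps = 0.1) {
  if (any(fpkm_ip < 0) || any(fpkm_ref < 0)) stop("FPKM values must be >= 0")
  if (eps < 0) stop("eps must be >= 0")
  if (eps == 0 && any(fpkm_ip == 0 | fpkm_ref == 0)) {
    stop("eps must be > 0 when an FPKM value is 0")
  }
  log2((fpkm_ip + eps) / (fpkm_ref + eps))
}

#' Build the per-transcript enrichment table with the dual filter
#'
#' For every transcript, computes the wild-type IP enrichment
#' `E_wt = log2_enrichment(WT_IP, WT_TOTAL)` and the null-mutant IP
#' enrichment `E_null` (against `WT_TOTAL` by default, or `NULL_TOTAL` when
#' supplied and `null_ref = "NULL_TOTAL"`), then applies three filters:
#' an abundance floor (mean `WT_TOTAL` FPKM >= `floor`, so that enrichment is
#' only called on transcripts with a substantial number of input reads), the
#' wild-type enrichment cutoff `E_wt >= cutoff`, and the null-specificity
#' filter `E_null < cutoff` (a transcript also enriched when the antibody
#' has no target protein to bind is nonspecific). `selected` is the
#' conjunction of the three.
#'
#' @param wt_ip,wt_total,null_ip `FPKMTable`s from [aggregate_replicates()]
#'   for the three required conditions; identical transcript universe.
#' @param null_total Optional `FPKMTable` for the null-mutant total.
#' @param eps Pseudocount passed to [log2_enrichment()] (default 0.1 FPKM).
#' @param floor Minimum mean `WT_TOTAL` FPKM (default 1).
#' @param cutoff Log2 enrichment cutoff (default 1).
#' @param null_ref Denominator for `E_null`: `"WT_TOTAL"` (default) or
#'   `"NULL_TOTAL"`.
#' @return A `data.frame` of enrichment records with columns
#'   `transcript_id`, `gene_id`, `fpkm_wt_ip`, `fpkm_wt_total`,
#'   `fpkm_null_ip`, `E_wt`, `E_null`, `passes_floor`, `passes_wt`,
#'   `passes_null`, `selected`; attributes record `eps`, `floor`, `cutoff`.
#' @export
build_enrichment_table <- function(wt_ip, wt_total, null_ip, null_total = NULL,
                                   eps = 0.1, floor = 1, cutoff = 1,
                                   null_ref = c("WT_TOTAL", "NULL_TOTAL")) {
  null_ref <- match.arg(null_ref)
  ids <- wt_total$transcript_id
  check_universe <- function(tab, what) {
    if (!setequal(tab$transcript_id, ids) || nrow(tab) != length(ids)) {
      offenders <- c(
        setdiff(ids, tab$transcript_id),
        setdiff(tab$transcript_id, ids)
      )
      stop(
        "transcript universe mismatch in ", what, ": ",
        paste(utils::head(offenders, 10L), collapse = ", ")
      )
    }
  }
  check_universe(wt_ip, "WT_IP")
  check_universe(null_ip, "NULL_IP")
  if (null_ref == "NULL_TOTAL" && is.null(null_total)) {
    stop("null_ref = 'NULL_TOTAL' but no NULL_TOTAL table supplied")
  }
  if (!is.null(null_total)) check_universe(null_total, "NULL_TOTAL")

  align <- function(tab) tab$mean_fpkm[match(ids, tab$transcript_id)]
  v_ip <- align(wt_ip)
  v_tot <- align(wt_total)
  v_nip <- align(null_ip)
  v_nref <- if (null_ref == "NULL_TOTAL") align(null_total) else v_tot

  e_wt <- log2_enrichment(v_ip, v_tot, eps)
  e_null <- log2_enrichment(v_nip, v_nref, eps)
  rec <- data.frame(
    transcript_id = ids,
    gene_id = wt_total$gene_id[match(ids, wt_total$transcript_id)],
    fpkm_wt_ip = v_ip,
    fpkm_wt_total = v_tot,
    fpkm_null_ip = v_nip,
    E_wt = e_wt,
    E_null = e_null,
    passes_floor = v_tot >= floor,
    passes_wt = e_wt >= cutoff,
    passes_null = e_null < cutoff,
    stringsAsFactors = FALSE
  )
  if (!is.null(null_total)) rec$fpkm_null_total <- align(null_total)
  rec$selected <- rec$passes_floor & rec$passes_wt & rec$passes_null
  attr(rec, "eps") <- eps
  attr(rec, "floor") <- floor
  attr(rec, "cutoff") <- cutoff
  attr(rec, "null_ref") <- null_ref
  rec
}

#' Ranked table of selected transcripts
#'
#' Keeps the records passing all filters, sorts them by decreasing wild-type
#' enrichment (ties broken by transcript id), and prepends a 1..n `rank`
#' column. Re-running on identical input gives byte-identical output.
#'
#' @param records Output of [build_enrichment_table()].
#' @param path Optional TSV output path.
#' @return The ranked `data.frame` (written to `path` when given).
#' @export
rank_table <- function(records, path = NULL) {
  sel <- records[records$selected, , drop = FALSE]
  ord <- order(-sel$E_wt, sel$transcript_id, method = "radix")
  sel <- sel[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(sel)), sel)
  rownames(out) <- NULL
  if (!is.null(path)) {
    num <- vapply(out, is.double, TRUE)
    fmt <- out
    fmt[num] <- lapply(fmt[num], function(x) sprintf("%.6g", x))
    utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Scatter data for the IP-versus-input enrichment plot
#'
#' One point per transcript detected in either the IP or the input library:
#' log2 mean FPKM in the input (x) against log2 mean FPKM in the IP (y), with
#' the enrichment class used for coloring (`">=1"` when `E_wt >= 1`, the
#' boundary included in the enriched class, else `"<1"`).
#'
#' @param records Output of [build_enrichment_table()].
#' @return `data.frame` with `transcript_id`, `log2_fpkm_wt_total`,
#'   `log2_fpkm_wt_ip`, `enriched_class`.
#' @export
enrichment_scatter <- function(records) {
  eps <- attr(records, "eps")
  if (is.null(eps) || eps <= 0) eps <- 0.1
  keep <- records$fpkm_wt_ip > 0 | records$fpkm_wt_total > 0
  r <- records[keep, , drop = FALSE]
  data.frame(
    transcript_id = r$transcript_id,
    log2_fpkm_wt_total = log2(r$fpkm_wt_total + eps),
    log2_fpkm_wt_ip = log2(r$fpkm_wt_ip + eps),
    enriched_class = ifelse(r$E_wt >= 1, ">=1", "<1"),
    stringsAsFactors = FALSE
  )
}
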