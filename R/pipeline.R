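#' Read a library manifest
#'
#' A manifest maps each BAM library to its condition and replicate: TSV with
#' header `path  condition  replicate`.
#'
#' @param path Manifest TSV path.
#' @return `data.frame` with `path`, `condition`, `replicate`.
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("path", "condition", "replicate")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  m
}

.validate_manifest <- function(manifest, required = c("WT_IP", "WT_TOTAL", "NULL_IP")) {
  bad_cond <- setdiff(unique(manifest$condition), RIP_CONDITIONS)
  if (length(bad_cond)) {
    stop("unknown condition(s) in manifest: ", paste(bad_cond, collapse = ", "))
  }
  missing <- setdiff(required, unique(manifest$condition))
  if (length(missing)) {
    stop("manifest missing required condition(s): ", paste(missing, collapse = ", "))
  }
  dup <- duplicated(manifest[c("condition", "replicate")])
  if (any(dup)) {
    stop("duplicate (condition, replicate) label(s) in manifest")
  }
  absent <- !file.exists(manifest$path)
  if (any(absent)) {
    stop("BAM file(s) not found: ", paste(manifest$path[absent], collapse = ", "))
  }
  invisible(manifest)
}

#' Run the full RIP-Seq enrichment pipeline
#'
#' Orchestrates quantification, enrichment and plotting from a single run
#' configuration: quantifies every library in the manifest, aggregates
#' replicates per condition, builds the enrichment table with the dual
#' wild-type/null filter, writes `ranked_table.tsv`, `scatter.tsv` and a
#' `run_metadata.yaml` sidecar (parameters plus input checksums) into
#' `outdir`, and renders coverage SVGs for the requested genes from the
#' wild-type IP replicates. Manifest problems (a missing required
#' condition, duplicate replicate labels, absent files) abort before any
#' computation; a failure while plotting one gene is a warning, not fatal.
#'
#' @param config A list or YAML file path with fields `gff`, `manifest`
#'   (path or `data.frame`), `outdir`, and optionally `min_mapq` (10),
#'   `require_proper_pair` (FALSE), `mode` ("contained"), `eps` (0.1),
#'   `floor` (1), `cutoff` (1), `null_ref` ("WT_TOTAL"), `plot_genes`
#'   (character vector), `chrom_alias` (named vector).
#' @return List with `genes`, `libraries`, `tables` (per-condition FPKM
#'   tables), `records`, `ranked`, `scatter` and output `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    min_mapq = 10, require_proper_pair = FALSE, mode = "contained",
    eps = 0.1, floor = 1, cutoff = 1, null_ref = "WT_TOTAL",
    plot_genes = character(0), chrom_alias = NULL
  )
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  for (k in c("gff", "manifest", "outdir")) {
    if (is.null(config[[k]])) stop("config field '", k, "' is required")
  }
  manifest <- if (is.data.frame(config$manifest)) {
    config$manifest
  } else {
    read_manifest(config$manifest)
  }
  required <- c("WT_IP", "WT_TOTAL", "NULL_IP")
  if (config$null_ref == "NULL_TOTAL") required <- c(required, "NULL_TOTAL")
  .validate_manifest(manifest, required)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  alias <- config$chrom_alias
  if (!is.null(alias)) alias <- unlist(alias)
  genes <- read_gff(config$gff, chrom_alias = alias)

  libs <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    libs[[i]] <- quantify_library(
      manifest$path[i], genes,
      condition = manifest$condition[i],
      replicate = manifest$replicate[i],
      min_mapq = config$min_mapq,
      require_proper_pair = config$require_proper_pair,
      mode = config$mode
    )
  }
  conds <- vapply(libs, `[[`, "", "condition")
  tables <- lapply(split(libs, conds), aggregate_replicates, genes = genes)

  records <- build_enrichment_table(
    wt_ip = tables$WT_IP, wt_total = tables$WT_TOTAL,
    null_ip = tables$NULL_IP, null_total = tables$NULL_TOTAL,
    eps = config$eps, floor = config$floor, cutoff = config$cutoff,
    null_ref = config$null_ref
  )
  ranked_path <- file.path(config$outdir, "ranked_table.tsv")
  ranked <- rank_table(records, path = ranked_path)
  scatter <- enrichment_scatter(records)
  scatter_path <- file.path(config$outdir, "scatter.tsv")
  utils::write.table(
    within(scatter, {
      log2_fpkm_wt_total <- sprintf("%.6g", log2_fpkm_wt_total)
      log2_fpkm_wt_ip <- sprintf("%.6g", log2_fpkm_wt_ip)
    }),
    scatter_path, sep = "\t", quote = FALSE, row.names = FALSE
  )

  plot_paths <- character(0)
  if (length(config$plot_genes)) {
    plot_dir <- file.path(config$outdir, "plots")
    dir.create(plot_dir, showWarnings = FALSE)
    wt_ip_rows <- which(manifest$condition == "WT_IP")
    wt_ip_rows <- wt_ip_rows[order(manifest$replicate[wt_ip_rows])]
    wt_ip_rows <- utils::head(wt_ip_rows, 3L)
    for (gid in config$plot_genes) {
      p <- tryCatch({
        g <- genes[[gid]]
        if (is.null(g)) stop("gene ", gid, " not in annotation")
        profiles <- lapply(wt_ip_rows, function(i) {
          fr <- extract_gene_fragments(
            manifest$path[i], g,
            min_mapq = config$min_mapq,
            require_proper_pair = config$require_proper_pair
          )
          coverage_profile(fr, g, library_id = .lib_id(
            manifest$condition[i], manifest$replicate[i]
          ))
        })
        out_svg <- file.path(plot_dir, paste0(gid, ".svg"))
        render_coverage_svg(g, profiles, exon_occurrence(g), out_svg)
        out_svg
      }, error = function(e) {
        warning("plotting ", gid, " failed: ", conditionMessage(e))
        NA_character_
      })
      plot_paths <- c(plot_paths, p)
    }
  }

  meta_path <- file.path(config$outdir, "run_metadata.yaml")
  yaml::write_yaml(list(
    package = "ripenrich",
    version = as.character(utils::packageVersion("ripenrich")),
    parameters = list(
      min_mapq = config$min_mapq,
      require_proper_pair = config$require_proper_pair,
      mode = config$mode, eps = config$eps, floor = config$floor,
      cutoff = config$cutoff, null_ref = config$null_ref
    ),
    inputs = list(
      gff = unname(config$gff),
      gff_md5 = unname(tools::md5sum(config$gff)),
      libraries = lapply(seq_len(nrow(manifest)), function(i) list(
        path = manifest$path[i],
        condition = manifest$condition[i],
        replicate = manifest$replicate[i],
        md5 = unname(tools::md5sum(manifest$path[i]))
      ))
    ),
    n_selected = nrow(ranked)
  ), meta_path)

  list(
    genes = genes, libraries = libs, tables = tables, records = records,
    ranked = ranked, scatter = scatter,
    paths = list(
      ranked_table = ranked_path, scatter = scatter_path,
      metadata = meta_path, plots = plot_paths
    )
  )
}

#' Per-library summary statistics
#'
#' One row per BAM: total alignment records, mapped fragments (the FPKM
#' denominator `N`), fragments assigned to at least one transcript, and
#' mapped-but-unassigned fragments.
#'
#' @param bams Character vector of BAM paths.
#' @param genes Gene models from [read_gff()].
#' @param ... Passed to [quantify_library()] (`min_mapq`, `mode`, ...).
#' @return `data.frame` with `path`, `total_records`, `mapped_fragments`,
#'   `assigned_fragments`, `unassigned_fragments`.
#' @export
library_stats <- function(bams, genes, ...) {
  rows <- lapply(bams, function(b) {
    total <- Rsamtools::countBam(b)$records
    lq <- quantify_library(b, genes, condition = "WT_IP", ...)
    data.frame(
      path = b,
      total_records = total,
      mapped_fragments = lq$N,
      assigned_fragments = lq$assigned,
      unassigned_fragments = lq$N - lq$assigned,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
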