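#' Per-base fragment coverage over a gene region
#'
#' Depth at base i is the number of fragments with at least one aligned
#' block covering i. Because a fragment's blocks are the merged union of its
#' two mates, bases covered by both mates count once (fragment coverage, the
#' same unit used for counting).
#'
#' @param frags Fragments from [extract_gene_fragments()].
#' @param g A `GeneModel`, or a list with `chrom`, `region_start`,
#'   `region_end` describing the region.
#' @param library_id Label stored in the profile.
#' @return A `CoverageProfile`: list with `gene_id`, `library_id`, `chrom`,
#'   `start`, `end` and `depth`, an integer vector of length
#'   `end - start + 1`.
#' @export
coverage_profile <- function(frags, g, library_id = NA_character_) {
  chrom <- g$chrom
  from <- g$region_start
  to <- g$region_end
  ub <- unlist(frags, use.names = FALSE)
  ub <- ub[as.character(seqnames(ub)) == chrom]
  if (length(ub) == 0L) {
    depth <- integer(to - from + 1L)
  } else {
    cov <- IRanges::coverage(IRanges::ranges(ub), width = max(to, max(end(ub))))
    depth <- as.integer(S4Vectors::window(cov, start = from, end = to))
  }
  structure(
    list(
      gene_id = if (!is.null(g$gene_id)) g$gene_id else NA_character_,
      library_id = library_id,
      chrom = chrom, start = from, end = to, depth = depth
    ),
    class = "CoverageProfile"
  )
}

# step-function vertices (x in base coords, y in depth) from a depth vector;
# run-length encoded so flat stretches contribute two points, not one per base
.depth_steps <- function(depth, from) {
  r <- rle(depth)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  x <- as.vector(rbind(from + starts - 1L, from + ends - 1L))
  y <- as.vector(rbind(r$values, r$values))
  list(x = x, y = y)
}

.svg_num <- function(x) sprintf("%.2f", x)

#' Render a gene's coverage figure as SVG
#'
#' Draws up to three replicate coverage tracks as overlaid step polylines in
#' the fixed color order red, green, blue, above the gene model: one
#' rectangle per constant-occurrence exonic interval with opacity equal to
#' the fraction of isoforms containing it, introns as a connector line, and
#' genomic coordinate labels. The vertical scale is shared across the
#' replicates (common maximum) so tracks are comparable. Output bytes are
#' deterministic for fixed input.
#'
#' @param g A `GeneModel`.
#' @param profiles List of 1-3 `CoverageProfile`s (replicates, plotted in
#'   the given order).
#' @param occ Occurrence intervals from [exon_occurrence()].
#' @param path Output `.svg` path.
#' @param width,height Image size in pixels.
#' @param colors Track colors, default `c("red", "green", "blue")`.
#' @return `path`, invisibly.
#' @export
render_coverage_svg <- function(g, profiles, occ, path,
                                width = 1000, height = 320,
                                colors = c("red", "green", "blue")) {
  stopifnot(inherits(g, "GeneModel"))
  if (inherits(profiles, "CoverageProfile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1L, length(profiles) <= 3L)
  from <- g$region_start
  to <- g$region_end
  span <- to - from + 1L
  margin <- 45
  panel_w <- width - 2 * margin
  model_h <- 40
  axis_h <- 25
  panel_h <- height - model_h - axis_h - 2 * margin / 3
  ymax <- max(1L, vapply(profiles, function(p) max(p$depth), 0L))
  xpos <- function(b) margin + (b - from) / max(1L, span - 1L) * panel_w
  ypos <- function(d) margin / 3 + panel_h * (1 - d / ymax)

  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(
      "<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%d\" height=\"%d\" viewBox=\"0 0 %d %d\">",
      as.integer(width), as.integer(height), as.integer(width), as.integer(height)
    ),
    sprintf("<title>%s coverage</title>", g$gene_id),
    sprintf(
      "<rect x=\"0\" y=\"0\" width=\"%d\" height=\"%d\" fill=\"white\"/>",
      as.integer(width), as.integer(height)
    )
  )
  # replicate tracks, fixed color order
  for (k in seq_along(profiles)) {
    p <- profiles[[k]]
    st <- .depth_steps(p$depth, p$start)
    pts <- paste(
      paste0(.svg_num(xpos(st$x)), ",", .svg_num(ypos(st$y))),
      collapse = " "
    )
    out <- c(out, sprintf(
      "<polyline class=\"coverage-track\" data-replicate=\"%d\" fill=\"none\" stroke=\"%s\" stroke-width=\"1\" points=\"%s\"/>",
      k, colors[k], pts
    ))
  }
  # y axis: max depth
  out <- c(out, sprintf(
    "<text x=\"%s\" y=\"%s\" font-size=\"11\" text-anchor=\"end\">%d</text>",
    .svg_num(margin - 5), .svg_num(ypos(ymax) + 4), ymax
  ))
  out <- c(out, sprintf(
    "<text x=\"%s\" y=\"%s\" font-size=\"11\" text-anchor=\"end\">0</text>",
    .svg_num(margin - 5), .svg_num(ypos(0) + 4)
  ))
  # gene model: intron connector + occurrence-shaded exon rectangles
  model_y <- margin / 3 + panel_h + 18
  out <- c(out, sprintf(
    "<line class=\"intron\" x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"black\" stroke-width=\"1\"/>",
    .svg_num(xpos(from)), .svg_num(model_y + 7),
    .svg_num(xpos(to)), .svg_num(model_y + 7)
  ))
  for (i in seq_len(nrow(occ))) {
    out <- c(out, sprintf(
      "<rect class=\"exon\" x=\"%s\" y=\"%s\" width=\"%s\" height=\"14\" fill=\"black\" fill-opacity=\"%s\"/>",
      .svg_num(xpos(occ$start[i])),
      .svg_num(model_y),
      .svg_num(pmax(0.5, xpos(occ$end[i]) - xpos(occ$start[i]))),
      sprintf("%.3f", occ$fraction[i])
    ))
  }
  # x axis labels: genomic coordinates
  axis_y <- model_y + model_h
  out <- c(out, sprintf(
    "<text x=\"%s\" y=\"%s\" font-size=\"11\" text-anchor=\"start\">%s:%d</text>",
    .svg_num(margin), .svg_num(axis_y), g$chrom, from
  ))
  out <- c(out, sprintf(
    "<text x=\"%s\" y=\"%s\" font-size=\"11\" text-anchor=\"end\">%d</text>",
    .svg_num(margin + panel_w), .svg_num(axis_y), to
  ))
  out <- c(out, sprintf(
    "<text x=\"%s\" y=\"%s\" font-size=\"12\" text-anchor=\"middle\" font-style=\"italic\">%s</text>",
    .svg_num(margin + panel_w / 2), .svg_num(axis_y), g$gene_id
  ))
  out <- c(out, "</svg>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
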