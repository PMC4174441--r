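#' Mean and SD of replicate Ct values
#'
#' Quantification uses the mean of the technical replicate Ct values of one
#' (sample, target) well group; the SD is reported alongside when at least
#' two replicates are present.
#'
#' @param replicates Numeric vector of Ct values (amplification cycles).
#' @return List with `mean`, `sd` (`NA` for a single value) and `n`.
#' @export
mean_ct <- function(replicates) {
  replicates <- replicates[!is.na(replicates)]
  if (length(replicates) == 0L) stop("no Ct replicate values")
  if (any(replicates <= 0)) stop("Ct values must be positive")
  list(
    mean = mean(replicates),
    sd = if (length(replicates) >= 2L) stats::sd(replicates) else NA_real_,
    n = length(replicates)
  )
}

#' Relative expression by the 2^-ddCt method
#'
#' Normalizes the target's Ct to a reference transcript measured in the same
#' sample (dCt), then to the control sample (ddCt), and converts cycles to
#' fold change assuming doubling per cycle:
#' `ddCt = (ct_target_sample - ct_ref_sample) - (ct_target_control -
#' ct_ref_control)`, fold change `2^-ddCt`.
#'
#' @param ct_target_sample Target Ct in the sample of interest.
#' @param ct_ref_sample Reference-transcript Ct in the same sample.
#' @param ct_target_control Target Ct in the control sample.
#' @param ct_ref_control Reference-transcript Ct in the control sample.
#' @return Fold change relative to the control sample.
#' @export
ddct_fold_change <- function(ct_target_sample, ct_ref_sample,
                             ct_target_control, ct_ref_control) {
  stopifnot(
    is.finite(ct_target_sample), is.finite(ct_ref_sample),
    is.finite(ct_target_control), is.finite(ct_ref_control)
  )
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}

#' RIP-qPCR recovery as percent of input
#'
#' Expresses the IP signal as a percentage of the total input RNA. The input
#' reaction uses only a fraction `f` of the material (e.g. a 10% aliquot),
#' so the input Ct is first adjusted by `-log2(1/f)` cycles to represent
#' 100% input; recovery is then `100 * 2^(ct_input_adj - ct_ip)`, i.e.
#' `100 * f * 2^(ct_input - ct_ip)`.
#'
#' @param ct_ip Ct of the immunoprecipitated sample.
#' @param ct_input Ct of the input aliquot.
#' @param input_fraction Fraction of total RNA in the input reaction, in
#'   (0, 1] (default 0.10).
#' @return Percent of input recovered (vectorized).
#' @export
percent_input <- function(ct_ip, ct_input, input_fraction = 0.10) {
  if (any(input_fraction <= 0) || any(input_fraction > 1)) {
    stop("input_fraction must be in (0, 1]")
  }
  stopifnot(all(is.finite(ct_ip)), all(is.finite(ct_input)))
  100 * input_fraction * 2^(ct_input - ct_ip)
}

#' Read a Ct table from TSV
#'
#' Expected columns: `sample_id`, `target_id`, then one column per technical
#' replicate (`ct1`, `ct2`, ...). Missing wells may be `NA`.
#'
#' @param path TSV path.
#' @return `data.frame` with `sample_id`, `target_id` and Ct replicate
#'   columns.
#' @export
read_ct_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "target_id")
  if (!all(need %in% names(tab))) {
    stop("Ct table must have columns sample_id, target_id, ct1..")
  }
  ct_cols <- grep("^ct", names(tab), value = TRUE)
  if (length(ct_cols) == 0L) stop("no ct columns in ", path)
  tab
}

.ct_means <- function(ct_table) {
  ct_cols <- grep("^ct", names(ct_table), value = TRUE)
  means <- apply(as.matrix(ct_table[ct_cols]), 1L, function(x) mean_ct(x)$mean)
  data.frame(
    sample_id = ct_table$sample_id,
    target_id = ct_table$target_id,
    ct = means,
    stringsAsFactors = FALSE
  )
}

.lookup_ct <- function(m, sample, target) {
  hit <- m$ct[m$sample_id == sample & m$target_id == target]
  if (length(hit) != 1L) {
    stop("expected one Ct group for (", sample, ", ", target, "), found ",
         length(hit))
  }
  hit
}

#' Table-level 2^-ddCt quantification
#'
#' Applies [ddct_fold_change()] to every (sample, target) of a Ct table,
#' using the mean of technical replicates, a reference transcript measured
#' in every sample, and a designated control sample. The reference target's
#' own rows and the control sample are reported too (fold change 1 for the
#' control by construction).
#'
#' @param ct_table From [read_ct_table()].
#' @param control_sample Sample id used as the calibrator.
#' @param reference_target Target id of the normalizer transcript.
#' @return `data.frame` with `sample_id`, `target_id`, `fold_change`.
#' @export
qpcr_ddct <- function(ct_table, control_sample, reference_target) {
  m <- .ct_means(ct_table)
  if (!control_sample %in% m$sample_id) {
    stop("control sample ", control_sample, " absent from table")
  }
  if (!reference_target %in% m$target_id) {
    stop("reference target ", reference_target, " absent from table")
  }
  rows <- m[m$target_id != reference_target, , drop = FALSE]
  fc <- mapply(function(s, t) {
    ddct_fold_change(
      .lookup_ct(m, s, t),
      .lookup_ct(m, s, reference_target),
      .lookup_ct(m, control_sample, t),
      .lookup_ct(m, control_sample, reference_target)
    )
  }, rows$sample_id, rows$target_id)
  data.frame(
    sample_id = rows$sample_id,
    target_id = rows$target_id,
    fold_change = unname(fc),
    stringsAsFactors = FALSE
  )
}

#' Table-level percent-input quantification for RIP-qPCR
#'
#' Applies [percent_input()] per target, pairing an IP sample with the input
#' sample of the same experiment. When several Ct tables (independent
#' experiments) are given, per-target mean and SD across experiments are
#' added.
#'
#' @param ct_tables One Ct table or a list of them (one per experiment).
#' @param ip_sample,input_sample Sample ids of the IP and the input aliquot.
#' @param input_fraction Input aliquot fraction, default 0.10.
#' @return `data.frame` with `experiment`, `target_id`, `percent_input`,
#'   plus `mean_percent_input` and `sd_percent_input` per target.
#' @export
qpcr_percent_input <- function(ct_tables, ip_sample = "IP",
                               input_sample = "INPUT",
                               input_fraction = 0.10) {
  if (is.data.frame(ct_tables)) ct_tables <- list(ct_tables)
  per_exp <- lapply(seq_along(ct_tables), function(i) {
    m <- .ct_means(ct_tables[[i]])
    targets <- sort(unique(m$target_id))
    pin <- vapply(targets, function(t) {
      percent_input(
        .lookup_ct(m, ip_sample, t),
        .lookup_ct(m, input_sample, t),
        input_fraction
      )
    }, 0)
    data.frame(
      experiment = i, target_id = targets, percent_input = unname(pin),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, per_exp)
  agg_m <- tapply(out$percent_input, out$target_id, mean)
  agg_s <- tapply(out$percent_input, out$target_id, stats::sd)
  out$mean_percent_input <- as.numeric(agg_m[out$target_id])
  out$sd_percent_input <- as.numeric(agg_s[out$target_id])
  out
}
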