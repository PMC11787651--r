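# Replicate QC: peptide ratios, coefficient-of-variation statistics,
# identification counts, and the summary tables mirroring standard
# histone-platform QC figures.

#' Peptide ratios within each backbone region
#'
#' The ratio of one modified form is its (post-split) area divided by the
#' summed areas of all searched forms sharing the same peptide backbone
#' region, charge states combined. Undetected forms contribute zero area
#' and get ratio 0; the denominator uses all searched forms by default
#' (\code{observed_only = TRUE} restricts it to detected forms).
#'
#' @param qt a \code{quant_table} from [quantify_run()].
#' @param observed_only restrict the denominator to detected forms.
#' @return the table with a \code{region} and a \code{ratio} column; an
#'   all-zero region gets NA ratios and \code{region_flagged = TRUE}.
#' @export
peptide_ratio <- function(qt, observed_only = FALSE) {
  qt$region <- paste0(qt$protein, "_", qt$start, "-", qt$end)
  agg <- tapply(ifelse(observed_only & !qt$detected, NA, qt$area),
                qt$region, sum, na.rm = TRUE)
  # areas of the same form at several charge states combine first
  fsum <- tapply(qt$area, qt$form_id, sum)
  rsum <- as.numeric(agg[qt$region])
  qt$ratio <- as.numeric(ifelse(rsum > 0, fsum[qt$form_id] / rsum,
                                NA_real_))
  qt$region_flagged <- rsum <= 0
  qt
}

#' Coefficient of variation, percent
#'
#' 100 times the sample standard deviation (n - 1 denominator) over the
#' mean.
#'
#' @param values numeric vector, length >= 2.
#' @return CV in percent.
#' @export
cv_percent <- function(values) {
  if (length(values) < 2) stop("CV needs at least two values")
  m <- mean(values)
  if (m == 0) stop("CV undefined for zero mean")
  100 * stats::sd(values) / m
}

#' Replicate QC summary
#'
#' Computes per-form CVs of retention time, peak area and peptide ratio
#' across replicates (complete cases: forms detected in every replicate)
#' and counts forms below each CV threshold, plus per-replicate
#' identification counts.
#'
#' @param quant_tables list of \code{quant_table}s, one per replicate.
#' @param cv_thresholds CV thresholds in percent.
#' @return list with \code{per_form} (form_id, cv_rt, cv_area, cv_ratio),
#'   \code{counts} (metric x threshold table), \code{ids_per_replicate},
#'   and \code{n_complete}.
#' @export
summarize_replicates <- function(quant_tables, cv_thresholds = c(5, 20)) {
  stopifnot(length(quant_tables) >= 2)
  qts <- lapply(quant_tables, peptide_ratio)
  ids_per_rep <- vapply(qts, function(q) sum(q$identified), integer(1))
  common <- Reduce(intersect, lapply(qts, function(q)
    q$form_id[q$detected]))
  per_form <- data.frame(form_id = common,
                         cv_rt = NA_real_, cv_area = NA_real_,
                         cv_ratio = NA_real_)
  for (i in seq_along(common)) {
    fid <- common[i]
    rt <- vapply(qts, function(q) q$rt_apex[match(fid, q$form_id)],
                 numeric(1))
    ar <- vapply(qts, function(q) q$area[match(fid, q$form_id)], numeric(1))
    ra <- vapply(qts, function(q) q$ratio[match(fid, q$form_id)], numeric(1))
    per_form$cv_rt[i] <- cv_percent(rt)
    per_form$cv_area[i] <- if (mean(ar) > 0) cv_percent(ar) else NA
    per_form$cv_ratio[i] <- if (!anyNA(ra) && mean(ra) > 0) cv_percent(ra)
                            else NA
  }
  counts <- sapply(cv_thresholds, function(th)
    c(rt = sum(per_form$cv_rt < th, na.rm = TRUE),
      area = sum(per_form$cv_area < th, na.rm = TRUE),
      ratio = sum(per_form$cv_ratio < th, na.rm = TRUE)))
  colnames(counts) <- paste0("cv_below_", cv_thresholds)
  list(per_form = per_form, counts = counts,
       ids_per_replicate = ids_per_rep, n_complete = length(common))
}

#' Long-format replicate table
#'
#' One row per (replicate, form): area, ratio, retention time and flags —
#' the CSV handed to downstream statistics tools.
#'
#' @param quant_tables list of \code{quant_table}s.
#' @return data.frame.
#' @export
replicate_long_table <- function(quant_tables) {
  qts <- lapply(quant_tables, peptide_ratio)
  do.call(rbind, lapply(seq_along(qts), function(r) {
    q <- qts[[r]]
    data.frame(replicate = r, form_id = q$form_id, region = q$region,
               charge = q$charge, rt_apex = q$rt_apex, area = q$area,
               ratio = q$ratio, points = q$points,
               detected = q$detected, identified = q$identified,
               stringsAsFactors = FALSE)
  }))
}

#' Points-across-the-peak histogram data
#'
#' @param qt a \code{quant_table}.
#' @return table of the \code{points} values of detected forms.
#' @export
points_across_peak <- function(qt) {
  table(qt$points[qt$detected])
}
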