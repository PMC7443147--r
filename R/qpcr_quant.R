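# Relative quantification arithmetic for qPCR: 2^-ddCt against a
# reference gene and a control sample, and ChIP dCt against input.
# Amplification efficiency is fixed at 2 (no efficiency calibration).

#' Summarize replicate threshold-cycle values
#'
#' @param sample_id Sample label.
#' @param target Gene/amplicon name.
#' @param replicate_cts Numeric vector of Ct values (>= 1; typically
#'   triplicates for expression, duplicates for ChIP).
#' @return List of class `ct_measurement`: mean_ct, sem_ct (NA when only
#'   one replicate), n, plus the labels.
#' @export
ct_measurement <- function(sample_id, target, replicate_cts) {
  cts <- as.numeric(replicate_cts)
  if (length(cts) < 1 || any(!is.finite(cts)) || any(cts <= 0))
    sf_stop("replicate Ct values must be finite and positive")
  structure(list(sample_id = as.character(sample_id),
                 target = as.character(target),
                 replicate_cts = cts,
                 mean_ct = mean(cts),
                 sem_ct = if (length(cts) > 1)
                   stats::sd(cts) / sqrt(length(cts)) else NA_real_,
                 n = length(cts)),
            class = "ct_measurement")
}

#' Relative expression by the 2^-ddCt method
#'
#' dCt(sample) = meanCt(target) - meanCt(reference); ddCt = dCt(sample) -
#' dCt(control); fold change = `2^-ddCt`.  The control sample's fold
#' change is 1 by construction.  The s.e.m. of ddCt, when all four sems
#' are available, is propagated by quadrature and reported alongside; it
#' is never used for gating.
#'
#' @param target_ct,reference_ct `ct_measurement`s for the sample of
#'   interest (target gene and reference gene, e.g. beta-actin).
#' @param control_target_ct,control_reference_ct The same pair for the
#'   control sample.
#' @return List of class `relative_expression`: sample_id, target,
#'   delta_ct, delta_delta_ct, fold_change, sem_ddct.
#' @export
#' @examples
#' s_t <- ct_measurement("hemin", "HBE1", 23)
#' s_r <- ct_measurement("hemin", "ACTB", 20)
#' c_t <- ct_measurement("ctrl", "HBE1", 25)
#' c_r <- ct_measurement("ctrl", "ACTB", 20)
#' ddct(s_t, s_r, c_t, c_r)$fold_change  # 4
ddct <- function(target_ct, reference_ct, control_target_ct,
                 control_reference_ct) {
  ms <- list(target_ct, reference_ct, control_target_ct, control_reference_ct)
  if (!all(vapply(ms, inherits, logical(1), "ct_measurement")))
    sf_stop("all four arguments must be ct_measurement objects")
  if (target_ct$target != control_target_ct$target)
    sf_stop(sprintf("target mismatch: '%s' vs control '%s'",
                    target_ct$target, control_target_ct$target))
  if (reference_ct$target != control_reference_ct$target)
    sf_stop(sprintf("reference mismatch: '%s' vs control '%s'",
                    reference_ct$target, control_reference_ct$target))
  d_sample <- target_ct$mean_ct - reference_ct$mean_ct
  d_control <- control_target_ct$mean_ct - control_reference_ct$mean_ct
  dd <- d_sample - d_control
  sems <- vapply(ms, `[[`, numeric(1), "sem_ct")
  sem_ddct <- if (all(is.finite(sems))) sqrt(sum(sems^2)) else NA_real_
  structure(list(sample_id = target_ct$sample_id,
                 target = target_ct$target,
                 delta_ct = d_sample,
                 delta_delta_ct = dd,
                 fold_change = 2^(-dd),
                 sem_ddct = sem_ddct),
            class = "relative_expression")
}

#' ChIP enrichment relative to input
#'
#' dCt = meanCt(IP) - meanCt(input); enrichment is reported as `2^-dCt`
#' (fold of input), so IP identical to input gives 1.
#'
#' @param ip_ct,input_ct `ct_measurement`s for the immunoprecipitate and
#'   its input, same amplicon.
#' @return List: target, delta_ct, enrichment.
#' @export
chip_enrichment <- function(ip_ct, input_ct) {
  if (!inherits(ip_ct, "ct_measurement") || !inherits(input_ct, "ct_measurement"))
    sf_stop("both arguments must be ct_measurement objects")
  if (ip_ct$target != input_ct$target)
    sf_stop(sprintf("amplicon mismatch: '%s' vs '%s'",
                    ip_ct$target, input_ct$target))
  d <- ip_ct$mean_ct - input_ct$mean_ct
  list(target = ip_ct$target, delta_ct = d, enrichment = 2^(-d))
}

#' Read a long-format Ct table from CSV
#'
#' Header `sample_id,target,ct`, one row per replicate reaction.
#' @param path CSV path.
#' @return data.frame.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) sf_stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "target", "ct")
  if (!all(need %in% names(df)))
    sf_stop("Ct table needs columns sample_id,target,ct",
            class = "screenforge_format_error")
  df
}

#' Fold changes for every sample/target in a long Ct table
#'
#' Applies [ddct()] to every (sample, target) pair against the named
#' reference gene and control sample.
#'
#' @param ct_table Long data.frame as read by [read_ct_table()].
#' @param reference Reference gene name (e.g. `"ACTB"`).
#' @param control_sample Control sample_id (fold change 1 by definition).
#' @return data.frame `sample_id, target, delta_ct, delta_delta_ct,
#'   fold_change, sem_ddct`.
#' @export
qpcr_fold_changes <- function(ct_table, reference, control_sample) {
  if (!reference %in% ct_table$target)
    sf_stop(sprintf("reference gene '%s' absent from Ct table", reference))
  if (!control_sample %in% ct_table$sample_id)
    sf_stop(sprintf("control sample '%s' absent from Ct table", control_sample))
  meas <- function(s, t) {
    cts <- ct_table$ct[ct_table$sample_id == s & ct_table$target == t]
    if (length(cts) == 0)
      sf_stop(sprintf("no Ct values for sample '%s', target '%s'", s, t))
    ct_measurement(s, t, cts)
  }
  targets <- setdiff(unique(ct_table$target), reference)
  samples <- unique(ct_table$sample_id)
  rows <- list()
  for (t in targets) {
    c_t <- meas(control_sample, t)
    c_r <- meas(control_sample, reference)
    for (s in samples) {
      r <- ddct(meas(s, t), meas(s, reference), c_t, c_r)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = s, target = t, delta_ct = r$delta_ct,
        delta_delta_ct = r$delta_delta_ct, fold_change = r$fold_change,
        sem_ddct = r$sem_ddct, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
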