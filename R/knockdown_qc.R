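#' Relative expression by the delta-delta-Ct method
#'
#' Computes knockdown expression as percent-of-control from qPCR threshold
#' cycles. Per condition, the mean Ct of the reference gene is subtracted
#' from the mean Ct of the target (dCt); the difference of dCt between the
#' knockdown (or mutant) and control conditions is ddCt; percent-of-control
#' is `100 * 2^(-ddCt)`. Replicates are unpaired wells, so Ct values are
#' averaged within each (role, condition) cell before differencing. The
#' standard error is propagated from the per-cell replicate SDs on the Ct
#' scale and transformed to the percent scale.
#'
#' @param wells Data.frame with columns `gene_role`
#'   (`target`/`reference`; other roles are ignored), `condition`
#'   (`knockdown`/`control`; `mutant` is accepted as a synonym of
#'   `knockdown`), `ct` (cycles), and optionally `replicate`.
#' @return A list: `percent_of_control`, `se_percent`, `ddct`, `se_ddct`,
#'   and `cells` (per-cell n, mean, sd).
#' @examples
#' w <- simulate_qpcr(efficiency = 50, n_reps = 3, noise_sd = 0)
#' relative_expression(w)$percent_of_control
#' @export
relative_expression <- function(wells) {
  abort_if(!all(c("gene_role", "condition", "ct") %in% names(wells)),
           "wells need gene_role, condition and ct columns")
  w <- wells[wells$gene_role %in% c("target", "reference"), , drop = FALSE]
  cond <- as.character(w$condition)
  cond[cond == "mutant"] <- "knockdown"
  w$condition <- cond
  abort_if(!all(c("knockdown", "control") %in% unique(cond)),
           "wells must cover both knockdown and control conditions")
  abort_if(any(!is.finite(w$ct)) || any(w$ct <= 0), "Ct values must be finite and positive")

  cells <- expand.grid(gene_role = c("target", "reference"),
                       condition = c("knockdown", "control"),
                       stringsAsFactors = FALSE)
  stats_ <- lapply(seq_len(nrow(cells)), function(i) {
    x <- w$ct[w$gene_role == cells$gene_role[i] & w$condition == cells$condition[i]]
    abort_if(length(x) == 0, "missing %s wells in %s condition",
             cells$gene_role[i], cells$condition[i])
    c(n = length(x), mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0)
  })
  cells$n <- vapply(stats_, `[[`, numeric(1), "n")
  cells$mean <- vapply(stats_, `[[`, numeric(1), "mean")
  cells$sd <- vapply(stats_, `[[`, numeric(1), "sd")

  cell <- function(role, cond) cells[cells$gene_role == role & cells$condition == cond, ]
  dct_kd <- cell("target", "knockdown")$mean - cell("reference", "knockdown")$mean
  dct_ct <- cell("target", "control")$mean - cell("reference", "control")$mean
  ddct <- dct_kd - dct_ct
  var_ddct <- sum(cells$sd^2 / cells$n)
  pct <- 100 * 2^(-ddct)
  se_pct <- pct * log(2) * sqrt(var_ddct)

  list(percent_of_control = pct, se_percent = se_pct,
       ddct = ddct, se_ddct = sqrt(var_ddct), cells = cells)
}

#' Knockdown-efficiency records from a qPCR table
#'
#' Runs [relative_expression()] per line on a long-format qPCR table.
#'
#' @param qpcr Data.frame with columns `line_id`, `gene_id`, `gene_role`,
#'   `condition`, `replicate`, `ct` and optionally `library`.
#' @return Data.frame: line_id, gene_id, library, percent_of_control, se.
#' @export
efficiency_records <- function(qpcr) {
  need <- c("line_id", "gene_id", "gene_role", "condition", "ct")
  abort_if(!all(need %in% names(qpcr)), "qPCR table needs columns: %s",
           paste(setdiff(need, names(qpcr)), collapse = ", "))
  ids <- unique(qpcr$line_id)
  rows <- lapply(ids, function(id) {
    sub <- qpcr[qpcr$line_id == id, , drop = FALSE]
    rx <- relative_expression(sub)
    data.frame(line_id = id,
               gene_id = sub$gene_id[sub$gene_role == "target"][1],
               library = if ("library" %in% names(sub)) sub$library[1] else NA_character_,
               percent_of_control = rx$percent_of_control,
               se = rx$se_percent, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-library efficiency summary
#'
#' Means and inclusive threshold proportions of percent-of-control values,
#' grouped by library.
#'
#' @param records Data.frame with `library` and `percent_of_control`
#'   columns (e.g. from [efficiency_records()]).
#' @param thresholds Percent thresholds; default `c(20, 30)`.
#' @return Data.frame: library, n, mean_percent, and one `p_le_<t>` column
#'   per threshold (proportion of lines with percent-of-control <= t).
#' @export
efficiency_summary <- function(records, thresholds = c(20, 30)) {
  abort_if(nrow(records) == 0, "no efficiency records")
  abort_if(any(records$percent_of_control <= 0, na.rm = TRUE),
           "percent_of_control must be positive")
  libs <- sort(unique(as.character(records$library)))
  out <- do.call(rbind, lapply(libs, function(lb) {
    x <- records$percent_of_control[records$library == lb]
    abort_if(length(x) == 0, "empty library group %s", lb)
    row <- data.frame(library = lb, n = length(x), mean_percent = mean(x),
                      stringsAsFactors = FALSE)
    for (t in thresholds) row[[paste0("p_le_", t)]] <- mean(x <= t)
    row
  }))
  rownames(out) <- NULL
  out
}

#' Compare two knockdown-efficiency distributions
#'
#' Welch two-sample t-test on percent-of-control values, per-group z-scores
#' (standardized within each group), threshold proportions, and a Q-Q
#' comparison using linear-interpolation quantiles.
#'
#' @param group_a,group_b Numeric vectors (>= 2 values each).
#' @param probs Quantile levels for the Q-Q pairs; default
#'   `seq(0.05, 0.95, by = 0.05)`.
#' @param thresholds Percent thresholds for the per-group proportions.
#' @return A list: per-group `mean`, `prop_le` (per threshold), `z`
#'   (z-scores), `qq` (data.frame prob/q_a/q_b), `max_qq_deviation`,
#'   `t_statistic`, `df`, `p_value`, and `degenerate` (TRUE when both
#'   groups have zero variance, in which case the t-test is undefined).
#' @export
compare_distributions <- function(group_a, group_b,
                                  probs = seq(0.05, 0.95, by = 0.05),
                                  thresholds = c(20, 30)) {
  abort_if(length(group_a) < 2 || length(group_b) < 2,
           "need at least 2 values per group")
  zscore <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else rep(0, length(x))
  qa <- stats::quantile(group_a, probs = probs, type = 7, names = FALSE)
  qb <- stats::quantile(group_b, probs = probs, type = 7, names = FALSE)
  degenerate <- stats::sd(group_a) == 0 && stats::sd(group_b) == 0
  if (degenerate) {
    t_stat <- NA_real_; df <- NA_real_; p <- NA_real_
  } else {
    tt <- stats::t.test(group_a, group_b, var.equal = FALSE)
    t_stat <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
  }
  prop_le <- function(x) stats::setNames(vapply(thresholds, function(t) mean(x <= t), numeric(1)),
                                         paste0("p_le_", thresholds))
  list(
    mean = c(a = mean(group_a), b = mean(group_b)),
    prop_le = list(a = prop_le(group_a), b = prop_le(group_b)),
    z = list(a = zscore(group_a), b = zscore(group_b)),
    qq = data.frame(prob = probs, q_a = qa, q_b = qb),
    max_qq_deviation = max(abs(qa - qb)),
    t_statistic = t_stat, df = df, p_value = p,
    degenerate = degenerate
  )
}

#' Flag a line as a likely off-target hit
#'
#' A hairpin's most likely off-target is the paralog of its target. A line
#' is flagged when the paralog is knocked down to a similar or lower level
#' than the target itself: `paralog_percent <= margin * target_percent`.
#'
#' @param target_percent,paralog_percent Percent-of-control expression
#'   (positive; vectors recycled).
#' @param margin Multiplicative margin defining "similar"; default 1.25.
#' @return Logical vector.
#' @examples
#' off_target_flag(c(20, 20), c(100, 18))
#' @export
off_target_flag <- function(target_percent, paralog_percent, margin = 1.25) {
  abort_if(any(target_percent <= 0) || any(paralog_percent <= 0),
           "expression percentages must be positive")
  paralog_percent <= margin * target_percent
}

#' Test for paralog compensation in a knockout
#'
#' In a frameshift/knockout mutant, a highly similar paralog may be
#' transcriptionally upregulated, masking loss-of-function phenotypes. The
#' test compares paralog expression between mutant and wild type (Welch
#' two-sided t) and requires specificity: unrelated/remote control genes
#' must not shift at the same alpha.
#'
#' @param paralog_mutant,paralog_wt Numeric expression replicates (>= 3
#'   each).
#' @param control_genes Named list; each element a list with numeric
#'   `mutant` and `wt` replicate vectors.
#' @param alpha Significance level for the verdict; default 0.01.
#' @return A list: `fold_change` (mean mutant / mean wt), `t_statistic`,
#'   `p_value`, `controls` (per-gene fold/p), and `verdict` in
#'   `compensation`/`ambiguous`/`none`. `compensation` requires the paralog
#'   significantly up and all controls non-significant; a significant
#'   control demotes the verdict to `ambiguous`.
#' @export
compensation_test <- function(paralog_mutant, paralog_wt,
                              control_genes = list(), alpha = 0.01) {
  abort_if(length(paralog_mutant) < 3 || length(paralog_wt) < 3,
           "need >= 3 replicates per condition")
  tt <- stats::t.test(paralog_mutant, paralog_wt, var.equal = FALSE)
  fold <- mean(paralog_mutant) / mean(paralog_wt)
  controls <- lapply(control_genes, function(g) {
    abort_if(length(g$mutant) < 3 || length(g$wt) < 3,
             "need >= 3 replicates per condition for control genes")
    ct <- stats::t.test(g$mutant, g$wt, var.equal = FALSE)
    list(fold_change = mean(g$mutant) / mean(g$wt), p_value = ct$p.value)
  })
  ctrl_sig <- vapply(controls, function(g) g$p_value < alpha, logical(1))
  paralog_up_sig <- tt$p.value < alpha && fold > 1
  verdict <- if (paralog_up_sig && !any(ctrl_sig)) {
    "compensation"
  } else if (paralog_up_sig && any(ctrl_sig)) {
    "ambiguous"
  } else "none"
  list(fold_change = fold, t_statistic = unname(tt$statistic),
       p_value = tt$p.value, controls = controls, alpha = alpha,
       verdict = verdict)
}
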