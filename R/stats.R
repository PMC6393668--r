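# Inferential layer: planned paired contrasts and repeated-measures ANOVA
# on the per-participant cell means.

#' Paired-samples t test (planned contrast)
#'
#' Two-tailed paired t test: `t = mean(x - y) / (sd(x - y) / sqrt(n))` with
#' the n - 1 variance denominator and `df = n - 1`. Zero-variance
#' differences are a degenerate-data error rather than an infinite
#' statistic.
#'
#' @param x,y Matched numeric samples of equal length (n >= 2).
#' @return A list with `t`, `df`, `p` (two-tailed).
#' @examples
#' paired_ttest(1:5, rep(0, 5)) # t = 4.2426, df = 4
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must be matched (equal length)",
                                   call. = FALSE)
  if (length(x) < 2L) stop("need n >= 2 pairs", call. = FALSE)
  d <- x - y
  if (stats::sd(d) < 1e-12) {
    stop("degenerate data: zero variance of paired differences", call. = FALSE)
  }
  res <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' Repeated-measures ANOVA
#'
#' One- or two-way within-subject ANOVA on a complete balanced layout,
#' fitted with `stats::aov()` using subject error strata
#' (`Error(subject/(A*B))`): each within factor is tested against its
#' factor-by-subject interaction (`F_A = MS_A / MS_{A x S}` etc.). No
#' sphericity correction is applied; degrees of freedom are the uncorrected
#' factorial ones.
#'
#' @param data Long-format `data.frame` of cell means: one row per subject x
#'   cell.
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of one or two within-subject factor
#'   columns.
#' @param subject Name of the subject identifier column.
#' @return An `anova_rm` object: `data.frame` with one row per term
#'   (`effect`, `ss`, `df`, `ms`, `f`, `p`; error strata have `f = NA`), with
#'   attribute `design` (`"oneway_rm"` or `"twoway_rm"`).
#' @export
rm_anova <- function(data, dv, within, subject = "participant") {
  if (!dv %in% names(data)) stop("missing dv column: ", dv, call. = FALSE)
  if (!all(within %in% names(data))) {
    stop("missing within-factor column(s)", call. = FALSE)
  }
  if (length(within) < 1L || length(within) > 2L) {
    stop("`within` must name one or two factors", call. = FALSE)
  }
  df <- data.frame(y = data[[dv]],
                   subject = factor(data[[subject]]),
                   lapply(data[within], factor))
  names(df)[3:(2 + length(within))] <- within
  if (nlevels(df$subject) < 2L) stop("need >= 2 participants", call. = FALSE)
  counts <- table(df[c("subject", within)])
  if (any(counts != 1L)) {
    bad <- which(counts != 1L, arr.ind = TRUE)
    stop(sprintf("incomplete/unbalanced layout: %d missing or duplicated subject x cell combinations",
                 nrow(bad)), call. = FALSE)
  }
  if (any(is.na(df$y))) stop("missing cell values", call. = FALSE)

  fixed <- paste(within, collapse = "*")
  form <- stats::as.formula(sprintf("y ~ %s + Error(subject/(%s))", fixed, fixed))
  fit <- stats::aov(form, data = df)
  out <- do.call(rbind, lapply(names(summary(fit)), function(stratum) {
    tab <- summary(fit)[[stratum]][[1]]
    eff <- trimws(rownames(tab))
    strat <- sub("^Error: ", "", stratum)
    eff[eff == "Residuals"] <- paste0("Residuals(", strat, ")")
    data.frame(effect = eff, ss = tab[["Sum Sq"]], df = tab[["Df"]],
               ms = tab[["Mean Sq"]],
               f = if ("F value" %in% names(tab)) tab[["F value"]] else NA_real_,
               p = if ("Pr(>F)" %in% names(tab)) tab[["Pr(>F)"]] else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "design") <- if (length(within) == 1L) "oneway_rm" else "twoway_rm"
  class(out) <- c("anova_rm", "data.frame")
  out
}

#' @export
print.anova_rm <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (%s)\n", attr(x, "design")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Full inferential report for a summarised experiment
#'
#' For each behavioural measure (accuracy, RT, d', criterion): the
#' repeated-measures ANOVA (two-way cue x stream when the summary is grouped
#' by stream, else one-way) and the planned paired contrasts valid vs
#' invalid, valid vs neutral and invalid vs neutral on per-participant
#' condition means (streams averaged), plus per-stream valid vs invalid
#' contrasts in the two-way case.
#'
#' @param summary A `condition_summary` from [summarize_experiment()].
#' @param measures Which cell measures to analyse.
#' @return A list with one element per measure, each containing `anova`
#'   (an `anova_rm`) and `contrasts` (a `data.frame` of t/df/p).
#' @export
experiment_stats <- function(summary,
                             measures = c("accuracy", "rt_ms", "dprime",
                                          "criterion")) {
  stopifnot(inherits(summary, "condition_summary"))
  all_cells <- summary$cells
  two_way <- summary$grouping == "by_condition_and_stream"
  res <- list()
  for (meas in measures) {
    # participants with an empty cell for this measure (e.g. no hits, hence
    # no RT) are excluded from its inferential analysis
    bad <- unique(all_cells$participant[is.na(all_cells[[meas]])])
    cells <- all_cells[!(all_cells$participant %in% bad), , drop = FALSE]
    if (length(bad)) {
      warning(sprintf("%s: excluding participant(s) %s with empty cells",
                      meas, paste(bad, collapse = ", ")), call. = FALSE)
    }
    if (length(unique(cells$participant)) < 2L) {
      res[[meas]] <- list(anova = NULL, contrasts = NULL,
                          excluded = bad)
      next
    }
    within <- if (two_way) c("cue_condition", "target_stream") else "cue_condition"
    aov_res <- rm_anova(cells, dv = meas, within = within)

    # condition means per participant, streams averaged
    cond_means <- function(cond, stream = NULL) {
      sel <- cells$cue_condition == cond
      if (!is.null(stream)) sel <- sel & cells$target_stream == stream
      sub <- cells[sel, , drop = FALSE]
      tapply(sub[[meas]], sub$participant, mean, na.rm = TRUE)
    }
    pair <- function(label, a, b) {
      ct <- paired_ttest(as.numeric(a), as.numeric(b))
      data.frame(contrast = label, t = ct$t, df = ct$df, p = ct$p)
    }
    contrasts <- rbind(
      pair("valid_vs_invalid", cond_means("valid"), cond_means("invalid")),
      pair("valid_vs_neutral", cond_means("valid"), cond_means("neutral")),
      pair("invalid_vs_neutral", cond_means("invalid"), cond_means("neutral")))
    if (two_way) {
      contrasts <- rbind(contrasts,
        pair("valid_vs_invalid_streamA", cond_means("valid", "A"),
             cond_means("invalid", "A")),
        pair("valid_vs_invalid_streamB", cond_means("valid", "B"),
             cond_means("invalid", "B")))
    }
    res[[meas]] <- list(anova = aov_res, contrasts = contrasts,
                        excluded = bad)
  }
  res
}
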