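# Agreement statistics: Kadaba CMC, RMSE, ROM, PTA, Bland-Altman limits of
# agreement, normality-gated paired tests, and report assembly.

#' Coefficient of multiple correlation (Kadaba, within-day form)
#'
#' For G aligned waveforms of one channel,
#' \deqn{CMC = \sqrt{1 - \frac{\sum_g\sum_t (Y_{gt}-\bar Y_t)^2 / (G(T-1))}
#'                        {\sum_g\sum_t (Y_{gt}-\bar Y)^2 / (GT-1)}}}
#' with \eqn{\bar Y_t} the across-waveform mean at each time point and
#' \eqn{\bar Y} the grand mean. For dissimilar waveforms the radicand can go
#' negative; it is then clamped to 0 and flagged (`attr(, "degenerate")`).
#' Identical constant waveforms make the statistic 0/0-undefined; a flagged
#' `NaN` is returned. Between-system use compares G = 2 waveforms (one per
#' system).
#'
#' @param waveforms numeric matrix `T x G` (columns = waveforms) or a list of
#'   equal-length numeric vectors.
#' @return CMC in \[0, 1\] (possibly flagged).
#' @export
cmc <- function(waveforms) {
  Y <- if (is.list(waveforms)) {
    len <- unique(lengths(waveforms))
    if (length(len) != 1) stop("waveforms must have equal length", call. = FALSE)
    do.call(cbind, waveforms)
  } else {
    as.matrix(waveforms)
  }
  Tn <- nrow(Y); G <- ncol(Y)
  if (G < 2 || Tn < 2) stop("CMC needs G >= 2 waveforms of T >= 2 samples",
                            call. = FALSE)
  ybar_t <- rowMeans(Y)
  ybar <- mean(Y)
  num <- sum((Y - ybar_t)^2) / (G * (Tn - 1))
  den <- sum((Y - ybar)^2) / (G * Tn - 1)
  if (den == 0) {
    out <- NaN
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  rad <- 1 - num / den
  if (rad < 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  sqrt(rad)
}

#' Root-mean-squared error between two waveforms
#'
#' @param a,b equal-length numeric vectors (degrees).
#' @return RMSE in degrees.
#' @export
rmse <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  sqrt(mean((a - b)^2))
}

#' Range of motion and angle at the point of target achieved
#'
#' `rom` is max minus min over the normalized movement; `pta` is the angle at
#' the final sample (100% of the movement, when the hand has reached the
#' target). Both require a time-normalized waveform.
#'
#' @param wf a normalized [angle_waveform()].
#' @param channel one of `"FE"`, `"AA"`, `"IE"`, `"EFE"`.
#' @return degrees.
#' @export
rom <- function(wf, channel) {
  channel <- match.arg(channel, ANGLE_CHANNELS)
  if (!wf$normalized) stop("ROM is defined on normalized waveforms", call. = FALSE)
  x <- wf$values[, channel]
  unname(max(x) - min(x))
}

#' @rdname rom
#' @export
pta <- function(wf, channel) {
  channel <- match.arg(channel, ANGLE_CHANNELS)
  if (!wf$normalized) stop("PTA is defined on normalized waveforms", call. = FALSE)
  unname(wf$values[nrow(wf$values), channel])
}

#' Bland-Altman analysis with 95% limits of agreement
#'
#' @param x,y paired parameter vectors (e.g. per-subject PTA via two systems).
#' @return list with `mean_diff`, `loa_lower`, `loa_upper` (mean difference
#'   +/- 1.96 sample SD), and per-pair `means` / `diffs`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop("Bland-Altman needs equal-length paired vectors, n >= 2", call. = FALSE)
  }
  d <- x - y
  m <- mean(d); s <- stats::sd(d)
  list(mean_diff = m, loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
       means = (x + y) / 2, diffs = d)
}

#' Normality-gated paired comparison
#'
#' Shapiro-Wilk on the paired differences decides the test: p > 0.05 keeps the
#' paired t-test, otherwise the Wilcoxon signed-rank test is used. Differences
#' with zero variance make both tests undefined; a flagged degenerate result
#' is returned instead of a p-value.
#'
#' @param x,y paired parameter vectors, n >= 3.
#' @param alpha significance level recorded in the result (default 0.05).
#' @return list with `test` (`"paired-t"`, `"wilcoxon"` or `"degenerate"`),
#'   `statistic`, `p_value`, `shapiro_p`, `significant`.
#' @export
paired_comparison <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("paired comparison needs equal-length vectors, n >= 3", call. = FALSE)
  }
  d <- x - y
  if (stats::sd(d) == 0) {
    return(list(test = "degenerate", statistic = NA_real_, p_value = NA_real_,
                shapiro_p = NA_real_, significant = FALSE))
  }
  sw <- stats::shapiro.test(d)$p.value
  if (sw > alpha) {
    tt <- stats::t.test(x, y, paired = TRUE)
    list(test = "paired-t", statistic = unname(tt$statistic),
         p_value = tt$p.value, shapiro_p = sw,
         significant = tt$p.value < alpha)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
    list(test = "wilcoxon", statistic = unname(wt$statistic),
         p_value = wt$p.value, shapiro_p = sw,
         significant = wt$p.value < alpha)
  }
}

# Per-subject mean of a per-trial statistic, then mean/SD across subjects --
# the aggregation used for every table-style summary.
subject_mean_sd <- function(values, subjects) {
  per_subject <- tapply(values, subjects, mean)
  c(mean = mean(per_subject), sd = stats::sd(per_subject))
}

#' Build an agreement report from LOOCV folds
#'
#' Aggregates, per task and channel: CMC and RMSE of the skeleton model and of
#' the refined model against the gold standard (per trial with G = 2, averaged
#' within subject, then mean +/- SD across subjects), PTA and ROM per system
#' with mean differences, Bland-Altman limits of agreement, and the
#' normality-gated paired test on the refined-vs-gold parameters.
#'
#' @param folds list of fold results from [loocv_refine()] (one task), or a
#'   named list of such lists (several tasks).
#' @return object of class `agreement_report`: a data frame (`$table`) plus
#'   the underlying per-subject parameter lists (`$params`).
#' @export
build_report <- function(folds) {
  if (length(folds) == 0) stop("empty input", call. = FALSE)
  by_task <- if (inherits(folds[[1]], "loocv_fold")) {
    tk <- folds[[1]]$input[[1]]$task
    stats::setNames(list(folds), if (is.null(tk)) "task" else tk)
  } else {
    folds
  }
  rows <- list()
  params <- list()
  for (task in names(by_task)) {
    tf <- by_task[[task]]
    for (ch in ANGLE_CHANNELS) {
      subj <- character(0)
      cmc_phi <- cmc_hat <- rmse_phi <- rmse_hat <- numeric(0)
      pta_phi <- pta_hat <- pta_gam <- rom_phi <- rom_hat <- rom_gam <- numeric(0)
      trial_subj <- character(0)
      for (fold in tf) {
        for (i in seq_along(fold$target)) {
          g <- fold$target[[i]]$values[, ch]
          p <- fold$input[[i]]$values[, ch]
          h <- fold$refined[[i]]$values[, ch]
          trial_subj <- c(trial_subj, fold$subject_id)
          cmc_phi <- c(cmc_phi, as.numeric(cmc(cbind(p, g))))
          cmc_hat <- c(cmc_hat, as.numeric(cmc(cbind(h, g))))
          rmse_phi <- c(rmse_phi, rmse(p, g))
          rmse_hat <- c(rmse_hat, rmse(h, g))
          pta_phi <- c(pta_phi, pta(fold$input[[i]], ch))
          pta_hat <- c(pta_hat, pta(fold$refined[[i]], ch))
          pta_gam <- c(pta_gam, pta(fold$target[[i]], ch))
          rom_phi <- c(rom_phi, rom(fold$input[[i]], ch))
          rom_hat <- c(rom_hat, rom(fold$refined[[i]], ch))
          rom_gam <- c(rom_gam, rom(fold$target[[i]], ch))
        }
      }
      agg <- function(v) subject_mean_sd(v, trial_subj)
      per_subj <- function(v) as.numeric(tapply(v, trial_subj, mean))
      na_ba <- list(mean_diff = NA_real_, loa_lower = NA_real_,
                    loa_upper = NA_real_)
      na_cmp <- list(test = "insufficient-n", statistic = NA_real_,
                     p_value = NA_real_)
      try_or <- function(expr, alt) tryCatch(expr, error = function(e) alt)
      ba_pta <- try_or(bland_altman(per_subj(pta_hat), per_subj(pta_gam)), na_ba)
      ba_rom <- try_or(bland_altman(per_subj(rom_hat), per_subj(rom_gam)), na_ba)
      cmp_pta <- try_or(paired_comparison(per_subj(pta_hat), per_subj(pta_gam)),
                        na_cmp)
      cmp_rom <- try_or(paired_comparison(per_subj(rom_hat), per_subj(rom_gam)),
                        na_cmp)
      rows[[length(rows) + 1]] <- data.frame(
        task = task, channel = ch,
        cmc_phi = agg(cmc_phi)[1], cmc_phi_sd = agg(cmc_phi)[2],
        cmc_refined = agg(cmc_hat)[1], cmc_refined_sd = agg(cmc_hat)[2],
        rmse_phi = agg(rmse_phi)[1], rmse_phi_sd = agg(rmse_phi)[2],
        rmse_refined = agg(rmse_hat)[1], rmse_refined_sd = agg(rmse_hat)[2],
        pta_phi = agg(pta_phi)[1], pta_refined = agg(pta_hat)[1],
        pta_gold = agg(pta_gam)[1],
        pta_diff_refined = mean(per_subj(pta_hat) - per_subj(pta_gam)),
        rom_phi = agg(rom_phi)[1], rom_refined = agg(rom_hat)[1],
        rom_gold = agg(rom_gam)[1],
        rom_diff_refined = mean(per_subj(rom_hat) - per_subj(rom_gam)),
        pta_loa_lower = ba_pta$loa_lower, pta_loa_upper = ba_pta$loa_upper,
        rom_loa_lower = ba_rom$loa_lower, rom_loa_upper = ba_rom$loa_upper,
        pta_test = cmp_pta$test, pta_p = cmp_pta$p_value,
        rom_test = cmp_rom$test, rom_p = cmp_rom$p_value,
        stringsAsFactors = FALSE)
      params[[paste(task, ch, sep = ".")]] <-
        list(subjects = unique(trial_subj),
             pta = list(phi = per_subj(pta_phi), refined = per_subj(pta_hat),
                        gold = per_subj(pta_gam)),
             rom = list(phi = per_subj(rom_phi), refined = per_subj(rom_hat),
                        gold = per_subj(rom_gam)))
    }
  }
  structure(list(table = do.call(rbind, rows), params = params),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>\n")
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf(paste0(" %s %-3s  CMC %.2f->%.2f  RMSE %6.2f->%6.2f deg  ",
                       "dPTA %+6.2f  dROM %+6.2f\n"),
                tab$task[i], tab$channel[i], tab$cmc_phi[i],
                tab$cmc_refined[i], tab$rmse_phi[i], tab$rmse_refined[i],
                tab$pta_diff_refined[i], tab$rom_diff_refined[i]))
  }
  invisible(x)
}

#' Write an agreement report to JSON
#'
#' @param report a [build_report()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(list(table = report$table), path, digits = NA,
                       auto_unbox = TRUE, dataframe = "rows", null = "null")
  invisible(path)
}

#' Bland-Altman plot
#'
#' @param ba a [bland_altman()] result.
#' @param main plot title.
#' @export
plot_bland_altman <- function(ba, main = "Bland-Altman") {
  graphics::plot(ba$means, ba$diffs, pch = 19, xlab = "mean of systems",
                 ylab = "difference", main = main)
  graphics::abline(h = ba$mean_diff, col = "red")
  graphics::abline(h = c(ba$loa_lower, ba$loa_upper), col = "grey40", lty = 2)
}
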