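#' CC probability by stimulus frequency or peak velocity
#'
#' Each half-cycle segment is one Bernoulli trial; the per-bin probability
#' is the fraction of CC segments among segments whose stimulus carries that
#' frequency (or peak velocity). For the built-in design the bins are
#' exactly the six frequencies / five velocities. Bins with no segments are
#' flagged empty (`NA` probability), never zero.
#'
#' @param segments Data frame of classified segments (needs `is_cc` and the
#'   axis column; a `participant` column enables per-participant grouping).
#' @param axis `"frequency"` or `"peak_velocity"`.
#' @param bins Bin values; default the sorted unique values present.
#' @param by_participant Return one row per participant x bin.
#' @return Data frame `bin` (Hz or cm/s), `probability`, `n_segments`,
#'   `n_cc` (plus `participant` when grouped).
#' @export
cc_probability <- function(segments, axis = c("frequency", "peak_velocity"),
                           bins = NULL, by_participant = FALSE) {
  axis <- match.arg(axis)
  if (!axis %in% names(segments)) stop("segments lack column: ", axis)
  if (is.null(bins)) bins <- sort(unique(segments[[axis]]))
  agg <- function(d, extra = NULL) {
    out <- do.call(rbind, lapply(bins, function(b) {
      sel <- abs(d[[axis]] - b) < 1e-9
      n <- sum(sel)
      data.frame(bin = b,
                 probability = if (n > 0) mean(d$is_cc[sel]) else NA_real_,
                 n_segments = n, n_cc = sum(d$is_cc[sel]))
    }))
    if (!is.null(extra)) out <- cbind(extra, out, row.names = NULL)
    out
  }
  if (by_participant) {
    if (!"participant" %in% names(segments)) {
      stop("segments lack a participant column")
    }
    do.call(rbind, lapply(split(segments, segments$participant), function(d) {
      agg(d, data.frame(participant = d$participant[1]))
    }))
  } else {
    agg(segments)
  }
}

#' Per-participant regression slopes of CC probability
#'
#' Fits an ordinary least-squares line of per-bin CC probability on the bin
#' value for every participant, then tests the slopes against zero with a
#' one-sample t-test (one-sided, greater: the hypothesis is that CC becomes
#' more likely as the axis value grows).
#'
#' @param segments Classified segments with a `participant` column.
#' @param axis `"frequency"` or `"peak_velocity"`.
#' @param bins Optional bin values (see [cc_probability()]).
#' @return List of class `slope_inference`: `slopes` (data frame
#'   `participant`, `slope`), `t_statistic`, `df`, `p_value`, `ci95`
#'   (two-sided 95% CI of the mean slope), `degenerate` flag.
#' @export
participant_slopes <- function(segments,
                               axis = c("frequency", "peak_velocity"),
                               bins = NULL) {
  axis <- match.arg(axis)
  tab <- cc_probability(segments, axis, bins = bins, by_participant = TRUE)
  slopes <- do.call(rbind, lapply(split(tab, tab$participant), function(d) {
    d <- d[!is.na(d$probability), ]
    if (nrow(d) < 3) {
      stop("participant ", d$participant[1], ": fewer than 3 bins with data")
    }
    data.frame(participant = d$participant[1],
               slope = unname(stats::coef(stats::lm(probability ~ bin, d))[2]))
  }))
  s <- slopes$slope
  degenerate <- stats::sd(s) == 0
  if (degenerate) {
    t_stat <- if (mean(s) == 0) 0 else sign(mean(s)) * Inf
    p <- if (mean(s) > 0) 0 else 1
    ci <- c(mean(s), mean(s))
  } else {
    tt_g <- stats::t.test(s, mu = 0, alternative = "greater")
    tt_2 <- stats::t.test(s, mu = 0)
    t_stat <- unname(tt_g$statistic)
    p <- tt_g$p.value
    ci <- as.numeric(tt_2$conf.int)
  }
  structure(
    list(slopes = slopes, t_statistic = t_stat, df = nrow(slopes) - 1,
         p_value = p, ci95 = ci, degenerate = degenerate, axis = axis),
    class = "slope_inference"
  )
}

#' @export
print.slope_inference <- function(x, ...) {
  cat(sprintf(
    "<slopes on %s> mean %.3g, %d/%d positive; one-sided t(%d) = %.2f, p = %.3g\n",
    x$axis, mean(x$slopes$slope), sum(x$slopes$slope > 0), nrow(x$slopes),
    x$df, x$t_statistic, x$p_value
  ))
  invisible(x)
}

#' Bin free-motion segments at the design frequencies
#'
#' Free (two-player style) motion has no prescribed frequency; each
#' half-cycle's measured frequency is half the reciprocal of its duration.
#' Segments are histogrammed with the design frequencies as bin centers,
#' edges at the midpoints, and open-ended outer bins, so per-bin counts
#' differ.
#'
#' @param segments Classified segments with `t_start`, `t_end`, `is_cc`.
#' @param bin_centers Bin centers in Hz.
#' @param by_participant Group by a `participant` column.
#' @return Data frame `bin` (Hz), `probability`, `n_segments`, `n_cc`.
#' @export
bin_free_motion <- function(segments,
                            bin_centers = c(0.25, 0.375, 0.5, 0.625, 0.75,
                                            0.875),
                            by_participant = FALSE) {
  bin_centers <- sort(bin_centers)
  f_meas <- 0.5 / (segments$t_end - segments$t_start)
  edges <- (bin_centers[-1] + bin_centers[-length(bin_centers)]) / 2
  segments$freq_bin <- bin_centers[findInterval(f_meas, edges) + 1]
  agg <- function(d) {
    do.call(rbind, lapply(bin_centers, function(b) {
      sel <- abs(d$freq_bin - b) < 1e-9
      n <- sum(sel)
      data.frame(bin = b,
                 probability = if (n > 0) mean(d$is_cc[sel]) else NA_real_,
                 n_segments = n, n_cc = sum(d$is_cc[sel]))
    }))
  }
  if (by_participant) {
    do.call(rbind, lapply(split(segments, segments$participant), function(d) {
      cbind(data.frame(participant = d$participant[1]), agg(d),
            row.names = NULL)
    }))
  } else {
    agg(segments)
  }
}

#' Mixed-design (split-plot) ANOVA of CC probability across experiments
#'
#' Between-subjects factor: experiment; within-subject factor: frequency
#' bin. Fits a repeated-measures multivariate linear model and reports the
#' univariate (sphericity-assumed) F tests with Type II sums of squares for
#' the unbalanced between factor, plus Tukey honest-significant-difference
#' comparisons of the experiments on participant means.
#'
#' @param data Long data frame with columns `participant`, `experiment`,
#'   `frequency`, `probability`. Participants missing any frequency cell are
#'   dropped with a warning (listwise exclusion).
#' @return List of class `anova_result`: `table` (effect, F, df1, df2, p),
#'   `tukey` (data frame of pairwise experiment comparisons), `n_dropped`.
#' @export
mixed_anova <- function(data) {
  need <- c("participant", "experiment", "frequency", "probability")
  if (!all(need %in% names(data))) {
    stop("data needs columns: ", paste(need, collapse = ", "))
  }
  data$experiment <- factor(data$experiment)
  data$frequency <- factor(data$frequency)
  freqs <- levels(data$frequency)

  wide <- stats::reshape(
    data[, need], direction = "wide", idvar = c("participant", "experiment"),
    timevar = "frequency", v.names = "probability"
  )
  ycols <- paste0("probability.", freqs)
  complete <- stats::complete.cases(wide[, ycols, drop = FALSE])
  if (any(!complete)) {
    warning(sum(!complete), " participant(s) dropped: missing frequency cells")
  }
  wide <- wide[complete, , drop = FALSE]
  if (nrow(wide) < 3) stop("too few complete participants")

  Y <- as.matrix(wide[, ycols, drop = FALSE])
  experiment <- droplevels(wide$experiment)

  if (length(freqs) == 1) {
    # no within factor: plain one-way between ANOVA
    fit <- stats::aov(Y[, 1] ~ experiment)
    tab <- summary(fit)[[1]]
    table <- data.frame(
      effect = "experiment",
      F = tab["experiment", "F value"],
      df1 = tab["experiment", "Df"],
      df2 = tab["Residuals", "Df"],
      p = tab["experiment", "Pr(>F)"]
    )
  } else {
    idata <- data.frame(frequency = factor(freqs, levels = freqs))
    mod <- if (nlevels(experiment) > 1) {
      stats::lm(Y ~ experiment)
    } else {
      stats::lm(Y ~ 1)
    }
    av <- car::Anova(mod, idata = idata, idesign = ~frequency, type = 2)
    # zero-variance designs trip sphericity machinery we do not use
    ut <- suppressWarnings(summary(av, multivariate = FALSE))$univariate.tests
    rows <- rownames(ut)
    pick <- setdiff(rows, "(Intercept)")
    table <- data.frame(
      effect = sub("experiment:frequency", "experiment x frequency", pick),
      F = ut[pick, "F value"],
      df1 = ut[pick, "num Df"],
      df2 = ut[pick, "den Df"],
      p = ut[pick, "Pr(>F)"],
      row.names = NULL
    )
    # a zero-variance effect is reported as F = 0, not NaN
    zero_ss <- ut[pick, "Sum Sq"] < 1e-12
    table$F[zero_ss] <- 0
    table$p[zero_ss] <- 1
  }

  tukey <- NULL
  if (nlevels(experiment) > 1) {
    pm <- rowMeans(Y)
    th <- stats::TukeyHSD(stats::aov(pm ~ experiment))$experiment
    tukey <- data.frame(comparison = rownames(th), th, row.names = NULL)
  }

  structure(
    list(table = table, tukey = tukey, n_dropped = sum(!complete),
         n_participants = nrow(wide)),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<mixed ANOVA> %d participants (%d dropped)\n",
              x$n_participants, x$n_dropped))
  print(x$table, row.names = FALSE)
  invisible(x)
}
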