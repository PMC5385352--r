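#' Hamming distance between two binary CC vectors
#'
#' Fraction of positions at which the two vectors differ.
#'
#' @param a,b Equal-length binary (0/1) vectors.
#' @return Value in `[0, 1]`.
#' @export
hamming_distance <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (length(a) == 0) stop("vectors must be non-empty")
  mean(a != b)
}

#' Mean pairwise Hamming distance of a section's CC matrix
#'
#' Averages the Hamming distance over all unordered pairs of rows
#' (participants); for 18 participants that is 153 comparisons. Computed via
#' column counts: a column where `c` of `N` participants are in CC
#' contributes `c (N - c)` differing pairs.
#'
#' @param m Binary matrix, participants x samples.
#' @return Distance score in `[0, 1]`, with attribute `n_pairs`.
#' @export
distance_score <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 participants")
  cs <- colSums(m)
  n_pairs <- n * (n - 1) / 2
  structure(sum(cs * (n - cs)) / (n_pairs * ncol(m)), n_pairs = n_pairs)
}

#' Per-section CC vectors of a cohort
#'
#' Slices each participant's per-trial CC vector into the trial's fixed
#' stimulus sections, giving the unit of the cross-participant similarity
#' analysis (31 sections for the built-in design).
#'
#' @param cohort_analysis Result of [analyze_cohort()].
#' @return List of class `cc_sections`: `vectors[[participant]][[trial]]` is
#'   a list of integer vectors (one per section), plus `meta` (data frame
#'   `trial`, `section`, `n_samples`) and `sample_rate`.
#' @export
section_cc_vectors <- function(cohort_analysis) {
  stim_trials <- cohort_analysis$stim_trials
  rate <- stim_trials[[1]]$trajectory$sample_rate
  analyses <- cohort_analysis$analyses
  n_p <- length(analyses)

  vectors <- lapply(seq_len(n_p), function(p) {
    lapply(seq_along(stim_trials), function(t) {
      st <- stim_trials[[t]]
      total <- max(st$sections$t_end)
      v <- cc_vector(analyses[[p]][[t]], sample_rate = rate, t0 = 0,
                     t_total = total)
      tt <- (seq_along(v) - 1) / rate
      lapply(seq_len(nrow(st$sections)), function(s) {
        v[tt >= st$sections$t_start[s] - 1e-9 &
            tt < st$sections$t_end[s] - 1e-9]
      })
    })
  })

  meta <- do.call(rbind, lapply(seq_along(stim_trials), function(t) {
    data.frame(
      trial = t,
      section = seq_len(nrow(stim_trials[[t]]$sections)),
      n_samples = vapply(vectors[[1]][[t]], length, 0L)
    )
  }))
  structure(list(vectors = vectors, meta = meta, sample_rate = rate),
            class = "cc_sections")
}

#' Real distance scores per stimulus section
#'
#' @param scv A `cc_sections` object (or a compatible list with a `vectors`
#'   element, see [section_cc_vectors()]).
#' @return Data frame `trial`, `section`, `score`.
#' @export
real_distance_scores <- function(scv) {
  vectors <- scv$vectors
  n_p <- length(vectors)
  out <- NULL
  for (t in seq_along(vectors[[1]])) {
    for (s in seq_along(vectors[[1]][[t]])) {
      m <- do.call(rbind, lapply(vectors, function(pv) pv[[t]][[s]]))
      out <- rbind(out, data.frame(trial = t, section = s,
                                   score = as.numeric(distance_score(m))))
    }
  }
  out
}

#' Trial-shuffled null distance scores
#'
#' For every shuffle and every trial section, each participant's CC vector
#' is replaced by their own vector from a uniformly random trial at the same
#' section index (the section order is never shuffled). Vectors from trials
#' whose sections differ in length are compared on the overlapping prefix
#' (cropped to the shortest section at that index). Scores are averaged over
#' shuffles. Deterministic given `seed`.
#'
#' @param scv A `cc_sections` object.
#' @param n_shuffles Number of shuffled datasets.
#' @param seed Integer seed governing all draws.
#' @return Data frame `trial`, `section`, `null_score`.
#' @export
shuffle_null <- function(scv, n_shuffles = 10000, seed = 1) {
  vectors <- scv$vectors
  n_p <- length(vectors)
  if (n_p < 2) stop("need at least 2 participants")
  n_trials <- length(vectors[[1]])
  n_sections <- max(vapply(vectors[[1]], length, 0L))
  set.seed(seed)

  pairs <- utils::combn(n_p, 2)
  n_pairs <- ncol(pairs)
  out <- NULL

  for (s in seq_len(n_sections)) {
    trials_s <- which(vapply(vectors[[1]], function(tv) length(tv) >= s, TRUE))
    if (length(trials_s) == 0) next
    L <- min(vapply(trials_s, function(t) length(vectors[[1]][[t]][[s]]), 0L))
    # stack cropped vectors: row id (p - 1) * n_trials_s + trial slot
    n_ts <- length(trials_s)
    V <- matrix(0, nrow = n_p * n_ts, ncol = L)
    for (p in seq_len(n_p)) {
      for (j in seq_len(n_ts)) {
        V[(p - 1) * n_ts + j, ] <- vectors[[p]][[trials_s[j]]][[s]][seq_len(L)]
      }
    }
    G <- tcrossprod(V)
    r <- diag(G)
    H <- (outer(r, rep(1, length(r))) + outer(rep(1, length(r)), r) - 2 * G) / L

    slots <- trials_s  # one null score per (trial, s) slot
    n_draws <- n_shuffles * length(slots)
    # independent uniform trial choice per participant, shuffle and slot
    U <- matrix(sample.int(n_ts, n_p * n_draws, replace = TRUE),
                nrow = n_p)
    total <- numeric(n_draws)
    for (k in seq_len(n_pairs)) {
      p <- pairs[1, k]; q <- pairs[2, k]
      rows_p <- (p - 1) * n_ts + U[p, ]
      rows_q <- (q - 1) * n_ts + U[q, ]
      total <- total + H[cbind(rows_p, rows_q)]
    }
    scores <- matrix(total / n_pairs, nrow = n_shuffles)
    out <- rbind(out, data.frame(trial = slots, section = s,
                                 null_score = colMeans(scores)))
  }
  out[order(out$trial, out$section), ]
}

#' Compare real and null distance scores with a matched-pair t-test
#'
#' Section scores are first averaged within trial (11 matched pairs for the
#' built-in design, giving the test 10 degrees of freedom), then compared
#' with a two-sided paired t-test. Lower real scores mean participants place
#' their CC segments more similarly than chance.
#'
#' @param real Data frame from [real_distance_scores()].
#' @param null Data frame from [shuffle_null()].
#' @return List of class `similarity_result`: `t_statistic`, `df`,
#'   `p_value`, `ci95`, `real_mean`, `real_sd`, `null_mean`, `null_sd`
#'   (mean/SD over section scores), `by_trial` (matched pairs),
#'   `degenerate` flag.
#' @export
compare_real_vs_null <- function(real, null) {
  m <- merge(real, null, by = c("trial", "section"))
  if (nrow(m) == 0) stop("no matching trial sections")
  by_trial <- do.call(rbind, lapply(split(m, m$trial), function(d) {
    data.frame(trial = d$trial[1], real = mean(d$score),
               null = mean(d$null_score))
  }))
  diffs <- by_trial$real - by_trial$null
  degenerate <- stats::sd(diffs) < 1e-10 * max(1, abs(mean(diffs)))
  if (degenerate) {
    t_stat <- if (mean(diffs) == 0) 0 else sign(mean(diffs)) * Inf
    p <- if (mean(diffs) == 0) 1 else 0
    ci <- c(mean(diffs), mean(diffs))
  } else {
    tt <- stats::t.test(by_trial$real, by_trial$null, paired = TRUE)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
    ci <- as.numeric(tt$conf.int)
  }
  structure(
    list(
      t_statistic = t_stat, df = nrow(by_trial) - 1, p_value = p, ci95 = ci,
      real_mean = mean(m$score), real_sd = stats::sd(m$score),
      null_mean = mean(m$null_score), null_sd = stats::sd(m$null_score),
      by_trial = by_trial, degenerate = degenerate
    ),
    class = "similarity_result"
  )
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf(
    "<similarity> real %.3f +- %.3f vs null %.3f +- %.3f; t(%d) = %.2f, p = %.3g\n",
    x$real_mean, x$real_sd, x$null_mean, x$null_sd, x$df, x$t_statistic,
    x$p_value
  ))
  invisible(x)
}

#' End-to-end similarity analysis of an analyzed cohort
#'
#' @param cohort_analysis Result of [analyze_cohort()].
#' @param n_shuffles,seed Passed to [shuffle_null()].
#' @return A `similarity_result` with the `real` and `null` score tables
#'   attached as `real_scores` / `null_scores`.
#' @export
similarity_analysis <- function(cohort_analysis, n_shuffles = 10000,
                                seed = 1) {
  scv <- section_cc_vectors(cohort_analysis)
  real <- real_distance_scores(scv)
  null <- shuffle_null(scv, n_shuffles = n_shuffles, seed = seed)
  res <- compare_real_vs_null(real, null)
  res$real_scores <- real
  res$null_scores <- null
  res
}
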