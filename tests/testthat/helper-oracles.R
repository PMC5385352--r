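# Independent oracles, written from first principles and kept separate from
# the implementation paths they check.

# dense brute-force sign-change scan of an acceleration function
oracle_azc_scan <- function(accel_fun, t_min, t_max, rate = 10000) {
  t <- seq(t_min, t_max, by = 1 / rate)
  a <- accel_fun(t)
  s <- sign(a)
  nz <- which(s != 0)
  s_f <- s
  last <- s[nz[1]]
  for (i in seq_along(s_f)) {
    if (s_f[i] == 0) s_f[i] <- last else last <- s_f[i]
  }
  ch <- which(s_f[-1] != s_f[-length(s_f)])
  t[ch] + (t[ch + 1] - t[ch]) * a[ch] / (a[ch] - a[ch + 1])
}

# minimum-jerk closed forms (duplicated here on purpose)
oracle_mj_accel <- function(t, onset, dur, disp) {
  tau <- (t - onset) / dur
  out <- numeric(length(t))
  inside <- tau > 0 & tau < 1
  out[inside] <- disp / dur^2 *
    (60 * tau[inside] - 180 * tau[inside]^2 + 120 * tau[inside]^3)
  out
}

# exhaustive optimal one-to-one matching within tolerance: maximize number
# of matches, then minimize total |dt|; enumerates all injections (small n)
oracle_match <- function(r, s, tol) {
  nr <- length(r)
  ns <- length(s)
  best <- list(n = -1L, cost = Inf)
  subsets_r <- lapply(0:(2^nr - 1), function(m) which(bitwAnd(m, 2^(seq_len(nr) - 1)) > 0))
  for (sub in subsets_r) {
    k <- length(sub)
    if (k > ns) next
    if (k < best$n) next
    if (k == 0) {
      cand_cost <- 0
      if (k > best$n || cand_cost < best$cost) best <- list(n = k, cost = cand_cost)
      next
    }
    idx <- utils::combn(ns, k)
    for (j in seq_len(ncol(idx))) {
      perms <- if (k == 1) matrix(1) else do.call(rbind, combinat_perms(k))
      for (pi in seq_len(nrow(perms))) {
        assign_s <- idx[perms[pi, ], j]
        dts <- abs(r[sub] - s[assign_s])
        if (all(dts <= tol)) {
          cost <- sum(dts)
          if (k > best$n || (k == best$n && cost < best$cost)) {
            best <- list(n = k, cost = cost)
          }
        }
      }
    }
  }
  best
}

combinat_perms <- function(k) {
  if (k == 1) return(list(1))
  out <- list()
  for (p in combinat_perms(k - 1)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1]] <- append(p, k, after = pos - 1)
    }
  }
  out
}

# definitional sums-of-squares for a balanced split-plot design
# (between factor g, subjects nested in g, within factor k)
oracle_splitplot <- function(y, group, subject, within) {
  group <- factor(group); subject <- factor(subject); within <- factor(within)
  G <- nlevels(group); K <- nlevels(within)
  n <- nlevels(subject) / G
  m <- mean(y)
  m_s <- tapply(y, subject, mean)
  m_g <- tapply(y, group, mean)
  m_k <- tapply(y, within, mean)
  m_gk <- tapply(y, list(group, within), mean)
  grp_of_subj <- tapply(as.character(group), subject, function(v) v[1])

  ss_exp <- n * K * sum((m_g - m)^2)
  ss_subj <- K * sum((m_s - m_g[grp_of_subj])^2)
  ss_freq <- G * n * sum((m_k - m)^2)
  ss_int <- n * sum((m_gk - outer(m_g, rep(1, K)) -
                       outer(rep(1, G), m_k) + m)^2)
  ss_tot <- sum((y - m)^2)
  ss_err <- ss_tot - ss_exp - ss_subj - ss_freq - ss_int

  df_exp <- G - 1; df_subj <- G * (n - 1)
  df_freq <- K - 1; df_int <- (G - 1) * (K - 1)
  df_err <- (K - 1) * G * (n - 1)
  data.frame(
    effect = c("experiment", "frequency", "experiment x frequency"),
    F = c((ss_exp / df_exp) / (ss_subj / df_subj),
          (ss_freq / df_freq) / (ss_err / df_err),
          (ss_int / df_int) / (ss_err / df_err)),
    df1 = c(df_exp, df_freq, df_int),
    df2 = c(df_subj, df_err, df_err)
  )
}

# exhaustive mean of the trial-shuffled null for tiny cases:
# vectors[[p]][[t]][[s]]; enumerates every per-participant trial assignment
oracle_shuffle_mean <- function(vectors, section) {
  n_p <- length(vectors)
  trials <- which(vapply(vectors[[1]], function(tv) length(tv) >= section, TRUE))
  L <- min(vapply(trials, function(t) length(vectors[[1]][[t]][[section]]), 0L))
  grid <- do.call(expand.grid, rep(list(trials), n_p))
  pairs <- utils::combn(n_p, 2)
  scores <- apply(grid, 1, function(u) {
    tot <- 0
    for (k in seq_len(ncol(pairs))) {
      a <- vectors[[pairs[1, k]]][[u[pairs[1, k]]]][[section]][seq_len(L)]
      b <- vectors[[pairs[2, k]]][[u[pairs[2, k]]]][[section]][seq_len(L)]
      tot <- tot + mean(a != b)
    }
    tot / ncol(pairs)
  })
  mean(scores)
}
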