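# Shared fixtures and independent oracles.

uk_fix <- uk_inputs()
china_fix <- china_inputs()

# Brute-force frontier oracle: a strategy is excluded iff some other strategy,
# or a convex combination of two others, attains at least its QALYs at no
# more than its cost (strictly better on one axis). Intended for continuous
# random planes (no exact ties).
oracle_on_frontier <- function(df) {
  n <- nrow(df)
  vapply(seq_len(n), function(i) {
    ci <- df$cost[i]; qi <- df$qaly[i]
    for (j in seq_len(n)) {
      if (j == i) next
      if (df$cost[j] <= ci && df$qaly[j] >= qi &&
          (df$cost[j] < ci || df$qaly[j] > qi)) return(FALSE)
    }
    for (j in seq_len(n)) {
      for (k in seq_len(n)) {
        if (j == i || k == i || j == k) next
        qj <- df$qaly[j]; qk <- df$qaly[k]
        if (qj < qi && qi < qk) {
          th <- (qi - qk) / (qj - qk)
          mix_cost <- th * df$cost[j] + (1 - th) * df$cost[k]
          if (mix_cost < ci) return(FALSE)
        }
      }
    }
    TRUE
  }, logical(1))
}

# Tolerance for a ratio (c_a - c_b)/(q_a - q_b) recomputed from printed
# values: the widest deviation reachable by perturbing each printed cost by
# +/- cost_ulp/2 and each printed QALY by +/- qaly_ulp/2.
printed_ratio_band <- function(ca, cb, qa, qb, cost_ulp = 1, qaly_ulp = 0.001) {
  dc <- ca - cb
  dq <- qa - qb
  dcs <- dc + c(-1, 1) * cost_ulp
  dqs <- dq + c(-1, 1) * qaly_ulp
  range(outer(dcs, dqs, "/"))
}

# Direct O(H^2) per-entrant accounting of the PD pathway cost; the
# independent oracle for the tunnel recursion.
pd_cost_oracle <- function(trace, profile) {
  H <- trace$horizon_weeks
  out <- numeric(H)
  entrants <- c(0, trace$new_pd[seq_len(H - 1)])
  alive <- numeric(H)  # alive[j]: current mass of the cohort that entered at j
  for (k in seq_len(H)) {
    alive[k] <- entrants[k]
    js <- which(alive[seq_len(k)] > 0)
    out[k] <- sum(alive[js] * profile[k - js + 1])
    alive[seq_len(k)] <- alive[seq_len(k)] * (1 - trace$q_pd_death[k])
  }
  out
}

# Minimal two-arm input set (reference + one TKI) for focused engine tests.
tiny_inputs <- function(seed = 99L, horizon = 260L) {
  gi <- gen_inputs(seed = seed, n_arms = 2L)
  gi$horizon_weeks <- as.integer(horizon)
  gi
}
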