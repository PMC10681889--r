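# Independent oracles used to cross-check the package implementations.
# These deliberately re-derive each quantity from first principles rather
# than calling the code path under test.

# ---- Efron partial log-likelihood for a single covariate ------------------
# brute-force objective; maximized with optimize() over a wide bracket
efron_loglik <- function(beta, time, status, x) {
  ll <- 0
  for (t in sort(unique(time[status == 1]))) {
    d_idx <- which(time == t & status == 1)
    r_idx <- which(time >= t)
    d <- length(d_idx)
    s_risk <- sum(exp(x[r_idx] * beta))
    s_tied <- sum(exp(x[d_idx] * beta))
    ll <- ll + sum(x[d_idx] * beta)
    for (l in seq_len(d) - 1)
      ll <- ll - log(s_risk - (l / d) * s_tied)
  }
  ll
}

efron_grid_mle <- function(time, status, x, lower = -8, upper = 8) {
  stats::optimize(function(b) efron_loglik(b, time, status, x),
                  c(lower, upper), maximum = TRUE, tol = 1e-9)$maximum
}

# ---- hand product-limit Kaplan-Meier --------------------------------------
km_hand <- function(time, status, at) {
  s <- 1
  for (t in sort(unique(time[status == 1]))) {
    if (t > at) break
    n_risk <- sum(time >= t)
    d <- sum(time == t & status == 1)
    s <- s * (1 - d / n_risk)
  }
  s
}

# ---- hand two-group log-rank (hypergeometric O-E / V) ---------------------
logrank_hand <- function(time, status, group) {
  g <- as.integer(as.factor(group)) - 1L  # 0/1
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[status == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1L)
    d <- sum(time == t & status == 1)
    d1 <- sum(time == t & status == 1 & g == 1L)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(statistic = o_minus_e^2 / v, o_minus_e = o_minus_e, v = v)
}

# ---- exhaustive-pair Harrell concordance ----------------------------------
harrell_c_hand <- function(time, status, risk) {
  conc <- disc <- tied <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    # usable pair: the earlier time is an observed event
    if (time[i] == time[j]) next
    a <- if (time[i] < time[j]) i else j   # earlier
    b <- if (time[i] < time[j]) j else i
    if (status[a] != 1) next
    if (risk[a] > risk[b]) conc <- conc + 1
    else if (risk[a] < risk[b]) disc <- disc + 1
    else tied <- tied + 1
  }
  (conc + 0.5 * tied) / (conc + disc + tied)
}

# ---- independent definite/provisional enumeration -------------------------
# iterates the 16 combinations in reverse order, building the group set
# directly from the rule table, with uncertain chromosomes free and the
# others pinned at their observed value
assign_risk_oracle <- function(statuses, rule) {
  chroms <- c("5", "17", "18", "20")
  groups <- character(0)
  for (code in 15:0) {
    bits <- as.integer(intToBits(code))[1:4]
    names(bits) <- chroms
    ok <- TRUE
    for (ch in chroms) {
      if (statuses[[ch]] == "gained" && bits[[ch]] != 1L) ok <- FALSE
      if (statuses[[ch]] == "not_gained" && bits[[ch]] != 0L) ok <- FALSE
    }
    if (!ok) next
    key <- paste(bits[c("5", "17", "18", "20")], collapse = ",")
    groups <- c(groups, rule$table[[key]])
  }
  base_bits <- ifelse(statuses[chroms] == "gained", 1L, 0L)
  baseline <- rule$table[[paste(base_bits, collapse = ",")]]
  list(definite = length(unique(groups)) == 1L, baseline = baseline,
       groups = groups)
}

# ---- karyotype string fuzzer ----------------------------------------------
mutate_karyotype <- function(k) {
  ops <- sample(1:5, 1)
  switch(ops,
         { # inject garbage token
           parts <- strsplit(k, ",", fixed = TRUE)[[1]]
           junk <- sample(c("??", "+foo", "qq(3)", "+", "-", "x!"), 1)
           pos <- sample(seq_along(parts), 1)
           paste(append(parts, junk, after = pos), collapse = ",")
         },
         substr(k, 1, max(1, nchar(k) - sample(1:5, 1))),  # truncate
         gsub("[0-9]", "", k),                              # strip digits
         paste0(k, "/", k),                                 # duplicate clone
         chartr("+-", "-+", k))                             # flip signs
}

# ---- piecewise-exponential times with a hazard change at t = 2 ------------
sim_time_varying <- function(n, lambda, mult_after2) {
  t1 <- stats::rexp(n, lambda)
  late <- t1 > 2
  t1[late] <- 2 + stats::rexp(sum(late), lambda * mult_after2)
  t1
}

default_rule <- hehrisk::load_risk_rule()
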