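# Independent reference implementations used as oracles. These deliberately
# share no code with the package: plain loops, enumeration and closed forms.

# --- toy rate tables -------------------------------------------------------

# rates: named list condition -> named list stimulus -> numeric vector of
# per-repetition evoked rates
toy_rate_table <- function(rates, protocol = "bar", site_id = "toy",
                           region = "Imc") {
  rows <- list()
  for (cond in names(rates)) {
    for (stim in names(rates[[cond]])) {
      v <- rates[[cond]][[stim]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        site_id = site_id, region = region, condition = cond,
        protocol = protocol, stimulus_key = as.numeric(stim),
        competitor_present = protocol == "loom_pair",
        repetition_index = seq_along(v), evoked_rate_spps = v)
    }
  }
  dplyr::bind_rows(rows)
}

# pairs: condition -> stimulus -> 2-column matrix (x = S1 alone, y = S1&S2)
toy_pair_rate_table <- function(pairs, site_id = "toy", region = "Imc") {
  rows <- list()
  for (cond in names(pairs)) {
    for (stim in names(pairs[[cond]])) {
      m <- pairs[[cond]][[stim]]
      for (proto in c("loom_single", "loom_pair")) {
        v <- if (proto == "loom_single") m[, 1] else m[, 2]
        rows[[length(rows) + 1]] <- tibble::tibble(
          site_id = site_id, region = region, condition = cond,
          protocol = proto, stimulus_key = as.numeric(stim),
          competitor_present = proto == "loom_pair",
          repetition_index = seq_along(v), evoked_rate_spps = v)
      }
    }
  }
  dplyr::bind_rows(rows)
}

# --- closed-form / quadrature oracles --------------------------------------

# expected DoG bar response by numerical integration of the two Gaussian
# densities over the bar extent [-L/2, L/2]
oracle_bar_response <- function(L, amp_exc, sigma_exc, amp_inh, sigma_inh) {
  mass <- function(sigma) {
    stats::integrate(function(u) stats::dnorm(u, 0, sigma), -L / 2, L / 2,
                     rel.tol = 1e-12)$value
  }
  max(0, amp_exc * mass(sigma_exc) - amp_inh * mass(sigma_inh))
}

# suppression index recomputed naively
oracle_si <- function(means, lengths) {
  means <- means[order(lengths)]
  peak <- max(means)
  asym <- mean(rev(means)[1:3])
  (peak - asym) / peak
}

# OLS via the normal equations
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# --- exhaustive permutation oracles ----------------------------------------

# all balanced reassignments for the SI test: at each stimulus value the
# pooled values are split into every (n_a choose pooled) subset; the cross
# product over stimulus values is walked with nested recursion
oracle_perm_si_exhaustive <- function(rates_a, rates_b, sign = 1) {
  stims <- names(rates_a)
  lengths <- as.numeric(stims)
  obs <- sign * (oracle_si(sapply(rates_a, mean), lengths) -
                   oracle_si(sapply(rates_b, mean), lengths))
  combos <- lapply(stims, function(s) {
    pool <- c(rates_a[[s]], rates_b[[s]])
    idx <- utils::combn(length(pool), length(rates_a[[s]]))
    lapply(seq_len(ncol(idx)), function(j) {
      list(a = pool[idx[, j]], b = pool[-idx[, j]])
    })
  })
  nulls <- c()
  walk <- function(level, ma, mb) {
    if (level > length(combos)) {
      nulls <<- c(nulls, sign * (oracle_si(ma, lengths) - oracle_si(mb, lengths)))
      return(invisible())
    }
    for (split in combos[[level]]) {
      walk(level + 1, c(ma, mean(split$a)), c(mb, mean(split$b)))
    }
  }
  walk(1, c(), c())
  tol <- 1e-9 * (1 + abs(obs))
  list(observed = obs, null = nulls,
       p = sum(nulls >= obs - tol) / length(nulls))
}

# same for the slope test, shuffling (x, y) pairs as units
oracle_perm_slope_exhaustive <- function(pairs_a, pairs_b, sign = 1) {
  stims <- names(pairs_a)
  slope_of <- function(mats) {
    x <- sapply(mats, function(m) mean(m[, 1]))
    y <- sapply(mats, function(m) mean(m[, 2]))
    oracle_ols(x, y)[["slope"]]
  }
  obs <- sign * (slope_of(pairs_b) - slope_of(pairs_a))
  combos <- lapply(stims, function(s) {
    pool <- rbind(pairs_a[[s]], pairs_b[[s]])
    idx <- utils::combn(nrow(pool), nrow(pairs_a[[s]]))
    lapply(seq_len(ncol(idx)), function(j) {
      list(a = pool[idx[, j], , drop = FALSE],
           b = pool[-idx[, j], , drop = FALSE])
    })
  })
  nulls <- c()
  walk <- function(level, as, bs) {
    if (level > length(combos)) {
      nulls <<- c(nulls, sign * (slope_of(bs) - slope_of(as)))
      return(invisible())
    }
    for (split in combos[[level]]) {
      walk(level + 1, c(as, list(split$a)), c(bs, list(split$b)))
    }
  }
  walk(1, list(), list())
  tol <- 1e-9 * (1 + abs(obs))
  list(observed = obs, null = nulls,
       p = sum(nulls >= obs - tol) / length(nulls))
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
oracle_signrank_enum <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}
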