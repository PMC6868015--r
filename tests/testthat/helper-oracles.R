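# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use different mechanics (scalar
# scans, double loops, dynamic programming, svd) than the functions they
# check.

# STTC by scalar interval merging and double-loop coincidence counting
sttc_oracle <- function(a, b, dt, duration) {
  tile <- function(tr) {
    s <- pmax(tr - dt, 0)
    e <- pmin(tr + dt, duration)
    tot <- 0
    cur_s <- s[1]
    cur_e <- e[1]
    if (length(tr) > 1) {
      for (i in 2:length(tr)) {
        if (s[i] <= cur_e) {
          cur_e <- max(cur_e, e[i])
        } else {
          tot <- tot + cur_e - cur_s
          cur_s <- s[i]
          cur_e <- e[i]
        }
      }
    }
    (tot + cur_e - cur_s) / duration
  }
  prop <- function(x, y) {
    hits <- 0
    for (xi in x) {
      for (yi in y) {
        if (abs(xi - yi) <= dt) {
          hits <- hits + 1
          break
        }
      }
    }
    hits / length(x)
  }
  t_a <- tile(a)
  t_b <- tile(b)
  p_a <- prop(a, b)
  p_b <- prop(b, a)
  terms <- c()
  if (1 - p_a * t_b != 0) terms <- c(terms, (p_a - t_b) / (1 - p_a * t_b))
  if (1 - p_b * t_a != 0) terms <- c(terms, (p_b - t_a) / (1 - p_b * t_a))
  if (length(terms) == 0) return(NA_real_)
  mean(terms)
}

# exhaustive scalar run-scan burst detector
burst_oracle <- function(train, isith, min_spikes = 5, max_core = 0.1) {
  n <- length(train)
  res <- list()
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && train[j + 1] - train[j] <= isith) j <- j + 1
    if (j > i) {
      ok <- TRUE
      if (isith > max_core) {
        ok <- FALSE
        for (k in i:(j - 1)) {
          if (train[k + 1] - train[k] <= max_core) ok <- TRUE
        }
      }
      if (ok && j - i + 1 >= min_spikes) {
        res[[length(res) + 1]] <- c(train[i], train[j], j - i + 1)
      }
    }
    i <- j + 1
  }
  if (length(res) == 0) {
    return(tibble::tibble(t_start_s = numeric(), t_end_s = numeric(),
                          n_spikes = integer()))
  }
  m <- do.call(rbind, res)
  tibble::tibble(t_start_s = m[, 1], t_end_s = m[, 2],
                 n_spikes = as.integer(m[, 3]))
}

# maximum one-to-one matching between two sorted time lists with a
# coincidence window, by LCS-style dynamic programming
max_matching_oracle <- function(a, b, tol) {
  na <- length(a)
  nb <- length(b)
  dp <- matrix(0L, na + 1, nb + 1)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      best <- max(dp[i, j + 1], dp[i + 1, j])
      if (abs(a[i] - b[j]) <= tol) best <- max(best, dp[i, j] + 1L)
      dp[i + 1, j + 1] <- best
    }
  }
  dp[na + 1, nb + 1]
}

# PCA by singular value decomposition of the centred matrix
pca_svd_oracle <- function(m) {
  centred <- sweep(m, 2, colMeans(m))
  sv <- svd(centred)
  vars <- sv$d^2 / (nrow(m) - 1)
  list(explained_pct = 100 * vars / sum(vars),
       loadings = sv$v, scores = centred %*% sv$v)
}

# fraction of times in a that have a partner in b within tol
frac_matched <- function(a, b, tol = 0.001) {
  if (length(a) == 0) return(NA_real_)
  if (length(b) == 0) return(0)
  mean(vapply(a, function(x) any(abs(b - x) <= tol), logical(1)))
}
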