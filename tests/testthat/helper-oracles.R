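# Independent brute-force oracles.  These deliberately use naive loops and
# direct textbook formulas, never the package's vectorized code paths.

# symmetric co-occurrence counts by explicit pair enumeration
oracle_glcm_counts <- function(L, Ng, off) {
  P <- matrix(0, Ng, Ng)
  for (r in seq_len(nrow(L))) for (c in seq_len(ncol(L))) {
    r2 <- r + off[1]; c2 <- c + off[2]
    if (r2 < 1 || r2 > nrow(L) || c2 < 1 || c2 > ncol(L)) next
    a <- L[r, c]; b <- L[r2, c2]
    if (a > 0 && b > 0) {
      P[a, b] <- P[a, b] + 1
      P[b, a] <- P[b, a] + 1
    }
  }
  P
}

# run-length counts by walking each scan line
oracle_glrlm_counts <- function(L, Ng, off) {
  counted <- matrix(FALSE, nrow(L), ncol(L))
  runs <- list()
  for (r in seq_len(nrow(L))) for (c in seq_len(ncol(L))) {
    if (L[r, c] == 0 || counted[r, c]) next
    # only start a run if the previous cell along the direction differs
    pr <- r - off[1]; pc <- c - off[2]
    if (pr >= 1 && pr <= nrow(L) && pc >= 1 && pc <= ncol(L) &&
        L[pr, pc] == L[r, c]) next
    len <- 0; rr <- r; cc <- c
    while (rr >= 1 && rr <= nrow(L) && cc >= 1 && cc <= ncol(L) &&
           L[rr, cc] == L[r, c]) {
      counted[rr, cc] <- TRUE
      len <- len + 1
      rr <- rr + off[1]; cc <- cc + off[2]
    }
    runs[[length(runs) + 1]] <- c(L[r, c], len)
  }
  if (!length(runs)) return(matrix(0, Ng, 1))
  rl <- do.call(rbind, runs)
  cnt <- matrix(0, Ng, max(rl[, 2]))
  for (i in seq_len(nrow(rl))) cnt[rl[i, 1], rl[i, 2]] <-
      cnt[rl[i, 1], rl[i, 2]] + 1
  cnt
}

# zones by recursive 8-connected flood fill
oracle_glszm_zones <- function(L) {
  seen <- matrix(FALSE, nrow(L), ncol(L))
  zones <- list()
  for (r in seq_len(nrow(L))) for (c in seq_len(ncol(L))) {
    if (L[r, c] == 0 || seen[r, c]) next
    lvl <- L[r, c]
    stack <- list(c(r, c)); size <- 0
    seen[r, c] <- TRUE
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- cur[1] + dr; cc <- cur[2] + dc
        if (rr < 1 || rr > nrow(L) || cc < 1 || cc > ncol(L)) next
        if (!seen[rr, cc] && L[rr, cc] == lvl) {
          seen[rr, cc] <- TRUE
          stack[[length(stack) + 1]] <- c(rr, cc)
        }
      }
    }
    zones[[length(zones) + 1]] <- c(lvl, size)
  }
  do.call(rbind, zones)
}

# dependence counts by explicit neighbourhood loops
oracle_gldm_counts <- function(L, Ng) {
  deps <- list()
  for (r in seq_len(nrow(L))) for (c in seq_len(ncol(L))) {
    if (L[r, c] == 0) next
    d <- 1
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nrow(L) || cc < 1 || cc > ncol(L)) next
      if (L[rr, cc] == L[r, c]) d <- d + 1
    }
    deps[[length(deps) + 1]] <- c(L[r, c], d)
  }
  dl <- do.call(rbind, deps)
  cnt <- matrix(0, Ng, max(dl[, 2]))
  for (i in seq_len(nrow(dl))) cnt[dl[i, 1], dl[i, 2]] <-
      cnt[dl[i, 1], dl[i, 2]] + 1
  cnt
}

# NGTDM n_i, s_i by explicit loops
oracle_ngtdm <- function(L, Ng) {
  n_i <- numeric(Ng); s_i <- numeric(Ng); Nvp <- 0
  for (r in seq_len(nrow(L))) for (c in seq_len(ncol(L))) {
    if (L[r, c] == 0) next
    nb <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nrow(L) || cc < 1 || cc > ncol(L)) next
      if (L[rr, cc] > 0) nb <- c(nb, L[rr, cc])
    }
    if (!length(nb)) next
    Nvp <- Nvp + 1
    lvl <- L[r, c]
    n_i[lvl] <- n_i[lvl] + 1
    s_i[lvl] <- s_i[lvl] + abs(lvl - mean(nb))
  }
  list(n = n_i, s = s_i, Nvp = Nvp)
}

# ICC(2,1) from aov() mean squares (independent ANOVA machinery)
oracle_icc <- function(m) {
  df <- data.frame(v = as.vector(m),
                   subj = factor(rep(seq_len(nrow(m)), ncol(m))),
                   rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  a <- summary(stats::aov(v ~ subj + rater, data = df))[[1]]
  msr <- a["subj", "Mean Sq"]
  msc <- a["rater", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  n <- nrow(m); k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# AUC by exhaustive positive/negative pair counting
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# plug-in MI by direct summation over a contingency table of counts
oracle_mi_table <- function(tab) {
  n <- sum(tab)
  out <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    if (tab[i, j] == 0) next
    pij <- tab[i, j] / n
    out <- out + pij * log(pij / (sum(tab[i, ]) / n * sum(tab[, j]) / n))
  }
  out
}

# Kaplan-Meier product-limit values by hand
oracle_km <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  s <- 1; out <- numeric(0)
  for (t in ut) {
    n_risk <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / n_risk)
    out <- c(out, s)
  }
  data.frame(time = ut, surv = out)
}

# two-group log-rank chi-square by direct O-E accumulation
oracle_logrank <- function(times, events, group) {
  g1 <- sort(unique(group))[1]
  ut <- sort(unique(times[events == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ut) {
    at <- times >= t
    n <- sum(at); n1 <- sum(at & group == g1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}
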