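# independent brute-force implementations used as oracles
fmax_oracle <- function(y, s) {
  best <- 0; best_t <- NA
  for (t in seq(0.01, 1, 0.01)) {
    prs <- c(); rcs <- c()
    for (i in seq_len(nrow(y))) {
      pred <- which(s[i, ] >= t)
      if (length(pred) > 0) {
        prs <- c(prs, sum(y[i, pred] == 1) / length(pred))
      }
      tru <- which(y[i, ] == 1)
      if (length(tru) > 0) {
        rcs <- c(rcs, sum(s[i, tru] >= t) / length(tru))
      }
    }
    if (length(prs) == 0) next
    pr <- mean(prs); rc <- mean(rcs)
    if (pr + rc > 0) {
      f <- 2 * pr * rc / (pr + rc)
      if (f > best + 1e-15) { best <- f; best_t <- t }
    }
  }
  list(fmax = best, threshold = best_t)
}

aupr_oracle <- function(y, s) {
  yv <- as.numeric(y); sv <- as.numeric(s)
  ord <- order(-sv, seq_along(sv))
  yv <- yv[ord]
  area <- 0; tp <- 0
  for (k in seq_along(yv)) {
    if (yv[k] == 1) { tp <- tp + 1; area <- area + tp / k }
  }
  area / sum(yv)
}

smin_oracle <- function(y, s, ic) {
  best <- Inf
  for (t in seq(0.01, 1, 0.01)) {
    ru <- 0; mi <- 0
    for (i in seq_len(nrow(y))) {
      for (j in seq_len(ncol(y))) {
        if (y[i, j] == 1 && s[i, j] < t) ru <- ru + ic[j]
        if (y[i, j] == 0 && s[i, j] >= t) mi <- mi + ic[j]
      }
    }
    best <- min(best, sqrt((ru / nrow(y))^2 + (mi / nrow(y))^2))
  }
  best
}

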