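# independent brute-force oracles, deliberately implemented differently
# from the package internals

# Passing-Bablok slope via explicit double loop and direct order
# statistics of the shifted median
oracle_pb_slope <- function(x, y) {
  s <- c()
  n <- length(x)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (x[j] != x[i]) {
      sl <- (y[j] - y[i]) / (x[j] - x[i])
      if (sl != -1) s <- c(s, sl)
    }
  }
  s <- sort(s)
  N <- length(s)
  K <- sum(s < -1)
  if (N %% 2 == 1) s[(N + 1) / 2 + K] else
    (s[N / 2 + K] + s[N / 2 + 1 + K]) / 2
}

# exhaustive Youden scan over every candidate cutoff, recomputing
# sensitivity/specificity by explicit counting
oracle_youden <- function(scores, labels, direction = "higher_abnormal") {
  u <- sort(unique(scores))
  cand <- c(-Inf, (u[-1] + u[-length(u)]) / 2, Inf)
  best <- NULL
  for (cth in cand) {
    call_pos <- if (direction == "higher_abnormal") scores >= cth else
      scores <= cth
    sens <- sum(call_pos & labels == 1) / sum(labels == 1)
    spec <- sum(!call_pos & labels == 0) / sum(labels == 0)
    j <- sens + spec - 1
    rec <- list(cutoff = cth, j = j, spec = spec)
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 &&
         (spec > best$spec ||
          (spec == best$spec && abs(cth) < abs(best$cutoff)))))
      best <- rec
  }
  best$cutoff
}

# AUC as the Mann-Whitney U statistic over all case/control pairs
oracle_auc <- function(scores, labels) {
  s1 <- scores[labels == 1]
  s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) tot <- tot + sum(a > s0) + 0.5 * sum(a == s0)
  tot / (length(s1) * length(s0))
}
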