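# Independent, loop-based oracles used to check the vectorized pipeline.
# These deliberately avoid stats::cor and the package's own code paths.

loopPearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  if (dx == 0 || dy == 0) return(0)
  num / sqrt(dx * dy)
}

# midranks (average ranks) computed by counting, not by rank()
loopMidranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- sum(x < x[i])
    ties <- sum(x == x[i])
    r[i] <- less + (ties + 1) / 2
  }
  r
}

loopSpearman <- function(x, y) loopPearson(loopMidranks(x), loopMidranks(y))

# loop-based evaluation of the full two-stage pipeline for tiny inputs
loopIbfe <- function(mats, kinds = c("pearson", "spearman")) {
  m <- nrow(mats[[1]])
  blocks <- list()
  for (X in mats) for (kind in kinds) {
    S <- matrix(0, m, m)
    f <- if (kind == "pearson") loopPearson else loopSpearman
    for (a in seq_len(m)) for (b in seq_len(m))
      S[a, b] <- if (a == b) 1 else f(X[a, ], X[b, ])
    blocks[[length(blocks) + 1]] <- S
  }
  Y <- do.call(cbind, blocks)
  Z <- matrix(0, m, m)
  for (a in seq_len(m)) for (b in seq_len(m))
    Z[a, b] <- if (a == b) 1 else loopPearson(Y[a, ], Y[b, ])
  Z
}

# entropy / mutual-information oracle from explicit pair counting
loopNMI <- function(a, b) {
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  cnt <- matrix(0, length(ua), length(ub))
  for (i in seq_len(n))
    cnt[match(a[i], ua), match(b[i], ub)] <- cnt[match(a[i], ua), match(b[i], ub)] + 1
  pij <- cnt / n; pa <- rowSums(pij); pb <- colSums(pij)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  if (H(pa) == 0 || H(pb) == 0) stop("degenerate partition in oracle")
  mi <- 0
  for (i in seq_along(ua)) for (j in seq_along(ub))
    if (pij[i, j] > 0) mi <- mi + pij[i, j] * log(pij[i, j] / (pa[i] * pb[j]))
  mi / sqrt(H(pa) * H(pb))
}

# two-group log-rank statistic from explicit observed-minus-expected sums
loopLogrank <- function(time, event, group) {
  tts <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (tt in tts) {
    atRisk <- time >= tt
    n <- sum(atRisk); n1 <- sum(atRisk & group)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & group)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# Kaplan-Meier product-limit computed by an explicit loop
loopKM <- function(time, event) {
  tts <- sort(unique(time[event == 1]))
  s <- 1; out <- numeric(length(tts))
  for (k in seq_along(tts)) {
    n <- sum(time >= tts[k])
    d <- sum(time == tts[k] & event == 1)
    s <- s * (1 - d / n)
    out[k] <- s
  }
  data.frame(time = tts, surv = out)
}

randomOmics <- function(m, n, seed, datatype = "toy") {
  set.seed(seed)
  OmicsMatrix(matrix(rnorm(m * n), m, n,
                     dimnames = list(sprintf("p%02d", seq_len(m)),
                                     paste0("f", seq_len(n)))),
              datatype = datatype)
}
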