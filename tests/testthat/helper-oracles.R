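# Independent oracles used by the unit tests.  They deliberately avoid the
# package's own code paths: counting-process tallies are plain loops, product
# integrals are explicit matrix loops, matrix exponentials go through
# Matrix::expm.

# Brute-force Nelson-Aalen: loop over every (event time, transition) pair and
# count movers / at-risk directly from the records.
brute_nelson_aalen <- function(data, space) {
  ev <- data[data$status == 1L, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(space$transitions))) {
    l <- space$transitions[i, 1L]; m <- space$transitions[i, 2L]
    times <- sort(unique(ev$exit[ev$from == l & ev$to == m]))
    for (u in times) {
      nev <- sum(ev$from == l & ev$to == m & ev$exit == u)
      atrisk <- sum(data$from == l & data$entry < u & data$exit >= u)
      out[[length(out) + 1L]] <- data.frame(
        time = u, from = l, to = m, increment = nev / atrisk,
        risk_set = atrisk)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$time, res$from, res$to), , drop = FALSE]
}

# Explicit product integral over table rows (R loop, one joint factor per
# distinct time).
brute_product <- function(tab, s, t, K, space) {
  times <- sort(unique(tab$time[tab$time > s & tab$time <= t]))
  P <- diag(K)
  for (u in times) {
    dA <- matrix(0, K, K)
    rows <- tab[tab$time == u, , drop = FALSE]
    for (r in seq_len(nrow(rows))) {
      li <- match(rows$from[r], space$states)
      mi <- match(rows$to[r], space$states)
      dA[li, mi] <- dA[li, mi] + rows$increment[r]
    }
    diag(dA) <- -rowSums(dA)
    P <- P %*% (diag(K) + dA)
  }
  P
}

expm_oracle <- function(Q, t) as.matrix(Matrix::expm(Q * t))

csl_model <- function() as_msm_model(preset("csl-constant"))

csl_Q <- function() {
  matrix(c(-7e-4, 5e-4, 2e-4,
           2e-3, -3.2e-3, 1.2e-3,
           0, 0, 0), 3, 3, byrow = TRUE)
}

csl_init <- function() c(0.43, 0.57, 0)
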