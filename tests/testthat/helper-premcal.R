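# shared fixtures, all built in code

# the published 19-item bank on its scored 0/1/2 categories, used as a
# generating bank in simulations
scored_bank <- function() {
  b <- equip_ph_bank()
  item_bank(b$item_ids, b$deltas)
}

# small deterministic toy bank
toy_bank <- function() {
  item_bank(c("a", "b", "c"),
            list(c(-1, 0.5), c(0, 1), c(-0.5, 0.2)))
}

# direct PCM category probabilities, written independently of the package
# (plain loop over the defining formula) for use as an oracle
oracle_pcm_probs <- function(deltas, theta) {
  m <- length(deltas)
  num <- numeric(m + 1)
  for (k in 0:m) {
    s <- 0
    if (k > 0) for (h in 1:k) s <- s + (theta - deltas[h])
    num[k + 1] <- exp(s)
  }
  num / sum(num)
}

# draw a complete response matrix from a bank at given thetas
draw_responses <- function(bank, theta, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  J <- n_items(bank)
  x <- matrix(NA_integer_, length(theta), J)
  for (j in seq_len(J)) {
    for (p in seq_along(theta)) {
      pr <- oracle_pcm_probs(bank$deltas[[j]], theta[p])
      x[p, j] <- sample(0:(length(pr) - 1), 1, prob = pr)
    }
  }
  response_matrix(x, item_ids = bank$item_ids)
}
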