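# independent oracles and tiny fixture builders shared across test files

# exact two-sided permutation p by full enumeration of group assignments
enum_perm_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  t_obs <- mean(x) - mean(y)
  combs <- utils::combn(length(pooled), n1)
  stats <- apply(combs, 2, function(idx) {
    mean(pooled[idx]) - mean(pooled[-idx])
  })
  mean(abs(stats) >= abs(t_obs) - 1e-12)
}

# exact two-sided sign-flip p over all 2^n sign patterns
enum_sign_p <- function(d) {
  n <- length(d)
  t_obs <- mean(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  stats <- as.numeric(signs %*% d) / n
  mean(abs(stats) >= abs(t_obs) - 1e-12)
}

# sequential-rejection Holm oracle: which hypotheses are rejected at alpha
holm_reject_oracle <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  rejected <- logical(m)
  for (k in seq_len(m)) {
    if (p[ord[k]] <= alpha / (m - k + 1)) rejected[ord[k]] <- TRUE else break
  }
  rejected
}

# naive per-token category counter, independent of score_lexicon internals
brute_category_pct <- function(tokens, lexicon) {
  toks <- tolower(tokens)
  vapply(lexicon, function(entries) {
    hits <- 0L
    for (tk in toks) {
      matched <- FALSE
      for (e in entries) {
        if (endsWith(e, "*")) {
          if (startsWith(tk, sub("\\*$", "", e))) matched <- TRUE
        } else if (tk == e) matched <- TRUE
        if (matched) break
      }
      hits <- hits + matched
    }
    100 * hits / length(toks)
  }, numeric(1))
}

# small deterministic corpus tibble without the generator
toy_corpus <- function(n = 8, domain = "memory") {
  words <- c("alpha", "bravo", "delta", "gamma", "osprey", "lintel")
  as_corpus(tibble::tibble(
    id = paste0("t", seq_len(n)),
    subject_id = paste0("s", seq_len(n)),
    domain = domain,
    topic = "",
    veracity = rep(c("truthful", "deceptive"), length.out = n),
    text = vapply(seq_len(n), function(i) {
      paste(paste(sample(words, 8, replace = TRUE), collapse = " "), ".")
    }, character(1))
  ))
}

# 95% binomial interval half-width around 0.5 for n Bernoulli trials
chance_band <- function(n) 1.96 * sqrt(0.25 / n)
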