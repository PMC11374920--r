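# Independent oracles kept deliberately naive: each re-derives a quantity by
# a route different from the implementation under test.

# SDI by brute force: sum per-section scores, divide by 3 * NT.
oracle_sdi <- function(scores) sum(scores) / (3 * length(scores))

# Welch statistic by direct arithmetic (x = first group, y = second).
oracle_welch <- function(x, y) {
  v1 <- var(x) / length(x)
  v2 <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Two-normal density crossing by numeric root finding (independent of the
# package's quadratic closed form).
oracle_normal_crossing <- function(m1, s1, m2, s2) {
  uniroot(function(x) dnorm(x, m1, s1) - dnorm(x, m2, s2),
          lower = min(m1, m2), upper = max(m1, m2), tol = 1e-12)$root
}

# Wilson score interval by its textbook formula.
oracle_wilson <- function(k, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- k / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(centre - half, centre + half)
}

# Minimal section-score table for one animal/region/modality.
make_scores <- function(scores, animal = "A1", region = "R", sex = "M",
                        modality = "cells") {
  tibble::tibble(animal = animal, sex = sex, region = region,
                 section_index = seq_along(scores), modality = modality,
                 score = scores)
}
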