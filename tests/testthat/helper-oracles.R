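# Independent oracles used across the suite. These deliberately do not
# share code with the package: power-series Bessel evaluation, a direct
# transcription of the cell-covered electrode formula built on it, and
# closed-form classical statistics.

# Modified Bessel functions by straight power-series summation
# (>= 40 terms; accurate in double precision while the summands do not
# catastrophically cancel, i.e. for moderate |z| cos(arg z)).
oracle_bessel_i0 <- function(z, nterms = 60) {
  total <- 0 + 0i
  term <- 1 + 0i
  for (k in 0:nterms) {
    if (k > 0) term <- term * (z^2 / 4) / k^2
    total <- total + term
  }
  total
}

oracle_bessel_i1 <- function(z, nterms = 60) {
  total <- 0 + 0i
  term <- z / 2
  for (k in 0:nterms) {
    if (k > 0) term <- term * (z^2 / 4) / (k * (k + 1))
    total <- total + term
  }
  total
}

# Direct evaluation of the cell-covered electrode formula, written
# independently of the package implementation.
oracle_cell_covered <- function(f, zn, alpha, rb, cm) {
  zm <- 1 / (1i * pi * f * cm * 1e-6)
  s <- 1 / zn + 1 / zm
  gam <- alpha * sqrt(s)
  spread <- (gam / 2) * oracle_bessel_i0(gam) / oracle_bessel_i1(gam)
  1 / ((1 / zn) * (zn / (zn + zm) + (zm / (zn + zm)) / (spread + rb * s)))
}

# Closed-form one-way fixed-effects ANOVA.
oracle_anova <- function(groups) {
  k <- length(groups)
  n <- vapply(groups, length, 1L)
  means <- vapply(groups, mean, 1)
  grand <- sum(n * means) / sum(n)
  ss_b <- sum(n * (means - grand)^2)
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  df_b <- k - 1
  df_w <- sum(n) - k
  f_stat <- (ss_b / df_b) / (ss_w / df_w)
  list(f = f_stat, p = stats::pf(f_stat, df_b, df_w, lower.tail = FALSE))
}

# Closed-form Student t-tests (paired; unpaired pooled-variance).
oracle_t_paired <- function(a, b) {
  d <- a - b
  n <- length(d)
  t_stat <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t_stat, p = 2 * stats::pt(-abs(t_stat), n - 1))
}

oracle_t_pooled <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
    (n1 + n2 - 2)
  t_stat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t_stat, p = 2 * stats::pt(-abs(t_stat), n1 + n2 - 2))
}

# Phi coefficient from the 2x2 contingency table of two binary masks.
oracle_phi <- function(mask_a, mask_b) {
  n11 <- as.numeric(sum(mask_a & mask_b))
  n10 <- as.numeric(sum(mask_a & !mask_b))
  n01 <- as.numeric(sum(!mask_a & mask_b))
  n00 <- as.numeric(sum(!mask_a & !mask_b))
  (n11 * n00 - n10 * n01) /
    sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
}
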