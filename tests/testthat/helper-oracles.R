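# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately avoid the code paths they verify.

# Site-by-site popANI/conANI enumeration over two profiles.
oracle_compare <- function(a, b, min_depth = 5L, min_count = 2L,
                           min_freq = 0.05) {
  common <- intersect(a$pos, b$pos)
  n_comp <- 0L; n_pop <- 0L; n_con <- 0L
  for (p in common) {
    ca <- a$counts[match(p, a$pos), ]
    cb <- b$counts[match(p, b$pos), ]
    if (sum(ca) < min_depth || sum(cb) < min_depth) next
    n_comp <- n_comp + 1L
    det <- function(cn) {
      d <- sum(cn)
      which(cn >= min_count & cn / d >= min_freq)
    }
    if (length(intersect(det(ca), det(cb))) == 0L) n_pop <- n_pop + 1L
    cons <- function(cn) which(cn == max(cn))[1L]  # first = A<C<G<T tie-break
    if (cons(ca) != cons(cb)) n_con <- n_con + 1L
  }
  list(n_compared = n_comp, n_pop_subs = n_pop, n_con_subs = n_con,
       popANI = if (n_comp > 0) 1 - n_pop / n_comp else NA_real_,
       conANI = if (n_comp > 0) 1 - n_con / n_comp else NA_real_)
}

# Benjamini-Hochberg from the definition: min over k >= i of p(k) * m / k.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(ranked[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Welch two-sample t from the closed form.
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x) / nx; vy <- var(y) / ny
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Tukey HSD adjusted p from the studentised-range closed form.
oracle_tukey <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  ns <- tapply(values, groups, length)
  ms <- tapply(values, groups, mean)
  dfres <- length(values) - k
  mse <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2))) / dfres
  prs <- combn(levels(groups), 2)
  p <- numeric(ncol(prs))
  for (i in seq_len(ncol(prs))) {
    g1 <- prs[1, i]; g2 <- prs[2, i]
    se <- sqrt(mse / 2 * (1 / ns[[g1]] + 1 / ns[[g2]]))
    q <- abs(ms[[g1]] - ms[[g2]]) / se
    p[i] <- ptukey(q, k, dfres, lower.tail = FALSE)
  }
  data.frame(group1 = prs[1, ], group2 = prs[2, ], p_adj = p)
}

# OLS slope, se and p by matrix algebra.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  n <- length(y)
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  t <- beta[2] / se
  list(slope = beta[2], se = se, df = n - 2, t = t,
       p = 2 * pt(-abs(t), n - 2))
}

# Random toy profile on <= max_sites sites of a small genome.
random_profile <- function(sample_id, species_id = "spX", genome_length = 60L,
                           max_sites = 50L, max_depth = 12L) {
  n <- sample.int(max_sites, 1L)
  pos <- sort(sample.int(genome_length, n)) - 1L
  counts <- matrix(0L, n, 4L)
  for (i in seq_len(n)) {
    nall <- sample(1:3, 1L, prob = c(0.6, 0.3, 0.1))
    bases <- sample.int(4L, nall)
    counts[i, bases] <- sample.int(max_depth, nall, replace = TRUE)
  }
  allele_profile(sample_id, species_id, genome_length, pos, counts)
}

# Profile with uniform depth at given positions, one base per site.
flat_profile <- function(sample_id, species_id, genome_length, pos,
                         base = "A", depth = 10L) {
  counts <- matrix(0L, length(pos), 4L)
  counts[, match(base, c("A", "C", "G", "T"))] <- depth
  allele_profile(sample_id, species_id, genome_length, pos, counts)
}
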