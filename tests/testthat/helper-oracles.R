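# Brute-force oracles: naive double loops and direct formula transcription,
# kept deliberately independent of the package's optimised implementations.

oracle_matrix <- function(seqs) {
  if (is.matrix(seqs)) toupper(seqs) else
    do.call(rbind, strsplit(toupper(seqs), ""))
}

# complete deletion, as documented
oracle_clean <- function(m) {
  keep <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m[, keep, drop = FALSE]
}

# pi by an explicit double loop over all pairs and sites
oracle_pi <- function(seqs) {
  m <- oracle_clean(oracle_matrix(seqs))
  n <- nrow(m)
  if (ncol(m) == 0) return(0)
  tot <- 0
  np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(m[i, ] != m[j, ])
    np <- np + 1
  }
  tot / np / ncol(m)
}

oracle_S <- function(seqs) {
  m <- oracle_clean(oracle_matrix(seqs))
  if (ncol(m) == 0) return(0L)
  sum(apply(m, 2, function(col) length(unique(col)) > 1))
}

oracle_theta_w <- function(seqs) {
  m <- oracle_clean(oracle_matrix(seqs))
  if (ncol(m) == 0) return(0)
  oracle_S(m) / (sum(1 / seq_len(nrow(m) - 1)) * ncol(m))
}

oracle_dxy <- function(m1, m2) {
  m <- oracle_clean(rbind(oracle_matrix(m1), oracle_matrix(m2)))
  n1 <- nrow(oracle_matrix(m1))
  a <- m[seq_len(n1), , drop = FALSE]
  b <- m[-seq_len(n1), , drop = FALSE]
  if (ncol(m) == 0) return(0)
  tot <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    tot <- tot + sum(a[i, ] != b[j, ])
  }
  tot / (nrow(a) * nrow(b)) / ncol(m)
}

# Tajima 1989, transcribed directly
oracle_tajima_d <- function(seqs) {
  m <- oracle_clean(oracle_matrix(seqs))
  n <- nrow(m)
  S <- oracle_S(m)
  if (S == 0) return(NA_real_)
  khat <- oracle_pi(m) * ncol(m)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (khat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

oracle_hd <- function(seqs) {
  m <- oracle_clean(oracle_matrix(seqs))
  n <- nrow(m)
  f <- table(apply(m, 1, paste, collapse = "")) / n
  n / (n - 1) * (1 - sum(f^2))
}

# R2, Ramos-Onsins & Rozas 2002, transcribed directly
oracle_r2 <- function(seqs) {
  m <- oracle_clean(oracle_matrix(seqs))
  n <- nrow(m)
  S <- oracle_S(m)
  if (S == 0) return(NA_real_)
  U <- numeric(n)
  for (s in seq_len(ncol(m))) {
    tab <- table(m[, s])
    for (b in names(tab)[tab == 1]) U[m[, s] == b] <- U[m[, s] == b] + 1
  }
  khat <- oracle_pi(m) * ncol(m)
  sqrt(sum((U - khat / 2)^2) / n) / S
}

# P(K >= k | theta, n) by direct unsigned-Stirling enumeration (small n)
oracle_stirling1 <- function(n) {
  s <- matrix(0, n + 1, n + 1)
  s[1, 1] <- 1
  for (m in 1:n) for (k in 1:m) {
    s[m + 1, k + 1] <- s[m, k] + (m - 1) * s[m, k + 1]
  }
  s[n + 1, 2:(n + 1)]
}

oracle_ewens_p_ge <- function(k, theta, n) {
  st <- oracle_stirling1(n)
  num <- st * theta^(1:n)
  p <- num / sum(num)
  sum(p[k:n])
}

oracle_fs <- function(seqs) {
  m <- oracle_clean(oracle_matrix(seqs))
  n <- nrow(m)
  khat <- oracle_pi(m) * ncol(m)
  k <- length(unique(apply(m, 1, paste, collapse = "")))
  if (khat <= 0) return(NA_real_)
  sp <- oracle_ewens_p_ge(k, khat, n)
  if (sp <= 0 || sp >= 1) return(NA_real_)
  log(sp / (1 - sp))
}

# random aligned sample with tunable polymorphism and optional missing data
random_alignment <- function(n, L, n_var = NULL, p_missing = 0) {
  if (is.null(n_var)) n_var <- max(1, rpois(1, L / 20))
  m <- matrix(sample(c("A", "C", "G", "T"), L, replace = TRUE),
              n, L, byrow = TRUE)
  var_sites <- sample(L, min(n_var, L))
  for (s in var_sites) {
    k <- sample(2:3, 1)
    bases <- sample(c("A", "C", "G", "T"), k)
    m[, s] <- sample(bases, n, replace = TRUE)
  }
  if (p_missing > 0) {
    idx <- which(matrix(runif(n * L) < p_missing, n, L))
    m[idx] <- sample(c("N", "-"), length(idx), replace = TRUE)
  }
  m
}

random_pair <- function(n1 = 5, n2 = 6, L = 120, ...) {
  m <- random_alignment(n1 + n2, L, ...)
  pop_pair(m[seq_len(n1), , drop = FALSE], m[-seq_len(n1), , drop = FALSE])
}
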