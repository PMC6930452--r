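# Shared fixtures and independent oracles, built in code at test time.

# Minimal two-chain PDB text: 4 residues per chain, several atoms each.
write_toy_pdb <- function(path) {
  fmt <- function(serial, name, res3, ch, resno, x, y, z) {
    sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s",
            serial, name, res3, ch, resno, x, y, z, 1.0, 0.0,
            substr(trimws(name), 1, 1))
  }
  lines <- character(0); serial <- 0
  res3 <- c("ALA", "LEU", "SER", "GLY")
  for (ci in 1:2) {
    ch <- c("A", "B")[ci]
    for (ri in 1:4) {
      base <- c(3 * ri, 2 * ci, 0)
      for (ai in 1:3) {   # N, CA, C backbone triplet around the base point
        serial <- serial + 1
        nm <- c(" N  ", " CA ", " C  ")[ai]
        off <- switch(ai, c(-0.5, 0, 0), c(0, 0, 0), c(0.5, 0, 0))
        lines <- c(lines, fmt(serial, nm, res3[ri], ch, ri,
                              base[1] + off[1], base[2] + off[2],
                              base[3] + off[3]))
      }
    }
    lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d", serial + 1,
                              res3[4], ch, 4L))
  }
  writeLines(c(lines, "END"), path)
  path
}

write_hetatm_only_pdb <- function(path) {
  writeLines(c(
    "HETATM    1  O   HOH A   1      10.000  10.000  10.000  1.00  0.00           O",
    "HETATM    2  O   HOH A   2      12.000  10.000  10.000  1.00  0.00           O",
    "END"), path)
  path
}

# O(N^2) double-loop oracle for the observed profile, written directly from
# the pairwise interaction formula; independent of the package's vectorized
# implementation.
brute_observed <- function(pos, h, cutoff = 9.0) {
  n <- nrow(pos)
  raw <- numeric(n)
  for (j in seq_len(n)) {
    acc <- 0
    for (i in seq_len(n)) {
      r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      if (r <= cutoff) {
        x <- r / cutoff
        w <- 1 - 0.5 * (7 * x^2 - 9 * x^4 + 5 * x^6 - x^8)
        acc <- acc + (h[i] + h[j]) * w
      }
    }
    raw[j] <- acc
  }
  raw / sum(raw)
}

# term-by-term KL summation oracle
brute_kl <- function(p, q) {
  q <- pmax(q, 1e-10); q <- q / sum(q)
  s <- 0
  for (i in seq_along(p)) if (p[i] > 0) s <- s + p[i] * log2(p[i] / q[i])
  s
}

# toy profile pair that is locally discordant: O follows T except for one
# planted outlier at a low-T position, so elimination has a single culprit
outlier_toy <- function(n = 10, outlier = 1, seed = 1) {
  set.seed(seed)
  t <- exp(-((seq_len(n) - (n + 1) / 2)^2) / 8)
  t <- t / sum(t)
  o <- t * exp(stats::rnorm(n, 0, 0.02))
  o[outlier] <- o[outlier] + 6 * max(t)
  o <- o / sum(o)
  list(t = t, o = o, r = rep(1 / n, n), outlier = outlier)
}

rigid_transform <- function(pos, angle = 0.7, shift = c(5, -3, 2)) {
  Rz <- matrix(c(cos(angle), -sin(angle), 0,
                 sin(angle), cos(angle), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  sweep(pos %*% t(Rz), 2, shift, `+`)
}
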