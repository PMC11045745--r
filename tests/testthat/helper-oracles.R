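# Independent oracles used across tests.  These deliberately avoid the code
# paths they are checking.

# brute-force solver for the coupled equilibrium: pure bisection on the
# single-strand concentration using the naive textbook expressions
oracle_coupled_ss <- function(C_T, L_T, Km, Kd, iter = 200L) {
  bal <- function(s) {
    ds <- Km * s^2
    PL <- C_T * s / (Kd + s)
    s + 2 * ds + PL - L_T
  }
  lo <- 0
  hi <- L_T
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (bal(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# naive textbook quadratic for the dimerization balance (the cancellation-
# prone form, fine as an oracle at moderate L_T * Km)
oracle_hybridization_ss <- function(L_T, Km) {
  if (Km == 0) return(L_T)
  (-1 + sqrt(1 + 8 * L_T * Km)) / (4 * Km)
}

# independent nearest-neighbor summation: the published 1 M NaCl table
# expanded to all 16 dinucleotide keys (each stack and its reverse
# complement share one physical value), plus initiation and symmetry terms
oracle_nn_sum <- function(s) {
  base <- list(AA = c(-6.6, -18.4), AU = c(-5.7, -15.5), UA = c(-8.1, -22.6),
               CA = c(-10.5, -27.8), GU = c(-10.2, -26.2), CU = c(-7.6, -19.2),
               GA = c(-13.3, -35.5), CG = c(-8.0, -19.4), GC = c(-14.2, -34.9),
               GG = c(-12.2, -29.7))
  full <- base
  for (k in names(base)) {
    ch <- strsplit(k, "")[[1]]
    rc <- paste0(chartr("AUGC", "UACG", ch[2]), chartr("AUGC", "UACG", ch[1]))
    full[[rc]] <- base[[k]]
  }
  ch <- strsplit(s, "")[[1]]
  tot <- c(dH = 0, dS = -10.8 - 1.4)
  for (i in seq_len(length(ch) - 1)) {
    v <- full[[paste0(ch[i], ch[i + 1])]]
    tot <- tot + c(dH = v[1], dS = v[2])
  }
  tot
}

# random self-complementary RNA of even length 2n: random half followed by
# its reverse complement
random_selfcomp_seq <- function(n_half) {
  bases <- c("A", "U", "G", "C")
  half <- paste(sample(bases, n_half, replace = TRUE), collapse = "")
  comp <- chartr("AUGC", "UACG", half)
  rc <- paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  paste0(half, rc)
}
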