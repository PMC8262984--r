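# Independent brute-force oracles used to verify the package's
# implementations.  These deliberately share no code with the functions
# they check.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n, id = "R1") {
  protein_set(id, paste(sample(AA20, n, replace = TRUE), collapse = ""))
}

# window-by-window motif check: position set membership, nothing shared
# with the regex implementation
oracle_scan_motif <- function(seqc) {
  chars <- strsplit(seqc, "")[[1]]
  n <- length(chars)
  hits <- integer(0)
  if (n >= 7) {
    for (i in 1:(n - 6)) {
      w <- chars[i:(i + 6)]
      ok <- w[1] == "C" &&
        w[2] %in% AA20 &&
        w[3] %in% c("L", "F") &&
        w[4] == "G" &&
        w[5] %in% AA20 &&
        w[6] == "W" &&
        w[7] %in% c("Y", "L")
      if (ok) hits <- c(hits, i)
    }
  }
  hits
}

# exhaustive His count in the clipped window
oracle_his_in_window <- function(seqc, cys, window) {
  chars <- strsplit(seqc, "")[[1]]
  lo <- max(1, cys - window); hi <- min(length(chars), cys + window)
  which(chars == "H" & seq_along(chars) >= lo & seq_along(chars) <= hi)
}

# plain bisection on the binding equilibrium
#   (dmax - B)(L0 - B) = K_D * B,  B in [0, min(dmax, L0)]
# independent of the closed-form quadratic route
oracle_bound_bisect <- function(L0, K_D, dmax, iter = 200) {
  f <- function(B) (dmax - B) * (L0 - B) - K_D * B
  lo <- 0; hi <- min(dmax, L0)
  if (hi == 0) return(0)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# direct re-evaluation of the TM sliding-window rule
oracle_tm_regions <- function(seqc, window = 19, threshold = 1.6,
                              min_len = 15) {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2, X = 0)
  h <- kd[strsplit(seqc, "")[[1]]]
  n <- length(h)
  if (n < window) return(NULL)
  half <- (window - 1) / 2
  above <- logical(n)
  for (c in (half + 1):(n - half)) {
    above[c] <- mean(h[(c - half):(c + half)]) > threshold
  }
  pos <- which(above)
  if (!length(pos)) return(NULL)
  regions <- list()
  cur <- c(pos[1], pos[1])
  for (p in pos[-1]) {
    if (p - cur[2] < 3) cur[2] <- p
    else { regions[[length(regions) + 1]] <- cur; cur <- c(p, p) }
  }
  regions[[length(regions) + 1]] <- cur
  keep <- Filter(function(r) r[2] - r[1] + 1 >= min_len, regions)
  if (!length(keep)) return(NULL)
  do.call(rbind, keep)
}

# column tally for logos/conservation
oracle_column_freq <- function(rows, col) {
  ch <- vapply(rows, function(s) substr(s, col, col), character(1))
  ch <- ch[ch %in% AA20]
  tab <- table(factor(ch, levels = AA20))
  as.numeric(tab) / max(length(ch), 1)
}

make_protein <- function(seqc, id = "P1") protein_set(id, seqc)
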