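# Independent brute-force oracles and fixture helpers shared across tests.
# The oracles deliberately use a different mechanism (perl regex lookahead /
# exhaustive substring predicates) than the package implementation.

random_proteins <- function(n, len_range = c(30, 200), seed = 1) {
  set.seed(seed)
  letters20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  lens <- sample(seq.int(len_range[1], len_range[2]), n, replace = TRUE)
  data.frame(id = sprintf("rp%04d", seq_len(n)),
             description = "",
             sequence = vapply(lens, function(L)
               paste(sample(letters20, L, replace = TRUE), collapse = ""),
               character(1)),
             stringsAsFactors = FALSE)
}

# reference-regex oracle for the hallmark engine: every (start0, end0) stored
# segment reachable from a G[KR] cut with an admissible N-terminal hallmark
oracle_cnidarian <- function(seq, window = 50, min_len = 4, max_len = 50) {
  g <- gregexpr("(?=G[KR])", seq, perl = TRUE)[[1]]
  if (g[1] == -1) {
    return(data.frame(start0 = integer(0), end0 = integer(0),
                      stored = character(0)))
  }
  rows <- list()
  for (i in as.integer(g)) {          # 1-based G position; basic at i + 1
    cut0 <- i + 1L                    # 0-based cut after the basic residue
    for (L in min_len:max_len) {
      s1 <- i - L + 1L                # stored is s1..i (1-based), ends at G
      if (s1 < 1L) next
      if (cut0 - (s1 - 1L) > window) next
      pep <- substr(seq, s1, i)
      if (substr(pep, 1, 1) == "Q" || substr(pep, 2, 2) == "P" ||
          substr(pep, 3, 3) == "P") {
        rows[[length(rows) + 1L]] <- data.frame(start0 = s1 - 1L, end0 = i,
                                                stored = pep,
                                                stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start0 = integer(0), end0 = integer(0),
                      stored = character(0)))
  }
  out <- unique(do.call(rbind, rows))
  out[order(out$start0, out$end0), , drop = FALSE]
}

# reference-regex oracle for the dibasic engine: fixed-length lookahead
# patterns (K/R)X^m(K/R) | X_k | (K/R)X^n(K/R) over all m, n, k
oracle_dibasic <- function(seqs, spacers = c(0, 2, 4, 6),
                           min_len = 6, max_len = 40) {
  out <- vector("list", length(seqs))
  for (m in spacers) for (n in spacers) for (k in min_len:max_len) {
    pat <- sprintf("(?=[KR].{%d}[KR].{%d}[KR].{%d}[KR])", m, k, n)
    hits <- gregexpr(pat, seqs, perl = TRUE)
    for (j in seq_along(seqs)) {
      p <- hits[[j]]
      if (p[1] == -1) next
      start0 <- as.integer(p) + m + 1L   # 0-based start of X_k
      out[[j]] <- rbind(out[[j]],
                        data.frame(start0 = start0, end0 = start0 + k))
    }
  }
  lapply(out, function(df) {
    if (is.null(df)) {
      return(data.frame(start0 = integer(0), end0 = integer(0)))
    }
    df <- unique(df)
    df[order(df$start0, df$end0), , drop = FALSE]
  })
}

# independently coded monoisotopic residue mass table (frozen from a
# published reference; used to cross-check the packaged config)
ORACLE_RESIDUE_MASSES <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

oracle_peptide_mass <- function(seq) {
  sum(ORACLE_RESIDUE_MASSES[strsplit(seq, "")[[1]]]) + 18.010565
}

random_peptide <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(names(ORACLE_RESIDUE_MASSES), len, replace = TRUE),
        collapse = "")
}
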