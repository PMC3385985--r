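# Independent oracles used across the test suite. These deliberately avoid
# the package's regex machinery: matches are derived from explicit repeat
# counting over character vectors, and (for tiny inputs) from exhaustive
# substring enumeration with decomposition loops.

# longest grammar match starting at 1-based position i, or 0 if none.
# chars: character vector of single letters.
oracle_longest_at <- function(chars, i, motif_id) {
  n <- length(chars)
  run_pairs <- function(j, first, second) {
    a <- 0L
    while (j + 2 * a + 1 <= n && chars[j + 2 * a] == first &&
           chars[j + 2 * a + 1] == second) a <- a + 1L
    a
  }
  if (motif_id == 1L) {
    a <- run_pairs(i, "G", "T")
    if (a < 3) return(0L)
    j <- i + 2L * a
    m <- 0L
    while (j + m <= n && chars[j + m] == "T") m <- m + 1L
    if (m < 3) return(0L)
    return(2L * a + m)
  }
  if (motif_id == 2L) {
    amax <- run_pairs(i, "G", "T")
    a <- amax - 1L                       # GTA can only sit at the run end
    if (a < 2) return(0L)
    j <- i + 2L * a
    if (!(j + 2 <= n && chars[j] == "G" && chars[j + 1] == "T" &&
          chars[j + 2] == "A")) return(0L)
    b <- run_pairs(j + 3L, "T", "G")
    if (b < 3) return(0L)
    return(2L * a + 3L + 2L * b)
  }
  if (motif_id == 3L) {
    amax <- run_pairs(i, "G", "T")
    if (amax < 4) return(0L)
    followed_by_ttt <- function(a) {
      j <- i + 2L * a
      j + 2 <= n && all(chars[j:(j + 2)] == "T")
    }
    if (!followed_by_ttt(amax)) return(2L * amax)
    if (amax >= 5) return(2L * (amax - 1L))  # shorter run escapes the tract
    return(0L)
  }
  stop("unknown motif")
}

# leftmost-longest non-overlapping matches of one motif on one strand
oracle_scan_forward <- function(sequence, motif_ids = 1:3) {
  chars <- strsplit(sequence, "")[[1]]
  out <- list()
  for (m in motif_ids) {
    i <- 1L
    while (i <= length(chars)) {
      L <- oracle_longest_at(chars, i, m)
      if (L > 0) {
        out[[length(out) + 1L]] <- data.frame(
          start = i - 1L, end = i - 1L + L, strand = "+", motif_id = m,
          stringsAsFactors = FALSE)
        i <- i + L
      } else {
        i <- i + 1L
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), motif_id = integer(0)))
  }
  do.call(rbind, out)
}

oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

oracle_scan <- function(sequence, mode = "double_stranded") {
  fw <- oracle_scan_forward(sequence)
  if (mode == "forward_only") return(fw[order(fw$start, fw$motif_id), ])
  n <- nchar(sequence)
  rc <- oracle_scan_forward(oracle_revcomp(sequence))
  if (nrow(rc)) {
    tmp <- rc$start
    rc$start <- n - rc$end
    rc$end <- n - tmp
    rc$strand <- "-"
  }
  out <- rbind(fw, rc)
  out[order(out$start, out$motif_id, out$strand), ]
}

# exhaustive substring checker for tiny sequences: tries every (a, m) or
# (a, b) decomposition of every substring.
oracle_full_match <- function(sub, motif_id, following = "") {
  L <- nchar(sub)
  is_rep <- function(x, unit) {
    nchar(x) %% nchar(unit) == 0 &&
      x == strrep(unit, nchar(x) / nchar(unit))
  }
  if (motif_id == 1L) {
    for (a in 3:floor(L / 2)) {
      m <- L - 2 * a
      if (m >= 3 && is_rep(substr(sub, 1, 2 * a), "GT") &&
          substr(sub, 2 * a + 1, L) == strrep("T", m)) return(TRUE)
    }
    return(FALSE)
  }
  if (motif_id == 2L) {
    for (a in 2:floor(L / 2)) {
      rest <- L - 2 * a - 3
      if (rest < 6 || rest %% 2 != 0) next
      if (is_rep(substr(sub, 1, 2 * a), "GT") &&
          substr(sub, 2 * a + 1, 2 * a + 3) == "GTA" &&
          is_rep(substr(sub, 2 * a + 4, L), "TG")) return(TRUE)
    }
    return(FALSE)
  }
  if (motif_id == 3L) {
    if (L %% 2 != 0 || L < 8) return(FALSE)
    if (!is_rep(sub, "GT")) return(FALSE)
    return(substr(following, 1, 3) != "TTT")
  }
  stop("unknown motif")
}

# enumeration-based leftmost-longest scan; O(n^2), tiny inputs only
oracle_enumerate <- function(sequence, motif_id) {
  n <- nchar(sequence)
  out <- list()
  i <- 1L
  while (i <= n) {
    best <- 0L
    for (L in seq_len(n - i + 1L)) {
      sub <- substr(sequence, i, i + L - 1L)
      fol <- substr(sequence, i + L, n)
      if (oracle_full_match(sub, motif_id, fol)) best <- L
    }
    if (best > 0) {
      out[[length(out) + 1L]] <- data.frame(start = i - 1L,
                                            end = i - 1L + best)
      i <- i + best
    } else {
      i <- i + 1L
    }
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0)))
  do.call(rbind, out)
}

# random test sequence with adjustable GT richness
random_seq <- function(n, gt_rich = FALSE) {
  if (gt_rich) {
    units <- sample(c("GT", "TG", "T", "G", "A", "C", "TT", "GTA"), n,
                    replace = TRUE,
                    prob = c(0.3, 0.1, 0.2, 0.1, 0.1, 0.05, 0.1, 0.05))
    substr(paste(units, collapse = ""), 1, n)
  } else {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }
}

# P(theta_A > theta_B) by Monte Carlo, independent of the integration path
mc_prob_greater <- function(a1, b1, a2, b2, draws = 1e6) {
  mean(stats::rbeta(draws, a1, b1) > stats::rbeta(draws, a2, b2))
}

# exact hypergeometric upper tail in linear space (small N only)
hyper_tail_linear <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# dummy annotation: every gene a single 1 kb exon (for expression tests)
flat_annotation <- function(gene_ids, len = 1000L) {
  g <- data.frame(gene_id = gene_ids, seqid = "chr1",
                  start = (seq_along(gene_ids) - 1L) * (len + 100L),
                  end = (seq_along(gene_ids) - 1L) * (len + 100L) + len,
                  strand = "+", stringsAsFactors = FALSE)
  tx <- data.frame(tx_id = paste0(gene_ids, ".t1"), gene_id = gene_ids,
                   stringsAsFactors = FALSE)
  f <- data.frame(tx_id = tx$tx_id, type = "exon", start = g$start,
                  end = g$end, stringsAsFactors = FALSE)
  genome_annotation(g, tx, f)
}
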