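# in-code fixtures and independent brute-force oracles

# small rectangular trace table: each cell/channel on the default-style grid
makeTraceDf <- function(cells = c("a", "b"),
                        times = c(-6, -4, -2, 0, 5, 10, 15, 20),
                        channels = c("YFP", "RFP"),
                        nuclear = function(cell, ch, t) 100 + pmax(0, t),
                        cyto = function(cell, ch, t) 100) {
  rows <- expand.grid(cell_id = cells, channel = channels,
                      frame_time = times, stringsAsFactors = FALSE)
  rows$nuclear_mean <- mapply(nuclear, rows$cell_id, rows$channel,
                              rows$frame_time)
  rows$cytoplasmic_mean <- mapply(cyto, rows$cell_id, rows$channel,
                                  rows$frame_time)
  rows$nuclear_area <- 25
  rows$cell_area <- 400
  rows
}

# CorrectedTraces built directly from a corrected-value matrix (basal 0)
makeCorrected <- function(mat, times, channel = "RFP") {
  n <- nrow(mat)
  new("CorrectedTraces",
      cell_ids = sprintf("c%02d", seq_len(n)), channel = channel,
      times = times, raw = mat, smoothed = mat, corrected = mat,
      basal = rep(0, n))
}

# three-moment CPV by explicit loops (oracle for cpv())
bruteCPV <- function(r, y) {
  n <- length(r)
  sr <- 0; sy <- 0; srr <- 0; syy <- 0; sd2 <- 0
  for (i in seq_len(n)) {
    sr <- sr + r[i]; sy <- sy + y[i]
    srr <- srr + r[i]^2; syy <- syy + y[i]^2
    sd2 <- sd2 + (r[i] - y[i])^2
  }
  (sd2 / n) / (srr / n + syy / n - 2 * (sr / n) * (sy / n))
}

# exhaustive 8-mer enumeration on both strands (oracle for scanPRE())
COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
revComp <- function(s)
  paste(rev(COMP[strsplit(s, "")[[1]]]), collapse = "")
bruteScanPRE <- function(seq_chr, max_mismatch = 1) {
  core <- strsplit("TGAAAC", "")[[1]]
  L <- nchar(seq_chr)
  hits <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq_chr else revComp(seq_chr)
    for (p in 1:(L - 5)) {
      frag <- strsplit(substr(s, p, p + 5), "")[[1]]
      mm <- sum(frag != core)
      if (mm <= max_mismatch) {
        cs1 <- if (strand == "+") p else L - (p + 5) + 1
        hits[[length(hits) + 1]] <- data.frame(
          start = max(1, cs1 - 1) - 1L, end = min(L, cs1 + 6),
          strand = strand, core_mismatches = mm,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0),
                      core_mismatches = integer(0)))
  out <- do.call(rbind, hits)
  out[order(out$start, out$strand), , drop = FALSE]
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# two-sided sign-test p by explicit binomial tail sums (oracle)
bruteSignP <- function(k, n) {
  lower <- sum(choose(n, 0:k)) / 2^n
  upper <- sum(choose(n, k:n)) / 2^n
  min(1, 2 * min(lower, upper))
}
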