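## Independent brute-force reference implementations used to cross-check
## the package's statistics. Deliberately naive: per-element loops and
## textbook formulas only.

oracle_rms <- function(u, U) {
  s <- 0; n <- 0
  for (k in seq_along(u)) { s <- s + (u[k] - U[k])^2; n <- n + 1 }
  sqrt(s / n)
}

oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_cv <- function(x) {
  m <- sum(x) / length(x)
  v <- sum((x - m)^2) / (length(x) - 1)
  sqrt(v) / m
}

## sup-distance of empirical CDFs evaluated on the pooled support
oracle_ks <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  d <- 0
  for (t in pts) {
    fa <- sum(a <= t) / length(a)
    fb <- sum(b <= t) / length(b)
    d <- max(d, abs(fa - fb))
  }
  d
}

## per-window scoring of a character sequence on both strands
oracle_scan <- function(seq_chr, pwm, threshold = pwm$threshold) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bases <- strsplit(seq_chr, "")[[1]]
  L <- nrow(pwm$mat)
  hits <- list()
  for (w in seq_len(length(bases) - L + 1)) {
    win <- bases[w:(w + L - 1)]
    if (any(!win %in% names(comp))) next
    sf <- sum(vapply(seq_len(L), function(j) pwm$mat[j, win[j]], 0))
    rcwin <- rev(unname(comp[win]))
    sr <- sum(vapply(seq_len(L), function(j) pwm$mat[j, rcwin[j]], 0))
    if (sf >= threshold)
      hits[[length(hits) + 1]] <- data.frame(start = w - 1L, strand = "+",
                                             E = sf)
    if (sr >= threshold)
      hits[[length(hits) + 1]] <- data.frame(start = w - 1L, strand = "-",
                                             E = sr)
  }
  if (length(hits) == 0)
    return(data.frame(start = integer(0), strand = character(0),
                      E = numeric(0)))
  do.call(rbind, hits)
}

oracle_bin_energy <- function(ann, loci_lengths, bin_width) {
  rows <- list()
  for (g in names(loci_lengths)) {
    len <- loci_lengths[[g]]
    nb <- max(1, ceiling(len / bin_width))
    for (b in seq_len(nb)) {
      lo <- (b - 1) * bin_width
      hi <- min(lo + bin_width, len)
      tot <- 0
      sub <- ann[ann$locus == g, , drop = FALSE]
      for (i in seq_len(nrow(sub)))
        if (sub$start[i] >= lo && sub$start[i] < hi) tot <- tot + sub$E[i]
      rows[[length(rows) + 1]] <- data.frame(locus = g, bin = b,
                                             E_bin = tot / (hi - lo))
    }
  }
  do.call(rbind, rows)
}

oracle_overlap_fraction <- function(ann, same_tf = FALSE) {
  n <- nrow(ann)
  ev <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (ann$locus[i] != ann$locus[j]) next
    if (same_tf && ann$tf[i] != ann$tf[j]) next
    ai <- ann$start[i]; bi <- ai + ann$length[i]
    aj <- ann$start[j]; bj <- aj + ann$length[j]
    if (ai < bj && aj < bi) ev <- ev + 1
  }
  ev / n
}

random_annotation <- function(n, loci_lengths = c(hb = 500, Kr = 500),
                              tfs = c("Bcd", "Hb", "Kr")) {
  loci <- sample(names(loci_lengths), n, replace = TRUE)
  len <- sample(6:10, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i)
    sample.int(loci_lengths[[loci[i]]] - len[i], 1) - 1L, 0L)
  df <- data.frame(tf = sample(tfs, n, replace = TRUE), locus = loci,
                   start = start, length = len,
                   strand = sample(c("+", "-"), n, replace = TRUE),
                   E = runif(n, 3, 15), stringsAsFactors = FALSE)
  df[order(df$locus, df$start), ]
}
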