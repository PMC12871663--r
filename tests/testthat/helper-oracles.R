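# Independent oracles kept deliberately separate from the package internals:
# a sliding-window guide-site scan, an exhaustive cleaved-subset enumerator
# for the editing simulator, and a log-choose Fisher enumeration.

oracle_revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# naive per-position scan for an ACGT protospacer + NGG-style PAM: builds the
# full window matrix and counts mismatches column-wise
oracle_scan_one_strand <- function(seq, proto, pam) {
  s <- strsplit(seq, "")[[1]]
  m <- nchar(proto)
  p <- nchar(pam)
  n <- length(s)
  if (n < m + p) return(data.frame(position = integer(), mismatches = integer()))
  starts <- 0:(n - m - p)
  w <- matrix(s[outer(1:m, starts, "+")], nrow = m)
  mism <- colSums(w != strsplit(proto, "")[[1]])
  pam_ch <- strsplit(pam, "")[[1]]
  pam_ok <- rep(TRUE, length(starts))
  for (j in seq_len(p)) {
    sc <- s[starts + m + j]
    pam_ok <- pam_ok & if (pam_ch[j] == "N") sc %in% c("A", "C", "G", "T")
    else sc == pam_ch[j]
  }
  data.frame(position = starts, mismatches = mism)[pam_ok, ]
}

oracle_find_sites <- function(seq, proto, pam, max_mm) {
  n <- nchar(seq)
  m <- nchar(proto)
  plus <- oracle_scan_one_strand(seq, proto, pam)
  plus <- plus[plus$mismatches <= max_mm, , drop = FALSE]
  if (nrow(plus)) {
    plus$strand <- "+"
    plus$cut_position <- plus$position + m - 3
  }
  minus <- oracle_scan_one_strand(oracle_revcomp(seq), proto, pam)
  minus <- minus[minus$mismatches <= max_mm, , drop = FALSE]
  if (nrow(minus)) {
    minus$position <- n - minus$position - m
    minus$strand <- "-"
    minus$cut_position <- minus$position + 3
  }
  out <- rbind(plus, minus)
  if (nrow(out) == 0) {
    return(data.frame(position = integer(), mismatches = integer(),
                      strand = character(), cut_position = integer()))
  }
  out[order(out$position, out$strand),
      c("position", "strand", "mismatches", "cut_position")]
}

# count surviving repeat copies when everything strictly between cuts a and b
# is deleted (units touching the open interval are destroyed)
oracle_outermost_total <- function(units, a, b) {
  keep <- units$end <= a | units$start >= b
  sum(units$unit_class[keep] %in%
        c("repeat-left", "repeat-right", "repeat-variant", "repeat-truncated"))
}

# exact copy-total distribution for independent cleavage + outermost-join:
# enumerate all 2^n cleaved subsets
oracle_enumerate_outermost <- function(units, cuts, p, parent_total) {
  n <- length(cuts)
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  probs <- apply(grid, 1, function(g) prod(ifelse(g, p, 1 - p)))
  totals <- apply(grid, 1, function(g) {
    if (sum(g) < 2) return(parent_total)
    cc <- sort(cuts[g])
    oracle_outermost_total(units, cc[1], cc[length(cc)])
  })
  out <- tapply(probs, totals, sum)
  data.frame(copy_total = as.numeric(names(out)), prob = as.numeric(out))
}

# two-sided Fisher p by direct log-choose enumeration
oracle_fisher <- function(a, b) {
  n1 <- sum(a)
  n2 <- sum(b)
  k <- a[1] + b[1]
  support <- max(0, k - n2):min(k, n1)
  logp <- lchoose(n1, support) + lchoose(n2, k - support) -
    lchoose(n1 + n2, k)
  p <- exp(logp)
  p_obs <- exp(lchoose(n1, a[1]) + lchoose(n2, k - a[1]) -
                 lchoose(n1 + n2, k))
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# small fully-specified array fixture: nl left/right dimers as 120-bp units
# starting at `offset`, no flanks
toy_units <- function(n_dimers, unit_length = 120, offset = 0) {
  starts <- offset + (seq_len(2 * n_dimers) - 1) * unit_length
  tibble::tibble(
    start = starts, end = starts + unit_length, strand = "+",
    unit_class = rep(c("repeat-left", "repeat-right"), n_dimers),
    family = rep(c("L-Rsp", "R-Rsp"), n_dimers)
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# plant protospacer+pam instances (with `mm` mismatches each) at given
# 0-based offsets in a sequence
plant_sites <- function(seq, proto, offsets, mm = 0, pam = "AGG") {
  s <- strsplit(seq, "")[[1]]
  for (o in offsets) {
    ins <- strsplit(proto, "")[[1]]
    if (mm > 0) {
      at <- sample(length(ins), mm)
      for (i in at) ins[i] <- sample(setdiff(c("A", "C", "G", "T"), ins[i]), 1)
    }
    s[(o + 1):(o + length(ins))] <- ins
    s[(o + length(ins) + 1):(o + length(ins) + nchar(pam))] <-
      strsplit(pam, "")[[1]]
  }
  paste(s, collapse = "")
}

toy_sites_acc <- function(cuts) {
  tibble::tibble(
    guide = "g", position = cuts - 17, strand = "+",
    mismatches = 0L, cut_position = cuts
  )
}
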