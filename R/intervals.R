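# Half-open interval algebra on a single chromosome.
#
# Intervals are data.frames with numeric columns `start` and `end`
# ([start, end), Mb). All set operations return canonical form: sorted by
# start, pairwise disjoint, zero-length pieces dropped. Touching pieces
# ([a,b) + [b,c)) are coalesced by union but do NOT count as overlapping.

iv <- function(start = numeric(), end = numeric()) {
  x <- data.frame(start = as.numeric(start), end = as.numeric(end))
  if (any(x$end < x$start)) stop("interval end < start")
  iv_canonical(x)
}

iv_canonical <- function(x) {
  x <- x[x$end > x$start, , drop = FALSE]
  if (nrow(x) <= 1L) {
    rownames(x) <- NULL
    return(x)
  }
  x <- x[order(x$start, x$end), , drop = FALSE]
  out_s <- x$start[1L]
  out_e <- x$end[1L]
  for (i in seq_len(nrow(x))[-1L]) {
    j <- length(out_s)
    if (x$start[i] <= out_e[j]) {
      out_e[j] <- max(out_e[j], x$end[i])
    } else {
      out_s <- c(out_s, x$start[i])
      out_e <- c(out_e, x$end[i])
    }
  }
  data.frame(start = out_s, end = out_e)
}

iv_union <- function(a, b) iv_canonical(rbind(a, b))

iv_intersect <- function(a, b) {
  a <- iv_canonical(a)
  b <- iv_canonical(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(iv())
  s <- e <- numeric()
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a$start[i], b$start)
    hi <- pmin(a$end[i], b$end)
    keep <- hi > lo
    s <- c(s, lo[keep])
    e <- c(e, hi[keep])
  }
  iv_canonical(data.frame(start = s, end = e))
}

iv_setdiff <- function(a, b) {
  a <- iv_canonical(a)
  b <- iv_canonical(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(a)
  for (i in seq_len(nrow(b))) {
    s <- e <- numeric()
    for (j in seq_len(nrow(a))) {
      # piece of a[j] left of b[i]
      if (a$start[j] < b$start[i]) {
        s <- c(s, a$start[j]); e <- c(e, min(a$end[j], b$start[i]))
      }
      # piece right of b[i]
      if (a$end[j] > b$end[i]) {
        s <- c(s, max(a$start[j], b$end[i])); e <- c(e, a$end[j])
      }
    }
    a <- iv_canonical(data.frame(start = s, end = e))
    if (nrow(a) == 0L) break
  }
  a
}

iv_length <- function(x) sum(x$end - x$start)

# TRUE iff the two interval sets share a region of positive length.
iv_overlaps <- function(a, b) iv_length(iv_intersect(a, b)) > 0

# TRUE iff every piece of a lies inside b.
iv_contains <- function(b, a) nrow(iv_setdiff(a, b)) == 0L

iv_span <- function(x) {
  if (nrow(x) == 0L) return(c(NA_real_, NA_real_))
  c(min(x$start), max(x$end))
}
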