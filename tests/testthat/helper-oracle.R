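# 1-ms discretized brute-force reference for the interval engine.
# Deliberately a different route from the package: per-millisecond membership
# vectors, run-length grouping, neighbour lookup on runs. Millisecond i of the
# vectors represents the half-open interval [i-1, i).

oracle_cover <- function(track) {
  v <- logical(track$trial_duration_ms)
  eps <- track$episodes
  for (i in seq_len(nrow(eps))) {
    v[seq(eps$begin_ms[i] + 1L, eps$end_ms[i])] <- TRUE
  }
  v
}

oracle_partition <- function(a, b) {
  va <- oracle_cover(a); vb <- oracle_cover(b)
  color <- ifelse(va & vb, "black", ifelse(va | vb, "gray", "white"))
  r <- rle(color)
  end <- cumsum(r$lengths); begin <- c(0L, head(end, -1L))
  n <- length(r$values)
  cls <- rep("not-applicable", n)
  for (i in seq_len(n)) {
    if (r$values[i] != "gray") next
    before <- i > 1L && r$values[i - 1L] == "black"
    after <- i < n && r$values[i + 1L] == "black"
    cls[i] <- if (before && after) "enclosed" else if (after) "preceding"
              else if (before) "following" else "isolated"
  }
  data.frame(
    begin_ms = begin, end_ms = end, color = r$values, gray_class = cls,
    a_ms = vapply(seq_len(n), function(i) sum(va[(begin[i] + 1L):end[i]]), numeric(1)),
    b_ms = vapply(seq_len(n), function(i) sum(vb[(begin[i] + 1L):end[i]]), numeric(1)),
    stringsAsFactors = FALSE
  )
}

oracle_outcomes <- function(opart, tolerance_ms, correction) {
  vapply(seq_len(nrow(opart)), function(i) {
    if (opart$color[i] == "black") return("FOG")
    if (opart$color[i] == "white") return("no_FOG")
    if (opart$gray_class[i] == "isolated") return("discussion")
    if (opart$end_ms[i] - opart$begin_ms[i] > tolerance_ms) return("discussion")
    if (correction == "include") "FOG" else "no_FOG"
  }, character(1))
}

oracle_table <- function(a, b) {
  va <- oracle_cover(a); vb <- oracle_cover(b)
  c(a = sum(va & vb), b = sum(va & !vb), c = sum(!va & vb), d = sum(!va & !vb))
}

# per-ms indicator of resolved FOG time, for set-inclusion checks
resolved_fog_vector <- function(resolved, N) {
  v <- logical(N)
  fog <- resolved[resolved$outcome == "FOG", , drop = FALSE]
  for (i in seq_len(nrow(fog))) v[seq(fog$begin_ms[i] + 1L, fog$end_ms[i])] <- TRUE
  v
}
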