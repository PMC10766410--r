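# Independent reference implementation of the pulse-detection semantics.
#
# Instead of sweeping with a running state, it repeatedly enumerates
# candidate confirmation indices from the start of the open segment: for
# each j the nadir is the minimum of the segment before j, qualification is
# the relative-rise test against that minimum, and the earliest confirmed j
# wins. The peak run is found via diff(), the nadir via which.min(). Used to
# pin down the detector's semantics on exhaustively enumerated and random
# series.
oracle_detect <- function(v, threshold, two_point) {
  v <- unname(v)
  n <- length(v)
  res <- list()
  start <- 1L
  repeat {
    found <- NULL
    if (start <= n - 1L) {
      for (j in (start + 1L):n) {
        seg <- v[start:(j - 1L)]
        nad_val <- min(seg)
        if (nad_val <= 0) next
        if (!((v[j] - nad_val) / nad_val >= threshold - 1e-12)) next
        if (two_point) {
          if (j >= n) next
          if (!((v[j + 1L] - nad_val) / nad_val >= threshold - 1e-12)) next
        }
        d <- diff(v[j:n])
        dec <- which(d < 0)
        run_end <- if (length(dec)) j + dec[1] - 1L else n
        peak <- j - 1L + which.max(v[j:run_end])
        nad_idx <- start - 1L + which.min(seg)
        found <- c(nad_idx, peak)
        break
      }
    }
    if (is.null(found)) break
    res[[length(res) + 1L]] <- found
    start <- found[2] + 1L
    if (start >= n) break
  }
  res
}

# Run the packaged detector on a bare value vector (uniform 10-min grid)
# and return (nadir index, peak index) pairs for comparison with the oracle.
detector_pairs <- function(v, threshold, criterion) {
  s <- hormone_series(seq(0, by = 10, length.out = length(v)), v)
  cs <- detect_pulses(s, criterion = criterion, threshold = threshold,
                      window_end = 10 * (length(v) - 1))
  if (!cs$n_pulses) return(list())
  lapply(seq_len(cs$n_pulses), function(i) {
    c(match(cs$pulses$nadir_time[i], s$times),
      match(cs$pulses$peak_time[i], s$times))
  })
}

# All value sequences of length n over the given alphabet, as a matrix with
# one sequence per row.
enumerate_series <- function(n, alphabet) {
  grid <- do.call(expand.grid, rep(list(alphabet), n))
  unname(as.matrix(grid))
}
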