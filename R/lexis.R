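# Split each case's follow-up (0, t_stop] at every crossing of an integer
# age or integer calendar year (the unit Lexis cells on which background
# rates are constant), plus any extra global breakpoints. Fully vectorised
# across cases; returns parallel vectors sorted by case then time.
#
# Returns list(case, t_lo, t_hi) with zero-width segments removed.
.lexis_segments <- function(t_stop, age_dx, year_dx, extra = numeric(0)) {
  n <- length(t_stop)
  stopifnot(length(age_dx) == n, length(year_dx) == n, all(t_stop > 0))

  crossings <- function(x0) {
    fr <- x0 %% 1
    first <- ifelse(fr == 0, 1, 1 - fr)
    cnt <- pmax(0, ceiling(t_stop - first))
    cnt[t_stop <= first] <- 0L
    ids <- rep.int(seq_len(n), cnt)
    list(ids = ids, t = first[ids] + (sequence(cnt) - 1))
  }
  ca <- crossings(age_dx)
  cy <- crossings(year_dx)

  ids <- c(ca$ids, cy$ids, seq_len(n))
  tt <- c(ca$t, cy$t, t_stop)
  for (e in extra) {
    hit <- which(e > 0 & e < t_stop)
    ids <- c(ids, hit); tt <- c(tt, rep.int(e, length(hit)))
  }
  o <- order(ids, tt)
  ids <- ids[o]; tt <- tt[o]
  m <- length(ids)
  prev <- c(0, tt[-m])
  t_lo <- ifelse(c(TRUE, ids[-1] != ids[-m]), 0, prev)
  keep <- (tt - t_lo) > 1e-9
  list(case = ids[keep], t_lo = t_lo[keep], t_hi = tt[keep])
}
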