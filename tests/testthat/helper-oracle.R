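# Independent brute-force oracle for the composition polytope
# {p >= 0, sum(p) = total, p1 >= p2 >= ... >= pn, declared fixed}:
# per-ingredient bounds by exhaustive sweep of an integer grid.  The first
# n-2 coordinates are enumerated explicitly; for each prefix the feasible
# values of coordinate n-1 form a contiguous interval (coordinate n is
# determined by the mass balance), so the full 0.1%-resolution feasible
# set is swept without materializing it.  Supports n in 1..4.  Entirely
# independent of the LP route used by feasible_bounds().

grid_bounds <- function(declared, step = 0.1, total = 100) {
  n <- length(declared)
  u <- round(total / step)                 # grid units
  d <- round(declared / step)              # NA where free
  stopifnot(n >= 1, n <= 4)
  if (n == 1) return(cbind(lo = total, hi = total))
  lo <- rep(Inf, n); hi <- rep(-Inf, n)
  upd <- function(i, vals) {
    if (length(vals)) {
      lo[i] <<- min(lo[i], min(vals)); hi[i] <<- max(hi[i], max(vals))
    }
  }
  # feasible interval of the second-to-last coordinate given the prefix
  # (prev = value of coordinate n-2, rem = remaining mass for last two)
  last_two <- function(prev, rem) {
    l <- ceiling(rem / 2)                  # encodes p_n <= p_{n-1}
    h <- pmin(prev, rem)                   # encodes ordering and p_n >= 0
    if (!is.na(d[n - 1])) { l <- pmax(l, d[n - 1]); h <- pmin(h, d[n - 1]) }
    if (!is.na(d[n])) {                    # p_{n-1} forced to rem - d_n
      forced <- rem - d[n]
      l <- pmax(l, forced); h <- pmin(h, forced)
    }
    list(l = l, h = h, ok = l <= h & rem >= 0)
  }
  if (n == 2) {
    p1 <- if (!is.na(d[1])) d[1] else 0:u
    p2 <- u - p1
    ok <- p2 >= 0 & p2 <= p1
    if (!is.na(d[2])) ok <- ok & p2 == d[2]
    upd(1, p1[ok]); upd(2, p2[ok])
  } else if (n == 3) {
    p1 <- if (!is.na(d[1])) d[1] else 0:u
    iv <- last_two(prev = p1, rem = u - p1)
    ok <- iv$ok
    upd(1, p1[ok]); upd(2, c(iv$l[ok], iv$h[ok]))
    upd(3, c((u - p1)[ok] - iv$h[ok], (u - p1)[ok] - iv$l[ok]))
  } else {
    p1v <- if (!is.na(d[1])) d[1] else 0:u
    p2v <- if (!is.na(d[2])) d[2] else 0:u
    g <- expand.grid(p1 = p1v, p2 = p2v)
    g <- g[g$p2 <= g$p1, ]
    rem <- u - g$p1 - g$p2
    iv <- last_two(prev = g$p2, rem = rem)
    ok <- iv$ok
    upd(1, g$p1[ok]); upd(2, g$p2[ok])
    upd(3, c(iv$l[ok], iv$h[ok]))
    upd(4, c(rem[ok] - iv$h[ok], rem[ok] - iv$l[ok]))
  }
  if (!is.finite(lo[1])) stop("grid oracle: empty feasible set")
  cbind(lo = lo * step, hi = hi * step)
}
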