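# Independent oracles: straightforward definitional implementations used to
# cross-check the package's optimized code paths. Deliberately written as
# plain loops / textbook formulas, sharing no code with R/.

# --- peak detection ---------------------------------------------------------

# all strict local maxima with plateaus collapsed to the floor-midpoint sample
oracle_local_maxima <- function(x) {
  n <- length(x)
  res <- integer(0)
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1]) {
      j <- i
      while (j < n && x[j + 1] == x[i]) j <- j + 1
      if (j <= n - 1 && x[j + 1] < x[i]) res <- c(res, (i + j) %/% 2)
    }
  }
  res
}

oracle_prominence <- function(x, p) {
  n <- length(x)
  lmin <- x[p]; lbase <- p
  for (i in seq(p - 1, 1)) {
    if (i < 1 || x[i] > x[p]) break
    if (x[i] < lmin) { lmin <- x[i]; lbase <- i }
  }
  rmin <- x[p]; rbase <- p
  for (i in seq(p + 1, n)) {
    if (i > n || x[i] > x[p]) break
    if (x[i] < rmin) { rmin <- x[i]; rbase <- i }
  }
  list(prom = x[p] - max(lmin, rmin), lbase = lbase, rbase = rbase)
}

oracle_width <- function(x, p, pr) {
  h <- x[p] - 0.5 * pr$prom
  i <- p
  while (i > pr$lbase && x[i] > h) i <- i - 1
  left <- if (x[i] < h) i + (h - x[i]) / (x[i + 1] - x[i]) else i
  i <- p
  while (i < pr$rbase && x[i] > h) i <- i + 1
  right <- if (x[i] < h) i - (h - x[i]) / (x[i - 1] - x[i]) else i
  right - left
}

# full pipeline: height filter, greedy-by-height distance thinning (ties to
# the earlier index), then width filter at half prominence
oracle_find_peaks <- function(x, min_distance, min_height, min_width = NULL) {
  cand <- oracle_local_maxima(x)
  cand <- cand[x[cand] >= min_height]
  kept <- logical(length(cand))
  avail <- rep(TRUE, length(cand))
  while (any(avail)) {
    hs <- x[cand]
    hs[!avail] <- -Inf
    best <- which(hs == max(hs))[1]
    kept[best] <- TRUE
    avail[best] <- FALSE
    avail[abs(cand - cand[best]) < min_distance & avail] <- FALSE
  }
  out <- cand[kept]
  widths <- vapply(out, function(p) oracle_width(x, p, oracle_prominence(x, p)),
                   numeric(1))
  proms <- vapply(out, function(p) oracle_prominence(x, p)$prom, numeric(1))
  if (!is.null(min_width)) {
    keep <- widths >= min_width
    out <- out[keep]; widths <- widths[keep]; proms <- proms[keep]
  }
  list(index = out, prominence = proms, width = widths)
}

# --- hypergeometric tail ----------------------------------------------------

# P(X >= a) for X ~ Hypergeom(m, n, k), by direct summation of point masses
# computed from binomial coefficients in log space
oracle_hyper_tail <- function(a, m, n, k) {
  lo <- max(0, k - n)
  hi <- min(k, m)
  if (a > hi) return(0)
  xs <- max(a, lo):hi
  sum(exp(lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)))
}

# --- two-sample statistics --------------------------------------------------

# classic Levene W and p from the one-way ANOVA formula on |x - group mean|
oracle_levene <- function(a, b) {
  za <- abs(a - mean(a)); zb <- abs(b - mean(b))
  na <- length(a); nb <- length(b); N <- na + nb
  zbar <- mean(c(za, zb))
  num <- (na * (mean(za) - zbar)^2 + nb * (mean(zb) - zbar)^2) / 1
  den <- (sum((za - mean(za))^2) + sum((zb - mean(zb))^2)) / (N - 2)
  w <- num / den
  list(w = w, p = stats::pf(w, 1, N - 2, lower.tail = FALSE))
}

oracle_student_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * stats::pt(-abs(t), na + nb - 2))
}

oracle_welch_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- stats::var(a) / na; vb <- stats::var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

# --- polynomial least squares ----------------------------------------------

# least-squares solution on the included points, raw monomial basis (QR
# solve; the explicit normal equations are numerically singular for degree 4
# on an 84 h axis)
oracle_polyfit <- function(y, t, degree, exclude_before) {
  keep <- t >= exclude_before
  X <- outer(t[keep], 0:degree, `^`)
  unname(qr.solve(X, y[keep]))
}

# --- shared fixtures --------------------------------------------------------

make_plate <- function(n_time = 5, wells = c(A1 = "WT", A2 = "WT"),
                       dt = 1 / 12, seed = 42) {
  set.seed(seed)
  times <- seq(0, by = dt, length.out = n_time)
  plate_series(
    times,
    matrix(stats::rnorm(n_time * length(wells), 100, 10), ncol = length(wells)),
    data.frame(well = names(wells), strain = unname(wells))
  )
}

random_signal <- function(n, seed) {
  set.seed(seed)
  # mixture of discrete-valued and continuous signals exercises plateaus/ties
  if (seed %% 3 == 0) {
    as.numeric(sample(0:6, n, replace = TRUE))
  } else {
    round(stats::rnorm(n, 0, 3), if (seed %% 3 == 1) 1 else 3)
  }
}
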