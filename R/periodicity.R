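#' Correlation of methylation between CpG pairs, by distance
#'
#' For each separation `d` in `d_range`, all pairs of sites lying within the
#' same feature and separated by exactly `d` bp (+ strand C to + strand C)
#' are pooled across features, and the Pearson correlation between the
#' left-site and right-site methylation fractions is computed over the
#' pooled pairs. Each pair is counted once (left < right). `r(d)` is
#' undefined (`NA`) when fewer than `min_pairs` pairs exist or either margin
#' has zero variance.
#'
#' @param sites a coverage-filtered [site_table()].
#' @param features features data.table of a single class (e.g. exons) or a
#'   [genome_annotation()] (all features used as-is).
#' @param d_range integer length-2, inclusive distance range (default 3-500).
#' @param min_pairs minimum pair count per distance (default 20).
#' @return a `correlation_profile` data.table: `d`, `r`, `n_pairs`.
#' @export
correlation_by_distance <- function(sites, features, d_range = c(3L, 500L),
                                    min_pairs = 20L) {
  ft <- if (inherits(features, "genome_annotation")) features$features else
    as.data.table(features)
  if (nrow(ft) == 0L) stopf("empty feature set")
  dmin <- as.integer(d_range[1L]); dmax <- as.integer(d_range[2L])
  ss <- data.table(contig = sites$contig, s = sites$pos, e = sites$pos, m = sites$m)
  ff <- data.table(contig = ft$contig, s = ft$start, e = ft$end - 1L,
                   fid = seq_len(nrow(ft)))
  setkey(ff, contig, s, e)
  hits <- foverlaps(ss, ff, type = "within", nomatch = NULL)
  dt <- hits[, .(fid, pos = i.s, m)]
  setorder(dt, fid, pos)
  nd <- dmax - dmin + 1L
  n <- sx <- sy <- sxx <- syy <- sxy <- numeric(nd)
  if (nrow(dt) >= 2L) {
    maxg <- max(dt[, .N, by = fid]$N) - 1L
    for (g in seq_len(max(maxg, 0L))) {
      x <- dt$m
      y <- data.table::shift(dt$m, -g)
      d <- data.table::shift(dt$pos, -g) - dt$pos
      samef <- data.table::shift(dt$fid, -g) == dt$fid
      ok <- which(samef %in% TRUE & d >= dmin & d <= dmax)
      if (!length(ok)) {
        # sorted positions: once every g-th neighbour is beyond dmax, stop
        if (all(is.na(d) | !(samef %in% TRUE) | d > dmax)) break
        next
      }
      di <- d[ok] - dmin + 1L
      n   <- n   + tabulate(di, nd)
      sx  <- sx  + vsum(di, x[ok], nd)
      sy  <- sy  + vsum(di, y[ok], nd)
      sxx <- sxx + vsum(di, x[ok]^2, nd)
      syy <- syy + vsum(di, y[ok]^2, nd)
      sxy <- sxy + vsum(di, x[ok] * y[ok], nd)
    }
  }
  covxy <- sxy - sx * sy / pmax(n, 1)
  vx <- sxx - sx^2 / pmax(n, 1)
  vy <- syy - sy^2 / pmax(n, 1)
  r <- rep(NA_real_, nd)
  def <- n >= min_pairs & vx > 1e-12 & vy > 1e-12
  r[def] <- covxy[def] / sqrt(vx[def] * vy[def])
  out <- data.table(d = dmin:dmax, r = r, n_pairs = as.integer(n))
  setattr(out, "class", c("correlation_profile", class(out)))
  out
}

# sum of w within integer groups 1..nd (rowsum-based accumulator)
vsum <- function(idx, w, nd) {
  out <- numeric(nd)
  rs <- rowsum(w, idx)
  out[as.integer(rownames(rs))] <- rs[, 1L]
  out
}

#' Remove the baseline trend from a correlation profile
#'
#' Ordinary least squares of `r` on `d` over the defined distances; the
#' residuals form the series handed to the Fourier transform. Distances with
#' undefined `r` are imputed as residual 0, which adds no spectral energy.
#'
#' @param profile a [correlation_by_distance()] result.
#' @return numeric residual series on the 1-bp grid `d_min..d_max`, with
#'   attributes `d` and `n_defined`.
#' @export
detrend_profile <- function(profile) {
  def <- !is.na(profile$r)
  if (sum(def) < 2L) stopf("fewer than 2 defined correlations; cannot detrend")
  fit <- lm(r ~ d, data = profile[def])
  res <- numeric(nrow(profile))
  res[def] <- resid(fit)
  attr(res, "d") <- profile$d
  attr(res, "n_defined") <- sum(def)
  res
}

#' Fourier spectrum of a residual correlation series
#'
#' Discrete Fourier transform of the series padded with `pad_zeros` zeros to
#' sharpen the frequency grid. Component `k` has frequency `k/N` cycles/bp
#' and period `N/k` bp, where `N` is the padded length. Amplitude is the
#' modulus of the component. Components up to the Nyquist index are kept.
#'
#' @param residuals numeric series on a 1-bp grid (see [detrend_profile()]).
#' @param pad_zeros zeros appended to the series (default 50000).
#' @return a `meth_spectrum` data.table: `index`, `freq`, `period`,
#'   `amplitude`; attributes `n_series`, `pad`.
#' @export
meth_spectrum <- function(residuals, pad_zeros = 50000L) {
  nser <- length(residuals)
  if (nser == 0L) stopf("empty residual series")
  series <- c(as.numeric(residuals), rep(0, pad_zeros))
  N <- length(series)
  amp <- Mod(fft(series))
  k <- seq_len(floor(N / 2))  # drop the DC term, keep to Nyquist
  out <- data.table(index = k, freq = k / N, period = N / k, amplitude = amp[k + 1L])
  setattr(out, "class", c("meth_spectrum", class(out)))
  setattr(out, "n_series", nser)
  setattr(out, "pad", as.integer(pad_zeros))
  out
}

#' Nucleosome-band intensity and dominant period of a spectrum
#'
#' `band_score` sums component amplitudes whose period lies in the closed
#' interval `period_band` (140-200 bp, the nucleosome repeat range);
#' `--power` style squared intensity via `power = TRUE`. `dominant_period`
#' is the period of the maximum-amplitude in-band component.
#'
#' @param spectrum a [meth_spectrum()].
#' @param period_band closed period interval in bp (default c(140, 200)).
#' @param power sum squared amplitudes instead of moduli.
#' @return `band_score`: numeric intensity. `dominant_period`: period in bp.
#' @export
band_score <- function(spectrum, period_band = c(140, 200), power = FALSE) {
  inb <- spectrum$period >= period_band[1L] & spectrum$period <= period_band[2L]
  if (!any(inb)) stopf("no spectral components in the period band")
  a <- spectrum$amplitude[inb]
  if (power) sum(a^2) else sum(a)
}

#' @rdname band_score
#' @export
dominant_period <- function(spectrum, period_band = c(140, 200)) {
  inb <- which(spectrum$period >= period_band[1L] & spectrum$period <= period_band[2L])
  if (!length(inb)) stopf("no spectral components in the period band")
  spectrum$period[inb[which.max(spectrum$amplitude[inb])]]
}

#' Empirical significance of the nucleosome-band intensity
#'
#' Null distribution from random circular shifts of the residual vector
#' (re-padded and re-transformed per shift);
#' `p = (1 + #\{null >= observed\}) / (1 + n_shuffles)`.
#'
#' @param profile a [correlation_by_distance()] result.
#' @param n_shuffles number of shifts (default 999).
#' @param seed optional seed.
#' @param period_band closed period interval in bp.
#' @param pad_zeros padding for each transform.
#' @param power squared intensity toggle, as in [band_score()].
#' @return list with `p`, `observed`, `null` (numeric vector).
#' @export
periodicity_null <- function(profile, n_shuffles = 999L, seed = NULL,
                             period_band = c(140, 200), pad_zeros = 50000L,
                             power = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  res <- detrend_profile(profile)
  score <- function(v) band_score(meth_spectrum(v, pad_zeros), period_band, power)
  obs <- score(res)
  nres <- length(res)
  shifts <- sample.int(nres, n_shuffles, replace = TRUE) - 1L
  null <- vapply(shifts, function(s) {
    if (s == 0L) return(obs)
    score(c(res[(s + 1L):nres], res[1L:s]))
  }, numeric(1L))
  list(p = (1 + sum(null >= obs)) / (1 + n_shuffles), observed = obs, null = null)
}
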