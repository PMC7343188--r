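#' @importFrom data.table data.table as.data.table setkey setkeyv foverlaps
#'   rbindlist setorder setorderv fread fwrite copy := .N .SD
#' @importFrom stats fft rnorm rpois rbinom runif rbeta qbeta pbinom p.adjust
#'   pnorm pt qnorm sd var quantile median lm resid coef t.test wilcox.test
#'   kruskal.test fisher.test kmeans loess predict setNames complete.cases
#'   rlnorm rmultinom
#' @importFrom utils head tail
NULL

# half-open [start, end) interval length
iv_len <- function(start, end) end - start

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

logit <- function(p) log(p / (1 - p))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# rows of `a` overlapping any row of `b`; both data.tables with
# contig/start/end in 0-based half-open coordinates; strand-blind
overlaps_any <- function(a, b) {
  if (nrow(a) == 0L) return(logical(0L))
  if (nrow(b) == 0L) return(rep(FALSE, nrow(a)))
  aa <- data.table(contig = a$contig, s = a$start, e = a$end - 1L)
  bb <- data.table(contig = b$contig, s = b$start, e = b$end - 1L)
  setkey(bb, contig, s, e)
  hits <- foverlaps(aa, bb, type = "any", nomatch = NULL, which = TRUE)
  out <- rep(FALSE, nrow(a))
  out[unique(hits$xid)] <- TRUE
  out
}

# seeds handed to downstream stages; kept below 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 104729 * offset) %% 2147483647)
}
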