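#' @keywords internal
"_PACKAGE"

#' @import stats
#' @import utils
#' @importFrom data.table fread fwrite data.table setDF
NULL

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

#' Closed-threshold lower/upper tail selection
#'
#' Selects the k = ceiling(q * n) smallest (or largest) values using a closed
#' threshold, so all values tied with the k-th order statistic are included
#' (the returned set may therefore exceed q * n).
#'
#' @param x numeric vector (NAs excluded from ranking and never selected).
#' @param q tail fraction in (0, 1).
#' @param lower if TRUE take the lower tail, else the upper tail.
#' @return logical vector along `x`.
#' @keywords internal
tail_select <- function(x, q, lower = TRUE) {
  ok <- !is.na(x)
  n <- sum(ok)
  if (n == 0L) return(rep(FALSE, length(x)))
  k <- max(1L, ceiling(q * n))
  xs <- sort(x[ok], decreasing = !lower)
  thr <- xs[min(k, n)]
  sel <- rep(FALSE, length(x))
  sel[ok] <- if (lower) x[ok] <= thr else x[ok] >= thr
  sel
}

## half-open 0-based window index for 1-based positions
window_index <- function(pos, window_size) (pos - 1L) %/% as.integer(window_size)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
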