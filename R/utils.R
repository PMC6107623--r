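#' Lower median
#'
#' Median using the lower-of-two convention: for an even number of values the
#' smaller of the two central order statistics is returned, so the result is
#' always an element of `x`. Deterministic and scale-equivariant; used for all
#' wave-feature medians.
#'
#' @param x Numeric vector; `NA`s are dropped.
#' @return A length-1 numeric, or `NA_real_` if no finite values remain.
#' @export
#' @examples
#' median_low(c(1, 2, 3, 4))  # 2, not 2.5
median_low <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sort(x)[ceiling(n / 2)]
}

# abort with a class so callers can distinguish validation from processing errors
stop_dropwave <- function(msg, class) {
  rlang::abort(msg, class = c(class, "dropwave_error"))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# running minimum with a fixed-width window clamped inside [1, n].
# The window always contains position i, so out[i] <= x[i].
running_min <- function(x, width) {
  n <- length(x)
  width <- as.integer(width)
  if (width > n) {
    stop_dropwave(
      sprintf("baseline window (%d samples) is longer than the series (%d)", width, n),
      "dropwave_config_error"
    )
  }
  if (width <= 1L) return(x)
  half <- (width - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    start <- i - half
    start <- max(1L, min(start, n - width + 1L))
    out[i] <- min(x[start:(start + width - 1L)])
  }
  out
}

# trapezoidal integral of y(t) between the two ends of the vectors
trapz_integral <- function(t, y) {
  if (length(t) < 2L) return(0)
  pracma::trapz(t, y)
}

round_half_up <- function(x) floor(x + 0.5)
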