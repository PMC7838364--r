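#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats cor sd cutree hclust as.dist phyper p.adjust rnorm runif setNames
#' @importFrom utils head
NULL

#' Fatty-acid keys used throughout the package
#'
#' The predominant seed-oil fatty acids tracked by the composition tables:
#' palmitic (C16:0), stearic (C18:0), oleic (C18:1), linoleic (C18:2),
#' alpha-linolenic (C18:3), arachidic (C20:0) and behenic (C22:0) acids,
#' plus a residual `other` category.
#'
#' @return Character vector of column names.
#' @export
fa_keys <- function() {
  c("C16:0", "C18:0", "C18:1", "C18:2", "C18:3", "C20:0", "C22:0", "other")
}

# internal: saturated / mono / poly groupings used by saturation_ratios()
.sfa_keys <- c("C16:0", "C18:0", "C20:0", "C22:0")
.mufa_keys <- "C18:1"
.pufa_keys <- c("C18:2", "C18:3")

stop_oilnet <- function(msg, class = "oilnet_error") {
  abort(msg, class = class)
}

check_fraction <- function(x, name, open_left = FALSE) {
  ok <- is.numeric(x) && all(x >= if (open_left) .Machine$double.xmin else 0) &&
    all(x <= 1)
  if (!ok) {
    stop_oilnet(sprintf("`%s` must be in %s", name,
                        if (open_left) "(0, 1]" else "[0, 1]"))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop_oilnet(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

# coefficient of variation: sample sd / mean; NA when the mean is zero
cv <- function(x) {
  m <- mean(x)
  if (!is.finite(m) || m == 0) return(NA_real_)
  sd(x) / m
}
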