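#' @importFrom stats aggregate cutree dist hclust predict runif setNames uniroot quantile
#' @importFrom utils combn read.table write.table head
#' @importFrom methods new is
NULL

# Locale-independent (byte-order) sort; all deterministic orderings in the
# package go through this so curated outputs are byte-identical across systems.
sort_c <- function(x, decreasing = FALSE) {
  sort(x, decreasing = decreasing, method = "radix")
}

order_c <- function(...) {
  order(..., method = "radix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x == floor(x)
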