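#' @importFrom rlang %||% .data abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map2 map_dbl map_int map_chr pmap imap list_rbind
#' @importFrom stats median mad phyper p.adjust kruskal.test ks.test wilcox.test
#'   rnbinom runif setNames quantile loess predict cor IQR
#' @importFrom utils combn head
NULL

# round half away from zero at `digits` decimals; base round() is half-to-even
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

`%||%` <- rlang::`%||%`

stop_ctcna <- function(...) rlang::abort(paste0(...), class = "ctcna_error")

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_ctcna(what, " is missing required column(s): ",
               paste(missing, collapse = ", "))
  }
  invisible(df)
}
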