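#' Convert percent loss-on-ignition to percent soil organic matter
#'
#' %OM = (%LOI x 0.7) - 0.23. Values below zero are floored at zero with a
#' warning (near-zero LOI lies outside the calibration range of the
#' conversion).
#'
#' @param loi Percent loss on ignition, in \[0, 100\] (vectorized).
#' @return Percent organic matter.
#' @export
percent_om <- function(loi) {
  if (any(loi < 0 | loi > 100, na.rm = TRUE)) {
    stop_invalid("%LOI must be within [0, 100]")
  }
  om <- loi * 0.7 - 0.23
  if (any(om < 0, na.rm = TRUE)) {
    warning("flooring ", sum(om < 0, na.rm = TRUE), " negative %OM value(s) at 0")
    om[om < 0] <- 0
  }
  om
}

#' Gross primary production
#'
#' GPP = ER - NEE (ecosystem respiration minus net ecosystem exchange).
#'
#' @param nee Net ecosystem exchange.
#' @param er Ecosystem respiration.
#' @return GPP, same units as the inputs.
#' @export
gpp <- function(nee, er) {
  er - nee
}

#' Correlation screen between two metric panels
#'
#' All pairwise correlations between the columns of `x` and `y`; pairs with
#' |r| >= `r_min` and p < `alpha` are flagged (unsigned r for flagging,
#' signed r reported). No multiplicity correction by default; Benjamini-
#' Hochberg adjustment of the p-values is available by flag. Constant
#' columns are excluded with a warning.
#'
#' @param x,y Numeric data.frames/matrices with matched rows (>= 4).
#' @param r_min Minimum |r| (default 0.6).
#' @param alpha Significance level (default 0.05).
#' @param method `"pearson"` or `"spearman"`.
#' @param adjust Apply Benjamini-Hochberg adjustment before flagging.
#' @return List with `pairs` (data.frame `x`, `y`, `r`, `p`, `sign`,
#'   `significant`) and `n_significant`.
#' @export
correlation_screen <- function(x, y, r_min = 0.6, alpha = 0.05,
                               method = c("pearson", "spearman"),
                               adjust = FALSE) {
  method <- match.arg(method)
  x <- as.data.frame(x)
  y <- as.data.frame(y)
  if (nrow(x) != nrow(y)) stop_invalid("x and y must have matched rows")
  if (nrow(x) < 4) stop_invalid("need at least 4 observations")
  drop_const <- function(df, label) {
    keep <- vapply(df, function(col) stats::var(col, na.rm = TRUE) > 0, logical(1))
    if (any(!keep)) {
      warning("excluding constant ", label, " column(s): ",
              paste(names(df)[!keep], collapse = ", "))
    }
    df[, keep, drop = FALSE]
  }
  x <- drop_const(x, "x")
  y <- drop_const(y, "y")
  grid <- expand.grid(x = names(x), y = names(y), stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    ct <- suppressWarnings(
      cor.test(x[[grid$x[i]]], y[[grid$y[i]]], method = method, exact = FALSE))
    data.frame(x = grid$x[i], y = grid$y[i],
               r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  }))
  if (is.null(res)) res <- data.frame(x = character(0), y = character(0),
                                      r = numeric(0), p = numeric(0))
  p_use <- if (adjust) stats::p.adjust(res$p, method = "BH") else res$p
  res$sign <- sign(res$r)
  res$significant <- abs(res$r) >= r_min & p_use < alpha
  list(pairs = res, n_significant = sum(res$significant, na.rm = TRUE))
}
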