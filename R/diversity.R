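#' Shannon diversity
#'
#' H = -sum p_i log(p_i) over the normalized positive entries; zero entries
#' contribute nothing. Natural log by default (ecology convention); the base
#' is configurable.
#'
#' @param abundances Nonnegative numeric vector (counts or relative
#'   abundances) with at least one positive entry.
#' @param base Logarithm base (default `exp(1)`).
#' @return Shannon index, a nonnegative scalar.
#' @export
shannon <- function(abundances, base = exp(1)) {
  if (any(abundances < 0) || anyNA(abundances)) {
    stop_invalid("abundances must be nonnegative and non-missing")
  }
  tot <- sum(abundances)
  if (tot == 0) stop_invalid("all-zero abundance vector has undefined diversity")
  p <- abundances[abundances > 0] / tot
  -sum(p * log(p, base = base))
}

#' Functional redundancy
#'
#' For each function category, FR = sum of the functional contributions f_i of
#' the contributing taxa divided by the number of unique contributing taxa;
#' the summary FR is the unweighted mean over categories with at least one
#' contributor. With unique taxon ids this is the mean positive contribution
#' per category; it is invariant to taxon order and scales linearly with the
#' contributions.
#'
#' @param fn A `function_table` (list with `contrib`: nonnegative taxa x
#'   category matrix), or such a matrix directly.
#' @return List with `fr` (scalar mean over categories) and `per_category`
#'   (data.frame `category`, `fr`, `n_contributing`).
#' @export
functional_redundancy <- function(fn) {
  contrib <- if (is.list(fn) && !is.null(fn$contrib)) fn$contrib else as.matrix(fn)
  if (any(contrib < 0)) stop_invalid("contributions must be nonnegative")
  if (is.null(colnames(contrib))) {
    colnames(contrib) <- sprintf("cat%03d", seq_len(ncol(contrib)))
  }
  per <- lapply(seq_len(ncol(contrib)), function(k) {
    f <- contrib[, k]
    contributing <- f > 0
    n <- sum(contributing)
    data.frame(category = colnames(contrib)[k],
               fr = if (n > 0) sum(f[contributing]) / n else NA_real_,
               n_contributing = n, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  if (all(is.na(per$fr))) stop_invalid("no taxon contributes to any category")
  list(fr = mean(per$fr, na.rm = TRUE), per_category = per)
}

#' Treatment effect sizes from a linear mixed model
#'
#' Fits `y ~ warming * clipping + (1 | block)` by REML: fixed warming,
#' clipping and interaction effects and a random block intercept. P-values
#' use the Satterthwaite degrees-of-freedom approximation by default; a
#' Wald-normal approximation is available. If the random-effect variance
#' degenerates to zero (singular fit) the model falls back to ordinary least
#' squares, noted in the `method` attribute.
#'
#' @param response Numeric vector, one value per row of `design`.
#' @param design Design data.frame with `warming`, `clipping`, `block`.
#' @param p_method `"satterthwaite"` (default) or `"normal"`.
#' @return data.frame with rows warming / clipping / interaction and columns
#'   `term`, `beta`, `se`, `p`; attribute `"method"` records the fit actually
#'   used (`"lmm"` or `"ols"`).
#' @export
fit_lmm <- function(response, design, p_method = c("satterthwaite", "normal")) {
  p_method <- match.arg(p_method)
  stopifnot(length(response) == nrow(design),
            all(c("warming", "clipping", "block") %in% names(design)))
  if (min(table(interaction(design$warming, design$clipping))) < 2) {
    stop_invalid("need at least 2 samples per treatment combination")
  }
  dat <- data.frame(y = response,
                    warming = design$warming,
                    clipping = design$clipping,
                    block = factor(design$block))
  X <- stats::model.matrix(~ warming * clipping, dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_invalid("rank-deficient fixed-effect design; aliased terms: ",
                 paste(aliased, collapse = ", "))
  }

  terms_map <- c(warming = "warming", clipping = "clipping",
                 `warming:clipping` = "interaction")
  as_effects <- function(beta, se, p) {
    keep <- names(terms_map)
    data.frame(term = unname(terms_map[keep]),
               beta = unname(beta[keep]), se = unname(se[keep]),
               p = unname(p[keep]), stringsAsFactors = FALSE)
  }

  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(y ~ warming * clipping + (1 | block),
                                    data = dat, REML = TRUE)),
    error = function(e) NULL)
  method <- "lmm"
  if (is.null(fit) || lme4::isSingular(fit, tol = 1e-5)) {
    # degenerate block variance: fall back to OLS
    method <- "ols"
    ols <- lm(y ~ warming * clipping, data = dat)
    sm <- summary(ols)$coefficients
    out <- as_effects(sm[, 1], sm[, 2], sm[, 4])
  } else {
    sm <- summary(fit)$coefficients
    beta <- sm[, "Estimate"]
    se <- sm[, "Std. Error"]
    p <- if (p_method == "satterthwaite") {
      sm[, "Pr(>|t|)"]
    } else {
      2 * pnorm(-abs(sm[, "t value"]))
    }
    out <- as_effects(beta, se, p)
  }
  attr(out, "method") <- method
  out
}

#' Renormalize effect sizes to \[-1, 1\]
#'
#' Divides each effect by the maximum absolute effect in the set
#' (sign-preserving), the transform used to place a panel of effect sizes on
#' a common -1..1 scale. An all-zero input maps to all zeros. Idempotent and
#' invariant to positive rescaling.
#'
#' @param betas Numeric vector of effect sizes.
#' @return Numeric vector of the same length in \[-1, 1\].
#' @export
renormalize_effects <- function(betas) {
  stopifnot(length(betas) > 0)
  m <- max(abs(betas))
  if (m == 0) return(betas * 0)
  betas / m
}

#' Compare linear and logarithmic functionality-biodiversity fits
#'
#' Ordinary least squares of functional diversity on taxonomic diversity
#' (linear) and on its natural log (logarithmic); reports the R-squared and
#' slope p-value of each and the winner by larger R-squared. A better
#' logarithmic fit indicates saturation of function with taxonomic richness,
#' the signature of functional redundancy.
#'
#' @param h_tax Positive taxonomic Shannon values.
#' @param h_fun Functional Shannon values, same length (>= 4).
#' @return List `r2_linear`, `r2_log`, `p_linear`, `p_log`, `winner`
#'   (`"linear"` or `"log"`).
#' @export
compare_fits <- function(h_tax, h_fun) {
  stopifnot(length(h_tax) == length(h_fun), length(h_tax) >= 4)
  if (any(h_tax <= 0)) stop_invalid("h_tax must be positive for the log fit")
  flin <- lm(h_fun ~ h_tax)
  flog <- lm(h_fun ~ log(h_tax))
  slope_p <- function(f) summary(f)$coefficients[2, 4]
  r2 <- function(f) summary(f)$r.squared
  out <- list(r2_linear = r2(flin), r2_log = r2(flog),
              p_linear = slope_p(flin), p_log = slope_p(flog))
  out$winner <- if (out$r2_log > out$r2_linear) "log" else "linear"
  out
}

#' Per-sample community function profile diversity
#'
#' Weighted function-category profile of each sample (relative abundance times
#' per-taxon contribution, summed over taxa) reduced to its Shannon
#' diversity. A convenience for functionality-biodiversity analyses when no
#' single-cell phenotype data are available.
#'
#' @param table A `pao_otu_table`.
#' @param fn A `function_table` covering the table's taxa.
#' @return Named numeric vector of per-sample functional Shannon values.
#' @export
function_profile_shannon <- function(table, fn) {
  rel <- relative_abundance(table)
  contrib <- fn$contrib[rownames(rel), , drop = FALSE]
  profile <- t(contrib) %*% rel   # category x sample
  apply(profile, 2, shannon)
}
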