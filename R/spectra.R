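#' Construct a single-cell Raman spectra set
#'
#' @param wavenumbers Strictly increasing grid in cm-1 within \[400, 2000\].
#' @param intensities Matrix, wavenumber x cell.
#' @param meta data.frame of per-cell metadata with at least `cell_id`.
#' @return Object of class `spectra_set`.
#' @export
spectra_set <- function(wavenumbers, intensities, meta = NULL) {
  intensities <- as.matrix(intensities)
  if (length(wavenumbers) != nrow(intensities)) {
    stop_invalid("wavenumber grid must match the intensity rows")
  }
  if (any(diff(wavenumbers) <= 0)) {
    stop_invalid("wavenumber grid must be strictly increasing")
  }
  if (is.null(meta)) {
    meta <- data.frame(cell_id = colnames(intensities) %||%
                         sprintf("cell%05d", seq_len(ncol(intensities))))
  }
  colnames(intensities) <- meta$cell_id
  structure(list(wavenumbers = as.numeric(wavenumbers),
                 intensities = intensities, meta = meta),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", ncol(x$intensities), " cells, ",
      length(x$wavenumbers), " wavenumbers [",
      min(x$wavenumbers), ", ", max(x$wavenumbers), "] cm-1\n", sep = "")
  invisible(x)
}

# Asymmetric least squares baseline (Eilers & Boelens). Penalized least
# squares with asymmetric weights: points above the baseline get weight p,
# points below 1 - p, so the fit hugs the lower envelope.
als_baseline <- function(y, lambda = 1e5, p = 0.01, n_iter = 10,
                         DtD = NULL) {
  n <- length(y)
  if (is.null(DtD)) DtD <- .als_penalty(n, lambda)
  w <- rep(1, n)
  z <- y
  for (i in seq_len(n_iter)) {
    M <- DtD$M
    M@x[DtD$diag_idx] <- DtD$diag_val + w
    z <- as.numeric(Matrix::solve(M, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (all(w_new == w)) break
    w <- w_new
  }
  z
}

# Second-difference penalty lambda * t(D) %*% D for a grid of length n,
# built once and shared across spectra. Returns the symmetric sparse matrix
# together with the positions of its diagonal entries in the @x slot so the
# per-iteration weight update can patch the diagonal without a rebuild.
.als_penalty <- function(n, lambda) {
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  M <- lambda * Matrix::crossprod(D)
  col <- rep(seq_len(n), diff(M@p))
  diag_idx <- which(col == M@i + 1L)
  list(M = M, diag_idx = diag_idx, diag_val = M@x[diag_idx])
}

#' Preprocess Raman spectra
#'
#' Baseline-corrects (asymmetric least squares), clips to nonnegative, bins
#' into consecutive 6 cm-1 intervals anchored at 400 cm-1 (the final partial
#' bin is retained), and vector-normalizes each spectrum to unit Euclidean
#' norm. On a 1 cm-1 grid from 400 to 2000 this yields 267 bins (266 full +
#' 1 partial). Baseline estimation requires the native fine grid: spectra
#' whose grid spacing already equals or exceeds the bin width are taken as
#' baseline-corrected and skip that step, which makes preprocessing exactly
#' idempotent on already-binned spectra.
#'
#' @param spectra A `spectra_set` (raw grid must span \[400, 2000\] within
#'   one bin width, with no gaps larger than the bin width).
#' @param bin_width Bin width in cm-1 (default 6).
#' @param lambda,p_asym Asymmetric-least-squares smoothness and asymmetry
#'   parameters.
#' @param baseline `"als"` (default) or `"none"`.
#' @return A preprocessed `spectra_set` on the binned grid (bin centres),
#'   each column with unit norm.
#' @export
preprocess_spectra <- function(spectra, bin_width = 6, lambda = 1e5,
                               p_asym = 0.01, baseline = c("als", "none")) {
  stopifnot(inherits(spectra, "spectra_set"))
  baseline <- match.arg(baseline)
  wn <- spectra$wavenumbers
  gaps <- diff(wn)
  if (any(gaps > bin_width + 1e-9)) {
    stop_invalid("wavenumber grid has gaps larger than the bin width (",
                 bin_width, " cm-1)")
  }
  if (wn[1] > 400 + bin_width || wn[length(wn)] < 2000 - bin_width) {
    stop_invalid("grid must span [400, 2000] cm-1 within one bin width")
  }
  already_binned <- median(gaps) >= bin_width - 1e-9
  Y <- spectra$intensities
  if (baseline == "als" && !already_binned) {
    DtD <- .als_penalty(nrow(Y), lambda)
    Y <- apply(Y, 2, function(y) {
      y - als_baseline(y, lambda, p_asym, DtD = DtD)
    })
  }
  Y[Y < 0] <- 0

  idx <- pmin(floor((wn - 400) / bin_width), floor((2000 - 400 - 1e-9) / bin_width))
  idx <- idx - min(idx)
  groups <- split(seq_along(wn), idx)
  centres <- vapply(groups, function(g) mean(wn[g]), numeric(1))
  B <- do.call(rbind, lapply(groups, function(g) colMeans(Y[g, , drop = FALSE])))

  norms <- sqrt(colSums(B^2))
  if (any(norms == 0)) {
    stop_invalid("cannot normalize spectrum with zero norm (cells: ",
                 paste(head(colnames(B)[norms == 0], 3), collapse = ", "), ")")
  }
  B <- sweep(B, 2, norms, "/")
  out <- spectra_set(centres, B, spectra$meta)
  attr(out, "preprocessed") <- TRUE
  out
}

#' Default biomarker band windows
#'
#' Band windows (cm-1) for the intracellular storage-polymer biomarkers:
#' polyP at 690-700 (P-O-P) and 1168-1180 (PO2-), PHA at 840 and 1725 (+/- 6),
#' peptidoglycan at 726 and 1421 (+/- 6) and 1573-1582, amide I-III at 1002,
#' 1220 and 1657 (+/- 6). Glycogen (478-484, skeletal C-C-O) and fatty acids
#' (1440-1460, CH2 bending) follow common Raman assignments and are
#' configurable.
#'
#' @return Named list of lists of 2-vectors (window bounds in cm-1).
#' @export
default_biomarker_bands <- function() {
  list(
    polyp = list(c(690, 700), c(1168, 1180)),
    pha = list(c(834, 846), c(1719, 1731)),
    glycogen = list(c(478, 484)),
    fa = list(c(1440, 1460)),
    peptidoglycan = list(c(720, 732), c(1415, 1427), c(1573, 1582)),
    amide = list(c(996, 1008), c(1214, 1226), c(1651, 1663))
  )
}

# Trapezoid integral of y over x.
.trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

# Integrate one band window with local linear background subtraction: the
# background is the line through the nearest grid points flanking the window
# (or the window edges if the window touches the grid boundary).
.band_area <- function(wn, y, window) {
  inside <- which(wn >= window[1] & wn <= window[2])
  if (length(inside) == 0) {
    stop_invalid("band window [", window[1], ", ", window[2],
                 "] contains no grid points")
  }
  lo <- max(1, min(inside) - 1)
  hi <- min(length(wn), max(inside) + 1)
  bg <- stats::approx(x = wn[c(lo, hi)], y = y[c(lo, hi)], xout = wn[inside])$y
  max(0, .trapz(wn[inside], y[inside] - bg))
}

#' Quantify biomarker band areas
#'
#' Integrates each biomarker's band windows by the trapezoid rule after local
#' linear background subtraction, summing across windows. Areas are floored
#' at zero.
#'
#' @param spectra A preprocessed `spectra_set` (or a single spectrum as a
#'   list with `wavenumbers` and `intensities`).
#' @param bands Named list of band windows, see [default_biomarker_bands()].
#' @return Matrix, cells x biomarkers, of nonnegative band areas.
#' @export
quantify_biomarkers <- function(spectra, bands = default_biomarker_bands()) {
  wn <- spectra$wavenumbers
  Y <- as.matrix(spectra$intensities)
  for (bm in names(bands)) {
    for (w in bands[[bm]]) {
      if (w[1] < min(wn) - 6 || w[2] > max(wn) + 6) {
        stop_invalid("band window for ", bm, " lies outside the grid")
      }
    }
  }
  out <- vapply(names(bands), function(bm) {
    vapply(seq_len(ncol(Y)), function(j) {
      sum(vapply(bands[[bm]], function(w) .band_area(wn, Y[, j], w), numeric(1)))
    }, numeric(1))
  }, numeric(ncol(Y)))
  out <- matrix(out, ncol = length(bands),
                dimnames = list(colnames(Y), names(bands)))
  out
}

#' Estimate per-spectrum noise level
#'
#' Robust noise SD from first differences of the spectrum (successive
#' differences cancel smooth signal; the factor sqrt(2) rescales to the
#' per-point SD).
#'
#' @param spectra A `spectra_set`.
#' @return Numeric vector, one noise SD per cell.
#' @export
estimate_noise <- function(spectra) {
  apply(as.matrix(spectra$intensities), 2, function(y) {
    mad(diff(y)) / sqrt(2)
  })
}

#' Confirm the PAO phenotype of single cells
#'
#' A cell is a confirmed PAO when its peptidoglycan, amide, PHA and polyP
#' band areas all exceed their detection thresholds. Default thresholds are
#' 3 x the cell's noise level (times the bandwidth, since areas integrate
#' over the window).
#'
#' @param levels Biomarker matrix from [quantify_biomarkers()] (cells x
#'   biomarkers), or a single named vector.
#' @param thresholds Named numeric vector of per-biomarker thresholds, a
#'   scalar, or NULL to derive 3 x `noise`.
#' @param noise Per-cell noise SD (recycled), used when `thresholds` is NULL.
#' @return Logical vector, one per cell.
#' @export
confirm_pao <- function(levels, thresholds = NULL, noise = 0) {
  if (is.null(dim(levels))) levels <- matrix(levels, 1, dimnames = list(NULL, names(levels)))
  need <- c("peptidoglycan", "amide", "pha", "polyp")
  if (!all(need %in% colnames(levels))) {
    stop_invalid("levels must include biomarkers: ", paste(need, collapse = ", "))
  }
  n <- nrow(levels)
  if (is.null(thresholds)) {
    thr <- matrix(3 * rep_len(noise, n), n, length(need))
  } else if (length(thresholds) == 1 && is.null(names(thresholds))) {
    thr <- matrix(thresholds, n, length(need))
  } else {
    if (!all(need %in% names(thresholds))) {
      stop_invalid("named thresholds must cover: ", paste(need, collapse = ", "))
    }
    thr <- matrix(rep(thresholds[need], each = n), n, length(need))
  }
  rowSums(levels[, need, drop = FALSE] > thr) == length(need)
}

#' Cluster cells into operational phenotypic units (OPUs)
#'
#' Agglomerative clustering of preprocessed (binned, vector-normalized)
#' spectra with cosine correlation distance d(x, y) = 1 - cos(x, y) and
#' average linkage, cutting the tree at `cutoff`. OPU labels are assigned by
#' descending cluster size (ties broken by lowest member index): OPU01 is the
#' largest.
#'
#' @param spectra A preprocessed `spectra_set` with >= 2 cells (a single cell
#'   yields one OPU with a warning).
#' @param cutoff Tree cut height on the cosine-distance scale (default 0.6).
#' @return List of class `opu_table`: `assignments` (named OPU label per
#'   cell), `sizes`, `mean_spectra` (bin x OPU matrix), `tree` (hclust), and
#'   the cell `meta`.
#' @export
cluster_opus <- function(spectra, cutoff = 0.6) {
  Y <- as.matrix(spectra$intensities)
  n <- ncol(Y)
  if (n < 2) {
    warning("fewer than 2 spectra; returning a single OPU")
    assignments <- setNames(rep("OPU01", n), colnames(Y))
    return(structure(list(assignments = assignments,
                          sizes = c(OPU01 = n),
                          mean_spectra = matrix(rowMeans(Y), ncol = 1,
                                                dimnames = list(NULL, "OPU01")),
                          tree = NULL, meta = spectra$meta),
                     class = "opu_table"))
  }
  Yn <- sweep(Y, 2, sqrt(colSums(Y^2)), "/")
  d <- stats::as.dist(pmax(1 - crossprod(Yn), 0))
  tree <- hclust(d, method = "average")
  raw <- cutree(tree, h = cutoff)

  size <- table(raw)
  first_member <- vapply(names(size), function(cl) min(which(raw == as.integer(cl))),
                         numeric(1))
  ord <- order(-as.integer(size), first_member)
  relabel <- setNames(sprintf("OPU%02d", seq_along(ord)), names(size)[ord])
  assignments <- setNames(unname(relabel[as.character(raw)]), colnames(Y))

  opus <- sort(unique(assignments))
  means <- vapply(opus, function(o) rowMeans(Y[, assignments == o, drop = FALSE]),
                  numeric(nrow(Y)))
  structure(list(assignments = assignments,
                 sizes = sort(table(assignments), decreasing = TRUE),
                 mean_spectra = means, tree = tree, meta = spectra$meta),
            class = "opu_table")
}

#' @export
print.opu_table <- function(x, ...) {
  cat("<opu_table> ", length(x$assignments), " cells in ",
      length(x$sizes), " OPUs\n", sep = "")
  invisible(x)
}

#' Per-sample OPU composition
#'
#' Relative OPU frequencies per sample; the input feeds [shannon()] for the
#' functional diversity of each sample. Samples with zero cells are excluded
#' with a warning.
#'
#' @param opus An `opu_table` whose `meta` maps every cell to a `sample_id`.
#' @param design Optional design; if given, restricted/ordered to its samples.
#' @return Matrix, sample x OPU, rows summing to 1.
#' @export
opu_abundance <- function(opus, design = NULL) {
  meta <- opus$meta
  if (is.null(meta$sample_id)) stop_invalid("opu meta must map cells to sample_id")
  tab <- table(meta$sample_id, opus$assignments[meta$cell_id])
  if (!is.null(design)) {
    missing <- setdiff(design$sample_id, rownames(tab))
    if (length(missing) > 0) {
      warning("samples with zero cells excluded: ", paste(missing, collapse = ", "))
    }
    tab <- tab[intersect(design$sample_id, rownames(tab)), , drop = FALSE]
  }
  comp <- sweep(unclass(tab), 1, rowSums(tab), "/")
  comp
}
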