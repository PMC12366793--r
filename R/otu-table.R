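#' Construct an OTU table
#'
#' A light container for taxa-by-sample amplicon count data together with the
#' per-OTU metadata the PAO identification filters act on: a lineage string
#' with a genus slot, an opaque per-OTU quality score (e-score, as emitted by
#' the upstream sequencing pipeline), and optional flags.
#'
#' @param counts Nonnegative integer matrix, taxa in rows (rownames are taxon
#'   ids), samples in columns.
#' @param taxonomy Character vector of lineage strings, one per taxon, using
#'   `;`-separated ranks with a `g__` genus slot (e.g.
#'   `"d__Bacteria;...;g__Sphingomonas;s__"`).
#' @param e_score Numeric vector of per-OTU quality scores.
#' @param flags Optional data.frame of per-taxon logical flags (e.g.
#'   `pao_candidate`).
#' @return An object of class `pao_otu_table`: a list with elements `counts`,
#'   `taxonomy`, `e_score`, `flags`.
#' @export
otu_table <- function(counts, taxonomy, e_score, flags = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("OTU%04d", seq_len(nrow(counts)))
  }
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop_invalid("counts must be nonnegative integers")
  }
  if (length(taxonomy) != nrow(counts)) {
    stop_invalid("taxonomy length must match the number of taxa")
  }
  if (length(e_score) != nrow(counts)) {
    stop_invalid("e_score length must match the number of taxa")
  }
  structure(
    list(
      counts = counts,
      taxonomy = setNames(as.character(taxonomy), rownames(counts)),
      e_score = setNames(as.numeric(e_score), rownames(counts)),
      flags = flags
    ),
    class = "pao_otu_table"
  )
}

#' @export
print.pao_otu_table <- function(x, ...) {
  cat("<pao_otu_table> ", nrow(x$counts), " taxa x ", ncol(x$counts),
      " samples\n", sep = "")
  invisible(x)
}

#' Number of taxa / samples in an OTU table
#' @param table A `pao_otu_table`.
#' @return Integer count.
#' @export
n_taxa <- function(table) nrow(table$counts)

#' @rdname n_taxa
#' @export
n_samples <- function(table) ncol(table$counts)

#' Per-sample relative abundances
#'
#' Converts counts to per-sample relative abundances. All-zero samples are
#' dropped with a warning (they carry no compositional information and would
#' otherwise produce 0/0 columns).
#'
#' @param table A `pao_otu_table` or a counts matrix.
#' @return Matrix of the same shape (minus any all-zero samples) with columns
#'   summing to 1.
#' @export
relative_abundance <- function(table) {
  counts <- if (inherits(table, "pao_otu_table")) table$counts else as.matrix(table)
  tot <- colSums(counts)
  if (any(tot == 0)) {
    warning("dropping ", sum(tot == 0),
            " all-zero sample(s) from relative-abundance conversion")
    counts <- counts[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  sweep(counts, 2, tot, "/")
}

# Mean over samples of per-sample relative abundance, one value per taxon.
# This is the abundance summary the 0.01 % filter rule is applied to.
mean_relative_abundance <- function(table) {
  rel <- relative_abundance(table)
  rowMeans(rel)
}

#' Extract the genus slot from lineage strings
#'
#' @param taxonomy Character vector of `;`-separated lineage strings.
#' @return Character vector of genus names; `NA` where the `g__` slot is
#'   missing or empty.
#' @export
extract_genus <- function(taxonomy) {
  vapply(strsplit(taxonomy, ";", fixed = TRUE), function(parts) {
    g <- grep("^\\s*g__", parts, value = TRUE)
    if (length(g) == 0) return(NA_character_)
    name <- sub("^\\s*g__", "", g[1])
    if (!nzchar(trimws(name))) NA_character_ else trimws(name)
  }, character(1))
}

#' Write / read an OTU table as TSV
#'
#' The on-disk layout is taxa in rows with `taxon`, `taxonomy`, `e_score`
#' columns followed by one column per sample.
#'
#' @param table A `pao_otu_table`.
#' @param path File path.
#' @return `write_otu_tsv` returns `path` invisibly; `read_otu_tsv` returns a
#'   `pao_otu_table`.
#' @export
write_otu_tsv <- function(table, path) {
  df <- data.frame(
    taxon = rownames(table$counts),
    taxonomy = unname(table$taxonomy),
    e_score = unname(table$e_score),
    table$counts,
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_otu_tsv
#' @export
read_otu_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("taxon", "taxonomy", "e_score")
  if (!all(required %in% names(df))) {
    stop_invalid("OTU TSV must have columns: ", paste(required, collapse = ", "))
  }
  counts <- as.matrix(df[, setdiff(names(df), required), drop = FALSE])
  rownames(counts) <- df$taxon
  otu_table(counts, df$taxonomy, df$e_score)
}
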