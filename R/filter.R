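#' Filter OTUs by abundance, quality score, and genus-level taxonomy
#'
#' Applies the PAO community preprocessing rules: OTUs with overall relative
#' abundance below 0.01 %, e-scores under 99, or lacking genus-level taxonomy
#' are removed. Overall relative abundance is the mean over samples of the
#' per-sample relative abundance (robust to uneven sequencing depth). Removed
#' taxa are reported in a ledger with their first failing reason under the
#' fixed rule order abundance -> e-score -> genus, so the ledger partitions
#' the removed set reproducibly.
#'
#' @param table A `pao_otu_table`.
#' @param min_rel_abund Minimum overall relative abundance (default 1e-4,
#'   i.e. 0.01 %).
#' @param min_escore Minimum e-score (default 99).
#' @return The filtered `pao_otu_table`, with the removal ledger (data.frame
#'   `taxon`, `reason`) attached as attribute `"removed"`.
#' @export
filter_otus <- function(table, min_rel_abund = 1e-4, min_escore = 99) {
  stopifnot(inherits(table, "pao_otu_table"))
  if (nrow(table$counts) == 0) {
    warning("empty OTU table; nothing to filter")
    attr(table, "removed") <- data.frame(taxon = character(0), reason = character(0))
    return(table)
  }
  abund <- mean_relative_abundance(table)
  genus <- extract_genus(table$taxonomy)

  fail_abund <- abund < min_rel_abund
  fail_escore <- table$e_score < min_escore
  fail_genus <- is.na(genus)

  reason <- rep(NA_character_, length(abund))
  reason[fail_genus] <- "genus"
  reason[fail_escore] <- "escore"
  reason[fail_abund] <- "abundance"      # rule order: abundance wins ties
  removed <- data.frame(taxon = names(abund)[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  keep <- is.na(reason)
  out <- otu_table(table$counts[keep, , drop = FALSE],
                   table$taxonomy[keep],
                   table$e_score[keep],
                   if (!is.null(table$flags)) table$flags[keep, , drop = FALSE])
  attr(out, "removed") <- removed
  out
}

#' Require the four PAO marker genes
#'
#' Retains only taxa whose function table records presence of all four polyP
#' and PHA cycling genes (ppk1, ppx, phaZ, phaC).
#'
#' @param table A `pao_otu_table`.
#' @param fn A `function_table` covering every taxon in `table`.
#' @return Filtered `pao_otu_table`.
#' @export
require_pao_genes <- function(table, fn) {
  stopifnot(inherits(table, "pao_otu_table"))
  genes <- fn$genes
  taxa <- rownames(table$counts)
  missing <- setdiff(taxa, rownames(genes))
  if (length(missing) > 0) {
    stop_invalid("taxa missing from the function table: ",
                 paste(head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) ", ...")
  }
  need <- c("ppk1", "ppx", "phaZ", "phaC")
  if (!all(need %in% colnames(genes))) {
    stop_invalid("function table must have gene columns: ",
                 paste(need, collapse = ", "))
  }
  keep <- rowSums(genes[taxa, need, drop = FALSE]) == 4L
  otu_table(table$counts[keep, , drop = FALSE],
            table$taxonomy[taxa[keep]],
            table$e_score[taxa[keep]],
            if (!is.null(table$flags)) table$flags[keep, , drop = FALSE])
}

#' FACS enrichment efficiency per taxon
#'
#' Ratio of a taxon's mean relative abundance in the sorted community to its
#' mean relative abundance in the bulk community. Taxa detected in the sorted
#' table but absent from the bulk get an `Inf` sentinel and are flagged.
#'
#' @param sorted_table,bulk_table `pao_otu_table`s sharing at least one taxon.
#' @return data.frame `taxon`, `sorted`, `bulk`, `efficiency`,
#'   `absent_in_bulk`.
#' @export
enrichment_efficiency <- function(sorted_table, bulk_table) {
  rs <- mean_relative_abundance(sorted_table)
  rb <- mean_relative_abundance(bulk_table)
  shared <- intersect(names(rs), names(rb))
  if (length(shared) == 0) stop_invalid("no shared taxa between the tables")
  s <- rs[shared]
  b <- rb[shared]
  eff <- ifelse(b > 0, s / b, ifelse(s > 0, Inf, NA_real_))
  data.frame(taxon = shared, sorted = unname(s), bulk = unname(b),
             efficiency = unname(eff),
             absent_in_bulk = unname(b == 0 & s > 0),
             stringsAsFactors = FALSE)
}

#' Pool replicates within treatments
#'
#' Randomly partitions the replicates of each treatment into `k_pools` groups
#' (seeded) and sums their counts, emulating the pooling of six soil
#' replicates into three pooled replicates ahead of cell sorting. Pooling
#' never mixes treatments and conserves total counts.
#'
#' @param table A `pao_otu_table` whose samples match `design$sample_id`.
#' @param design A design data.frame from [gen_design()].
#' @param k_pools Number of pools per treatment (must divide the replicate
#'   count of every treatment).
#' @param seed Integer seed for the random partition.
#' @return List with `table` (pooled `pao_otu_table`) and `design` (pooled
#'   design: `sample_id`, `treatment`, `warming`, `clipping`, `pool`,
#'   `members`).
#' @export
pool_replicates <- function(table, design, k_pools = 3L, seed = 1L) {
  stopifnot(inherits(table, "pao_otu_table"))
  assert_positive_int(k_pools, "k_pools")
  design <- design[match(colnames(table$counts), design$sample_id), ]
  if (anyNA(design$sample_id)) {
    stop_invalid("every sample in the table must appear in the design")
  }
  split_trt <- split(design$sample_id, design$treatment)
  bad <- vapply(split_trt, function(ids) length(ids) %% k_pools != 0, logical(1))
  if (any(bad)) {
    counts <- vapply(split_trt, length, integer(1))
    stop_invalid("replicates per treatment (",
                 paste(names(counts), counts, sep = "=", collapse = ", "),
                 ") must be divisible by k_pools = ", k_pools)
  }
  with_seed(substream_seed(seed, "pool"), {
    pooled_cols <- list()
    pooled_design <- list()
    for (trt in sort(names(split_trt))) {
      ids <- sample(split_trt[[trt]])
      per <- length(ids) / k_pools
      for (k in seq_len(k_pools)) {
        members <- sort(ids[seq((k - 1) * per + 1, k * per)])
        pid <- sprintf("%s_pool%d", trt, k)
        pooled_cols[[pid]] <- rowSums(table$counts[, members, drop = FALSE])
        row <- design[design$treatment == trt, ][1, c("treatment", "warming", "clipping")]
        pooled_design[[pid]] <- data.frame(
          sample_id = pid, row, pool = k,
          members = paste(members, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
    counts <- do.call(cbind, pooled_cols)
    rownames(counts) <- rownames(table$counts)
    pd <- do.call(rbind, pooled_design)
    rownames(pd) <- NULL
    list(
      table = otu_table(counts, table$taxonomy, table$e_score, table$flags),
      design = pd
    )
  })
}
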