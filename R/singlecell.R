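#' Sum single-cell counts into a pseudobulk profile
#'
#' Per-gene sum over the selected cells, with no other preprocessing.
#' Duplicate gene ids are collapsed by their mean AFTER summation (the
#' pseudobulk duplicate rule, distinct from the bulk read-time mean).
#'
#' @param cells A [cell_matrix()].
#' @param selector Integer/logical index of cells, or a list with any of
#'   `cell_type`, `sample` to select by label.
#' @return Object of class `pseudobulk_sample`: `values` (named gene
#'   sums), `n_cells`, `group`, `normalized = FALSE`.
#' @export
make_pseudobulk <- function(cells, selector = NULL) {
  stopifnot(inherits(cells, "cell_matrix"))
  idx <- seq_len(ncol(cells$counts))
  group <- "all"
  if (is.list(selector) && !is.null(selector$cell_type) ||
      is.list(selector) && !is.null(selector$sample)) {
    keep <- rep(TRUE, length(idx))
    if (!is.null(selector$cell_type))
      keep <- keep & cells$cell_labels %in% selector$cell_type
    if (!is.null(selector$sample))
      keep <- keep & cells$sample_labels %in% selector$sample
    idx <- idx[keep]
    group <- paste(c(selector$cell_type, selector$sample), collapse = "/")
  } else if (!is.null(selector)) {
    idx <- idx[selector]
  }
  if (length(idx) == 0) stop("empty cell selection")
  sums <- Matrix::rowSums(cells$counts[, idx, drop = FALSE])
  names(sums) <- cells$gene_ids
  if (anyDuplicated(cells$gene_ids)) {
    collapsed <- average_duplicate_genes(matrix(sums, ncol = 1),
                                         cells$gene_ids)
    sums <- drop(collapsed$values)
    names(sums) <- collapsed$gene_ids
  }
  structure(list(values = sums, n_cells = length(idx), group = group,
                 normalized = FALSE),
            class = "pseudobulk_sample")
}

#' Normalize a pseudobulk profile to 10,000 total counts
#'
#' Each gene's count is divided by the total and multiplied by 10,000.
#'
#' @param pb A `pseudobulk_sample`.
#' @return The sample with `values` summing to 10,000 and
#'   `normalized = TRUE`.
#' @export
normalize_pseudobulk <- function(pb) {
  stopifnot(inherits(pb, "pseudobulk_sample"))
  total <- sum(pb$values)
  if (total <= 0) stop("pseudobulk total is zero")
  pb$values <- pb$values / total * 10000
  pb$normalized <- TRUE
  pb
}

#' Bootstrap phase heterogeneity across cell types
#'
#' Quantifies how heterogeneous the clock phases are within each cell type
#' at each time point. Per time point: `n` is `floor(frac x count of the
#' smaller cell-type population)` (the same `n` for every type, removing
#' cell-number bias); for each cell type, `n_reps` rounds draw `n`
#' distinct cells (cells are replaced between rounds), sum them into a
#' pseudobulk restricted to the model's predictor genes, and predict its
#' circadian time. The resulting circular samples of predicted hours are
#' summarized (circular mean/SD) and compared between types with Rao's
#' homogeneity tests and the Wallraff test.
#'
#' @param cells A [cell_matrix()].
#' @param model A trained `taufisher_model`.
#' @param cell_types Character vector of >= 2 cell-type labels.
#' @param n_reps Pseudobulk replicates per type per time point
#'   (default 500).
#' @param frac Fraction of the smaller population drawn per round
#'   (default 0.2).
#' @param seed Master seed; per-(type, time point) streams are derived
#'   deterministically so results do not depend on evaluation order.
#' @param log2 Passed to [predict.taufisher_model()] (default TRUE: raw
#'   pseudobulk counts go in directly).
#' @return Object of class `heterogeneity_result`: `summary` (data frame
#'   per type x time point with circular mean/sd), `tests` (data frame per
#'   time point with Rao mean/dispersion and Wallraff p-values),
#'   `predictions` (list time point -> type -> predicted hours).
#' @export
bootstrap_phase_heterogeneity <- function(cells, model, cell_types,
                                          n_reps = 500, frac = 0.2,
                                          seed = 1, log2 = TRUE) {
  stopifnot(inherits(cells, "cell_matrix"),
            inherits(model, "taufisher_model"))
  if (length(cell_types) < 2) stop("need at least 2 cell types")
  samples <- unique(cells$sample_labels)
  gene_rows <- which(cells$gene_ids %in% model$genes)
  if (length(gene_rows) < 2)
    stop("fewer than 2 predictor genes present in the single-cell data")
  sub_counts <- cells$counts[gene_rows, , drop = FALSE]
  sub_genes <- cells$gene_ids[gene_rows]
  predictions <- list()
  summary_rows <- list()
  test_rows <- list()
  for (sm in samples) {
    in_sample <- cells$sample_labels == sm
    pools <- lapply(cell_types, function(ct) {
      pool <- which(in_sample & cells$cell_labels == ct)
      pool[order(cells$cell_ids[pool])]   # column-order invariance
    })
    names(pools) <- cell_types
    n <- floor(frac * min(lengths(pools)))
    if (n == 0)
      stop("sampling size n = 0 at time point ", sm,
           " (smallest population ", min(lengths(pools)), " cells)")
    hours_by_type <- lapply(cell_types, function(ct) {
      set.seed(derive_seed(seed, "het", sm, ct))
      pool <- pools[[ct]]
      pb_mat <- vapply(seq_len(n_reps), function(r) {
        sel <- pool[sample.int(length(pool), n)]
        Matrix::rowSums(sub_counts[, sel, drop = FALSE])
      }, numeric(length(gene_rows)))
      rownames(pb_mat) <- sub_genes
      if (anyDuplicated(sub_genes)) {
        collapsed <- average_duplicate_genes(pb_mat, sub_genes)
        pb_mat <- collapsed$values
      }
      predict(model, pb_mat, log2 = log2)$hour
    })
    names(hours_by_type) <- cell_types
    predictions[[sm]] <- hours_by_type
    for (ct in cell_types) {
      cs <- circular_mean_sd(hours_by_type[[ct]])
      summary_rows[[length(summary_rows) + 1]] <-
        data.frame(sample = sm, time = cells$sample_times[[sm]],
                   cell_type = ct, n_cells_per_rep = n, n_reps = n_reps,
                   circ_mean = cs$mean, circ_sd = cs$sd,
                   stringsAsFactors = FALSE)
    }
    rao <- rao_homogeneity_test(hours_by_type)
    wal <- wallraff_test(hours_by_type, grid = 1)
    test_rows[[length(test_rows) + 1]] <-
      data.frame(sample = sm, time = cells$sample_times[[sm]],
                 rao_p_mean = rao$p_mean,
                 rao_p_dispersion = rao$p_dispersion,
                 wallraff_p = wal$p, stringsAsFactors = FALSE)
  }
  structure(list(summary = do.call(rbind, summary_rows),
                 tests = do.call(rbind, test_rows),
                 predictions = predictions),
            class = "heterogeneity_result")
}
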