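#' Expression table container
#'
#' Normalised log2 intensities for a treated-vs-control comparison, the
#' input of [fold_changes()].
#'
#' @param values Numeric matrix of log2 intensities, genes in rows,
#'   samples in columns.
#' @param condition Character/factor of length `ncol(values)` with values
#'   `"treated"` / `"control"` (>= 2 replicates each).
#' @param genes Gene identifiers (default: rownames of `values`).
#' @return An object of class `il_expression`.
#' @export
expression_table <- function(values, condition, genes = rownames(values)) {
  values <- as.matrix(values)
  condition <- as.character(condition)
  stopifnot(length(condition) == ncol(values),
            all(condition %in% c("treated", "control")),
            sum(condition == "treated") >= 2L,
            sum(condition == "control") >= 2L,
            all(is.finite(values)))
  if (is.null(genes)) genes <- sprintf("g%04d", seq_len(nrow(values)))
  structure(list(values = values, condition = condition,
                 genes = as.character(genes)),
            class = "il_expression")
}

#' Per-gene fold changes and p-values
#'
#' For each gene the fold change is the ratio of condition means on the
#' linear intensity scale (treated over control) and the p-value comes
#' from a Welch two-sample t-test on the log2 values. A gene with zero
#' variance in both groups gets p = 1 when the means are equal and p = 0
#' otherwise.
#'
#' @param x An [expression_table()] object.
#' @return Data frame with columns `gene`, `fold`, `p`.
#' @export
fold_changes <- function(x) {
  stopifnot(inherits(x, "il_expression"))
  tr <- x$values[, x$condition == "treated", drop = FALSE]
  ct <- x$values[, x$condition == "control", drop = FALSE]
  fold <- rowMeans(2^tr) / rowMeans(2^ct)
  p <- vapply(seq_len(nrow(x$values)), function(i) {
    a <- tr[i, ]; b <- ct[i, ]
    if (stats::sd(a) < 1e-12 && stats::sd(b) < 1e-12) {
      return(if (abs(mean(a) - mean(b)) < 1e-12) 1 else 0)
    }
    tryCatch(stats::t.test(a, b, var.equal = FALSE)$p.value,
             error = function(e) 1)
  }, 0)
  data.frame(gene = x$genes, fold = fold, p = p, stringsAsFactors = FALSE)
}

#' Filter differentially expressed genes by fold change and p-value
#'
#' The screening rule: a gene is called up if its fold change is at least
#' `fold_cut` and its p-value at most `alpha`; down if its fold change is
#' at most `1/fold_cut` at the same p-value. Both thresholds are
#' inclusive. No multiple-testing correction is applied.
#'
#' @param results Data frame from [fold_changes()] (columns `gene`,
#'   `fold`, `p`).
#' @param fold_cut Fold-change cutoff (> 1; default 3).
#' @param alpha P-value cutoff (default 0.05).
#' @return List with character vectors `up` and `down`.
#' @export
de_filter <- function(results, fold_cut = 3, alpha = 0.05) {
  stopifnot(fold_cut > 1)
  if (nrow(results) == 0L) return(list(up = character(), down = character()))
  keep <- results$p <= alpha
  list(up = results$gene[keep & results$fold >= fold_cut],
       down = results$gene[keep & results$fold <= 1 / fold_cut])
}

#' qPCR relative quantification by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct_target - Ct_reference`; the condition means give
#' `ddCt = mean dCt(treated) - mean dCt(control)` and the fold change
#' `2^-ddCt`. The standard error of `ddCt` (replicate spread of the two
#' condition means, combined in quadrature) is propagated to the fold
#' scale as `ln(2) * fold * se(ddCt)`.
#'
#' @param ct Data frame with columns `sample`, `condition`
#'   (`"treated"`/`"control"`), `gene` (`"target"`/`"reference"`) and `ct`
#'   (cycles, in (0, 45)). Every sample must carry both genes.
#' @return List with `fold`, `se`, `ddct` and the per-sample `dct` table.
#' @export
ddct_fold_change <- function(ct) {
  stopifnot(is.data.frame(ct),
            all(c("sample", "condition", "gene", "ct") %in% names(ct)),
            all(ct$condition %in% c("treated", "control")),
            all(ct$gene %in% c("target", "reference")),
            all(ct$ct > 0 & ct$ct < 45))
  wide <- merge(
    stats::aggregate(ct ~ sample + condition, data = ct[ct$gene == "target", ],
                     FUN = mean),
    stats::aggregate(ct ~ sample + condition,
                     data = ct[ct$gene == "reference", ], FUN = mean),
    by = c("sample", "condition"), suffixes = c("_target", "_reference"),
    all = TRUE)
  if (anyNA(wide$ct_target) || anyNA(wide$ct_reference)) {
    stop("every sample needs both a target and a reference Ct", call. = FALSE)
  }
  wide$dct <- wide$ct_target - wide$ct_reference
  if (!all(c("treated", "control") %in% wide$condition)) {
    stop("both conditions are required", call. = FALSE)
  }
  dct_t <- wide$dct[wide$condition == "treated"]
  dct_c <- wide$dct[wide$condition == "control"]
  ddct <- mean(dct_t) - mean(dct_c)
  se_m <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0
  se_ddct <- sqrt(se_m(dct_t)^2 + se_m(dct_c)^2)
  fold <- 2^(-ddct)
  list(fold = fold, se = log(2) * fold * se_ddct, ddct = ddct,
       dct = wide[, c("sample", "condition", "dct")])
}

#' SRM protein level as target/Cat peak-area ratio
#'
#' Per replicate, each peptide contributes the peak area of its
#' highest-intensity transition; peptide areas are summed per protein and
#' the target sum is normalised to the Cat (control protein) sum. The
#' summary is the mean and standard deviation over replicates.
#'
#' @param areas Data frame with columns `protein` (`"target"`/`"control"`),
#'   `peptide`, `area` (>= 0), `replicate`, and optionally `transition`
#'   (when several transitions per peptide are reported, the largest area
#'   is used).
#' @return List with `per_replicate` (data frame `replicate`, `ratio`),
#'   `mean`, `sd`.
#' @export
srm_protein_ratio <- function(areas) {
  stopifnot(is.data.frame(areas),
            all(c("protein", "peptide", "area", "replicate") %in% names(areas)),
            all(areas$protein %in% c("target", "control")),
            all(areas$area >= 0))
  # best transition per (replicate, protein, peptide)
  best <- stats::aggregate(area ~ replicate + protein + peptide, data = areas,
                           FUN = max)
  sums <- stats::aggregate(area ~ replicate + protein, data = best, FUN = sum)
  reps <- sort(unique(sums$replicate))
  ratio <- vapply(reps, function(r) {
    cat_sum <- sums$area[sums$replicate == r & sums$protein == "control"]
    tgt_sum <- sums$area[sums$replicate == r & sums$protein == "target"]
    if (length(cat_sum) == 0L || cat_sum == 0) {
      stop("zero or missing Cat (control) peak-area sum in replicate ", r,
           call. = FALSE)
    }
    if (length(tgt_sum) == 0L) tgt_sum <- 0
    tgt_sum / cat_sum
  }, 0)
  list(per_replicate = data.frame(replicate = reps, ratio = ratio),
       mean = mean(ratio),
       sd = if (length(ratio) > 1L) stats::sd(ratio) else 0)
}

#' Rank promoter candidates into induction tiers
#'
#' Sorts candidates by fold change (descending, ties broken by
#' identifier) and assigns them to contiguous tiers of near-equal size
#' (default high / medium / low).
#'
#' @param folds Named numeric vector of fold changes (>= as many
#'   candidates as tiers).
#' @param tiers Tier labels, strongest first.
#' @return Data frame with columns `gene`, `fold`, `tier`, sorted by
#'   decreasing fold.
#' @examples
#' rank_promoters(c(ydfO = 116.61, ydfA = 47.69, marR = 17.37))
#' @export
rank_promoters <- function(folds, tiers = c("high", "medium", "low")) {
  stopifnot(is.numeric(folds), !is.null(names(folds)),
            length(folds) >= length(tiers), length(tiers) >= 1L)
  ord <- order(-folds, names(folds))
  n <- length(folds)
  k <- length(tiers)
  sizes <- diff(round(seq(0, n, length.out = k + 1L)))
  data.frame(gene = names(folds)[ord], fold = unname(folds[ord]),
             tier = rep(tiers, times = sizes), stringsAsFactors = FALSE)
}
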