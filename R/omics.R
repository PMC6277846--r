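#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector (validated
#' inputs, then [stats::p.adjust()] with `method = "BH"`).
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @examples
#' bh_adjust(c(0.005, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0 | pvalues > 1))
    stop("p-values must be numeric in [0, 1] with no missing values")
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differential expression from fold-changes and adjusted p-values
#'
#' A feature is called `up` when `log2fc >= lfc_threshold` and
#' `padj < alpha`, `down` when `log2fc <= -lfc_threshold` and
#' `padj < alpha`, otherwise `ns`. The default threshold of 1.5 on the
#' log2 scale follows the convention of calling features with
#' |log2 change| >= 1.5 at adjusted p < 0.05; the earlier "1.5-fold"
#' reading is available via `lfc_threshold = log2(1.5)`.
#'
#' @param records `data.frame` with columns `feature_id`, `log2fc` and
#'   either `padj` or `pvalue` (when only `pvalue` is present, `padj` is
#'   filled via [bh_adjust()]).
#' @param lfc_threshold Threshold on |log2 fold-change| (default 1.5).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return The input with columns `padj` and `call`
#'   (`up`/`down`/`ns`).
#' @export
call_deg <- function(records, lfc_threshold = 1.5, alpha = 0.05) {
  stopifnot(is.data.frame(records),
            all(c("feature_id", "log2fc") %in% names(records)))
  if (!"padj" %in% names(records)) {
    if (!"pvalue" %in% names(records))
      stop("records must contain 'padj' (or 'pvalue' to be adjusted)")
    records$padj <- bh_adjust(records$pvalue)
  }
  if (anyNA(records$padj)) stop("missing padj values")
  records$call <- ifelse(
    records$padj < alpha & records$log2fc >= lfc_threshold, "up",
    ifelse(records$padj < alpha & records$log2fc <= -lfc_threshold,
           "down", "ns"))
  records
}

#' Spectral-count fold-changes between two conditions
#'
#' Label-free proteomics rule: spectral counts are averaged across
#' replicates within each condition; a protein is significant when the
#' (pseudocounted) La/Ca fold-change exceeds 2 in either direction.
#'
#' @param counts Matrix or `data.frame` of non-negative integer spectral
#'   counts, proteins in rows (rownames = protein ids), one column per
#'   replicate.
#' @param condition Character vector over columns with exactly two
#'   levels; fold-changes are `case` over `reference`.
#' @param reference,case The two condition labels (default `"Ca"`,
#'   `"La"`).
#' @param pseudocount Added to both condition means before the ratio
#'   (default 1), so absent proteins yield finite fold-changes.
#' @param fc_threshold Significance threshold on the fold-change
#'   (default 2; significant when FC > 2 or FC < 1/2).
#' @return `data.frame` with `protein_id`, `mean_ref`, `mean_case`,
#'   `fold_change`, `significant`, `direction` (`up`/`down`/`ns`).
#' @examples
#' sc <- rbind(xox = c(10, 12, 11, 44, 46, 45))
#' spectral_fold_changes(sc, condition = rep(c("Ca", "La"), each = 3))
#' @export
spectral_fold_changes <- function(counts, condition, reference = "Ca",
                                  case = "La", pseudocount = 1,
                                  fc_threshold = 2) {
  counts <- as.matrix(counts)
  stopifnot(length(condition) == ncol(counts), pseudocount >= 0,
            fc_threshold > 1)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("spectral counts must be non-negative integers")
  for (lev in c(reference, case))
    if (!any(condition == lev))
      stop("no replicate columns for condition '", lev, "'")
  m_ref <- rowMeans(counts[, condition == reference, drop = FALSE])
  m_case <- rowMeans(counts[, condition == case, drop = FALSE])
  fc <- (m_case + pseudocount) / (m_ref + pseudocount)
  sig <- fc > fc_threshold | fc < 1 / fc_threshold
  data.frame(
    protein_id = if (!is.null(rownames(counts))) rownames(counts)
                 else paste0("p", seq_len(nrow(counts))),
    mean_ref = m_ref, mean_case = m_case, fold_change = fc,
    significant = sig,
    direction = ifelse(sig & fc > 1, "up", ifelse(sig, "down", "ns")),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Transcript/protein concordance
#'
#' Joins RNA-level and protein-level calls over the union of feature
#' ids (absent = `ns`) and classifies each feature:
#' `concordant_up`/`concordant_down` (both change the same way),
#' `discordant` (both change, opposite ways), `rna_only`/`protein_only`
#' (one level changes), `ns` (neither).
#'
#' @param rna_calls Named character vector or `data.frame` with
#'   `feature_id` and `call` (`up`/`down`/`ns`).
#' @param protein_calls Same shape for protein calls.
#' @return List with `cells` (`data.frame`: `feature_id`, `rna_call`,
#'   `protein_call`, `category`) and `counts` (named integer vector over
#'   all six categories; sums to the joined feature total).
#' @export
concordance_matrix <- function(rna_calls, protein_calls) {
  as_named <- function(x, what) {
    if (is.data.frame(x)) {
      stopifnot(all(c("feature_id", "call") %in% names(x)))
      stats::setNames(as.character(x$call), x$feature_id)
    } else if (!is.null(names(x))) {
      stats::setNames(as.character(x), names(x))
    } else stop(what, " must be a named vector or a data.frame")
  }
  rna <- as_named(rna_calls, "rna_calls")
  prot <- as_named(protein_calls, "protein_calls")
  ids <- union(names(rna), names(prot))
  r <- ifelse(ids %in% names(rna), rna[ids], "ns")
  p <- ifelse(ids %in% names(prot), prot[ids], "ns")
  category <- mapply(function(rc, pc) {
    if (rc == "ns" && pc == "ns") "ns"
    else if (rc == "ns") "protein_only"
    else if (pc == "ns") "rna_only"
    else if (rc == pc) paste0("concordant_", rc)
    else "discordant"
  }, r, p, USE.NAMES = FALSE)
  lv <- c("concordant_up", "concordant_down", "discordant",
          "rna_only", "protein_only", "ns")
  cells <- data.frame(feature_id = ids, rna_call = unname(r),
                      protein_call = unname(p), category = category,
                      stringsAsFactors = FALSE)
  list(cells = cells,
       counts = table(factor(category, levels = lv)))
}

#' Metabolite log-ratios with Welch tests
#'
#' For each metabolite, the log2 ratio of condition means (case over
#' reference) plus a two-sided Welch t-test on log2 abundances. Zeros
#' are replaced by half the smallest positive abundance in the table;
#' all-zero metabolites are excluded with a warning.
#'
#' @param abundances Matrix/`data.frame`, metabolites in rows, one
#'   column per replicate; non-negative.
#' @param condition Character vector over columns with two levels.
#' @param reference,case Condition labels (default `"Ca"`, `"La"`).
#' @return `data.frame` with `metabolite`, `log2_ratio`, `pvalue`.
#' @export
metabolite_log_ratios <- function(abundances, condition,
                                  reference = "Ca", case = "La") {
  x <- as.matrix(abundances)
  stopifnot(length(condition) == ncol(x), all(x >= 0))
  if (sum(condition == reference) < 2L || sum(condition == case) < 2L)
    stop("need >= 2 replicates per condition for testing")
  all_zero <- rowSums(x) == 0
  if (any(all_zero)) {
    warning("excluding all-zero metabolite(s): ",
            paste(rownames(x)[all_zero], collapse = ", "))
    x <- x[!all_zero, , drop = FALSE]
  }
  pos <- x[x > 0]
  if (length(pos)) x[x == 0] <- min(pos) / 2
  lx <- log2(x)
  ref_cols <- condition == reference
  case_cols <- condition == case
  out <- data.frame(
    metabolite = if (!is.null(rownames(x))) rownames(x)
                 else paste0("m", seq_len(nrow(x))),
    log2_ratio = log2(rowMeans(x[, case_cols, drop = FALSE]) /
                        rowMeans(x[, ref_cols, drop = FALSE])),
    pvalue = apply(lx, 1, function(row) {
      a <- row[case_cols]; b <- row[ref_cols]
      if (stats::sd(a) == 0 && stats::sd(b) == 0)
        return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
      stats::t.test(a, b)$p.value
    }),
    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Spearman's rho with average ranks for ties; the two-sided p-value is
#' computed by full permutation enumeration when `n <= 8` and by the
#' t-distribution approximation otherwise.
#'
#' @param predicted,observed Equal-length numeric vectors, `n >= 3`.
#' @return List with `rho`, `p`, `n` and `method`.
#' @examples
#' rank_correlation(1:3, c(30, 20, 10))  # rho = -1
#' @export
rank_correlation <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length")
  n <- length(predicted)
  stopifnot(n >= 3)
  rho <- stats::cor(predicted, observed, method = "spearman")
  if (n <= 8) {
    rx <- rank(predicted); ry <- rank(observed)
    perms <- permutations_of(n)
    rhos <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p <- min(p, 1)
    method <- "t approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

# all permutations of 1..n as an (n!) x n matrix
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Pairwise replicate correlation on log counts
#'
#' Pearson correlation between replicate columns on `log2(count + 1)`,
#' the standard reproducibility check for count-based omics replicates.
#'
#' @param counts Matrix/`data.frame`, features in rows, replicates in
#'   columns (>= 2).
#' @return `data.frame` with `rep_a`, `rep_b`, `pearson_r`; constant
#'   columns give `NA` with a warning.
#' @export
replicate_correlation <- function(counts) {
  x <- log2(as.matrix(counts) + 1)
  stopifnot(ncol(x) >= 2)
  cols <- colnames(x)
  if (is.null(cols)) cols <- paste0("rep", seq_len(ncol(x)))
  pairs <- utils::combn(ncol(x), 2)
  out <- data.frame(rep_a = cols[pairs[1, ]], rep_b = cols[pairs[2, ]],
                    pearson_r = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    a <- x[, pairs[1, i]]; b <- x[, pairs[2, i]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("constant replicate vector; correlation undefined")
    } else {
      out$pearson_r[i] <- stats::cor(a, b)
    }
  }
  out
}
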