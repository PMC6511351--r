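#' ROI time-series container
#'
#' @param matrix ROI x time matrix of mean signals.
#' @param roi_ids Ordered integer ROI ids matching the rows.
#' @param tr Sampling interval, seconds.
#' @return A `roi_timeseries` object.
#' @export
roi_timeseries <- function(matrix, roi_ids, tr) {
  stopifnot(is.matrix(matrix), nrow(matrix) == length(roi_ids),
            !anyNA(matrix), tr > 0)
  structure(list(matrix = matrix, roi_ids = as.integer(roi_ids), tr = tr),
            class = "roi_timeseries")
}

#' Extract mean ROI time series
#'
#' Row i of the result is the unweighted mean, at each time point, of the
#' voxels carrying atlas label `roi_ids[i]`.
#'
#' @param run A [bold4d()] on the atlas grid.
#' @param atlas An `atlas_networks`.
#' @return A [roi_timeseries()] with one row per atlas ROI.
#' @export
extract_roi_timeseries <- function(run, atlas) {
  stopifnot(inherits(run, "bold4d"), inherits(atlas, "atlas_networks"))
  d <- dim(run$data)
  if (!identical(d[1:3], dim(atlas$labels)))
    stop("BOLD grid ", paste(d[1:3], collapse = "x"),
         " does not match atlas grid ",
         paste(dim(atlas$labels), collapse = "x"))
  lab <- as.integer(atlas$labels)
  ids <- sort(unique(lab[lab > 0L]))
  expected <- as.integer(names(atlas$assignment))
  missing <- setdiff(expected, ids)
  if (length(missing))
    stop("ROI(s) with zero voxels in the label volume: ",
         paste(missing, collapse = ", "))
  m <- matrix(run$data, prod(d[1:3]), d[4])
  out <- rowsum(m[lab > 0L, , drop = FALSE], lab[lab > 0L]) /
    as.numeric(table(lab[lab > 0L]))
  roi_timeseries(unname(out), ids, run$tr)
}

#' Pearson correlation of two series
#'
#' Plain sample Pearson correlation with explicit validation: both series
#' must have equal length at least 3 and nonzero variance.
#'
#' @param x,y Numeric vectors.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for a constant series")
  cor(x, y)
}

#' Fisher r-to-z transform
#'
#' `z = atanh(r)`, the variance-stabilizing transform applied to
#' correlations before averaging and testing. Values at or beyond ±1
#' (possible in degenerate, noise-free data) are clamped to
#' ±(1 - 1e-7) with a warning rather than returning ±Inf.
#'
#' @param r Correlation(s).
#' @return z value(s); odd and strictly increasing in `r`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) {
    warning("correlation magnitude >= 1 clamped to 1 - 1e-7 before atanh")
    r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  }
  atanh(r)
}

#' Pairwise ROI functional connectivity
#'
#' All pairwise Pearson correlations between ROI mean time series,
#' together with their Fisher z transform (the diagonal is set to `NA` on
#' the z scale; self-connectivity is never used).
#'
#' @param ts A [roi_timeseries()].
#' @return A `roi_fc` object: list with `r` (symmetric ROI x ROI matrix),
#'   `z`, `roi_ids`.
#' @export
roi_fc <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  if (ncol(ts$matrix) < 3) stop("need at least 3 time points")
  sds <- apply(ts$matrix, 1, sd)
  if (any(sds == 0))
    stop("constant time series for ROI(s): ",
         paste(ts$roi_ids[sds == 0], collapse = ", "))
  r <- cor(t(ts$matrix))
  z <- suppressWarnings(fisher_z(r))
  if (any(abs(r[upper.tri(r)]) >= 1))
    warning("off-diagonal correlation magnitude >= 1 clamped before atanh")
  diag(z) <- NA_real_
  structure(list(r = r, z = z, roi_ids = ts$roi_ids), class = "roi_fc")
}

#' Per-subject 3x3 network connectivity matrix
#'
#' Averages the Fisher z values of pairwise ROI connectivity within and
#' between networks: the diagonal entry for network N is the mean z over
#' unordered ROI pairs inside N (intra-FC; `NA` for a single-ROI
#' network), the off-diagonal (M, N) entry the mean z over all pairs with
#' one ROI in each (inter-FC). Averaging happens on the z scale;
#' `scale = "r"` averages raw correlations instead for sensitivity
#' checks.
#'
#' @param fc A [roi_fc()].
#' @param atlas An `atlas_networks` assigning every ROI to a network.
#' @param scale `"z"` (default) or `"r"`.
#' @return A symmetric 3x3 matrix with network dimnames, class
#'   `network_fc_matrix`.
#' @export
network_matrix <- function(fc, atlas, scale = c("z", "r")) {
  scale <- match.arg(scale)
  stopifnot(inherits(fc, "roi_fc"), inherits(atlas, "atlas_networks"))
  ids <- as.character(fc$roi_ids)
  unassigned <- ids[!ids %in% names(atlas$assignment)]
  if (length(unassigned))
    stop("ROI(s) without network assignment: ",
         paste(unassigned, collapse = ", "))
  net <- atlas$assignment[ids]
  nets <- unique(unname(atlas$assignment))
  vals <- if (scale == "z") fc$z else fc$r
  out <- matrix(NA_real_, length(nets), length(nets),
                dimnames = list(nets, nets))
  for (i in seq_along(nets)) for (j in i:length(nets)) {
    rows <- which(net == nets[i]); cols <- which(net == nets[j])
    if (i == j) {
      if (length(rows) >= 2) {
        sub <- vals[rows, rows, drop = FALSE]
        out[i, i] <- mean(sub[upper.tri(sub)])
      }                                   # single-ROI network: intra NA
    } else {
      out[i, j] <- out[j, i] <- mean(vals[rows, cols])
    }
  }
  class(out) <- c("network_fc_matrix", class(out))
  out
}

#' Group comparison of network connectivity
#'
#' Six two-sample tests on the subject-level network matrix entries — the
#' 3 intra-network (diagonal) and 3 inter-network (off-diagonal) values —
#' with Benjamini-Hochberg FDR control applied separately within the
#' intra family and within the inter family. Also returns the group-mean
#' matrices (entries averaged across subjects on the z scale) and their
#' difference (patients minus controls).
#'
#' @param patients,controls Lists of `network_fc_matrix` (one per
#'   subject).
#' @param alpha FDR level (default 0.05).
#' @param var_equal Pooled-variance Student t (default) or Welch.
#' @return A `group_fc_comparison`: list with `table` (one row per network
#'   pair: group means/SDs, t, df, raw and BH-adjusted p, significance),
#'   `mean_patient`, `mean_control`, `difference`, `alpha`.
#' @export
compare_groups <- function(patients, controls, alpha = 0.05,
                           var_equal = TRUE) {
  stopifnot(length(patients) >= 2, length(controls) >= 2)
  dn <- dimnames(patients[[1]])
  ok <- function(m) identical(dimnames(m), dn) && all(dim(m) == dim(patients[[1]]))
  if (!all(vapply(patients, ok, TRUE)) || !all(vapply(controls, ok, TRUE)))
    stop("inconsistent network ordering across subjects")
  nets <- dn[[1]]
  if (length(nets) != 3)
    stop("compare_groups expects 3x3 network matrices (PVN, HVN, VSN)")
  pairs <- rbind(
    data.frame(n1 = nets, n2 = nets, type = "intra"),
    data.frame(n1 = c(nets[1], nets[2], nets[2]),
               n2 = c(nets[3], nets[3], nets[1]), type = "inter"))
  stack <- function(ms, i, j) vapply(ms, function(m) m[i, j], 0)
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs$n1[k]; j <- pairs$n2[k]
    a <- stack(patients, i, j); b <- stack(controls, i, j)
    if (anyNA(a) || anyNA(b)) {
      # single-ROI network: intra-FC undefined, reported as missing
      return(data.frame(pair = if (i == j) i else paste(i, j, sep = "-"),
                        type = pairs$type[k],
                        patient_mean = NA_real_, patient_sd = NA_real_,
                        control_mean = NA_real_, control_sd = NA_real_,
                        t = NA_real_, df = NA_real_, p_raw = NA_real_))
    }
    tt <- ttest_two_sample(a, b, var_equal = var_equal)
    data.frame(pair = if (i == j) i else paste(i, j, sep = "-"),
               type = pairs$type[k],
               patient_mean = mean(a), patient_sd = sd(a),
               control_mean = mean(b), control_sd = sd(b),
               t = tt$t, df = tt$df, p_raw = tt$p)
  })
  tab <- do.call(rbind, rows)
  tab$p_fdr <- NA_real_
  for (ty in c("intra", "inter")) {
    sel <- tab$type == ty & !is.na(tab$p_raw)
    if (any(sel)) tab$p_fdr[sel] <- fdr_bh(tab$p_raw[sel], alpha)$adjusted
  }
  tab$significant <- !is.na(tab$p_fdr) & tab$p_fdr <= alpha
  avg <- function(ms) {
    s <- Reduce(`+`, lapply(ms, function(m) ifelse(is.na(m), 0, m)))
    n <- Reduce(`+`, lapply(ms, function(m) !is.na(m)))
    out <- s / n
    dimnames(out) <- dn
    out
  }
  mp <- avg(patients); mc <- avg(controls)
  structure(list(table = tab, mean_patient = mp, mean_control = mc,
                 difference = mp - mc, alpha = alpha,
                 n_patient = length(patients), n_control = length(controls)),
            class = "group_fc_comparison")
}

#' @export
print.group_fc_comparison <- function(x, ...) {
  cat(sprintf("Network FC group comparison (%d patients vs %d controls, FDR %.2f per family)\n",
              x$n_patient, x$n_control, x$alpha))
  tab <- x$table
  tab$patient <- sprintf("%.4f ± %.4f", tab$patient_mean, tab$patient_sd)
  tab$control <- sprintf("%.4f ± %.4f", tab$control_mean, tab$control_sd)
  tab$sig <- ifelse(tab$significant, "*", "")
  print(tab[, c("pair", "type", "patient", "control", "p_raw", "p_fdr", "sig")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Correlate connectivity with a clinical covariate
#'
#' Pearson correlation (two-tailed p) plus the simple least-squares
#' regression of `covariate` on `fc_values`; significance at p < 0.05.
#'
#' @param fc_values Per-subject connectivity values.
#' @param covariate Paired clinical covariate (e.g. blood ammonia).
#' @return List with `r`, `p`, `slope`, `intercept`, `n`, `significant`.
#' @export
correlate_clinical <- function(fc_values, covariate) {
  keep <- complete.cases(fc_values, covariate)
  x <- fc_values[keep]; y <- covariate[keep]
  if (length(x) != length(y)) stop("inputs must be paired")
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (sd(y) == 0 || sd(x) == 0)
    stop("correlation undefined for a constant input")
  ct <- cor.test(x, y)
  fit <- lm(y ~ x)
  list(r = unname(ct$estimate), p = ct$p.value,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n = length(x), significant = ct$p.value < 0.05)
}
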