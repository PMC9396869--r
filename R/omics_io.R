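#' Assemble a multi-omics dataset
#'
#' Bundles matched gene expression (GE), copy-number (CNV) and DNA-methylation
#' (METH) matrices into a validated container. All matrices must have samples
#' in rows (identical order) and features in columns. CNV features and METH
#' probes are mapped to gene symbols; every mapped gene must be present among
#' the GE columns.
#'
#' @param ge numeric matrix, m samples x n1 genes, with dimnames.
#' @param cnv numeric matrix of segment-mean values (may have 0 columns).
#' @param meth numeric matrix of beta-values in `[0, 1]` (may have 0 columns).
#' @param cnv_map named character vector: CNV feature id -> gene symbol.
#' @param meth_map named character vector: METH probe id -> gene symbol.
#' @return An object of class `omics_dataset`.
#' @export
omics_dataset <- function(ge, cnv = NULL, meth = NULL,
                          cnv_map = character(), meth_map = character()) {
  ge <- as.matrix(ge)
  if (is.null(cnv)) cnv <- matrix(0, nrow(ge), 0, dimnames = list(rownames(ge), NULL))
  if (is.null(meth)) meth <- matrix(0, nrow(ge), 0, dimnames = list(rownames(ge), NULL))
  cnv <- as.matrix(cnv); meth <- as.matrix(meth)
  ds <- structure(list(samples = rownames(ge), ge = ge, cnv = cnv, meth = meth,
                       cnv_map = cnv_map, meth_map = meth_map),
                  class = "omics_dataset")
  validate_omics_dataset(ds)
}

validate_omics_dataset <- function(ds) {
  m <- nrow(ds$ge)
  if (m < 2L) stop("at least 2 samples are required")
  if (is.null(rownames(ds$ge))) stop("GE matrix must carry sample identifiers as rownames")
  for (nm in c("cnv", "meth")) {
    if (nrow(ds[[nm]]) != m)
      stop(sprintf("%s matrix has %d rows but GE has %d", toupper(nm), nrow(ds[[nm]]), m))
    if (ncol(ds[[nm]]) > 0 && !identical(rownames(ds[[nm]]), ds$samples))
      stop(sprintf("%s sample order differs from GE", toupper(nm)))
  }
  ids <- c(colnames(ds$ge), colnames(ds$cnv), colnames(ds$meth))
  if (anyDuplicated(ids))
    stop("duplicate feature identifiers: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (ncol(ds$meth) > 0) {
    bad <- which(ds$meth < 0 | ds$meth > 1, arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("beta-value outside [0,1] in probe '%s' (sample '%s')",
                   colnames(ds$meth)[bad[1, 2]], rownames(ds$meth)[bad[1, 1]]))
  }
  for (mp in list(cnv = ds$cnv_map, meth = ds$meth_map)) {
    if (length(mp) && !all(mp %in% colnames(ds$ge)))
      stop("mapped gene(s) absent from GE matrix: ",
           paste(setdiff(mp, colnames(ds$ge)), collapse = ", "))
  }
  if (length(ds$cnv_map) && anyDuplicated(ds$cnv_map))
    stop("CNV feature -> gene map must be injective (one CNV feature per gene)")
  ds
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat(sprintf("omics_dataset: %d samples | %d GE genes | %d CNV features | %d METH probes\n",
              length(x$samples), ncol(x$ge), ncol(x$cnv), ncol(x$meth)))
  invisible(x)
}

.read_matrix_file <- function(path, what) {
  if (!file.exists(path)) stop(sprintf("%s file not found: %s", what, path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  ids <- as.character(df[[1L]])
  mat <- df[, -1L, drop = FALSE]
  for (j in seq_along(mat)) {
    v <- mat[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop(sprintf("non-numeric value '%s' in %s file, row %d (sample '%s'), column '%s'",
                     v[bad[1]], what, bad[1], ids[bad[1]], colnames(mat)[j]))
      mat[[j]] <- vn
    }
  }
  m <- as.matrix(mat)
  rownames(m) <- ids
  m
}

.drop_zero_variance <- function(mat, what) {
  if (ncol(mat) == 0) return(mat)
  v <- apply(mat, 2, stats::var)
  drop <- which(!is.finite(v) | v == 0)
  if (length(drop)) {
    message(sprintf("dropping %d zero-variance %s feature(s): %s", length(drop), what,
                    paste(colnames(mat)[drop], collapse = ", ")))
    mat <- mat[, -drop, drop = FALSE]
  }
  mat
}

#' Read multi-omics matrices and the feature-to-gene map from delimited text
#'
#' Matrices are TSV (comma also accepted) with the first column holding sample
#' identifiers and a header row of feature identifiers. The mapping file has
#' columns `feature_id`, `feature_type` (`CNV` or `METH`) and `gene_symbol`.
#' CNV and METH samples may be a superset of GE samples; the returned dataset
#' is restricted to the common samples in GE order. Zero-variance features are
#' dropped with a message.
#'
#' @param ge_path,cnv_path,meth_path,mapping_path file paths; `cnv_path`,
#'   `meth_path` and `mapping_path` may be `NULL` for expression-only data.
#' @return An `omics_dataset`.
#' @export
read_omics <- function(ge_path, cnv_path = NULL, meth_path = NULL, mapping_path = NULL) {
  ge <- .read_matrix_file(ge_path, "GE")
  cnv <- if (!is.null(cnv_path)) .read_matrix_file(cnv_path, "CNV")
  meth <- if (!is.null(meth_path)) .read_matrix_file(meth_path, "METH")
  cnv_map <- character(); meth_map <- character()
  if (!is.null(mapping_path)) {
    if (!file.exists(mapping_path)) stop("mapping file not found: ", mapping_path)
    mp <- utils::read.table(mapping_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    need <- c("feature_id", "feature_type", "gene_symbol")
    if (!all(need %in% names(mp)))
      stop("mapping file must have columns: ", paste(need, collapse = ", "))
    cnv_map <- stats::setNames(mp$gene_symbol[mp$feature_type == "CNV"],
                               mp$feature_id[mp$feature_type == "CNV"])
    meth_map <- stats::setNames(mp$gene_symbol[mp$feature_type == "METH"],
                                mp$feature_id[mp$feature_type == "METH"])
  }
  samples <- rownames(ge)
  for (other in list(cnv, meth)) {
    if (!is.null(other)) samples <- intersect(samples, rownames(other))
  }
  if (!length(samples)) stop("no samples shared between the omics matrices")
  ge <- ge[samples, , drop = FALSE]
  if (!is.null(cnv)) cnv <- cnv[samples, , drop = FALSE]
  if (!is.null(meth)) meth <- meth[samples, , drop = FALSE]
  ge <- .drop_zero_variance(ge, "GE")
  if (!is.null(cnv)) cnv <- .drop_zero_variance(cnv, "CNV")
  if (!is.null(meth)) meth <- .drop_zero_variance(meth, "METH")
  if (!is.null(cnv)) cnv_map <- cnv_map[names(cnv_map) %in% colnames(cnv)]
  if (!is.null(meth)) meth_map <- meth_map[names(meth_map) %in% colnames(meth)]
  cnv_map <- cnv_map[cnv_map %in% colnames(ge)]
  meth_map <- meth_map[meth_map %in% colnames(ge)]
  omics_dataset(ge, cnv, meth, cnv_map, meth_map)
}

#' Write an omics dataset back to delimited text
#'
#' Inverse of [read_omics()]: writes `ge.tsv`, `cnv.tsv`, `meth.tsv` and
#' `map.tsv` into `dir`.
#'
#' @param ds an `omics_dataset`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
write_omics <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wrt <- function(mat, path) {
    df <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- c(wrt(ds$ge, file.path(dir, "ge.tsv")))
  if (ncol(ds$cnv)) paths <- c(paths, wrt(ds$cnv, file.path(dir, "cnv.tsv")))
  if (ncol(ds$meth)) paths <- c(paths, wrt(ds$meth, file.path(dir, "meth.tsv")))
  map <- rbind(
    if (length(ds$cnv_map)) data.frame(feature_id = names(ds$cnv_map),
                                       feature_type = "CNV", gene_symbol = unname(ds$cnv_map)),
    if (length(ds$meth_map)) data.frame(feature_id = names(ds$meth_map),
                                        feature_type = "METH", gene_symbol = unname(ds$meth_map)))
  if (!is.null(map)) {
    utils::write.table(map, file.path(dir, "map.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, file.path(dir, "map.tsv"))
  }
  invisible(paths)
}

#' Ordered quantile (rank-based inverse normal) transform
#'
#' Maps a vector to normal scores: `qnorm((rank - 0.5) / n)` with average
#' ranks on ties. Used to bring methylation beta-values to an approximately
#' Gaussian scale before regression and network scoring.
#'
#' @param values numeric vector, length >= 2, finite, not all identical.
#' @return numeric vector of normal scores (monotone in the input, mean ~ 0).
#' @export
orq_transform <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  if (!all(is.finite(values))) stop("values must be finite")
  if (length(unique(values)) == 1L)
    stop("all values identical; ordered quantile transform undefined")
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 0.5) / length(values))
}

#' Select methylation probes associated with their gene's expression
#'
#' For each METH probe mapped to a gene with a GE column, fits the simple
#' linear regression of the gene's expression on the (ordered-quantile
#' transformed) probe values and reports the slope p-value and R-squared.
#' A probe is selected when `p < p_threshold` and `R^2 > r2_threshold`;
#' only selected probes become METH nodes of the network.
#'
#' @param ds an `omics_dataset` with at least 3 samples.
#' @param p_threshold significance level for the slope (default 0.05).
#' @param r2_threshold minimum R-squared (default 0.3).
#' @param transform apply [orq_transform()] to the probe first (default TRUE).
#' @return data.frame with columns `probe`, `gene`, `p_value`, `r2`, `selected`.
#' @export
screen_meth_probes <- function(ds, p_threshold = 0.05, r2_threshold = 0.3,
                               transform = TRUE) {
  if (nrow(ds$ge) < 3L) stop("need at least 3 samples for probe screening")
  probes <- colnames(ds$meth)
  out <- vector("list", length(probes))
  n <- nrow(ds$ge)
  for (k in seq_along(probes)) {
    pr <- probes[k]
    gene <- unname(ds$meth_map[pr])
    if (is.null(gene) || is.na(gene) || !gene %in% colnames(ds$ge)) {
      warning(sprintf("probe '%s' maps to no GE gene; skipped", pr))
      next
    }
    x <- ds$meth[, pr]
    if (transform) x <- orq_transform(x)
    y <- ds$ge[, gene]
    r <- stats::cor(x, y)
    r2 <- r * r
    # slope t-test of the simple regression, via the correlation
    if (r2 >= 1) {
      p <- 0
    } else {
      tval <- r * sqrt((n - 2) / (1 - r2))
      p <- 2 * stats::pt(-abs(tval), df = n - 2)
    }
    out[[k]] <- data.frame(probe = pr, gene = gene, p_value = p, r2 = r2,
                           selected = (p < p_threshold) && (r2 > r2_threshold))
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(probe = character(), gene = character(),
                      p_value = numeric(), r2 = numeric(), selected = logical())
  rownames(res) <- NULL
  res
}

#' Differential-methylation probe filter between two sample groups
#'
#' Per probe, a Welch two-sample test on mean beta-value plus an effect-size
#' filter: keep probes with `p < p_threshold` and `|delta beta| >= `
#' the `delta_quantile` quantile of all `|delta beta|` values, where
#' `delta beta = mean(case) - mean(control)`.
#'
#' @param meth_case,meth_control beta-value matrices (samples x probes) with
#'   identical probe columns; each group needs >= 2 samples.
#' @param delta_quantile quantile of `|delta beta|` used as the effect cut-off
#'   (default 0.75).
#' @param p_threshold significance level (default 0.05).
#' @return data.frame with `probe`, `p_value`, `delta_beta`, `selected`.
#' @export
dm_probe_filter <- function(meth_case, meth_control, delta_quantile = 0.75,
                            p_threshold = 0.05) {
  if (nrow(meth_case) < 2L || nrow(meth_control) < 2L)
    stop("each group needs at least 2 samples")
  if (!identical(colnames(meth_case), colnames(meth_control)))
    stop("the two groups must share the same probes in the same order")
  n1 <- nrow(meth_case); n2 <- nrow(meth_control)
  m1 <- colMeans(meth_case); m2 <- colMeans(meth_control)
  v1 <- apply(meth_case, 2, stats::var); v2 <- apply(meth_control, 2, stats::var)
  delta <- m1 - m2
  se2 <- v1 / n1 + v2 / n2
  p <- ifelse(se2 == 0, ifelse(delta == 0, 1, 0), NA_real_)
  ok <- se2 > 0
  if (any(ok)) {
    tval <- delta[ok] / sqrt(se2[ok])
    df <- se2[ok]^2 / ((v1[ok] / n1)^2 / (n1 - 1) + (v2[ok] / n2)^2 / (n2 - 1))
    p[ok] <- 2 * stats::pt(-abs(tval), df = df)
  }
  cut <- stats::quantile(abs(delta), delta_quantile, names = FALSE)
  data.frame(probe = colnames(meth_case), p_value = unname(p),
             delta_beta = unname(delta),
             selected = unname(p < p_threshold & abs(delta) >= cut))
}
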