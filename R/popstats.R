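#' Allele frequency from genotype counts
#'
#' Two estimators are provided because published reports use both. The
#' `standard` estimator counts mutant allele copies,
#' `(2 n_hom + n_het) / (2 n_total)`. The `printed` mode follows the
#' Hardy--Weinberg screening formula exactly as it is usually typeset,
#' `F = (2 ObsAa + Obsaa) / [2 (ObsAA + ObsAa + Obsaa)]`, i.e. with the
#' heterozygote count doubled; the two coincide when
#' `n_het == n_hom`. Full precision is returned; display rounding is
#' left to [format_frequency()].
#'
#' @param n_het heterozygous carriers.
#' @param n_hom homozygous carriers.
#' @param n_total genotyped samples.
#' @param mode `"standard"` (default) or `"printed"`.
#' @return frequency in `[0, 1]`.
#' @examples
#' allele_frequency(9, 9, 41)                    # 27/82
#' allele_frequency(8, 6, 41, mode = "printed")  # 22/82
#' @export
allele_frequency <- function(n_het, n_hom, n_total,
                             mode = c("standard", "printed")) {
  mode <- match.arg(mode)
  if (n_total < 1L)
    cry_error("n_total must be >= 1", "cryscreen_parameter_error")
  if (n_het < 0 || n_hom < 0 || n_het + n_hom > n_total)
    cry_error("genotype counts exceed the total",
              "cryscreen_consistency_error")
  switch(mode,
         standard = (2 * n_hom + n_het) / (2 * n_total),
         printed = (2 * n_het + n_hom) / (2 * n_total))
}

#' Genotype concordance between two calling methods
#'
#' @param calls_a,calls_b character vectors of calls, aligned by
#'   sample; when both are named the names must agree (an alignment
#'   error is raised otherwise).
#' @param sample_ids optional sample labels for the discrepancy list.
#' @return list of class `concordance`: `n_concordant`, `n_total`,
#'   `rate`, `discrepancies` (data.frame `sample_id`, `call_a`,
#'   `call_b`).
#' @export
concordance <- function(calls_a, calls_b, sample_ids = NULL) {
  if (length(calls_a) != length(calls_b))
    cry_error("call lists differ in length", "cryscreen_alignment_error")
  if (!is.null(names(calls_a)) && !is.null(names(calls_b))) {
    if (!identical(names(calls_a), names(calls_b))) {
      if (!setequal(names(calls_a), names(calls_b)))
        cry_error("sample ids do not match", "cryscreen_alignment_error")
      calls_b <- calls_b[names(calls_a)]
    }
    if (is.null(sample_ids)) sample_ids <- names(calls_a)
  }
  if (is.null(sample_ids)) sample_ids <- seq_along(calls_a)
  agree <- calls_a == calls_b
  structure(list(
    n_concordant = sum(agree), n_total = length(agree),
    rate = sum(agree) / length(agree),
    discrepancies = data.frame(sample_id = sample_ids[!agree],
                               call_a = unname(calls_a[!agree]),
                               call_b = unname(calls_b[!agree]),
                               stringsAsFactors = FALSE)),
    class = "concordance")
}

#' @exportS3Method base::print
print.concordance <- function(x, ...) {
  cat(sprintf("<concordance> %d/%d = %d%%\n", x$n_concordant, x$n_total,
              round(100 * x$rate)))
  invisible(x)
}

#' Per-location carrier summary for one genotyping method
#'
#' Carriers are `Sr` or `rr` calls. Percentages are of each location's
#' sample count, rounded to the nearest integer for display; the raw
#' fractions are retained alongside.
#'
#' @param table a cohort table: data.frame with `sample_id`,
#'   `location`, `method`, `call` (long format, as returned by
#'   [cohort_table()]).
#' @param method which method's calls to summarise.
#' @return data.frame per location: `n`, `pct_carriers`, `pct_hom`,
#'   `pct_het` (integer display values) and `frac_carriers`,
#'   `frac_hom`, `frac_het`.
#' @export
carrier_summary <- function(table, method) {
  if (!nrow(table))
    cry_error("cohort table is empty", "cryscreen_parameter_error")
  if (!method %in% table$method)
    cry_error(sprintf("unknown method '%s'", method),
              "cryscreen_lookup_error")
  tab <- table[table$method == method, , drop = FALSE]
  locs <- unique(tab$location)
  rows <- lapply(locs, function(l) {
    calls <- tab$call[tab$location == l]
    n <- length(calls)
    f_hom <- sum(calls == "rr") / n
    f_het <- sum(calls == "Sr") / n
    data.frame(location = l, n = n,
               pct_carriers = as.integer(round(100 * (f_hom + f_het))),
               pct_hom = as.integer(round(100 * f_hom)),
               pct_het = as.integer(round(100 * f_het)),
               frac_carriers = f_hom + f_het, frac_hom = f_hom,
               frac_het = f_het, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assemble a long-format cohort table from per-method calls
#'
#' @param calls named list of call vectors (method -> named character
#'   vector of sample calls) or a wide data.frame with `sample_id`,
#'   `location` and one column per method.
#' @param locations named character vector sample_id -> location
#'   (required for the list form).
#' @return data.frame `sample_id`, `location`, `method`, `call`.
#' @export
cohort_table <- function(calls, locations = NULL) {
  if (is.data.frame(calls)) {
    methods <- setdiff(names(calls), c("sample_id", "location"))
    out <- do.call(rbind, lapply(methods, function(m)
      data.frame(sample_id = calls$sample_id, location = calls$location,
                 method = m, call = calls[[m]],
                 stringsAsFactors = FALSE)))
    return(out)
  }
  stopifnot(!is.null(names(calls)), !is.null(locations))
  do.call(rbind, lapply(names(calls), function(m) {
    v <- calls[[m]]
    data.frame(sample_id = names(v),
               location = unname(locations[names(v)]), method = m,
               call = unname(v), stringsAsFactors = FALSE)
  }))
}

#' Principal component analysis of a genotype matrix
#'
#' Sites (columns) are coded 0/1/2 mutant-allele doses with `NA` for
#' missing calls. Missing entries are mean-imputed per site, columns
#' are mean-centred, and projections are taken from the singular value
#' decomposition (no scaling).
#'
#' @param mat numeric matrix, samples x sites.
#' @param n_comp number of components to report (default
#'   `min(dim) - 1`).
#' @return list of class `genotype_pca`: `projections` (samples x
#'   components), `explained` (fraction of variance per component,
#'   non-increasing).
#' @export
genotype_pca <- function(mat, n_comp = NULL) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L || ncol(mat) < 1L)
    cry_error("need >= 2 samples and >= 1 site",
              "cryscreen_parameter_error")
  for (j in seq_len(ncol(mat))) {
    miss <- is.na(mat[, j])
    if (any(miss)) mat[miss, j] <- mean(mat[, j], na.rm = TRUE)
  }
  mat[is.na(mat)] <- 0  # sites with every call missing
  centred <- scale(mat, center = TRUE, scale = FALSE)
  if (all(abs(centred) < .Machine$double.eps^0.5))
    cry_error("genotype matrix has no variance",
              "cryscreen_degenerate_error")
  sv <- svd(centred)
  k <- if (is.null(n_comp)) min(dim(centred)) else min(n_comp, min(dim(centred)))
  proj <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  rownames(proj) <- rownames(mat)
  colnames(proj) <- paste0("PC", seq_len(k))
  structure(list(projections = proj,
                 explained = (sv$d^2 / sum(sv$d^2))[seq_len(k)]),
            class = "genotype_pca")
}

#' Per-site association scan against a binary label
#'
#' For each site, mutant and reference allele counts (2 x called
#' samples) are cross-tabulated against the label and tested with
#' Fisher's exact test (two-sided) — an exact choice suited to small
#' cohorts. Sites with missing calls are tested on the observed calls.
#'
#' @param mat numeric matrix, samples x sites, 0/1/2 doses with `NA`
#'   missing.
#' @param labels binary vector (two levels, both present).
#' @return data.frame sorted by site order: `site`, `p_value`,
#'   `neg_log10_p`.
#' @export
association_scan <- function(mat, labels) {
  mat <- as.matrix(mat)
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2L)
    cry_error("labels must contain exactly two classes",
              "cryscreen_parameter_error")
  if (length(labels) != nrow(mat))
    cry_error("labels must match the number of samples",
              "cryscreen_alignment_error")
  sites <- colnames(mat)
  if (is.null(sites)) sites <- as.character(seq_len(ncol(mat)))
  p <- vapply(seq_len(ncol(mat)), function(j) {
    g <- mat[, j]
    ok <- !is.na(g)
    if (!any(ok)) return(NA_real_)
    alt <- tapply(g[ok], labels[ok], sum)
    n2 <- tapply(rep(2, sum(ok)), labels[ok], sum)
    alt[is.na(alt)] <- 0; n2[is.na(n2)] <- 0
    tab <- rbind(alt = alt, ref = n2 - alt)
    if (any(dim(tab) != 2L) || any(colSums(tab) == 0)) return(NA_real_)
    fisher.test(tab)$p.value
  }, numeric(1))
  data.frame(site = sites, p_value = p, neg_log10_p = -log10(p),
             stringsAsFactors = FALSE)
}

#' Read a genotype matrix from TSV (samples x sites, 0/1/2, "." = NA)
#'
#' @param path TSV with a `sample_id` first column.
#' @return numeric matrix with sample rownames.
#' @export
read_genotype_matrix <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- d[[1L]]
  m <- as.matrix(d[, -1L, drop = FALSE])
  m[m == "."] <- NA
  storage.mode(m) <- "numeric"
  rownames(m) <- ids
  m
}
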