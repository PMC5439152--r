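# Accuracy evaluation: animal-wise and marker-wise Pearson correlations of
# true vs imputed allele dosages, ancestor-genotyping categories and
# minor-allele-frequency bins.  All reports are tibbles.

#' Minor-allele-frequency bin edges
#'
#' The standard bins: (0, 0.025], (0.025, 0.05], (0.05, 0.075],
#' (0.075, 0.10], then 0.05-wide bins up to 0.50.  Bins are half-open
#' `(lo, hi]` except the first, which is closed at 0.
#'
#' @return numeric vector of bin edges.
#' @export
maf_bin_edges <- function() {
  c(0, 0.025, 0.05, 0.075, 0.10, 0.15, 0.20, 0.25, 0.30, 0.35, 0.40, 0.45, 0.50)
}

maf_bin_label <- function(maf) {
  edges <- maf_bin_edges()
  idx <- findInterval(maf, edges, left.open = TRUE, rightmost.closed = TRUE)
  idx[maf <= edges[2]] <- 1L # first bin closed at 0
  idx[maf > 0.5] <- NA_integer_
  labs <- paste0("(", head(edges, -1), ",", edges[-1], "]")
  labs[1] <- paste0("[0,", edges[2], "]")
  factor(labs[idx], levels = labs)
}

#' Animal-wise imputation accuracy
#'
#' Pearson correlation between true and imputed allele dosages across markers
#' within each animal; animals whose true dosages have zero variance are
#' flagged and excluded from the mean.
#'
#' @param true_dosage n x M matrix of true dosages (or genotypes).
#' @param imputed_dosage n x M matrix of imputed dosages.
#' @param ids optional ids (default rownames).
#' @return tibble with columns `id`, `r`, `defined`; the mean over defined
#'   animals is attached as attribute `mean_r` and returned by
#'   [glance.accuracy_report()].
#' @export
animalwise_accuracy <- function(true_dosage, imputed_dosage, ids = NULL) {
  stopifnot(all(dim(true_dosage) == dim(imputed_dosage)))
  ids <- ids %||% rownames(true_dosage) %||% as.character(seq_len(nrow(true_dosage)))
  r <- vapply(seq_len(nrow(true_dosage)), function(i) {
    x <- true_dosage[i, ]
    y <- imputed_dosage[i, ]
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)
  }, numeric(1))
  out <- tibble::tibble(id = ids, r = r, defined = !is.na(r))
  out <- structure(out, mean_r = mean(r, na.rm = TRUE),
                   class = c("accuracy_report", class(out)))
  out
}

#' Marker-wise imputation accuracy with MAF bins
#'
#' Both vectors are standardized by the mean and standard deviation of the
#' true genotypes before the cross-product, so a naive imputation that
#' returns a constant (e.g. twice the allele frequency) scores exactly zero.
#' Markers monomorphic in truth are flagged undefined and excluded from bin
#' means.
#'
#' @param true_geno n x M matrix of true genotypes.
#' @param imputed_dosage n x M matrix of imputed dosages.
#' @return tibble with columns `marker`, `maf`, `maf_bin`, `r`, `defined`;
#'   attribute `mean_r` is the mean over defined markers.
#' @export
markerwise_accuracy <- function(true_geno, imputed_dosage) {
  stopifnot(all(dim(true_geno) == dim(imputed_dosage)))
  n <- nrow(true_geno)
  mu <- colMeans(true_geno)
  s <- apply(true_geno, 2, sd)
  maf <- pmin(mu / 2, 1 - mu / 2)
  r <- rep(NA_real_, ncol(true_geno))
  def <- s > 0
  if (any(def)) {
    zt <- sweep(sweep(true_geno[, def, drop = FALSE], 2, mu[def]), 2, s[def], "/")
    zi <- sweep(sweep(imputed_dosage[, def, drop = FALSE], 2, mu[def]), 2,
                s[def], "/")
    r[def] <- colSums(zt * zi) / (n - 1)
  }
  out <- tibble::tibble(marker = seq_len(ncol(true_geno)), maf = maf,
                        maf_bin = maf_bin_label(maf), r = r, defined = def)
  structure(out, mean_r = mean(r, na.rm = TRUE),
            class = c("accuracy_report", class(out)))
}

#' Mean marker-wise accuracy per MAF bin
#' @param marker_report output of [markerwise_accuracy()].
#' @return tibble with `maf_bin`, `n_markers`, `mean_r` (NA for empty bins).
#' @export
maf_bin_means <- function(marker_report) {
  marker_report |>
    dplyr::filter(.data$defined) |>
    dplyr::group_by(.data$maf_bin, .drop = FALSE) |>
    dplyr::summarise(n_markers = dplyr::n(),
                     mean_r = mean(.data$r), .groups = "drop")
}

#' Classify a test individual by its high-density-genotyped ancestors
#'
#' Categories, in precedence order: Both (both parents HD), SireMGS (sire and
#' maternal grandsire HD, dam not), DamPGS (dam and paternal grandsire HD,
#' sire not), Sire, Dam, Other.
#'
#' @param individual id or row index.
#' @param ped a [pedigree()].
#' @param hd_ids ids genotyped at high density.
#' @return character category label.
#' @export
classify_category <- function(individual, ped, hd_ids) {
  i <- if (is.character(individual)) match(individual, ped$id) else individual
  hd <- function(id) !is.na(id) && id %in% hd_ids
  sire <- ped$sire[i]
  dam <- ped$dam[i]
  mgs <- if (!is.na(dam)) ped$sire[match(dam, ped$id)] else NA_character_
  pgs <- if (!is.na(sire)) ped$sire[match(sire, ped$id)] else NA_character_
  if (hd(sire) && hd(dam)) return("Both")
  if (hd(sire) && hd(mgs) && !hd(dam)) return("SireMGS")
  if (hd(dam) && hd(pgs) && !hd(sire)) return("DamPGS")
  if (hd(sire)) return("Sire")
  if (hd(dam)) return("Dam")
  "Other"
}

#' Summarize accuracies by category and MAF bin
#'
#' @param animal_report output of [animalwise_accuracy()] with an added
#'   `category` column (see [classify_category()]), or without one.
#' @param marker_report optional output of [markerwise_accuracy()].
#' @param path optional path: writes the summary as a tab-separated table.
#' @return tibble with columns `group_type`, `group`, `n`, `mean_r`.
#' @export
summarize_accuracy <- function(animal_report, marker_report = NULL,
                               path = NULL) {
  rows <- list()
  ok <- dplyr::filter(animal_report, .data$defined)
  rows$overall <- tibble::tibble(group_type = "overall", group = "animalwise",
                                 n = nrow(ok), mean_r = mean(ok$r))
  if ("category" %in% names(animal_report)) {
    rows$cat <- ok |>
      dplyr::group_by(.data$category) |>
      dplyr::summarise(n = dplyr::n(), mean_r = mean(.data$r),
                       .groups = "drop") |>
      dplyr::transmute(group_type = "category", group = .data$category,
                       n = .data$n, mean_r = .data$mean_r)
  }
  if (!is.null(marker_report)) {
    rows$overall_m <- tibble::tibble(
      group_type = "overall", group = "markerwise",
      n = sum(marker_report$defined),
      mean_r = attr(marker_report, "mean_r"))
    rows$maf <- maf_bin_means(marker_report) |>
      dplyr::transmute(group_type = "maf_bin",
                       group = as.character(.data$maf_bin),
                       n = .data$n_markers,
                       mean_r = ifelse(.data$n_markers > 0, .data$mean_r,
                                       NA_real_))
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(path)) {
    utils::write.table(
      dplyr::mutate(out, mean_r = sprintf("%.6f", .data$mean_r)),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' @export
tidy.imputation_result <- function(x, ...) {
  n <- nrow(x$genotypes)
  M <- ncol(x$genotypes)
  tibble::tibble(
    id = rep(x$pedigree$id, each = M),
    marker = rep(seq_len(M), times = n),
    genotype = as.vector(t(x$genotypes)),
    dosage = as.vector(t(x$dosages)))
}

#' @export
glance.imputation_result <- function(x, ...) {
  tab <- table(factor(x$provenance, levels = c("observed", "heuristic", "hmm")))
  tibble::tibble(
    n_individuals = nrow(x$genotypes),
    n_markers = ncol(x$genotypes),
    training_mode = x$training_mode,
    frac_observed = as.vector(tab["observed"]) / sum(tab),
    frac_heuristic = as.vector(tab["heuristic"]) / sum(tab),
    frac_hmm = as.vector(tab["hmm"]) / sum(tab),
    mean_theta = mean(x$params$theta),
    mean_eps = mean(x$params$eps))
}

#' @export
glance.accuracy_report <- function(x, ...) {
  tibble::tibble(n = sum(x$defined), mean_r = attr(x, "mean_r"))
}

#' Plot an accuracy report
#'
#' Animal-wise reports plot the per-animal correlation distribution;
#' marker-wise reports plot mean accuracy per MAF bin.
#'
#' @param object an `accuracy_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.accuracy_report <- function(object, ...) {
  if ("maf_bin" %in% names(object)) {
    maf_bin_means(object) |>
      ggplot2::ggplot(ggplot2::aes(x = .data$maf_bin, y = .data$mean_r)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "minor allele frequency bin",
                    y = "mean marker-wise accuracy (r)") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  } else {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$r)) +
      ggplot2::geom_histogram(bins = 30) +
      ggplot2::labs(x = "animal-wise accuracy (r)", y = "animals") +
      ggplot2::theme_minimal()
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
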