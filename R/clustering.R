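#' Build a standardized feature matrix for profile clustering
#'
#' Features are either the per-participant glycemic-variability metric
#' vector (`mode = "gv_metrics"`), the deciles of each participant's glucose
#' distribution (`mode = "glucose_deciles"`, requires `cohort`), or both.
#' Participants with any undefined (NA) feature are dropped with a message;
#' zero-variance columns are dropped with a warning (they cannot be
#' standardized); remaining columns are z-standardized.
#'
#' @param metrics Per-participant metric table ([cohort_metrics()]).
#' @param mode `"gv_metrics"`, `"glucose_deciles"` or `"both"`.
#' @param cohort [cgm_cohort] supplying raw series for decile features.
#' @return A numeric matrix (rows = participants, rownames = IDs, columns
#'   standardized to mean 0, SD 1) with attribute `feature_names`.
#' @export
build_feature_matrix <- function(metrics,
                                 mode = c("gv_metrics", "glucose_deciles", "both"),
                                 cohort = NULL) {
  mode <- match.arg(mode)
  feats <- NULL
  if (mode %in% c("gv_metrics", "both")) {
    feats <- as.matrix(metrics[, gv_metric_names(), drop = FALSE])
    rownames(feats) <- metrics$participant_id
  }
  if (mode %in% c("glucose_deciles", "both")) {
    if (is.null(cohort)) stop("decile features require `cohort`", call. = FALSE)
    dec <- t(vapply(metrics$participant_id, function(id) {
      stats::quantile(cohort$series[[id]]$value, probs = seq(0.1, 0.9, 0.1),
                      type = 7)
    }, numeric(9)))
    colnames(dec) <- paste0("decile_", 1:9)
    rownames(dec) <- metrics$participant_id
    feats <- if (is.null(feats)) dec else cbind(feats, dec)
  }
  complete <- stats::complete.cases(feats)
  if (any(!complete)) {
    message("dropping ", sum(!complete), " participant(s) with undefined features")
    feats <- feats[complete, , drop = FALSE]
  }
  if (nrow(feats) < 3) stop("need at least 3 participants to cluster", call. = FALSE)
  sds <- apply(feats, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(feats)[sds == 0], collapse = ", "))
    feats <- feats[, sds > 0, drop = FALSE]
  }
  if (ncol(feats) == 0) stop("no informative features remain", call. = FALSE)
  out <- scale(feats)
  attr(out, "feature_names") <- colnames(out)
  out
}

#' Agglomerative clustering of glucose profiles
#'
#' Hierarchical agglomerative clustering with Ward linkage (`ward.D2`) on
#' Euclidean distances, cut at `k` clusters. Deterministic for a fixed
#' feature matrix.
#'
#' @param features Standardized feature matrix ([build_feature_matrix()]).
#' @param k Number of clusters, `2 <= k < n`.
#' @return Integer cluster labels, one per row of `features`.
#' @export
agglomerate <- function(features, k) {
  n <- nrow(features)
  if (k < 2 || k >= n) stop("k must satisfy 2 <= k < n", call. = FALSE)
  hc <- stats::hclust(stats::dist(features), method = "ward.D2")
  stats::cutree(hc, k = k)
}

#' Assess whether distinct glucose-profile clusters exist
#'
#' Cuts the Ward dendrogram at each `k` in `k_range`, computes the mean
#' silhouette width per cut, and declares clusters distinct when the best
#' silhouette reaches `silhouette_threshold` (0.25 is the conventional
#' weak-structure cutoff). Degenerate inputs (all pairwise distances zero)
#' yield `distinct = FALSE` with `degenerate = TRUE`.
#'
#' @param features Standardized feature matrix.
#' @param k_range Candidate cluster counts (default 2:8), clipped to `n - 1`.
#' @param silhouette_threshold Minimum mean silhouette for "distinct".
#' @return An object of class `cluster_assessment`: list with `k_range`,
#'   `silhouette` (per k), `labels` (list per k), `chosen_k`,
#'   `max_silhouette`, `distinct`, `degenerate`.
#' @export
assess_clusters <- function(features, k_range = 2:8,
                            silhouette_threshold = 0.25) {
  n <- nrow(features)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (length(k_range) == 0) {
    stop("no valid k in range for n = ", n, call. = FALSE)
  }
  d <- stats::dist(features)
  degenerate <- max(d) == 0
  hc <- if (!degenerate) stats::hclust(d, method = "ward.D2") else NULL
  sil <- rep(NA_real_, length(k_range))
  labels <- vector("list", length(k_range))
  names(labels) <- as.character(k_range)
  for (i in seq_along(k_range)) {
    if (degenerate) {
      labels[[i]] <- rep(1L, n)
      next
    }
    lab <- stats::cutree(hc, k = k_range[i])
    labels[[i]] <- lab
    sw <- cluster::silhouette(lab, d)
    sil[i] <- if (is.matrix(sw)) mean(sw[, "sil_width"]) else NA_real_
  }
  if (all(is.na(sil))) {
    chosen_k <- NA_integer_
    max_sil <- NA_real_
    distinct <- FALSE
  } else {
    best <- which.max(sil)
    chosen_k <- k_range[best]
    max_sil <- sil[best]
    distinct <- max_sil >= silhouette_threshold
  }
  structure(list(k_range = k_range, silhouette = sil, labels = labels,
                 chosen_k = chosen_k, max_silhouette = max_sil,
                 distinct = distinct, degenerate = degenerate,
                 threshold = silhouette_threshold),
            class = "cluster_assessment")
}

#' @export
print.cluster_assessment <- function(x, ...) {
  cat("<cluster_assessment>\n")
  if (x$degenerate) cat("  degenerate input (all profiles identical)\n")
  for (i in seq_along(x$k_range)) {
    cat(sprintf("  k = %d: mean silhouette %s\n", x$k_range[i],
                ifelse(is.na(x$silhouette[i]), "NA",
                       sprintf("%.3f", x$silhouette[i]))))
  }
  cat(sprintf("  distinct clusters: %s (max silhouette %s at k = %s, threshold %.2f)\n",
              x$distinct,
              ifelse(is.na(x$max_silhouette), "NA", sprintf("%.3f", x$max_silhouette)),
              ifelse(is.na(x$chosen_k), "NA", x$chosen_k), x$threshold))
  invisible(x)
}
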