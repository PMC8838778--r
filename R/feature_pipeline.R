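## Assembly of the 42-feature table and the prescreening chain:
## correlation filter -> PCA-based feature selection -> SMOTE balancing.

#' Canonical names of the 42 features
#'
#' Order: gender, the three spirometer-like features, then the 38
#' time-frequency features.
#'
#' @return Character vector of length 42.
#' @export
feature_names <- function() {
  c("gender", "total_dec", "total_dec_1st_sec", "max_peak",
    tf_feature_names())
}

#' Assemble the feature table of a corpus
#'
#' For each record the signal is resampled to the canonical 44,100 Hz,
#' peak-normalised, validated, and the 42 features are computed. Records
#' failing validation are excluded and listed in the `excluded` attribute.
#'
#' @param samples A `blow_corpus` or list of records, each a list with
#'   fields `signal` ([audio_signal()]), `age`, `gender` and optionally
#'   `sample_id`.
#' @param cwd_cfg A [cwd_config()] for the time-frequency features.
#' @param n_fft,hop,floor_db STFT parameters for the spirometer-like
#'   features.
#' @param min_s,max_s,clip_thresh Validation bounds, see
#'   [validate_exhalation()].
#' @return A `feature_table` data frame: `sample_id`, the 42 feature
#'   columns, and `age`. Attribute `excluded` records rejected samples.
#' @export
assemble_features <- function(samples, cwd_cfg = cwd_config(),
                              n_fft = 2048L, hop = 512L, floor_db = 80,
                              min_s = 2, max_s = 15, clip_thresh = 0.01) {
  if (length(samples) == 0) stop("empty input: no samples to assemble")
  rows <- vector("list", length(samples))
  excluded <- list()
  for (i in seq_along(samples)) {
    rec <- samples[[i]]
    if (is.null(rec$sample_id)) rec$sample_id <- sprintf("s%04d", i)
    one <- features_one(rec, cwd_cfg = cwd_cfg, n_fft = n_fft, hop = hop,
                        floor_db = floor_db, min_s = min_s, max_s = max_s,
                        clip_thresh = clip_thresh)
    if (is.null(one$row)) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(sample_id = rec$sample_id, reason = one$reason)
    } else {
      rows[[i]] <- one$row
    }
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) stop("every sample failed validation")
  tbl <- do.call(rbind, rows)
  rownames(tbl) <- NULL
  stopifnot(identical(setdiff(names(tbl), c("sample_id", "age")),
                      feature_names()))
  attr(tbl, "excluded") <- if (length(excluded))
    do.call(rbind, excluded) else data.frame(sample_id = character(),
                                             reason = character())
  class(tbl) <- c("feature_table", "data.frame")
  tbl
}

feature_columns <- function(table) {
  setdiff(names(table), c("sample_id", "age"))
}

## Validate one record and compute its feature row (or an exclusion reason).
features_one <- function(rec, cwd_cfg = cwd_config(), n_fft = 2048L,
                         hop = 512L, floor_db = 80, min_s = 2, max_s = 15,
                         clip_thresh = 0.01) {
  sig <- resample_audio(rec$signal, 44100)
  rep <- validate_exhalation(sig, min_s, max_s, clip_thresh)
  if (!rep$ok)
    return(list(row = NULL, reason = paste(rep$messages, collapse = "; ")))
  sig <- normalize_peak(sig)
  sp <- spiro_features(sig, n_fft = n_fft, hop = hop, floor_db = floor_db)
  tf <- extract_tf_features(sig, cfg = cwd_cfg)
  list(row = data.frame(sample_id = rec$sample_id, gender = rec$gender,
                        t(sp), t(tf), age = rec$age),
       reason = NULL)
}

#' Write / read a feature table as CSV
#'
#' Fixed header: `sample_id`, the 42 canonical feature names, `age`;
#' comma-separated, `.` decimal, UTF-8.
#'
#' @param table A `feature_table`.
#' @param path CSV path.
#' @return `path` (write) or the `feature_table` (read).
#' @export
write_feature_table <- function(table, path) {
  write.csv(as.data.frame(table)[, c("sample_id", feature_names(), "age")],
            path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tbl <- read.csv(path, fileEncoding = "UTF-8")
  missing <- setdiff(c("sample_id", feature_names(), "age"), names(tbl))
  if (length(missing))
    stop("feature CSV is missing column(s): ", paste(missing, collapse = ", "))
  class(tbl) <- c("feature_table", "data.frame")
  tbl
}

#' Drop highly correlated features
#'
#' Computes pairwise Pearson correlations between feature columns and, for
#' every pair with `|r|` above the threshold, drops the later feature in
#' canonical column order. `gender` (the first feature column) is never
#' dropped. Constant columns have undefined correlation; they are treated
#' as `|r| = 0` with a warning.
#'
#' @param table A `feature_table` (>= 3 rows).
#' @param threshold Correlation threshold in (0, 1), default 0.9.
#' @return List with `table` (filtered) and `dropped` (character vector).
#' @export
correlation_filter <- function(table, threshold = 0.9) {
  if (nrow(table) < 3) stop("need at least 3 rows to estimate correlations")
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0, 1)")
  cols <- feature_columns(table)
  X <- as.matrix(table[, cols, drop = FALSE])
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    warning("constant feature column(s) treated as uncorrelated: ",
            paste(cols[sds == 0], collapse = ", "))
  suppressWarnings(r <- abs(cor(X)))
  r[is.na(r)] <- 0
  drop <- logical(length(cols))
  for (j in seq_along(cols)[-1]) {
    for (i in seq_len(j - 1L)) {
      if (!drop[i] && r[i, j] > threshold) { drop[j] <- TRUE; break }
    }
  }
  drop[cols == "gender"] <- FALSE
  dropped <- cols[drop]
  out <- table[, c("sample_id"[("sample_id" %in% names(table))],
                   setdiff(cols, dropped),
                   "age"[("age" %in% names(table))]), drop = FALSE]
  class(out) <- class(table)
  list(table = out, dropped = dropped)
}

#' PCA-based feature selection
#'
#' Standardises the feature columns, fits a PCA, keeps the leading
#' components whose cumulative explained-variance ratio reaches
#' `evr_target`, scores each original feature by
#' `sum_c EVR_c * loading[c, feature]^2` over those components, and keeps
#' the smallest prefix of features (in decreasing score order) whose
#' cumulative score reaches `evr_target` of the total score. `gender` is
#' always kept. This realises the reported end point of the reduction — a
#' named subset of original features — rather than projected components.
#'
#' @param table A `feature_table`.
#' @param evr_target Explained-variance target in (0, 1], default 0.999.
#' @return List with `table` (selected columns, original order), `kept`
#'   (names in decreasing score order) and `report` (`evr_cum`, `n_components`,
#'   `scores`).
#' @export
pca_select <- function(table, evr_target = 0.999) {
  cols <- feature_columns(table)
  X <- as.matrix(table[, cols, drop = FALSE])
  if (nrow(X) < length(cols) + 1L)
    warning("fewer rows than features + 1; PCA restricted to available rank")
  sds <- apply(X, 2, sd)
  mus <- colMeans(X)
  Z <- sweep(X, 2, mus)
  ok <- sds > 0
  Z[, ok] <- sweep(Z[, ok, drop = FALSE], 2, sds[ok], "/")
  Z[, !ok] <- 0 # zero-variance features carry no loading
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  ncomp <- if (evr_target >= 1) length(evr) else
    which(cumsum(evr) >= evr_target)[1]
  load2 <- pc$rotation[, seq_len(ncomp), drop = FALSE]^2
  scores <- as.numeric(load2 %*% evr[seq_len(ncomp)])
  names(scores) <- cols
  ord <- order(scores, decreasing = TRUE)
  if (evr_target >= 1) {
    kept <- cols[ord]
  } else {
    cum <- cumsum(scores[ord]) / sum(scores)
    n_keep <- which(cum >= evr_target)[1]
    kept <- cols[ord][seq_len(n_keep)]
  }
  if (!"gender" %in% kept && "gender" %in% cols) kept <- c(kept, "gender")
  keep_cols <- cols[cols %in% kept]
  out <- table[, c("sample_id"[("sample_id" %in% names(table))], keep_cols,
                   "age"[("age" %in% names(table))]), drop = FALSE]
  class(out) <- class(table)
  list(table = out, kept = kept,
       report = list(evr_cum = cumsum(evr), n_components = ncomp,
                     scores = sort(scores, decreasing = TRUE)))
}

#' SMOTE class balancing
#'
#' Synthetic Minority Oversampling: every minority class is augmented with
#' rows interpolated between a real member and one of its `k` nearest
#' same-class neighbours (`s = u + lambda * (v - u)`, `lambda ~ U(0, 1)`)
#' until all classes match the majority count. Deterministic given `seed`.
#'
#' @param table A `feature_table` (or any data frame of numeric feature
#'   columns plus optional `sample_id`/`age`).
#' @param labels Class label per row.
#' @param k Number of nearest neighbours considered (reduced when a class
#'   is smaller than `k + 1`).
#' @param seed Integer seed.
#' @return List with `table` (original plus synthetic rows), `labels`
#'   (extended), `synthetic` (logical flag per row), `added` (named count
#'   per class) and `provenance` (data frame: base row, neighbour row,
#'   lambda for each synthetic row).
#' @export
smote_balance <- function(table, labels, k = 5L, seed = 1L) {
  if (k < 1) stop("`k` must be at least 1")
  labels <- as.character(labels)
  counts <- base::table(labels)
  if (any(counts < 2))
    stop("cannot interpolate singleton class(es): ",
         paste(names(counts)[counts < 2], collapse = ", "))
  cols <- feature_columns(table)
  X <- as.matrix(table[, cols, drop = FALSE])
  target <- max(counts)
  new_rows <- list(); new_labels <- character(); prov <- list()
  with_seed(seed, {
    for (cls in sort(names(counts))) {
      need <- target - counts[[cls]]
      if (need == 0) next
      idx <- which(labels == cls)
      D <- as.matrix(dist(X[idx, , drop = FALSE]))
      diag(D) <- Inf
      k_eff <- min(k, length(idx) - 1L)
      nn <- apply(D, 1, function(d) order(d)[seq_len(k_eff)],
                  simplify = FALSE)
      if (is.matrix(nn)) nn <- asplit(nn, 2)
      base_seq <- rep(seq_along(idx), length.out = need)
      for (j in seq_len(need)) {
        b <- base_seq[j]
        v <- nn[[b]][sample.int(k_eff, 1L)]
        lam <- runif(1)
        s <- X[idx[b], ] + lam * (X[idx[v], ] - X[idx[b], ])
        new_rows[[length(new_rows) + 1L]] <- s
        new_labels <- c(new_labels, cls)
        prov[[length(prov) + 1L]] <-
          data.frame(base = idx[b], neighbour = idx[v], lambda = lam,
                     class = cls)
      }
    }
  })
  added <- base::table(factor(new_labels, levels = sort(names(counts))))
  if (length(new_rows) == 0) {
    return(list(table = table, labels = labels,
                synthetic = rep(FALSE, nrow(table)),
                added = added, provenance = NULL))
  }
  syn <- as.data.frame(do.call(rbind, new_rows))
  names(syn) <- cols
  if ("sample_id" %in% names(table))
    syn$sample_id <- sprintf("syn_%s_%03d", new_labels,
                             seq_along(new_labels))
  if ("age" %in% names(table)) syn$age <- NA_real_
  out <- rbind(as.data.frame(table)[, names(table), drop = FALSE],
               syn[, names(table), drop = FALSE])
  rownames(out) <- NULL
  class(out) <- class(table)
  list(table = out, labels = c(labels, new_labels),
       synthetic = c(rep(FALSE, nrow(table)), rep(TRUE, length(new_labels))),
       added = added, provenance = do.call(rbind, prov))
}

#' Run the prescreening chain
#'
#' Correlation filter followed by PCA-based selection (SMOTE is applied
#' later, inside cross-validation folds, unless the evaluation is run in
#' corpus-level balancing mode). Age labels are never consulted.
#'
#' @param table A `feature_table`.
#' @param cor_threshold Correlation threshold, see [correlation_filter()].
#' @param evr_target Explained-variance target, see [pca_select()].
#' @return List with `table` and a `report` (`dropped_by_correlation`,
#'   `pca_kept`, `evr_cum`).
#' @export
prescreen <- function(table, cor_threshold = 0.9, evr_target = 0.999) {
  cf <- correlation_filter(table, cor_threshold)
  ps <- pca_select(cf$table, evr_target)
  list(table = ps$table,
       report = structure(list(dropped_by_correlation = cf$dropped,
                               pca_kept = ps$kept,
                               evr_cum = ps$report$evr_cum),
                          class = "prescreen_report"))
}

#' @export
print.prescreen_report <- function(x, ...) {
  cat("Prescreening report\n")
  cat("  dropped by correlation:",
      if (length(x$dropped_by_correlation))
        paste(x$dropped_by_correlation, collapse = ", ") else "(none)", "\n")
  cat("  kept after PCA selection:", length(x$pca_kept), "features\n")
  invisible(x)
}
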