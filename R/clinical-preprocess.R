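#' KNN imputation of a clinical table
#'
#' Continuous cells are filled with the mean of the k nearest rows, where
#' distance is Euclidean over the standardized, mutually observed continuous
#' features (standardized by this table's observed mean/sd; distance ties are
#' broken by row order). Categorical (ordinal/nominal) cells are filled with
#' the column mode. Observed cells are never changed, so the operation is
#' idempotent.
#'
#' @param table a \code{\linkS4class{ClinicalTable}}.
#' @param k neighbour count (default 5).
#' @return the table with no remaining missing cells.
#' @export
imputeTable <- function(table, k = 5L) {
  stopifnot(is(table, "ClinicalTable"), k >= 1L)
  df <- table@values
  kinds <- table@kinds
  cont <- names(kinds)[kinds == "continuous"]
  allMissing <- names(df)[vapply(df, function(v) all(is.na(v)), logical(1))]
  if (length(allMissing))
    stopf("feature(s) missing in every row: %s",
          paste(allMissing, collapse = ", "))

  # Standardized continuous matrix for the distance metric (NA preserved).
  Z <- NULL
  if (length(cont)) {
    Z <- sapply(cont, function(f) {
      v <- df[[f]]
      mu <- mean(v, na.rm = TRUE)
      s <- sd(v, na.rm = TRUE)
      if (!is.finite(s) || s == 0) s <- 1
      (v - mu) / s
    })
    Z <- matrix(Z, nrow = nrow(df), dimnames = list(NULL, cont))
  }

  for (f in cont) {
    miss <- which(is.na(df[[f]]))
    if (!length(miss)) next
    donors <- which(!is.na(df[[f]]))
    for (i in miss) {
      shared <- !is.na(Z[i, ])
      d <- vapply(donors, function(j) {
        both <- shared & !is.na(Z[j, ])
        if (!any(both)) return(Inf)
        sqrt(sum((Z[i, both] - Z[j, both])^2))
      }, numeric(1))
      ord <- order(d, donors)  # ties broken by row order
      nn <- donors[ord][seq_len(min(k, length(donors)))]
      df[i, f] <- mean(df[[f]][nn])
    }
  }

  for (f in names(kinds)[kinds != "continuous"]) {
    miss <- which(is.na(df[[f]]))
    if (!length(miss)) next
    obs <- df[[f]][!is.na(df[[f]])]
    tab <- table(obs)
    mode <- names(tab)[which.max(tab)]
    df[miss, f] <- mode
  }

  new("ClinicalTable", values = df, kinds = kinds,
      levelsList = table@levelsList, subjectIds = table@subjectIds)
}

#' Flag and winsorize outlier rows with an isolation forest
#'
#' Anomaly scores are computed over the continuous features of an already
#' imputed table; the top \code{contamination} fraction of rows is flagged
#' and winsorized to the 1st/99th percentile per continuous feature (rows are
#' handled, not dropped, so n is preserved).
#'
#' @param table an imputed \code{\linkS4class{ClinicalTable}}.
#' @param contamination flagged fraction, in [0, 0.5).
#' @param seed RNG seed for the forest.
#' @return list with \code{flags} (logical per row) and \code{table}
#'   (winsorized copy).
#' @export
flagOutliers <- function(table, contamination = 0.05, seed = 1L) {
  stopifnot(is(table, "ClinicalTable"))
  if (contamination >= 0.5 || contamination < 0)
    stopf("contamination must lie in [0, 0.5)")
  df <- table@values
  cont <- names(table@kinds)[table@kinds == "continuous"]
  n <- nrow(df)
  flags <- rep(FALSE, n)
  nFlag <- floor(contamination * n)
  if (nFlag > 0 && length(cont)) {
    X <- as.matrix(df[cont])
    if (anyNA(X)) stopf("flagOutliers requires an imputed table")
    sc <- isolationScores(X, seed = seed)
    flags[order(sc, decreasing = TRUE)[seq_len(nFlag)]] <- TRUE
    lo <- apply(X, 2, quantile, probs = 0.01)
    hi <- apply(X, 2, quantile, probs = 0.99)
    for (j in seq_along(cont)) {
      v <- df[[cont[j]]]
      v[flags] <- pmin(pmax(v[flags], lo[j]), hi[j])
      df[[cont[j]]] <- v
    }
  }
  list(flags = flags,
       table = new("ClinicalTable", values = df, kinds = table@kinds,
                   levelsList = table@levelsList,
                   subjectIds = table@subjectIds))
}

#' Fit preprocessing state on training rows
#'
#' Learns per-feature min/max for min-max scaling of continuous features,
#' deterministic rank ranges for ordinal features (from their declared level
#' ordering), and category vocabularies for nominal features. Nothing outside
#' the supplied (training) table is read, which is what makes downstream
#' application leakage-free.
#'
#' @param table the training \code{\linkS4class{ClinicalTable}} (imputed).
#' @param k KNN imputation neighbour count carried in the state.
#' @param contamination isolation-forest contamination carried in the state.
#' @return a \code{\linkS4class{PreprocessState}}.
#' @export
fitPreprocess <- function(table, k = 5L, contamination = 0.05) {
  stopifnot(is(table, "ClinicalTable"))
  df <- table@values
  kinds <- table@kinds
  mins <- maxs <- means <- sds <- setNames(
    rep(NA_real_, length(kinds)), names(kinds))
  vocab <- list()
  ordLevels <- list()
  for (f in names(kinds)) {
    if (kinds[f] == "continuous") {
      v <- df[[f]]
      mins[f] <- min(v, na.rm = TRUE)
      maxs[f] <- max(v, na.rm = TRUE)
      means[f] <- mean(v, na.rm = TRUE)
      sds[f] <- sd(v, na.rm = TRUE)
    } else if (kinds[f] == "ordinal") {
      lv <- table@levelsList[[f]]
      ordLevels[[f]] <- lv
      mins[f] <- 0
      maxs[f] <- length(lv) - 1
    } else {
      vocab[[f]] <- sort(unique(as.character(df[[f]][!is.na(df[[f]])])))
    }
  }
  new("PreprocessState", mins = mins, maxs = maxs, means = means,
      sds = sds, vocab = vocab, ordinalLevels = ordLevels, kinds = kinds,
      k = as.integer(k), contamination = contamination, fitted = TRUE)
}

#' Scale and encode a clinical table with a fitted state
#'
#' Continuous features map to [0, 1] via training min/max (out-of-range
#' values clamp; constant training features map to 0). Ordinal features map
#' to integer ranks in their declared level order, then min-max scale.
#' Nominal features expand one-hot with an explicit unknown-category column.
#' Column order is deterministic (original feature order, categories in
#' vocabulary order).
#'
#' @param table an imputed \code{\linkS4class{ClinicalTable}}.
#' @param state a fitted \code{\linkS4class{PreprocessState}}.
#' @return numeric matrix, one row per subject.
#' @export
scaleAndEncode <- function(table, state) {
  stopifnot(is(table, "ClinicalTable"), is(state, "PreprocessState"))
  if (!isTRUE(state@fitted)) stopf("preprocess state is not fitted")
  df <- table@values
  cols <- list()
  for (f in names(state@kinds)) {
    kind <- state@kinds[f]
    if (!f %in% names(df)) stopf("feature '%s' absent from table", f)
    if (kind == "continuous") {
      rng <- state@maxs[f] - state@mins[f]
      v <- if (rng == 0) rep(0, nrow(df))
           else pmin(pmax((df[[f]] - state@mins[f]) / rng, 0), 1)
      cols[[f]] <- v
    } else if (kind == "ordinal") {
      lv <- state@ordinalLevels[[f]]
      r <- match(as.character(df[[f]]), lv) - 1
      if (anyNA(r)) stopf("unknown ordinal level in feature '%s'", f)
      rng <- state@maxs[f] - state@mins[f]
      cols[[f]] <- if (rng == 0) rep(0, nrow(df)) else r / rng
    } else {
      lv <- state@vocab[[f]]
      x <- as.character(df[[f]])
      for (cat in lv)
        cols[[paste0(f, "=", cat)]] <- as.numeric(x == cat)
      cols[[paste0(f, "=__unknown__")]] <- as.numeric(!x %in% lv)
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- table@subjectIds
  out
}

#' Invert min-max scaling for continuous/ordinal columns
#'
#' @param mat matrix produced by \code{\link{scaleAndEncode}}.
#' @param state the fitted state used to produce it.
#' @return matrix of original-scale values for the invertible columns.
#' @export
inverseScale <- function(mat, state) {
  inv <- names(state@kinds)[state@kinds %in% c("continuous", "ordinal")]
  out <- sapply(inv, function(f) {
    rng <- state@maxs[f] - state@mins[f]
    mat[, f] * rng + state@mins[f]
  })
  matrix(out, nrow = nrow(mat), dimnames = list(rownames(mat), inv))
}

#' Default clause templates for record serialization
#'
#' Covers the five deployed clinical features. Each clause contains a
#' \code{\{value\}} placeholder.
#' @return named character vector feature -> clause template.
#' @export
defaultTemplate <- function() {
  c(UPDRS = "UPDRS total score is {value}.",
    Age = "Age is {value} years.",
    MoCA = "MoCA impairment score is {value}.",
    HY_stage = "Hoehn and Yahr stage is {value}.",
    Weight = "Weight is {value} kilograms.")
}

#' Serialize one clinical record to text for the encoder
#'
#' Deterministic natural-language rendering: one clause per template entry,
#' in template order. Identical records give identical strings.
#'
#' @param record named list or one-row data.frame of (imputed) feature values.
#' @param template named clause vector as in \code{\link{defaultTemplate}};
#'   empty template yields an empty string.
#' @return a single string.
#' @export
serializeRecord <- function(record, template = defaultTemplate()) {
  if (is.data.frame(record)) record <- as.list(record[1, , drop = FALSE])
  if (!length(template)) return("")
  absent <- setdiff(names(template), names(record))
  if (length(absent))
    stopf("template references absent feature(s): %s",
          paste(absent, collapse = ", "))
  clauses <- vapply(names(template), function(f) {
    v <- record[[f]]
    vs <- if (is.numeric(v)) format(round_half_up(v, 1), trim = TRUE,
                                    scientific = FALSE)
          else as.character(v)
    gsub("{value}", vs, template[[f]], fixed = TRUE)
  }, character(1))
  paste(clauses, collapse = " ")
}
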